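# Independent brute-force oracles used to validate the estimators.
# These deliberately use plain loops over state values, not the package's
# own joint-tabulation code paths.

# Plug-in mutual information by direct double summation over the support.
oracle_mi <- function(x, y) {
  n <- length(x)
  total <- 0
  for (xv in unique(x)) {
    for (yv in unique(y)) {
      pxy <- sum(x == xv & y == yv) / n
      if (pxy == 0) next
      px <- sum(x == xv) / n
      py <- sum(y == yv) / n
      total <- total + pxy * log2(pxy / (px * py))
    }
  }
  total
}

oracle_entropy <- function(x) {
  n <- length(x)
  total <- 0
  for (xv in unique(x)) {
    p <- sum(x == xv) / n
    total <- total - p * log2(p)
  }
  total
}

# I(X;Z|Y) as a weighted sum of per-slice brute-force MIs.
oracle_cmi <- function(x, z, y) {
  n <- length(x)
  total <- 0
  for (yv in unique(y)) {
    sel <- y == yv
    total <- total + (sum(sel) / n) * oracle_mi(x[sel], z[sel])
  }
  total
}

# Binomial tail critical value by exhaustive summation of the pmf,
# built from choose() rather than pbinom().
oracle_np_critical <- function(n, p, alpha) {
  pmf <- vapply(0:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
                numeric(1))
  for (zeta in 0:n) {
    tail <- if (zeta == n) 0 else sum(pmf[(zeta + 2):(n + 1)])
    if (tail <= alpha) return(zeta)
  }
  n
}

# Reference greedy objective evaluation built on the oracles above
# (linear-form criteria only), for exhaustive step-optimality scans.
oracle_linear_score <- function(xc, y, selected_feats, alpha, beta) {
  rel <- oracle_mi(xc, y)
  nF <- length(selected_feats)
  if (nF == 0L) return(rel)
  red <- sum(vapply(selected_feats, function(s) oracle_mi(xc, s),
                    numeric(1)))
  cred <- sum(vapply(selected_feats, function(s) oracle_cmi(xc, s, y),
                     numeric(1)))
  rel - alpha(nF) * red + beta(nF) * cred
}

# Small deterministic paired-count table: 3 features x 6 samples with a
# binary phenotype, used for hand-audited reporting checks.
audit_fixture <- function() {
  counts <- matrix(c(10, 20, 30, 40, 50, 60,
                     90, 70, 60, 40, 30, 20,
                      0, 10, 10, 20, 20, 20),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("fA", "fB", "fC"),
                                   paste0("s", 1:6)))
  table <- abundance_table(counts,
                           taxonomy = c("p__One", "p__Two", "p__Three"))
  labels <- label_vector(c("omnivore", "omnivore", "omnivore",
                           "vegetarian", "vegetarian", "vegetarian"),
                         sample_ids = paste0("s", 1:6))
  list(table = table, labels = labels)
}

# Random discrete vectors for property-style loops.
rand_states <- function(n, card) sample.int(card, n, replace = TRUE) - 1L

# Write a minimal BIOM 1.0 JSON file by string templating (independent of
# the package's writer), dense or sparse.
write_raw_biom <- function(path, counts, feature_ids, sample_ids,
                           matrix_type = "dense", taxonomy = NULL,
                           sample_md = NULL) {
  K <- nrow(counts); M <- ncol(counts)
  row_meta <- function(i) {
    if (is.null(taxonomy)) return("null")
    sprintf('{"taxonomy": [%s]}',
            paste(sprintf('"%s"',
                          strsplit(taxonomy[i], "; ", fixed = TRUE)[[1]]),
                  collapse = ", "))
  }
  col_meta <- function(j) {
    if (is.null(sample_md)) return("null")
    sprintf('{%s}', paste(sprintf('"%s": "%s"', colnames(sample_md),
                                  unlist(sample_md[j, ])),
                          collapse = ", "))
  }
  rows <- paste(sprintf('{"id": "%s", "metadata": %s}', feature_ids,
                        vapply(seq_len(K), row_meta, character(1))),
                collapse = ",\n")
  cols <- paste(sprintf('{"id": "%s", "metadata": %s}', sample_ids,
                        vapply(seq_len(M), col_meta, character(1))),
                collapse = ",\n")
  data <- if (matrix_type == "dense") {
    paste(apply(counts, 1, function(r)
      sprintf("[%s]", paste(r, collapse = ","))), collapse = ",\n")
  } else {
    trip <- which(counts != 0, arr.ind = TRUE)
    paste(sprintf("[%d,%d,%g]", trip[, 1] - 1L, trip[, 2] - 1L,
                  counts[trip]), collapse = ",\n")
  }
  json <- sprintf(paste0(
    '{"id": "fixture", "format": "Biological Observation Matrix 1.0.0",',
    '"format_url": "http://biom-format.org", "type": "OTU table",',
    '"generated_by": "test", "date": "2015-01-01T00:00:00",',
    '"matrix_type": "%s", "matrix_element_type": "int",',
    '"shape": [%d, %d], "rows": [%s], "columns": [%s], "data": [%s]}'),
    matrix_type, K, M, rows, cols, data)
  writeLines(json, path)
  path
}
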