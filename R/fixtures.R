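#' Generate a synthetic abundance table with planted structure
#'
#' Simulates a `K x M` count table with a balanced binary phenotype and
#' four kinds of features, so that every selector in the package can be
#' benchmarked against a known ground truth:
#'
#' * **informative**: negative-binomial counts whose mean differs between
#'   the classes by `effect_size` standard deviations of the base
#'   distribution;
#' * **redundant**: Poisson resamples of an informative parent (strongly
#'   correlated with it, hence carrying no new information);
#' * **XOR pairs**: two-level abundance features built from binary latent
#'   bits that are exactly balanced within each class - each member is
#'   marginally independent of the phenotype in the realized sample, while
#'   the pair's parity determines the class exactly;
#' * **noise**: class-independent negative-binomial counts.
#'
#' Base feature means are log-normal and rescaled so the expected
#' per-sample total is `depth`.  Feature order is randomly permuted; the
#' returned ground-truth index sets refer to the permuted table.  The
#' output is fully determined by `seed`.
#'
#' @param K number of features; default 100.
#' @param M number of samples (must be even; classes are balanced);
#'   default 100.
#' @param n_informative number of class-shifted features; default 10.
#' @param n_redundant number of noisy copies of informative features
#'   (requires `n_informative >= 1`); default 5.
#' @param n_xor_pairs number of parity-coupled pairs; default 1.
#' @param effect_size class mean shift in units of the base feature's
#'   standard deviation; default 1.
#' @param depth expected per-sample total count; default 10000.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed); default 1, typical of 16S count tables.
#' @param seed integer seed.
#' @return A list with elements `table` (an [abundance_table()]),
#'   `metadata` (a `sample_metadata` data.frame with a binary `class`
#'   column), and `truth` (list of index vectors `informative`,
#'   `redundant`, `xor` plus the pair matrix `xor_pairs`, and `noise`).
#' @examples
#' sim <- synthetic_abundance(K = 20, M = 40, seed = 1)
#' sim$truth$informative
#' @export
synthetic_abundance <- function(K = 100L, M = 100L, n_informative = 10L,
                                n_redundant = 5L, n_xor_pairs = 1L,
                                effect_size = 1, depth = 10000,
                                dispersion = 1, seed = 1L) {
  K <- as.integer(K); M <- as.integer(M)
  if (M %% 2L != 0L) stop("M must be even (balanced classes)")
  n_planted <- n_informative + n_redundant + 2L * n_xor_pairs
  if (n_planted > K) stop("planted features exceed K")
  if (n_redundant > 0L && n_informative < 1L) {
    stop("redundant features need an informative parent")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  set.seed(seed)

  classes <- rep(c("case", "control"), each = M %/% 2L)
  is_case <- classes == "case"

  mu <- rlnorm(K, meanlog = log(depth / K), sdlog = 1)
  mu <- mu * depth / sum(mu)            # expected column total ~ depth
  base_sd <- sqrt(mu + mu^2 / dispersion)

  counts <- matrix(0, nrow = K, ncol = M)
  idx_inf <- seq_len(n_informative)
  idx_red <- seq_len(n_redundant) + n_informative
  idx_xor <- seq_len(2L * n_xor_pairs) + n_informative + n_redundant
  idx_noise <- setdiff(seq_len(K), c(idx_inf, idx_red, idx_xor))

  for (i in idx_inf) {
    mu_case <- mu[i] + effect_size * base_sd[i]
    counts[i, ] <- rnbinom(M, size = dispersion,
                           mu = ifelse(is_case, mu_case, mu[i]))
  }
  if (n_redundant > 0L) {
    parents <- rep_len(idx_inf, n_redundant)
    for (j in seq_len(n_redundant)) {
      counts[idx_red[j], ] <- rpois(M, lambda = counts[parents[j], ] + 1)
    }
  }
  # XOR pairs: exactly balanced bits within each class, noiseless two-level
  # abundance so the parity structure (and each member's marginal
  # independence of the class) holds exactly in the realized sample
  if (n_xor_pairs > 0L) {
    half <- M %/% 2L
    if (half %% 2L != 0L) stop("M/2 must be even for exact XOR balance")
    lo <- pmax(1, round(depth / K / 4))
    hi <- round(3 * depth / K)
    for (p in seq_len(n_xor_pairs)) {
      b1 <- integer(M)
      b1[is_case] <- sample(rep(0:1, half / 2L))
      b1[!is_case] <- sample(rep(0:1, half / 2L))
      b2 <- as.integer(xor(b1, is_case))
      i1 <- idx_xor[2L * p - 1L]; i2 <- idx_xor[2L * p]
      counts[i1, ] <- ifelse(b1 == 1L, hi, lo)
      counts[i2, ] <- ifelse(b2 == 1L, hi, lo)
    }
  }
  for (i in idx_noise) {
    counts[i, ] <- rnbinom(M, size = dispersion, mu = mu[i])
  }

  perm <- sample.int(K)
  counts <- counts[perm, , drop = FALSE]
  where <- order(perm)                  # where[i] = new row of old feature i

  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Verrucomicrobia")
  feature_ids <- sprintf("OTU%05d", seq_len(K))
  taxonomy <- paste0("k__Bacteria; p__", sample(phyla, K, replace = TRUE),
                     "; g__Genus", seq_len(K))
  sample_ids <- sprintf("S%04d", seq_len(M))

  metadata <- data.frame(class = classes, row.names = sample_ids,
                         stringsAsFactors = FALSE)
  class(metadata) <- c("sample_metadata", "data.frame")

  table <- abundance_table(counts, feature_ids = feature_ids,
                           taxonomy = taxonomy, sample_ids = sample_ids)
  xor_pairs <- if (n_xor_pairs > 0L) {
    matrix(where[idx_xor], ncol = 2L, byrow = TRUE)
  } else {
    matrix(integer(0), ncol = 2L)
  }
  list(table = table, metadata = metadata,
       truth = list(informative = sort(where[idx_inf]),
                    redundant = sort(where[idx_red]),
                    xor = sort(where[idx_xor]),
                    xor_pairs = xor_pairs,
                    noise = sort(where[idx_noise])))
}
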