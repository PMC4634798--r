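#' Configuration for Neyman-Pearson feature selection
#'
#' NPFS runs a base greedy criterion (the "SF" in "NPFS-SF", e.g.
#' NPFS-MIM) on `n_bootstraps` resampled datasets, each time selecting `k`
#' features, and then tests each feature's selection count against the
#' binomial null in which every feature is equally likely to be picked
#' (success probability `k/K`).
#'
#' @param k features selected per bootstrap replicate (`k < K`).
#' @param objective base criterion name or [make_objective()] result;
#'   default `"mim"`.
#' @param n_bootstraps number of bootstrap replicates; default 100.
#' @param alpha_level significance level of the binomial tail test in
#'   (0, 1); default 0.05.
#' @param subsample_fraction fraction of samples drawn (with replacement)
#'   per replicate, in (0, 1]; default 1 (bootstrap-size resamples).
#' @param seed integer master seed; replicate `r` uses `seed + r` so the
#'   result is independent of how replicates are scheduled.
#' @param n_workers number of worker processes for the map phase; the
#'   output is identical for any value.
#' @param n_bins discretization bins passed to [greedy_select()].
#' @return An object of class `npfs_config`.
#' @export
npfs_config <- function(k, objective = "mim", n_bootstraps = 100L,
                        alpha_level = 0.05, subsample_fraction = 1,
                        seed = 1L, n_workers = 1L, n_bins = 10L) {
  k <- as.integer(k)
  n_bootstraps <- as.integer(n_bootstraps)
  if (k < 1L) stop("k must be >= 1")
  if (n_bootstraps < 1L) stop("n_bootstraps must be >= 1")
  if (alpha_level <= 0 || alpha_level >= 1) {
    stop("alpha_level must be in (0, 1)")
  }
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("subsample_fraction must be in (0, 1]")
  }
  structure(list(k = k, objective = as_objective(objective),
                 n_bootstraps = n_bootstraps, alpha_level = alpha_level,
                 subsample_fraction = subsample_fraction,
                 seed = as.integer(seed), n_workers = as.integer(n_workers),
                 n_bins = as.integer(n_bins)),
            class = "npfs_config")
}

#' Per-feature bootstrap selection counts
#'
#' The map phase of NPFS: for each replicate, draw
#' `ceiling(subsample_fraction * M)` samples uniformly with replacement
#' (seeded as `seed + replicate`), run the base greedy criterion selecting
#' `k` features on the subsample, and increment each selected feature's
#' count.  A draw that contains a single class is redrawn (up to 100
#' times, within the replicate's own RNG stream).  Counts always sum to
#' `k * n_bootstraps`, and are bitwise identical for any `n_workers`.
#'
#' @param table an [abundance_table()] (or numeric matrix).
#' @param labels a [label_vector()] (or factor/character vector) aligned to
#'   the table.
#' @param config an [npfs_config()].
#' @return Integer vector of `K` selection counts.
#' @export
bootstrap_selection_counts <- function(table, labels, config) {
  stopifnot(inherits(config, "npfs_config"))
  counts <- if (inherits(table, "abundance_table")) table$counts else
    as.matrix(table)
  yv <- if (inherits(labels, "label_vector")) labels$values else
    as.character(labels)
  if (length(yv) != ncol(counts)) stop("labels not aligned to table")
  K <- nrow(counts); M <- ncol(counts)
  if (config$k >= K) stop("k must be smaller than the number of features")
  m <- as.integer(ceiling(config$subsample_fraction * M))

  one_rep <- function(r) {
    set.seed(config$seed + r)
    idx <- NULL
    for (attempt in seq_len(100L)) {
      cand <- sample.int(M, m, replace = TRUE)
      if (length(unique(yv[cand])) >= 2L) { idx <- cand; break }
    }
    if (is.null(idx)) {
      stop("bootstrap replicate ", r,
           " drew a single class 100 times in a row")
    }
    res <- greedy_select(counts[, idx, drop = FALSE], yv[idx], config$k,
                         objective = config$objective,
                         n_bins = config$n_bins)
    res$feature_indices
  }

  picks <- if (config$n_workers > 1L) {
    parallel::mclapply(seq_len(config$n_bootstraps), one_rep,
                       mc.cores = config$n_workers)
  } else {
    lapply(seq_len(config$n_bootstraps), one_rep)
  }
  err <- vapply(picks, inherits, logical(1), "try-error")
  if (any(err)) stop(picks[[which(err)[1]]])
  tabulate(unlist(picks), nbins = K)
}

#' Binomial critical value for the Neyman-Pearson test
#'
#' The smallest integer \eqn{\zeta \in [0, n]} such that
#' \eqn{P(\mathrm{Bin}(n, p_0) > \zeta) \le \alpha}.  A feature is declared
#' relevant iff its selection count strictly exceeds \eqn{\zeta}, which
#' makes the per-feature test size at most \eqn{\alpha} by construction.
#'
#' @param n_bootstraps number of Bernoulli trials \eqn{n}.
#' @param null_rate null selection probability \eqn{p_0} (NPFS uses
#'   `k / K`), in (0, 1).
#' @param alpha_level significance level \eqn{\alpha}, in (0, 1).
#' @return Integer critical value \eqn{\zeta}.
#' @examples
#' np_critical_value(100, 0.05, 0.05)
#' @export
np_critical_value <- function(n_bootstraps, null_rate, alpha_level) {
  n <- as.integer(n_bootstraps)
  if (null_rate <= 0 || null_rate >= 1) stop("null_rate must be in (0, 1)")
  if (alpha_level <= 0 || alpha_level >= 1) {
    stop("alpha_level must be in (0, 1)")
  }
  zeta <- 0:n
  tail <- pbinom(zeta, n, null_rate, lower.tail = FALSE)
  # tolerate floating-point ties when the tail equals alpha exactly
  zeta[min(which(tail <= alpha_level * (1 + 1e-12) + 1e-15))]
}

#' Neyman-Pearson feature selection
#'
#' Composes [bootstrap_selection_counts()] and [np_critical_value()] with
#' null rate `k / K`: features whose counts exceed the critical value are
#' declared relevant.  The size of the relevant set is data-driven - `k`
#' is only the per-replicate guess, not the output size.
#'
#' @inheritParams bootstrap_selection_counts
#' @return An object of class `npfs_result`: list with
#'   `selection_counts` (K integers), `critical_value`, `relevant`
#'   (indices with counts above the critical value, ordered by decreasing
#'   count), `null_rate`, and the `config`.
#' @seealso [as_selection_result()] to convert the relevant set into a
#'   ranked [selection_result()].
#' @export
npfs_select <- function(table, labels, config) {
  cnt <- bootstrap_selection_counts(table, labels, config)
  K <- length(cnt)
  null_rate <- config$k / K
  zeta <- np_critical_value(config$n_bootstraps, null_rate,
                            config$alpha_level)
  rel <- which(cnt > zeta)
  rel <- rel[order(-cnt[rel], rel)]
  structure(list(selection_counts = cnt, critical_value = zeta,
                 relevant = rel, null_rate = null_rate, config = config),
            class = "npfs_result")
}

#' @export
print.npfs_result <- function(x, ...) {
  cat(sprintf(
    "npfs_result: %d/%d features relevant (counts > %d of %d, p0 = %.4f)\n",
    length(x$relevant), length(x$selection_counts), x$critical_value,
    x$config$n_bootstraps, x$null_rate))
  invisible(x)
}

#' Convert an NPFS result to a ranked selection
#'
#' Relevant features ordered by decreasing selection count (ties broken by
#' index); scores are the counts.
#'
#' @param result an `npfs_result`.
#' @param table the [abundance_table()] the result refers to.
#' @return A [selection_result()].
#' @export
as_selection_result <- function(result, table) {
  stopifnot(inherits(result, "npfs_result"),
            inherits(table, "abundance_table"))
  idx <- result$relevant
  selection_result(idx, table$feature_ids[idx],
                   result$selection_counts[idx],
                   method = paste0("NPFS-", result$config$objective$name),
                   k = NA_integer_)
}
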