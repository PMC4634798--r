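#' Encode a binary phenotype as +/-1
#'
#' @param labels a [label_vector()] (or character/factor vector) with
#'   exactly two classes.
#' @param positive_class the class coded `+1`; the other class is `-1`.
#' @return Numeric vector of `+1`/`-1`, one per sample.
#' @export
encode_binary_labels <- function(labels, positive_class) {
  yv <- if (inherits(labels, "label_vector")) labels$values else
    as.character(labels)
  classes <- sort(unique(yv))
  if (length(classes) != 2L) {
    stop("need exactly two classes (got ", length(classes),
         "); collapse the phenotype with a label mapping first")
  }
  if (!positive_class %in% classes) {
    stop("positive_class '", positive_class, "' not among classes: ",
         paste(classes, collapse = ", "))
  }
  ifelse(yv == positive_class, 1, -1)
}

#' Data-derived regularization grid
#'
#' The grid anchor is
#' \eqn{\lambda_{max} = \max_j |x_j^\top y| / M}, the smallest penalty at
#' which the l1-penalized least-squares solution is exactly zero; the grid
#' is `n_values` log-spaced values descending from \eqn{\lambda_{max}} to
#' `eps_ratio * lambda_max`.
#'
#' @param X numeric `K x M` design (features in rows).
#' @param y numeric response of length `M` (+/-1 coded labels).
#' @param n_values grid length, `>= 2`; default 100.
#' @param eps_ratio ratio of the smallest to the largest grid value, in
#'   (0, 1); default `1e-4`.
#' @return Strictly descending numeric vector of penalties.
#' @export
lambda_grid <- function(X, y, n_values = 100L, eps_ratio = 1e-4) {
  n_values <- as.integer(n_values)
  if (n_values < 2L) stop("n_values must be >= 2")
  if (eps_ratio <= 0 || eps_ratio >= 1) stop("eps_ratio must be in (0, 1)")
  M <- ncol(X)
  if (length(y) != M) stop("y not aligned to X")
  lmax <- max(abs(as.vector(X %*% y))) / M
  if (lmax <= 0) stop("all features orthogonal to y: lambda_max is 0")
  exp(seq(log(lmax), log(eps_ratio * lmax), length.out = n_values))
}

#' Fit l1-penalized least squares at one penalty
#'
#' Minimizes
#' \deqn{\frac{1}{2M} \| y - X^\top \theta \|_2^2 + \lambda \|\theta\|_1}
#' over \eqn{\theta \in R^K} by cyclic coordinate descent with
#' KKT-violation screening (coordinates are activated from a residual
#' correlation check computed by a matrix product, then iterated to
#' convergence).  For \eqn{\lambda \ge \lambda_{max}} the returned solution
#' is exactly zero.
#'
#' @param X numeric `K x M` design (features in rows).
#' @param y numeric response of length `M`.
#' @param lam penalty \eqn{\lambda > 0}.
#' @param theta optional warm start (length `K`).
#' @param tol scale-free convergence tolerance for the coordinate-descent
#'   fallback: a sweep converges when the largest energy change
#'   `a_j * delta_j^2` falls below `tol * mean(y^2)`; default `1e-10`.
#' @param max_iter cap on coordinate-descent sweeps; default 100000.
#' @param strict when the direct active-set solve cannot be verified
#'   (degenerate support), keep grinding coordinate descent down to a
#'   machine-precision fixed point (`TRUE`, the default) or accept the
#'   fixed point at `tol` (`FALSE`; used for the inner cross-validation
#'   fits, whose held-out costs do not need machine precision).
#' @details Cyclic coordinate descent with KKT-violation screening is run
#'   in short bursts; after each burst the stationarity system restricted
#'   to the current support is solved exactly and the candidate is
#'   accepted only if its signs match and the full KKT conditions hold, in
#'   which case it is the global minimum of this convex problem.  On
#'   ill-conditioned supports where the direct solve fails, plain
#'   coordinate descent finishes the job.
#' @return Numeric coefficient vector of length `K`.
#' @export
fit_lasso <- function(X, y, lam, theta = NULL, tol = 1e-10,
                      max_iter = 100000L, strict = TRUE) {
  K <- nrow(X); M <- ncol(X)
  if (length(y) != M) stop("y not aligned to X")
  if (lam <= 0) stop("lam must be positive")
  if (is.null(theta)) theta <- numeric(K)
  a <- rowSums(X^2) / M               # curvature per coordinate
  r <- y - as.vector(crossprod(X, theta))
  in_active <- logical(K)
  in_active[theta != 0 & a > 0] <- TRUE
  vy <- mean(y^2); if (vy <= 0) vy <- 1
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  kkt_slack <- lam * 1e-9 + 1e-14

  # exact solve of the stationarity system on a candidate support; signs
  # that flip are dropped and the system re-solved; the result is accepted
  # only if the full KKT conditions verify, in which case it is the global
  # minimum of this convex problem
  try_polish <- function(theta) {
    act <- which(theta != 0)
    s <- sign(theta[act])
    for (attempt in seq_len(8L)) {
      if (length(act) == 0L) return(NULL)
      A <- X[act, , drop = FALSE]
      sol <- tryCatch(
        qr.solve(A %*% t(A) / M, as.vector(A %*% y) / M - lam * s,
                 tol = 1e-12),
        error = function(e) NULL)
      if (is.null(sol)) return(NULL)
      bad <- which(sign(sol) != s)
      if (length(bad) > 0L) {
        act <- act[-bad]; s <- s[-bad]
        next
      }
      r2 <- y - as.vector(crossprod(A, sol))
      g2 <- as.vector(X %*% r2) / M
      if (all(abs(g2[-act]) <= lam + kkt_slack)) {
        theta[] <- 0; theta[act] <- sol
        return(theta)
      }
      return(NULL)
    }
    NULL
  }

  it <- 0L
  cur_tol <- tol
  repeat {
    # a burst of coordinate-descent sweeps over the active set
    active <- which(in_active)
    delta <- Inf
    for (sweep in seq_len(50L)) {
      delta <- 0
      for (j in active) {
        cj <- sum(X[j, ] * r) / M + a[j] * theta[j]
        tj <- soft(cj, lam) / a[j]
        d <- tj - theta[j]
        if (d != 0) {
          r <- r - X[j, ] * d
          theta[j] <- tj
          delta <- max(delta, a[j] * d * d)
        }
      }
      it <- it + 1L
      if (delta < cur_tol * vy || length(active) == 0L) break
    }
    # exact KKT screen over all coordinates; at lam >= lambda_max no
    # coordinate ever activates, so theta stays identically zero
    g <- as.vector(X %*% r) / M
    viol <- which(!in_active & a > 0 & abs(g) > lam + kkt_slack)
    if (length(viol) > 0L) {
      in_active[viol] <- TRUE
      next
    }
    if (all(theta == 0)) return(theta)    # no violations from zero
    polished <- try_polish(theta)
    if (!is.null(polished)) return(polished)
    if (delta < max(cur_tol, 1e-14) * vy) {
      # CD fixed point at the current tolerance but the direct solve was
      # rejected (e.g. a degenerate, saturated support): grind further,
      # down to a machine-precision fixed point
      if (!strict || cur_tol <= 1e-14) return(theta)
      cur_tol <- cur_tol * 1e-2
    }
    if (it > max_iter) {
      stop(sprintf(
        "coordinate descent did not converge: energy change %.3e > %.3e",
        delta, cur_tol * vy))
    }
  }
}

#' Cross-validated choice of the penalty
#'
#' Sweeps the data-derived [lambda_grid()] with warm starts, scoring each
#' penalty by the mean held-out cost
#' \eqn{\frac{1}{2 M_{val}} \|y_{val} - X_{val}^\top \theta\|_2^2} over
#' stratified folds, picks the penalty with the smallest mean cost (ties
#' toward the larger penalty), and refits on all data at that penalty.
#'
#' @param X numeric `K x M` design (features in rows).
#' @param y numeric `+1`/`-1` response of length `M`.
#' @param folds number of stratified CV folds, `>= 2`; default 5.
#' @param n_values,eps_ratio grid parameters, see [lambda_grid()].
#' @param seed integer seed for the fold assignment.
#' @param zero_tol coefficients with `|theta| > zero_tol` form the support.
#' @return An object of class `lasso_model`: list with `theta`,
#'   `lambda_chosen`, `lambda_grid`, `cv_scores`, `support`.
#' @export
cv_select_lambda <- function(X, y, folds = 5L, n_values = 100L,
                             eps_ratio = 1e-4, seed = 1L,
                             zero_tol = 1e-8) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  M <- ncol(X)
  grid <- lambda_grid(X, y, n_values = n_values, eps_ratio = eps_ratio)

  # fold assignment: stratified for discrete (+/-1) responses, plain
  # random for continuous ones
  set.seed(seed)
  fold_id <- integer(M)
  discrete_y <- length(unique(y)) <= 2L
  if (discrete_y) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    fold_id <- rep_len(seq_len(folds), M)[sample.int(M)]
  }

  cv <- matrix(NA_real_, nrow = length(grid), ncol = folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); va <- which(fold_id == f)
    if (length(va) == 0L || length(tr) == 0L ||
        (discrete_y && length(unique(y[tr])) < 2L)) {
      stop("fold ", f, " lost a class; use fewer folds")
    }
    th <- numeric(nrow(X))
    for (i in seq_along(grid)) {
      th <- fit_lasso(X[, tr, drop = FALSE], y[tr], grid[i], theta = th,
                      tol = 1e-8, strict = FALSE)
      resid <- y[va] - as.vector(crossprod(X[, va, drop = FALSE], th))
      cv[i, f] <- sum(resid^2) / (2 * length(va))
    }
  }
  cv_mean <- rowMeans(cv)
  best <- which.min(cv_mean)           # ties: first = largest lambda
  th <- numeric(nrow(X))
  for (i in seq_len(best)) th <- fit_lasso(X, y, grid[i], theta = th)
  structure(list(theta = th, lambda_chosen = grid[best],
                 lambda_grid = grid, cv_scores = cv_mean,
                 support = which(abs(th) > zero_tol)),
            class = "lasso_model")
}

#' @export
print.lasso_model <- function(x, ...) {
  cat(sprintf(
    "lasso_model: lambda = %.4g (grid of %d), support size %d\n",
    x$lambda_chosen, length(x$lambda_grid), length(x$support)))
  invisible(x)
}

#' Embedded feature selection by the lasso
#'
#' Converts counts to per-sample relative abundance, encodes the binary
#' phenotype as `+/-1`, runs [cv_select_lambda()], and returns the support
#' of the fitted coefficient vector ordered by decreasing `|theta|`, with
#' the coefficients as scores.  The support size is data-driven; an empty
#' support is returned as an empty selection, not an error.
#'
#' @param table an [abundance_table()].
#' @param labels a [label_vector()] with exactly two classes.
#' @param positive_class class coded `+1`; default the lexicographically
#'   first class.
#' @param standardize scale each feature row to unit standard deviation
#'   before fitting (relative abundances already share a scale, so the
#'   default is `FALSE`).
#' @inheritParams cv_select_lambda
#' @return A [selection_result()] with the fitted [cv_select_lambda()]
#'   model attached as attribute `"model"`.
#' @export
lasso_select <- function(table, labels, positive_class = NULL,
                         folds = 5L, n_values = 100L, eps_ratio = 1e-4,
                         seed = 1L, zero_tol = 1e-8,
                         standardize = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  yv <- if (inherits(labels, "label_vector")) labels$values else
    as.character(labels)
  classes <- sort(unique(yv))
  if (is.null(positive_class)) positive_class <- classes[1]
  y <- encode_binary_labels(yv, positive_class)
  X <- relative_abundance(table)
  if (standardize) {
    s <- apply(X, 1L, sd)
    s[s == 0] <- 1
    X <- X / s
  }
  model <- cv_select_lambda(X, y, folds = folds, n_values = n_values,
                            eps_ratio = eps_ratio, seed = seed,
                            zero_tol = zero_tol)
  idx <- model$support[order(-abs(model$theta[model$support]),
                             model$support)]
  res <- selection_result(idx, table$feature_ids[idx], model$theta[idx],
                          method = "lasso", k = NA_integer_)
  attr(res, "model") <- model
  res
}
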