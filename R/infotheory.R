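#' Discretize abundance values
#'
#' Maps a vector of counts or real values to small integer states for the
#' plug-in information estimators.  Integer-valued inputs with at most
#' `n_bins` distinct values are rank-encoded as-is (each distinct count is
#' its own state); otherwise values are binned into `n_bins`
#' equal-frequency bins by rank, with ties always sharing a bin.  The map
#' is deterministic for a fixed input.
#'
#' @param values numeric vector (counts or reals), length `M >= 1`.
#' @param n_bins target number of bins, `>= 2`.
#' @return An object of class `discrete_vector`: an integer vector of
#'   0-based states with attribute `cardinality`.  A constant input yields
#'   a single state (cardinality 1).
#' @examples
#' discretize(c(0, 0, 3, 3, 7), n_bins = 10)  # states 0 0 1 1 2
#' @export
discretize <- function(values, n_bins = 10L) {
  if (length(values) < 1L) stop("empty input")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (anyNA(values)) stop("NA in values")
  u <- unique(values)
  if (length(u) <= n_bins && all(values == round(values))) {
    states <- match(values, sort(u)) - 1L
    card <- length(u)
  } else {
    M <- length(values)
    r <- rank(values, ties.method = "min")
    states <- as.integer(floor((r - 1L) * n_bins / M))
    states <- match(states, sort(unique(states))) - 1L
    card <- max(states) + 1L
  }
  new_discrete(states, card)
}

new_discrete <- function(states, cardinality) {
  structure(as.integer(states), cardinality = as.integer(cardinality),
            class = "discrete_vector")
}

#' @export
print.discrete_vector <- function(x, ...) {
  cat(sprintf("discrete_vector: %d samples, %d states\n", length(x),
              attr(x, "cardinality")))
  print(as.integer(x))
  invisible(x)
}

# Coerce to 0-based integer states with a cardinality attribute.
as_discrete <- function(x) {
  if (inherits(x, "discrete_vector")) return(x)
  if (is.factor(x)) {
    return(new_discrete(as.integer(x) - 1L, nlevels(x)))
  }
  if (is.character(x)) x <- factor(x)
  if (is.factor(x)) return(as_discrete(x))
  if (anyNA(x)) stop("NA in discrete input")
  if (!all(x == round(x))) {
    stop("non-integer input: discretize() it first")
  }
  u <- sort(unique(x))
  new_discrete(match(x, u) - 1L, length(u))
}

card_of <- function(x) attr(x, "cardinality")

# ---- internal estimators on 0-based integer states -------------------------

.entropy_counts <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

.entropy <- function(s, c) {
  n <- length(s)
  .entropy_counts(tabulate(s + 1L, nbins = c), n)
}

.mi <- function(x, cx, y, cy) {
  n <- length(x)
  jt <- tabulate(x + cx * y + 1L, nbins = cx * cy)
  px <- tabulate(x + 1L, nbins = cx) / n
  py <- tabulate(y + 1L, nbins = cy) / n
  nz <- which(jt > 0L)
  p <- jt[nz] / n
  ix <- ((nz - 1L) %% cx) + 1L
  iy <- ((nz - 1L) %/% cx) + 1L
  v <- sum(p * log2(p / (px[ix] * py[iy])))
  max(v, 0)
}

# I(X;Z|Y) = sum_y p(y) I(X;Z | Y = y), plug-in on the conditional slices
.cmi <- function(x, cx, z, cz, y, cy) {
  n <- length(x)
  total <- 0
  for (yv in 0:(cy - 1L)) {
    sel <- which(y == yv)
    if (length(sel) == 0L) next
    total <- total + (length(sel) / n) * .mi(x[sel], cx, z[sel], cz)
  }
  max(total, 0)
}

# merge two state vectors into one joint state vector
.joint <- function(x, cx, y, cy) {
  list(s = x + cx * y, c = cx * cy)
}

# ---- exported estimators ---------------------------------------------------

#' Empirical Shannon entropy (bits)
#'
#' Plug-in estimate \eqn{-\sum_x p(x) \log_2 p(x)} with the convention
#' \eqn{0 \log 0 = 0}.
#'
#' @param x a `discrete_vector` (from [discretize()]) or an integer/factor
#'   vector of states.
#' @return Nonnegative entropy in bits.
#' @export
entropy <- function(x) {
  x <- as_discrete(x)
  .entropy(x, card_of(x))
}

#' Empirical mutual information (bits)
#'
#' Plug-in estimate of
#' \eqn{I(X;Y) = \sum_{y}\sum_{x} p(x,y) \log_2
#' \frac{p(x,y)}{p(x)\,p(y)}} over the empirical joint distribution of the
#' paired samples.  Cells with \eqn{p(x,y)=0} contribute 0 and tiny
#' negative floating-point residue is clamped to 0.
#'
#' @param x,y paired `discrete_vector`s (or integer/factor vectors) of
#'   equal length.
#' @return Nonnegative mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  x <- as_discrete(x); y <- as_discrete(y)
  if (length(x) != length(y)) stop("x and y differ in length")
  .mi(x, card_of(x), y, card_of(y))
}

#' Empirical conditional mutual information (bits)
#'
#' Plug-in estimate of \eqn{I(X;X'|Y) = \sum_y p(y)\, I(X;X' \mid Y=y)}
#' computed on the conditional slices of the data.
#'
#' @param x,x2 paired feature vectors (`discrete_vector` or integer/factor).
#' @param y the conditioning variable, same length.
#' @return Nonnegative conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(x, x2, y) {
  x <- as_discrete(x); x2 <- as_discrete(x2); y <- as_discrete(y)
  if (length(x) != length(x2) || length(x) != length(y)) {
    stop("inputs differ in length")
  }
  .cmi(x, card_of(x), x2, card_of(x2), y, card_of(y))
}
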