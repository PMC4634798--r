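#' Objective-function catalog for the greedy filter search
#'
#' Builds the parameterization of one of the nine information-theoretic
#' selection criteria.  The linear-form criteria score a candidate \eqn{X}
#' against the already-selected set \eqn{F} as
#' \deqn{J(X,Y,F) = I(X;Y) - \alpha(|F|) \sum_{X' \in F} I(X;X')
#'   + \beta(|F|) \sum_{X' \in F} I(X;X'|Y),}
#' with \eqn{\alpha,\beta \ge 0}: MIM (\eqn{\alpha=\beta=0}), MIFS
#' (\eqn{\alpha} constant, \eqn{\beta=0}), mRMR (\eqn{\alpha=1/|F|},
#' \eqn{\beta=0}), JMI (\eqn{\alpha=\beta=1/|F|}), CIFE
#' (\eqn{\alpha=\beta=1}).  The nonlinear criteria follow the standard
#' filter-criterion survey definitions: CMIM scores
#' \eqn{\min_{X'\in F} I(X;Y|X')}; ICAP scores
#' \eqn{I(X;Y) - \sum_{X'} \max(0, I(X;X') - I(X;X'|Y))}; DISR scores
#' \eqn{\sum_{X'} I(X,X';Y) / H(X,X',Y)}; CondMI scores
#' \eqn{I(X;Y \mid F)} with the whole selected set as one joint variable.
#' Every criterion reduces to \eqn{I(X;Y)} when \eqn{F} is empty.
#'
#' @param name one of `"mim"`, `"mifs"`, `"mrmr"`, `"jmi"`, `"cife"`,
#'   `"cmim"`, `"icap"`, `"disr"`, `"condmi"` (case-insensitive).
#' @param mifs_beta redundancy weight of MIFS (its constant \eqn{\alpha});
#'   default 1.
#' @return An object of class `objective_params` with elements `name`,
#'   `form` (`"linear"` or the criterion name), and for linear criteria the
#'   `alpha` and `beta` rules as functions of `|F|`.
#' @examples
#' make_objective("jmi")   # alpha = beta = 1/|F|
#' make_objective("mrmr")  # alpha = 1/|F|, beta = 0
#' @export
make_objective <- function(name, mifs_beta = 1) {
  key <- tolower(as.character(name)[1])
  zero <- function(nF) 0
  one <- function(nF) 1
  inv <- function(nF) 1 / nF
  obj <- switch(key,
    mim    = list(form = "linear", alpha = zero, beta = zero),
    mifs   = list(form = "linear", alpha = function(nF) mifs_beta,
                  beta = zero),
    mrmr   = list(form = "linear", alpha = inv, beta = zero),
    jmi    = list(form = "linear", alpha = inv, beta = inv),
    cife   = list(form = "linear", alpha = one, beta = one),
    cmim   = list(form = "cmim"),
    icap   = list(form = "icap"),
    disr   = list(form = "disr"),
    condmi = list(form = "condmi"),
    stop("unknown objective '", name, "'; valid names: mim, mifs, mrmr, ",
         "jmi, cife, cmim, icap, disr, condmi")
  )
  obj$name <- toupper(key)
  class(obj) <- "objective_params"
  obj
}

as_objective <- function(objective) {
  if (inherits(objective, "objective_params")) return(objective)
  make_objective(objective)
}

#' @export
print.objective_params <- function(x, ...) {
  cat(sprintf("objective_params: %s (%s form)\n", x$name, x$form))
  invisible(x)
}

#' Score one candidate feature under a selection criterion
#'
#' Evaluates the objective of [make_objective()] for a single candidate
#' against the current selected set, from scratch.  [greedy_select()]
#' computes the same quantities incrementally; this function is the
#' reference evaluation (used, e.g., to audit step optimality).
#'
#' @param candidate index of the candidate feature.
#' @param features list of discretized features (`discrete_vector`s), one
#'   per table row.
#' @param labels a `discrete_vector` (or factor) of class labels.
#' @param state list with element `selected`: integer indices already in
#'   \eqn{F}, in selection order.
#' @param params an `objective_params` (or criterion name).
#' @return The objective value in bits.
#' @export
objective_score <- function(candidate, features, labels, state,
                            params = make_objective("mim")) {
  params <- as_objective(params)
  selected <- as.integer(state$selected)
  if (candidate %in% selected) stop("candidate already selected")
  y <- as_discrete(labels); cy <- card_of(y)
  x <- as_discrete(features[[candidate]]); cx <- card_of(x)
  rel <- .mi(x, cx, y, cy)
  nF <- length(selected)
  if (nF == 0L) return(rel)
  xs <- lapply(features[selected], as_discrete)
  red <- vapply(xs, function(s) .mi(x, cx, s, card_of(s)), numeric(1))
  switch(params$form,
    linear = {
      cred <- vapply(xs, function(s)
        .cmi(x, cx, s, card_of(s), y, cy), numeric(1))
      rel - params$alpha(nF) * sum(red) + params$beta(nF) * sum(cred)
    },
    cmim = {
      min(vapply(xs, function(s)
        .cmi(x, cx, y, cy, s, card_of(s)), numeric(1)))
    },
    icap = {
      cred <- vapply(xs, function(s)
        .cmi(x, cx, s, card_of(s), y, cy), numeric(1))
      rel - sum(pmax(0, red - cred))
    },
    disr = {
      sum(vapply(xs, function(s) {
        j <- .joint(x, cx, s, card_of(s))
        h <- .entropy(.joint(j$s, j$c, y, cy)$s, j$c * cy)
        if (h <= 0) 0 else .mi(j$s, j$c, y, cy) / h
      }, numeric(1)))
    },
    condmi = {
      z <- xs[[1]]; cz <- card_of(z)
      if (nF > 1L) {
        for (s in xs[-1]) {
          jz <- .joint(z, cz, s, card_of(s)); z <- jz$s; cz <- jz$c
        }
      }
      .cmi(x, cx, y, cy, z, cz)
    }
  )
}

#' Greedy forward feature selection
#'
#' The standard greedy filter search: start from an empty selected set
#' \eqn{F}, and for `k` iterations add the candidate feature that
#' maximizes the criterion's objective, removing it from the candidate
#' pool.  Each feature row is discretized with [discretize()] before
#' estimation.  Ties in the argmax are broken toward the lowest feature
#' index, so the output is deterministic.
#'
#' Pairwise redundancy terms are accumulated incrementally (one new
#' mutual-information term per candidate per step), so a full run costs
#' `O(kK)` estimator evaluations.
#'
#' @param table an [abundance_table()] (or a plain numeric feature-by-sample
#'   matrix).
#' @param labels a [label_vector()] aligned to the table (or a factor or
#'   character vector of per-sample classes).
#' @param k number of features to select, `1 <= k <= K`.
#' @param objective criterion name or [make_objective()] result; default
#'   `"mim"`.
#' @param n_bins discretization bins for [discretize()]; default 10.
#' @return A [selection_result()]; `scores` holds the objective value of
#'   each feature at the step it was selected.
#' @examples
#' sim <- synthetic_abundance(K = 30, M = 60, n_informative = 3,
#'                            n_redundant = 0, n_xor_pairs = 0,
#'                            effect_size = 3, seed = 1)
#' labs <- extract_labels(sim$table, sim$metadata, "class")
#' greedy_select(labs$table, labs$labels, k = 3, objective = "jmi")
#' @export
greedy_select <- function(table, labels, k, objective = "mim",
                          n_bins = 10L) {
  params <- as_objective(objective)
  counts <- if (inherits(table, "abundance_table")) table$counts else
    as.matrix(table)
  yv <- if (inherits(labels, "label_vector")) labels$values else
    as.character(labels)
  if (length(yv) != ncol(counts)) stop("labels not aligned to table")
  if (length(unique(yv)) < 2L) stop("fewer than two classes in labels")
  K <- nrow(counts)
  k <- as.integer(k)
  if (k < 1L || k > K) stop("k must be between 1 and the number of features")
  feats <- lapply(seq_len(K), function(i) discretize(counts[i, ], n_bins))
  y <- as_discrete(factor(yv))
  sel <- greedy_core(feats, y, k, params)
  ids <- if (inherits(table, "abundance_table")) table$feature_ids else
    (rownames(counts) %||% paste0("F", seq_len(K)))
  selection_result(sel$selected, ids[sel$selected], sel$scores,
                   method = params$name, k = k)
}

# incremental engine; feats: list of discrete_vectors, y: discrete_vector
greedy_core <- function(feats, y, k, params) {
  K <- length(feats)
  cy <- card_of(y)
  cards <- vapply(feats, card_of, integer(1))
  rel <- vapply(seq_len(K), function(j)
    .mi(feats[[j]], cards[j], y, cy), numeric(1))

  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(K)
  sum_red <- numeric(K)   # sum over F of I(X;X')
  sum_cred <- numeric(K)  # sum over F of I(X;X'|Y)
  icap_acc <- numeric(K)  # sum over F of max(0, I - I|Y)
  cmim_min <- rep(Inf, K) # min over F of I(X;Y|X')
  disr_acc <- numeric(K)  # sum over F of I(X,X';Y)/H(X,X',Y)
  z <- NULL; cz <- NULL   # joint state of F (CondMI only)

  for (step in seq_len(k)) {
    nF <- length(selected)
    cand_scores <- if (nF == 0L) {
      rel[remaining]
    } else {
      switch(params$form,
        linear = rel[remaining] -
          params$alpha(nF) * sum_red[remaining] +
          params$beta(nF) * sum_cred[remaining],
        cmim = cmim_min[remaining],
        icap = rel[remaining] - icap_acc[remaining],
        disr = disr_acc[remaining],
        condmi = vapply(remaining, function(j)
          .cmi(feats[[j]], cards[j], y, cy, z, cz), numeric(1))
      )
    }
    pick <- remaining[which.max(cand_scores)]  # ties: lowest index
    selected <- c(selected, pick)
    scores <- c(scores, max(cand_scores))
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0L) break

    xs <- feats[[pick]]; cs <- cards[pick]
    need_pairs <- params$form %in% c("linear", "icap", "cmim", "disr")
    if (need_pairs && step < k) {
      for (j in remaining) {
        xj <- feats[[j]]; cj <- cards[j]
        if (params$form %in% c("linear", "icap")) {
          r <- .mi(xj, cj, xs, cs)
          cr <- .cmi(xj, cj, xs, cs, y, cy)
          sum_red[j] <- sum_red[j] + r
          sum_cred[j] <- sum_cred[j] + cr
          icap_acc[j] <- icap_acc[j] + max(0, r - cr)
        } else if (params$form == "cmim") {
          cmim_min[j] <- min(cmim_min[j],
                             .cmi(xj, cj, y, cy, xs, cs))
        } else if (params$form == "disr") {
          jj <- .joint(xj, cj, xs, cs)
          h <- .entropy(.joint(jj$s, jj$c, y, cy)$s, jj$c * cy)
          disr_acc[j] <- disr_acc[j] +
            if (h <= 0) 0 else .mi(jj$s, jj$c, y, cy) / h
        }
      }
    }
    if (params$form == "condmi") {
      if (is.null(z)) {
        z <- as.integer(xs); cz <- cs
      } else {
        jz <- .joint(z, cz, xs, cs); z <- jz$s; cz <- jz$c
      }
    }
  }
  list(selected = selected, scores = scores)
}
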