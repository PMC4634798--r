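#' Construct an abundance table
#'
#' A feature-by-sample matrix of nonnegative counts with feature identifiers
#' (e.g. Greengenes OTU IDs), optional taxonomy lineage strings, and sample
#' identifiers.  This is the container every selector in the package
#' operates on: `K` features in rows, `M` samples in columns.
#'
#' @param counts numeric matrix, `K x M`, nonnegative; rows are features,
#'   columns are samples.
#' @param feature_ids character vector of `K` unique feature identifiers.
#'   Defaults to `rownames(counts)`.
#' @param taxonomy optional character vector of `K` lineage strings (joined
#'   with `"; "`); empty strings when absent.
#' @param sample_ids character vector of `M` unique sample identifiers.
#'   Defaults to `colnames(counts)`.
#' @param metadata optional data.frame of per-sample metadata with row names
#'   equal to sample IDs (as obtained from an embedded-metadata BIOM file).
#' @return An object of class `abundance_table`: a list with elements
#'   `counts`, `feature_ids`, `taxonomy`, `sample_ids`, `metadata`.
#' @examples
#' m <- matrix(c(1, 0, 2, 3, 0, 5), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
#' abundance_table(m)
#' @export
abundance_table <- function(counts, feature_ids = rownames(counts),
                            taxonomy = NULL, sample_ids = colnames(counts),
                            metadata = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(feature_ids)) {
    feature_ids <- paste0("F", seq_len(nrow(counts)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(ncol(counts)))
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (is.null(taxonomy)) taxonomy <- rep("", nrow(counts))
  taxonomy <- as.character(taxonomy)

  if (nrow(counts) < 1L) stop("abundance table needs at least one feature")
  if (ncol(counts) < 2L) stop("abundance table needs at least two samples")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative")
  }
  if (length(feature_ids) != nrow(counts)) {
    stop("feature_ids length does not match nrow(counts)")
  }
  if (length(sample_ids) != ncol(counts)) {
    stop("sample_ids length does not match ncol(counts)")
  }
  if (length(taxonomy) != nrow(counts)) {
    stop("taxonomy length does not match nrow(counts)")
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature IDs: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(counts) <- list(feature_ids, sample_ids)
  structure(list(counts = counts, feature_ids = feature_ids,
                 taxonomy = taxonomy, sample_ids = sample_ids,
                 metadata = metadata),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (any(nzchar(x$taxonomy))) cat("  taxonomy: present\n")
  if (!is.null(x$metadata)) {
    cat(sprintf("  embedded sample metadata: %s\n",
                paste(colnames(x$metadata), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Subset the samples of an abundance table
#'
#' @param table an [abundance_table()].
#' @param samples integer or character vector of samples to keep, in the
#'   order requested.
#' @return An `abundance_table` restricted to those samples.
#' @keywords internal
#' @export
subset_samples <- function(table, samples) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.character(samples)) samples <- match(samples, table$sample_ids)
  if (anyNA(samples)) stop("unknown sample in subset")
  md <- table$metadata
  if (!is.null(md)) md <- md[table$sample_ids[samples], , drop = FALSE]
  abundance_table(table$counts[, samples, drop = FALSE],
                  feature_ids = table$feature_ids,
                  taxonomy = table$taxonomy,
                  sample_ids = table$sample_ids[samples],
                  metadata = md)
}

#' Construct a label vector
#'
#' Per-sample discrete phenotype values aligned to the columns of an
#' [abundance_table()].
#'
#' @param values character (or coercible) vector of class labels, one per
#'   sample.
#' @param sample_ids character vector of sample identifiers aligned to
#'   `values`.
#' @param classes ordered set of distinct labels; defaults to the sorted
#'   unique values.
#' @return An object of class `label_vector` with elements `values`,
#'   `classes`, `sample_ids`.
#' @export
label_vector <- function(values, sample_ids = names(values),
                         classes = sort(unique(as.character(values)))) {
  values <- as.character(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(values))
  sample_ids <- as.character(sample_ids)
  if (length(values) != length(sample_ids)) {
    stop("values and sample_ids differ in length")
  }
  if (length(classes) < 2L) stop("fewer than two classes")
  if (!all(values %in% classes)) stop("label value outside declared classes")
  structure(list(values = values, classes = classes,
                 sample_ids = sample_ids),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("label_vector: %d samples, classes: %s\n", length(x$values),
              paste(x$classes, collapse = ", ")))
  print(table(factor(x$values, levels = x$classes)))
  invisible(x)
}

#' Construct a selection result
#'
#' The ordered output of a selector: feature indices in selection order
#' (the "F1, F2, ..." rank), matching feature IDs and per-step scores.
#'
#' @param feature_indices integer vector of selected row indices, in
#'   selection order.
#' @param feature_ids character vector of the matching feature IDs.
#' @param scores numeric vector of per-step scores (objective value at
#'   selection time, selection counts for NPFS, coefficients for lasso).
#' @param method character, name of the selection method.
#' @param k the requested number of features (NA when the method sizes the
#'   set itself).
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(feature_indices, feature_ids, scores, method,
                             k = length(feature_indices)) {
  feature_indices <- as.integer(feature_indices)
  if (length(feature_ids) != length(feature_indices) ||
      length(scores) != length(feature_indices)) {
    stop("selection_result fields differ in length")
  }
  if (anyDuplicated(feature_indices)) stop("duplicate selected features")
  structure(list(feature_indices = feature_indices,
                 feature_ids = as.character(feature_ids),
                 scores = as.numeric(scores),
                 method = as.character(method), k = k),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d features\n", x$method,
              length(x$feature_indices)))
  n <- min(length(x$feature_indices), 10L)
  if (n > 0L) {
    print(data.frame(rank = seq_len(n),
                     feature_id = x$feature_ids[seq_len(n)],
                     score = signif(x$scores[seq_len(n)], 5)),
          row.names = FALSE)
    if (length(x$feature_indices) > n) cat("  ...\n")
  }
  invisible(x)
}

#' @export
length.selection_result <- function(x) length(x$feature_indices)
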