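#' Per-sample relative abundance
#'
#' Divides each sample column by its total count so columns sum to 1.
#'
#' @param table an [abundance_table()] or numeric feature-by-sample matrix.
#' @return Numeric `K x M` matrix of relative abundances.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "abundance_table")) table$counts else
    as.matrix(table)
  tot <- colSums(m)
  if (any(tot <= 0)) {
    bad <- colnames(m)[which(tot <= 0)] %||%
      as.character(which(tot <= 0))
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "))
  }
  sweep(m, 2L, tot, "/")
}

#' Between-class abundance differences of selected features
#'
#' For each selected feature, computes the mean relative abundance in each
#' of the two phenotype classes and their signed difference
#' (first class minus second class, classes ordered lexicographically), and
#' sorts the records by decreasing `|difference|`.  A negative difference
#' means the feature is on average more abundant in the second class.
#'
#' @param table an [abundance_table()].
#' @param labels a [label_vector()] with exactly two classes, aligned to
#'   the table.
#' @param selection a nonempty [selection_result()].
#' @param top_n keep only the `top_n` largest absolute differences;
#'   default all.
#' @return A data.frame of class `group_difference_report` with columns
#'   `feature_id`, `taxonomy`, `selection_rank`, one `mean_<class>` column
#'   per class, and `difference`; attribute `"sign_convention"` documents
#'   the sign.
#' @export
group_difference_report <- function(table, labels, selection,
                                    top_n = Inf) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(selection, "selection_result"))
  yv <- if (inherits(labels, "label_vector")) labels$values else
    as.character(labels)
  if (length(yv) != ncol(table$counts)) stop("labels not aligned to table")
  classes <- sort(unique(yv))
  if (length(classes) != 2L) {
    stop("the difference report is pairwise: need exactly two classes")
  }
  if (length(selection$feature_indices) == 0L) stop("empty selection")

  ra <- relative_abundance(table)
  idx <- selection$feature_indices
  m1 <- rowMeans(ra[idx, yv == classes[1], drop = FALSE])
  m2 <- rowMeans(ra[idx, yv == classes[2], drop = FALSE])
  out <- data.frame(feature_id = selection$feature_ids,
                    taxonomy = table$taxonomy[idx],
                    selection_rank = seq_along(idx),
                    m1 = m1, m2 = m2,
                    difference = m1 - m2,
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(out)[4:5] <- paste0("mean_", classes)
  out <- out[order(-abs(out$difference), out$selection_rank), , drop = FALSE]
  if (is.finite(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  attr(out, "sign_convention") <- sprintf(
    "difference = mean_%s - mean_%s (negative: higher in %s)",
    classes[1], classes[2], classes[2])
  class(out) <- c("group_difference_report", "data.frame")
  out
}

#' @export
print.group_difference_report <- function(x, ...) {
  cat("group_difference_report:", attr(x, "sign_convention"), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a difference report to TSV
#'
#' The sign convention is recorded as a leading `#` comment line.
#'
#' @param report a [group_difference_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_difference_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", attr(report, "sign_convention")), con)
  write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
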