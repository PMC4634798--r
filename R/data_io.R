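#' Read a BIOM abundance table
#'
#' Reads a BIOM 1.0 JSON table (`matrix_type` `"dense"` or `"sparse"`) or a
#' BIOM 2.1 HDF5 table and returns a densified [abundance_table()].
#' Taxonomy is populated from the observation metadata when present (list
#' values are joined with `"; "`).  Per-sample metadata embedded in the BIOM
#' file, if any, is attached as the table's `metadata` data.frame so that
#' [extract_labels()] can be used without a separate mapping file.
#'
#' @param path path to a `.biom` file.
#' @return An [abundance_table()].
#' @seealso [write_biom_table()], [read_mapping()], [extract_labels()]
#' @export
read_biom_table <- function(path) {
  if (!file.exists(path)) stop("BIOM file not found: ", path)
  b <- tryCatch({
    if (is_hdf5(path)) {
      biomformat::biom(biomformat::read_hdf5_biom(path))
    } else {
      biomformat::read_biom(path)
    }
  }, error = function(e) {
    stop("failed to parse BIOM file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  m <- as(biomformat::biom_data(b), "matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("BIOM file '", path, "' lacks row or column ids")
  }
  taxonomy <- join_observation_metadata(
    tryCatch(biomformat::observation_metadata(b), error = function(e) NULL),
    rownames(m))
  metadata <- normalize_sample_metadata(
    tryCatch(biomformat::sample_metadata(b), error = function(e) NULL),
    colnames(m))
  abundance_table(m, feature_ids = rownames(m), taxonomy = taxonomy,
                  sample_ids = colnames(m), metadata = metadata)
}

# HDF5 files open with an 8-byte magic number
is_hdf5 <- function(path) {
  magic <- readBin(path, "raw", n = 8L)
  length(magic) == 8L &&
    identical(magic, as.raw(c(0x89, 0x48, 0x44, 0x46, 0x0d, 0x0a, 0x1a, 0x0a)))
}

join_observation_metadata <- function(om, ids) {
  taxonomy <- rep("", length(ids))
  names(taxonomy) <- ids
  if (is.null(om)) return(unname(taxonomy))
  if (is.data.frame(om)) {
    cols <- grep("taxonomy", colnames(om), ignore.case = TRUE)
    if (length(cols) == 0L) cols <- seq_len(ncol(om))
    joined <- apply(om[, cols, drop = FALSE], 1L, function(r) {
      r <- as.character(r)
      paste(r[!is.na(r) & nzchar(r)], collapse = "; ")
    })
    taxonomy[rownames(om)] <- joined
  } else if (is.list(om)) {
    for (id in names(om)) {
      v <- om[[id]]
      if (is.null(v)) next
      if (is.list(v)) v <- v[["taxonomy"]] %||% unlist(v)
      v <- as.character(unlist(v))
      taxonomy[id] <- paste(v[!is.na(v) & nzchar(v)], collapse = "; ")
    }
  }
  unname(taxonomy)
}

normalize_sample_metadata <- function(sm, ids) {
  if (is.null(sm)) return(NULL)
  if (is.data.frame(sm)) {
    sm[] <- lapply(sm, as.character)
    return(sm[ids, , drop = FALSE])
  }
  if (is.list(sm)) {
    cols <- unique(unlist(lapply(sm, names)))
    if (is.null(cols)) return(NULL)
    out <- as.data.frame(
      lapply(cols, function(cn) {
        vapply(ids, function(id) {
          v <- sm[[id]][[cn]]
          if (is.null(v)) NA_character_ else as.character(v)
        }, character(1))
      }), optional = TRUE)
    colnames(out) <- cols
    rownames(out) <- ids
    return(out)
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an abundance table as BIOM 1.0 JSON
#'
#' Writes a dense BIOM 1.0 JSON file carrying counts, feature and sample
#' IDs, taxonomy (as observation metadata) and any embedded sample
#' metadata.  `read_biom_table(write_biom_table(x, p))` recovers `x`.
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biom_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  K <- nrow(table$counts); M <- ncol(table$counts)
  rows <- lapply(seq_len(K), function(i) {
    md <- if (nzchar(table$taxonomy[i])) {
      list(taxonomy = strsplit(table$taxonomy[i], "; ", fixed = TRUE)[[1]])
    } else NULL
    list(id = jsonlite::unbox(table$feature_ids[i]), metadata = md)
  })
  cols <- lapply(seq_len(M), function(j) {
    md <- NULL
    if (!is.null(table$metadata)) {
      rec <- table$metadata[table$sample_ids[j], , drop = FALSE]
      md <- lapply(as.list(rec), function(v) jsonlite::unbox(as.character(v)))
    }
    list(id = jsonlite::unbox(table$sample_ids[j]), metadata = md)
  })
  is_int <- all(table$counts == round(table$counts))
  data <- unname(lapply(seq_len(K), function(i) {
    v <- table$counts[i, ]
    if (is_int) as.integer(v) else as.numeric(v)
  }))
  doc <- list(
    id = jsonlite::unbox("none"),
    format = jsonlite::unbox("Biological Observation Matrix 1.0.0"),
    format_url = jsonlite::unbox("http://biom-format.org"),
    type = jsonlite::unbox("OTU table"),
    generated_by = jsonlite::unbox(
      paste0("otuselect ", as.character(utils::packageVersion("otuselect")))),
    date = jsonlite::unbox(format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    matrix_type = jsonlite::unbox("dense"),
    matrix_element_type = jsonlite::unbox(if (is_int) "int" else "float"),
    shape = c(K, M),
    rows = rows,
    columns = cols,
    data = data
  )
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a QIIME-style tab-delimited mapping file
#'
#' The first row is a header whose first column names the sample-ID column;
#' a leading `"#"` (the `#SampleID` dialect) is tolerated and stripped.
#' All values are kept as raw strings.
#'
#' @param path path to a TSV mapping file.
#' @return A data.frame of class `sample_metadata` with one row per sample,
#'   row names equal to the sample IDs, and one character column per
#'   metadata field.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("mapping file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  header[1] <- sub("^#", "", header[1])
  ncols <- length(header)
  if (ncols < 2L) stop("mapping file header has no metadata columns")
  body <- fields[-1]
  bad <- which(lengths(body) != ncols)
  if (length(bad) > 0L) {
    stop(sprintf("mapping file '%s': line %d has %d fields, expected %d",
                 path, bad[1] + 1L, lengths(body)[bad[1]], ncols))
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs in mapping file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- as.data.frame(do.call(rbind, lapply(body, `[`, -1L)),
                       optional = TRUE)
  colnames(out) <- header[-1]
  rownames(out) <- ids
  out[] <- lapply(out, as.character)
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Align a phenotype column to an abundance table
#'
#' Restricts the table to the samples that are present in the metadata with
#' a usable value in `column` (empty strings and `"NA"` are dropped, not
#' errored), preserving the table's sample order, and returns the aligned
#' label vector.
#'
#' @param table an [abundance_table()].
#' @param metadata a data.frame keyed by sample ID (from [read_mapping()]
#'   or the table's embedded metadata); `NULL` means use
#'   `table$metadata`.
#' @param column name of the phenotype column.
#' @param label_map optional named character vector recoding raw label
#'   values (`c(old = "new", ...)`), applied before the class check; use it
#'   to collapse multi-valued phenotypes to two classes.
#' @return A list with elements `table` (the restricted table) and
#'   `labels` (a [label_vector()]).
#' @export
extract_labels <- function(table, metadata = NULL, column,
                           label_map = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(metadata)) metadata <- table$metadata
  if (is.null(metadata)) {
    stop("no metadata: supply a mapping file or a BIOM file with ",
         "embedded sample metadata")
  }
  if (!column %in% colnames(metadata)) {
    stop("column '", column, "' not found in metadata (available: ",
         paste(colnames(metadata), collapse = ", "), ")")
  }
  values <- as.character(metadata[[column]])
  names(values) <- rownames(metadata)
  keep_ids <- intersect(table$sample_ids, rownames(metadata))
  if (length(keep_ids) == 0L) {
    stop("no overlapping samples between table and metadata")
  }
  v <- values[keep_ids]
  usable <- !is.na(v) & nzchar(v) & v != "NA"
  keep_ids <- keep_ids[usable]
  v <- v[usable]
  if (!is.null(label_map)) {
    hit <- v %in% names(label_map)
    v[hit] <- label_map[v[hit]]
  }
  if (length(unique(v)) < 2L) {
    stop("fewer than two classes in column '", column, "' after filtering")
  }
  # preserve the table's own sample order
  ord <- match(intersect(table$sample_ids, keep_ids), keep_ids)
  keep_ids <- keep_ids[ord]; v <- v[ord]
  tab <- subset_samples(table, keep_ids)
  list(table = tab,
       labels = label_vector(unname(v), sample_ids = keep_ids))
}

#' Write a ranked selection to TSV
#'
#' One row per selected feature, in selection order, with columns `rank`
#' (1-based), `feature_id`, `taxonomy` and `score`.
#'
#' @param result a [selection_result()].
#' @param table the [abundance_table()] the selection refers to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, table, path) {
  stopifnot(inherits(result, "selection_result"),
            inherits(table, "abundance_table"))
  idx <- result$feature_indices
  if (length(idx) > 0L &&
      (min(idx) < 1L || max(idx) > nrow(table$counts))) {
    stop("selected feature index out of range for table")
  }
  df <- data.frame(rank = seq_along(idx),
                   feature_id = result$feature_ids,
                   taxonomy = table$taxonomy[idx],
                   score = result$scores,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
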