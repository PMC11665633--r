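# Tabular input/output and taxonomic lineage parsing.
#
# TSV dialect: tab separator, no quoting, UTF-8, header required. Empty or
# "NA" abundance cells are errors -- the method has no missing-data
# semantics, and silent imputation would change rank statistics.

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE, na.strings = NULL,
                    fileEncoding = "UTF-8")
}

# Convert character columns of a feature table to a numeric matrix, erroring
# on any cell that does not parse as a finite number.
to_numeric_matrix <- function(df, feature_ids, path) {
  m <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df),
              dimnames = list(feature_ids, colnames(df)))
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    bad <- is.na(col) | col == "" | col == "NA"
    num <- suppressWarnings(as.numeric(col))
    bad <- bad | !is.finite(num)
    if (any(bad)) {
      stop("non-numeric or missing abundance in '", path, "', sample '",
           colnames(df)[j], "', feature '", feature_ids[which(bad)[1]], "'")
    }
    m[, j] <- num
  }
  m
}

#' Read a feature table and sample metadata from paired TSV files
#'
#' The feature table has feature ids in the first column and one column per
#' sample; the metadata file has a sample-id column (by default its first
#' column) plus named label columns.
#'
#' @param table_path Path to the feature-by-sample TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @param class_column Name of the metadata column holding the two-level class.
#' @param subclass_column Optional name of the subclass column.
#' @param sample_column Name of the metadata column holding sample ids;
#'   default the first column.
#' @param reference_level Optional class level to anchor negative scores.
#' @return A validated list with elements `table` ([abundance_table]) and
#'   `groups` ([sample_groups]).
#' @export
read_feature_table <- function(table_path, metadata_path, class_column,
                               subclass_column = NULL, sample_column = NULL,
                               reference_level = NULL) {
  tab <- read_tsv_raw(table_path)
  if (ncol(tab) < 2) stop("feature table needs a feature-id column plus samples")
  feature_ids <- tab[[1]]
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id(s) in ", table_path, ": ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  values <- to_numeric_matrix(tab[-1], feature_ids, table_path)

  meta <- read_tsv_raw(metadata_path)
  if (is.null(sample_column)) sample_column <- colnames(meta)[1]
  for (col in c(sample_column, class_column, subclass_column)) {
    if (!col %in% colnames(meta)) {
      stop("column '", col, "' not found in ", metadata_path)
    }
  }
  groups <- sample_groups(
    class_labels = meta[[class_column]],
    subclass_labels = if (is.null(subclass_column)) NULL else meta[[subclass_column]],
    sample_ids = meta[[sample_column]],
    reference_level = reference_level
  )
  validate_inputs(abundance_table(values), groups)
}

#' Read the classic LEfSe single-file format
#'
#' A single TSV in which designated leading rows carry the class labels,
#' optional subclass labels, and optional sample ids, and every remaining row
#' is a feature. The first cell of each row is the row's name.
#'
#' @param path Path to the file.
#' @param class_row 1-based row index of the class-label row. Default 1.
#' @param subclass_row Optional row index of the subclass row.
#' @param id_row Optional row index of the sample-id row; when absent, sample
#'   ids `S1..Sn` are generated.
#' @param reference_level Optional class level to anchor negative scores.
#' @return As [read_feature_table()].
#' @export
read_lefse_classic <- function(path, class_row = 1, subclass_row = NULL,
                               id_row = NULL, reference_level = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("classic-format file needs a class row and >=1 feature row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop("ragged row ", bad, " ('", cells[[bad]][1], "'): ", widths[bad],
         " columns, expected ", widths[1])
  }
  n_samp <- widths[1] - 1
  if (n_samp < 1) stop("no sample columns found")
  label_rows <- c(class_row, subclass_row, id_row)
  if (class_row > length(cells)) stop("class_row ", class_row, " out of range")
  row_values <- function(i) cells[[i]][-1]
  class_labels <- row_values(class_row)
  subclass_labels <- if (!is.null(subclass_row)) row_values(subclass_row) else NULL
  sample_ids <- if (!is.null(id_row)) row_values(id_row) else paste0("S", seq_len(n_samp))

  feat_idx <- setdiff(seq_along(cells), label_rows)
  if (length(feat_idx) == 0) stop("no feature rows")
  feature_ids <- vapply(cells[feat_idx], `[`, character(1), 1)
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id(s): ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  df <- as.data.frame(do.call(rbind, lapply(cells[feat_idx], `[`, -1)),
                      stringsAsFactors = FALSE)
  colnames(df) <- sample_ids
  values <- to_numeric_matrix(df, feature_ids, path)
  groups <- sample_groups(class_labels, subclass_labels,
                          sample_ids = sample_ids,
                          reference_level = reference_level)
  validate_inputs(abundance_table(values), groups)
}

#' Split a lineage-style feature id into rank names
#'
#' @param feature_id Nonempty string, e.g.
#'   `"k__Bacteria|p__Firmicutes|c__Clostridia"`. Rank prefixes are preserved
#'   verbatim, never interpreted.
#' @param separator Separator between ranks; `"|"` (default) or `"; "`.
#' @return Character vector of rank names, root first.
#' @examples
#' parse_lineage("k__Bacteria|p__Firmicutes")
#' @export
parse_lineage <- function(feature_id, separator = "|") {
  if (!is.character(feature_id) || length(feature_id) != 1 || !nzchar(feature_id)) {
    stop("feature_id must be a single nonempty string")
  }
  parts <- strsplit(feature_id, separator, fixed = TRUE)[[1]]
  if (length(parts) == 0 || any(!nzchar(parts))) {
    stop("empty lineage component in '", feature_id, "'")
  }
  parts
}

#' Write marker results to TSV
#'
#' Writes a two-column TSV with the exact header `features<TAB>scores`. Scores
#' are rendered with enough significant digits that [read_results()] recovers
#' them to printing precision.
#'
#' @param result A marker-result data frame with columns `features`, `scores`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(is.data.frame(result),
            all(c("features", "scores") %in% colnames(result)))
  lines <- c("features\tscores",
             if (nrow(result) > 0) {
               paste(result$features, sprintf("%.10g", result$scores), sep = "\t")
             })
  # write to a sibling temp file then rename: no partial file on error
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp, useBytes = TRUE)
  if (!file.rename(tmp, path)) stop("cannot write ", path)
  invisible(path)
}

#' Read marker results written by [write_results()]
#'
#' @param path Path to a results TSV with `features` and `scores` columns.
#' @return A `marker_result` data frame.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("features", "scores") %in% colnames(df))) {
    stop("not a results file (expected 'features' and 'scores' columns): ", path)
  }
  marker_result(data.frame(features = as.character(df$features),
                           scores = as.numeric(df$scores),
                           stringsAsFactors = FALSE))
}
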