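# Core domain types: abundance table, sample grouping, pipeline configuration.

#' Construct an abundance table
#'
#' A feature-by-sample matrix of nonnegative relative abundances or scaled
#' counts, with unique feature and sample identifiers. Feature identifiers may
#' be pipe-delimited taxonomic lineages (e.g. `k__Bacteria|p__Firmicutes`).
#'
#' @param values Numeric matrix, features in rows, samples in columns. All
#'   entries must be finite and nonnegative; every sample column must have a
#'   positive sum.
#' @param feature_ids Character vector of unique feature identifiers
#'   (default: `rownames(values)`).
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: `colnames(values)`).
#' @return An object of class `abundance_table`: the validated matrix with
#'   feature ids as rownames and sample ids as colnames.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
#'             dimnames = list(c("fA", "fB"), c("s1", "s2", "s3")))
#' abundance_table(m)
#' @export
abundance_table <- function(values,
                            feature_ids = rownames(values),
                            sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (features x samples)")
  }
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("feature and sample identifiers are required (dimnames or explicit)")
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values)) {
    stop("length of feature_ids (", length(feature_ids),
         ") does not match number of rows (", nrow(values), ")")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length of sample_ids (", length(sample_ids),
         ") does not match number of columns (", ncol(values), ")")
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("abundance values must be finite (no NA/NaN/Inf)")
  if (any(values < 0)) stop("negative abundance values are not allowed")
  cs <- colSums(values)
  if (any(cs <= 0)) {
    stop("sample column(s) with non-positive total abundance: ",
         paste(sample_ids[cs <= 0], collapse = ", "))
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", nrow(x), " features x ", ncol(x), " samples\n", sep = "")
  invisible(x)
}

#' Construct per-sample class (and optional subclass) labels
#'
#' Class labels must have exactly two levels; the reference level is mapped to
#' negative effect-size scores downstream. By default the reference level is
#' the first level in order of first appearance, which keeps the sign
#' convention deterministic without locale-dependent sorting.
#'
#' @param class_labels Character or factor vector of per-sample class labels.
#' @param subclass_labels Optional per-sample subclass labels. Empty strings or
#'   missing values are an error: the strict consistency screen has no
#'   semantics for an "unlabelled" stratum.
#' @param sample_ids Sample identifiers, aligned with the labels (default:
#'   `names(class_labels)`).
#' @param reference_level Which class level anchors the negative score sign;
#'   defaults to the first level in order of appearance.
#' @return An object of class `sample_groups`, a list with elements
#'   `sample_ids`, `class_labels` (factor, reference level first),
#'   `subclass_labels` (factor or `NULL`), and `reference_level`.
#' @examples
#' sample_groups(c(s1 = "ctrl", s2 = "ctrl", s3 = "case", s4 = "case"))
#' @export
sample_groups <- function(class_labels, subclass_labels = NULL,
                          sample_ids = names(class_labels),
                          reference_level = NULL) {
  if (is.null(sample_ids)) {
    stop("sample ids are required (names on class_labels or explicit)")
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(class_labels)) {
    stop("sample_ids and class_labels lengths differ")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in groups")
  cls <- as.character(class_labels)
  if (any(is.na(cls) | cls == "")) stop("missing or empty class labels")
  lev <- unique(cls)  # order of first appearance
  if (length(lev) != 2) {
    stop("exactly two classes required, found ", length(lev), ": ",
         paste(lev, collapse = ", "))
  }
  if (!is.null(reference_level)) {
    if (!reference_level %in% lev) {
      stop("reference_level '", reference_level, "' is not a class level")
    }
    lev <- c(reference_level, setdiff(lev, reference_level))
  }
  cls <- factor(cls, levels = lev)
  sub <- NULL
  if (!is.null(subclass_labels)) {
    sub <- as.character(subclass_labels)
    if (length(sub) != length(sample_ids)) {
      stop("subclass_labels length differs from sample count")
    }
    if (any(is.na(sub) | sub == "")) {
      stop("missing or empty subclass labels (remove the column or label every sample)")
    }
    sub <- factor(sub, levels = unique(sub))
  }
  structure(
    list(sample_ids = sample_ids, class_labels = cls,
         subclass_labels = sub, reference_level = lev[1]),
    class = "sample_groups"
  )
}

#' @export
print.sample_groups <- function(x, ...) {
  cat("<sample_groups> ", length(x$sample_ids), " samples; classes: ",
      paste(levels(x$class_labels), collapse = " vs "),
      " (reference: ", x$reference_level, ")",
      if (!is.null(x$subclass_labels)) {
        paste0("; subclasses: ", paste(levels(x$subclass_labels), collapse = ", "))
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' Pipeline configuration
#'
#' Tuning parameters of the biomarker-discovery pipeline. Defaults follow the
#' conventional LEfSe settings: alpha 0.05 for both rank-test screens, a
#' minimum absolute LDA score of 2.0, and no multiple-testing correction.
#'
#' @param kruskal_threshold Significance level for the per-feature
#'   Kruskal-Wallis class screen; in (0, 1). Default 0.05.
#' @param wilcox_threshold Significance level for each Wilcoxon subclass
#'   comparison; in (0, 1). Default 0.05.
#' @param lda_threshold Minimum absolute LDA score reported; nonnegative.
#'   Default 2.0 which, at the default `scale_constant`, corresponds to a raw
#'   effect size of 100 in scaled relative-abundance units.
#' @param adjust_method Multiple-testing correction applied to each screen;
#'   one of `"none"`, `"holm"`, `"hochberg"`, `"hommel"`, `"bonferroni"`,
#'   `"BH"`, `"BY"`, `"fdr"`. Default `"none"`.
#' @param effect_mode `"projection"` (default): per-feature absolute effect is
#'   the between-class discriminant-score gap times the feature's absolute
#'   unit-normalized coefficient. `"averaged"`: compatibility variant taking
#'   the mean of that quantity and the absolute between-class feature-mean
#'   difference.
#' @param scale_constant Per-sample total after rescaling; default 1e6
#'   (counts per million).
#' @return An object of class `pipeline_config` (a validated list).
#' @examples
#' pipeline_config(adjust_method = "BH")
#' @export
pipeline_config <- function(kruskal_threshold = 0.05,
                            wilcox_threshold = 0.05,
                            lda_threshold = 2.0,
                            adjust_method = "none",
                            effect_mode = c("projection", "averaged"),
                            scale_constant = 1e6) {
  effect_mode <- match.arg(effect_mode)
  stopifnot(is.numeric(kruskal_threshold), length(kruskal_threshold) == 1,
            is.numeric(wilcox_threshold), length(wilcox_threshold) == 1,
            is.numeric(lda_threshold), length(lda_threshold) == 1,
            is.numeric(scale_constant), length(scale_constant) == 1)
  if (kruskal_threshold <= 0 || kruskal_threshold >= 1) {
    stop("kruskal_threshold must be in (0, 1)")
  }
  if (wilcox_threshold <= 0 || wilcox_threshold >= 1) {
    stop("wilcox_threshold must be in (0, 1)")
  }
  if (lda_threshold < 0) stop("lda_threshold must be >= 0")
  if (scale_constant <= 0) stop("scale_constant must be positive")
  adjust_method <- validate_adjust_method(adjust_method)
  structure(
    list(kruskal_threshold = kruskal_threshold,
         wilcox_threshold = wilcox_threshold,
         lda_threshold = lda_threshold,
         adjust_method = adjust_method,
         effect_mode = effect_mode,
         scale_constant = scale_constant),
    class = "pipeline_config"
  )
}

# Supported p.adjust families; "fdr" is an alias of "BH" in stats::p.adjust.
validate_adjust_method <- function(method) {
  ok <- c("none", "holm", "hochberg", "hommel", "bonferroni", "BH", "BY", "fdr")
  if (!is.character(method) || length(method) != 1 || !method %in% ok) {
    stop("unknown adjust method '", paste(method, collapse = ","),
         "'; must be one of: ", paste(ok, collapse = ", "))
  }
  method
}

#' Validate and align an abundance table with its sample metadata
#'
#' Reorders the grouping information to match the table's sample order,
#' dropping metadata rows for samples not present in the table. Every table
#' sample must be covered by the metadata. Idempotent: validating an already
#' validated pair changes nothing.
#'
#' @param table An [abundance_table].
#' @param groups A [sample_groups] covering at least the table's samples.
#' @return A list with elements `table` and `groups`, aligned by sample id.
#' @export
validate_inputs <- function(table, groups) {
  if (!inherits(table, "abundance_table")) table <- abundance_table(table)
  if (!inherits(groups, "sample_groups")) {
    stop("'groups' must be a sample_groups object")
  }
  idx <- match(colnames(table), groups$sample_ids)
  if (anyNA(idx)) {
    stop("sample(s) in table missing from groups: ",
         paste(colnames(table)[is.na(idx)], collapse = ", "))
  }
  aligned <- sample_groups(
    class_labels = as.character(groups$class_labels)[idx],
    subclass_labels = if (is.null(groups$subclass_labels)) NULL else
      as.character(groups$subclass_labels)[idx],
    sample_ids = groups$sample_ids[idx],
    reference_level = groups$reference_level
  )
  counts <- table(aligned$class_labels)
  if (any(counts < 2)) {
    stop("each class needs at least 2 samples; counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  list(table = table, groups = aligned)
}
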