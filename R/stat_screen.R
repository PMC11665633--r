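# Nonparametric screening: Kruskal-Wallis across classes, Wilcoxon rank-sum
# across subclass strata with strict sign consistency, p-value adjustment.
#
# Both tests use the asymptotic (chi-squared / normal) p-values with tie
# correction, matching the defaults of the stock implementations they mirror;
# exact permutation tests are out of scope and the approximation error at
# small n is documented in the methods vignette.

#' Adjust a vector of p-values
#'
#' Thin, validated wrapper around [stats::p.adjust()] restricted to the
#' supported family. `"none"` is the identity; every other method is
#' pointwise no smaller than the input.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @param method One of `"none"`, `"holm"`, `"hochberg"`, `"hommel"`,
#'   `"bonferroni"`, `"BH"`, `"BY"`, `"fdr"`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p_values, method = "none") {
  method <- validate_adjust_method(method)
  stopifnot(is.numeric(p_values))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  if (method == "none") return(p_values)
  stats::p.adjust(p_values, method = method)
}

# Standardized Wilcoxon rank-sum statistic with tie-corrected variance and no
# continuity correction. z is computed from the rank-sum of `x`, so z < 0
# means x tends to be smaller than y. Zero-variance data give z = 0, p = 1.
ranksum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  e <- n1 * (n + 1) / 2
  ties <- table(r)
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) return(list(z = 0, p_value = 1))
  z <- (w - e) / sqrt(v)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Kruskal-Wallis class screen
#'
#' Tests each feature for a distributional difference between the two classes
#' with the tie-corrected Kruskal-Wallis statistic (chi-squared reference,
#' df = 1). Constant features carry no rank information and short-circuit to
#' p = 1. A feature is retained when its (optionally adjusted) p-value is
#' strictly below `alpha`; adjustment is applied across all features.
#'
#' @param table An [abundance_table].
#' @param groups A [sample_groups] aligned with the table.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param adjust_method Multiple-testing correction; default `"none"`.
#' @return A data frame with columns `feature_id`, `statistic`, `p_value`,
#'   `p_adjusted`, `retained`.
#' @export
kruskal_wallis_screen <- function(table, groups, alpha = 0.05,
                                  adjust_method = "none") {
  v <- validate_inputs(table, groups)
  table <- v$table; groups <- v$groups
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  cls <- groups$class_labels
  stat <- p <- numeric(nrow(table))
  for (i in seq_len(nrow(table))) {
    x <- table[i, ]
    if (length(unique(x)) < 2) {  # constant feature: no rank information
      stat[i] <- 0; p[i] <- 1
    } else {
      k <- stats::kruskal.test(x, cls)
      stat[i] <- unname(k$statistic)
      p[i] <- if (is.finite(k$p.value)) k$p.value else 1
    }
  }
  padj <- adjust_pvalues(p, adjust_method)
  data.frame(feature_id = rownames(table), statistic = stat, p_value = p,
             p_adjusted = padj, retained = padj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Strict sign-consistent Wilcoxon subclass screen
#'
#' For every cross-class pair of subclass strata -- each subclass stratum
#' observed in the reference class against each stratum observed in the other
#' class -- computes the standardized rank-sum z (normal approximation, tie
#' corrected, no continuity correction) and its two-sided p-value. A feature
#' survives only if every pairwise comparison is significant at `alpha`
#' (after within-feature adjustment) AND all z-scores share one sign: the
#' "strict" multiclass strategy. Without subclass labels the screen is an
#' identity pass-through.
#'
#' Strata empty within a class are skipped; a feature with no valid stratum
#' pair falls back to the class-level decision (it survives).
#'
#' @param table An [abundance_table].
#' @param groups A [sample_groups]; subclass labels optional.
#' @param retained_features Feature ids that passed the class screen.
#' @param alpha Per-comparison significance level; default 0.05.
#' @param adjust_method Correction applied within each feature's set of
#'   pairwise comparisons; default `"none"`.
#' @return A list with `features` (surviving ids, in input order) and
#'   `comparisons` (data frame: `feature_id`, `stratum_ref`, `stratum_other`,
#'   `z_score`, `p_value`, `p_adjusted`).
#' @export
wilcoxon_subclass_screen <- function(table, groups, retained_features,
                                     alpha = 0.05, adjust_method = "none") {
  v <- validate_inputs(table, groups)
  table <- v$table; groups <- v$groups
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  retained_features <- intersect(rownames(table), retained_features)
  empty_cmp <- data.frame(feature_id = character(), stratum_ref = character(),
                          stratum_other = character(), z_score = numeric(),
                          p_value = numeric(), p_adjusted = numeric(),
                          stringsAsFactors = FALSE)
  if (is.null(groups$subclass_labels)) {
    return(list(features = retained_features, comparisons = empty_cmp))
  }
  cls <- groups$class_labels
  sub <- groups$subclass_labels
  ref <- levels(cls)[1]
  idx_ref <- which(cls == ref)
  idx_oth <- which(cls != ref)
  strata_ref <- unique(as.character(sub[idx_ref]))
  strata_oth <- unique(as.character(sub[idx_oth]))

  surviving <- character(0)
  cmp_list <- list()
  for (f in retained_features) {
    x <- table[f, ]
    zs <- ps <- numeric(0); sr <- so <- character(0)
    for (a in strata_ref) {
      ia <- idx_ref[sub[idx_ref] == a]
      if (length(ia) < 1) next
      for (b in strata_oth) {
        ib <- idx_oth[sub[idx_oth] == b]
        if (length(ib) < 1) next
        t <- ranksum_z(x[ia], x[ib])
        zs <- c(zs, t$z); ps <- c(ps, t$p_value)
        sr <- c(sr, a); so <- c(so, b)
      }
    }
    if (length(zs) == 0) {  # no valid pair: class-level decision stands
      surviving <- c(surviving, f)
      next
    }
    padj <- adjust_pvalues(ps, adjust_method)
    cmp_list[[f]] <- data.frame(feature_id = f, stratum_ref = sr,
                                stratum_other = so, z_score = zs,
                                p_value = ps, p_adjusted = padj,
                                stringsAsFactors = FALSE)
    sig <- all(padj < alpha)
    consistent <- all(zs > 0) || all(zs < 0)
    if (sig && consistent) surviving <- c(surviving, f)
  }
  comparisons <- if (length(cmp_list)) {
    r <- do.call(rbind, cmp_list); rownames(r) <- NULL; r
  } else empty_cmp
  list(features = surviving, comparisons = comparisons)
}
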