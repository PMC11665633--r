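# Scaling, degenerate-feature filtering, direct two-class LDA, effect sizes,
# the log10 score transform, the end-to-end pipeline, and the bootstrap
# reference estimator used only for comparison experiments.

#' Rescale every sample to a fixed total
#'
#' Divides each sample column by its sum and multiplies by `scale_constant`
#' (default one million), so inputs may be proportions or counts
#' interchangeably: the pipeline is invariant to per-sample scale.
#'
#' @param table An [abundance_table] with positive column sums.
#' @param scale_constant Target per-sample total; default 1e6.
#' @return The rescaled [abundance_table].
#' @export
normalize_per_million <- function(table, scale_constant = 1e6) {
  if (!inherits(table, "abundance_table")) table <- abundance_table(table)
  if (scale_constant <= 0) stop("scale_constant must be positive")
  cs <- colSums(table)
  if (any(cs <= 0)) {
    stop("zero-sum sample column(s): ",
         paste(colnames(table)[cs <= 0], collapse = ", "))
  }
  abundance_table(sweep(unclass(table), 2, cs / scale_constant, "/"))
}

#' Drop degenerate features
#'
#' Removes features that would make the within-class scatter singular or that
#' carry no information: all-zero features, zero-variance (constant)
#' features, and exact duplicate rows (the first occurrence in input order is
#' kept). This filtering replaces the random-noise injection of older
#' implementations; collinear features in practice are those rarely or never
#' observed.
#'
#' @param table An [abundance_table].
#' @return A list with `table` (the filtered [abundance_table]) and `dropped`
#'   (character vector of removed feature ids, possibly empty).
#' @export
filter_degenerate <- function(table) {
  if (!inherits(table, "abundance_table")) table <- abundance_table(table)
  m <- unclass(table)
  const <- apply(m, 1, function(x) all(x == x[1]))  # covers all-zero rows
  dup <- duplicated(split(m, row(m)))
  drop <- const | dup
  if (all(drop)) stop("all features are degenerate (constant or duplicated)")
  list(table = abundance_table(m[!drop, , drop = FALSE]),
       dropped = rownames(m)[drop])
}

#' Fit a two-class linear discriminant
#'
#' Direct full-data LDA: the discriminant direction is
#' `w = solve(S_w, mu1 - mu0)` with `S_w` the pooled within-class scatter
#' matrix, returned unit-normalized. No subsampling, no noise injection, no
#' random number generation. If the scatter solve fails, the error names the
#' candidate collinear features (those beyond the numerical rank of `S_w`).
#'
#' @param table A filtered, scaled [abundance_table].
#' @param groups A [sample_groups]; both classes need >= 2 samples.
#' @param tol Relative tolerance for the scatter solve; default 1e-10.
#' @return An object of class `lda_fit`: a list with `w_unit` (named
#'   unit-norm coefficient vector), `delta_ld` (absolute difference between
#'   the two class means of the discriminant scores), `class_feature_means`
#'   (2 x n_features matrix, reference class first), and `class_levels`.
#' @export
fit_two_class_lda <- function(table, groups, tol = 1e-10) {
  v <- validate_inputs(table, groups)
  x <- t(unclass(v$table))                       # samples x features
  cls <- v$groups$class_labels
  lev <- levels(cls)
  x0 <- x[cls == lev[1], , drop = FALSE]
  x1 <- x[cls == lev[2], , drop = FALSE]
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  sw <- crossprod(sweep(x0, 2, mu0)) + crossprod(sweep(x1, 2, mu1))
  d <- mu1 - mu0
  w <- tryCatch(
    solve(sw, d, tol = tol),
    error = function(e) {
      q <- qr(sw, tol = tol)
      bad <- colnames(x)[q$pivot[seq_len(ncol(x))[-seq_len(q$rank)]]]
      stop("within-class scatter is numerically singular; candidate ",
           "collinear features: ", paste(bad, collapse = ", "),
           " (filter or remove them)", call. = FALSE)
    }
  )
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("degenerate discriminant (identical class means)")
  w_unit <- w / nrm
  means <- rbind(mu0, mu1)
  rownames(means) <- lev
  structure(
    list(w_unit = stats::setNames(w_unit, colnames(x)),
         delta_ld = abs(sum(w_unit * d)),
         class_feature_means = means,
         class_levels = lev),
    class = "lda_fit"
  )
}

# Effect sizes from an arbitrary unit coefficient vector plus class means.
# Shared by the direct fit and the bootstrap-substitution experiments; for a
# genuine fit delta_ld equals |w . (mu1 - mu0)| and may be passed through.
effects_from_w <- function(w_unit, class_feature_means,
                           mode = c("projection", "averaged"),
                           delta_ld = NULL) {
  mode <- match.arg(mode)
  d <- class_feature_means[2, ] - class_feature_means[1, ]  # non-ref minus ref
  if (is.null(delta_ld)) delta_ld <- abs(sum(w_unit * d))
  mag <- delta_ld * abs(w_unit)
  if (mode == "averaged") mag <- (abs(d) + mag) / 2
  data.frame(feature_id = names(w_unit),
             raw_effect = sign(d) * mag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-feature signed effect sizes from an LDA fit
#'
#' In `"projection"` mode (default) the absolute effect of feature *i* is
#' `delta_ld * |w_unit[i]|`: the between-class gap of discriminant scores
#' scaled by the feature's unit-normalized coefficient. `"averaged"` is a
#' compatibility variant averaging this with the absolute between-class
#' feature-mean difference. In both modes the sign is that of the
#' non-reference-class mean minus the reference-class mean.
#'
#' @param fit An `lda_fit` from [fit_two_class_lda()].
#' @param mode `"projection"` or `"averaged"`.
#' @return Data frame with columns `feature_id`, `raw_effect`.
#' @export
compute_effect_sizes <- function(fit, mode = c("projection", "averaged")) {
  stopifnot(inherits(fit, "lda_fit"))
  effects_from_w(fit$w_unit, fit$class_feature_means, match.arg(mode),
                 delta_ld = fit$delta_ld)
}

marker_result <- function(df, class_levels = NULL) {
  stopifnot(is.data.frame(df), all(c("features", "scores") %in% colnames(df)))
  structure(df, class = c("marker_result", "data.frame"),
            class_levels = class_levels)
}

#' Transform effect sizes to LDA scores and apply the reporting threshold
#'
#' The LDA score is `sign(raw) * log10(|raw|)`. Features with zero raw effect
#' are excluded before the transform; features with `|score| >=
#' lda_threshold` are kept (the comparison is inclusive), ordered by
#' descending score with ties broken by feature id.
#'
#' @param effects Data frame with `feature_id` and `raw_effect` columns.
#' @param lda_threshold Minimum absolute score reported; default 2.0, which
#'   corresponds to an absolute raw effect of 100 in scaled-abundance units.
#' @param class_levels Optional two class names (reference first) attached to
#'   the result for plotting.
#' @return A `marker_result` data frame with columns `features`, `scores`.
#' @export
score_and_threshold <- function(effects, lda_threshold = 2.0,
                                class_levels = NULL) {
  stopifnot(is.data.frame(effects),
            all(c("feature_id", "raw_effect") %in% colnames(effects)))
  raw <- effects$raw_effect
  keep <- raw != 0
  score <- sign(raw[keep]) * log10(abs(raw[keep]))
  id <- effects$feature_id[keep]
  keep2 <- abs(score) >= lda_threshold
  score <- score[keep2]; id <- id[keep2]
  ord <- order(-score, id)
  marker_result(data.frame(features = id[ord], scores = score[ord],
                           stringsAsFactors = FALSE),
                class_levels = class_levels)
}

#' @export
print.marker_result <- function(x, ...) {
  cat("<marker_result> ", nrow(x), " feature(s)\n", sep = "")
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Run the full biomarker-discovery pipeline
#'
#' Composition of: per-sample rescaling, degenerate-feature filtering, the
#' Kruskal-Wallis class screen, the strict Wilcoxon subclass screen (when
#' subclass labels are present), direct full-data LDA restricted to the
#' surviving features, effect-size computation, and score thresholding. The
#' whole path is deterministic -- it neither reads nor writes random number
#' generator state -- so no seed is needed and repeated runs are identical.
#'
#' @param table An [abundance_table] (counts or proportions; rescaled
#'   internally).
#' @param groups A [sample_groups].
#' @param config A [pipeline_config].
#' @return A `marker_result` data frame (`features`, `scores`); zero
#'   surviving features yield an empty result, not an error. Attributes
#'   `dropped` (filtered feature ids) and `class_levels` are attached.
#' @examples
#' sim <- generate_synthetic(synthetic_spec(n_features = 40, seed = 7))
#' run_lefse(sim$table, sim$groups)
#' @export
run_lefse <- function(table, groups, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- validate_inputs(table, groups)
  st <- pipeline_survivors(v$table, v$groups, config)
  lev <- levels(v$groups$class_labels)
  if (length(st$features) == 0) {
    res <- marker_result(data.frame(features = character(), scores = numeric(),
                                    stringsAsFactors = FALSE),
                         class_levels = lev)
    attr(res, "dropped") <- st$dropped
    return(res)
  }
  sub <- abundance_table(unclass(st$table)[st$features, , drop = FALSE])
  fit <- fit_two_class_lda(sub, v$groups)
  eff <- compute_effect_sizes(fit, config$effect_mode)
  res <- score_and_threshold(eff, config$lda_threshold, class_levels = lev)
  attr(res, "dropped") <- st$dropped
  res
}

# Shared front half of the pipeline: scale, filter, screen.
# Returns the scaled filtered table plus the surviving feature ids.
pipeline_survivors <- function(table, groups, config) {
  scaled <- normalize_per_million(table, config$scale_constant)
  filt <- filter_degenerate(scaled)
  kw <- kruskal_wallis_screen(filt$table, groups,
                              alpha = config$kruskal_threshold,
                              adjust_method = config$adjust_method)
  retained <- kw$feature_id[kw$retained]
  wx <- wilcoxon_subclass_screen(filt$table, groups, retained,
                                 alpha = config$wilcox_threshold,
                                 adjust_method = config$adjust_method)
  list(table = filt$table, features = wx$features, dropped = filt$dropped,
       kw = kw, comparisons = wx$comparisons)
}

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring
# (or removing) the caller's global .Random.seed afterwards. Keeps every
# stochastic operation explicit-seed-only, with no global side effects.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Bootstrap-averaged LDA coefficients (reference estimator)
#'
#' Reproduces, for comparison experiments only, the subsample-averaging
#' strategy of the original tool: fit the discriminant on `n_boot` random
#' subsets of `fraction` of the samples (without replacement, each subset
#' keeping >= 2 samples per class, with bounded retries), unit-normalize each
#' coefficient vector, sign-align it to the direct full-data fit, and
#' average. The main pipeline never uses this path.
#'
#' @param table A scaled, filtered [abundance_table].
#' @param groups A [sample_groups].
#' @param n_boot Number of subsample iterations; default 30.
#' @param fraction Fraction of samples drawn per iteration; default 2/3.
#'   `fraction = 1` makes every replicate the full fit.
#' @param seed Integer seed for the private RNG stream (required; this
#'   estimator is the only stochastic step in the package).
#' @param max_retries Resampling retries per iteration before giving up.
#' @return List with `w_boot` (mean of sign-aligned unit coefficient
#'   vectors), `w_direct` (the direct full-data unit coefficients),
#'   `replicates` (n_boot x n_features matrix of aligned unit coefficients),
#'   `n_boot`, and `fraction`.
#' @export
bootstrap_lda <- function(table, groups, n_boot = 30, fraction = 2/3, seed,
                          max_retries = 1000) {
  if (missing(seed)) stop("an explicit seed is required for bootstrap_lda")
  stopifnot(n_boot >= 1, fraction > 0, fraction <= 1)
  v <- validate_inputs(table, groups)
  direct <- fit_two_class_lda(v$table, v$groups)
  cls <- v$groups$class_labels
  n <- length(cls)
  k <- max(4L, floor(fraction * n))
  reps <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_boot, ncol = length(direct$w_unit),
                  dimnames = list(NULL, names(direct$w_unit)))
    for (b in seq_len(n_boot)) {
      ok <- FALSE
      for (r in seq_len(max_retries)) {
        idx <- sample.int(n, k)
        ct <- tabulate(cls[idx], nbins = 2)  # both classes must keep >= 2
        if (all(ct >= 2)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw a subsample with >= 2 samples per class")
      sub_tab <- abundance_table(unclass(v$table)[, idx, drop = FALSE])
      sub_grp <- sample_groups(as.character(cls)[idx],
                               sample_ids = v$groups$sample_ids[idx],
                               reference_level = v$groups$reference_level)
      w <- fit_two_class_lda(sub_tab, sub_grp)$w_unit
      if (sum(w * direct$w_unit) < 0) w <- -w  # sign-align before averaging
      out[b, ] <- w
    }
    out
  })
  list(w_boot = colMeans(reps), w_direct = direct$w_unit,
       replicates = reps, n_boot = n_boot, fraction = fraction)
}
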