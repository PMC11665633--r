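# Synthetic compositional data with spike-in ground truth, the bootstrap
# stability experiment, and the ranked TP-minus-FP evaluation statistic.

#' Specification for the synthetic-data generator
#'
#' Describes a compositional (per-sample sum-constrained) community with
#' log-normal latent abundances, a configurable number of spiked
#' differentially abundant features of known direction, optional subclass
#' structure, and structural zeros.
#'
#' @param n_features Total number of features; default 100.
#' @param n_samples_per_class Pair of per-class sample counts; default
#'   `c(30, 30)`.
#' @param n_spiked Number of truly differential features; default 10.
#'   Directions alternate between the two classes.
#' @param fold_change Multiplicative effect applied to spiked features in
#'   their enriched class; must be >= 1. Default 4.
#' @param subclass_count Subclass strata per class (0 = no subclass labels);
#'   default 0.
#' @param sparsity Fraction of structurally-zero entries among non-spiked
#'   features, in \[0, 1); default 0.2.
#' @param base_log_mean,base_log_sd Mean and SD on the log scale of the
#'   latent per-feature baselines and sample noise; defaults 0 and 1.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_features = 100, n_samples_per_class = c(30, 30),
                           n_spiked = 10, fold_change = 4,
                           subclass_count = 0, sparsity = 0.2,
                           base_log_mean = 0, base_log_sd = 1, seed = 1) {
  stopifnot(n_features >= 2, length(n_samples_per_class) == 2,
            all(n_samples_per_class >= 2))
  if (n_spiked > n_features) stop("n_spiked must be <= n_features")
  if (fold_change < 1) stop("fold_change must be >= 1")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  if (subclass_count < 0) stop("subclass_count must be >= 0")
  structure(
    list(n_features = as.integer(n_features),
         n_samples_per_class = as.integer(n_samples_per_class),
         n_spiked = as.integer(n_spiked), fold_change = fold_change,
         subclass_count = as.integer(subclass_count), sparsity = sparsity,
         base_log_mean = base_log_mean, base_log_sd = base_log_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic abundance dataset with known ground truth
#'
#' Latent abundances are log-normal around per-feature baselines; spiked
#' features are multiplied by `fold_change` in their enriched class;
#' structural zeros are injected at the sparsity rate, sparing spiked
#' features so the ground truth stays well defined; columns are closed to
#' proportions. When `subclass_count > 0`, each class is split evenly into
#' strata and a small per-feature multiplicative shift, shared across
#' classes, distinguishes the strata (so the strict consistency screen is
#' exercised without breaking the spiked signal).
#'
#' @param spec A [synthetic_spec].
#' @return List with `table` (an [abundance_table] of proportions), `groups`
#'   (a [sample_groups] with classes `ctrl`/`case`, `ctrl` as reference), and
#'   `truth` (data frame: `feature_id`, `direction` with `+1` = enriched in
#'   `case`, `-1` = enriched in `ctrl`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n0 <- spec$n_samples_per_class[1]; n1 <- spec$n_samples_per_class[2]
  n <- n0 + n1; p <- spec$n_features
  fid <- sprintf("feat%03d", seq_len(p))
  sid <- sprintf("sample%03d", seq_len(n))
  cls <- rep(c("ctrl", "case"), c(n0, n1))
  with_seed(spec$seed, {
    logm <- matrix(stats::rnorm(p * n, spec$base_log_mean, spec$base_log_sd),
                   p, n)
    truth_dir <- integer(0)
    if (spec$n_spiked > 0) {
      truth_dir <- rep_len(c(1L, -1L), spec$n_spiked)
      for (i in seq_len(spec$n_spiked)) {
        enriched <- if (truth_dir[i] > 0) cls == "case" else cls == "ctrl"
        logm[i, enriched] <- logm[i, enriched] + log(spec$fold_change)
      }
    }
    sub <- NULL
    if (spec$subclass_count > 0) {
      sub <- character(n)
      sub[cls == "ctrl"] <- paste0("sub", rep_len(seq_len(spec$subclass_count), n0))
      sub[cls == "case"] <- paste0("sub", rep_len(seq_len(spec$subclass_count), n1))
      # per-feature stratum shift, common to both classes: consistent with
      # the spiked signal, so strict screening can pass for true markers
      shift <- matrix(stats::rnorm(p * spec$subclass_count, 0, 0.2),
                      p, spec$subclass_count)
      for (j in seq_len(spec$subclass_count)) {
        logm[, sub == paste0("sub", j)] <-
          logm[, sub == paste0("sub", j)] + shift[, j]
      }
    }
    m <- exp(logm)
    if (spec$sparsity > 0 && spec$n_spiked < p) {
      idx <- (spec$n_spiked + 1):p
      mask <- matrix(stats::runif(length(idx) * n) < spec$sparsity,
                     length(idx), n)
      m[idx, ][mask] <- 0
    }
    cs <- colSums(m)
    if (any(cs <= 0)) stop("a sample column is entirely zero; lower sparsity")
    m <- sweep(m, 2, cs, "/")
    dimnames(m) <- list(fid, sid)
    list(table = abundance_table(m),
         groups = sample_groups(cls, subclass_labels = sub, sample_ids = sid,
                                reference_level = "ctrl"),
         truth = data.frame(feature_id = fid[seq_len(spec$n_spiked)],
                            direction = truth_dir,
                            stringsAsFactors = FALSE))
  })
}

#' Bootstrap stability experiment
#'
#' Mirrors the instability analysis of subsample-averaged coefficient
#' estimation: for each of `n_repeats` repeats and each bootstrap count in
#' `boot_grid`, the screening stages run as usual but the direct LDA
#' coefficients are replaced by the bootstrap-averaged ones before scoring,
#' and the selected feature set is recorded. The deterministic direct path
#' is run `n_repeats` times as a control (its selected sets are always
#' identical).
#'
#' @param table An [abundance_table].
#' @param groups A [sample_groups].
#' @param config A [pipeline_config].
#' @param boot_grid Bootstrap iteration counts; default `seq(5, 100, by = 5)`.
#' @param n_repeats Repeats per grid point; default 20.
#' @param seed Integer seed for the private RNG stream (required).
#' @return List with `summary` (data frame per grid point: `n_boot`,
#'   `union_size`, `intersection_size`, `mean_jaccard`, `mean_coef_var`),
#'   `sets` (list of lists of selected feature-id vectors, `sets[[g]][[r]]`),
#'   `direct_sets` (list of the `n_repeats` direct-mode selections),
#'   `all_union` / `all_intersection` (over every bootstrap run), and
#'   `survivors` (features entering LDA).
#' @export
stability_experiment <- function(table, groups, config = pipeline_config(),
                                 boot_grid = seq(5, 100, by = 5),
                                 n_repeats = 20, seed) {
  if (missing(seed)) stop("an explicit seed is required for stability_experiment")
  v <- validate_inputs(table, groups)
  st <- pipeline_survivors(v$table, v$groups, config)
  if (length(st$features) == 0) stop("no features survive the screens")
  sub_tab <- abundance_table(unclass(st$table)[st$features, , drop = FALSE])
  fit <- fit_two_class_lda(sub_tab, v$groups)
  lev <- levels(v$groups$class_labels)

  select_with <- function(w_unit) {
    eff <- effects_from_w(w_unit / sqrt(sum(w_unit^2)),
                          fit$class_feature_means, config$effect_mode)
    score_and_threshold(eff, config$lda_threshold, class_levels = lev)$features
  }

  direct_sets <- lapply(seq_len(n_repeats), function(r) select_with(fit$w_unit))

  sets <- vector("list", length(boot_grid))
  summ <- data.frame(n_boot = boot_grid, union_size = NA_integer_,
                     intersection_size = NA_integer_, mean_jaccard = NA_real_,
                     mean_coef_var = NA_real_)
  run_seed <- 0L
  for (g in seq_along(boot_grid)) {
    b <- boot_grid[g]
    runs <- vector("list", n_repeats)
    ws <- matrix(NA_real_, n_repeats, length(fit$w_unit))
    for (r in seq_len(n_repeats)) {
      run_seed <- run_seed + 1L
      bt <- bootstrap_lda(sub_tab, v$groups, n_boot = b,
                          seed = seed + run_seed)
      ws[r, ] <- bt$w_boot
      runs[[r]] <- select_with(bt$w_boot)
    }
    sets[[g]] <- runs
    uni <- Reduce(union, runs)
    int <- Reduce(intersect, runs)
    jac <- c()
    for (i in seq_len(n_repeats - 1)) {
      for (j in (i + 1):n_repeats) {
        u <- union(runs[[i]], runs[[j]])
        jac <- c(jac, if (length(u) == 0) 1 else
          length(intersect(runs[[i]], runs[[j]])) / length(u))
      }
    }
    summ$union_size[g] <- length(uni)
    summ$intersection_size[g] <- length(int)
    summ$mean_jaccard[g] <- mean(jac)
    summ$mean_coef_var[g] <- mean(apply(ws, 2, stats::var))
  }
  all_runs <- unlist(sets, recursive = FALSE)
  list(summary = summ, sets = sets, direct_sets = direct_sets,
       all_union = Reduce(union, all_runs),
       all_intersection = Reduce(intersect, all_runs),
       survivors = st$features)
}

#' Ranked true-positive minus false-positive differences
#'
#' For a ranked feature list and disjoint truth annotations, counts at each
#' cutoff *k* the annotated true positives minus the annotated false
#' positives among the top *k* features. Unannotated features count toward
#' neither. Both the raw difference and the cutoff-normalized ratio are
#' reported.
#'
#' @param ranked_features Character vector, best first.
#' @param truth_positive_set,truth_negative_set Disjoint character vectors of
#'   annotated feature ids.
#' @param cutoffs Integer cutoffs, each <= `length(ranked_features)`.
#' @return Data frame with columns `cutoff`, `tp`, `fp`, `difference`,
#'   `normalized` (= difference / cutoff).
#' @export
enrichment_difference <- function(ranked_features, truth_positive_set,
                                  truth_negative_set,
                                  cutoffs = seq_along(ranked_features)) {
  if (length(intersect(truth_positive_set, truth_negative_set))) {
    stop("truth sets must be disjoint")
  }
  if (any(cutoffs < 1) || any(cutoffs > length(ranked_features))) {
    stop("cutoffs must lie in 1..length(ranked_features)")
  }
  out <- data.frame(cutoff = as.integer(cutoffs), tp = NA_integer_,
                    fp = NA_integer_)
  for (i in seq_along(cutoffs)) {
    top <- ranked_features[seq_len(cutoffs[i])]
    out$tp[i] <- length(intersect(top, truth_positive_set))
    out$fp[i] <- length(intersect(top, truth_negative_set))
  }
  out$difference <- out$tp - out$fp
  out$normalized <- out$difference / out$cutoff
  out
}
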