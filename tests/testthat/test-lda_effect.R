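# LDA, effect sizes, score transform, pipeline composition, bootstrap
# reference estimator.

test_that("normalize_per_million rescales columns exactly", {
  tab <- abundance_table(matrix(c(0.2, 0.8, 3, 1), nrow = 2,
                                dimnames = list(c("fA", "fB"), c("s1", "s2"))))
  out <- normalize_per_million(tab)
  expect_equal(unclass(out)[, "s1"], c(fA = 2e5, fB = 8e5))
  expect_equal(colSums(out), c(s1 = 1e6, s2 = 1e6), tolerance = 1e-9)
  # scale invariance of the rescale itself
  out2 <- normalize_per_million(abundance_table(unclass(tab) * 37.5))
  expect_equal(unclass(out), unclass(out2), tolerance = 1e-12)
  expect_error(
    abundance_table(matrix(c(0, 0, 1, 2), 2,
                           dimnames = list(c("a", "b"), c("z", "s")))),
    "non-positive total")
})

test_that("filter_degenerate drops zero, constant, duplicate rows only", {
  m <- rbind(zero = c(0, 0, 0, 0),
             const = c(5, 5, 5, 5),
             keep1 = c(1, 2, 3, 4),
             dup = c(1, 2, 3, 4),
             keep2 = c(4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:4)
  out <- filter_degenerate(abundance_table(m))
  expect_identical(rownames(out$table), c("keep1", "keep2"))
  expect_setequal(out$dropped, c("zero", "const", "dup"))
  # full-rank table passes through untouched
  ok <- filter_degenerate(out$table)
  expect_identical(unclass(ok$table), unclass(out$table))
  expect_length(ok$dropped, 0L)
  expect_error(filter_degenerate(abundance_table(
    matrix(1, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))),
    "all features are degenerate")
})

test_that("fit_two_class_lda reproduces the closed-form 2-D example", {
  x <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
             c(5, 0), c(3, 0), c(4, 1), c(4, -1))
  x <- x + 2  # shift positive for abundance invariants
  tab <- abundance_table(t(x), feature_ids = c("f1", "f2"),
                         sample_ids = paste0("s", 1:8))
  g <- sample_groups(rep(c("c0", "c1"), each = 4),
                     sample_ids = paste0("s", 1:8))
  fit <- fit_two_class_lda(tab, g)
  expect_equal(abs(unname(fit$w_unit)), c(1, 0), tolerance = 1e-12)
  expect_equal(fit$delta_ld, 4, tolerance = 1e-12)
  expect_equal(unname(fit$class_feature_means["c1", ] -
                      fit$class_feature_means["c0", ]), c(4, 0))

  # swapping class labels flips nothing that matters
  g2 <- sample_groups(rep(c("c0", "c1"), each = 4),
                      sample_ids = paste0("s", 1:8), reference_level = "c1")
  fit2 <- fit_two_class_lda(tab, g2)
  expect_equal(abs(fit2$w_unit), abs(fit$w_unit), tolerance = 1e-12)
  expect_equal(fit2$delta_ld, fit$delta_ld, tolerance = 1e-12)

  # single-feature reduction: w = +/-1, delta = |mean diff|
  tab1 <- abundance_table(matrix(c(1, 2, 3, 7, 8, 9), nrow = 1,
                                 dimnames = list("f", paste0("s", 1:6))))
  g1 <- sample_groups(rep(c("a", "b"), each = 3),
                      sample_ids = paste0("s", 1:6))
  fit1 <- fit_two_class_lda(tab1, g1)
  expect_equal(abs(unname(fit1$w_unit)), 1)
  expect_equal(fit1$delta_ld, 6)
})

test_that("LDA matches closed-form and MASS oracles on random instances", {
  skip_if_not_installed("MASS")
  set.seed(88)
  for (k in 1:100) {
    p <- sample(2:6, 1)
    inst <- random_lda_instance(n_per_class = sample(8:15, 1), n_features = p)
    obj <- as_pipeline_objects(inst$x0, inst$x1)
    fit <- fit_two_class_lda(obj$table, obj$groups)
    w_ref <- lda_closed_form(inst$x0, inst$x1)
    if (sum(w_ref * fit$w_unit) < 0) w_ref <- -w_ref
    expect_equal(unname(fit$w_unit), unname(w_ref), tolerance = 1e-8)
    wm <- MASS::lda(rbind(inst$x0, inst$x1),
                    rep(c("a", "b"), c(nrow(inst$x0), nrow(inst$x1))))$scaling[, 1]
    wm <- wm / sqrt(sum(wm^2))
    if (sum(wm * fit$w_unit) < 0) wm <- -wm
    expect_equal(unname(fit$w_unit), unname(wm), tolerance = 1e-8)
  }
})

test_that("singular scatter errors and names collinear candidates", {
  m <- rbind(f1 = c(1, 2, 3, 4, 5, 6),
             f2 = c(2, 4, 6, 8, 10, 12))  # exact multiple
  colnames(m) <- paste0("s", 1:6)
  g <- sample_groups(rep(c("a", "b"), each = 3), sample_ids = paste0("s", 1:6))
  expect_error(fit_two_class_lda(abundance_table(m), g),
               "singular; candidate collinear features: f[12]")
})

test_that("effect sizes follow the projection and averaged definitions", {
  # both feature means higher in the non-reference class: d = (4, 1)
  fit <- structure(list(
    w_unit = c(f1 = 0.6, f2 = 0.8),
    delta_ld = 10,
    class_feature_means = matrix(c(0, 0, 4, 1), nrow = 2, byrow = TRUE,
                                 dimnames = list(c("a", "b"), c("f1", "f2"))),
    class_levels = c("a", "b")), class = "lda_fit")
  proj <- compute_effect_sizes(fit, "projection")
  expect_equal(proj$raw_effect, c(6, 8))  # delta_ld * |w|, signs of d
  avg <- compute_effect_sizes(fit, "averaged")
  expect_equal(avg$raw_effect, c((4 + 6) / 2, (1 + 8) / 2))

  # the 2-D worked example: w=(1,0), delta=4 -> projection (+4, 0)
  fit2 <- structure(list(
    w_unit = c(f1 = 1, f2 = 0), delta_ld = 4,
    class_feature_means = matrix(c(0, 0, 4, 0), 2, byrow = TRUE,
                                 dimnames = list(c("a", "b"), c("f1", "f2"))),
    class_levels = c("a", "b")), class = "lda_fit")
  expect_equal(compute_effect_sizes(fit2, "projection")$raw_effect, c(4, 0))
  expect_equal(compute_effect_sizes(fit2, "averaged")$raw_effect, c(4, 0))
})

test_that("score transform, threshold inclusivity, ordering, monotonicity", {
  eff <- data.frame(feature_id = c("a", "b", "c", "d", "e"),
                    raw_effect = c(100, -1000, 50, 0, 1e4))
  res <- score_and_threshold(eff, 2.0)
  expect_identical(res$features, c("e", "a", "b"))  # desc score; c,d excluded
  expect_equal(res$scores, c(4, 2, -3))
  # |raw| = 50 -> |score| = 1.699 < 2 excluded; raw 0 excluded pre-transform
  expect_false(any(c("c", "d") %in% res$features))
  # ties broken lexicographically
  tie <- score_and_threshold(
    data.frame(feature_id = c("z", "y"), raw_effect = c(100, 100)), 2)
  expect_identical(tie$features, c("y", "z"))
  # monotone: retained set shrinks as the threshold rises
  res3 <- score_and_threshold(eff, 3.0)
  expect_true(all(res3$features %in% res$features))
})

test_that("pipeline is scale invariant and handles empty survivor sets", {
  sim <- sep_dataset()
  r1 <- run_lefse(sim$table, sim$groups)
  r2 <- run_lefse(abundance_table(unclass(sim$table) * 1234.5), sim$groups)
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-9)

  # pure-null, tight alpha: no survivors -> empty result, not an error
  nullsim <- generate_synthetic(synthetic_spec(n_features = 10, n_spiked = 0,
                                               sparsity = 0, seed = 2))
  res <- run_lefse(nullsim$table, nullsim$groups,
                   pipeline_config(kruskal_threshold = 1e-6))
  expect_s3_class(res, "marker_result")
  expect_equal(nrow(res), 0L)
})

test_that("spiked features are detected with the spiked sign", {
  sim <- sep_dataset(seed = 15)
  res <- run_lefse(sim$table, sim$groups)
  for (i in seq_len(nrow(sim$truth))) {
    f <- sim$truth$feature_id[i]
    expect_true(f %in% res$features)
    expect_equal(sign(res$scores[res$features == f]), sim$truth$direction[i])
  }
})

test_that("run_lefse touches no global RNG state", {
  sim <- sep_dataset()
  set.seed(777)
  poisoned <- .Random.seed
  r1 <- run_lefse(sim$table, sim$groups)
  expect_identical(.Random.seed, poisoned)
  r2 <- run_lefse(sim$table, sim$groups)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("bootstrap_lda: degenerate fraction reproduces the direct fit", {
  sim <- sep_dataset(n_per_class = 8, n_features = 5, seed = 21)
  scaled <- normalize_per_million(sim$table)
  sub <- abundance_table(unclass(scaled)[1:4, , drop = FALSE])
  bt <- bootstrap_lda(sub, sim$groups, n_boot = 7, fraction = 1, seed = 5)
  expect_equal(bt$w_boot, bt$w_direct, tolerance = 1e-12)
  expect_equal(nrow(bt$replicates), 7L)
  # defaults per the convention: 30 iterations, 2/3 of samples
  expect_identical(formals(bootstrap_lda)$n_boot, 30)
  expect_identical(eval(formals(bootstrap_lda)$fraction), 2 / 3)
  expect_error(bootstrap_lda(sub, sim$groups, n_boot = 2), "seed is required")
})

test_that("bootstrap coefficient deviation shrinks with n_boot", {
  sim <- sep_dataset(n_per_class = 15, n_features = 8, seed = 33)
  scaled <- normalize_per_million(sim$table)
  sub <- abundance_table(unclass(scaled)[1:6, , drop = FALSE])
  mad_at <- function(nb, seeds) {
    mean(vapply(seeds, function(s) {
      bt <- bootstrap_lda(sub, sim$groups, n_boot = nb, seed = s)
      mean(abs(bt$w_boot - bt$w_direct))
    }, numeric(1)))
  }
  m10 <- mad_at(10, 1:6)
  m1000 <- mad_at(1000, 101:106)
  expect_lt(m1000, m10)
})
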