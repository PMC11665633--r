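# Screening-stage tests against hand computations, exact enumeration, and
# the stock stats implementations.

test_that("KW screen reproduces the hand-computable instance and retains it", {
  m <- matrix(c(1, 2, 3, 4, 5, 6,
                2, 2, 2, 2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("sep", "flat"), paste0("s", 1:6)))
  g <- sample_groups(setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6)))
  scr <- kruskal_wallis_screen(abundance_table(m), g, alpha = 0.05)
  i <- match("sep", scr$feature_id)
  # H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7
  expect_equal(scr$statistic[i], 27 / 7, tolerance = 1e-12)
  expect_equal(scr$p_value[i], 0.04953461, tolerance = 1e-6)
  expect_true(scr$retained[i])
  # constant feature: p forced to 1, never retained
  j <- match("flat", scr$feature_id)
  expect_equal(scr$p_value[j], 1)
  expect_false(scr$retained[j])
})

test_that("rank-sum z matches the hand-computable instance and wilcox.test", {
  # strata {1,2,3} vs {4,5,6}: W = 6, E = 10.5, Var = 5.25
  t <- ldamarker:::ranksum_z(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t$z, (6 - 10.5) / sqrt(5.25), tolerance = 1e-12)
  expect_equal(t$z, -1.963961, tolerance = 1e-6)
  expect_equal(t$p_value, 0.04953461, tolerance = 1e-6)

  # agreement with stats::wilcox.test(correct = FALSE) p-values, with ties
  set.seed(71)
  for (k in 1:25) {
    x <- sample(1:8, 6, replace = TRUE)
    y <- sample(2:9, 7, replace = TRUE)
    ours <- ldamarker:::ranksum_z(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("asymptotic tests agree with exact enumeration at small n", {
  # tie-corrected variance must equal the brute-force variance of W over all
  # label assignments (exact identity); p-values agree within the documented
  # small-sample asymptotic error (0.55 for tied data at n <= 10; see the
  # methods vignette).
  set.seed(909)
  for (k in 1:40) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- sample(1:6, n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE)
    if (length(unique(c(x, y))) < 2) next
    enum <- ranksum_enumeration(x, y)
    ours <- ldamarker:::ranksum_z(x, y)
    n <- n1 + n2
    r <- rank(c(x, y)); ties <- table(r)
    v_formula <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    expect_equal(enum$v, v_formula, tolerance = 1e-10)
    expect_lt(abs(ours$p_value - enum$p_two_sided), 0.55)  # absolute bound

    # KW p for two groups vs the same enumeration (H is a monotone transform
    # of |W - E|, so the enumeration two-sided p transfers)
    g <- sample_groups(setNames(rep(c("a", "b"), c(n1, n2)),
                                paste0("s", 1:n)))
    tab <- abundance_table(matrix(c(x, y), nrow = 1,
                                  dimnames = list("f", paste0("s", 1:n))))
    kw <- kruskal_wallis_screen(tab, g)
    expect_lt(abs(kw$p_value[1] - enum$p_two_sided), 0.55)
  }
})

test_that("two-group KW and Wilcoxon give matching p-values without ties", {
  set.seed(4242)
  for (k in 1:100) {
    n1 <- sample(4:9, 1); n2 <- sample(4:9, 1)
    x <- rnorm(n1); y <- rnorm(n2)  # continuous: no ties
    g <- sample_groups(setNames(rep(c("a", "b"), c(n1, n2)),
                                paste0("s", seq_len(n1 + n2))))
    tab <- abundance_table(matrix(c(x, y) + 10, nrow = 1,
                                  dimnames = list("f", g$sample_ids)))
    kw <- kruskal_wallis_screen(tab, g)
    wz <- ldamarker:::ranksum_z(x, y)
    expect_equal(kw$p_value[1], wz$p_value, tolerance = 1e-10)
  }
})

test_that("rank tests are invariant to strictly monotone transforms", {
  sim <- sep_dataset(n_per_class = 8, n_features = 10, seed = 9)
  scr1 <- kruskal_wallis_screen(sim$table, sim$groups)
  tab2 <- abundance_table(exp(unclass(sim$table)))
  scr2 <- kruskal_wallis_screen(tab2, sim$groups)
  expect_equal(scr1$p_value, scr2$p_value, tolerance = 1e-12)
  expect_identical(scr1$retained, scr2$retained)
})

test_that("adjust_pvalues matches step-up/step-down oracles and is monotone", {
  expect_identical(adjust_pvalues(c(0.5, 0.01), "none"), c(0.5, 0.01))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_error(adjust_pvalues(0.5, "magic"), "unknown adjust")
  expect_error(adjust_pvalues(c(-0.1, 0.5), "BH"), "\\[0, 1\\]")
  set.seed(5)
  p <- runif(30)
  for (m in c("holm", "hochberg", "hommel", "bonferroni", "BH", "BY", "fdr")) {
    expect_true(all(adjust_pvalues(p, m) >= p), info = m)
    expect_true(all(adjust_pvalues(p, m) <= 1), info = m)
  }
  expect_identical(adjust_pvalues(p, "fdr"), adjust_pvalues(p, "BH"))
})

test_that("KW null retention is calibrated near alpha", {
  # 40 seeds x 50 null features; binomial 3-SD band around the pooled rate
  set.seed(31)
  tot <- 0L; ret <- 0L
  for (s in 1:40) {
    sim <- generate_synthetic(synthetic_spec(n_features = 50, n_spiked = 0,
                                             sparsity = 0, seed = s))
    scr <- kruskal_wallis_screen(sim$table, sim$groups)
    tot <- tot + nrow(scr); ret <- ret + sum(scr$retained)
  }
  band <- 3 * sqrt(tot * 0.05 * 0.95)
  expect_gt(ret, tot * 0.05 - band)
  expect_lt(ret, tot * 0.05 + band)
})

test_that("strict subclass screen requires significance and one sign", {
  # 16 samples: class a strata u,v and class b strata u,v; feature "flip"
  # has opposite directions in the two strata (all four cross comparisons
  # significant, mixed signs) -> rejected; feature "consist" is uniform.
  ids <- paste0("s", 1:16)
  cls <- rep(c("a", "b"), each = 8)
  sub <- rep(rep(c("u", "v"), each = 4), 2)
  flip <- c(1:4, 101:104, 11:14, 51:54)  # a:u < b:u but a:v > b:v
  consist <- c(1:8, 11:18)
  tab <- abundance_table(rbind(flip = flip, consist = consist),
                         sample_ids = ids)
  g <- sample_groups(cls, subclass_labels = sub, sample_ids = ids)
  out <- wilcoxon_subclass_screen(tab, g, c("flip", "consist"), alpha = 0.05)
  cmp <- out$comparisons
  flip_cmp <- cmp[cmp$feature_id == "flip", ]
  expect_equal(nrow(flip_cmp), 4L)
  expect_true(all(flip_cmp$p_value < 0.05))
  expect_true(length(unique(sign(flip_cmp$z_score))) > 1)
  expect_false("flip" %in% out$features)
  expect_true("consist" %in% out$features)

  # no subclass labels -> identity pass-through
  g2 <- sample_groups(cls, sample_ids = ids)
  out2 <- wilcoxon_subclass_screen(tab, g2, c("flip", "consist"))
  expect_identical(out2$features, c("flip", "consist"))
  expect_equal(nrow(out2$comparisons), 0L)
})
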