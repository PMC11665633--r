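# Shared fixtures and independent oracles, all built in code.

# Small well-formed table: 3 features x 4 samples, two classes.
tiny_table <- function() {
  m <- matrix(c(1, 2, 3, 4,
                4, 3, 2, 1,
                1, 1, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("fA", "fB", "fC"),
                              c("s1", "s2", "s3", "s4")))
  abundance_table(m)
}

tiny_groups <- function(subclass = FALSE) {
  sample_groups(
    c(s1 = "ctrl", s2 = "ctrl", s3 = "case", s4 = "case"),
    subclass_labels = if (subclass) c("u", "v", "u", "v") else NULL
  )
}

# A larger two-class dataset with separated features, for LDA paths.
sep_dataset <- function(n_per_class = 10, n_features = 6, seed = 42,
                        subclass = FALSE) {
  sim <- generate_synthetic(synthetic_spec(
    n_features = n_features, n_samples_per_class = rep(n_per_class, 2),
    n_spiked = 2, fold_change = 6, sparsity = 0,
    subclass_count = if (subclass) 2 else 0, seed = seed))
  sim
}

# --- Independent oracles -------------------------------------------------

# Exact permutation distribution of the rank-sum statistic W (sum of ranks
# of the first group) over all assignments of n1 labels to the pooled data.
ranksum_enumeration <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  w_obs <- sum(r[seq_len(n1)])
  e <- mean(ws)
  list(w_obs = w_obs, ws = ws, e = e, v = mean((ws - e)^2),
       p_two_sided = mean(abs(ws - e) >= abs(w_obs - e) - 1e-12))
}

# Closed-form two-class LDA direction: solve(Sw, mu1 - mu0), unit norm.
lda_closed_form <- function(x0, x1) {
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  sw <- crossprod(sweep(x0, 2, mu0)) + crossprod(sweep(x1, 2, mu1))
  w <- solve(sw, mu1 - mu0)
  w / sqrt(sum(w^2))
}

# Random full-rank two-class dataset in matrix form (samples x features).
random_lda_instance <- function(n_per_class, n_features) {
  x0 <- matrix(rnorm(n_per_class * n_features), n_per_class)
  x1 <- matrix(rnorm(n_per_class * n_features, mean = 1), n_per_class)
  colnames(x0) <- colnames(x1) <- paste0("f", seq_len(n_features))
  list(x0 = x0, x1 = x1)
}

# Wrap a samples-x-features pair as pipeline objects (shifting to positive
# values so the abundance invariants hold).
as_pipeline_objects <- function(x0, x1) {
  x <- rbind(x0, x1)
  x <- x - min(x) + 1
  tab <- abundance_table(t(x), feature_ids = colnames(x),
                         sample_ids = sprintf("s%d", seq_len(nrow(x))))
  grp <- sample_groups(rep(c("a", "b"), c(nrow(x0), nrow(x1))),
                       sample_ids = colnames(tab))
  list(table = tab, groups = grp)
}
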