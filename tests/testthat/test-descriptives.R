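test_that("summarize_protein reports the Table-1-style layout", {
  # the ratio depends only on the extremes
  v <- c(0.30, runif(100, 0.4, 4.0), 4.36)
  s <- summarize_protein(v)
  expect_equal(s$max_min_ratio, 14.5)
  expect_equal(s$min, 0.30)
  expect_equal(s$max, 4.36)

  s2 <- summarize_protein(c(5, 5, 5, 5))
  expect_equal(s2$median, 5)
  expect_equal(s2$max_min_ratio, 1.0)
  expect_equal(s2$sd, 0)

  s3 <- summarize_protein(1:5)
  expect_equal(s3$median, 3)
  expect_equal(s3$max_min_ratio, 5.0)
  expect_equal(s3$p25, 2)  # type-7 interpolation on 1..5

  expect_error(summarize_protein(numeric()), "no values")
  expect_error(summarize_protein(c(1, 0, 2)), "positive")
})

test_that("summarize_protein is permutation-invariant", {
  set.seed(1)
  v <- rlnorm(101)
  expect_equal(summarize_protein(v), summarize_protein(sample(v)))
})

test_that("normality test keeps level under the null and detects skew", {
  # Shapiro-Wilk branch
  ps <- vapply(1:100, function(s) {
    set.seed(s); test_normality(rnorm(5000))$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.99)
  set.seed(7)
  expect_lt(test_normality(rlnorm(5000))$p_value, 0.05)
  # large-n branch (D'Agostino-Pearson)
  set.seed(8)
  big <- test_normality(rnorm(6000))
  expect_equal(big$method, "D'Agostino-Pearson K2")
  expect_gt(big$p_value, 0.01)
  set.seed(9)
  expect_lt(test_normality(rlnorm(6000))$p_value, 1e-6)
  expect_error(test_normality(rnorm(5)), "at least 8")
  # default synthetic analytes are non-Gaussian
  cohort <- generate_cohort(default_study_config(), seed = 3)
  expect_lt(test_normality(cohort$`PAPP-A`)$p_value, 0.05)
})

test_that("sex_contrast uses the median-percent convention with its sign", {
  # construct exact medians: male 1.29, female 1.00
  df <- data.frame(
    subject_id = paste0("s", 1:12),
    pair_id = rep(paste0("p", 1:6), each = 2),
    zygosity = "MZ",
    sex = rep(c("male", "female"), each = 6),
    age = 80,
    P = c(1.19, 1.19, 1.29, 1.29, 1.39, 1.39,
          0.90, 0.90, 1.00, 1.00, 1.10, 1.10),
    stringsAsFactors = FALSE)
  cohort <- new_twin_cohort(df, "P")
  sc <- sex_contrast(cohort, "P", n_boot = 200, seed = 1)
  expect_equal(sc$pct_diff_median, 29)

  # sign convention: female median double the male median -> -50%
  df2 <- df; df2$P <- c(rep(1, 6), rep(2, 6))
  expect_equal(sex_contrast(new_twin_cohort(df2, "P"), "P",
                            n_boot = 200, seed = 1)$pct_diff_median, -50)

  # identical distributions -> no signal
  set.seed(2)
  n <- 60
  df3 <- data.frame(subject_id = paste0("s", 1:(2 * n)),
                    pair_id = rep(paste0("p", 1:n), each = 2),
                    zygosity = "DZ",
                    sex = rep(rep(c("male", "female"), each = 2),
                              length.out = 2 * n),
                    age = 80, P = rlnorm(2 * n),
                    stringsAsFactors = FALSE)
  sc3 <- sex_contrast(new_twin_cohort(df3, "P"), "P", n_boot = 500, seed = 3)
  expect_gt(sc3$p_value, 0.05)

  df4 <- df; df4$sex <- "male"
  expect_error(sex_contrast(new_twin_cohort(df4, "P"), "P"), "both sexes")
})

test_that("sex_contrast percent difference is antisymmetric under label swap", {
  cohort <- generate_cohort(default_study_config(), seed = 5)
  d <- sex_contrast(cohort, "STC2", n_boot = 50, seed = 1)$pct_diff_median
  swapped <- cohort
  swapped$sex <- factor(ifelse(cohort$sex == "male", "female", "male"),
                        levels = c("female", "male"))
  d_swap <- sex_contrast(swapped, "STC2", n_boot = 50, seed = 1)$pct_diff_median
  expect_equal(d_swap, 100 * (1 / (1 + d / 100) - 1), tolerance = 1e-10)
})

test_that("cluster-robust correlation keeps the Pearson point estimate", {
  set.seed(10)
  n <- 100
  cl <- rep(1:(n / 2), each = 2)
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  est <- cluster_robust_correlation(x, y, cl)
  expect_equal(est$r, cor(x, y))
  expect_equal(est$n_units, n / 2)
  expect_true(est$ci_low <= est$r && est$r <= est$ci_high)

  # degenerate perfect fit: sandwich warns about the zero-residual bread
  est1 <- suppressWarnings(cluster_robust_correlation(x, x, cl))
  expect_equal(est1$r, 1.0)

  expect_error(cluster_robust_correlation(x, rep(1, n), cl), "zero variance")
  expect_error(cluster_robust_correlation(1:4, c(2, 1, 4, 3), c(1, 1, 2, 2)),
               "at least 3 clusters")
})

test_that("clustering widens the standard error under within-pair correlation", {
  set.seed(11)
  wins <- 0
  for (rep in 1:20) {
    n_pair <- 150
    shx <- rnorm(n_pair); shy <- rnorm(n_pair)
    x <- rep(shx, each = 2) + 0.4 * rnorm(2 * n_pair)
    y <- 0.3 * x + rep(shy, each = 2) + 0.4 * rnorm(2 * n_pair)
    cl <- rep(seq_len(n_pair), each = 2)
    clustered <- cluster_robust_correlation(x, y, cl)$se
    naive <- cluster_robust_correlation(x, y, seq_along(x))$se
    wins <- wins + (clustered > naive)
  }
  expect_gte(wins, 19)
})

test_that("cluster-robust CI coverage is near nominal on independent data", {
  hits <- 0
  n_rep <- 400
  for (s in seq_len(n_rep)) {
    set.seed(2000 + s)
    n_cl <- 500
    x <- rnorm(2 * n_cl); y <- rnorm(2 * n_cl)
    est <- cluster_robust_correlation(x, y, rep(seq_len(n_cl), each = 2))
    hits <- hits + (est$ci_low <= 0 && 0 <= est$ci_high)
  }
  expect_gte(hits / n_rep, 0.925)
  expect_lte(hits / n_rep, 0.975)
})

test_that("duplicated cluster members match the subsampled analysis", {
  # duplicating each subject into a 2-member cluster adds no information:
  # clustered p-values should behave like the plain test on the singletons
  rej_dup <- 0; rej_sub <- 0
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    set.seed(3000 + s)
    n <- 150
    x <- rnorm(n); y <- rnorm(n)
    xd <- rep(x, each = 2); yd <- rep(y, each = 2)
    p_dup <- cluster_robust_correlation(xd, yd, rep(1:n, each = 2))$p_value
    p_sub <- cor.test(x, y)$p.value
    rej_dup <- rej_dup + (p_dup < 0.05)
    rej_sub <- rej_sub + (p_sub < 0.05)
  }
  expect_lt(abs(rej_dup - rej_sub) / n_rep, 0.05)
})

test_that("age groups use left-open right-closed boundaries", {
  g <- assign_age_group(c(73.5, 75.0, 75.1, 80.0, 80.5, 85.0, 85.1, 94.3))
  expect_equal(as.character(g),
               c("<=75", "<=75", "(75,80]", "(75,80]", "(80,85]", "(80,85]",
                 ">85", ">85"))
})

test_that("the synthetic cohort reproduces the published age trends", {
  cohort <- generate_cohort(default_study_config(), seed = 17)
  r_pappa <- age_correlations(cohort, "PAPP-A")
  expect_gt(r_pappa$r, 0.05)
  r_igf1 <- age_correlations(cohort, "IGF-I")
  expect_lt(r_igf1$r, 0)
  # sex contrasts point the published way
  expect_gt(sex_contrast(cohort, "PAPP-A", n_boot = 50)$pct_diff_median, 0)
  expect_lt(sex_contrast(cohort, "IGF-II", n_boot = 50)$pct_diff_median, 0)
})
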