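test_that("model specs enforce the admissible component sets", {
  expect_error(twin_model_spec("ACDE"), "not identifiable")
  expect_error(twin_model_spec("AC"), "E must be included")
  expect_error(twin_model_spec("ABE"), "ACE, ADE, AE, CE, E")
  s <- twin_model_spec("ae", covariates = "age")
  expect_equal(s$label, "AE")
  expect_equal(s$covariates, "age")
})

test_that("likelihoods nest: ACE >= AE >= E and ADE >= AE", {
  po <- sim_ae_pairs(0.6, 150, 150, seed = 1)
  z <- split_zyg(po)
  fits <- fit_all_models(z$mz, z$dz)
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  expect_gte(lls["ACE"], lls["AE"] - 1e-6)
  expect_gte(lls["ADE"], lls["AE"] - 1e-6)
  expect_gte(lls["AE"], lls["E"] - 1e-6)
  expect_gte(lls["CE"], lls["E"] - 1e-6)
  # all components non-negative, implied correlations in [0, 1]
  for (f in fits) {
    expect_true(all(f$components >= 0))
    V <- sum(f$components)
    rmz <- (f$components[["A"]] + f$components[["C"]] +
              f$components[["D"]]) / V
    rdz <- (0.5 * f$components[["A"]] + f$components[["C"]] +
              0.25 * f$components[["D"]]) / V
    expect_true(rmz >= 0 && rmz <= 1 + 1e-9)
    expect_true(rdz >= 0 && rdz <= 1 + 1e-9)
    expect_equal(f$aic, 2 * f$n_params - 2 * f$loglik)
  }
})

test_that("no familial resemblance drives the additive variance to zero", {
  po <- sim_ae_pairs(0, 5000, 5000, seed = 2)
  z <- split_zyg(po)
  f <- fit_twin_model(z$mz, z$dz, twin_model_spec("AE"))
  expect_lt(f$h2, 0.05)
  expect_lt(f$components[["A"]] / sum(f$components), 0.05)
})

test_that("AE recovery is approximately unbiased across the h2 range", {
  for (h2_true in c(0.2, 0.5, 0.8)) {
    errs <- vapply(1:8, function(s) {
      po <- sim_ae_pairs(h2_true, 4000, 4000, seed = 100 * h2_true + s)
      z <- split_zyg(po)
      fit_twin_model(z$mz, z$dz, twin_model_spec("AE"))$h2 - h2_true
    }, numeric(1))
    expect_lt(abs(mean(errs)), 0.03)
  }
})

test_that("refitting identical data reproduces identical estimates", {
  po <- sim_ae_pairs(0.6, 100, 100, seed = 3)
  z <- split_zyg(po)
  f1 <- fit_twin_model(z$mz, z$dz, twin_model_spec("ACE"))
  f2 <- fit_twin_model(z$mz, z$dz, twin_model_spec("ACE"))
  expect_identical(f1$components, f2$components)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("the grid oracle agrees with the ML optimizer on small data", {
  spec <- twin_model_spec("AE")
  for (s in 1:10) {
    po <- sim_ae_pairs(runif(1, 0.2, 0.8), 15, 15, seed = 400 + s)
    z <- split_zyg(po)
    ml <- fit_twin_model(z$mz, z$dz, spec)
    grid <- grid_oracle_fit(z$mz, z$dz, spec, grid_step = 0.05)
    # the optimizer must at least match the best lattice point
    expect_gte(ml$loglik, grid$loglik - 1e-6)
    # and land within one lattice step of it
    a2_ml <- ml$components[["A"]] / sum(ml$components)
    a2_grid <- grid$components[["A"]] / sum(grid$components)
    expect_lt(abs(a2_ml - a2_grid), 0.05 + 0.01)
    expect_lt(abs(log(sum(ml$components) / sum(grid$components))),
              log(1 + 0.05) + 0.01)
  }
  expect_error(grid_oracle_fit(split_zyg(sim_ae_pairs(0.5, 10, 10, 1))$mz,
                               split_zyg(sim_ae_pairs(0.5, 10, 10, 1))$dz,
                               spec, grid_step = 0.3), "coarse")
})

test_that("the E-only grid search reproduces the closed-form ML variance", {
  po <- sim_ae_pairs(0.5, 20, 20, seed = 11)
  z <- split_zyg(po)
  grid <- grid_oracle_fit(z$mz, z$dz, twin_model_spec("E"), grid_step = 0.05)
  yy <- c(po$y1, po$y2)
  v_closed <- mean((yy - mean(yy))^2)
  expect_equal(grid$components[["E"]], v_closed, tolerance = 1e-12)
  expect_equal(unname(grid$mean$coefficients["beta0"]), mean(yy))
  # matches the analytic E fit from the main fitter too
  fe <- fit_twin_model(z$mz, z$dz, twin_model_spec("E"))
  expect_equal(fe$components[["E"]], v_closed)
  expect_equal(fe$loglik, grid$loglik, tolerance = 1e-9)
})

test_that("perfect MZ resemblance pushes the additive share to the top", {
  po <- sim_ae_pairs(0, 20, 20, seed = 12)
  po$y2[po$zygosity == "MZ"] <- po$y1[po$zygosity == "MZ"]
  z <- split_zyg(po)
  grid <- grid_oracle_fit(z$mz, z$dz, twin_model_spec("AE"), grid_step = 0.1)
  expect_gte(grid$components[["A"]] / sum(grid$components), 0.5)
})

test_that("likelihood-ratio tests detect signal and respect identity", {
  po <- sim_ae_pairs(0.6, 10000, 10000, seed = 13)
  z <- split_zyg(po)
  fae <- fit_twin_model(z$mz, z$dz, twin_model_spec("AE"))
  fe <- fit_twin_model(z$mz, z$dz, twin_model_spec("E"))
  lrt <- likelihood_ratio_test(fae, fe, mixture = TRUE)
  expect_lt(lrt$p_value, 0.001)
  expect_equal(lrt$df, 1)
  expect_true(lrt$boundary)
  expect_lte(lrt$p_mixture, lrt$p_value)

  self <- likelihood_ratio_test(fae, fae)
  expect_equal(self$chi2, 0)
  expect_equal(self$p_value, 1)

  face <- fit_twin_model(z$mz, z$dz, twin_model_spec("ACE"))
  expect_error(likelihood_ratio_test(fae, face), "not nested")
})

test_that("AIC selection prefers the generating model and breaks ties", {
  picks <- vapply(1:20, function(s) {
    po <- sim_ae_pairs(0.7, 1000, 1000, seed = 500 + s)
    z <- split_zyg(po)
    select_model_aic(fit_all_models(z$mz, z$dz))$spec$label
  }, character(1))
  expect_gt(mean(picks == "AE"), 0.5)

  po <- sim_ae_pairs(0.5, 50, 50, seed = 14)
  z <- split_zyg(po)
  fae <- fit_twin_model(z$mz, z$dz, twin_model_spec("AE"))
  tie <- fit_twin_model(z$mz, z$dz, twin_model_spec("ACE"))
  tie$aic <- fae$aic  # constructed exact tie
  expect_equal(select_model_aic(list(tie, fae))$spec$label, "AE")
  expect_identical(select_model_aic(list(fae)), fae)
  expect_error(select_model_aic(list()), "no fits")
})

test_that("ADE and AE agree on the total genetic variance under AE truth", {
  po <- sim_ae_pairs(0.6, 10000, 10000, seed = 15)
  z <- split_zyg(po)
  fae <- fit_twin_model(z$mz, z$dz, twin_model_spec("AE"))
  fade <- fit_twin_model(z$mz, z$dz, twin_model_spec("ADE"))
  gen_ae <- fae$components[["A"]]
  gen_ade <- fade$components[["A"]] + fade$components[["D"]]
  expect_lt(abs(gen_ade - gen_ae) / sum(fae$components), 0.03)
})

test_that("heritability extraction is the (A+D)/V arithmetic identity", {
  po <- sim_ae_pairs(0.67, 2000, 2000, seed = 16)
  z <- split_zyg(po)
  f <- fit_twin_model(z$mz, z$dz, twin_model_spec("AE"))
  bh <- broad_sense_heritability(f)
  expect_equal(bh$h2,
               (f$components[["A"]] + f$components[["D"]]) /
                 sum(f$components))
  expect_true(bh$ci[1] <= bh$h2 && bh$h2 <= bh$ci[2])
  expect_true(all(bh$ci >= 0 & bh$ci <= 1))
})

test_that("delta-method CI matches a parametric bootstrap", {
  po <- sim_ae_pairs(0.6, 500, 500, seed = 17)
  z <- split_zyg(po)
  f <- fit_twin_model(z$mz, z$dz, twin_model_spec("AE"))
  a2_hat <- f$components[["A"]] / sum(f$components)
  v_hat <- sum(f$components)
  boots <- vapply(1:400, function(s) {
    cfg <- sim_config(500, 500, proteins = list(
      protein_sim_model("P", a2 = a2_hat, e2 = 1 - a2_hat,
                        total_var = v_hat)), seed = 7000 + s)
    pb <- split_zyg(to_pair_observations(generate_cohort(cfg), "P",
                                         quiet = TRUE))
    fit_twin_model(pb$mz, pb$dz, twin_model_spec("AE"))$h2
  }, numeric(1))
  boot_ci <- unname(quantile(boots, c(0.025, 0.975)))
  expect_equal(f$h2_ci[1], boot_ci[1], tolerance = 0.03)
  expect_equal(f$h2_ci[2], boot_ci[2], tolerance = 0.03)
})

test_that("covariate adjustment removes shared-covariate inflation", {
  po <- sim_ae_pairs(0.5, 3000, 3000, seed = 18, beta_age = 0.06,
                     beta_sex = 0.4)
  z <- split_zyg(po)
  fu <- fit_twin_model(z$mz, z$dz, twin_model_spec("AE"))
  fa <- fit_twin_model(z$mz, z$dz, twin_model_spec("AE", c("age", "sex")))
  expect_gt(fu$h2, fa$h2)
  expect_lt(abs(fa$h2 - 0.5), 0.05)              # ~4 SE at 3000 pairs/zygosity
  # recovered mean coefficients (absolute bounds ~3-4 SE)
  expect_lt(abs(unname(fa$mean$coefficients["beta_age"]) - 0.06), 0.01)
  expect_lt(abs(unname(fa$mean$coefficients["beta_sex"]) - 0.4), 0.08)
})

test_that("sensitivity modes count outliers correctly and keep estimates", {
  cohort <- generate_cohort(default_study_config(), seed = 19)
  # fixture: cap everything below the 3 ng/mL threshold, then push exactly
  # one member of one MZ pair above it
  cohort$`PAPP-A` <- pmin(cohort$`PAPP-A`, 2.9)
  idx <- which(cohort$zygosity == "MZ")[1]
  cohort$`PAPP-A`[idx] <- 5.0
  sa_ex <- sensitivity_analysis(cohort, "PAPP-A", mode = "exclude")
  sa_tr <- sensitivity_analysis(cohort, "PAPP-A", mode = "truncate")
  expect_equal(sa_ex$n_pairs_removed, 1L)
  expect_equal(sa_tr$n_pairs_removed, 0L)
  expect_equal(sa_ex$fits$sensitivity_unadjusted$n_pairs_mz, 124)
  expect_equal(sa_tr$fits$sensitivity_unadjusted$n_pairs_mz, 125)

  # no value above threshold: exclusion is a no-op
  clean <- generate_cohort(default_study_config(), seed = 20)
  clean$`PAPP-A` <- pmin(clean$`PAPP-A`, 2.9)
  sa0 <- sensitivity_analysis(clean, "PAPP-A", mode = "exclude")
  expect_identical(sa0$fits$sensitivity_unadjusted$components,
                   sa0$fits$primary_unadjusted$components)
  expect_error(sensitivity_analysis(cohort, "PAPP-A", mode = "winsorize"))
  expect_error(sensitivity_analysis(cohort, "PAPP-A", mode = "exclude",
                                    thresholds = c(STC2 = 55)),
               "no outlier threshold")
})

test_that("rank inverse-normal transform yields a normal-looking phenotype", {
  cohort <- generate_cohort(default_study_config(), seed = 21)
  sa <- sensitivity_analysis(cohort, "STC2", mode = "transform")
  expect_equal(sa$fits$sensitivity_unadjusted$n_pairs_mz, 125)
  # transformed h2 stays in the vicinity of the primary estimate
  expect_equal(sa$fits$sensitivity_unadjusted$h2,
               sa$fits$primary_unadjusted$h2, tolerance = 0.15)
})
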