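# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# Subject-level data frame for a small cohort: 2 MZ pairs + 1 DZ pair with
# all four proteins, hand-checkable by inspection.
toy_cohort_df <- function() {
  data.frame(
    subject_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    pair_id    = c("p1", "p1", "p2", "p2", "p3", "p3"),
    zygosity   = c("MZ", "MZ", "MZ", "MZ", "DZ", "DZ"),
    sex        = c("F", "F", "M", "M", "F", "F"),
    age        = c(74.1, 74.1, 81.0, 81.0, 77.3, 77.3),
    `PAPP-A`   = c(1.10, 1.20, 0.95, 0.90, 1.40, 1.05),
    STC2       = c(28.1, 30.2, 25.7, 27.0, 33.3, 29.9),
    `IGF-I`    = c(88, 92, 75, 80, 101, 96),
    `IGF-II`   = c(401, 410, 388, 395, 455, 430),
    check.names = FALSE, stringsAsFactors = FALSE)
}

write_toy_csv <- function(df = toy_cohort_df()) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Exchangeable bivariate-normal pairs with within-pair correlation rho.
sim_exch_pairs <- function(n, rho, seed, zygosity = "MZ", mu = 0, sd = 1) {
  set.seed(seed)
  sh <- rnorm(n); u1 <- rnorm(n); u2 <- rnorm(n)
  age <- runif(n, 73.2, 94.3)
  structure(data.frame(pair_id = paste0(tolower(zygosity), seq_len(n)),
                       zygosity = zygosity,
                       sex = rep(c("female", "male"), length.out = n),
                       age1 = age, age2 = age,
                       y1 = mu + sd * (sqrt(rho) * sh + sqrt(1 - rho) * u1),
                       y2 = mu + sd * (sqrt(rho) * sh + sqrt(1 - rho) * u2),
                       stringsAsFactors = FALSE),
            class = c("pair_observations", "data.frame"))
}

# MZ + DZ pairs under an AE model with additive proportion a2 (unit total
# variance), via the package generator on the identity scale.
sim_ae_pairs <- function(a2, n_mz, n_dz, seed, beta_age = 0, beta_sex = 0) {
  cfg <- sim_config(n_mz, n_dz,
                    proteins = list(protein_sim_model(
                      "P", a2 = a2, e2 = 1 - a2,
                      beta_age = beta_age, beta_sex = beta_sex)),
                    seed = seed)
  to_pair_observations(generate_cohort(cfg), "P", quiet = TRUE)
}

split_zyg <- function(po) {
  list(mz = po[po$zygosity == "MZ", ], dz = po[po$zygosity == "DZ", ])
}
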