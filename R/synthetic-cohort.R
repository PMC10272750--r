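#' Specify the generative model for one protein
#'
#' Latent values are built per pair member as
#' `mu + beta_sex * I(male) + beta_age * (age - age_mean) + a*A + c*C + d*D + e*E`
#' with standard-normal latent factors whose cross-twin correlations follow
#' biometrical genetics: additive factors correlate 1 in MZ and 0.5 in DZ
#' pairs, dominance factors 1 in MZ and 0.25 in DZ pairs, the shared
#' environment C is common to both members and E is member-specific. The
#' loadings are `a = sqrt(a2 * total_var)` and so on. `skew_transform =
#' "exponential"` exponentiates the latent value, so the latent scale is log
#' ng/mL, yielding strictly positive right-skewed concentrations and turning
#' an additive sex effect into a multiplicative median ratio.
#'
#' @param name Protein name.
#' @param mu Baseline latent mean (female, at the cohort mean age).
#' @param a2,c2,d2,e2 Variance proportions on the latent scale; they must sum
#'   to one and at most one of `c2`, `d2` may be nonzero (shared environment
#'   and dominance cannot be separated with MZ/DZ pairs alone).
#' @param total_var Residual latent variance (excluding sex and age effects).
#' @param beta_sex Additive male effect, latent scale.
#' @param beta_age Latent slope per year of age.
#' @param skew_transform `"identity"` or `"exponential"`.
#' @return A `protein_sim_model` list.
#' @export
protein_sim_model <- function(name, mu = 0, a2 = 0, c2 = 0, d2 = 0,
                              e2 = 1 - a2 - c2 - d2, total_var = 1,
                              beta_sex = 0, beta_age = 0,
                              skew_transform = c("identity", "exponential")) {
  skew_transform <- match.arg(skew_transform)
  props <- c(a2 = a2, c2 = c2, d2 = d2, e2 = e2)
  if (any(props < -1e-12) || any(props > 1 + 1e-12)) {
    stop("variance proportions must lie in [0, 1]")
  }
  if (abs(sum(props) - 1) > 1e-12) {
    stop("a2 + c2 + d2 + e2 must equal 1 (got ", sum(props), ")")
  }
  if (c2 > 0 && d2 > 0) {
    stop("c2 and d2 cannot both be nonzero: C and D are not jointly ",
         "identifiable from MZ/DZ pairs")
  }
  if (total_var <= 0) stop("total_var must be positive")
  structure(list(name = name, mu = mu, a2 = a2, c2 = c2, d2 = d2, e2 = e2,
                 total_var = total_var, beta_sex = beta_sex,
                 beta_age = beta_age, skew_transform = skew_transform),
            class = "protein_sim_model")
}

#' Specify a synthetic twin-cohort design
#'
#' @param n_mz_pairs,n_dz_pairs Numbers of intact MZ and DZ pairs.
#' @param male_pair_fraction Fraction of pairs that are male (same-sex pairs,
#'   so this is also the expected male subject fraction).
#' @param age_min,age_max,age_mean Age range and mean in years. Ages are drawn
#'   from a truncated-exponential distribution on `[age_min, age_max]` whose
#'   rate is solved so the mean equals `age_mean`; elderly cohorts are
#'   bottom-heavy in age, which this shape reproduces from only the three
#'   published numbers.
#' @param proteins List of [protein_sim_model()] objects.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param cross_corr Optional protein-by-protein correlation matrix applied to
#'   the additive-genetic and unique-environment factor draws, inducing
#'   cross-protein correlation; `NULL` (default) draws proteins independently.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_mz_pairs, n_dz_pairs, male_pair_fraction = 0.33,
                       age_min = 73.2, age_max = 94.3, age_mean = 78.8,
                       proteins = list(), seed = 20230601L,
                       cross_corr = NULL) {
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0,
            male_pair_fraction >= 0, male_pair_fraction <= 1)
  if (!(age_min < age_mean && age_mean < age_max)) {
    stop("ages must satisfy age_min < age_mean < age_max")
  }
  if (!is.null(cross_corr)) {
    p <- length(proteins)
    stopifnot(is.matrix(cross_corr), nrow(cross_corr) == p,
              ncol(cross_corr) == p)
  }
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 male_pair_fraction = male_pair_fraction,
                 age_min = age_min, age_max = age_max, age_mean = age_mean,
                 proteins = proteins, seed = as.integer(seed),
                 cross_corr = cross_corr),
            class = "sim_config")
}

#' Default synthetic design emulating the study cohort
#'
#' Returns the design used throughout the package's tests and examples:
#' 125 MZ and 173 DZ intact same-sex pairs (596 subjects), 33% male, ages on
#' 73.2–94.3 years with mean 78.8, and four log-normal proteins (PAPP-A,
#' STC2, IGF-I, IGF-II). Every constant is derived from the published cohort
#' summaries:
#' * `a2` is the published unadjusted AE heritability (0.67, 0.71, 0.62,
#'   0.59), with `c2 = d2 = 0` and `e2 = 1 - a2`;
#' * `mu` is the log of the published median concentration;
#' * `beta_sex` is the log of the published male/female median ratio
#'   (+29%, +18%, +19% and -28%);
#' * `beta_age` reproduces the published age correlations (0.19 for PAPP-A,
#'   -0.12 for IGF-I, none for STC2 and IGF-II) via
#'   `r * sigma_latent / sd(age)`;
#' * `total_var` is the total latent variance implied by the published
#'   mean/SD pairs (`log(1 + CV^2)`) minus the variance contributed by the
#'   sex and age terms, so the marginal dispersion matches the published
#'   coefficients of variation.
#'
#' The `beta_age`/`total_var` values are calibrated approximations (the
#' published correlations are on the observed, not latent, scale), not claims
#' of exactness.
#'
#' @param seed Integer seed stored in the config.
#' @return A [sim_config()].
#' @export
default_study_config <- function(seed = 20230601L) {
  proteins <- list(
    protein_sim_model("PAPP-A", mu = 0.1310, a2 = 0.67, e2 = 0.33,
                      total_var = 0.1003, beta_sex = 0.2546,
                      beta_age = 0.01359, skew_transform = "exponential"),
    protein_sim_model("STC2", mu = 3.3776, a2 = 0.71, e2 = 0.29,
                      total_var = 0.0594, beta_sex = 0.1655,
                      beta_age = 0, skew_transform = "exponential"),
    protein_sim_model("IGF-I", mu = 4.4773, a2 = 0.62, e2 = 0.38,
                      total_var = 0.1059, beta_sex = 0.1740,
                      beta_age = -0.00841, skew_transform = "exponential"),
    protein_sim_model("IGF-II", mu = 6.0064, a2 = 0.59, e2 = 0.41,
                      total_var = 0.0755, beta_sex = -0.2469,
                      beta_age = 0, skew_transform = "exponential")
  )
  sim_config(n_mz_pairs = 125L, n_dz_pairs = 173L, male_pair_fraction = 0.33,
             age_min = 73.2, age_max = 94.3, age_mean = 78.8,
             proteins = proteins, seed = seed)
}

#' Expected within-pair correlation implied by a generative model
#'
#' On the latent (identity-transform) scale the within-pair correlation is
#' `a2 + c2 + d2` for MZ pairs and `0.5*a2 + 0.25*d2 + c2` for DZ pairs,
#' the classical biometrical coefficients.
#'
#' @param model A [protein_sim_model()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return The expected correlation (scalar).
#' @export
expected_pair_correlations <- function(model, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  if (zygosity == "MZ") {
    model$a2 + model$c2 + model$d2
  } else {
    0.5 * model$a2 + 0.25 * model$d2 + model$c2
  }
}

# Solve the truncated-exponential rate so that E[age - age_min] hits target.
.trunc_exp_rate <- function(L, target_mean) {
  stopifnot(target_mean > 0, target_mean < L)
  if (abs(target_mean - L / 2) < 1e-9) return(1e-9)  # ~uniform
  m <- function(lam) 1 / lam - L / expm1(lam * L)
  stats::uniroot(function(l) m(l) - target_mean,
                 lower = 1e-8, upper = 50, tol = 1e-12)$root
}

.draw_ages <- function(n, age_min, age_max, age_mean) {
  L <- age_max - age_min
  lam <- .trunc_exp_rate(L, age_mean - age_min)
  u <- stats::runif(n)
  age_min + (-log(1 - u * (1 - exp(-lam * L))) / lam)
}

# n x p standard-normal draws with cross-column correlation R (or identity).
.draw_factors <- function(n, p, chol_R = NULL) {
  z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  if (!is.null(chol_R)) z <- z %*% chol_R
  z
}

#' Generate a synthetic twin cohort
#'
#' For each pair: sex is drawn once (same-sex design) with probability
#' `male_pair_fraction`, a single age is drawn and shared by both twins, and
#' each protein's values are built from the latent factor structure described
#' in [protein_sim_model()]. DZ additive factors are composed as
#' `sqrt(0.5)*shared + sqrt(0.5)*unique` (correlation 0.5) and DZ dominance
#' factors as `0.5*shared + sqrt(0.75)*unique` (correlation 0.25).
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A `twin_cohort` with `2 * (n_mz_pairs + n_dz_pairs)` subjects.
#' @examples
#' cohort <- generate_cohort(default_study_config(), seed = 1)
#' nrow(cohort)  # 596
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  n_pairs <- config$n_mz_pairs + config$n_dz_pairs
  p <- length(config$proteins)
  pnames <- vapply(config$proteins, `[[`, character(1), "name")
  if (n_pairs == 0L || p == 0L) {
    empty <- data.frame(subject_id = character(), pair_id = character(),
                        zygosity = character(), sex = character(),
                        age = numeric(), stringsAsFactors = FALSE)
    for (nm in pnames) empty[[nm]] <- numeric()
    return(new_twin_cohort(empty, pnames))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  zyg <- rep(c("MZ", "DZ"), c(config$n_mz_pairs, config$n_dz_pairs))
  pair_id <- sprintf("%s%04d", tolower(zyg),
                     c(seq_len(config$n_mz_pairs), seq_len(config$n_dz_pairs)))
  sex <- ifelse(stats::runif(n_pairs) < config$male_pair_fraction,
                "male", "female")
  age <- .draw_ages(n_pairs, config$age_min, config$age_max, config$age_mean)

  chol_R <- if (!is.null(config$cross_corr)) chol(config$cross_corr) else NULL
  # latent factors, one column per protein
  A_sh <- .draw_factors(n_pairs, p, chol_R)
  A_u1 <- .draw_factors(n_pairs, p, chol_R)
  A_u2 <- .draw_factors(n_pairs, p, chol_R)
  C_sh <- .draw_factors(n_pairs, p)
  D_sh <- .draw_factors(n_pairs, p)
  D_u1 <- .draw_factors(n_pairs, p)
  D_u2 <- .draw_factors(n_pairs, p)
  E_1  <- .draw_factors(n_pairs, p, chol_R)
  E_2  <- .draw_factors(n_pairs, p, chol_R)

  mz <- zyg == "MZ"
  male <- as.numeric(sex == "male")
  vals1 <- matrix(NA_real_, n_pairs, p)
  vals2 <- matrix(NA_real_, n_pairs, p)
  for (j in seq_len(p)) {
    m <- config$proteins[[j]]
    a <- sqrt(m$a2 * m$total_var)
    cc <- sqrt(m$c2 * m$total_var)
    d <- sqrt(m$d2 * m$total_var)
    e <- sqrt(m$e2 * m$total_var)
    A1 <- ifelse(mz, A_sh[, j], sqrt(0.5) * A_sh[, j] + sqrt(0.5) * A_u1[, j])
    A2 <- ifelse(mz, A_sh[, j], sqrt(0.5) * A_sh[, j] + sqrt(0.5) * A_u2[, j])
    D1 <- ifelse(mz, D_sh[, j], 0.5 * D_sh[, j] + sqrt(0.75) * D_u1[, j])
    D2 <- ifelse(mz, D_sh[, j], 0.5 * D_sh[, j] + sqrt(0.75) * D_u2[, j])
    base <- m$mu + m$beta_sex * male + m$beta_age * (age - config$age_mean)
    y1 <- base + a * A1 + cc * C_sh[, j] + d * D1 + e * E_1[, j]
    y2 <- base + a * A2 + cc * C_sh[, j] + d * D2 + e * E_2[, j]
    if (m$skew_transform == "exponential") {
      y1 <- exp(y1); y2 <- exp(y2)
    }
    vals1[, j] <- y1
    vals2[, j] <- y2
  }

  idx <- rep(seq_len(n_pairs), each = 2)
  member <- rep(1:2, n_pairs)
  df <- data.frame(
    subject_id = sprintf("%s_%d", pair_id[idx], member),
    pair_id = pair_id[idx],
    zygosity = zyg[idx],
    sex = sex[idx],
    age = age[idx],
    stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    v <- numeric(2L * n_pairs)
    v[member == 1] <- vals1[, j]
    v[member == 2] <- vals2[, j]
    df[[pnames[j]]] <- v
  }
  new_twin_cohort(df, pnames)
}

#' Serialize a simulation config to YAML
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  obj <- unclass(config)
  obj$proteins <- lapply(obj$proteins, unclass)
  if (!is.null(obj$cross_corr)) obj$cross_corr <- as.vector(obj$cross_corr)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a simulation config from YAML
#' @param path YAML file written by [write_sim_config()].
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  proteins <- lapply(obj$proteins, function(m) {
    protein_sim_model(m$name, mu = m$mu, a2 = m$a2, c2 = m$c2, d2 = m$d2,
                      e2 = m$e2, total_var = m$total_var,
                      beta_sex = m$beta_sex, beta_age = m$beta_age,
                      skew_transform = m$skew_transform)
  })
  cross <- NULL
  if (!is.null(obj$cross_corr)) {
    pn <- length(proteins)
    cross <- matrix(unlist(obj$cross_corr), pn, pn)
  }
  sim_config(obj$n_mz_pairs, obj$n_dz_pairs, obj$male_pair_fraction,
             obj$age_min, obj$age_max, obj$age_mean, proteins,
             seed = obj$seed, cross_corr = cross)
}
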