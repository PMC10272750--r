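#' Within-pair Pearson correlation for one zygosity group
#'
#' `ordering = "file_order"` correlates (y1, y2) as ordered in the input
#' file; because twins carry no natural order, `"double_entry"` augments the
#' data with member-swapped copies, which removes the arbitrary labelling
#' (an ICC-type estimator). The Fisher-z confidence interval always uses the
#' pair count as n — double entry does not double the information.
#'
#' @param pairs A `pair_observations` data frame, all of one zygosity.
#' @param ordering `"file_order"` (default) or `"double_entry"`.
#' @param conf_level Confidence level.
#' @return A `correlation_estimate` row (`r`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, `n_units` = number of pairs, `method`).
#' @export
within_pair_pearson <- function(pairs, ordering = c("file_order", "double_entry"),
                                conf_level = 0.95) {
  ordering <- match.arg(ordering)
  zyg <- unique(as.character(pairs$zygosity))
  if (length(zyg) > 1) stop("pairs must be of a single zygosity")
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 pairs")
  y1 <- pairs$y1; y2 <- pairs$y2
  if (stats::sd(y1) == 0 || stats::sd(y2) == 0) stop("zero variance")
  r <- if (ordering == "file_order") {
    stats::cor(y1, y2)
  } else {
    stats::cor(c(y1, y2), c(y2, y1))
  }
  z <- atanh(r)
  se_z <- 1 / sqrt(n - 3)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- data.frame(
    r = r, se = se_z,
    ci_low = tanh(z - zq * se_z), ci_high = tanh(z + zq * se_z),
    p_value = 2 * stats::pnorm(-abs(z / se_z)),
    n_obs = n, n_units = n,
    method = paste0("within-pair Pearson (", ordering, "), Fisher-z CI"),
    stringsAsFactors = FALSE)
  class(est) <- c("correlation_estimate", "data.frame")
  est
}

#' Intraclass correlation by exchangeable bivariate-normal maximum likelihood
#'
#' Fits, by ML, a bivariate normal for each pair with a common member
#' variance, within-pair correlation `rho`, and a mean that is either a
#' common intercept (unadjusted) or `beta0 + beta_age*age_i + beta_sex*I(male)`
#' (adjusted); covariates enter the joint likelihood in one stage, not by
#' pre-residualization. `rho` is the reported ICC. The default confidence
#' interval inverts the profile likelihood (robust near the `rho -> 1`
#' boundary); `ci_method = "fisher"` uses the faster Fisher-z approximation.
#'
#' @param pairs A `pair_observations` data frame, all of one zygosity.
#' @param covariates Character subset of `c("age", "sex")`; empty for the
#'   unadjusted model.
#' @param conf_level Confidence level.
#' @param ci_method `"profile"` (default) or `"fisher"`.
#' @return An `icc_estimate` list: `icc`, `ci_low`, `ci_high`, `adjusted`,
#'   `covariates`, `n_pairs`, `loglik`, `coefficients`, `sigma2`,
#'   `ci_method`, `converged`.
#' @export
icc_ml <- function(pairs, covariates = character(), conf_level = 0.95,
                   ci_method = c("profile", "fisher")) {
  ci_method <- match.arg(ci_method)
  if (length(covariates) > 0) {
    covariates <- match.arg(covariates, c("age", "sex"), several.ok = TRUE)
  }
  zyg <- unique(as.character(pairs$zygosity))
  if (length(zyg) > 1) stop("pairs must be of a single zygosity")
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 pairs")
  y1 <- pairs$y1; y2 <- pairs$y2
  des <- .mean_design(pairs, covariates)
  k <- ncol(des$X1)

  # theta = (betas, log sigma2, atanh rho)
  nll <- function(theta, rho_fixed = NULL) {
    if (is.null(rho_fixed)) {
      beta <- theta[seq_len(k)]
      s2 <- exp(theta[k + 1])
      rho <- tanh(theta[k + 2])
    } else {
      beta <- theta[seq_len(k)]
      s2 <- exp(theta[k + 1])
      rho <- rho_fixed
    }
    -.ll_bvn_pairs(y1, y2, drop(des$X1 %*% beta), drop(des$X2 %*% beta),
                   s2, rho * s2)
  }
  # moment start
  beta0 <- mean(c(y1, y2))
  s2_0 <- stats::var(c(y1, y2))
  r0 <- min(0.95, max(-0.95, stats::cor(c(y1, y2), c(y2, y1))))
  start <- c(beta0, rep(0, k - 1), log(s2_0), atanh(r0))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  icc <- tanh(opt$par[k + 2])
  ll_max <- -opt$value
  beta_hat <- opt$par[seq_len(k)]
  names(beta_hat) <- colnames(des$X1)

  if (ci_method == "fisher") {
    se_z <- 1 / sqrt(n - 3)
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(atanh(icc) + c(-1, 1) * zq * se_z)
  } else {
    ci <- .profile_ci_rho(nll, opt$par[seq_len(k + 1)], icc, ll_max,
                          conf_level)
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 adjusted = length(covariates) > 0, covariates = covariates,
                 n_pairs = n, loglik = ll_max,
                 coefficients = beta_hat, sigma2 = exp(opt$par[k + 1]),
                 ci_method = ci_method,
                 converged = opt$convergence == 0),
            class = "icc_estimate")
}

# Profile-likelihood CI for rho: roots of D(rho) = qchisq(conf, 1), profiling
# out mean and variance at each rho.
.profile_ci_rho <- function(nll, inner_start, rho_hat, ll_max, conf_level) {
  crit <- stats::qchisq(conf_level, df = 1) / 2
  prof <- function(rho) {
    op <- stats::optim(inner_start, function(th) nll(th, rho_fixed = rho),
                       method = "BFGS", control = list(reltol = 1e-12))
    (ll_max - (-op$value)) - crit
  }
  lo_bound <- -1 + 1e-8
  hi_bound <- 1 - 1e-8
  lo <- if (rho_hat <= lo_bound + 1e-8 || prof(lo_bound) < 0) {
    -1
  } else {
    stats::uniroot(prof, c(lo_bound, rho_hat), tol = 1e-6)$root
  }
  hi <- if (rho_hat >= hi_bound - 1e-8 || prof(hi_bound) < 0) {
    1
  } else {
    stats::uniroot(prof, c(rho_hat, hi_bound), tol = 1e-6)$root
  }
  c(lo, hi)
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC (%s): %.3f [%.3f, %.3f], %d pairs (%s CI)\n",
              if (x$adjusted) paste("adjusted for",
                                    paste(x$covariates, collapse = "+"))
              else "unadjusted",
              x$icc, x$ci_low, x$ci_high, x$n_pairs, x$ci_method))
  invisible(x)
}

#' Compare MZ and DZ within-pair correlations
#'
#' Two-sample Fisher-z test of equal correlations. A significantly larger MZ
#' correlation is the classical signature of a genetic component.
#'
#' @param est_mz,est_dz `correlation_estimate` rows carrying `r` and
#'   `n_units`.
#' @return List with `z`, `p_value` (two-sided) and `p_one_sided` (for
#'   r_MZ > r_DZ).
#' @export
compare_zygosity_correlations <- function(est_mz, est_dz) {
  stopifnot(!is.null(est_mz$n_units), !is.null(est_dz$n_units))
  z <- (atanh(est_mz$r) - atanh(est_dz$r)) /
    sqrt(1 / (est_mz$n_units - 3) + 1 / (est_dz$n_units - 3))
  list(z = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       p_one_sided = stats::pnorm(z, lower.tail = FALSE))
}

#' Zygosity-specific similarity table for a cohort
#'
#' One row per protein and zygosity with the Pearson correlation and the
#' unadjusted and age/sex-adjusted ML ICCs, each with its CI.
#'
#' @param cohort A `twin_cohort`.
#' @param proteins Protein names (default: all).
#' @param ordering Passed to [within_pair_pearson()].
#' @param ci_method Passed to [icc_ml()].
#' @return Data frame with one row per protein x zygosity.
#' @export
similarity_table <- function(cohort, proteins = cohort_proteins(cohort),
                             ordering = "file_order",
                             ci_method = "profile") {
  rows <- list()
  for (p in proteins) {
    po <- to_pair_observations(cohort, p, quiet = TRUE)
    for (z in c("MZ", "DZ")) {
      pz <- po[po$zygosity == z, ]
      pe <- within_pair_pearson(pz, ordering = ordering)
      iu <- icc_ml(pz, ci_method = ci_method)
      ia <- icc_ml(pz, covariates = c("age", "sex"), ci_method = ci_method)
      rows[[length(rows) + 1]] <- data.frame(
        protein = p, zygosity = z, n_pairs = nrow(pz),
        pearson_r = pe$r, pearson_lo = pe$ci_low, pearson_hi = pe$ci_high,
        icc_unadj = iu$icc, icc_unadj_lo = iu$ci_low,
        icc_unadj_hi = iu$ci_high,
        icc_adj = ia$icc, icc_adj_lo = ia$ci_low, icc_adj_hi = ia$ci_high,
        ordering = ordering, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
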