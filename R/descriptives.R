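#' Summary statistics for one protein's concentrations
#'
#' Reports the layout used for non-Gaussian analytes: n, min, P25, median,
#' P75, max, the max:min ratio (one decimal) and mean (SD). Quantiles use
#' linear interpolation between order statistics (`stats::quantile` type 7),
#' the common default; the P25/P75 values depend on this rule, so it is fixed
#' and documented.
#'
#' @param values Numeric vector of strictly positive concentrations.
#' @return A one-row data frame: `n`, `min`, `p25`, `median`, `p75`, `max`,
#'   `max_min_ratio`, `mean`, `sd`.
#' @export
summarize_protein <- function(values) {
  if (length(values) == 0) stop("no values to summarize")
  if (anyNA(values)) values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values to summarize")
  if (any(values <= 0)) {
    stop("all values must be positive (max:min ratio undefined otherwise)")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(
    n = length(values),
    min = min(values), p25 = q[1], median = q[2], p75 = q[3],
    max = max(values),
    max_min_ratio = round(max(values) / min(values), 1),
    mean = mean(values),
    sd = stats::sd(values))
}

#' Omnibus normality test
#'
#' Shapiro–Wilk for n up to 5000 (the implementation's supported range);
#' D'Agostino–Pearson K2 (combined skewness and kurtosis z-statistics) for
#' larger samples. The original analysis does not name its normality test;
#' this choice is a documented convention and the returned object records
#' which test ran.
#'
#' @param values Numeric vector, n >= 8.
#' @return List with `p_value`, `statistic`, `method`.
#' @export
test_normality <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8) stop("need at least 8 observations for the normality test")
  if (n <= 5000) {
    sw <- stats::shapiro.test(values)
    return(list(p_value = unname(sw$p.value), statistic = unname(sw$statistic),
                method = "Shapiro-Wilk"))
  }
  .dagostino_pearson(values)
}

# D'Agostino-Pearson omnibus K2: z-transforms of sample skewness (D'Agostino
# 1970) and kurtosis (Anscombe & Glynn 1983), K2 = zs^2 + zk^2 ~ chisq(2).
.dagostino_pearson <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness z
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  zs <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis z
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- zs^2 + zk^2
  list(p_value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       statistic = K2, method = "D'Agostino-Pearson K2")
}

#' Male-female contrast of median concentrations
#'
#' The contrast is the percent difference of medians,
#' `100 * (median_male - median_female) / median_female` (positive = higher
#' in males). Because co-twins share sex, subjects are not independent; the
#' p-value therefore comes from a cluster bootstrap that resamples whole
#' pairs with replacement and recomputes the median difference, rather than
#' from a naive rank test. The two-sided p is `2 * min(P(diff <= 0),
#' P(diff >= 0))` over bootstrap replicates (with the +1 small-sample
#' correction), capped at 1.
#'
#' @param cohort A `twin_cohort`.
#' @param protein Protein column name.
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Seed for the bootstrap resampling.
#' @return List with `pct_diff_median`, `median_male`, `median_female`,
#'   `p_value`, `n_boot`, `method`.
#' @export
sex_contrast <- function(cohort, protein, n_boot = 10000, seed = 1L) {
  if (!protein %in% cohort_proteins(cohort)) stop("unknown protein: ", protein)
  y <- cohort[[protein]]
  keep <- !is.na(y)
  y <- y[keep]
  sex <- as.character(cohort$sex)[keep]
  pid <- cohort$pair_id[keep]
  if (!any(sex == "male") || !any(sex == "female")) {
    stop("both sexes must be present")
  }
  med_m <- stats::median(y[sex == "male"])
  med_f <- stats::median(y[sex == "female"])
  pct <- 100 * (med_m - med_f) / med_f

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  ids <- unique(pid)
  by_pair <- split(seq_along(y), pid)[ids]
  diffs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    take <- unlist(by_pair[sample.int(length(ids), replace = TRUE)],
                   use.names = FALSE)
    yb <- y[take]; sb <- sex[take]
    mm <- if (any(sb == "male")) stats::median(yb[sb == "male"]) else NA_real_
    ff <- if (any(sb == "female")) stats::median(yb[sb == "female"]) else NA_real_
    diffs[b] <- mm - ff
  }
  diffs <- diffs[!is.na(diffs)]
  B <- length(diffs)
  p_lo <- (1 + sum(diffs <= 0)) / (B + 1)
  p_hi <- (1 + sum(diffs >= 0)) / (B + 1)
  list(pct_diff_median = pct, median_male = med_m, median_female = med_f,
       p_value = min(1, 2 * min(p_lo, p_hi)), n_boot = B,
       method = "cluster bootstrap of median difference (pairs resampled)")
}

#' Pearson correlation with twin-pair cluster-robust inference
#'
#' The point estimate is the ordinary Pearson correlation. Standard error,
#' confidence interval and p-value come from regressing standardized y on
#' standardized x (the slope equals r) with a sandwich variance estimator
#' clustered on the pair identifier, so within-pair dependence widens the
#' interval instead of biasing it. CI and p use the normal approximation on
#' the slope.
#'
#' @param x,y Numeric vectors of equal length.
#' @param cluster_id Cluster (pair) identifier per observation.
#' @param conf_level Confidence level (default 0.95).
#' @return A `correlation_estimate` data frame row: `r`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, `n_obs`, `n_units`, `method`.
#' @export
cluster_robust_correlation <- function(x, y, cluster_id, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) == length(cluster_id))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]; cluster_id <- cluster_id[keep]
  if (length(unique(cluster_id)) < 3) stop("need at least 3 clusters")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))
  fit <- stats::lm(ys ~ xs)
  r <- unname(stats::coef(fit)["xs"])
  vc <- sandwich::vcovCL(fit, cluster = cluster_id)
  se <- sqrt(vc["xs", "xs"])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- data.frame(
    r = r, se = se,
    ci_low = r - zq * se, ci_high = r + zq * se,
    p_value = 2 * stats::pnorm(-abs(r / se)),
    n_obs = length(x), n_units = length(unique(cluster_id)),
    method = "Pearson, cluster-robust (sandwich) inference",
    stringsAsFactors = FALSE)
  class(est) <- c("correlation_estimate", "data.frame")
  est
}

#' Assign the reporting age group
#'
#' Bins are left-open/right-closed: `<=75`, `(75,80]`, `(80,85]`, `>85`
#' years, so 75.0 falls in the first group and 80.0 in the second.
#'
#' @param age Numeric vector of ages (> 0), years.
#' @return Factor with levels `"<=75"`, `"(75,80]"`, `"(80,85]"`, `">85"`.
#' @export
assign_age_group <- function(age) {
  stopifnot(all(age > 0, na.rm = TRUE))
  cut(age, breaks = c(0, 75, 80, 85, Inf),
      labels = c("<=75", "(75,80]", "(80,85]", ">85"), right = TRUE)
}

#' Cluster-robust correlation of each protein with age
#'
#' @param cohort A `twin_cohort`.
#' @param proteins Protein names (default: all).
#' @param sex Optional `"male"` or `"female"` to restrict the cohort.
#' @return Data frame, one row per protein, columns of
#'   [cluster_robust_correlation()] plus `protein` and `sex`.
#' @export
age_correlations <- function(cohort, proteins = cohort_proteins(cohort),
                             sex = NULL) {
  df <- as.data.frame(cohort)
  label <- if (is.null(sex)) "all" else sex
  if (!is.null(sex)) df <- df[as.character(df$sex) == sex, ]
  rows <- lapply(proteins, function(p) {
    est <- cluster_robust_correlation(df$age, df[[p]], df$pair_id)
    cbind(data.frame(protein = p, sex = label, stringsAsFactors = FALSE), est)
  })
  do.call(rbind, rows)
}

#' Pairwise cluster-robust correlations between proteins
#'
#' @param cohort A `twin_cohort`.
#' @param proteins Protein names (default: all).
#' @return Data frame with one row per unordered protein pair.
#' @export
protein_correlations <- function(cohort, proteins = cohort_proteins(cohort)) {
  df <- as.data.frame(cohort)
  combos <- utils::combn(proteins, 2)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    p1 <- combos[1, k]; p2 <- combos[2, k]
    est <- cluster_robust_correlation(df[[p1]], df[[p2]], df$pair_id)
    cbind(data.frame(protein_1 = p1, protein_2 = p2,
                     stringsAsFactors = FALSE), est)
  })
  do.call(rbind, rows)
}
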