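# Bivariate-normal pair log-likelihood, common member variance v and
# within-pair covariance cv; m1/m2 are member means (scalar or vector).
# Returns -Inf outside the positive-definite region.
.ll_bvn_pairs <- function(y1, y2, m1, m2, v, cv) {
  n <- length(y1)
  if (n == 0L) return(0)
  det <- v * v - cv * cv
  if (!is.finite(det) || det <= 0 || v <= 0) return(-Inf)
  r1 <- y1 - m1
  r2 <- y2 - m2
  quad <- (v * (sum(r1 * r1) + sum(r2 * r2)) - 2 * cv * sum(r1 * r2)) / det
  -n * log(2 * pi) - 0.5 * n * log(det) - 0.5 * quad
}

# Central-difference gradient of f at x.
.num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xm <- x
    xp[i] <- xp[i] + hi
    xm[i] <- xm[i] - hi
    (f(xp) - f(xm)) / (2 * hi)
  }, numeric(1))
}

# Member design matrices for the mean model: intercept, optionally centered
# age and male indicator. Returns list(X1, X2, center) for pairs data.
.mean_design <- function(pairs, covariates) {
  n <- nrow(pairs)
  X1 <- matrix(1, n, 1)
  X2 <- matrix(1, n, 1)
  nms <- "beta0"
  center <- 0
  if ("age" %in% covariates) {
    center <- mean(c(pairs$age1, pairs$age2))
    X1 <- cbind(X1, pairs$age1 - center)
    X2 <- cbind(X2, pairs$age2 - center)
    nms <- c(nms, "beta_age")
  }
  if ("sex" %in% covariates) {
    male <- as.numeric(pairs$sex == "male")
    X1 <- cbind(X1, male)
    X2 <- cbind(X2, male)
    nms <- c(nms, "beta_sex")
  }
  colnames(X1) <- colnames(X2) <- nms
  list(X1 = X1, X2 = X2, age_center = center)
}
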