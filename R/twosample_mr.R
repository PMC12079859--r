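mr_estimate <- function(method, beta, se, pval, n_snp) {
  structure(list(method = method, beta = unname(beta), se = unname(se),
                 pval = unname(pval), n_snp = n_snp),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (SE %.4f, p = %.3g, nsnp = %d)\n",
              x$method, x$beta, x$se, x$pval, x$n_snp))
  invisible(x)
}

check_pairs <- function(pairs, min_snps, method) {
  if (nrow(pairs) < min_snps) {
    stop("insufficient instruments for ", method, ": need >= ", min_snps)
  }
}

ratio_stats <- function(pairs) {
  list(ratio = pairs$beta_out / pairs$beta_exp,
       ratio_se = abs(pairs$se_out / pairs$beta_exp))
}

#' Wald ratio for a single instrument
#'
#' `beta = beta_out / beta_exp` with the first-order delta-method SE
#' `|se_out / beta_exp|`.
#'
#' @param pair one row of a harmonized-pairs table.
#' @return an `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(pair) {
  if (pair$beta_exp == 0) stop("exposure beta is zero: Wald ratio undefined")
  b <- pair$beta_out / pair$beta_exp
  se <- abs(pair$se_out / pair$beta_exp)
  mr_estimate("wald", b, se, 2 * pnorm(-abs(b / se)), 1L)
}

ivw_closed_form <- function(bx, by, se_y) {
  w <- 1 / se_y^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  list(beta = beta, se_fixed = se_fixed, w = w)
}

#' Inverse-variance-weighted MR
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1/se_out^2`. The default multiplicative
#' random-effects model scales the fixed-effect SE by
#' `max(1, sqrt(Q/Q_df))`.
#'
#' @param pairs harmonized-pairs table.
#' @param model `"random"` (default) or `"fixed"`.
#' @return an `mr_estimate` with method `"ivw"`.
#' @export
ivw <- function(pairs, model = c("random", "fixed")) {
  model <- match.arg(model)
  check_pairs(pairs, 1, "ivw")
  if (nrow(pairs) == 1) {
    warning("single instrument: IVW reduces to the Wald ratio")
    return(wald_ratio(pairs[1, ]))
  }
  cf <- ivw_closed_form(pairs$beta_exp, pairs$beta_out, pairs$se_out)
  se <- cf$se_fixed
  if (model == "random") {
    rs <- ratio_stats(pairs)
    q <- sum((rs$ratio - cf$beta)^2 / rs$ratio_se^2)
    se <- se * max(1, sqrt(q / (nrow(pairs) - 1)))
  }
  mr_estimate("ivw", cf$beta, se, 2 * pnorm(-abs(cf$beta / se)), nrow(pairs))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an
#' intercept (weights `1/se_out^2`), after orienting all exposure betas
#' positive. The intercept estimates average directional pleiotropy; the
#' slope is the pleiotropy-adjusted causal effect. SEs use the
#' multiplicative random-effects convention (residual sd floored at 1)
#' and p-values a t reference on `k - 2` df.
#'
#' @param pairs harmonized-pairs table with at least 3 rows.
#' @return list with elements `slope` and `intercept`, each an
#'   `mr_estimate`.
#' @export
mr_egger <- function(pairs) {
  check_pairs(pairs, 3, "mr_egger")
  flip <- sign(pairs$beta_exp)
  flip[flip == 0] <- 1
  bx <- pairs$beta_exp * flip
  by <- pairs$beta_out * flip
  w <- 1 / pairs$se_out^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  scale <- max(1, sm$sigma) / sm$sigma
  k <- nrow(pairs)
  one <- function(term, method) {
    b <- sm$coefficients[term, 1]
    se <- sm$coefficients[term, 2] * scale
    mr_estimate(method, b, se, 2 * stats::pt(-abs(b / se), df = k - 2), k)
  }
  list(slope = one("bx", "egger_slope"),
       intercept = one("(Intercept)", "egger_intercept"))
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  b <- ratio[ord]
  ws <- w[ord] / sum(w)
  s <- cumsum(ws) - ws / 2
  if (s[1] >= 0.5) return(b[1])
  k <- max(which(s < 0.5))
  if (k == length(b)) return(b[length(b)])
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

boot_pairs <- function(pairs) {
  p <- pairs
  p$beta_exp <- rnorm(nrow(p), pairs$beta_exp, pairs$se_exp)
  p$beta_out <- rnorm(nrow(p), pairs$beta_out, pairs$se_out)
  p
}

#' Weighted-median MR
#'
#' Inverse-variance-weighted median of the per-instrument Wald ratios:
#' ratios are ordered, cumulative standardized weights computed, and the
#' 0.5 crossing found by linear interpolation. The SE comes from a
#' seeded parametric bootstrap (betas redrawn from their normal
#' approximations).
#'
#' @param pairs harmonized-pairs table with at least 3 rows.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed RNG seed.
#' @return an `mr_estimate` with method `"weighted_median"`.
#' @export
weighted_median <- function(pairs, n_boot = 1000, seed = 1) {
  check_pairs(pairs, 3, "weighted_median")
  rs <- ratio_stats(pairs)
  w <- 1 / rs$ratio_se^2
  est <- weighted_median_point(rs$ratio, w)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      p <- boot_pairs(pairs)
      r <- p$beta_out / p$beta_exp
      weighted_median_point(r, 1 / (p$se_out / p$beta_exp)^2)
    }, 1)
  })
  se <- sd(boot)
  mr_estimate("weighted_median", est, se, 2 * pnorm(-abs(est / se)), nrow(pairs))
}

weighted_mode_point <- function(ratio, w, bandwidth_factor) {
  s <- min(sd(ratio), mad(ratio))
  if (s == 0) return(ratio[1])
  h <- max(bandwidth_factor * 0.9 * s / length(ratio)^0.2, 1e-8)
  d <- density(ratio, weights = w / sum(w), bw = h,
               from = min(ratio) - 3 * h, to = max(ratio) + 3 * h, n = 2048)
  d$x[which.max(d$y)]
}

#' Weighted-mode MR
#'
#' Mode of the inverse-variance-weighted Gaussian kernel density over the
#' per-instrument Wald ratios. Bandwidth is `bandwidth_factor` times a
#' MAD-based rule (`0.9 * min(sd, mad) * k^(-1/5)`). SE from a seeded
#' parametric bootstrap.
#'
#' @param pairs harmonized-pairs table with at least 3 rows.
#' @param bandwidth_factor multiplier on the bandwidth rule (default 1).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed RNG seed.
#' @return an `mr_estimate` with method `"weighted_mode"`.
#' @export
weighted_mode <- function(pairs, bandwidth_factor = 1, n_boot = 1000, seed = 1) {
  check_pairs(pairs, 3, "weighted_mode")
  rs <- ratio_stats(pairs)
  w <- 1 / rs$ratio_se^2
  est <- weighted_mode_point(rs$ratio, w, bandwidth_factor)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      p <- boot_pairs(pairs)
      r <- p$beta_out / p$beta_exp
      weighted_mode_point(r, 1 / (p$se_out / p$beta_exp)^2, bandwidth_factor)
    }, 1)
  })
  se <- sd(boot)
  mr_estimate("weighted_mode", est, se, 2 * pnorm(-abs(est / se)), nrow(pairs))
}

#' Instrument heterogeneity and strength diagnostics
#'
#' Cochran's Q of the per-instrument Wald ratios around the IVW estimate
#' (`Q = sum w_j (ratio_j - beta_ivw)^2`, `w_j = (se_out_j /
#' beta_exp_j)^-2`), with `I2 = max(0, (Q - Q_df)/Q)` and the average
#' heterogeneity `Q_het = Q / (Q_df - 1)` (defined for `Q_df > 1`).
#' Per-instrument strength `F_j = (beta_exp_j / se_exp_j)^2` is averaged
#' into `mean_F`; `total_R2 = sum 2 eaf (1 - eaf) beta_exp^2` when EAF is
#' available.
#'
#' @param pairs harmonized-pairs table (>= 2 rows).
#' @param est the [ivw()] estimate computed on the same pairs.
#' @return list of class `heterogeneity_stats` with `Q`, `Q_df`, `Q_p`,
#'   `I2`, `Q_het`, `mean_F`, `total_R2`.
#' @export
heterogeneity <- function(pairs, est) {
  check_pairs(pairs, 2, "heterogeneity")
  rs <- ratio_stats(pairs)
  w <- 1 / rs$ratio_se^2
  q <- sum(w * (rs$ratio - est$beta)^2)
  q_df <- nrow(pairs) - 1
  f <- (pairs$beta_exp / pairs$se_exp)^2
  total_r2 <- if (!anyNA(pairs$eaf_exp)) {
    sum(2 * pairs$eaf_exp * (1 - pairs$eaf_exp) * pairs$beta_exp^2)
  } else NA_real_
  structure(list(Q = q, Q_df = q_df,
                 Q_p = stats::pchisq(q, q_df, lower.tail = FALSE),
                 I2 = if (q > 0) max(0, (q - q_df) / q) else 0,
                 Q_het = if (q_df > 1) q / (q_df - 1) else NA_real_,
                 mean_F = mean(f), total_R2 = total_r2),
            class = "heterogeneity_stats")
}

#' Steiger directionality test
#'
#' Compares the variance explained by the instruments in the exposure
#' versus the outcome using the sample-size-only approximation
#' `r2_j = z_j^2 / (z_j^2 + n - 2)` summed over instruments.
#' `direction_correct` is TRUE when the exposure r2 is at least the
#' outcome r2 (ties reported correct with `tie = TRUE`); the p-value is a
#' Fisher-z test comparing the two correlations.
#'
#' @param pairs harmonized-pairs table.
#' @param n_exp,n_out per-trait sample sizes; default to the median of
#'   the per-variant `n_exp` / `n_out` columns.
#' @return list of class `steiger_result` with `r2_exposure`,
#'   `r2_outcome`, `direction_correct`, `tie`, `steiger_p`.
#' @export
steiger <- function(pairs, n_exp = NULL, n_out = NULL) {
  if (is.null(n_exp)) n_exp <- median(pairs$n_exp)
  if (is.null(n_out)) n_out <- median(pairs$n_out)
  if (is.na(n_exp) || is.na(n_out)) stop("sample sizes required for Steiger test")
  z_x <- pairs$beta_exp / pairs$se_exp
  z_y <- pairs$beta_out / pairs$se_out
  r2x <- min(sum(z_x^2 / (z_x^2 + n_exp - 2)), 1)
  r2y <- min(sum(z_y^2 / (z_y^2 + n_out - 2)), 1)
  rx <- sqrt(r2x); ry <- sqrt(r2y)
  zstat <- (atanh(pmin(rx, 1 - 1e-12)) - atanh(pmin(ry, 1 - 1e-12))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  structure(list(r2_exposure = r2x, r2_outcome = r2y,
                 direction_correct = r2x >= r2y, tie = r2x == r2y,
                 steiger_p = 2 * pnorm(-abs(zstat))),
            class = "steiger_result")
}

#' PP_H4-weighted two-sample multivariable MR
#'
#' Tissue-partitioned MVMR on summary statistics: each instrument's
#' exposure beta is scaled by its colocalization posterior in each tissue
#' (`bx_A = bx * pp4_A`, `bx_B = bx * pp4_B`) and the outcome betas are
#' regressed on both scaled exposures jointly, without intercept, with
#' weights `1/se_out^2`. Coefficients are tissue-specific direct effects.
#' By default instruments below `pp4_thresh` in both tissues are
#' excluded (mirroring partition membership); set `exclude_below = FALSE`
#' to keep them at their (near-zero) weights.
#'
#' @param pairs harmonized-pairs table.
#' @param pp4 data.frame with columns `variant_id`, `pp4_a`, `pp4_b`
#'   (values in `[0, 1]`) covering every pair.
#' @param pp4_thresh membership gate (default 0.9, strict).
#' @param exclude_below drop instruments below the gate in both tissues?
#' @return list of class `mvmr_pp4_result` with elements `a`, `b` (each
#'   an `mr_estimate` with method `"mvmr"`) and `cond_F` (named numeric:
#'   heuristic conditional instrument-strength index per exposure).
#' @export
mvmr_pp4_weighted <- function(pairs, pp4, pp4_thresh = 0.9,
                              exclude_below = TRUE) {
  idx <- match(pairs$variant_id, pp4$variant_id)
  if (anyNA(idx)) stop("pp4 table does not cover all instruments")
  pa <- pp4$pp4_a[idx]; pb <- pp4$pp4_b[idx]
  if (any(pa < 0 | pa > 1 | pb < 0 | pb > 1)) stop("PP_H4 values must lie in [0, 1]")
  keep <- if (exclude_below) (pa > pp4_thresh | pb > pp4_thresh) else rep(TRUE, length(pa))
  if (sum(keep) < 2) stop("fewer than 2 instruments pass the PP_H4 gate")
  p <- pairs[keep, , drop = FALSE]
  pa <- pa[keep]; pb <- pb[keep]
  bxa <- p$beta_exp * pa
  bxb <- p$beta_exp * pb
  w <- 1 / p$se_out^2
  x <- cbind(a = bxa * sqrt(w), b = bxb * sqrt(w))
  active <- colSums(x^2) > 0
  if (all(active) && qr(x)$rank < 2) {
    stop("collinearity: the two PP_H4-scaled exposures are proportional")
  }
  k <- nrow(p)
  fit <- lm(p$beta_out ~ 0 + bxa + bxb, weights = w)
  sm <- summary(fit)
  scale <- max(1, sm$sigma) / sm$sigma
  one <- function(term) {
    cf <- sm$coefficients
    if (!term %in% rownames(cf) || is.na(coef(fit)[term])) {
      return(mr_estimate("mvmr", NA_real_, NA_real_, NA_real_, k))
    }
    b <- cf[term, 1]; se <- cf[term, 2] * scale
    mr_estimate("mvmr", b, se, 2 * pnorm(-abs(b / se)), k)
  }
  # heuristic conditional strength: weighted residual variance of each
  # scaled exposure after projecting out the other, per instrument
  cond_f <- c(a = NA_real_, b = NA_real_)
  if (all(active)) {
    ra <- resid(lm(bxa ~ 0 + bxb, weights = w))
    rb <- resid(lm(bxb ~ 0 + bxa, weights = w))
    cond_f <- c(a = sum(w * ra^2) / k, b = sum(w * rb^2) / k)
  }
  structure(list(a = one("bxa"), b = one("bxb"), cond_F = cond_f,
                 n_used = k),
            class = "mvmr_pp4_result")
}
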