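#' Build a weighted genetic risk score
#'
#' Per-individual weighted sum of effect-allele dosages,
#' `score_i = sum_j w_j * dosage_ij`, with weights taken from the
#' exposure GWAS betas of the instrument subset. Dosage columns must be
#' aligned to the exposure effect alleles before calling.
#'
#' @param cohort a [cohort_data()].
#' @param subset data.frame with columns `variant_id`, `weight`.
#' @return list of class `grs` with fields `score` (numeric per
#'   individual), `variant_ids`, `weights`.
#' @export
build_grs <- function(cohort, subset) {
  missing_ids <- setdiff(subset$variant_id, colnames(cohort$dosages))
  if (length(missing_ids) > 0) {
    stop("alignment error: variant(s) absent from dosage matrix: ",
         paste(head(missing_ids, 5), collapse = ", "))
  }
  w <- as.numeric(subset$weight)
  score <- as.numeric(cohort$dosages[, subset$variant_id, drop = FALSE] %*% w)
  structure(list(score = score, variant_ids = as.character(subset$variant_id),
                 weights = w),
            class = "grs")
}

#' Rank-based inverse normal transformation
#'
#' Blom-offset transform `qnorm((r_i - 3/8) / (n + 1/4))` with average
#' ranks for ties. Applied to continuous outcomes before IV regression.
#'
#' @param y numeric vector, `length(y) >= 2`, non-constant.
#' @return numeric vector of the same length.
#' @export
rank_int <- function(y) {
  if (length(y) < 2) stop("need at least two observations")
  if (length(unique(y)) == 1) stop("degenerate input: constant vector")
  r <- rank(y, ties.method = "average")
  qnorm((r - 3 / 8) / (length(y) + 1 / 4))
}

is_binary <- function(v) all(v %in% c(0, 1))

# assemble the model frame used by both IV stages
iv_frame <- function(cohort, outcome_name, covariates) {
  covs <- cohort$covariates[, covariates, drop = FALSE]
  names(covs) <- paste0(".cov_", seq_along(covariates))
  cbind(data.frame(.y = cohort$phenotypes[[outcome_name]]), covs)
}

stage1_fit <- function(x_std, grs_score, covs_df) {
  df <- cbind(data.frame(.x = x_std, .g = grs_score), covs_df)
  fit <- lm(.x ~ ., data = df)
  cf <- summary(fit)$coefficients
  # a constant (e.g. all-zero) score is dropped by lm; report F as NA
  f_stat <- if (".g" %in% rownames(cf) && !is.na(coef(fit)[".g"]))
    cf[".g", "t value"]^2 else NA_real_
  list(xhat = fitted(fit), f_stat = f_stat)
}

#' Covariate-adjusted one-sample instrumental-variable regression
#'
#' Two-stage estimator on individual-level data. Stage 1 regresses the
#' standardized exposure on the genetic risk score plus covariates;
#' stage 2 regresses the outcome on the stage-1 fitted exposure plus the
#' same covariates (linear for continuous outcomes, logistic for binary
#' ones). The estimate is the stage-2 coefficient on the fitted exposure,
#' i.e. per one SD of exposure. Standard errors are model-based by
#' default; `se_method = "bootstrap"` re-runs both stages on seeded
#' nonparametric resamples (recommended for logistic outcomes, where the
#' plug-in SE is anti-conservative).
#'
#' @param cohort a [cohort_data()].
#' @param grs a [build_grs()] result.
#' @param exposure_name continuous exposure column in
#'   `cohort$phenotypes`.
#' @param outcome_name outcome column (continuous or 0/1 binary).
#' @param covariates character vector of covariate column names.
#' @param se_method `"model"` or `"bootstrap"`.
#' @param n_boot bootstrap resamples (default 500).
#' @param seed RNG seed for the bootstrap.
#' @return list of class `iv_result` with `estimate`, `se`, `pval`,
#'   `model` ("univariable"), `outcome_type`, `n`, `f_stat`.
#' @export
iv_regression <- function(cohort, grs, exposure_name, outcome_name,
                          covariates, se_method = c("model", "bootstrap"),
                          n_boot = 500, seed = 1) {
  se_method <- match.arg(se_method)
  x <- cohort$phenotypes[[exposure_name]]
  if (is_binary(x)) stop("exposure must be continuous")
  y <- cohort$phenotypes[[outcome_name]]
  binary <- is_binary(y)
  if (binary && min(sum(y == 1), sum(y == 0)) < 10) {
    warning("fewer than 10 cases (or controls): estimate will be unstable")
  }
  covs_df <- iv_frame(cohort, outcome_name, covariates)[, -1, drop = FALSE]
  x_std <- x / sd(x)
  s1 <- stage1_fit(x_std, grs$score, covs_df)
  df2 <- cbind(data.frame(.y = y, .xhat = s1$xhat), covs_df)
  if (binary) {
    fit2 <- glm(.y ~ ., data = df2, family = binomial())
    if (!fit2$converged) stop("logistic stage failed to converge (separation?)")
  } else {
    fit2 <- lm(.y ~ ., data = df2)
  }
  cf <- summary(fit2)$coefficients
  est <- cf[".xhat", 1]
  se <- cf[".xhat", 2]
  if (se_method == "bootstrap") {
    n <- length(y)
    boot <- withr_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        s1b <- stage1_fit(x_std[idx], grs$score[idx], covs_df[idx, , drop = FALSE])
        df2b <- cbind(data.frame(.y = y[idx], .xhat = s1b$xhat),
                      covs_df[idx, , drop = FALSE])
        fb <- if (binary) suppressWarnings(glm(.y ~ ., data = df2b, family = binomial()))
              else lm(.y ~ ., data = df2b)
        coef(fb)[".xhat"]
      }, 1)
    })
    se <- sd(boot)
  }
  structure(list(estimate = unname(est), se = unname(se),
                 pval = 2 * pnorm(-abs(est / se)),
                 model = "univariable",
                 outcome_type = if (binary) "binary" else "continuous",
                 n = length(y), f_stat = s1$f_stat),
            class = "iv_result")
}

#' @export
print.iv_result <- function(x, ...) {
  cat(sprintf("%s IV estimate (%s outcome): %.4f (SE %.4f, p = %.3g, n = %d, F = %.1f)\n",
              x$model, x$outcome_type, x$estimate, x$se, x$pval, x$n, x$f_stat))
  invisible(x)
}

#' Two-score multivariable one-sample MR
#'
#' Quantifies the direct effect of each of two (possibly SNP-overlapping)
#' partition GRS. Stage 1 is run separately per score (exposure ~ GRS_k +
#' covariates); stage 2 regresses the outcome on both fitted exposures
#' plus covariates jointly. Each coefficient is the partition's direct
#' effect per SD of exposure.
#'
#' @param cohort a [cohort_data()].
#' @param grs_a,grs_b [build_grs()] results for the two partitions.
#' @param exposure_name,outcome_name,covariates as in
#'   [iv_regression()].
#' @return list of class `mvmr_onesample_result` with elements `a` and
#'   `b` (each an `iv_result` labelled "multivariable"; a score whose
#'   fitted exposure is dropped for collinearity gets NA estimate) and
#'   `fitted_cor`, the correlation of the two fitted exposures.
#' @export
mvmr_two_scores <- function(cohort, grs_a, grs_b, exposure_name,
                            outcome_name, covariates) {
  x <- cohort$phenotypes[[exposure_name]]
  if (is_binary(x)) stop("exposure must be continuous")
  y <- cohort$phenotypes[[outcome_name]]
  binary <- is_binary(y)
  covs_df <- iv_frame(cohort, outcome_name, covariates)[, -1, drop = FALSE]
  x_std <- x / sd(x)
  s1a <- stage1_fit(x_std, grs_a$score, covs_df)
  s1b <- stage1_fit(x_std, grs_b$score, covs_df)
  fc <- suppressWarnings(stats::cor(s1a$xhat, s1b$xhat))
  if (is.na(fc) || abs(fc) > 0.95) {
    xm <- cbind(1, s1a$xhat, s1b$xhat, as.matrix(covs_df))
    kappa_val <- tryCatch(kappa(xm, exact = TRUE), error = function(e) Inf)
    warning(sprintf("fitted exposures nearly collinear (cor = %.3f, condition number = %.3g)",
                    fc, kappa_val))
  }
  # a score that was dropped in its first stage (constant / collinear with
  # covariates) contributes no instrumented variation: exclude its fitted
  # exposure from stage 2 and flag the coefficient as NA
  use_a <- !is.na(s1a$f_stat); use_b <- !is.na(s1b$f_stat)
  if (!use_a && !use_b) stop("both scores degenerate in stage 1")
  df2 <- data.frame(.y = y)
  if (use_a) df2$.xa <- s1a$xhat
  if (use_b) df2$.xb <- s1b$xhat
  df2 <- cbind(df2, covs_df)
  fit2 <- if (binary) glm(.y ~ ., data = df2, family = binomial())
          else lm(.y ~ ., data = df2)
  cf <- summary(fit2)$coefficients
  one <- function(term, f_stat) {
    if (!term %in% rownames(cf) || is.na(coef(fit2)[term])) {
      res <- list(estimate = NA_real_, se = NA_real_, pval = NA_real_)
    } else {
      res <- list(estimate = unname(cf[term, 1]), se = unname(cf[term, 2]),
                  pval = 2 * pnorm(-abs(cf[term, 1] / cf[term, 2])))
    }
    structure(c(res, list(model = "multivariable",
                          outcome_type = if (binary) "binary" else "continuous",
                          n = length(y), f_stat = f_stat)),
              class = "iv_result")
  }
  structure(list(a = one(".xa", s1a$f_stat), b = one(".xb", s1b$f_stat),
                 fitted_cor = fc),
            class = "mvmr_onesample_result")
}
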