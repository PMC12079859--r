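test_that("wald_ratio arithmetic and its bootstrap-validated SE", {
  p <- make_pairs(0.1, 0.05, se_exp = 0.001, se_out = 0.02)
  w <- wald_ratio(p[1, ])
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(wald_ratio(make_pairs(0.1, 0)[1, ])$beta, 0)
  expect_error(wald_ratio(make_pairs(0, 0.1)[1, ]), "zero")

  # delta-method SE vs a large parametric bootstrap on one strong pair
  set.seed(1)
  b <- rnorm(2e5, 0.05, 0.02) / 0.1  # se_exp ~ 0 so only outcome varies
  expect_lt(abs(sd(b) / w$se - 1), 0.05)
})

test_that("ivw equals the closed-form weighted regression", {
  # symmetric toy case
  p <- make_pairs(c(1, 1), c(0.4, 0.6), se_out = 1)
  expect_equal(ivw(p, model = "fixed")$beta, 0.5)

  # k = 1 relaxes to the Wald ratio with a warning
  expect_warning(w1 <- ivw(make_pairs(0.1, 0.05)[1, ]), "single instrument")
  expect_equal(w1$beta, 0.5)

  # 20 random pairs against an independent WLS oracle
  set.seed(4)
  p2 <- make_pairs(rnorm(20, 0.1, 0.03), rnorm(20, 0.03, 0.02),
                   se_out = runif(20, 0.01, 0.05))
  est <- ivw(p2, model = "fixed")
  w <- 1 / p2$se_out^2
  expect_equal(est$beta, sum(w * p2$beta_exp * p2$beta_out) /
                 sum(w * p2$beta_exp^2), tolerance = 1e-12)
  fit <- lm(beta_out ~ 0 + beta_exp, data = p2, weights = w)
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / sum(w * p2$beta_exp^2)), tolerance = 1e-12)
  # random-effects SE never below fixed
  expect_gte(ivw(p2, model = "random")$se, est$se)
})

test_that("mr_egger recovers planted slope and intercept and is flip-invariant", {
  # exact fit: by = 0.3 * bx
  pe <- make_pairs(c(0.1, 0.2, 0.3), c(0.03, 0.06, 0.09))
  eg <- mr_egger(pe)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-9)
  expect_equal(eg$intercept$beta, 0, tolerance = 1e-9)

  set.seed(8)
  k <- 50
  bx <- runif(k, 0.05, 0.3)
  se_out <- runif(k, 0.005, 0.02)
  by <- 0.02 + 0.1 * bx + rnorm(k, 0, se_out)
  pr <- make_pairs(bx, by, se_out = se_out)
  eg1 <- mr_egger(pr)
  expect_lt(abs(eg1$slope$beta - 0.1), 2 * eg1$slope$se)
  expect_lt(abs(eg1$intercept$beta - 0.02), 2 * eg1$intercept$se)

  # joint sign flip of any pair leaves estimates unchanged
  pr2 <- pr
  pr2$beta_exp[3] <- -pr2$beta_exp[3]
  pr2$beta_out[3] <- -pr2$beta_out[3]
  eg2 <- mr_egger(pr2)
  expect_equal(eg2$slope$beta, eg1$slope$beta, tolerance = 1e-12)
  expect_equal(eg2$intercept$beta, eg1$intercept$beta, tolerance = 1e-12)

  expect_error(mr_egger(pr[1:2, ]), "insufficient")
})

test_that("weighted_median interpolates cumulative weights as hand-computed", {
  # odd k, equal weights: the middle ratio
  pm <- make_pairs(c(1, 1, 1), c(0.1, 0.3, 0.2), se_out = 1)
  expect_equal(weighted_median(pm, n_boot = 50, seed = 1)$beta, 0.2)

  # hand-computed interpolation: ratios (0.1, 0.2, 0.9), weights (1, 1, 8)
  ph <- make_pairs(c(1, 1, 1), c(0.1, 0.2, 0.9),
                   se_out = c(1, 1, sqrt(1 / 8)))
  # cumulative standardized weights: s = (cumsum(w) - w/2) / 10 = (.05,.15,.6)
  # 0.5 crossing between ratio 0.2 and 0.9: 0.2 + 0.7 * (0.5-0.15)/(0.6-0.15)
  hand <- 0.2 + (0.9 - 0.2) * (0.5 - 0.15) / (0.6 - 0.15)
  expect_equal(weighted_median(ph, n_boot = 50, seed = 1)$beta, hand,
               tolerance = 1e-12)

  # identical ratios: estimate c with small bootstrap SE
  pc <- make_pairs(c(0.1, 0.2, 0.3), c(0.05, 0.10, 0.15),
                   se_exp = 1e-6, se_out = 1e-6)
  wm <- weighted_median(pc, n_boot = 100, seed = 2)
  expect_equal(wm$beta, 0.5, tolerance = 1e-6)
  expect_lt(wm$se, 1e-4)
})

test_that("weighted_mode finds the dominant cluster and ignores weight scaling", {
  ratios <- c(rep(0.5, 7), 3, 3.2)
  pm <- make_pairs(rep(0.2, 9), 0.2 * ratios, se_out = 0.02)
  m1 <- weighted_mode(pm, n_boot = 50, seed = 1)
  expect_lt(abs(m1$beta - 0.5), 0.1)

  # identical ratios give the common value
  pc <- make_pairs(c(0.1, 0.2, 0.4), c(0.07, 0.14, 0.28), se_out = 0.01)
  expect_equal(weighted_mode(pc, n_boot = 50, seed = 1)$beta, 0.7,
               tolerance = 1e-6)

  # doubling all outcome SEs rescales weights uniformly: same mode
  pm2 <- pm
  pm2$se_out <- pm$se_out * 2
  m2 <- weighted_mode(pm2, n_boot = 50, seed = 1)
  expect_equal(m2$beta, m1$beta, tolerance = 1e-9)
})

test_that("heterogeneity implements Q, I2, Q_het and F as printed", {
  # identical ratios: Q = 0, I2 = 0
  pc <- make_pairs(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12), se_out = 0.01)
  h0 <- heterogeneity(pc, ivw(pc))
  expect_equal(h0$Q, 0, tolerance = 1e-18)
  expect_equal(h0$I2, 0)

  # constructed pairs: verify against independently computed Q, then the
  # printed transformations I2 = (Q - df)/Q and Q_het = Q/(df - 1)
  set.seed(6)
  p <- make_pairs(runif(6, 0.1, 0.3), rnorm(6, 0.05, 0.03),
                  se_exp = 0.01, se_out = runif(6, 0.01, 0.03))
  est <- ivw(p)
  h <- heterogeneity(p, est)
  ratio <- p$beta_out / p$beta_exp
  wq <- (p$beta_exp / p$se_out)^2
  q_oracle <- sum(wq * (ratio - est$beta)^2)
  expect_equal(h$Q, q_oracle, tolerance = 1e-12)
  expect_equal(h$Q_df, 5)
  expect_equal(h$I2, max(0, (q_oracle - 5) / q_oracle))
  expect_equal(h$Q_het, q_oracle / 4)
  # F for bx = 0.1, se_x = 0.01 is 100
  pF <- make_pairs(0.1, 0.05, se_exp = 0.01)
  expect_equal(heterogeneity(rbind(pF, pF), ivw(rbind(pF, pF)))$mean_F, 100)
  # total R2 from EAF
  expect_equal(h$total_R2, sum(2 * p$eaf_exp * (1 - p$eaf_exp) * p$beta_exp^2))
})

test_that("steiger orients X -> Y correctly", {
  # strong exposure, null outcome
  p <- make_pairs(rep(0.2, 5), rep(0.001, 5), se_exp = 0.01, se_out = 0.02)
  s <- steiger(p)
  expect_true(s$direction_correct)
  expect_lt(s$steiger_p, 0.05)
  expect_true(s$r2_exposure > s$r2_outcome)

  # symmetric case: tie reported as correct with the tie flag
  ps <- make_pairs(0.2, 0.2, se_exp = 0.02, se_out = 0.02)
  ss <- steiger(ps)
  expect_true(ss$direction_correct && ss$tie)
  expect_equal(ss$steiger_p, 1)

  p_na <- p
  p_na$n_exp <- NA
  expect_error(steiger(p_na), "sample size")

  # simulated X -> Y chain, 50 instruments, 100 seeds
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    bx <- rnorm(50, 0, 0.1)
    by <- 0.2 * bx + rnorm(50, 0, 0.005)
    steiger(make_pairs(bx, by, se_exp = 0.01, se_out = 0.01,
                       n_exp = 1e5, n_out = 1e5))$direction_correct
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})

test_that("mvmr_pp4_weighted reduces, errors and recovers as specified", {
  set.seed(11)
  k <- 20
  bx <- runif(k, 0.1, 0.3) * sample(c(-1, 1), k, TRUE)
  pp4a <- c(runif(10, 0.92, 1), runif(10, 0, 0.05))
  pp4b <- c(runif(10, 0, 0.05), runif(10, 0.92, 1))
  se_out <- runif(k, 0.01, 0.03)
  by <- 0.1 * bx * pp4a + 0 * bx * pp4b + rnorm(k, 0, se_out)
  pairs <- make_pairs(bx, by, se_out = se_out)
  tab <- data.frame(variant_id = pairs$variant_id, pp4_a = pp4a, pp4_b = pp4b)
  mv <- mvmr_pp4_weighted(pairs, tab)
  expect_lt(abs(mv$a$beta - 0.1), 2 * mv$a$se)
  expect_lt(abs(mv$b$beta - 0), 2 * mv$b$se)
  expect_equal(mv$n_used, 20)

  # pp4_b all zero: A equals univariable weighted regression on scaled bx
  tab0 <- tab; tab0$pp4_b <- 0
  mv0 <- mvmr_pp4_weighted(pairs, tab0)
  w <- 1 / pairs$se_out[1:10]^2  # only the ten A-members survive the gate
  keep <- tab0$pp4_a > 0.9
  bxa <- (pairs$beta_exp * tab0$pp4_a)[keep]
  byk <- pairs$beta_out[keep]
  wk <- 1 / pairs$se_out[keep]^2
  expect_equal(mv0$a$beta, sum(wk * bxa * byk) / sum(wk * bxa^2),
               tolerance = 1e-12)
  expect_true(is.na(mv0$b$beta))

  # proportional pp4 columns: collinearity error
  tabc <- tab; tabc$pp4_b <- tabc$pp4_a
  expect_error(mvmr_pp4_weighted(pairs, tabc), "collinear")

  expect_error(mvmr_pp4_weighted(pairs, tab[1:3, ]), "cover")
})

test_that("estimators agree under a no-pleiotropy simulation and ignore order", {
  set.seed(13)
  k <- 40
  bx <- runif(k, 0.08, 0.3)
  se_out <- runif(k, 0.008, 0.02)
  by <- 0.12 * bx + rnorm(k, 0, se_out)
  p <- make_pairs(bx, by, se_exp = 0.005, se_out = se_out)
  est <- list(ivw = ivw(p)$beta,
              egger = mr_egger(p)$slope$beta,
              wmedian = weighted_median(p, n_boot = 100, seed = 1)$beta,
              wmode = weighted_mode(p, n_boot = 100, seed = 1)$beta)
  for (e in est) expect_lt(abs(e - 0.12), 0.03)

  # pair-order invariance for the deterministic point estimates
  shuf <- p[sample.int(k), ]
  expect_equal(ivw(shuf)$beta, est$ivw, tolerance = 1e-12)
  expect_equal(mr_egger(shuf)$slope$beta, est$egger, tolerance = 1e-12)

  # fixed-effect IVW minimizes Q over a grid of candidate slopes
  q_of <- function(b) sum((by / bx - b)^2 * (bx / se_out)^2)
  b_ivw <- ivw(p, model = "fixed")$beta
  grid <- seq(b_ivw - 0.05, b_ivw + 0.05, length.out = 201)
  expect_true(all(q_of(b_ivw) <= vapply(grid, q_of, 1) + 1e-9))
})
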