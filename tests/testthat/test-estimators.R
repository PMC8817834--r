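test_that("Wald ratio arithmetic, sign, and error cases", {
  d <- data.frame(beta_exp = 0.5, se_exp = 0.01, beta_out = 0.1,
                  se_out = 0.05)
  est <- waldRatio(d)
  expect_equal(estimate(est), 0.2)
  expect_equal(stdError(est), 0.1)
  expect_equal(confInt(est), 0.2 + c(-1, 1) * qnorm(0.975) * 0.1)

  d$beta_exp <- -0.5
  expect_equal(estimate(waldRatio(d)), -0.2)
  expect_equal(stdError(waldRatio(d)), 0.1)

  d$beta_exp <- 0
  expect_error(waldRatio(d), "zero")

  # second-order SE exceeds first-order and adds the exposure term
  d2 <- data.frame(beta_exp = 0.5, se_exp = 0.05, beta_out = 0.1,
                   se_out = 0.05)
  expect_equal(stdError(waldRatio(d2, secondOrder = TRUE)),
               sqrt(0.05^2 / 0.25 + 0.01 * 0.0025 / 0.0625))
})

test_that("first-order Wald SE matches the Monte-Carlo SD of the ratio", {
  # sigma_Y / |beta_X * theta| = 0.02/0.25 = 0.08, well inside the regime
  bx <- 0.5; theta <- 0.5; sy <- 0.02
  est <- waldRatio(data.frame(beta_exp = bx, se_exp = 0.001,
                              beta_out = theta * bx, se_out = sy))
  set.seed(401)
  draws <- rnorm(1e5, theta * bx, sy) / bx
  expect_lt(abs(stdError(est) - sd(draws)) / sd(draws), 0.02)
})

test_that("IVW pooling: homogeneity, MRE inflation, single-instrument fallback", {
  # two instruments with identical ratio estimates: Q = 0, SE = fixed-effect
  d <- data.frame(beta_exp = c(0.2, 0.4), se_exp = 0.01,
                  beta_out = c(0.06, 0.12), se_out = c(0.02, 0.05))
  fit <- mrIVW(d)
  expect_equal(estimate(fit), 0.3)
  expect_equal(heterogeneity(fit)@q, 0)
  w <- d$beta_exp^2 / d$se_out^2
  expect_equal(stdError(fit), 1 / sqrt(sum(w)))

  # overdispersed set: SE inflated by sqrt(Q/(J-1)); underdispersion floored
  d3 <- randInstruments(8, seed = 5, theta = 0.2)
  d3$beta_out <- d3$beta_out + rnorm(8, 0, 0.3)   # gross heterogeneity
  fit3 <- mrIVW(d3)
  q <- heterogeneity(fit3)@q
  expect_gt(q / 7, 1)
  w3 <- d3$beta_exp^2 / d3$se_out^2
  expect_equal(stdError(fit3), sqrt(q / 7) / sqrt(sum(w3)))

  expect_message(one <- mrIVW(d[1, ]), "single instrument")
  expect_equal(methodLabel(one@estimate), "wald_ratio")
  expect_equal(estimate(one), 0.3)
})

test_that("IVW equals the zero-intercept WLS slope (lm oracle)", {
  for (s in 1:10) {
    d <- randInstruments(sample(4:12, 1), seed = 700 + s)
    expect_equal(estimate(mrIVW(d)), wlsOracleIVW(d), tolerance = 1e-12)
  }
})

test_that("weighted median interpolates at half the weight and is symmetric", {
  # equal weights, ratios {0.1, 0.2, 0.9}: plain median
  d <- data.frame(beta_exp = 1, se_exp = 0.01,
                  beta_out = c(0.1, 0.2, 0.9), se_out = 1)
  est <- mrWeightedMedian(d, nBoot = 200, seed = 1)
  expect_equal(estimate(est), 0.2)

  d2 <- randInstruments(9, seed = 12)
  e1 <- mrWeightedMedian(d2, nBoot = 100, seed = 9)
  perm <- d2[sample(nrow(d2)), ]
  e2 <- mrWeightedMedian(perm, nBoot = 100, seed = 9)
  expect_equal(estimate(e1), estimate(e2))

  expect_error(mrWeightedMedian(d2[1:2, ], nBoot = 100, seed = 1),
               "at least 3")
  expect_warning(mrWeightedMedian(d2, nBoot = 50, seed = 1), "nBoot")
  expect_error(mrWeightedMedian(d2, nBoot = 100), "seed")
})

test_that("weighted median resists directional contamination better than IVW", {
  # 3 of 10 instruments share a positive pleiotropic offset
  theta <- 0.1
  reps <- 200
  bias_ivw <- bias_wm <- numeric(reps)
  for (r in seq_len(reps)) {
    sc <- simulationScenario(10, theta, 5e4, 3e4, betaXScale = 0.15,
      pleiotropy = list(type = "outliers", indices = 1:3, offset_scale = 3),
      seed = 5000 + r)
    sim <- simulateHarmonized(sc)
    bias_ivw[r] <- estimate(mrIVW(sim$data)) - theta
    bias_wm[r] <- mrlong:::.weightedMedianPoint(
      sim$data$beta_out / sim$data$beta_exp,
      sim$data$beta_exp^2 / sim$data$se_out^2) - theta
  }
  expect_lt(abs(mean(bias_wm)), abs(mean(bias_ivw)))
})

test_that("MR-Egger recovers a noiseless affine relation exactly", {
  set.seed(33)
  bx <- runif(6, 0.1, 0.5)
  d <- data.frame(beta_exp = bx, se_exp = 0.01,
                  beta_out = 0.05 + 0.3 * bx, se_out = runif(6, 0.02, 0.08))
  eg <- mrEgger(d)
  expect_equal(estimate(eg@slope), 0.3, tolerance = 1e-12)
  expect_equal(estimate(eg@intercept), 0.05, tolerance = 1e-12)
  # zero residuals: multiplicative scale floored at 1, SEs = unscaled WLS
  w <- 1 / d$se_out^2
  X <- cbind(1, bx)
  V <- solve(t(X) %*% (w * X))
  expect_equal(stdError(eg@slope), sqrt(V[2, 2]), tolerance = 1e-9)
  expect_equal(stdError(eg@intercept), sqrt(V[1, 1]), tolerance = 1e-9)

  expect_error(mrEgger(d[1:2, ]), "at least 3")
  d0 <- d; d0$beta_exp <- 0.3
  expect_error(mrEgger(d0), "spread")
})

test_that("Egger slope and intercept match the WLS oracle on random instances", {
  for (s in 1:10) {
    d <- randInstruments(sample(5:15, 1), seed = 900 + s,
                         alpha = rnorm(1, 0, 0.05))
    eg <- mrEgger(d)
    or <- wlsOracleEgger(d)
    expect_equal(estimate(eg@slope), or$slope, tolerance = 1e-12)
    expect_equal(estimate(eg@intercept), or$intercept, tolerance = 1e-12)
  }
})

test_that("Egger intercept tracks the mean pleiotropic effect", {
  mu <- 0.04
  reps <- 300
  int_dir <- int_bal <- numeric(reps)
  # instruments are significance-selected (p < 5e-8 on the exposure), as
  # in any real instrument set; a SNP whose exposure effect is
  # indistinguishable from zero cannot be oriented, and its pleiotropic
  # offset would be misassigned, dragging the intercept at x = 0
  gws <- function(d) d[abs(d$beta_exp) / d$se_exp > qnorm(1 - 2.5e-8), ]
  for (r in seq_len(reps)) {
    sc_d <- simulationScenario(15, 0.1, 1e6, 5e4, betaXScale = 0.2,
      pleiotropy = list(type = "directional", mu_alpha = mu, tau = 0.01),
      seed = 7000 + r)
    sc_b <- simulationScenario(15, 0.1, 1e6, 5e4, betaXScale = 0.2,
      pleiotropy = list(type = "balanced", tau = 0.02),
      seed = 8000 + r)
    int_dir[r] <- estimate(
      mrEgger(gws(simulateHarmonized(sc_d)$data))@intercept)
    int_bal[r] <- estimate(
      mrEgger(gws(simulateHarmonized(sc_b)$data))@intercept)
  }
  expect_lt(abs(mean(int_dir) - mu), 3 * sd(int_dir) / sqrt(reps))
  expect_lt(abs(mean(int_bal)), 3 * sd(int_bal) / sqrt(reps))
})

test_that("leave-one-out reproduces direct subset recomputation", {
  d <- randInstruments(7, seed = 21)
  loo <- mrLeaveOneOut(d)
  expect_length(loo, 8L)
  expect_named(loo, c(d$snp, "(all)"))
  for (j in seq_len(7)) {
    direct <- mrIVW(d[-j, ])
    expect_equal(estimate(loo[[j]]), estimate(direct))
    expect_equal(stdError(loo[[j]]), stdError(direct))
  }
  expect_equal(estimate(loo[["(all)"]]), estimate(mrIVW(d)))

  # identical instruments: every leave-one-out estimate equals the full one
  dd <- data.frame(beta_exp = rep(0.3, 5), se_exp = 0.01,
                   beta_out = rep(0.09, 5), se_out = 0.04)
  loo2 <- mrLeaveOneOut(dd)
  ests <- vapply(loo2, estimate, numeric(1))
  expect_true(all(abs(ests - 0.3) < 1e-12))
})
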