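test_that("Daly encoding emits share-weighted effects coding", {
  # K = 2, equal shares: plain +1 / -1 effects coding
  df <- data.frame(g = c("a", "b", "a", "b"))
  de <- daly_encode(df, daly_spec(df))
  expect_equal(drop(de$X), c(1, -1, 1, -1), ignore_attr = TRUE)

  # K = 2, shares (0.8, 0.2): reference row scores -w1/w2 = -4
  df2 <- data.frame(g = c(rep("a", 8), rep("b", 2)))
  de2 <- daly_encode(df2, daly_spec(df2))
  expect_equal(unique(drop(de2$X)), c(1, -4))

  # K = 3, shares (0.5, 0.3, 0.2): reference row scores (-2.5, -1.5)
  df3 <- data.frame(g = c(rep("a", 5), rep("b", 3), rep("c", 2)))
  de3 <- daly_encode(df3, daly_spec(df3))
  expect_equal(unname(de3$X[10, ]), c(-2.5, -1.5))
  expect_equal(ncol(de3$X), 2L)

  # contract errors
  expect_error(daly_encode(data.frame(g = c("a", "x")), daly_spec(df2)),
               "not in spec")
  bad <- structure(list(g = list(categories = c("a", "b"),
                                 shares = c(1, 0))), class = "daly_spec")
  expect_error(daly_encode(df, bad), "zero-share reference")
  expect_error(daly_spec(data.frame(g = rep("a", 4))), ">= 2 categories")
})

test_that("implied coefficients satisfy the Daly constraint to 1e-10", {
  set.seed(21)
  df <- data.frame(
    a = sample(c("x", "y", "z"), 400, TRUE, prob = c(.5, .3, .2)),
    b = sample(c("u", "v"), 400, TRUE, prob = c(.7, .3)))
  de <- daly_encode(df, daly_spec(df))
  set.seed(22)
  sim <- generate_probit_data(rnorm(ncol(de$X), 0, 0.4),
                              c(-1, -0.3, 0.4, 1.1), design = de, seed = 23)
  fit <- fit_ordered_probit(de, sim$y)
  ic <- implied_coefficients(fit)
  for (cv in unique(ic$covariate)) {
    rows <- ic[ic$covariate == cv, ]
    expect_lt(abs(sum(rows$share * rows$coef)), 1e-10)
  }
})

test_that("predicted probabilities follow the normal threshold model", {
  X <- matrix(0, 1, 1)
  P <- predict_probs(0, c(-1, 0, 1, 2), X)
  expect_equal(P[1, 1], pnorm(-1), ignore_attr = TRUE)
  expect_equal(P[1, 2], pnorm(0) - pnorm(-1), ignore_attr = TRUE)
  expect_equal(sum(P), 1)
  # rows sum to 1, entries in (0,1), across random inputs
  set.seed(31)
  Xr <- matrix(rnorm(200 * 3), 200, 3)
  Pr <- predict_probs(c(0.4, -0.2, 0.1), c(-1.2, -0.2, 0.5, 1.4), Xr)
  expect_equal(rowSums(Pr), rep(1, 200), tolerance = 1e-12)
  expect_true(all(Pr > 0 & Pr < 1))
  # increasing the index strictly lowers the most-sedentary probability
  xb <- seq(-2, 2, length.out = 50)
  P1 <- predict_probs(1, c(-1, 0, 1, 2), matrix(xb))[, 1]
  expect_true(all(diff(P1) < 0))
  expect_error(predict_probs(1, c(0, 0, 1, 2), matrix(xb)),
               "strictly increasing")
})

test_that("log-likelihood matches closed forms and is additive", {
  X1 <- matrix(0, 1, 1)
  expect_equal(ordered_probit_loglik(0, c(0, 0.5, 1, 1.5), X1, 1), log(0.5))
  X2 <- rbind(X1, X1)
  expect_equal(ordered_probit_loglik(0, c(0, 0.5, 1, 1.5), X2, c(1, 1)),
               2 * log(0.5))
  expect_error(ordered_probit_loglik(0, c(0, 0.5, 1, 1.5), X1, 7),
               "outcomes must lie")
  # on average the true parameters beat perturbed ones
  set.seed(41)
  diffs <- replicate(10, {
    d <- generate_probit_data(c(0.5, -0.3), c(-1, -0.3, 0.4, 1.1),
                              n = 400, seed = sample.int(1e6, 1))
    ordered_probit_loglik(c(0.5, -0.3), c(-1, -0.3, 0.4, 1.1), d$X, d$y) -
      ordered_probit_loglik(c(0.8, 0.1), c(-1.3, -0.5, 0.6, 1.4), d$X, d$y)
  })
  expect_gt(mean(diffs), 0)
})

test_that("maximum likelihood recovers simulated parameters within 3 SEs", {
  beta <- c(0.5, -0.3, 0.2)
  eta <- c(-1, -0.3, 0.4, 1.1)
  d <- generate_probit_data(beta, eta, n = 5000, seed = 71)
  fit <- fit_ordered_probit(d$X, d$y)
  expect_true(fit$converged)
  expect_lt(fit$score_norm, 1e-8)
  expect_lt(fit$loglik, 0)
  z <- abs(c(fit$beta, fit$eta) - c(beta, eta)) / c(fit$se_beta, fit$se_eta)
  expect_true(all(z < 3))
})

test_that("the likelihood optimum is unique across random starts", {
  d <- generate_probit_data(c(0.4, -0.2), c(-0.8, 0, 0.6, 1.3),
                            n = 1000, seed = 81)
  set.seed(82)
  lls <- replicate(5, {
    init <- list(beta = rnorm(2, 0, 0.5),
                 eta = sort(rnorm(4, c(-1, -0.3, 0.4, 1.1), 0.2)))
    fit_ordered_probit(d$X, d$y, init = init)$loglik
  })
  expect_lt(diff(range(lls)), 1e-6)
})

test_that("fitted optimum matches the reference ordered probit (MASS::polr)", {
  skip_if_not_installed("MASS")
  d <- generate_probit_data(c(0.5, -0.3), c(-1, -0.3, 0.4, 1.1),
                            n = 2000, seed = 91)
  fit <- fit_ordered_probit(d$X, d$y)
  X <- d$X
  pf <- MASS::polr(factor(d$y) ~ X, method = "probit",
                   control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(fit$loglik, as.numeric(logLik(pf)), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(coef(pf)), tolerance = 1e-4)
  expect_equal(unname(fit$eta), unname(pf$zeta), tolerance = 1e-4)
})

test_that("estimator refuses designs missing an outcome category", {
  d <- generate_probit_data(0.3, c(-1, -0.3, 0.4, 1.1), n = 200, seed = 5)
  y <- d$y
  y[y == 5L] <- 4L
  expect_error(fit_ordered_probit(d$X, y), "category")
})

# a small fitted Daly model reused by the marginal-effects tests
fit_small_daly <- function(n = 50, seed = 301) {
  set.seed(seed)
  df <- data.frame(
    a = sample(c("x", "y", "z"), n, TRUE, prob = c(.5, .3, .2)),
    b = sample(c("u", "v"), n, TRUE))
  de <- daly_encode(df, daly_spec(df))
  sim <- generate_probit_data(seq(-0.4, 0.4, length.out = ncol(de$X)),
                              c(-1, -0.3, 0.4, 1.1), design = de,
                              seed = seed + 1)
  list(fit = fit_ordered_probit(de, sim$y), design = de)
}

test_that("marginal effects match an independent finite recomputation", {
  m <- fit_small_daly()
  fit <- m$fit
  for (cv in names(m$design$spec)) {
    cols <- which(m$design$map$covariate == cv)
    for (cat in m$design$spec[[cv]]$categories) {
      got <- marginal_effect_outcome1(fit, cv, cat)
      enc <- pasindex:::.daly_row(m$design$spec, cv, cat)
      want <- oracle_marginal_effect1(fit$beta, fit$eta[1], m$design$X,
                                      cols, enc)
      expect_equal(got$effect_pp, want, tolerance = 1e-10)
    }
  }
  expect_error(marginal_effect_outcome1(fit, "a", "nope"), "unknown category")
})

test_that("marginal effects across the five outcomes sum to zero", {
  m <- fit_small_daly(n = 120, seed = 311)
  for (cv in names(m$design$spec)) {
    for (cat in m$design$spec[[cv]]$categories) {
      tot <- sum(vapply(1:5, function(j)
        marginal_effect_outcome1(m$fit, cv, cat, outcome = j)$effect_pp,
        numeric(1)))
      expect_lt(abs(tot), 1e-10)
    }
  }
})

test_that("a category at the Daly average has zero effect, and signs invert", {
  m <- fit_small_daly(n = 200, seed = 321)
  fit <- m$fit
  # force one covariate's coefficients to zero: its categories all sit at
  # the average, so the discrete change vanishes
  fit0 <- fit
  cols <- which(m$design$map$covariate == "a")
  fit0$beta[cols] <- 0
  for (cat in m$design$spec[["a"]]$categories)
    expect_equal(marginal_effect_outcome1(fit0, "a", cat)$effect_pp, 0)
  # positive implied coefficient => less likely to be most sedentary
  ic <- implied_coefficients(fit)
  for (r in seq_len(nrow(ic))) {
    eff <- marginal_effect_outcome1(fit, ic$covariate[r], ic$category[r])
    if (abs(ic$coef[r]) > 1e-12)
      expect_true(sign(eff$effect_pp) == -sign(ic$coef[r]))
  }
})

test_that("significance stars follow the conventional thresholds", {
  expect_equal(stars(c(0.0005, 0.005, 0.03, 0.07, 0.5)),
               c("***", "**", "*", ".", ""))
  expect_equal(stars(0.001), "**")   # boundaries are strict
  expect_equal(stars(0.05), ".")
  expect_error(stars(1.2))
})
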