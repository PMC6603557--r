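test_that("paired t-test matches hand-computed values and the df convention", {
  r <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  # agreement with stats::t.test as an independent implementation
  set.seed(51)
  x <- rnorm(20); y <- rnorm(20)
  mine <- paired_t_test(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$ci, as.numeric(ref$conf.int), tolerance = 1e-12)
  # identical inputs; degenerate zero-variance difference
  same <- paired_t_test(x, x)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  degen <- paired_t_test(c(2, 3, 4), c(1, 2, 3))   # zero-variance difference
  expect_true(is.infinite(degen$t) && degen$p == 0 && degen$effect_r == 1)
  # 34 paired datasets give df = 33
  expect_equal(paired_t_test(rnorm(34), rnorm(34))$df, 33)
  expect_error(paired_t_test(1, 1), "two pairs")
})

test_that("the quadrature log-likelihood matches brute-force integration", {
  beta <- c(1.1, 0, -0.2, 0, -0.35, rep(0, 7))
  d <- simulate_lmm_data(beta, 0.4, 6, n_subjects = 2, n_datasets = 1, seed = 52)
  fit <- fit_gamma_lmm(d)
  X <- sepkit:::lmm_design(d)
  y <- d$n30_amplitude_uv
  subj <- as.integer(factor(d$subject_id))
  brute <- function(b, sg, sh) {
    eta <- drop(X %*% b)
    sum(sapply(seq_len(max(subj)), function(i) {
      jj <- subj == i
      log(stats::integrate(Vectorize(function(z) {
        mu <- exp(eta[jj] + z)
        exp(sum(stats::dgamma(y[jj], shape = sh, rate = sh / mu, log = TRUE)) +
              stats::dnorm(z, 0, sg, log = TRUE))
      }), -8 * sg, 8 * sg, rel.tol = 1e-12)$value)
    }))
  }
  expect_equal(fit$loglik, brute(fit$beta, fit$sigma_subject, fit$shape),
               tolerance = 1e-4)
  # and at a non-optimal point too
  gh <- pracma::gaussHermite(21)
  theta <- c(beta, log(0.3), log(5))
  expect_equal(sepkit:::gamma_lmm_loglik(theta, X, y, subj, gh, "log"),
               brute(beta, 0.3, 5), tolerance = 1e-4)
})

test_that("with no between-subject variance the fit collapses to the gamma GLM", {
  beta <- c(1.2, 0.05, -0.25, 0, -0.3, rep(0, 7))
  d <- simulate_lmm_data(beta, 0, 10, n_subjects = 12, n_datasets = 1, seed = 53)
  fit <- fit_gamma_lmm(d)
  glm0 <- stats::glm(d$n30_amplitude_uv ~ sepkit:::lmm_design(d) - 1,
                     family = stats::Gamma(link = "log"))
  expect_lt(max(abs(fit$beta - stats::coef(glm0))), 1e-3)
  expect_lt(fit$sigma_subject, 0.05)
})

test_that("an intercept-only constant response is fit exactly on the log scale", {
  d <- simulate_lmm_data(rep(0, 12), 0, 5, n_subjects = 3, n_datasets = 1,
                         seed = 54)
  d$n30_amplitude_uv <- 2.5
  fit <- suppressWarnings(fit_gamma_lmm(d))
  expect_equal(unname(fit$beta[1]), log(2.5), tolerance = 1e-4)
  expect_lt(max(abs(fit$beta[-1])), 1e-4)
})

test_that("AICc applies the small-sample correction", {
  fit <- list(loglik = -100, n_par = 14, n_obs = 408)
  class(fit) <- "gamma_lmm"
  expect_equal(aicc(fit), 200 + 28 + 2 * 14 * 15 / (408 - 15))
  expect_gt(aicc(fit), -2 * fit$loglik + 2 * 14)   # AICc > AIC
  expect_error(aicc(fit, n_obs = 15), "exceed")
})

test_that("estimated marginal means follow the cell coding", {
  beta <- c(1.11, 0.01, -0.21, 0.01, -0.35, 0.04, 0.02, 0.03, 0, 0.07, 0, -0.04)
  d <- simulate_lmm_data(beta, 0.3, 8, n_subjects = 17, n_datasets = 2, seed = 55)
  fit <- fit_gamma_lmm(d)
  em <- estimated_marginal_means(fit)
  expect_equal(nrow(em), 12)
  ref <- em[em$filter == "FIR" & em$band == "0.5-1000" & em$ica == "no", ]
  expect_equal(ref$emmean, exp(unname(fit$beta[1])), tolerance = 1e-10)
  # every cell mean within 3 SE of the generating truth
  truth <- exp(drop(sepkit:::lmm_design(em) %*% beta))
  expect_true(all(abs(em$emmean - truth) < 3.2 * em$se))
  expect_true(all(em$lcl < em$emmean & em$emmean < em$ucl))
})

test_that("all-equal responses give 12 identical cell means and unit ratios", {
  d <- simulate_lmm_data(rep(0, 12), 0, 5, n_subjects = 4, n_datasets = 1,
                         seed = 56)
  d$n30_amplitude_uv <- 3.1
  fit <- suppressWarnings(fit_gamma_lmm(d))
  em <- estimated_marginal_means(fit)
  expect_lt(diff(range(em$emmean)), 1e-3)
  ct <- lmm_contrasts(fit, "ica_within", seed = 1)
  expect_true(all(abs(ct$ratio - 1) < 1e-3))
})

test_that("contrast coding algebra holds: no-ICA/ICA at the reference cell is -beta2", {
  beta <- c(1.11, 0.01, -0.21, 0.01, -0.35, 0.04, 0.02, 0.03, 0, 0.07, 0, -0.04)
  d <- simulate_lmm_data(beta, 0.3, 8, n_subjects = 17, n_datasets = 2, seed = 57)
  fit <- fit_gamma_lmm(d)
  ct <- lmm_contrasts(fit, "ica_within", seed = 2)
  ref <- ct[ct$filter == "FIR" & ct$band == "0.5-1000", ]
  expect_equal(log(ref$ratio), -unname(fit$beta[3]), tolerance = 1e-10)
  expect_equal(nrow(ct), 6)
  expect_equal(nrow(lmm_contrasts(fit, "filter_within", seed = 2)), 6)
  expect_equal(nrow(lmm_contrasts(fit, "band_within", seed = 2)), 12)
})

test_that("single-step max-|z| adjustment controls family-wise error near nominal", {
  # the adjustment machinery is exercised directly on simulated z-vectors
  # with a known correlation, mirroring a no-effect model
  m <- 6
  set.seed(58)
  A <- matrix(rnorm(m * 12), m)
  V <- A %*% t(A) + diag(m)
  C <- stats::cov2cor(V)
  U <- chol(C)
  null_p <- replicate(500, {
    z <- drop(rnorm(m) %*% U)
    # package-style adjusted p for the most extreme statistic
    max(abs(z))
  })
  set.seed(59)
  Zd <- matrix(rnorm(1e5 * m), ncol = m) %*% U
  maxabs <- do.call(pmax, as.data.frame(abs(Zd)))
  crit <- stats::quantile(maxabs, 0.95, names = FALSE)
  fwe <- mean(null_p > crit)
  expect_lte(fwe, 0.06)
  expect_gte(fwe, 0.02)   # not absurdly conservative either
})

test_that("contrasts agree with glmer + emmeans on a simulated dataset", {
  beta <- c(1.11, 0.01, -0.21, 0.01, -0.35, 0.04, 0.02, 0.03, 0, 0.07, 0, -0.04)
  d <- simulate_lmm_data(beta, 0.3, 8, n_subjects = 17, n_datasets = 2, seed = 60)
  fit <- fit_gamma_lmm(d)
  dd <- transform(d,
                  filter = factor(filter, levels = c("FIR", "IIR")),
                  ica = factor(ica, levels = c("no", "yes")),
                  band = factor(band, levels = c("0.5-1000", "3-1000", "30-1000")))
  g <- suppressWarnings(
    lme4::glmer(n30_amplitude_uv ~ filter * ica * band + (1 | subject_id),
                data = dd, family = stats::Gamma(link = "log")))
  ref <- lme4::fixef(g)
  # same coding; Laplace vs adaptive quadrature -> small differences allowed
  expect_lt(max(abs(fit$beta[c(1, 2, 3, 4, 5)] -
                      ref[c("(Intercept)", "filterIIR", "icayes",
                            "band3-1000", "band30-1000")])), 0.03)
  em <- emmeans::emmeans(g, ~ filter * band * ica, type = "response")
  es <- as.data.frame(em)
  mine <- estimated_marginal_means(fit)
  key <- paste(mine$filter, mine$band, mine$ica)
  ref_key <- paste(es$filter, es$band, es$ica)
  expect_lt(max(abs(mine$emmean - es$response[match(key, ref_key)])), 0.05)
})

test_that("the identity link is fittable and AICc can compare links", {
  beta <- c(1.11, 0.01, -0.21, 0.01, -0.35, 0.04, 0.02, 0.03, 0, 0.07, 0, -0.04)
  d <- simulate_lmm_data(beta, 0.25, 8, n_subjects = 10, n_datasets = 2,
                         seed = 61)
  f_log <- fit_gamma_lmm(d, link = "log")
  f_id <- fit_gamma_lmm(d, link = "identity")
  expect_true(is.finite(f_id$aicc) && is.finite(f_log$aicc))
  # data generated under the log link should prefer it
  expect_lt(f_log$aicc, f_id$aicc)
})

test_that("responses must be positive and the grid complete", {
  d <- simulate_lmm_data(rep(0, 12), 0.2, 5, n_subjects = 3, seed = 62)
  d2 <- d; d2$n30_amplitude_uv[1] <- -1
  expect_error(fit_gamma_lmm(d2), "positive")
  d3 <- d[d$band != "30-1000", ]
  expect_error(fit_gamma_lmm(d3), "rank")
})

test_that("rescaling all responses shifts only the intercept", {
  beta <- c(1.0, 0, -0.2, 0, -0.3, rep(0, 7))
  d <- simulate_lmm_data(beta, 0.25, 8, n_subjects = 8, n_datasets = 1,
                         seed = 63)
  f1 <- fit_gamma_lmm(d)
  d2 <- d; d2$n30_amplitude_uv <- 4 * d2$n30_amplitude_uv
  f2 <- fit_gamma_lmm(d2)
  expect_equal(unname(f2$beta[1] - f1$beta[1]), log(4), tolerance = 1e-3)
  expect_lt(max(abs(f2$beta[-1] - f1$beta[-1])), 1e-3)
  c1 <- lmm_contrasts(f1, "ica_within", seed = 3)
  c2 <- lmm_contrasts(f2, "ica_within", seed = 3)
  expect_equal(c2$ratio, c1$ratio, tolerance = 1e-3)
  expect_equal(c2$z, c1$z, tolerance = 1e-2)
})
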