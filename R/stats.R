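#' Dependent (paired) t-test with effect size
#'
#' Classic paired t-test on the differences `d = x - y`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1`, two-sided p from the
#' t distribution, effect size `r = sqrt(t^2 / (t^2 + df))`, and a t-based
#' 95% CI for the mean difference.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `t`, `df`, `p`, `effect_r`, `mean_diff`, `ci`.
#' @export
paired_t_test <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least two pairs", call. = FALSE)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    ci <- c(m, m)
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df)
    q <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- m + c(-1, 1) * q * s / sqrt(n)
  }
  r <- if (is.infinite(t)) 1 else sqrt(t^2 / (t^2 + df))
  list(t = t, df = df, p = p, effect_r = r, mean_diff = m, ci = ci)
}

# Canonical 12-cell grid of the factorial design.
cell_grid <- function() {
  g <- expand.grid(ica = c("yes", "no"),
                   band = c("0.5-1000", "3-1000", "30-1000"),
                   filter = c("FIR", "IIR"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("filter", "band", "ica")]
}

# Fixed-effect model matrix with the reference coding FILTER (IIR = 1),
# ICA (yes = 1), FREQUENCY1 (3-1000 = 1), FREQUENCY2 (30-1000 = 1) and all
# interactions: 12 columns, full rank on the complete grid.
lmm_design <- function(df) {
  FIL <- as.numeric(df$filter == "IIR")
  ICA <- as.numeric(df$ica == "yes")
  F1 <- as.numeric(df$band == "3-1000")
  F2 <- as.numeric(df$band == "30-1000")
  if (any(!(df$band %in% c("0.5-1000", "3-1000", "30-1000"))))
    stop("unknown band level", call. = FALSE)
  X <- cbind(1, FIL, ICA, F1, F2, FIL * ICA, FIL * F1, FIL * F2,
             ICA * F1, ICA * F2, FIL * ICA * F1, FIL * ICA * F2)
  colnames(X) <- c("(Intercept)", "filterIIR", "icayes", "band3-1000",
                   "band30-1000", "filterIIR:icayes", "filterIIR:band3-1000",
                   "filterIIR:band30-1000", "icayes:band3-1000",
                   "icayes:band30-1000", "filterIIR:icayes:band3-1000",
                   "filterIIR:icayes:band30-1000")
  X
}

# Marginal log-likelihood of the gamma random-intercept model, integrating
# the scalar subject effect by adaptive (mode/curvature rescaled)
# Gauss-Hermite quadrature. theta = c(beta, log sigma, log shape).
gamma_lmm_loglik <- function(theta, X, y, subj, gh, link, zenv = NULL) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1])
  shape <- exp(theta[p + 2])
  eta <- drop(X %*% beta)
  S <- max(subj)
  nobs_i <- tabulate(subj, S)

  logf_sum <- function(z) {  # per-subject sum of gamma log-densities
    mu <- if (link == "log") exp(eta + z[subj]) else eta + z[subj]
    if (link == "identity" && any(mu <= 0)) return(rep(-Inf, S))
    lf <- shape * log(shape) - lgamma(shape) + (shape - 1) * log(y) -
      shape * log(mu) - shape * y / mu
    drop(rowsum(lf, subj))
  }

  # Newton for the per-subject mode of h(z) = sum_j log f + log phi(z);
  # warm-started from the previous evaluation's modes when available
  z <- numeric(S)
  if (!is.null(zenv) && !is.null(zenv$z) && length(zenv$z) == S) z <- zenv$z
  if (link == "identity") {
    zlow <- -vapply(split(eta, subj), min, numeric(1)) + 1e-6
    z <- pmax(z, zlow + 0.1)
  }
  g2 <- rep(-1, S)
  for (it in 1:60) {
    if (link == "log") {
      mu <- exp(eta + z[subj])
      g1 <- drop(rowsum(shape * (y / mu - 1), subj)) - z / sigma^2
      g2 <- -drop(rowsum(shape * y / mu, subj)) - 1 / sigma^2
    } else {
      mu <- eta + z[subj]
      if (any(mu <= 0)) return(-1e10)
      g1 <- drop(rowsum(shape * (y / mu^2 - 1 / mu), subj)) - z / sigma^2
      g2 <- drop(rowsum(shape * (1 / mu^2 - 2 * y / mu^3), subj)) - 1 / sigma^2
      g2 <- pmin(g2, -1e-8)
    }
    step <- g1 / g2
    znew <- z - step
    if (link == "identity") znew <- pmax(znew, zlow)
    z <- znew
    if (max(abs(step)) < 1e-10) break
  }
  if (!is.null(zenv)) zenv$z <- z
  s_i <- 1 / sqrt(-g2)

  T_ <- length(gh$x)
  hmat <- matrix(-Inf, S, T_)
  for (t in seq_len(T_)) {
    zt <- z + sqrt(2) * s_i * gh$x[t]
    ht <- logf_sum(zt) + stats::dnorm(zt, 0, sigma, log = TRUE)
    hmat[, t] <- ht + gh$x[t]^2
  }
  mx <- apply(hmat, 1, max)
  if (any(!is.finite(mx))) return(-1e10)
  ll_i <- log(sqrt(2) * s_i) + mx +
    log(rowSums(exp(hmat - mx) * rep(gh$w, each = S)))
  val <- sum(ll_i)
  if (!is.finite(val)) return(-1e10)
  val
}

#' Fit the gamma random-intercept model of the factorial comparison
#'
#' Maximum marginal likelihood for
#' \deqn{y_{ij} \sim \mathrm{Gamma}(\mathrm{shape},\ \mu_{ij}),\qquad
#'       g(\mu_{ij}) = x_{ij}^\top\beta + z_i,\qquad
#'       z_i \sim N(0, \sigma^2),}
#' with the 12-coefficient fixed-effect coding (reference cell: FIR,
#' 0.5-1000 Hz, no ICA) of filter class, passband and ICA use and all their
#' interactions, and a scalar subject random intercept. The subject
#' integral is evaluated by adaptive Gauss-Hermite quadrature (default 21
#' nodes, mode/curvature rescaled per subject) and `(\beta, \log\sigma,
#' \log \mathrm{shape})` are optimized jointly, starting from the
#' independence gamma GLM. With the log link, fixed effects act
#' multiplicatively and contrasts exponentiate to amplitude ratios.
#'
#' @param data `data.frame` with columns `subject_id`, `filter`
#'   (`"FIR"`/`"IIR"`), `band` (`"0.5-1000"`, `"3-1000"`, `"30-1000"`),
#'   `ica` (`"yes"`/`"no"`), `n30_amplitude_uv` (> 0).
#' @param link `"log"` (default) or `"identity"` (for AICc link selection).
#' @param nodes Number of Gauss-Hermite nodes (default 21).
#' @param start Optional start `c(beta, log sigma, log shape)`.
#' @param control Passed to [stats::nlminb()].
#' @return A `gamma_lmm` object: `beta`, `sigma_subject`, `shape`,
#'   `loglik`, `aicc`, `vcov` (fixed effects), `link`, convergence info.
#' @export
fit_gamma_lmm <- function(data, link = c("log", "identity"), nodes = 21L,
                          start = NULL, control = list(iter.max = 500,
                                                       eval.max = 1000)) {
  link <- match.arg(link)
  need <- c("subject_id", "filter", "band", "ica", "n30_amplitude_uv")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  y <- data$n30_amplitude_uv
  if (any(y <= 0))
    stop("responses must be strictly positive (gamma support)", call. = FALSE)
  X <- lmm_design(data)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient: the 12-cell grid is incomplete",
         call. = FALSE)
  subj <- as.integer(factor(data$subject_id))
  gh <- pracma::gaussHermite(nodes)
  zenv <- new.env(parent = emptyenv())
  negll <- function(theta) -gamma_lmm_loglik(theta, X, y, subj, gh, link, zenv)

  if (is.null(start)) {
    glm0 <- stats::glm(y ~ X - 1, family = stats::Gamma(link = link))
    disp <- summary(glm0)$dispersion
    start <- c(stats::coef(glm0), log(0.2), log(max(1 / disp, 0.1)))
  }
  opt <- stats::nlminb(start, negll, control = control)
  if (opt$convergence != 0 && opt$objective >= 1e9)
    stop("gamma mixed-model fit did not converge: ", opt$message, call. = FALSE)
  par <- opt$par
  p <- ncol(X)
  H <- stats::optimHess(par, negll)
  Vfull <- tryCatch(solve(H), error = function(e) {
    sv <- svd(H)
    d <- ifelse(sv$d > max(sv$d) * 1e-12, 1 / sv$d, 0)
    sv$v %*% (d * t(sv$u))
  })
  beta <- par[seq_len(p)]
  names(beta) <- colnames(X)
  vcov_beta <- Vfull[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  n_par <- p + 2L
  ll <- -opt$objective
  fit <- structure(list(
    beta = beta, sigma_subject = exp(par[p + 1]), shape = exp(par[p + 2]),
    loglik = ll, link = link, vcov = vcov_beta, vcov_full = Vfull,
    n_obs = length(y), n_subjects = max(subj), n_par = n_par,
    nodes = nodes, convergence = opt$convergence, message = opt$message),
    class = "gamma_lmm")
  fit$aicc <- aicc(fit)
  fit
}

#' @export
print.gamma_lmm <- function(x, ...) {
  cat(sprintf("<gamma_lmm> link=%s, n=%d obs / %d subjects\n", x$link,
              x$n_obs, x$n_subjects))
  cat(sprintf("  sigma_subject=%.3f, shape=%.2f, logLik=%.2f, AICc=%.2f\n",
              x$sigma_subject, x$shape, x$loglik, x$aicc))
  se <- sqrt(diag(x$vcov))
  print(round(data.frame(estimate = x$beta, se = se, t = x$beta / se), 3))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = AIC + 2p(p+1)/(n - p - 1)` with `p` the number of estimated
#' parameters (12 fixed effects + sigma + shape = 14) -- used to choose
#' between the identity and log links.
#'
#' @param fit A `gamma_lmm`.
#' @param n_obs Number of observations (default from the fit).
#' @return Numeric AICc.
#' @export
aicc <- function(fit, n_obs = fit$n_obs) {
  p <- fit$n_par
  if (n_obs - p - 1 <= 0)
    stop("AICc undefined: n must exceed the parameter count + 1", call. = FALSE)
  -2 * fit$loglik + 2 * p + 2 * p * (p + 1) / (n_obs - p - 1)
}

#' Estimated marginal means of the 12 design cells
#'
#' Model-based cell means on the response (microvolt) scale: for the log
#' link, `exp(x_cell' beta)` with delta-method SE and an exponentiated
#' normal-theory CI.
#'
#' @param fit A `gamma_lmm`.
#' @param level Confidence level (default 0.95).
#' @return `data.frame`: `filter`, `band`, `ica`, `emmean`, `se`, `lcl`,
#'   `ucl`.
#' @export
estimated_marginal_means <- function(fit, level = 0.95) {
  grid <- cell_grid()
  Xc <- lmm_design(grid)
  eta <- drop(Xc %*% fit$beta)
  se_eta <- sqrt(rowSums((Xc %*% fit$vcov) * Xc))
  q <- stats::qnorm(1 - (1 - level) / 2)
  if (fit$link == "log") {
    grid$emmean <- exp(eta)
    grid$se <- exp(eta) * se_eta
    grid$lcl <- exp(eta - q * se_eta)
    grid$ucl <- exp(eta + q * se_eta)
  } else {
    grid$emmean <- eta
    grid$se <- se_eta
    grid$lcl <- eta - q * se_eta
    grid$ucl <- eta + q * se_eta
  }
  grid
}

#' Ratio contrasts with single-step multiplicity adjustment
#'
#' Pairwise contrasts within one factor family, on the log scale (so the
#' reported estimate is an amplitude ratio), with asymptotic z statistics.
#' The default multiplicity adjustment is single-step: the null
#' distribution of the maximum |z| over the family is evaluated by seeded
#' Monte-Carlo sampling of a multivariate normal with the contrasts'
#' estimated correlation (an emmeans-style Tukey adjustment); the same
#' max-|z| quantile calibrates the simultaneous CIs. Holm and no adjustment
#' are available as fallbacks.
#'
#' @param fit A `gamma_lmm` with log link.
#' @param family `"filter_within"` (FIR/IIR at each band x ICA),
#'   `"band_within"` (the three band pairs at each filter x ICA) or
#'   `"ica_within"` (no-ICA/ICA at each filter x band).
#' @param adjust `"mc"`, `"holm"` or `"none"`.
#' @param level Confidence level.
#' @param n_draws Monte-Carlo draws for the max-|z| null (default 1e5).
#' @param seed Seed for the Monte-Carlo step (required for `"mc"`).
#' @return `data.frame` with the family labels, `ratio`, `se`, `lcl`,
#'   `ucl`, `z`, `p` (adjusted).
#' @export
lmm_contrasts <- function(fit, family = c("filter_within", "band_within",
                                          "ica_within"),
                          adjust = c("mc", "holm", "none"), level = 0.95,
                          n_draws = 1e5, seed = 1) {
  family <- match.arg(family)
  adjust <- match.arg(adjust)
  if (fit$link != "log")
    stop("ratio contrasts require the log link", call. = FALSE)
  grid <- cell_grid()
  Xc <- lmm_design(grid)
  row_of <- function(filter, band, ica)
    Xc[grid$filter == filter & grid$band == band & grid$ica == ica, ]
  bands <- c("0.5-1000", "3-1000", "30-1000")
  L <- list(); lab <- list()
  if (family == "filter_within") {
    for (ica in c("yes", "no")) for (b in bands) {
      L[[length(L) + 1L]] <- row_of("FIR", b, ica) - row_of("IIR", b, ica)
      lab[[length(lab) + 1L]] <- data.frame(ica = ica, band = b,
                                            contrast = "FIR/IIR")
    }
  } else if (family == "band_within") {
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    for (f in c("FIR", "IIR")) for (ica in c("yes", "no")) for (pr in pairs) {
      L[[length(L) + 1L]] <- row_of(f, bands[pr[1]], ica) -
        row_of(f, bands[pr[2]], ica)
      lab[[length(lab) + 1L]] <- data.frame(
        filter = f, ica = ica,
        contrast = paste(bands[pr[1]], bands[pr[2]], sep = "/"))
    }
  } else {
    for (f in c("FIR", "IIR")) for (b in bands) {
      L[[length(L) + 1L]] <- row_of(f, b, "no") - row_of(f, b, "yes")
      lab[[length(lab) + 1L]] <- data.frame(filter = f, band = b,
                                            contrast = "no-ICA/ICA")
    }
  }
  Lm <- do.call(rbind, L)
  est <- drop(Lm %*% fit$beta)
  V <- Lm %*% fit$vcov %*% t(Lm)
  se <- sqrt(diag(V))
  z <- est / se
  p_un <- 2 * stats::pnorm(-abs(z))
  m <- length(z)
  if (adjust == "mc") {
    C <- stats::cov2cor(V)
    set.seed(seed)
    U <- chol(C + diag(1e-10, m))
    Zd <- matrix(stats::rnorm(n_draws * m), n_draws, m) %*% U
    maxabs <- do.call(pmax, as.data.frame(abs(Zd)))
    p_adj <- vapply(abs(z), function(zz) (1 + sum(maxabs >= zz)) /
                      (n_draws + 1), numeric(1))
    crit <- stats::quantile(maxabs, level, names = FALSE)
  } else if (adjust == "holm") {
    p_adj <- stats::p.adjust(p_un, "holm")
    crit <- stats::qnorm(1 - (1 - level) / 2)
  } else {
    p_adj <- p_un
    crit <- stats::qnorm(1 - (1 - level) / 2)
  }
  out <- do.call(rbind, lab)
  out$ratio <- exp(est)
  out$se <- exp(est) * se      # delta-method SE on the ratio scale
  out$lcl <- exp(est - crit * se)
  out$ucl <- exp(est + crit * se)
  out$z <- z
  out$p <- p_adj
  out
}

#' Simulate amplitudes from the gamma random-intercept model
#'
#' Draws the complete 12-cell grid for `n_subjects` subjects x `n_datasets`
#' repeated datasets from the generative model: subject intercepts
#' `z_i ~ N(0, sigma^2)`, responses gamma with mean
#' `exp(x' beta + z_i)` (log link) and the given shape. Used for parameter
#' recovery and null simulations.
#'
#' @param beta 12-vector of fixed effects (log scale, Eq.-style coding).
#' @param sigma_subject Random-intercept SD.
#' @param shape Gamma shape parameter.
#' @param n_subjects,n_datasets Grid replication.
#' @param seed Seed.
#' @return `data.frame` in the input format of [fit_gamma_lmm()].
#' @export
simulate_lmm_data <- function(beta, sigma_subject, shape, n_subjects = 17,
                              n_datasets = 2, seed = 1) {
  stopifnot(length(beta) == 12L)
  set.seed(seed)
  cells <- cell_grid()
  df <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    do.call(rbind, lapply(seq_len(n_datasets), function(j) {
      d <- cells
      d$subject_id <- sprintf("S%02d", i)
      d$dataset_id <- sprintf("S%02d_D%d", i, j)
      d
    }))
  }))
  z <- stats::rnorm(n_subjects, 0, sigma_subject)
  zi <- z[as.integer(factor(df$subject_id))]
  mu <- exp(drop(lmm_design(df) %*% beta) + zi)
  df$n30_amplitude_uv <- stats::rgamma(nrow(df), shape = shape,
                                       rate = shape / mu)
  df[, c("subject_id", "dataset_id", "filter", "band", "ica",
         "n30_amplitude_uv")]
}
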