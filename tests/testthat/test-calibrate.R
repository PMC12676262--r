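# Calibration building blocks: prior transforms, Gibbs conditionals, the
# bias FFBS, Metropolis targets and the full sampler.

lognormal_priors <- function(mu, sigma)
  lapply(seq_along(mu), function(i)
    list(type = "lognormal", mu = mu[i], sigma = sigma[i]))

test_that("transform_phi: Jacobian values and round trips", {
  pr <- lognormal_priors(rep(0, 4), rep(1, 4))
  tp <- transform_phi(rep(1, 4), pr)
  # lognormal, eta = 1, sigma = 1: each factor (eta sigma)^{-1} = 1
  expect_equal(tp$log_jacobian, 0)
  expect_equal(tp$g, rep(0, 4))
  # uniform(0, 1) at 0.5: factor 2 + 2 = 4
  pu <- list(list(type = "uniform", a = 0, b = 1))
  expect_equal(transform_phi(0.5, pu)$log_jacobian, log(4))
  # round trip to 1e-12
  pr2 <- list(list(type = "lognormal", mu = -3, sigma = 0.5),
              list(type = "uniform", a = 0.2, b = 1.7))
  eta <- c(0.07, 0.9)
  expect_equal(inverse_transform_phi(transform_phi(eta, pr2)$g, pr2), eta,
               tolerance = 1e-12)
  # boundary values are flagged infinite
  expect_false(is.finite(transform_phi(c(0.2, 0.9),
                                       rev(pr2))$log_jacobian))
})

test_that("tau2_gibbs: prior reduction, scalar conjugacy, moments", {
  cfg <- calib_config(lognormal_priors(0, 0.5), n0z = 2, d0z = 1, b_t = 1)
  # zero residuals and zero increments: IG(S_field + b n0, b d0)
  Tn <- 3; Sf <- 2
  z <- matrix(0, Tn, Sf); y <- z; u <- matrix(0, Tn + 1, Sf)
  U_chol <- chol(diag(Sf))
  set.seed(701)
  draws <- replicate(3e4, tau2_gibbs(u, y, z, U_chol, cfg)[1])
  # reciprocal is Gamma(S_field + n0, rate d0)
  expect_equal(mean(1 / draws), (Sf + 2) / 1, tolerance = 0.02)
  ks <- suppressWarnings(ks.test(1 / draws, pgamma, shape = Sf + 2,
                                 rate = 1))
  expect_gt(ks$p.value, 0.01)
  # S_field = 1, U = 1: scalar normal-IG conjugacy with two Gaussian terms
  z1 <- matrix(1.4, 1, 1); y1 <- matrix(0.2, 1, 1)
  u1 <- matrix(c(0.3, 0.8), 2, 1)
  set.seed(702)
  d1 <- replicate(4e4, tau2_gibbs(u1, y1, z1, chol(diag(1)), cfg)[1])
  sh <- 1 + 2                       # S_field + b n0
  ra <- 1 + 0.5 * ((0.8 - 0.3)^2 + (1.4 - 0.2 - 0.8)^2)
  expect_equal(mean(1 / d1), sh / ra, tolerance = 0.02)
  expect_equal(var(1 / d1), sh / ra^2, tolerance = 0.05)
})

test_that("y_gibbs: precision-weighted limits and scalar arithmetic", {
  Sf <- 1
  mk_cond <- function(mu, Sig, factor = 0.5)
    list(list(mu = mu, Sigma = matrix(Sig), factor = factor))
  z <- matrix(2, 1, 1); u <- matrix(0, 2, 1)
  # tau2 -> Inf: posterior mean -> emulator mean
  set.seed(703)
  d <- replicate(3e3, y_gibbs(mk_cond(0.7, 0.4), 1e12, z, u)[1, 1])
  expect_equal(mean(d), 0.7, tolerance = 0.05)
  # Sigma -> large: posterior mean -> z - u
  d2 <- replicate(3e3, y_gibbs(mk_cond(0.7, 1e10), 0.3, z, u)[1, 1])
  expect_equal(mean(d2), 2, tolerance = 0.05)
  # scalar precision-weighted average by hand
  mu <- 0.7; Sig <- 0.4; tau2 <- 0.3
  B <- 1 / (1 / Sig + 1 / tau2)
  bmean <- B * (mu / Sig + 2 / tau2)
  d3 <- replicate(3e4, y_gibbs(mk_cond(mu, Sig), tau2, z, u)[1, 1])
  expect_equal(mean(d3), bmean, tolerance = 0.01)
  expect_equal(var(d3), B, tolerance = 0.05)
  # degenerate emulator conditional: y pinned at mu exactly
  d4 <- y_gibbs(mk_cond(0.7, 0, factor = 0), 0.3, z, u)
  expect_equal(d4[1, 1], 0.7)
})

test_that("bias_ffbs: scalar Kalman oracle and joint-Gaussian moments", {
  cfg <- calib_config(lognormal_priors(0, 0.5), m0z = 0, M0z = diag(1),
                      tau2_init = 1)
  # T = 1, S_field = 1 by hand: prior u1 ~ N(0, t0 M0 + t1) vs obs z - y
  z <- matrix(1.2, 1, 1); y <- matrix(0.2, 1, 1); tau2 <- 0.5
  set.seed(704)
  d <- replicate(4e4, bias_ffbs(z, y, tau2, diag(1), cfg)[2, 1])
  Atil <- 1 * 1 + tau2 * 1          # tau0^2 M0 + tau1^2 U
  Qtil <- Atil + tau2
  m1 <- Atil / Qtil * (1.2 - 0.2)
  C1 <- tau2 * (Atil - Atil^2 / Qtil) / tau2
  expect_equal(mean(d), m1, tolerance = 0.02)
  expect_equal(var(d), C1, tolerance = 0.05)
  # zero discrepancy with a tight prior: bias concentrates near zero
  cfg2 <- calib_config(lognormal_priors(0, 0.5), m0z = 0,
                       M0z = diag(2) * 1e-6, tau2_init = 1e-6)
  zb <- matrix(0, 3, 2); yb <- zb
  db <- bias_ffbs(zb, yb, rep(1e-6, 3), diag(2), cfg2)
  expect_lt(max(abs(db)), 0.05)
  # joint draw moments match the brute-force joint-Gaussian conditional
  # (T = 3, S_field = 2, random-walk state space)
  set.seed(705)
  Tn <- 3; Sf <- 2
  U <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  tau2v <- c(0.7, 0.4, 1.1)
  zc <- matrix(rnorm(Tn * Sf), Tn, Sf); yc <- matrix(0, Tn, Sf)
  cfg3 <- calib_config(lognormal_priors(0, 0.5), m0z = 0, M0z = diag(Sf),
                       tau2_init = 0.9)
  # oracle: joint Gaussian over u_0..u_3 (dim 8) observed via u_t + noise
  nb <- (Tn + 1) * Sf
  Om <- matrix(0, nb, nb)
  bi <- function(t) (t * Sf + 1):((t + 1) * Sf)
  Om[bi(0), bi(0)] <- 0.9 * diag(Sf)      # tau0^2 M0z
  for (t in 1:Tn) {
    for (s in 0:(t - 1)) {
      Om[bi(t), bi(s)] <- Om[bi(t - 1), bi(s)]
      Om[bi(s), bi(t)] <- t(Om[bi(t), bi(s)])
    }
    Om[bi(t), bi(t)] <- Om[bi(t - 1), bi(t - 1)] + tau2v[t] * U
  }
  obs <- unlist(lapply(1:Tn, bi))
  H <- Om[obs, obs] + diag(rep(tau2v, each = Sf))
  K <- Om[, obs] %*% solve(H)
  mean_or <- K %*% as.vector(t(zc))
  cov_or <- Om - K %*% t(Om[, obs])
  dj <- replicate(2e4, as.vector(t(bias_ffbs(zc, yc, tau2v, U, cfg3))))
  emp_mean <- rowMeans(dj)
  emp_cov <- cov(t(dj))
  expect_lt(max(abs(emp_mean - mean_or)), 0.03)
  expect_lt(max(abs(emp_cov - cov_or)), 0.05)
})

test_that("log_target_phi: scalar assembly, additivity, monotonicity", {
  pr <- list(list(type = "lognormal", mu = 0, sigma = 1))
  cfg <- calib_config(pr, rho = 1.5)
  Sf <- 1; Tn <- 1
  z <- matrix(1.5, 1, 1)
  state <- list(y = matrix(1.1, 1, 1), u = matrix(c(0, 0.2), 2, 1),
                tau2 = 0.5)
  cond <- list(list(mu = 0.9, Sigma = matrix(0.4), factor = 0.5))
  U <- diag(1)
  eta <- 1.3
  lt <- log_target_phi(eta, 1.5, state, cond, z, U, cfg)
  # hand assembly: y-term at (B b, B), z-term, bias innovation, prior
  B <- 1 / (1 / 0.4 + 1 / 0.5)
  bmean <- B * (0.9 / 0.4 + (1.5 - 0.2) / 0.5)
  hand <- dnorm(1.1, bmean, sqrt(B), log = TRUE) +
    dnorm(1.5, 1.1 + 0.2, sqrt(0.5), log = TRUE) +
    dnorm(0.2, 0, sqrt(0.5), log = TRUE) +
    dlnorm(eta, 0, 1, log = TRUE) - log(1 / (eta * 1))
  expect_equal(lt, hand, tolerance = 1e-10)
  # out-of-support value
  expect_identical(log_target_phi(-1, 1.5, state, cond, z, U, cfg), -Inf)
  # inflating the residuals decreases the target
  state_bad <- state; state_bad$y <- matrix(3.5, 1, 1)
  expect_lt(log_target_phi(eta, 1.5, state_bad, cond, z, U, cfg), lt)
  # additivity audit: changing only rho (through U) leaves the z-data and
  # y-emulator terms unchanged
  U2 <- diag(1) * 1  # scalar U cannot change; use two locations
  cfg2 <- calib_config(list(list(type = "lognormal", mu = 0, sigma = 1)),
                       rho = 1)
  z2 <- matrix(c(1.5, 0.4), 1, 2)
  st2 <- list(y = matrix(c(1.1, 0.3), 1, 2),
              u = rbind(c(0, 0), c(0.2, -0.1)), tau2 = 0.5)
  cond2 <- list(list(mu = c(0.9, 0.2), Sigma = diag(2) * 0.4,
                     factor = 0.5))
  Ua <- dynemu:::build_U(matrix(1:2, ncol = 1), 1)
  Ub <- dynemu:::build_U(matrix(1:2, ncol = 1), 3)
  la <- log_target_phi(1.3, 1, st2, cond2, z2, Ua, cfg2)
  lb <- log_target_phi(1.3, 3, st2, cond2, z2, Ub, cfg2)
  bias_term <- function(U, tau2, du)
    -0.5 * (2 * log(2 * pi * tau2) + as.numeric(determinant(U)$modulus) +
              t(du) %*% solve(U, du) / tau2)
  du <- c(0.2, -0.1)
  expect_equal(la - lb,
               as.numeric(bias_term(Ua, 0.5, du) - bias_term(Ub, 0.5, du)),
               tolerance = 1e-10)
})

test_that("metropolis_step: acceptance rules and a numeric-oracle rate", {
  # equal target values: always accept
  set.seed(706)
  for (i in 1:10) {
    st <- metropolis_step(0.3, function(g) 5, eps = 1)
    expect_true(st$accepted)
  }
  # vanishing proposal: the chain never moves beyond numerical noise
  st2 <- metropolis_step(c(1, 2), function(g) sum(-g^2), eps = 1e-12)
  expect_lt(max(abs(st2$g - c(1, 2))), 1e-9)
  # empirical acceptance on a standard normal target vs 2-D quadrature
  s <- 0.8
  set.seed(707)
  g <- 0; acc <- 0; n <- 2e4
  for (i in seq_len(n)) {
    st <- metropolis_step(g, function(x) dnorm(x, log = TRUE), eps = s)
    if (st$accepted) acc <- acc + 1
    g <- st$g
  }
  xs <- seq(-6, 6, length.out = 241)
  ys <- seq(-6, 6, length.out = 241)
  fx <- dnorm(xs)
  arate <- 0
  for (i in seq_along(xs)) {
    a <- pmin(1, dnorm(ys) / dnorm(xs[i]))
    arate <- arate + fx[i] * sum(dnorm(ys, xs[i], s) * a) * diff(ys)[1]
  }
  arate <- arate * diff(xs)[1]
  expect_equal(acc / n, arate, tolerance = 0.03)
})

test_that("emulator_conditional: interpolation identity and flat limit", {
  w <- lv_world()
  fit <- w$fit
  cache <- calib_prepare(fit, 1:2)
  fnew <- ar_fnew_builder(w$y0, 1)
  # eta equal to a training input: factor ~ 0 and mu equals the training row
  x3 <- fit$X[3, ]
  cond <- emulator_conditional(fit, x3, 2, 1:2, fnew, cache)
  expect_lt(cond[[1]]$factor, 1e-6)
  for (t in c(1, 5, fit$spec$n_time))
    expect_equal(cond[[t]]$mu, w$Y[t + 1, 3, ], tolerance = 1e-5,
                 ignore_attr = TRUE)
  # far input under a large decay: no borrowing, prior covariance intact
  far <- c(60, 60, 60, 60)
  cond2 <- emulator_conditional(fit, far, 2, 1:2, fnew, cache)
  expect_equal(cond2[[1]]$factor, 1, tolerance = 1e-12)
  expect_equal(cond2[[1]]$Sigma, cache$Sig_f[[2]], tolerance = 1e-10)
})

test_that("calibration chain: KF marginal equals a brute-force Gaussian", {
  # small AR(1) chain: compare calib_kf's marginal likelihood with the
  # direct joint-Gaussian density of the observations
  set.seed(708)
  w <- lv_world()
  cache <- calib_prepare(w$fit, 1:2)
  eta <- c(1.2, 0.05, 0.8, 0.05)
  ch <- dynemu:::calib_chain(w$fit, eta, 1, cache)
  Tn <- ch$Tn; S <- ch$S
  tau2 <- rep(0.3, Tn)
  v <- matrix(rnorm(Tn * S, sd = 0.8), Tn, S)
  # brute force: y-chain is linear-Gaussian; build the joint over all y_t
  nb <- Tn * S
  Mu <- matrix(0, Tn, S)
  x <- w$y0
  for (t in 1:Tn) { x <- as.numeric(ch$A[[t]] %*% x) + ch$cvec[[t]]
                    Mu[t, ] <- x }
  Om <- matrix(0, nb, nb)
  bi <- function(t) ((t - 1) * S + 1):(t * S)
  for (t in 1:Tn) {
    if (t == 1) {
      Om[bi(1), bi(1)] <- ch$W
    } else {
      for (s in 1:(t - 1)) {
        Om[bi(t), bi(s)] <- ch$A[[t]] %*% Om[bi(t - 1), bi(s)]
        Om[bi(s), bi(t)] <- t(Om[bi(t), bi(s)])
      }
      Om[bi(t), bi(t)] <- ch$A[[t]] %*% Om[bi(t - 1), bi(t - 1)] %*%
        t(ch$A[[t]]) + ch$W
    }
  }
  H <- Om + diag(rep(tau2, each = S))
  resid <- as.vector(t(v - Mu))
  ll_or <- -0.5 * (nb * log(2 * pi) +
                     as.numeric(determinant(H)$modulus) +
                     t(resid) %*% solve(H, resid))
  ll_kf <- dynemu:::calib_kf(ch, v, tau2, w$y0, 1:2)$loglik
  expect_equal(ll_kf, as.numeric(ll_or), tolerance = 1e-8)
})

test_that("run_calibration: Gibbs-only reduction recovers conditionals", {
  # eps = 0 proposals freeze eta at its start: the sampler is pure Gibbs
  # over (tau2, u, y); its tau2 draws must match the stated IG conditional
  w <- lv_world()
  set.seed(709)
  ytrue <- w$Y[-1, 2, ]
  fd <- make_field_data(ytrue, tau2 = 0.05^2, bias = FALSE)
  cfg <- calib_config(w$marg, rho = 1.5, eps = 1e-12, eps_big = 1e-12,
                      adapt = 0)
  cal <- run_calibration(fd$z, w$fit, 1:2, cfg, iters = 200,
                         eta_init = w$X[2, ])
  expect_equal(unname(cal$eta[200, ]), unname(w$X[2, ]), tolerance = 1e-9)
  # at a training input the latent y is pinned to the training trajectory
  expect_lt(max(abs(cal$y[200, , ] - ytrue)), 0.05)
  # tau2 draws stay within the support of the stated IG conditional
  expect_true(all(cal$tau2 > 0))
  # traces have the documented shapes
  expect_equal(dim(cal$eta), c(200L, 4L))
  expect_equal(dim(cal$u), c(200L, nrow(fd$z) + 1L, 2L))
})

test_that("bias-modularized mode updates the bias path post hoc", {
  w <- lv_world()
  set.seed(710)
  ytrue <- w$Y[-1, 4, ]
  fd <- make_field_data(ytrue, tau2 = 0.05^2, bias = FALSE)
  cfg <- calib_config(w$marg, rho = 1.5, bias_modularized = TRUE)
  cal <- run_calibration(fd$z, w$fit, 1:2, cfg, iters = 100)
  expect_true(all(is.finite(cal$u)))
  expect_true(all(is.finite(cal$eta)))
  s <- summary(cal, burn = 20)
  expect_equal(nrow(s), 4)
})
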