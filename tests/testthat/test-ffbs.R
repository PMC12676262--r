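# Forward filter, backward smoother/sampler and predictive distributions,
# checked against hand evaluations and the brute-force joint-Gaussian oracle.

test_that("forward_filter reproduces the scalar hand evaluation", {
  spec <- dlm_spec(matrix(1), matrix(1), matrix(1), matrix(1), 1, "mniw",
                   m0 = matrix(0), M0 = matrix(1), n0 = 2, D0 = matrix(1))
  f <- forward_filter(list(matrix(3)), spec)
  expect_equal(f$a[[1]][1, 1], 0)
  expect_equal(f$A[[1]][1, 1], 2)
  expect_equal(f$Q[[1]][1, 1], 3)
  expect_equal(f$m[[2]][1, 1], 2)
  expect_equal(f$M[[2]][1, 1], 2 / 3)
  expect_equal(f$D[[2]][1, 1], 1 + 3)
  expect_equal(f$n[2], 3)
})

test_that("infinite observation noise makes the filter ignore the data", {
  set.seed(201)
  inst <- random_dlm(p = 2, N = 2, S = 2, Tn = 2)
  spec_noisy <- dlm_spec(inst$FF, inst$G, lapply(inst$V, function(v) 1e12 * v),
                         inst$W, 2, "mniw", inst$m0, inst$M0,
                         n0 = 4, D0 = diag(2))
  f <- forward_filter(inst$Y, spec_noisy)
  for (t in 1:2) {
    expect_equal(f$m[[t + 1]], f$a[[t]], tolerance = 1e-6)
    expect_equal(f$M[[t + 1]], f$A[[t]], tolerance = 1e-6)
  }
})

test_that("filter and smoother match the joint-Gaussian oracle", {
  set.seed(202)
  for (rep in 1:3) {
    inst <- random_dlm(p = sample(1:3, 1), N = sample(1:3, 1),
                       S = sample(1:3, 1), Tn = sample(2:4, 1))
    filt <- forward_filter(inst$Y, inst$spec)
    sm <- backward_moments(filt)
    orc <- dlm_joint_oracle(inst)
    Tn <- inst$spec$n_time
    for (t in seq_len(Tn)) {
      of <- oracle_filtered(orc, t)
      expect_equal(filt$m[[t + 1]], of$mean, tolerance = 1e-8)
      expect_equal(filt$M[[t + 1]], of$cov, tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
    for (t in 0:Tn) {
      os <- oracle_smoothed(orc, t)
      expect_equal(sm$h[[t + 1]], os$mean, tolerance = 1e-8)
      expect_equal(sm$H[[t + 1]], os$cov, tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
    expect_equal(filt$D[[Tn + 1]],
                 inst$spec$D0 + orc$D_increment, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(filt$n[Tn + 1],
                 inst$spec$n0 + sum(vapply(inst$Y, nrow, 1L)))
  }
})

test_that("mnig filter: scalar identity, zero residual, shared moments", {
  set.seed(203)
  inst <- random_dlm(p = 2, N = 3, S = 1, Tn = 3)
  spec_ig <- dlm_spec(inst$FF, inst$G, inst$V, inst$W, 3, "mnig",
                      inst$m0, inst$M0, n0 = 2, d0 = 1, R = matrix(1))
  f_iw <- forward_filter(inst$Y, inst$spec)
  f_ig <- forward_filter(inst$Y, spec_ig)
  # S = 1, R = 1: rate increments are half the D increments
  for (t in 1:3) {
    expect_equal(f_ig$d[t + 1] - f_ig$d[t],
                 (f_iw$D[[t + 1]][1, 1] - f_iw$D[[t]][1, 1]) / 2,
                 tolerance = 1e-10)
    # mean/row-covariance recursions are shared
    expect_equal(f_ig$m[[t + 1]], f_iw$m[[t + 1]], tolerance = 1e-12)
    expect_equal(f_ig$M[[t + 1]], f_iw$M[[t + 1]], tolerance = 1e-12)
  }
  expect_equal(f_ig$n[4], 2 + 3 * 3 * 1 / 2)
  # zero residual: d unchanged, shape still increments
  spec0 <- dlm_spec(matrix(1), matrix(1), matrix(1), matrix(0), 1, "mnig",
                    m0 = matrix(2), M0 = matrix(1e-12), n0 = 2, d0 = 1,
                    R = matrix(1))
  f0 <- forward_filter(list(matrix(2)), spec0)
  expect_equal(f0$d[2], 1, tolerance = 1e-9)
  expect_equal(f0$n[2], 2.5)
})

test_that("backward_moments: T = 1 and the W = 0, G = I collapse", {
  spec <- dlm_spec(matrix(1), matrix(1), matrix(1), matrix(1), 1, "mniw",
                   m0 = matrix(0), M0 = matrix(1), n0 = 2, D0 = matrix(1))
  filt <- forward_filter(list(matrix(3)), spec)
  sm <- backward_moments(filt)
  expect_equal(sm$h[[2]], filt$m[[2]])
  expect_equal(sm$H[[2]], filt$M[[2]])
  # W = 0, G = I: smoothed means constant over time
  set.seed(204)
  Tn <- 3; N <- 2; S <- 2; p <- 2
  FF <- lapply(1:Tn, function(t) matrix(rnorm(N * p), N, p))
  Y <- lapply(1:Tn, function(t) matrix(rnorm(N * S), N, S))
  spec2 <- dlm_spec(FF, diag(p), diag(N), matrix(0, p, p), Tn, "mniw",
                    m0 = matrix(0, p, S), M0 = diag(p), n0 = S + 2,
                    D0 = diag(S))
  sm2 <- backward_moments(forward_filter(Y, spec2))
  for (t in 0:(Tn - 1))
    expect_equal(sm2$h[[t + 1]], sm2$h[[t + 2]], tolerance = 1e-10)
})

test_that("ffbs draws: terminal marginals, prior limit, lag-1 conditional", {
  set.seed(205)
  inst <- random_dlm(p = 1, N = 1, S = 1, Tn = 3)
  L <- 6000
  dr <- ffbs(inst$Y, inst$spec, L)
  filt <- dr$filter
  Tn <- 3
  # Theta_T marginal: hyper-T with (m_T, M_T, n_T, D_T); mean and variance
  thT <- dr$Theta[, Tn + 1, 1, 1]
  nT <- filt$n[Tn + 1]; DT <- filt$D[[Tn + 1]][1, 1]; MT <- filt$M[[Tn + 1]][1, 1]
  expect_equal(mean(thT), filt$m[[Tn + 1]][1, 1], tolerance = 0.06)
  expect_equal(var(thT), MT * DT / (nT - 2), tolerance = 0.12 * MT * DT)
  # Sigma draws have mean D_T / (n_T - 2)
  expect_equal(mean(dr$Sigma[, 1, 1]), DT / (nT - 2),
               tolerance = 0.1 * DT / (nT - 2))
  # lag-1 conditional: regression slope of Theta_t on Theta_{t+1} equals the
  # smoothing gain M_t G' A_{t+1}^{-1}
  t <- 2
  gain <- filt$M[[t + 1]][1, 1] * inst$G[[t + 1]][1, 1] / filt$A[[t + 1]][1, 1]
  slope <- coef(lm(dr$Theta[, t + 1, 1, 1] ~ dr$Theta[, t + 2, 1, 1]))[2]
  expect_equal(unname(slope), gain, tolerance = 0.12 * max(abs(gain), 0.1))
  # huge V: posterior path draws reproduce the prior path distribution
  specV <- dlm_spec(inst$FF, inst$G, lapply(inst$V, function(v) 1e10 * v),
                    inst$W, 3, "mniw", inst$m0, inst$M0, n0 = 3,
                    D0 = matrix(1))
  drV <- ffbs(inst$Y, specV, 4000)
  th0 <- drV$Theta[, 1, 1, 1]
  expect_equal(mean(th0), inst$m0[1, 1], tolerance = 0.1)
})

test_that("predictive_conditional: interpolation, J = 0, scalar case", {
  set.seed(206)
  N <- 5; p <- 2; S <- 2
  X <- matrix(runif(N * 2), N, 2)
  V <- sq_exp_corr(X, X, 4)
  FF <- matrix(rnorm(N * p), N, p)
  Theta <- matrix(rnorm(p * S), p, S)
  Sigma <- rspd(S)
  Y <- FF %*% Theta + matrix(rnorm(N * S), N, S)
  # held-in inputs: mean reproduces training rows, row covariance is zero
  sel <- c(2, 4)
  pc <- predictive_conditional(FF[sel, ], V[, sel], V[sel, sel],
                               Theta, Sigma, Y, FF, V)
  expect_equal(pc$mean, Y[sel, ], tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(pc$rowcov)), 1e-10)
  expect_equal(pc$value, Y[sel, ], tolerance = 1e-6, ignore_attr = TRUE)
  # J = 0: no borrowing
  Fn <- matrix(rnorm(p), 1, p)
  pc0 <- predictive_conditional(Fn, matrix(0, N, 1), matrix(1),
                                Theta, Sigma, Y, FF, V)
  expect_equal(pc0$mean, Fn %*% Theta, tolerance = 1e-12)
  expect_equal(pc0$rowcov[1, 1], 1, tolerance = 1e-12)
  # 1 x 1: scalar Gaussian conditioning formula by hand
  v <- matrix(1); j <- matrix(0.6); vn <- matrix(1)
  th <- matrix(0.5); sg <- matrix(1); y <- matrix(2); f1 <- matrix(1)
  pc1 <- predictive_conditional(matrix(1), j, vn, th, sg, y, f1, v)
  expect_equal(pc1$mean[1, 1], 0.5 + 0.6 * (2 - 0.5), tolerance = 1e-12)
  expect_equal(pc1$rowcov[1, 1], 1 - 0.36, tolerance = 1e-12)
})

test_that("predictive_hyper_t_moments: collapse, dof, composition oracle", {
  set.seed(207)
  N <- 5; p <- 2; S <- 1
  X <- matrix(runif(N * 2), N, 2)
  V <- sq_exp_corr(X, X, 4)
  FF <- matrix(rnorm(N * p), N, p)
  Tn <- 2
  Y <- lapply(1:Tn, function(t) FF %*% matrix(rnorm(p * S), p, S) +
                matrix(rnorm(N * S), N, S))
  spec <- dlm_spec(FF, diag(p), V, diag(p), Tn, "mniw",
                   m0 = matrix(0, p, S), M0 = diag(p), n0 = S + 2,
                   D0 = diag(S))
  dr <- ffbs(Y, spec, 3000)
  filt <- dr$filter; sm <- dr$smooth
  # training-subset collapse: scale matrix numerically zero
  sel <- c(1, 3)
  pm <- predictive_hyper_t_moments(FF[sel, ], V[, sel], V[sel, sel],
                                   sm$h[[Tn + 1]], sm$H[[Tn + 1]],
                                   Y[[Tn]], FF, V,
                                   n_T = filt$n[Tn + 1],
                                   D_T = filt$D[[Tn + 1]])
  expect_lt(max(abs(pm$rowscale)), 1e-8)
  expect_equal(pm$location, Y[[Tn]][sel, , drop = FALSE],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(pm$n, filt$n[Tn + 1])
  # composition over posterior draws matches the hyper-T moments at a new
  # input
  xn <- matrix(c(0.35, 0.55), 1, 2)
  Jn <- sq_exp_corr(X, xn, 4)
  Fn <- matrix(rnorm(p), 1, p)
  pm2 <- predictive_hyper_t_moments(Fn, Jn, matrix(1), sm$h[[Tn + 1]],
                                    sm$H[[Tn + 1]], Y[[Tn]], FF, V,
                                    n_T = filt$n[Tn + 1],
                                    D_T = filt$D[[Tn + 1]])
  comp <- vapply(seq_len(dr$L), function(l) {
    pc <- predictive_conditional(Fn, Jn, matrix(1),
                                 matrix(dr$Theta[l, Tn + 1, , ], p, S),
                                 matrix(dr$Sigma[l, , ], S, S),
                                 Y[[Tn]], FF, V)
    pc$value[1, 1]
  }, numeric(1))
  nT <- pm2$n
  exp_var <- pm2$rowscale[1, 1] * pm2$D[1, 1] / (nT - 2)
  expect_equal(mean(comp), pm2$location[1, 1],
               tolerance = 0.1 * max(sqrt(exp_var), 0.05))
  expect_equal(var(comp), exp_var, tolerance = 0.15 * exp_var)
})

test_that("properties: dof bookkeeping, column exchangeability, H <= M", {
  set.seed(208)
  inst <- random_dlm(p = 2, N = 3, S = 3, Tn = 3)
  filt <- forward_filter(inst$Y, inst$spec)
  sm <- backward_moments(filt)
  expect_equal(filt$n[4], inst$spec$n0 + 3 * 3)
  # smoothing never inflates row covariance: M_t - H_t is PSD
  for (t in 1:3) {
    ev <- eigen(filt$M[[t + 1]] - sm$H[[t + 1]], symmetric = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
  # permuting the S columns of Y, D0, m0 permutes D_t consistently
  perm <- c(3, 1, 2)
  inst_p <- inst
  inst_p$Y <- lapply(inst$Y, function(y) y[, perm])
  spec_p <- dlm_spec(inst$FF, inst$G, inst$V, inst$W, 3, "mniw",
                     inst$m0[, perm], inst$M0, n0 = inst$spec$n0,
                     D0 = inst$spec$D0[perm, perm])
  filt_p <- forward_filter(inst_p$Y, spec_p)
  expect_equal(filt_p$D[[4]], filt$D[[4]][perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(filt_p$m[[4]], filt$m[[4]][, perm], tolerance = 1e-10)
})
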