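# Latent emulated-field chain for calibration.
#
# At a new mechanistic input eta, one stored emulator draw (Theta_{1:T},
# Sigma) induces a linear-Gaussian chain over the emulated row
# y_t(eta) (1 x S):
#
#   y_t' = t(Theta_t,1) y_{t-1}' [+ t(Theta_t,2) y_{t-2}'] + c_t(eta) + w_t,
#   w_t ~ N(0, fac(eta) * Sigma),   fac(eta) = 1 - t(J) V^{-1} J,
#   c_t(eta) = t( t(J) V^{-1} (Y_t - F_t Theta_t) ),
#
# which is the conditional predictive distribution of the new row given the
# training rows, with the autoregressive design evaluated at the *latent*
# previous value. Field data observe s_field coordinates of y_t through the
# bias + noise model. Written in companion form (state dimension
# ar_order * S), this admits an exact Kalman-filter marginal likelihood in
# eta (used as the Metropolis target) and an exact joint FFBS draw of
# y_{1:T} (used as the y-update), both bounded and well-behaved even when
# fac(eta) -> 0 at a training input.

# Build the per-season chain matrices at eta for stored draw l.
calib_chain <- function(fit, eta, l, cache) {
  Tn <- fit$spec$n_time
  S <- fit$spec$S
  q <- fit$ar_order * S
  J <- sq_exp_corr(fit$X, matrix(eta, nrow = 1), fit$beta)
  fac <- max(1 - as.numeric(crossprod(J, cache$Vinv %*% J)), 0)
  Sig <- cache$Sig_full[[l]]
  A <- vector("list", Tn); cvec <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Th <- cache$Th[[l]][[t]]                  # p x S
    ct <- as.numeric(crossprod(J, cache$Vr_full[[l]][[t]]))
    if (fit$ar_order == 1) {
      A[[t]] <- t(Th)
      cvec[[t]] <- ct
    } else {
      A1 <- t(Th[seq_len(S), , drop = FALSE])
      A2 <- t(Th[S + seq_len(S), , drop = FALSE])
      A[[t]] <- rbind(cbind(A1, A2),
                      cbind(diag(S), matrix(0, S, S)))
      cvec[[t]] <- c(ct, rep(0, S))
    }
  }
  W <- matrix(0, q, q)
  W[seq_len(S), seq_len(S)] <- fac * Sig
  # tiny nugget keeps every prediction covariance regular (degenerate at
  # training inputs and in carried companion blocks otherwise); well below
  # any observation noise, so inference is unaffected
  W <- W + diag(1e-8 * max(mean(diag(Sig)), 1e-6), q)
  list(A = A, cvec = cvec, W = W, fac = fac, S = S, q = q, Tn = Tn)
}

# Forward Kalman pass of the chain against v_t = z_t - u_t; returns the
# marginal log-likelihood and the filtered moments (for backward sampling).
calib_kf <- function(chain, v, tau2, y0, s_field) {
  S <- chain$S; q <- chain$q; Tn <- chain$Tn
  Sf <- length(s_field)
  x <- c(y0, if (q > S) y0 else NULL)         # deterministic initial state
  P <- matrix(0, q, q)
  xf <- vector("list", Tn); Pf <- vector("list", Tn)
  xp <- vector("list", Tn); Pp <- vector("list", Tn)
  ll <- 0
  for (t in seq_len(Tn)) {
    At <- chain$A[[t]]
    xpred <- as.numeric(At %*% x) + chain$cvec[[t]]
    Ppred <- sym(At %*% P %*% t(At) + chain$W)
    resid <- v[t, ] - xpred[s_field]
    Sobs <- Ppred[s_field, s_field, drop = FALSE] + diag(tau2[t], Sf)
    Uo <- chol(sym(Sobs))
    w <- forwardsolve(t(Uo), resid)
    ll <- ll - 0.5 * (Sf * log(2 * pi) + 2 * sum(log(diag(Uo))) +
                        sum(w * w))
    K <- t(backsolve(Uo, forwardsolve(t(Uo),
                                      t(Ppred[, s_field, drop = FALSE]))))
    x <- xpred + as.numeric(K %*% resid)
    P <- sym(Ppred - K %*% Ppred[s_field, , drop = FALSE])
    xp[[t]] <- xpred; Pp[[t]] <- Ppred
    xf[[t]] <- x; Pf[[t]] <- P
  }
  list(loglik = ll, xf = xf, Pf = Pf, xp = xp, Pp = Pp)
}

# One exact joint draw of y_{1:T} (T x S) from its full conditional given
# v_t = z_t - u_t, by backward sampling of the filtered chain.
calib_y_draw <- function(chain, v, tau2, y0, s_field) {
  kf <- calib_kf(chain, v, tau2, y0, s_field)
  Tn <- chain$Tn; S <- chain$S; q <- chain$q
  x <- kf$xf[[Tn]] +
    as.numeric(crossprod(psd_root(kf$Pf[[Tn]]), stats::rnorm(q)))
  y <- matrix(NA_real_, Tn, S)
  y[Tn, ] <- x[seq_len(S)]
  for (t in seq(Tn - 1, 1)) {
    At1 <- chain$A[[t + 1]]
    Up <- chol_spd(kf$Pp[[t + 1]], label = "chain prediction covariance")
    CrossT <- At1 %*% kf$Pf[[t]]            # Cov(x_{t+1}, x_t | v_{1:t})
    G <- t(solve_chol(Up, CrossT))          # Pf At1' Pp1^{-1}
    mean_t <- kf$xf[[t]] + as.numeric(G %*% (x - kf$xp[[t + 1]]))
    cov_t <- sym(kf$Pf[[t]] - G %*% CrossT)
    x <- mean_t + as.numeric(crossprod(psd_root(cov_t), stats::rnorm(q)))
    y[t, ] <- x[seq_len(S)]
  }
  y
}

# Metropolis target with the latent chain marginalized by the Kalman filter:
# log p(z - u | eta, tau2) + bias innovation terms + prior on the
# transformed scale.
log_target_phi_kf <- function(eta, rho, state, chain, z, U, config,
                              y0, s_field,
                              include_bias = !config$bias_modularized,
                              U_chol = NULL) {
  tp <- transform_phi(eta, config$priors)
  if (!is.finite(tp$log_jacobian)) return(-Inf)
  ll <- tp$log_prior - tp$log_jacobian
  if (config$sample_rho) {
    if (rho <= 0) return(-Inf)
    rp <- config$rho_prior
    ll <- ll + stats::dlnorm(rho, rp$mu, rp$sigma, log = TRUE) +
      log(rho * rp$sigma)
  }
  Tn <- nrow(z); Sf <- ncol(z)
  v <- z - (if (include_bias) state$u[-1, , drop = FALSE] else 0)
  ll <- ll + calib_kf(chain, v, state$tau2, y0, s_field)$loglik
  if (include_bias) {
    if (is.null(U_chol)) U_chol <- chol_spd(U, label = "U")
    ldU <- logdet_chol(U_chol)
    for (t in seq_len(Tn)) {
      du <- state$u[t + 1, ] - state$u[t, ]
      w <- forwardsolve(t(U_chol), du)
      ll <- ll - 0.5 * (Sf * log(2 * pi * state$tau2[t]) + ldU +
                          sum(w * w) / state$tau2[t])
    }
  }
  ll
}
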