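# Modularized Bayesian melding of field data with the emulator: Gibbs updates
# for the per-season noise variances tau2_t and the emulated field values
# y_t(eta), an exact FFBS update of the dynamic spatial bias u_{0:T}, and a
# random-walk Metropolis update of phi = (rho, eta) on a transformed scale.
# Each MCMC iteration conditions on one *stored* emulator posterior draw
# (modularization): emulation is never re-run during calibration.

#' Calibration configuration
#'
#' @param priors list, one element per mechanistic parameter: either
#'   `list(type = "lognormal", mu=, sigma=)` or
#'   `list(type = "uniform", a=, b=)`.
#' @param rho decay of the bias-increment correlation `U(rho)`; by default it
#'   is held fixed (`sample_rho = FALSE`), matching the reported experiments.
#' @param sample_rho if `TRUE`, `rho` joins the Metropolis block with a
#'   lognormal prior `rho_prior`.
#' @param rho_prior lognormal `(mu, sigma)` prior for `rho` when sampled.
#' @param coords `S_field x dcoord` field-location coordinates for `U(rho)`
#'   (defaults to `1:S_field` on a line).
#' @param b_t per-season prior multiplier for `tau2_t` (default 1).
#' @param n0z,d0z prior shape/rate of the noise variances.
#' @param m0z,M0z prior mean (scalar or vector) and row covariance of the
#'   initial bias.
#' @param tau2_init initial value of every `tau2_t` (also `tau0^2`).
#' @param eps proposal standard deviation of the Metropolis random walk
#'   (`Upsilon = eps^2 I` on the transformed scale).
#' @param eps_big,mix_p the random walk proposes a large exploratory step of
#'   standard deviation `eps_big` (prior scale on the transformed axes) with
#'   probability `mix_p`, and the small adaptive step otherwise; the mixture
#'   is symmetric, so the Metropolis acceptance rule is unchanged. Large
#'   steps let the chain hop between the narrow high-likelihood regions that
#'   an interpolating emulator induces near its training inputs.
#' @param adapt number of pilot iterations during which `eps` is adapted
#'   towards a 20-40% acceptance window, after which it is frozen.
#' @param bias_modularized if `TRUE`, parameters are sampled treating the
#'   emulator as unbiased (`u = 0` in the data terms), and the bias path is
#'   drawn post hoc conditional on each sampled parameter state.
#' @param phi_target `"collapsed"` (default) updates `phi = (rho, eta)` from
#'   its partially collapsed conditional with the emulated values `y_t`
#'   integrated out analytically (`z_t - u_t ~ N(mu_t(eta),
#'   Sigma_t(eta) + tau2_t I)`), which stays bounded when the emulator
#'   conditional degenerates at a training input; `"conditional"` uses the
#'   full conditional given the current `y_t` ([log_target_phi()]), which
#'   develops unbounded density spikes at training inputs because the
#'   interpolating emulator is exact there. Both are valid Metropolis
#'   targets (the `y_t` Gibbs draw follows the `phi` update), but the
#'   collapsed form mixes over the input space instead of locking onto the
#'   nearest training run.
#' @return object of class `calib_config`.
#' @export
calib_config <- function(priors, rho = 1.5, sample_rho = FALSE,
                         rho_prior = list(mu = 0, sigma = 1), coords = NULL,
                         b_t = 1, n0z = 2, d0z = 1, m0z = 0, M0z = NULL,
                         tau2_init = 1, eps = 0.1, adapt = 500,
                         eps_big = 1, mix_p = 0.25,
                         bias_modularized = FALSE,
                         phi_target = c("collapsed", "conditional")) {
  phi_target <- match.arg(phi_target)
  stopifnot(is.list(priors), length(priors) >= 1)
  for (pr in priors) {
    if (!pr$type %in% c("lognormal", "uniform"))
      stop("prior type must be lognormal or uniform", call. = FALSE)
    if (pr$type == "uniform" && pr$a >= pr$b)
      stop("uniform prior needs a < b", call. = FALSE)
  }
  if (any(b_t <= 0)) stop("b_t must be positive", call. = FALSE)
  structure(list(priors = priors, rho = rho, sample_rho = sample_rho,
                 rho_prior = rho_prior, coords = coords, b_t = b_t,
                 n0z = n0z, d0z = d0z, m0z = m0z, M0z = M0z,
                 tau2_init = tau2_init, eps = eps, adapt = adapt,
                 eps_big = eps_big, mix_p = mix_p,
                 bias_modularized = bias_modularized,
                 phi_target = phi_target),
            class = "calib_config")
}

# U(rho): exponential correlation over the field-location coordinates.
build_U <- function(coords, rho) {
  D <- as.matrix(stats::dist(as_matrix_design(coords)))
  exp(-D / rho)
}

#' Transform mechanistic parameters to the real line, and its Jacobian
#'
#' Lognormal components map by `g_i(eta_i) = (log eta_i - mu_i) / sigma_i`;
#' uniform components by `logit((eta_i - a_i) / (b_i - a_i))`. The Jacobian
#' `J = |det dg/deta|` is `prod 1 / (eta_i sigma_i)` for lognormal components
#' and `prod [(eta_i - a_i)^{-1} + (b_i - eta_i)^{-1}]` for uniform ones.
#'
#' @param eta parameter vector strictly inside the prior support.
#' @param priors prior list as in [calib_config()].
#' @return list with `g` (transformed vector), `log_jacobian`, and the
#'   prior log-density `log_prior` on the original scale.
#' @export
transform_phi <- function(eta, priors) {
  d <- length(eta)
  g <- numeric(d); lj <- 0; lp <- 0
  for (i in seq_len(d)) {
    pr <- priors[[i]]
    if (pr$type == "lognormal") {
      if (eta[i] <= 0) return(list(g = rep(NA_real_, d),
                                   log_jacobian = -Inf, log_prior = -Inf))
      g[i] <- (log(eta[i]) - pr$mu) / pr$sigma
      lj <- lj - log(eta[i] * pr$sigma)
      lp <- lp + stats::dlnorm(eta[i], pr$mu, pr$sigma, log = TRUE)
    } else {
      if (eta[i] <= pr$a || eta[i] >= pr$b)
        return(list(g = rep(NA_real_, d),
                    log_jacobian = -Inf, log_prior = -Inf))
      u <- (eta[i] - pr$a) / (pr$b - pr$a)
      g[i] <- log(u) - log1p(-u)
      lj <- lj + log(1 / (eta[i] - pr$a) + 1 / (pr$b - eta[i]))
      lp <- lp - log(pr$b - pr$a)
    }
  }
  list(g = g, log_jacobian = lj, log_prior = lp)
}

#' Inverse of the prior transform
#'
#' @param g transformed (real-line) vector.
#' @inheritParams transform_phi
#' @return parameter vector on the original scale.
#' @export
inverse_transform_phi <- function(g, priors) {
  d <- length(g)
  eta <- numeric(d)
  for (i in seq_len(d)) {
    pr <- priors[[i]]
    eta[i] <- if (pr$type == "lognormal") exp(pr$mu + pr$sigma * g[i])
              else pr$a + (pr$b - pr$a) * stats::plogis(g[i])
  }
  eta
}

#' Emulator conditional moments at a mechanistic input
#'
#' For one stored posterior draw `(Theta_{0:T}, Sigma)` and one input `eta`,
#' returns for every season the conditional predictive moments of the
#' emulated field restricted to the field locations:
#' `mu_t(eta) = Fnew_t(eta) Theta_t(Sf) +
#'   t(J(eta)) V^{-1} (Y_t(Sf) - F_t Theta_t(Sf))` and
#' `Sigma_t(eta) = (1 - t(J(eta)) V^{-1} J(eta)) Sigma(Sf)`,
#' where `Sf` selects the field-location columns. When `eta` equals a
#' training input the scalar factor vanishes and the moments collapse onto
#' that input's training row.
#'
#' Autoregressive designs make `Fnew_t(eta)` depend on the previous season's
#' emulated value, so the caller supplies it through `fnew_fun`.
#'
#' @param fit a [emulator_fit()] object. Field locations must index into the
#'   emulation locations for the `mniw` structure (`Sigma(Sf)` is the
#'   corresponding sub-block); for `mnig`, `Sigma(Sf) = sigma2 * R(Sf)`.
#' @param eta mechanistic input (length `d`).
#' @param l index of the stored posterior draw to condition on.
#' @param s_field integer indices of the field locations within the
#'   emulation locations.
#' @param fnew_fun function `(t, y_prev)` returning the `1 x p` design row
#'   at the new input for season `t`, given the `1 x S_field` emulated value
#'   of season `t - 1` (see [ar_fnew_builder()]).
#' @param cache optional precomputed per-draw training residual solves from
#'   [calib_prepare()]; avoids re-solving against `V` at every proposal.
#' @return list of per-season lists with `mu` (length `S_field`), `Sigma`
#'   (`S_field x S_field`), and the scalar kernel deflation `factor`.
#' @export
emulator_conditional <- function(fit, eta, l, s_field, fnew_fun,
                                 cache = NULL) {
  stopifnot(inherits(fit, "dyn_emulator"))
  Tn <- fit$spec$n_time
  S <- fit$spec$S
  J <- sq_exp_corr(fit$X, matrix(eta, nrow = 1), fit$beta)  # N x 1
  if (is.null(cache)) cache <- calib_prepare(fit, s_field, draw_ids = l)
  Sig_f <- cache$Sig_f[[l]]
  JtVinvJ <- as.numeric(crossprod(J, cache$Vinv %*% J))
  factor <- max(1 - JtVinvJ, 0)
  out <- vector("list", Tn)
  y_prev <- NULL
  for (t in seq_len(Tn)) {
    Fnew <- matrix(fnew_fun(t, y_prev), nrow = 1)
    mu <- as.numeric(Fnew %*% cache$Th_f[[l]][[t]] +
                       crossprod(J, cache$Vr[[l]][[t]]))
    out[[t]] <- list(mu = mu, Sigma = factor * Sig_f, factor = factor)
    y_prev <- mu
  }
  out
}

#' Precompute calibration quantities per stored emulator draw
#'
#' Caches, for each stored posterior draw, the field-restricted states
#' `Theta_t(Sf)`, the solved training residuals `V^{-1}(Y_t(Sf) -
#' F_t Theta_t(Sf))`, the restricted column covariance, and `V^{-1}` itself.
#' These do not depend on the mechanistic input, so the Metropolis loop only
#' pays for kernel evaluations.
#'
#' @inheritParams emulator_conditional
#' @param draw_ids draws to prepare (default: all stored draws).
#' @return cache list consumed by [emulator_conditional()].
#' @export
calib_prepare <- function(fit, s_field, draw_ids = seq_len(fit$L)) {
  Tn <- fit$spec$n_time
  S <- fit$spec$S
  Vinv <- chol2inv(fit$V_chol)
  Th_f <- vector("list", fit$L); Vr <- vector("list", fit$L)
  Sig_f <- vector("list", fit$L)
  Th <- vector("list", fit$L); Vr_full <- vector("list", fit$L)
  Sig_full <- vector("list", fit$L)
  for (l in draw_ids) {
    Sfull <- sigma_of_draw(fit, l)
    Sig_full[[l]] <- Sfull
    Sig_f[[l]] <- Sfull[s_field, s_field, drop = FALSE]
    Th_f[[l]] <- vector("list", Tn); Vr[[l]] <- vector("list", Tn)
    Th[[l]] <- vector("list", Tn); Vr_full[[l]] <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      Tht <- matrix(fit$draws$Theta[l, t + 1, , ], fit$spec$p, S)
      Th[[l]][[t]] <- Tht
      Tf <- Tht[, s_field, drop = FALSE]
      Th_f[[l]][[t]] <- Tf
      resid_full <- fit$filter$Y[[t]] - fit$spec$FF[[t]] %*% Tht
      Vr_full[[l]][[t]] <- Vinv %*% resid_full
      Vr[[l]][[t]] <- Vr_full[[l]][[t]][, s_field, drop = FALSE]
    }
  }
  list(Vinv = Vinv, Th_f = Th_f, Vr = Vr, Sig_f = Sig_f,
       Th = Th, Vr_full = Vr_full, Sig_full = Sig_full)
}

#' Autoregressive design-row builder for new inputs
#'
#' Returns a closure producing the `1 x p` design row for season `t` at a
#' new input from the emulated previous value(s), seeded with the shared
#' initial state `y0`. Mirrors [build_ar_design()] including its `Y_0` lag
#' padding. The closure keeps the lag-2 value internally for AR(2).
#'
#' @param y0 length-`S_field` initial state at the new input.
#' @param ar_order 1 or 2.
#' @return function `(t, y_prev)`; pass `y_prev = NULL` at `t = 1`.
#' @export
ar_fnew_builder <- function(y0, ar_order = 1) {
  y0 <- as.numeric(y0)
  lag2 <- y0
  lag1 <- y0
  function(t, y_prev) {
    if (t == 1) {
      lag2 <<- y0; lag1 <<- y0
    } else {
      lag2 <<- lag1; lag1 <<- as.numeric(y_prev)
    }
    if (ar_order == 1) lag1 else c(lag1, lag2)
  }
}

#' Gibbs update of the per-season noise variances
#'
#' Draws `tau2_t ~ IG(b_t n0z + S_field, b_t d0z + (Q1 + Q2)/2)` with
#' `Q1 = (u_t - u_{t-1})' U^{-1} (u_t - u_{t-1})` and
#' `Q2 = sum_i (z_t(s_i) - y_t(s_i) - u_t(s_i))^2`.
#'
#' @param u `(T+1) x S_field` bias path (row 1 is `u_0`).
#' @param y,z `T x S_field` emulated values and field data.
#' @param U_chol Cholesky factor of `U(rho)`.
#' @param config a [calib_config()].
#' @return length-`T` vector of variance draws.
#' @export
tau2_gibbs <- function(u, y, z, U_chol, config) {
  Tn <- nrow(z); Sf <- ncol(z)
  b <- rep_len(config$b_t, Tn)
  out <- numeric(Tn)
  for (t in seq_len(Tn)) {
    du <- u[t + 1, ] - u[t, ]
    Q1 <- as.numeric(quad_chol(U_chol, matrix(du, ncol = 1)))
    resid <- z[t, ] - y[t, ] - u[t + 1, ]
    Q2 <- sum(resid^2)
    if (!is.finite(Q1) || !is.finite(Q2))
      stop("non-finite quadratic form in tau2 update", call. = FALSE)
    out[t] <- rinvgamma(1, b[t] * config$n0z + Sf,
                        b[t] * config$d0z + 0.5 * (Q1 + Q2))
  }
  out
}

# Moments (B_t, B_t b_t) of the y_t full conditional; degenerate branch when
# the emulator deflation factor vanishes (y_t == mu_t exactly).
y_full_conditional <- function(cond_t, tau2_t, z_t, u_t) {
  Sf <- length(cond_t$mu)
  if (cond_t$factor < 1e-12) {
    return(list(mean = cond_t$mu, cov = matrix(0, Sf, Sf), degenerate = TRUE))
  }
  Sinv <- solve(cond_t$Sigma)
  B <- solve(Sinv + diag(Sf) / tau2_t)
  b <- Sinv %*% cond_t$mu + (z_t - u_t) / tau2_t
  list(mean = as.numeric(B %*% b), cov = sym(B), degenerate = FALSE)
}

#' Gibbs update of the emulated field values
#'
#' Draws `y_t(eta) ~ N(B_t b_t, B_t)` with
#' `B_t^{-1} = Sigma_t(eta)^{-1} + tau_t^{-2} I` and
#' `b_t = Sigma_t(eta)^{-1} mu_t(eta) + tau_t^{-2} (z_t - u_t)`. When the
#' emulator conditional is degenerate (input equals a training input) the
#' draw is `y_t = mu_t` exactly.
#'
#' @param cond per-season conditionals from [emulator_conditional()].
#' @param tau2 length-`T` noise variances.
#' @param z `T x S_field` field data.
#' @param u `(T+1) x S_field` bias path.
#' @return `T x S_field` matrix of draws.
#' @export
y_gibbs <- function(cond, tau2, z, u) {
  Tn <- nrow(z); Sf <- ncol(z)
  out <- matrix(NA_real_, Tn, Sf)
  for (t in seq_len(Tn)) {
    fc <- y_full_conditional(cond[[t]], tau2[t], z[t, ], u[t + 1, ])
    if (fc$degenerate) out[t, ] <- fc$mean
    else out[t, ] <- fc$mean +
        as.numeric(crossprod(psd_root(fc$cov), stats::rnorm(Sf)))
  }
  out
}

#' FFBS draw of the dynamic bias path
#'
#' One joint draw of `u_{0:T}` from its full conditional given the residual
#' series `z_t - y_t`, via the forward recursions
#' `A_t = tau2_{t-1} M_{t-1} + tau2_t U`, `Q_t = A_t + tau2_t I`,
#' `m_t = m_{t-1} + A_t Q_t^{-1} (z_t - y_t - m_{t-1})`,
#' `M_t = (A_t - A_t Q_t^{-1} A_t) / tau2_t` (the filtered covariance of
#' `u_t` is `tau2_t M_t`), followed by joint backward sampling:
#' `u_T ~ N(m_T, tau2_T M_T)` and, conditioning on the draw already made,
#' `u_t | u_{t+1} ~ N(m_t + P_t A_{t+1}^{-1} (u_{t+1} - m_t),
#'  P_t - P_t A_{t+1}^{-1} P_t)` with `P_t = tau2_t M_t`.
#'
#' @param z,y `T x S_field` field data and current emulated values.
#' @param tau2 length-`T` noise variances (`tau0^2` for the prior taken from
#'   `config$tau2_init`).
#' @param U `S_field x S_field` bias-increment correlation.
#' @param config a [calib_config()].
#' @return `(T+1) x S_field` matrix: one joint draw of `u_{0:T}`.
#' @export
bias_ffbs <- function(z, y, tau2, U, config) {
  Tn <- nrow(z); Sf <- ncol(z)
  tau2_all <- c(config$tau2_init, tau2)    # index t+1 holds tau2_t
  m <- vector("list", Tn + 1); M <- vector("list", Tn + 1)
  A <- vector("list", Tn + 1)
  m[[1]] <- rep(rep_len(config$m0z, Sf), length.out = Sf)
  M0 <- if (is.null(config$M0z)) diag(Sf) else as.matrix(config$M0z)
  M[[1]] <- M0
  for (t in seq_len(Tn)) {
    At <- sym(tau2_all[t] * M[[t]] + tau2_all[t + 1] * U)
    Qt <- At + diag(tau2_all[t + 1], Sf)
    UQ <- chol_spd(Qt, label = "bias forecast covariance")
    resid <- z[t, ] - y[t, ] - m[[t]]
    gain <- At %*% solve_chol(UQ, diag(Sf))
    m[[t + 1]] <- as.numeric(m[[t]] + gain %*% resid)
    M[[t + 1]] <- sym((At - gain %*% At) / tau2_all[t + 1])
    A[[t + 1]] <- At
  }
  u <- matrix(NA_real_, Tn + 1, Sf)
  PT <- sym(tau2_all[Tn + 1] * M[[Tn + 1]])
  u[Tn + 1, ] <- m[[Tn + 1]] +
    as.numeric(crossprod(psd_root(PT), stats::rnorm(Sf)))
  # backward conditional sampling: u_t | u_{t+1}, z_{1:t} for the random
  # walk has mean m_t + P_t A_{t+1}^{-1} (u_{t+1} - m_t) and covariance
  # P_t - P_t A_{t+1}^{-1} P_t, with P_t = tau2_t M_t the filtered
  # covariance (drawing from the marginal smoothed moments instead would
  # break the joint law of the path)
  for (t in seq(Tn - 1, 0)) {
    At1 <- A[[t + 2]]
    UA <- chol_spd(At1, label = "bias prior covariance")
    Pt <- sym(tau2_all[t + 1] * M[[t + 1]])
    gain <- t(solve_chol(UA, Pt))
    mean_t <- as.numeric(m[[t + 1]] + gain %*% (u[t + 2, ] - m[[t + 1]]))
    cov_t <- sym(Pt - gain %*% Pt)
    u[t + 1, ] <- mean_t +
      as.numeric(crossprod(psd_root(cov_t), stats::rnorm(Sf)))
  }
  u
}

#' Log full-conditional of the Metropolis block phi = (rho, eta)
#'
#' Sum of (i) Gaussian terms for the current `y_t` at the recomputed
#' moments `(B_t(eta) b_t(eta), B_t(eta))`, (ii) the field-data terms
#' `N(z_t | y_t + u_t, tau2_t I)` (constant in `phi`; kept for the audit
#' trail), (iii) the bias innovation terms `N(u_t | u_{t-1}, tau2_t U(rho))`,
#' and (iv) the prior evaluated on the transformed scale
#' (`log p(eta) - log J(eta)`, plus the same for `rho` when sampled).
#' Returns `-Inf` outside the prior support.
#'
#' @param eta,rho current mechanistic input and bias-correlation decay.
#' @param state list with `y`, `u`, `tau2` (current Gibbs state).
#' @param cond emulator conditionals at `eta` (from
#'   [emulator_conditional()]).
#' @param z field data.
#' @param U bias correlation at `rho`.
#' @param config a [calib_config()].
#' @param include_bias include the bias-related terms (dropped under bias
#'   modularization).
#' @return scalar log-density (up to a constant).
#' @export
log_target_phi <- function(eta, rho, state, cond, z, U, config,
                           include_bias = !config$bias_modularized,
                           U_chol = NULL) {
  tp <- transform_phi(eta, config$priors)
  if (!is.finite(tp$log_jacobian)) return(-Inf)
  lp <- tp$log_prior - tp$log_jacobian
  if (config$sample_rho) {
    if (rho <= 0) return(-Inf)
    rp <- config$rho_prior
    # lognormal prior on rho; transform g = (log rho - mu)/sigma
    lp <- lp + stats::dlnorm(rho, rp$mu, rp$sigma, log = TRUE) +
      log(rho * rp$sigma)
  }
  Tn <- nrow(z); Sf <- ncol(z)
  ll <- lp
  if (is.null(U_chol)) U_chol <- chol_spd(U, label = "U")
  ldU <- logdet_chol(U_chol)
  for (t in seq_len(Tn)) {
    fc <- y_full_conditional(cond[[t]], state$tau2[t], z[t, ],
                             if (include_bias) state$u[t + 1, ] else
                               rep(0, Sf))
    dev <- state$y[t, ] - fc$mean
    if (fc$degenerate) {
      # point mass at mu_t: continuous part replaced by a tight Gaussian
      ll <- ll + sum(stats::dnorm(dev, 0, 1e-6, log = TRUE))
    } else {
      Uc <- chol(fc$cov)
      v <- forwardsolve(t(Uc), dev)
      ll <- ll - 0.5 * (Sf * log(2 * pi) + 2 * sum(log(diag(Uc))) +
                          sum(v * v))
    }
    resid <- z[t, ] - state$y[t, ] -
      (if (include_bias) state$u[t + 1, ] else 0)
    ll <- ll + sum(stats::dnorm(resid, 0, sqrt(state$tau2[t]), log = TRUE))
    if (include_bias) {
      du <- state$u[t + 1, ] - state$u[t, ]
      v <- forwardsolve(t(U_chol), du)
      ll <- ll - 0.5 * (Sf * log(2 * pi * state$tau2[t]) + ldU +
                          sum(v * v) / state$tau2[t])
    }
  }
  ll
}

#' Partially collapsed log target for phi = (rho, eta)
#'
#' Log conditional of `phi` with the emulated field values integrated out:
#' `sum_t log N(z_t - u_t | mu_t(eta), Sigma_t(eta) + tau2_t I)` plus the
#' bias innovation terms and the prior on the transformed scale. Bounded at
#' training inputs (where `Sigma_t` vanishes) and therefore the default
#' Metropolis target of [run_calibration()].
#'
#' @inheritParams log_target_phi
#' @return scalar log-density (up to a constant).
#' @export
log_target_phi_collapsed <- function(eta, rho, state, cond, z, U, config,
                                     include_bias = !config$bias_modularized,
                                     U_chol = NULL) {
  tp <- transform_phi(eta, config$priors)
  if (!is.finite(tp$log_jacobian)) return(-Inf)
  lp <- tp$log_prior - tp$log_jacobian
  if (config$sample_rho) {
    if (rho <= 0) return(-Inf)
    rp <- config$rho_prior
    lp <- lp + stats::dlnorm(rho, rp$mu, rp$sigma, log = TRUE) +
      log(rho * rp$sigma)
  }
  Tn <- nrow(z); Sf <- ncol(z)
  ll <- lp
  if (include_bias) {
    if (is.null(U_chol)) U_chol <- chol_spd(U, label = "U")
    ldU <- logdet_chol(U_chol)
  }
  for (t in seq_len(Tn)) {
    resid <- z[t, ] - cond[[t]]$mu -
      (if (include_bias) state$u[t + 1, ] else 0)
    Ct <- cond[[t]]$Sigma + diag(state$tau2[t], Sf)
    Uc <- chol(sym(Ct))
    v <- forwardsolve(t(Uc), resid)
    ll <- ll - 0.5 * (Sf * log(2 * pi) + 2 * sum(log(diag(Uc))) +
                        sum(v * v))
    if (include_bias) {
      du <- state$u[t + 1, ] - state$u[t, ]
      w <- forwardsolve(t(U_chol), du)
      ll <- ll - 0.5 * (Sf * log(2 * pi * state$tau2[t]) + ldU +
                          sum(w * w) / state$tau2[t])
    }
  }
  ll
}

#' One Metropolis random-walk step on the transformed scale
#'
#' Symmetric Gaussian proposal `g* = g + N(0, Upsilon)`; accept with
#' probability `min(1, exp(log_target(phi*) - log_target(phi)))`.
#'
#' @param g current transformed state vector.
#' @param log_target function of the transformed vector returning the log
#'   target density.
#' @param eps proposal standard deviation (`Upsilon = eps^2 I`).
#' @param current_lt log target at `g` (recomputed if `NULL`).
#' @param eps_big,mix_p optional symmetric mixture component: with
#'   probability `mix_p` the proposal standard deviation is `eps_big`
#'   instead of `eps`.
#' @return list with `g`, `log_target`, `accepted`.
#' @export
metropolis_step <- function(g, log_target, eps, current_lt = NULL,
                            eps_big = eps, mix_p = 0) {
  if (is.null(current_lt)) current_lt <- log_target(g)
  sd_use <- if (mix_p > 0 && stats::runif(1) < mix_p) eps_big else eps
  prop <- g + stats::rnorm(length(g), sd = sd_use)
  lt_prop <- log_target(prop)
  accept <- is.finite(lt_prop) &&
    log(stats::runif(1)) < (lt_prop - current_lt)
  if (accept) list(g = prop, log_target = lt_prop, accepted = TRUE)
  else list(g = g, log_target = current_lt, accepted = FALSE)
}

#' Modularized MCMC calibration of mechanistic parameters from field data
#'
#' Runs `iters` sweeps of: (1) Gibbs update of `tau2_{1:T}`; (2) FFBS update
#' of the bias path `u_{0:T}` (post hoc under bias modularization); (3) a
#' Metropolis random-walk update of `phi = (rho, eta)` on the transformed
#' scale; (4) Gibbs update of the emulated field values `y_{1:T}(eta)`.
#' Each sweep conditions on one stored emulator posterior draw, cycling
#' through the `L` stored draws; emulation is never re-run. The proposal
#' scale is adapted towards 20-40% acceptance during the first
#' `config$adapt` sweeps, then frozen.
#'
#' @param z `T x S_field` field observations.
#' @param fit a [emulator_fit()] whose seasons match `z`.
#' @param s_field indices of the field locations within the emulation
#'   locations.
#' @param config a [calib_config()].
#' @param iters number of MCMC sweeps.
#' @param eta_init optional starting value (defaults to the prior median).
#' @param y0_field length-`S_field` initial state at the new input for the
#'   autoregressive design (defaults to the training `Y_0` restricted to
#'   `s_field`).
#' @return object of class `calib_fit` with trace matrices `eta`
#'   (`iters x d`), `rho`, `tau2` (`iters x T`), arrays `u`, `y`, the
#'   acceptance rate and the frozen proposal scale.
#' @export
run_calibration <- function(z, fit, s_field, config, iters = 2000,
                            eta_init = NULL, y0_field = NULL) {
  stopifnot(inherits(fit, "dyn_emulator"), inherits(config, "calib_config"))
  z <- as.matrix(z)
  Tn <- nrow(z); Sf <- ncol(z)
  if (Tn != fit$spec$n_time)
    stop("field data seasons disagree with the emulator", call. = FALSE)
  if (fit$structure_name == "mniw" &&
      (length(s_field) < 1 || any(s_field > fit$spec$S)))
    stop("under mniw emulation the field locations must index into the
emulation locations", call. = FALSE)
  d <- length(config$priors)
  S <- fit$spec$S
  collapsed <- config$phi_target == "collapsed"
  coords <- if (is.null(config$coords)) matrix(seq_len(Sf), ncol = 1)
            else as_matrix_design(config$coords)
  Y0 <- fit$Y_hist[[1]]
  y0_full <- Y0[1, ]
  if (is.null(y0_field)) y0_field <- y0_full[s_field]
  if (is.null(eta_init))
    eta_init <- vapply(config$priors, function(pr)
      if (pr$type == "lognormal") exp(pr$mu) else (pr$a + pr$b) / 2,
      numeric(1))
  eta <- eta_init
  rho <- config$rho
  U <- build_U(coords, rho)
  U_chol <- chol_spd(U, label = "U")
  tau2 <- rep(config$tau2_init, Tn)
  u <- matrix(0, Tn + 1, Sf)
  L <- fit$L
  fnew_fun <- ar_fnew_builder(y0_field, fit$ar_order)
  cache <- calib_prepare(fit, s_field)
  # initialize the latent emulated values from the chain mean at eta_init
  chain <- calib_chain(fit, eta, 1, cache)
  y_full <- matrix(NA_real_, Tn, S)
  xs <- c(y0_full, if (fit$ar_order == 2) y0_full else NULL)
  for (t in seq_len(Tn)) {
    xs <- as.numeric(chain$A[[t]] %*% xs) + chain$cvec[[t]]
    y_full[t, ] <- xs[seq_len(S)]
  }
  y <- y_full[, s_field, drop = FALSE]
  eps <- config$eps
  n_acc <- 0; n_tot <- 0
  acc_window <- 0; win <- 0
  tr_eta <- matrix(NA_real_, iters, d)
  tr_rho <- numeric(iters)
  tr_tau2 <- matrix(NA_real_, iters, Tn)
  tr_u <- array(NA_real_, c(iters, Tn + 1, Sf))
  tr_y <- array(NA_real_, c(iters, Tn, Sf))
  include_bias <- !config$bias_modularized
  for (it in seq_len(iters)) {
    l <- ((it - 1) %% L) + 1
    chain <- calib_chain(fit, eta, l, cache)
    state <- list(y = y, u = u, tau2 = tau2)
    # (1) tau2
    tau2 <- tau2_gibbs(if (include_bias) u else 0 * u, y, z, U_chol, config)
    state$tau2 <- tau2
    # (2) bias path
    if (include_bias) {
      u <- bias_ffbs(z, y, tau2, U, config)
      state$u <- u
    }
    # (3) Metropolis on phi
    g_eta <- transform_phi(eta, config$priors)$g
    g_all <- if (config$sample_rho) c(log(rho), g_eta) else g_eta
    lt_fun <- function(g) {
      if (config$sample_rho) {
        rho_p <- exp(g[1])
        eta_p <- inverse_transform_phi(g[-1], config$priors)
        U_p <- build_U(coords, rho_p)
      } else {
        rho_p <- rho
        eta_p <- inverse_transform_phi(g, config$priors)
        U_p <- U
      }
      if (collapsed) {
        chain_p <- calib_chain(fit, eta_p, l, cache)
        log_target_phi_kf(eta_p, rho_p, state, chain_p, z, U_p, config,
                          y0 = y0_full, s_field = s_field,
                          include_bias = include_bias,
                          U_chol = if (config$sample_rho) NULL else U_chol)
      } else {
        cond_p <- emulator_conditional(fit, eta_p, l, s_field, fnew_fun,
                                       cache)
        log_target_phi(eta_p, rho_p, state, cond_p, z, U_p, config,
                       include_bias = include_bias,
                       U_chol = if (config$sample_rho) NULL else U_chol)
      }
    }
    step <- metropolis_step(g_all, lt_fun, eps,
                            eps_big = config$eps_big, mix_p = config$mix_p)
    if (step$accepted) {
      if (config$sample_rho) {
        rho <- exp(step$g[1])
        eta <- inverse_transform_phi(step$g[-1], config$priors)
        U <- build_U(coords, rho)
        U_chol <- chol_spd(U, label = "U")
      } else {
        eta <- inverse_transform_phi(step$g, config$priors)
      }
      chain <- calib_chain(fit, eta, l, cache)
      n_acc <- n_acc + 1
      acc_window <- acc_window + 1
    }
    n_tot <- n_tot + 1; win <- win + 1
    # pilot adaptation of the proposal scale, frozen after config$adapt
    if (it <= config$adapt && win >= 50) {
      rate <- acc_window / win
      if (rate < 0.2) eps <- eps * 0.7
      if (rate > 0.4) eps <- eps * 1.4
      acc_window <- 0; win <- 0
    }
    # (4) y update: exact joint FFBS draw of the latent chain (collapsed)
    # or the per-season conditional update (printed form)
    if (collapsed) {
      v <- z - (if (include_bias) u[-1, , drop = FALSE] else 0)
      y_full <- calib_y_draw(chain, v, tau2, y0_full, s_field)
      y <- y_full[, s_field, drop = FALSE]
    } else {
      cond <- emulator_conditional(fit, eta, l, s_field, fnew_fun, cache)
      y <- y_gibbs(cond, tau2, z, if (include_bias) u else 0 * u)
    }
    # post hoc bias under modularization
    if (!include_bias) {
      u <- bias_ffbs(z, y, tau2, U, config)
    }
    tr_eta[it, ] <- eta
    tr_rho[it] <- rho
    tr_tau2[it, ] <- tau2
    tr_u[it, , ] <- u
    tr_y[it, , ] <- y
  }
  structure(list(eta = tr_eta, rho = tr_rho, tau2 = tr_tau2, u = tr_u,
                 y = tr_y, accept_rate = n_acc / n_tot, eps = eps,
                 config = config, s_field = s_field),
            class = "calib_fit")
}

#' Posterior summaries of a calibration run
#'
#' @param object a `calib_fit`.
#' @param burn number of initial sweeps discarded.
#' @param ... unused.
#' @return data frame with the median and (2.5%, 97.5%) quantiles per
#'   mechanistic parameter (and `rho` if sampled).
#' @export
summary.calib_fit <- function(object, burn = floor(nrow(object$eta) / 4),
                              ...) {
  keep <- seq(burn + 1, nrow(object$eta))
  qs <- t(apply(object$eta[keep, , drop = FALSE], 2, stats::quantile,
                probs = c(0.5, 0.025, 0.975)))
  out <- data.frame(parameter = paste0("eta", seq_len(ncol(object$eta))),
                    median = qs[, 1], q2.5 = qs[, 2], q97.5 = qs[, 3],
                    row.names = NULL)
  if (object$config$sample_rho) {
    rq <- stats::quantile(object$rho[keep], c(0.5, 0.025, 0.975))
    out <- rbind(out, data.frame(parameter = "rho", median = rq[1],
                                 q2.5 = rq[2], q97.5 = rq[3]))
  }
  out
}
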