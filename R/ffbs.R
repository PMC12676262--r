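# Exact forward filtering, backward smoothing and joint backward sampling for
# matrix-variate dynamic linear models
#
#   Y_t = F_t Theta_t + E_t,        E_t ~ MN(0, V_t, Sigma)
#   Theta_t = G_t Theta_{t-1} + G_t, G_t ~ MN(0, W_t, Sigma)
#
# with conjugate priors (Theta_0, Sigma) ~ MNIW(m0, M0, n0, D0) ("mniw"),
# Sigma = sigma^2 R with sigma^2 ~ IG(n0, d0) ("mnig"), or Sigma = I fixed
# ("identity"). The first- and second-moment recursions are identical across
# the three structures; only the scale bookkeeping differs.

#' Specify a matrix-variate dynamic linear model
#'
#' Collects the observation/transition matrices, row covariances and the
#' conjugate prior for one of the three column-covariance structures.
#' Per-time matrices may be supplied as a single matrix (recycled over all
#' `T` seasons) or as a list of length `T`.
#'
#' @param FF observation matrix `N_t x p_t`, or list of them.
#' @param G transition matrix `p_t x p_{t-1}`, or list.
#' @param V `N_t x N_t` SPD row correlation of the observation noise, or list.
#' @param W `p_t x p_t` SPD row covariance of the state innovation, or list.
#'   A zero matrix is allowed (no innovation).
#' @param n_time number of seasons `T`.
#' @param structure `"mniw"` (unstructured `Sigma ~ IW(n0, D0)`), `"mnig"`
#'   (`Sigma = sigma^2 R`, `sigma^2 ~ IG(n0, d0)`), or `"identity"`
#'   (`Sigma = I`, no scale learning).
#' @param m0,M0 prior mean (`p x S`) and row covariance (`p x p`) of `Theta_0`.
#' @param n0 prior inverse-Wishart degrees of freedom (mniw; requires
#'   `n0 > S - 1`) or inverse-gamma shape (mnig).
#' @param D0 prior `S x S` inverse-Wishart scale (mniw only).
#' @param d0 prior inverse-gamma rate (mnig only).
#' @param R fixed `S x S` SPD column correlation (mnig only; `diag(R) = 1`).
#' @return an object of class `dlm_spec`.
#' @export
dlm_spec <- function(FF, G, V, W, n_time,
                     structure = c("mniw", "mnig", "identity"),
                     m0, M0, n0 = NULL, D0 = NULL, d0 = NULL, R = NULL) {
  structure <- match.arg(structure)
  as_list <- function(x) {
    if (is.list(x)) {
      if (length(x) != n_time) stop("per-time list must have length T",
                                    call. = FALSE)
      lapply(x, as.matrix)
    } else rep(list(as.matrix(x)), n_time)
  }
  m0 <- as.matrix(m0)
  S <- ncol(m0); p <- nrow(m0)
  spec <- list(FF = as_list(FF), G = as_list(G), V = as_list(V),
               W = as_list(W), n_time = n_time, structure = structure,
               m0 = m0, M0 = as.matrix(M0), S = S, p = p)
  check_spd_dims(spec$M0, p, "M0")
  if (structure == "mniw") {
    if (is.null(n0) || is.null(D0))
      stop("mniw structure requires n0 and D0", call. = FALSE)
    if (n0 <= S - 1) stop("mniw requires n0 > S - 1", call. = FALSE)
    spec$n0 <- n0; spec$D0 <- as.matrix(D0)
    check_spd_dims(spec$D0, S, "D0")
  } else if (structure == "mnig") {
    if (is.null(n0) || is.null(d0) || is.null(R))
      stop("mnig structure requires n0, d0 and R", call. = FALSE)
    if (n0 <= 0 || d0 <= 0) stop("mnig requires n0, d0 > 0", call. = FALSE)
    spec$n0 <- n0; spec$d0 <- d0; spec$R <- as.matrix(R)
    check_spd_dims(spec$R, S, "R")
    spec$R_chol <- chol_spd(spec$R, label = "R")
  }
  # conformality along the chain
  p_prev <- p
  for (t in seq_len(n_time)) {
    Gt <- spec$G[[t]]
    if (ncol(Gt) != p_prev)
      stop(sprintf("G[[%d]] has %d columns; expected %d", t, ncol(Gt), p_prev),
           call. = FALSE)
    pt <- nrow(Gt)
    Ft <- spec$FF[[t]]
    if (ncol(Ft) != pt)
      stop(sprintf("F[[%d]] has %d columns; expected %d", t, ncol(Ft), pt),
           call. = FALSE)
    check_spd_dims(spec$V[[t]], nrow(Ft), sprintf("V[[%d]]", t))
    check_spd_dims(spec$W[[t]], pt, sprintf("W[[%d]]", t))
    p_prev <- pt
  }
  class(spec) <- "dlm_spec"
  spec
}

as_Y_list <- function(Y, n_time) {
  if (is.list(Y)) lapply(Y, as.matrix) else rep(list(as.matrix(Y)), n_time)
}

#' Forward (Kalman) filter for the matrix-variate DLM
#'
#' Runs the conjugate filtering recursions
#' `a_t = G_t m_{t-1}`, `A_t = G_t M_{t-1} G_t' + W_t`,
#' `q_t = F_t a_t`, `Q_t = F_t A_t F_t' + V_t`,
#' `m_t = a_t + A_t F_t' Q_t^{-1} (Y_t - q_t)`,
#' `M_t = A_t - A_t F_t' Q_t^{-1} F_t A_t`,
#' with scale updates `n_t = n_{t-1} + N`,
#' `D_t = D_{t-1} + (Y_t - q_t)' Q_t^{-1} (Y_t - q_t)` (mniw) or
#' `n_t = n_{t-1} + N S / 2`,
#' `d_t = d_{t-1} + tr[(Y_t - q_t)' Q_t^{-1} (Y_t - q_t) R^{-1}] / 2` (mnig).
#'
#' @param Y list of `T` observation matrices `N_t x S` (a single matrix is
#'   recycled).
#' @param spec a [dlm_spec()].
#' @return an object of class `dlm_filter`: per-time lists `a, A, q, Q, m, M`
#'   (states indexed `[[t + 1]]` for `t = 0, ..., T`) and the scale trajectory
#'   `n` plus `D` (mniw) or `d` (mnig).
#' @export
forward_filter <- function(Y, spec) {
  stopifnot(inherits(spec, "dlm_spec"))
  Tn <- spec$n_time
  Y <- as_Y_list(Y, Tn)
  if (length(Y) != Tn) stop("Y must have length T", call. = FALSE)
  mniw <- spec$structure == "mniw"
  mnig <- spec$structure == "mnig"
  out <- list(a = vector("list", Tn), A = vector("list", Tn),
              q = vector("list", Tn), Q = vector("list", Tn),
              Q_chol = vector("list", Tn),
              m = vector("list", Tn + 1), M = vector("list", Tn + 1),
              n = numeric(Tn + 1), structure = spec$structure)
  out$m[[1]] <- spec$m0; out$M[[1]] <- spec$M0
  if (mniw) {
    out$D <- vector("list", Tn + 1)
    out$n[1] <- spec$n0; out$D[[1]] <- spec$D0
  } else if (mnig) {
    out$d <- numeric(Tn + 1)
    out$n[1] <- spec$n0; out$d[1] <- spec$d0
  }
  for (t in seq_len(Tn)) {
    Ft <- spec$FF[[t]]; Gt <- spec$G[[t]]
    Vt <- spec$V[[t]]; Wt <- spec$W[[t]]
    Yt <- Y[[t]]
    N <- nrow(Yt)
    if (ncol(Yt) != spec$S || nrow(Ft) != N)
      stop(sprintf("Y[[%d]] not conformal with spec", t), call. = FALSE)
    a <- Gt %*% out$m[[t]]
    A <- sym(Gt %*% out$M[[t]] %*% t(Gt) + Wt)
    q <- Ft %*% a
    Q <- sym(Ft %*% A %*% t(Ft) + Vt)
    UQ <- tryCatch(chol_spd(Q, label = sprintf("Q at t=%d", t)),
                   error = function(e) stop(conditionMessage(e), call. = FALSE))
    E <- Yt - q
    QinvE <- solve_chol(UQ, E)          # Q^{-1} (Y - q),  N x S
    AFt <- A %*% t(Ft)                  # p x N
    m <- a + AFt %*% QinvE
    M <- sym(A - AFt %*% solve_chol(UQ, t(AFt)))
    out$a[[t]] <- a; out$A[[t]] <- A
    out$q[[t]] <- q; out$Q[[t]] <- Q; out$Q_chol[[t]] <- UQ
    out$m[[t + 1]] <- m; out$M[[t + 1]] <- M
    if (mniw) {
      out$n[t + 1] <- out$n[t] + N
      out$D[[t + 1]] <- sym(out$D[[t]] + crossprod(E, QinvE))
    } else if (mnig) {
      out$n[t + 1] <- out$n[t] + N * spec$S / 2
      RinvEq <- solve_chol(spec$R_chol, t(crossprod(E, QinvE)))
      out$d[t + 1] <- out$d[t] + 0.5 * sum(diag(RinvEq))
    }
  }
  out$spec <- spec
  out$Y <- Y
  class(out) <- "dlm_filter"
  out
}

#' Backward (Rauch-Tung-Striebel) smoothed moments
#'
#' Computes the marginal smoothed moments `h_t, H_t` of
#' `Theta_t | Y_{1:T}` by the backward recursion
#' `h_t = m_t + M_t G_{t+1}' A_{t+1}^{-1} (h_{t+1} - a_{t+1})`,
#' `H_t = M_t - M_t G_{t+1}' A_{t+1}^{-1} (A_{t+1} - H_{t+1}) A_{t+1}^{-1}
#'        G_{t+1} M_t`,
#' initialized at `h_T = m_T`, `H_T = M_T`.
#'
#' @param filt a [forward_filter()] result.
#' @return object of class `dlm_smooth` with lists `h`, `H` indexed
#'   `[[t + 1]]` for `t = 0, ..., T`.
#' @export
backward_moments <- function(filt) {
  stopifnot(inherits(filt, "dlm_filter"))
  spec <- filt$spec
  Tn <- spec$n_time
  h <- vector("list", Tn + 1); H <- vector("list", Tn + 1)
  h[[Tn + 1]] <- filt$m[[Tn + 1]]
  H[[Tn + 1]] <- filt$M[[Tn + 1]]
  for (t in seq(Tn - 1, 0)) {
    Gt1 <- spec$G[[t + 1]]
    A1 <- filt$A[[t + 1]]
    UA <- chol_spd(A1, label = sprintf("A at t=%d", t + 1))
    Mt <- filt$M[[t + 1]]
    Gain <- t(solve_chol(UA, Gt1 %*% Mt))      # M_t G' A^{-1},  p x p
    h[[t + 1]] <- filt$m[[t + 1]] + Gain %*% (h[[t + 2]] - filt$a[[t + 1]])
    H[[t + 1]] <- sym(Mt - Gain %*% (A1 - H[[t + 2]]) %*% t(Gain))
  }
  structure(list(h = h, H = H), class = "dlm_smooth")
}

#' Forward-filter backward-sampler: joint posterior draws
#'
#' Draws `L` joint samples of `(Theta_{0:T}, Sigma)` (mniw),
#' `(Theta_{0:T}, sigma^2)` (mnig) or `Theta_{0:T}` (identity) from the exact
#' posterior. The forward pass is run once; the backward pass draws
#' `Theta_T ~ MN(m_T, M_T, Sigma)` and then, for `t = T-1, ..., 0`,
#' `Theta_t | Theta_{t+1} ~ MN(m_t + B_t (Theta_{t+1} - a_{t+1}),
#'  M_t - B_t G_{t+1} M_t, Sigma)` with gain
#' `B_t = M_t G_{t+1}' A_{t+1}^{-1}`. The gains and conditional covariances
#' are computed once and reused across all `L` draws.
#'
#' @inheritParams forward_filter
#' @param L number of joint posterior draws (`>= 1`).
#' @param filt optionally, a precomputed [forward_filter()] output for `Y`.
#' @return object of class `dlm_draws`: `Theta` is an
#'   `L x (T+1) x p x S` array; `Sigma` an `L x S x S` array (mniw) or
#'   `sigma2` a length-`L` vector (mnig); plus the filter and the smoothed
#'   moments from [backward_moments()].
#' @export
ffbs <- function(Y, spec, L, filt = NULL) {
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  if (is.null(filt)) filt <- forward_filter(Y, spec)
  spec <- filt$spec
  Tn <- spec$n_time
  p <- spec$p; S <- spec$S
  smooth <- backward_moments(filt)
  # Precompute per-time gains and conditional covariance Cholesky factors.
  Gain <- vector("list", Tn); Ucond <- vector("list", Tn)
  for (t in seq(Tn - 1, 0)) {
    Gt1 <- spec$G[[t + 1]]
    UA <- chol_spd(filt$A[[t + 1]], label = sprintf("A at t=%d", t + 1))
    Mt <- filt$M[[t + 1]]
    B <- t(solve_chol(UA, Gt1 %*% Mt))
    Cc <- sym(Mt - B %*% Gt1 %*% Mt)
    Gain[[t + 1]] <- B
    Ucond[[t + 1]] <- psd_root(Cc, label = "conditional covariance")
  }
  UMT <- psd_root(filt$M[[Tn + 1]], label = "M_T")
  mniw <- spec$structure == "mniw"
  mnig <- spec$structure == "mnig"
  Theta <- array(NA_real_, c(L, Tn + 1, p, S))
  Sigma <- if (mniw) array(NA_real_, c(L, S, S)) else NULL
  sigma2 <- if (mnig) numeric(L) else NULL
  for (l in seq_len(L)) {
    if (mniw) {
      Sig <- rinvwishart(filt$n[Tn + 1], filt$D[[Tn + 1]])
      Sigma[l, , ] <- Sig
    } else if (mnig) {
      s2 <- rinvgamma(1, filt$n[Tn + 1], filt$d[Tn + 1])
      sigma2[l] <- s2
      Sig <- s2 * spec$R
    } else {
      Sig <- diag(S)
    }
    USig <- chol_spd(Sig, label = "Sigma draw")
    Th_next <- rmatnorm(filt$m[[Tn + 1]], UMT, USig, chol = TRUE)
    Theta[l, Tn + 1, , ] <- Th_next
    for (t in seq(Tn - 1, 0)) {
      mean_t <- filt$m[[t + 1]] +
        Gain[[t + 1]] %*% (Th_next - filt$a[[t + 1]])
      Th_t <- rmatnorm(mean_t, Ucond[[t + 1]], USig, chol = TRUE)
      Theta[l, t + 1, , ] <- Th_t
      Th_next <- Th_t
    }
  }
  structure(list(Theta = Theta, Sigma = Sigma, sigma2 = sigma2,
                 filter = filt, smooth = smooth, L = L,
                 structure = spec$structure),
            class = "dlm_draws")
}

#' One conditional predictive draw at new inputs
#'
#' Given one posterior draw `(Theta_t, Sigma)`, draws the `Ntilde x S` block
#' of outputs at new inputs from
#' `MN(Fnew Theta + t(J) V^{-1} (Y - F Theta), Vnew - t(J) V^{-1} J, Sigma)`.
#' When the new inputs are a subset of the training inputs the mean reproduces
#' the corresponding training rows exactly and the row covariance is zero.
#'
#' @param Fnew `Ntilde x p` observation matrix at the new inputs.
#' @param J `N x Ntilde` cross-correlation block between training and new
#'   inputs.
#' @param Vnew `Ntilde x Ntilde` correlation block among the new inputs.
#' @param Theta one `p x S` posterior state draw at time `t`.
#' @param Sigma one `S x S` column covariance draw (use `sigma2 * R` for the
#'   mnig structure, `diag(S)` for identity).
#' @param Y `N x S` training observations at time `t`.
#' @param FF `N x p` training observation matrix at time `t`.
#' @param V `N x N` training correlation at time `t` (or its Cholesky factor
#'   via `V_chol`).
#' @param V_chol optional upper-triangular Cholesky factor of `V`.
#' @param draw if `FALSE`, return the conditional mean and row covariance
#'   without sampling.
#' @return a list with `mean`, `rowcov`, and (if `draw`) `value`.
#' @export
predictive_conditional <- function(Fnew, J, Vnew, Theta, Sigma, Y, FF, V,
                                   V_chol = NULL, draw = TRUE) {
  Fnew <- as.matrix(Fnew); J <- as.matrix(J); Vnew <- as.matrix(Vnew)
  if (nrow(Fnew) == 0)
    return(list(mean = matrix(0, 0, ncol(Y)), rowcov = Vnew,
                value = matrix(0, 0, ncol(Y))))
  UV <- if (is.null(V_chol)) chol_spd(V, label = "V") else V_chol
  resid <- Y - FF %*% Theta
  JtVinv_resid <- crossprod(J, solve_chol(UV, resid))
  mean <- Fnew %*% Theta + JtVinv_resid
  rowcov <- sym(Vnew - quad_chol(UV, J))
  if (!all(is.finite(rowcov)))
    stop("augmented covariance is not positive definite: invalid kernel",
         call. = FALSE)
  out <- list(mean = mean, rowcov = rowcov)
  if (draw) {
    # Held-in inputs make directions of rowcov exactly singular; clip
    # round-off-level eigenvalues to zero so interpolation stays exact.
    ev <- eigen(rowcov, symmetric = TRUE)
    lam <- ev$values
    lam[lam < 1e-10 * max(lam, 1)] <- 0
    rt <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
    Z <- matrix(stats::rnorm(nrow(Fnew) * ncol(Y)), nrow(Fnew), ncol(Y))
    USig <- chol_spd(Sigma, label = "Sigma")
    out$value <- mean + rt %*% Z %*% USig
  }
  out
}

#' Hyper-T moments of the posterior predictive at new inputs
#'
#' Returns the location, row scale and degrees of freedom of the hyper-T
#' posterior predictive density of the new-input block at time `t`:
#' location `Fnew h_t + t(J) V^{-1} (Y - F h_t)`, row scale
#' `Fnew H_t Fnew' + Vnew - t(F H_t Fnew' + J) (F H_t F' + V)^{-1}
#'  (F H_t Fnew' + J)`, with `(n_T, D_T)` from the filter. For new inputs
#' inside the training set the row scale collapses to zero.
#'
#' @inheritParams predictive_conditional
#' @param h,H smoothed moments `h_t` (`p x S`) and `H_t` (`p x p`) at time `t`
#'   from [backward_moments()].
#' @param n_T,D_T terminal scale parameters from the filter (for the mnig
#'   structure pass `d_T` and `R` to [dhyper_t_scalar()] instead).
#' @return list with `location` (`Ntilde x S`), `rowscale`
#'   (`Ntilde x Ntilde`), `n` and `D`; entries have univariate-t margins with
#'   `n - S + 1` degrees of freedom.
#' @export
predictive_hyper_t_moments <- function(Fnew, J, Vnew, h, H, Y, FF, V,
                                       n_T, D_T, V_chol = NULL) {
  Fnew <- as.matrix(Fnew); J <- as.matrix(J); Vnew <- as.matrix(Vnew)
  UV <- if (is.null(V_chol)) chol_spd(V, label = "V") else V_chol
  location <- Fnew %*% h + crossprod(J, solve_chol(UV, Y - FF %*% h))
  P <- sym(FF %*% H %*% t(FF) + V)           # F H F' + V
  UP <- chol_spd(P, label = "F H F' + V")
  Cross <- FF %*% H %*% t(Fnew) + J          # N x Ntilde
  rowscale <- sym(Fnew %*% H %*% t(Fnew) + Vnew - quad_chol(UP, Cross))
  list(location = location, rowscale = rowscale, n = n_T, D = D_T)
}
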