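# Model comparison for the matrix-variate DLM fits: WAIC with analytic and
# Monte-Carlo log pointwise predictive density, the per-time WAIC curve and
# its standard error, and the Gelfand-Ghosh posterior predictive loss
# D = G + P with closed-form penalties for the three column-covariance
# structures.

# log p(Y_t | Y_{1:T}) under the fitted structure (analytic, Theta and the
# scale integrated against their smoothed posterior)
log_pred_density_t <- function(filt, smooth, t, Yt = NULL) {
  spec <- filt$spec
  Tn <- spec$n_time
  if (is.null(Yt)) Yt <- filt$Y[[t]]
  Ft <- spec$FF[[t]]
  loc <- Ft %*% smooth$h[[t + 1]]
  rowscale <- sym(Ft %*% smooth$H[[t + 1]] %*% t(Ft) + spec$V[[t]])
  switch(spec$structure,
    mniw = dhyper_t(Yt, loc, rowscale, filt$n[Tn + 1], filt$D[[Tn + 1]]),
    mnig = dhyper_t_scalar(Yt, loc, rowscale, filt$n[Tn + 1],
                           filt$d[Tn + 1], spec$R),
    identity = dmatnorm(Yt, loc, rowscale, diag(spec$S)))
}

#' WAIC for a fitted matrix-variate DLM
#'
#' Computes `WAIC = -2 (lppd - p_WAIC)`. The lppd is available analytically
#' as a sum of hyper-T (mniw), hyper-T-scalar (mnig) or matrix-normal
#' (identity) log-densities of the observed seasons under the smoothed
#' posterior; a Monte-Carlo version (log-mean-exp over the stored joint
#' draws) is reported alongside. The effective-parameter penalty is the
#' per-season posterior variance of the log conditional density
#' `log p(Y_t | Theta_t, Sigma)` summed over seasons. The per-season curve
#' `WAIC_t` and its standard error `sqrt(T * var(WAIC_t))` are included.
#'
#' @param draws a `dlm_draws` object from [ffbs()] (carries the filter,
#'   smoothed moments and the observed data).
#' @param use default `"analytic"`: which lppd enters the reported WAIC.
#' @return object of class `waic_report` with fields `lppd_analytic`,
#'   `lppd_mc`, `p_waic`, `waic`, `se_waic`, `waic_t`, `lppd_t`, `p_waic_t`.
#' @export
waic <- function(draws, use = c("analytic", "mc")) {
  stopifnot(inherits(draws, "dlm_draws"))
  use <- match.arg(use)
  filt <- draws$filter
  spec <- filt$spec
  Tn <- spec$n_time
  L <- draws$L
  if (L < 2) stop("need at least 2 draws to estimate p_WAIC", call. = FALSE)
  smooth <- draws$smooth
  lppd_t <- vapply(seq_len(Tn), function(t)
    log_pred_density_t(filt, smooth, t), numeric(1))
  ll <- matrix(NA_real_, L, Tn)       # log p(Y_t | Theta_t^(l), Sigma^(l))
  for (l in seq_len(L)) {
    Sig <- switch(spec$structure,
                  mniw = matrix(draws$Sigma[l, , ], spec$S, spec$S),
                  mnig = draws$sigma2[l] * spec$R,
                  identity = diag(spec$S))
    for (t in seq_len(Tn)) {
      Th <- matrix(draws$Theta[l, t + 1, , ], spec$p, spec$S)
      ll[l, t] <- dmatnorm(filt$Y[[t]], spec$FF[[t]] %*% Th,
                           spec$V[[t]], Sig)
    }
  }
  lppd_mc_t <- apply(ll, 2, logmeanexp)
  p_waic_t <- apply(ll, 2, stats::var)
  lppd_analytic <- sum(lppd_t)
  lppd_mc <- sum(lppd_mc_t)
  p_waic <- sum(p_waic_t)
  lppd_used_t <- if (use == "analytic") lppd_t else lppd_mc_t
  waic_t <- -2 * (lppd_used_t - p_waic_t)
  out <- list(lppd_analytic = lppd_analytic, lppd_mc = lppd_mc,
              p_waic = p_waic,
              waic = -2 * (sum(lppd_used_t) - p_waic),
              waic_t = waic_t, lppd_t = lppd_t, lppd_mc_t = lppd_mc_t,
              p_waic_t = p_waic_t, se_waic = waic_se(waic_t),
              use = use, structure = spec$structure)
  class(out) <- "waic_report"
  out
}

#' @export
print.waic_report <- function(x, ...) {
  cat(sprintf("WAIC report (%s structure, lppd: %s)\n", x$structure, x$use))
  cat(sprintf("  lppd            %.4f\n", x$lppd_analytic))
  cat(sprintf("  lppd (MC)       %.4f\n", x$lppd_mc))
  cat(sprintf("  p_WAIC          %.4f\n", x$p_waic))
  cat(sprintf("  WAIC            %.4f  (se %.4f)\n", x$waic, x$se_waic))
  invisible(x)
}

#' Standard error of the WAIC from its per-season terms
#'
#' `se = sqrt(T * var(WAIC_t))` over the `T` per-season WAIC contributions.
#'
#' @param waic_t numeric vector of per-season WAIC terms (`T >= 2`).
#' @return scalar standard error.
#' @export
waic_se <- function(waic_t) {
  Tn <- length(waic_t)
  if (Tn < 2) stop("need at least two seasons for se(WAIC)", call. = FALSE)
  sqrt(Tn * stats::var(waic_t))
}

#' Gelfand-Ghosh posterior predictive loss D = G + P
#'
#' Goodness of fit `G = sum_t || Y_t - F_t h_t ||_F^2` (identical across
#' column-covariance structures sharing the mean path) plus the replicate-
#' variance penalty in closed form:
#' `P_iw = tr(D_T) / (n_T - 2) * sum_t tr(H_t)`,
#' `P_ig = d_T * tr(R) / (n_T - 1) * sum_t tr(H_t)`,
#' `P_id = S * sum_t tr(H_t)`.
#'
#' @param draws a `dlm_draws` object from [ffbs()].
#' @return object of class `gpd_report` with fields `G`, `P`, `D` and
#'   `structure`.
#' @export
gpd_score <- function(draws) {
  stopifnot(inherits(draws, "dlm_draws"))
  filt <- draws$filter
  spec <- filt$spec
  Tn <- spec$n_time
  smooth <- draws$smooth
  G <- sum(vapply(seq_len(Tn), function(t) {
    E <- filt$Y[[t]] - spec$FF[[t]] %*% smooth$h[[t + 1]]
    sum(E * E)
  }, numeric(1)))
  trH <- sum(vapply(seq_len(Tn), function(t)
    sum(diag(smooth$H[[t + 1]])), numeric(1)))
  nT <- filt$n[Tn + 1]
  P <- switch(spec$structure,
    mniw = {
      if (nT <= 2) stop("penalty undefined: n_T <= 2", call. = FALSE)
      sum(diag(filt$D[[Tn + 1]])) / (nT - 2) * trH
    },
    mnig = {
      if (nT <= 1) stop("penalty undefined: n_T <= 1", call. = FALSE)
      filt$d[Tn + 1] * sum(diag(spec$R)) / (nT - 1) * trH
    },
    identity = spec$S * trH)
  structure(list(G = G, P = P, D = G + P, structure = spec$structure),
            class = "gpd_report")
}

#' @export
print.gpd_report <- function(x, ...) {
  cat(sprintf("Posterior predictive loss (%s structure)\n", x$structure))
  cat(sprintf("  G = %.4f   P = %.4f   D = G + P = %.4f\n", x$G, x$P, x$D))
  invisible(x)
}
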