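# Built-in deterministic mechanistic systems and synthetic-data generators:
# Lotka-Volterra predator-prey ODEs, an SIR reaction-diffusion PDE on a
# regular grid, network activation diffusion, Latin hypercube designs and
# field-data generation with a dynamic spatial bias. All simulators are
# deterministic given their parameters; randomness enters only through
# design generation and observation noise.

# Classic fixed-step fourth-order Runge-Kutta on dy/dt = f(t, y).
rk4_integrate <- function(f, y0, times, dt) {
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y <- y0
  for (i in seq_along(times)[-1]) {
    t0 <- times[i - 1]; t1 <- times[i]
    nstep <- max(1L, ceiling((t1 - t0) / dt - 1e-9))
    h <- (t1 - t0) / nstep
    for (s in seq_len(nstep)) {
      tt <- t0 + (s - 1) * h
      k1 <- f(tt, y)
      k2 <- f(tt + h / 2, y + h / 2 * k1)
      k3 <- f(tt + h / 2, y + h / 2 * k2)
      k4 <- f(tt + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i, ] <- y
  }
  out
}

#' Solve the Lotka-Volterra predator-prey system
#'
#' Integrates `du/dt = eta1 u - eta2 u v`, `dv/dt = -eta3 v + eta4 u v`
#' (prey `u`, predator `v`) with fixed-step RK4. `eta1` is the intrinsic prey
#' growth rate and `eta3` the intrinsic predator loss rate (per unit time);
#' `eta2` and `eta4` are the interaction rates scaling the population
#' product, typically one to two orders of magnitude smaller. The system has
#' the fixed point `(eta3/eta4, eta1/eta2)` and conserves
#' `eta4 u - eta3 log u + eta2 v - eta1 log v` along orbits.
#'
#' @param eta length-4 positive rate vector `(eta1, eta2, eta3, eta4)`.
#' @param u0,v0 positive initial prey and predator populations.
#' @param times increasing vector of output times (first entry is the
#'   initial time).
#' @param dt integrator step (default 0.01).
#' @return matrix with columns `u`, `v`, one row per output time.
#' @export
lv_solve <- function(eta, u0, v0, times, dt = 0.01) {
  if (length(eta) != 4 || any(eta <= 0))
    stop("eta must be four positive rates", call. = FALSE)
  if (u0 <= 0 || v0 <= 0)
    stop("initial populations must be positive", call. = FALSE)
  f <- function(t, y) {
    c(eta[1] * y[1] - eta[2] * y[1] * y[2],
      -eta[3] * y[2] + eta[4] * y[1] * y[2])
  }
  out <- rk4_integrate(f, c(u0, v0), times, dt)
  colnames(out) <- c("u", "v")
  if (!all(is.finite(out))) stop("Lotka-Volterra solver diverged",
                                 call. = FALSE)
  out
}

# Vectorized LV over N parameter sets sharing an initial condition; returns a
# (T+1) x N x 2 tensor of (u, v) at integer-indexed 'times'.
lv_ensemble <- function(etas, u0, v0, times, dt = 0.01) {
  etas <- as.matrix(etas)
  N <- nrow(etas)
  f <- function(t, y) {
    u <- y[1:N]; v <- y[(N + 1):(2 * N)]
    c(etas[, 1] * u - etas[, 2] * u * v,
      -etas[, 3] * v + etas[, 4] * u * v)
  }
  traj <- rk4_integrate(f, c(rep(u0, N), rep(v0, N)), times, dt)
  out <- array(NA_real_, c(length(times), N, 2))
  out[, , 1] <- traj[, 1:N]
  out[, , 2] <- traj[, (N + 1):(2 * N)]
  out
}

# 5-point discrete Laplacian with zero-flux (mirrored) boundaries on an
# nx x ny grid, unit spacing.
laplacian_neumann <- function(M) {
  up    <- rbind(M[1, , drop = FALSE], M[-nrow(M), , drop = FALSE])
  down  <- rbind(M[-1, , drop = FALSE], M[nrow(M), , drop = FALSE])
  left  <- cbind(M[, 1, drop = FALSE], M[, -ncol(M), drop = FALSE])
  right <- cbind(M[, -1, drop = FALSE], M[, ncol(M), drop = FALSE])
  up + down + left + right - 4 * M
}

#' Solve the SIR reaction-diffusion system on a regular grid
#'
#' Method-of-lines solution of
#' `dS/dt = -eta1 S I / N + alpha1 lap(S)`,
#' `dI/dt =  eta1 S I / N - eta2 I + alpha2 lap(I)`,
#' `dR/dt =  eta2 I + alpha3 lap(R)`,
#' with the 5-point Laplacian at unit grid spacing, zero-flux boundaries and
#' fixed-step RK4. The step size obeys the explicit diffusion stability bound
#' `dt <= 0.9 / (4 max(alpha))` (capped at 0.05 for reaction accuracy). Output is reported at
#' integer times `0, ..., n_time` (`n_time + 1` time points including time
#' 0). The total population `sum(S + I + R)` is conserved.
#'
#' @param eta length-2 vector: transmission rate `eta1`, recovery rate
#'   `eta2`.
#' @param alpha length-3 nonnegative diffusion coefficients for S, I, R.
#' @param nx,ny grid dimensions (`>= 2`).
#' @param n_time number of unit time steps to report.
#' @param N_pop per-site population scale entering the transmission term.
#' @param seeds integer matrix with columns `(row, col, I0)` giving seeded
#'   sites and their initial infection counts; default seeds the grid centre
#'   and the bottom-left corner with 1 each.
#' @param dt optional integrator step override.
#' @return list of arrays `S`, `I`, `R`, each `(n_time+1) x nx x ny`.
#' @export
sir_pde_solve <- function(eta, alpha, nx, ny, n_time, N_pop = 100,
                          seeds = NULL, dt = NULL) {
  if (length(eta) != 2 || any(eta < 0))
    stop("eta must be two nonnegative rates", call. = FALSE)
  if (length(alpha) != 3 || any(alpha < 0))
    stop("alpha must be three nonnegative diffusion coefficients",
         call. = FALSE)
  if (nx < 2 || ny < 2) stop("grid must be at least 2 x 2", call. = FALSE)
  if (is.null(seeds))
    seeds <- rbind(c(ceiling(nx / 2), ceiling(ny / 2), 1), c(1, 1, 1))
  if (is.null(dt)) dt <- min(0.05, 0.9 / (4 * max(alpha, 0.25)))
  S <- matrix(N_pop, nx, ny); I <- matrix(0, nx, ny); R <- matrix(0, nx, ny)
  for (i in seq_len(nrow(seeds))) {
    I[seeds[i, 1], seeds[i, 2]] <- seeds[i, 3]
    S[seeds[i, 1], seeds[i, 2]] <- N_pop - seeds[i, 3]
  }
  rhs <- function(S, I, R) {
    inf <- eta[1] * S * I / N_pop
    rec <- eta[2] * I
    list(S = -inf + alpha[1] * laplacian_neumann(S),
         I = inf - rec + alpha[2] * laplacian_neumann(I),
         R = rec + alpha[3] * laplacian_neumann(R))
  }
  outS <- array(NA_real_, c(n_time + 1, nx, ny))
  outI <- outS; outR <- outS
  outS[1, , ] <- S; outI[1, , ] <- I; outR[1, , ] <- R
  nstep <- max(1L, ceiling(1 / dt - 1e-9))
  h <- 1 / nstep
  for (tt in seq_len(n_time)) {
    for (s in seq_len(nstep)) {
      k1 <- rhs(S, I, R)
      k2 <- rhs(S + h / 2 * k1$S, I + h / 2 * k1$I, R + h / 2 * k1$R)
      k3 <- rhs(S + h / 2 * k2$S, I + h / 2 * k2$I, R + h / 2 * k2$R)
      k4 <- rhs(S + h * k3$S, I + h * k3$I, R + h * k3$R)
      S <- S + h / 6 * (k1$S + 2 * k2$S + 2 * k3$S + k4$S)
      I <- I + h / 6 * (k1$I + 2 * k2$I + 2 * k3$I + k4$I)
      R <- R + h / 6 * (k1$R + 2 * k2$R + 2 * k3$R + k4$R)
    }
    if (!all(is.finite(S)) || !all(is.finite(I)) || !all(is.finite(R)))
      stop(sprintf("SIR PDE integrator became unstable at t=%d", tt),
           call. = FALSE)
    outS[tt + 1, , ] <- S; outI[tt + 1, , ] <- I; outR[tt + 1, , ] <- R
  }
  list(S = outS, I = outI, R = outR)
}

#' Run a deterministic network activation diffusion
#'
#' Iterates the spreading-activation rules: each node keeps
#' `reservoir(t, n) = r * inflow(t, n)`, passes
#' `outflow(t, n) = (1 - d)(1 - r) * inflow(t, n) / deg(n)` to each
#' neighbour, and receives
#' `inflow(t, n) = sum_neighbours outflow(t-1, .) + reservoir(t-1, n)`.
#' Activation is reported as inflow, with `inflow(0, n)` the seeded
#' activation. With `d = 0` total activation is conserved; in general the
#' total is multiplied by `1 - d (1 - r)` per step (scalar `r`).
#'
#' @param adjacency `n x n` symmetric 0/1 matrix.
#' @param r retention in `[0, 1]`, scalar or length-`n` vector.
#' @param d decay in `[0, 1]`, scalar.
#' @param activation0 length-`n` nonnegative initial activation.
#' @param n_time number of steps.
#' @return `(n_time + 1) x n` matrix of activations (inflow) over time.
#' @export
network_diffusion_run <- function(adjacency, r, d, activation0, n_time) {
  A <- as.matrix(adjacency)
  n <- nrow(A)
  if (!isSymmetric(A) || any(!A %in% c(0, 1)))
    stop("adjacency must be symmetric 0/1", call. = FALSE)
  if (any(r < 0) || any(r > 1) || d < 0 || d > 1)
    stop("r and d must lie in [0, 1]", call. = FALSE)
  deg <- rowSums(A)
  if (any(deg == 0 & activation0 > 0))
    stop("isolated node carries activation (degree zero)", call. = FALSE)
  r <- rep_len(r, n)
  out <- matrix(0, n_time + 1, n)
  inflow <- activation0
  out[1, ] <- inflow
  for (t in seq_len(n_time)) {
    reservoir <- r * inflow
    per_edge <- ifelse(deg > 0, (1 - d) * (1 - r) * inflow / deg, 0)
    inflow <- as.numeric(A %*% per_edge) + reservoir
    out[t + 1, ] <- inflow
  }
  out
}

#' Small-world network fixture
#'
#' A 30-node ring where each node links to its two nearest neighbours on each
#' side, with a fixed set of rewired chords. The network topology behind the
#' published diffusion experiment is unstated, so this fixture is synthetic
#' and non-replicating; it exists to exercise the simulator and calibration
#' code on a realistic graph.
#'
#' @param n number of nodes.
#' @return `n x n` 0/1 symmetric adjacency matrix.
#' @export
network_fixture <- function(n = 30) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (off in 1:2) {
      j <- ((i - 1 + off) %% n) + 1
      A[i, j] <- A[j, i] <- 1L
    }
  }
  chords <- cbind(c(1, 5, 9, 14, 20), c(16, 23, 27, 3, 8))
  A[chords] <- 1L
  A[chords[, 2:1]] <- 1L
  diag(A) <- 0L
  A
}

#' Latin hypercube design with marginal transforms
#'
#' Stratified one-point-per-stratum sampling per dimension: ranks of each
#' column form a permutation of `1..n`. Uniform strata draws are mapped
#' through the inverse CDF of each dimension's marginal.
#'
#' @param n number of design points (`>= 2`).
#' @param marginals list of length `d`; each element is
#'   `list(type = "lognormal", mu=, sigma=)` or
#'   `list(type = "uniform", a=, b=)`.
#' @return `n x d` design matrix.
#' @export
lhs_design <- function(n, marginals) {
  if (n < 2) stop("need at least two design points", call. = FALSE)
  d <- length(marginals)
  out <- matrix(NA_real_, n, d)
  for (j in seq_len(d)) {
    u <- (sample.int(n) - 1 + stats::runif(n)) / n
    m <- marginals[[j]]
    out[, j] <- switch(m$type,
      lognormal = stats::qlnorm(u, meanlog = m$mu, sdlog = m$sigma),
      uniform = stats::qunif(u, min = m$a, max = m$b),
      stop("unknown marginal type", call. = FALSE))
  }
  out
}

# The lognormal input world of the predator-prey experiments: eta1, eta3
# near 1 and the interaction rates eta2, eta4 near 0.05.
lv_prior_marginals <- function() {
  list(list(type = "lognormal", mu = 0, sigma = 0.5),
       list(type = "lognormal", mu = -3, sigma = 0.5),
       list(type = "lognormal", mu = 0, sigma = 0.5),
       list(type = "lognormal", mu = -3, sigma = 0.5))
}

#' Generate synthetic field observations with dynamic bias
#'
#' Builds `z_t(s) = y_t(s) + u_t(s) + eps_t(s)` from a simulator trajectory
#' `y` at the true mechanistic input, where `u` is a random walk with
#' Gaussian-process increments `u_t = u_{t-1} + N(0, tau2_t U(rho))`
#' (`u_0 = 0`) and `eps_t(s) ~ N(0, tau2_t)` iid. Ground truth is returned
#' for recovery experiments.
#'
#' @param y_true `T x S_field` matrix of simulator outputs at the true input
#'   restricted to the field locations.
#' @param tau2 observation variance, scalar or length-`T`.
#' @param U `S_field x S_field` correlation of the bias increments.
#' @param bias if `FALSE`, `u` is identically zero.
#' @return list with `z` (`T x S_field`), `u` (`(T+1) x S_field`) and `tau2`.
#' @export
make_field_data <- function(y_true, tau2, U = NULL, bias = TRUE) {
  y_true <- as.matrix(y_true)
  Tn <- nrow(y_true); Sf <- ncol(y_true)
  tau2 <- rep_len(tau2, Tn)
  if (is.null(U)) U <- diag(Sf)
  UU <- chol_spd(U, label = "U")
  u <- matrix(0, Tn + 1, Sf)
  z <- matrix(NA_real_, Tn, Sf)
  for (t in seq_len(Tn)) {
    if (bias) {
      inc <- sqrt(tau2[t]) * as.numeric(crossprod(UU, stats::rnorm(Sf)))
      u[t + 1, ] <- u[t, ] + inc
    }
    z[t, ] <- y_true[t, ] + u[t + 1, ] + stats::rnorm(Sf, sd = sqrt(tau2[t]))
  }
  list(z = z, u = u, tau2 = tau2)
}
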