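# Matrix-variate distribution layer: samplers and log-densities for the
# matrix-normal, inverse-Wishart, inverse-gamma, hyper-T and hyper-T-scalar
# families that underpin the conjugate state-space emulator.
#
# Parameterizations. The inverse-Wishart IW(n, D) has density proportional to
#   det(D)^{n/2} exp(-tr(D Sigma^{-1}) / 2) / det(Sigma)^{(n+S+1)/2},
# so E[Sigma] = D / (n - S - 1). The hyper-T is the Sigma-marginal of the
# matrix-normal-inverse-Wishart; its entries have univariate-t margins with
# n - S + 1 degrees of freedom (see [matrix_t_dof()] for the canonical
# matrix-T mapping). The hyper-T-scalar marginalizes sigma^2 ~ IG(shape, rate)
# from a matrix-normal with column covariance sigma^2 R.

#' Draw from a matrix-normal distribution
#'
#' Samples `Theta ~ MN(mean, M, Sigma)` where `M` is the `p x p` row
#' covariance and `Sigma` the `S x S` column covariance, via
#' `Theta = mean + t(LM) Z LS` with `Z` a matrix of iid standard normals and
#' `LM, LS` the Cholesky factors. Equivalently `vec(Theta)` is multivariate
#' normal with covariance `Sigma %x% M`.
#'
#' @param mean `p x S` mean matrix.
#' @param rowSigma `p x p` row covariance (or its Cholesky factor, see `chol`).
#' @param colSigma `S x S` column covariance (or its Cholesky factor).
#' @param chol if `TRUE`, `rowSigma`/`colSigma` are upper-triangular Cholesky
#'   factors (as from [chol()]); a zero matrix is accepted and yields a
#'   degenerate draw at `mean`.
#' @return a `p x S` matrix draw.
#' @seealso [dmatnorm()]
#' @export
rmatnorm <- function(mean, rowSigma, colSigma, chol = FALSE) {
  mean <- as.matrix(mean)
  p <- nrow(mean); S <- ncol(mean)
  check_spd_dims(as.matrix(rowSigma), p, "rowSigma")
  check_spd_dims(as.matrix(colSigma), S, "colSigma")
  UM <- if (chol) as.matrix(rowSigma) else chol_spd(rowSigma, label = "rowSigma")
  US <- if (chol) as.matrix(colSigma) else chol_spd(colSigma, label = "colSigma")
  Z <- matrix(stats::rnorm(p * S), p, S)
  mean + crossprod(UM, Z) %*% US
}

#' Matrix-normal log-density
#'
#' Log of the matrix-normal density
#' `MN(X | mean, rowSigma, colSigma)`, computed through Cholesky
#' log-determinants and triangular solves. Identical to the `pS`-dimensional
#' multivariate normal log-density of `vec(X)` with covariance
#' `colSigma %x% rowSigma`.
#'
#' @inheritParams rmatnorm
#' @param X `p x S` matrix at which to evaluate.
#' @param log return the log-density (default) or the density.
#' @return scalar (log-)density.
#' @export
dmatnorm <- function(X, mean, rowSigma, colSigma, log = TRUE) {
  X <- as.matrix(X); mean <- as.matrix(mean)
  p <- nrow(X); S <- ncol(X)
  if (!all(dim(mean) == c(p, S)))
    stop("dimensions of 'X' and 'mean' disagree", call. = FALSE)
  check_spd_dims(as.matrix(rowSigma), p, "rowSigma")
  check_spd_dims(as.matrix(colSigma), S, "colSigma")
  UM <- chol_spd(rowSigma, label = "rowSigma")
  US <- chol_spd(colSigma, label = "colSigma")
  E <- X - mean
  # tr(Sigma^{-1} t(E) M^{-1} E) = || LM^{-T} E LS^{-1} ||_F^2
  A <- forwardsolve(t(UM), E)        # p x S
  B <- t(backsolve(US, t(A), transpose = TRUE)) # right-solve by chol of Sigma
  quad <- sum(B * B)
  ll <- -0.5 * (p * S * log(2 * pi) + S * logdet_chol(UM) +
                  p * logdet_chol(US) + quad)
  if (log) ll else exp(ll)
}

#' Draw from an inverse-Wishart distribution
#'
#' Uses the Bartlett decomposition of the Wishart `W(n, D^{-1})` and inverts,
#' so draws follow the IW(n, D) parameterization with mean `D / (n - S - 1)`.
#'
#' @param n degrees of freedom; must exceed `S - 1`.
#' @param D `S x S` symmetric positive-definite scale matrix.
#' @return an `S x S` SPD draw.
#' @export
rinvwishart <- function(n, D) {
  D <- as.matrix(D)
  S <- nrow(D)
  check_spd_dims(D, S, "D")
  if (n <= S - 1)
    stop("inverse-Wishart requires n > S - 1", call. = FALSE)
  # Bartlett: W = L A t(A) t(L) ~ Wishart(n, D^{-1}) where D = t(U) U and
  # L = U^{-1} is a factor of D^{-1}.
  A <- diag(sqrt(stats::rchisq(S, df = n - seq_len(S) + 1)), S)
  if (S > 1) A[lower.tri(A)] <- stats::rnorm(S * (S - 1) / 2)
  U <- chol_spd(D, label = "D")
  # factor of D^{-1}: solve U X = I gives U^{-1} (upper triangular)
  Uinv <- backsolve(U, diag(S))
  LA <- Uinv %*% A
  W <- tcrossprod(LA)
  Winv <- chol2inv(chol(W))
  sym(Winv)
}

#' Inverse-gamma draws (shape/rate)
#'
#' @param n number of draws.
#' @param shape,rate positive inverse-gamma parameters; the density is
#'   proportional to `x^{-(shape+1)} exp(-rate / x)`.
#' @return numeric vector of positive draws.
#' @export
rinvgamma <- function(n, shape, rate) {
  if (any(shape <= 0) || any(rate <= 0))
    stop("inverse-gamma shape and rate must be positive", call. = FALSE)
  1 / stats::rgamma(n, shape = shape, rate = rate)
}

#' Hyper-T log-density
#'
#' Density of the matrix-variate hyper-T, obtained by integrating the column
#' covariance `Sigma ~ IW(n, D)` out of `MN(m, M, Sigma)`:
#' \deqn{p(X) = \frac{\Gamma_S((n+p)/2)\,
#'   \det(I_S + D^{-1}(X-m)^\top M^{-1}(X-m))^{-(n+p)/2}}
#'   {\pi^{pS/2}\,\Gamma_S(n/2)\,\det(M)^{S/2}\,\det(D)^{p/2}}.}
#' Each entry has a univariate-t margin with `n - S + 1` degrees of freedom,
#' mean `m[i,j]` and squared scale `D[j,j] * M[i,i] / n`.
#'
#' @param X,m `p x S` matrices (point of evaluation and location).
#' @param M `p x p` SPD row scale.
#' @param n degrees of freedom of the integrated inverse-Wishart (`> S - 1`).
#' @param D `S x S` SPD column scale.
#' @param log return the log-density (default) or the density.
#' @return scalar (log-)density, finite for any real `X`.
#' @export
dhyper_t <- function(X, m, M, n, D, log = TRUE) {
  X <- as.matrix(X); m <- as.matrix(m)
  p <- nrow(X); S <- ncol(X)
  if (!all(dim(m) == c(p, S)))
    stop("dimensions of 'X' and 'm' disagree", call. = FALSE)
  if (n <= S - 1) stop("hyper-T requires n > S - 1", call. = FALSE)
  UM <- chol_spd(M, label = "M")
  UD <- chol_spd(D, label = "D")
  E <- X - m
  A <- forwardsolve(t(UM), E)                  # p x S, M^{-1/2} E
  Q <- crossprod(A)                            # t(E) M^{-1} E, S x S
  # det(I + D^{-1} Q) = det(D + Q) / det(D); use chol of D + Q
  Udq <- chol_spd(D + Q, label = "D + quadratic form")
  ld_core <- logdet_chol(Udq) - logdet_chol(UD)
  ll <- lmvgamma((n + p) / 2, S) - lmvgamma(n / 2, S) -
    p * S / 2 * log(pi) - S / 2 * logdet_chol(UM) - p / 2 * logdet_chol(UD) -
    (n + p) / 2 * ld_core
  if (log) ll else exp(ll)
}

#' Draw from the hyper-T distribution
#'
#' Composition sampler: `Sigma ~ IW(n, D)`, then `Theta ~ MN(m, M, Sigma)`.
#'
#' @inheritParams dhyper_t
#' @return a `p x S` matrix draw.
#' @export
rhyper_t <- function(m, M, n, D) {
  Sigma <- rinvwishart(n, D)
  rmatnorm(m, M, Sigma)
}

#' Hyper-T-scalar log-density
#'
#' Density of the matrix-variate t obtained by integrating
#' `sigma^2 ~ IG(shape, rate)` out of `MN(m, M, sigma^2 R)` for a fixed
#' correlation matrix `R`:
#' \deqn{p(X) = \frac{\Gamma(pS/2 + n)}{\Gamma(n)} (2\pi d)^{-pS/2}
#'   |M|^{-S/2} |R|^{-p/2}
#'   \left(1 + \frac{1}{2d}\,\mathrm{tr}[R^{-1}(X-m)^\top M^{-1}(X-m)]
#'   \right)^{-(pS/2+n)}}
#' with `n = shape`, `d = rate`.
#'
#' @inheritParams dhyper_t
#' @param shape,rate positive inverse-gamma parameters of the integrated
#'   `sigma^2`.
#' @param R `S x S` SPD correlation matrix (held fixed).
#' @export
dhyper_t_scalar <- function(X, m, M, shape, rate, R, log = TRUE) {
  X <- as.matrix(X); m <- as.matrix(m)
  p <- nrow(X); S <- ncol(X)
  if (!all(dim(m) == c(p, S)))
    stop("dimensions of 'X' and 'm' disagree", call. = FALSE)
  if (shape <= 0 || rate <= 0)
    stop("'shape' and 'rate' must be positive", call. = FALSE)
  UM <- chol_spd(M, label = "M")
  UR <- chol_spd(R, label = "R")
  E <- X - m
  A <- forwardsolve(t(UM), E)
  B <- t(backsolve(UR, t(A), transpose = TRUE))
  quad <- sum(B * B)                           # tr(R^{-1} t(E) M^{-1} E)
  ll <- lgamma(p * S / 2 + shape) - lgamma(shape) -
    p * S / 2 * log(2 * pi * rate) - S / 2 * logdet_chol(UM) -
    p / 2 * logdet_chol(UR) -
    (p * S / 2 + shape) * log1p(quad / (2 * rate))
  if (log) ll else exp(ll)
}

#' Canonical matrix-T degrees of freedom
#'
#' The hyper-T with inverse-Wishart degrees of freedom `n` is the canonical
#' matrix-T with `n - S + 1` degrees of freedom (the IW dof is *not*
#' automatically the matrix-T dof). Summary methods report both.
#'
#' @param n inverse-Wishart degrees of freedom.
#' @param S column dimension.
#' @return canonical matrix-T degrees of freedom `n - S + 1`.
#' @export
matrix_t_dof <- function(n, S) n - S + 1
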