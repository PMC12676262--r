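# Internal linear-algebra helpers shared by all modules.
#
# All log-determinants and quadratic forms go through Cholesky factors and
# triangular solves; explicit inverses are never formed.

#' Symmetrize a square matrix
#'
#' Floating-point subtraction forms (filter/smoother updates) lose exact
#' symmetry; `(A + t(A)) / 2` restores it before any Cholesky.
#' @param A square numeric matrix.
#' @return symmetric matrix.
#' @keywords internal
sym <- function(A) (A + t(A)) / 2

#' Cholesky of a symmetric positive-definite matrix with adaptive jitter
#'
#' Squared-exponential kernels on dense designs are near-singular, so a plain
#' `chol()` can fail on matrices that are PD in exact arithmetic. Jitter is
#' added to the diagonal starting at 1e-10 and grown tenfold up to 1e-6;
#' failure beyond that is an error.
#'
#' @param A symmetric positive-definite matrix.
#' @param jitter0 initial diagonal jitter.
#' @param jitter_max maximum diagonal jitter attempted.
#' @param label name used in the error message.
#' @return upper-triangular Cholesky factor `U` with `t(U) %*% U = A`.
#' @keywords internal
chol_spd <- function(A, jitter0 = 1e-10, jitter_max = 1e-6, label = "matrix") {
  A <- sym(as.matrix(A))
  U <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(U)) return(U)
  jit <- jitter0
  d <- nrow(A)
  while (jit <= jitter_max) {
    U <- tryCatch(chol(A + diag(jit, d)), error = function(e) NULL)
    if (!is.null(U)) return(U)
    jit <- jit * 10
  }
  stop(sprintf("Cholesky factorization of %s failed even with jitter %g",
               label, jitter_max), call. = FALSE)
}

# log(det(A)) from an upper-triangular Cholesky factor
logdet_chol <- function(U) 2 * sum(log(diag(U)))

# Solve A x = b given upper-triangular Cholesky factor U of A
solve_chol <- function(U, b) backsolve(U, forwardsolve(t(U), b))

# t(X) %*% A^{-1} %*% Y via triangular solves (A = t(U) U)
quad_chol <- function(U, X, Y = X) {
  Lx <- forwardsolve(t(U), X)
  Ly <- if (identical(X, Y)) Lx else forwardsolve(t(U), Y)
  crossprod(Lx, Ly)
}

# multivariate log-Gamma function Gamma_S(a)
lmvgamma <- function(a, S) {
  S * (S - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(S)) / 2))
}

as_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = length(x), ncol = 1)
}

check_spd_dims <- function(A, n, name) {
  if (!is.matrix(A) || nrow(A) != n || ncol(A) != n)
    stop(sprintf("'%s' must be a %d x %d matrix", name, n, n), call. = FALSE)
  invisible(TRUE)
}

# Root R with crossprod(R) = A for a symmetric PSD matrix, tolerating exact
# singularity (negative eigenvalues from round-off are clipped at zero).
psd_root <- function(A, label = "matrix") {
  A <- sym(as.matrix(A))
  U <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(U)) return(U)
  ev <- eigen(A, symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values), 1))
    stop(sprintf("%s is not positive semidefinite", label), call. = FALSE)
  sqrt(pmax(ev$values, 0)) * t(ev$vectors)
}

logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}
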