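# Shared fixtures: random SPD matrices, random DLM instances, and the small
# Lotka-Volterra training world used across modules.

rspd <- function(k, scale = 1) {
  A <- matrix(rnorm(k * k), k)
  scale * (crossprod(A) / k + diag(k))
}

# A random conformal mniw DLM instance with its data.
random_dlm <- function(p = 2, N = 2, S = 2, Tn = 3, structure = "mniw",
                       R = NULL) {
  FF <- lapply(seq_len(Tn), function(t) matrix(rnorm(N * p), N, p))
  G <- lapply(seq_len(Tn), function(t) matrix(rnorm(p * p), p, p))
  V <- lapply(seq_len(Tn), function(t) rspd(N))
  W <- lapply(seq_len(Tn), function(t) rspd(p))
  m0 <- matrix(rnorm(p * S), p, S)
  M0 <- rspd(p)
  Y <- lapply(seq_len(Tn), function(t) matrix(rnorm(N * S), N, S))
  spec <- if (structure == "mniw") {
    dlm_spec(FF, G, V, W, Tn, "mniw", m0, M0, n0 = S + 2, D0 = rspd(S))
  } else if (structure == "mnig") {
    if (is.null(R)) R <- diag(S)
    dlm_spec(FF, G, V, W, Tn, "mnig", m0, M0, n0 = 2, d0 = 1, R = R)
  } else {
    dlm_spec(FF, G, V, W, Tn, "identity", m0, M0)
  }
  list(spec = spec, Y = Y, FF = FF, G = G, V = V, W = W, m0 = m0, M0 = M0)
}

# Small Lotka-Volterra training world (shared by emulator and calibration
# tests); cached per session.
lv_world <- local({
  cache <- NULL
  function(N = 30, Tn = 12, L = 50, seed = 4242) {
    key <- paste(N, Tn, L, seed)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$val)
    set.seed(seed)
    marg <- list(list(type = "lognormal", mu = 0, sigma = 0.5),
                 list(type = "lognormal", mu = -3, sigma = 0.5),
                 list(type = "lognormal", mu = 0, sigma = 0.5),
                 list(type = "lognormal", mu = -3, sigma = 0.5))
    X <- lhs_design(N, marg)
    Y <- log(dynemu:::lv_ensemble(X, 30, 4, 0:Tn))
    fit <- emulator_fit(Y, X, ar_order = 1, structure = "mniw", L = L)
    val <- list(X = X, Y = Y, fit = fit, marg = marg, y0 = log(c(30, 4)))
    cache <<- list(key = key, val = val)
    val
  }
})
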