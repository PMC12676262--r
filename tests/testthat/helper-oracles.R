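# Independent oracles.
#
# dlm_joint_oracle builds the full joint Gaussian over the stacked state and
# observation rows of a matrix-variate DLM conditional on the column
# covariance (which factors out of all first/second row moments), and
# conditions it by brute force. It shares no code with the filter/smoother.

dlm_joint_oracle <- function(inst) {
  spec <- inst$spec
  Tn <- spec$n_time
  p <- spec$p; S <- spec$S
  N <- vapply(inst$Y, nrow, 1L)
  nb <- (Tn + 1) * p + sum(N)
  Om <- matrix(0, nb, nb)
  Mu <- matrix(0, nb, S)
  bi <- function(t) (t * p + 1):((t + 1) * p)          # Theta_t rows
  y_off <- (Tn + 1) * p + c(0, cumsum(N))
  yi <- function(t) (y_off[t] + 1):(y_off[t + 1])      # Y_t rows
  Om[bi(0), bi(0)] <- inst$M0
  Mu[bi(0), ] <- inst$m0
  for (t in seq_len(Tn)) {
    G <- inst$G[[t]]
    Mu[bi(t), ] <- G %*% Mu[bi(t - 1), ]
    for (s in 0:(t - 1)) {
      Om[bi(t), bi(s)] <- G %*% Om[bi(t - 1), bi(s)]
      Om[bi(s), bi(t)] <- t(Om[bi(t), bi(s)])
    }
    Om[bi(t), bi(t)] <- G %*% Om[bi(t - 1), bi(t - 1)] %*% t(G) +
      inst$W[[t]]
  }
  for (t in seq_len(Tn)) {
    FF <- inst$FF[[t]]
    Mu[yi(t), ] <- FF %*% Mu[bi(t), ]
    for (s in 0:Tn) {
      Om[yi(t), bi(s)] <- FF %*% Om[bi(t), bi(s)]
      Om[bi(s), yi(t)] <- t(Om[yi(t), bi(s)])
    }
  }
  for (t in seq_len(Tn)) for (s in seq_len(Tn)) {
    Om[yi(t), yi(s)] <- inst$FF[[t]] %*% Om[bi(t), bi(s)] %*%
      t(inst$FF[[s]]) + if (t == s) inst$V[[t]] else 0
  }
  Yst <- do.call(rbind, inst$Y)
  yall <- unlist(lapply(seq_len(Tn), yi))
  cond <- function(rows, obs_rows) {
    Oab <- Om[rows, obs_rows, drop = FALSE]
    K <- Oab %*% solve(Om[obs_rows, obs_rows, drop = FALSE])
    list(mean = Mu[rows, , drop = FALSE] +
           K %*% (Yst[match(obs_rows, yall), , drop = FALSE] -
                    Mu[obs_rows, , drop = FALSE]),
         cov = Om[rows, rows, drop = FALSE] - K %*% t(Oab))
  }
  resid <- Yst - Mu[yall, , drop = FALSE]
  D_T <- crossprod(resid, solve(Om[yall, yall], resid))
  list(bi = bi, yi = yi, yall = yall, cond = cond, D_increment = D_T,
       Tn = Tn)
}

# filtered oracle moments of Theta_t given Y_{1:t}
oracle_filtered <- function(orc, t) {
  obs <- unlist(lapply(seq_len(t), orc$yi))
  orc$cond(orc$bi(t), obs)
}

# smoothed oracle moments of Theta_t given Y_{1:T}
oracle_smoothed <- function(orc, t) orc$cond(orc$bi(t), orc$yall)
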