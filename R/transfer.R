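# Season/episode Bayesian transfer learning: tile each season's N x S output
# matrix into K = k1 * k2 sub-blocks ("episodes") of size r x c and stream
# them through the same FFBS machinery as K*T pseudo-times. The shared column
# covariance is then c x c, reducing the cubic cost from S^3 to K * c^3.

#' Episode partition of a season
#'
#' @param N,S full row (input) and column (location) dimensions.
#' @param r,c rows and columns per episode; must divide `N` and `S`.
#' @return object of class `partition_spec` with `k1 = N/r`, `k2 = S/c` and
#'   `K = k1 * k2`.
#' @export
partition_spec <- function(N, S, r, c) {
  if (N %% r != 0 || S %% c != 0)
    stop("r must divide N and c must divide S", call. = FALSE)
  structure(list(N = N, S = S, r = r, c = c,
                 k1 = N / r, k2 = S / c, K = (N / r) * (S / c)),
            class = "partition_spec")
}

#' Parent index of an episode
#'
#' The stream orders episodes `k = 1, ..., K` within season `t`; the parent
#' (immediately preceding index) is `(k - 1, t)` for `k >= 2`, `(K, t - 1)`
#' for `k = 1, t >= 2`, and `(0, 0)` for the first episode of the stream.
#'
#' @param k episode index in `1..K`.
#' @param t season index in `1..T`.
#' @param K episodes per season.
#' @param n_time number of seasons (used only for range checking).
#' @return integer vector `c(k', t')`.
#' @export
parent_index <- function(k, t, K, n_time = Inf) {
  if (k < 1 || k > K || t < 1 || t > n_time)
    stop("episode index out of range", call. = FALSE)
  if (k >= 2) c(k - 1, t)
  else if (t >= 2) c(K, t - 1)
  else c(0, 0)
}

#' Partition per-season data into an episode stream
#'
#' Tiles each `Y_t` into `K` blocks of size `r x c`. Within a season,
#' column-blocks vary fastest, then row-blocks (episode `k` maps to row-block
#' `(k - 1) %/% k2 + 1` and column-block `(k - 1) %% k2 + 1`), so a column
#' partition walks the grid columns in order. `V_{k,t}` is the corresponding
#' diagonal `r x r` block of `V_t`; `F_{k,t}` takes the episode's rows of
#' `F_t`. The season transition `G_t` (and innovation `W_t`) is applied at
#' the first episode of each season; within a season the state is carried
#' with `G = I` and, by default, no innovation (`within_season_w = "zero"`).
#'
#' @param Y,FF,G,V,W per-season data/model matrices: single matrices or lists
#'   of length `n_time` (`Y_t` is `N x S`, `F_t` is `N x p`).
#' @param n_time number of seasons.
#' @param part a [partition_spec()]. The shared column covariance of the
#'   stream is `c x c`, so the mniw prior scale must be `c x c`.
#' @param within_season_w `"zero"` (default) or `"full"`: innovation
#'   covariance used by episodes `k >= 2` of a season.
#' @return object of class `episode_stream`: ordered lists `Y, FF, G, V, W`
#'   of length `K * n_time`, the index table `index` (episode, season,
#'   row-block, col-block, parent), and the partition.
#' @export
partition_stream <- function(Y, FF, G, V, W, n_time, part,
                             within_season_w = c("zero", "full")) {
  stopifnot(inherits(part, "partition_spec"))
  within_season_w <- match.arg(within_season_w)
  Y <- as_Y_list(Y, n_time)
  FFl <- as_Y_list(FF, n_time); Gl <- as_Y_list(G, n_time)
  Vl <- as_Y_list(V, n_time); Wl <- as_Y_list(W, n_time)
  K <- part$K; r <- part$r; c <- part$c; k2 <- part$k2
  p <- ncol(FFl[[1]])
  sY <- vector("list", K * n_time); sF <- sY; sG <- sY; sV <- sY; sW <- sY
  idx <- NULL
  pos <- 0
  for (t in seq_len(n_time)) {
    if (nrow(Y[[t]]) != part$N || ncol(Y[[t]]) != part$S)
      stop(sprintf("Y[[%d]] is not %d x %d", t, part$N, part$S),
           call. = FALSE)
    for (k in seq_len(K)) {
      i_blk <- (k - 1) %/% k2 + 1
      j_blk <- (k - 1) %% k2 + 1
      rows <- ((i_blk - 1) * r + 1):(i_blk * r)
      cols <- ((j_blk - 1) * c + 1):(j_blk * c)
      pos <- pos + 1
      sY[[pos]] <- Y[[t]][rows, cols, drop = FALSE]
      sF[[pos]] <- FFl[[t]][rows, , drop = FALSE]
      sV[[pos]] <- Vl[[t]][rows, rows, drop = FALSE]
      if (k == 1) {
        sG[[pos]] <- Gl[[t]]
        sW[[pos]] <- Wl[[t]]
      } else {
        sG[[pos]] <- diag(p)
        sW[[pos]] <- if (within_season_w == "zero") matrix(0, p, p)
                     else Wl[[t]]
      }
      pa <- parent_index(k, t, K, n_time)
      idx <- rbind(idx, c(k, t, i_blk, j_blk, pa))
    }
  }
  colnames(idx) <- c("episode", "season", "row_block", "col_block",
                     "parent_episode", "parent_season")
  structure(list(Y = sY, FF = sF, G = sG, V = sV, W = sW,
                 index = as.data.frame(idx), part = part,
                 n_time = n_time), class = "episode_stream")
}

#' FFBS over an episode stream
#'
#' Treats the `K * T` episodes as sequential pseudo-times of a single
#' matrix-variate DLM with shared `c x c` column covariance and runs the
#' plain [ffbs()]. With `K = 1` this is bit-identical to [ffbs()] on the
#' original sequence at matched seeds. After the full stream
#' `n_final = n0 + K * T * r` under the mniw structure.
#'
#' @param stream an [partition_stream()] result.
#' @param m0,M0 prior mean/row covariance for the state (`p x c`, `p x p`).
#' @param structure,n0,D0,d0,R column-covariance structure and prior, as in
#'   [dlm_spec()]; scales are `c x c`.
#' @param L number of joint posterior draws.
#' @return a `dlm_draws` object over the `K * T` pseudo-times, with the
#'   stream attached as attribute `stream`.
#' @export
streaming_ffbs <- function(stream, m0, M0,
                           structure = c("mniw", "mnig", "identity"),
                           n0 = NULL, D0 = NULL, d0 = NULL, R = NULL, L = 1) {
  stopifnot(inherits(stream, "episode_stream"))
  structure <- match.arg(structure)
  spec <- dlm_spec(FF = stream$FF, G = stream$G, V = stream$V, W = stream$W,
                   n_time = length(stream$Y), structure = structure,
                   m0 = m0, M0 = M0, n0 = n0, D0 = D0, d0 = d0, R = R)
  out <- ffbs(stream$Y, spec, L)
  attr(out, "stream") <- stream
  out
}

#' Reassemble per-episode one-step forecasts into season matrices
#'
#' Concatenates the episode-level forecast means `q_{k,t}` back into an
#' `N x S` matrix per season (the tiling inverse of [partition_stream()]).
#'
#' @param filt the `filter` component of a [streaming_ffbs()] result.
#' @param stream the matching `episode_stream`.
#' @return list of `n_time` reassembled `N x S` forecast matrices.
#' @export
reassemble_forecasts <- function(filt, stream) {
  part <- stream$part
  K <- part$K; r <- part$r; c <- part$c; k2 <- part$k2
  lapply(seq_len(stream$n_time), function(t) {
    out <- matrix(NA_real_, part$N, part$S)
    for (k in seq_len(K)) {
      i_blk <- (k - 1) %/% k2 + 1
      j_blk <- (k - 1) %% k2 + 1
      rows <- ((i_blk - 1) * r + 1):(i_blk * r)
      cols <- ((j_blk - 1) * c + 1):(j_blk * c)
      out[rows, cols] <- filt$q[[(t - 1) * K + k]]
    }
    out
  })
}

#' Episode stream with per-episode autoregressive designs
#'
#' Builds the column-episode stream used for large-field emulation with
#' autoregressive observation matrices: season `t` is split into `k2 = S/c`
#' column blocks, and each episode regresses its own block on the same
#' block of the previous season(s), `F_{k,t} = [Y_{k,t-1}, Y_{k,t-2}]`
#' (lags padded with the block of `Y_0`). Row correlation `V` is shared by
#' all episodes (the full kernel over the inputs); `G = I` and the season
#' innovation `W = I` is applied at the first episode of each season.
#'
#' @param Y_hist list of `T + 1` output matrices (`[[1]]` is `Y_0`).
#' @param V `N x N` input correlation matrix.
#' @param c columns per episode; must divide `S`.
#' @param ar_order 1 or 2.
#' @return an `episode_stream` over `k2 * T` episodes with `p = ar_order*c`.
#' @export
ar_episode_stream <- function(Y_hist, V, c, ar_order = 1) {
  Tn <- length(Y_hist) - 1
  N <- nrow(Y_hist[[1]]); S <- ncol(Y_hist[[1]])
  part <- partition_spec(N, S, N, c)
  k2 <- part$k2
  p <- ar_order * c
  sY <- vector("list", k2 * Tn); sF <- sY; sG <- sY; sV <- sY; sW <- sY
  idx <- NULL
  pos <- 0
  for (t in seq_len(Tn)) {
    for (k in seq_len(k2)) {
      cols <- ((k - 1) * c + 1):(k * c)
      pos <- pos + 1
      sY[[pos]] <- Y_hist[[t + 1]][, cols, drop = FALSE]
      lag1 <- Y_hist[[max(t - 1, 0) + 1]][, cols, drop = FALSE]
      sF[[pos]] <- if (ar_order == 1) lag1 else
        cbind(lag1, Y_hist[[max(t - 2, 0) + 1]][, cols, drop = FALSE])
      sV[[pos]] <- V
      sG[[pos]] <- diag(p)
      sW[[pos]] <- if (k == 1) diag(p) else matrix(0, p, p)
      pa <- parent_index(k, t, k2, Tn)
      idx <- rbind(idx, c(k, t, 1, k, pa))
    }
  }
  colnames(idx) <- c("episode", "season", "row_block", "col_block",
                     "parent_episode", "parent_season")
  structure(list(Y = sY, FF = sF, G = sG, V = sV, W = sW,
                 index = as.data.frame(idx), part = part,
                 n_time = Tn), class = "episode_stream")
}
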