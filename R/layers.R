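# Minimal CNN layer kit: batched tensors are arrays of dim (h, w, C, N).
# Convolutions are im2col + BLAS matrix products; every forward has a
# matching hand-derived backward. Index matrices are cached per geometry so
# the R-level cost is one big matrix multiply per layer per batch.

.idx_cache <- new.env(parent = emptyenv())

# im2col index matrix for one padded sample: rows are output positions
# (row-major over (i, j)), columns are (kernel row, kernel col, channel).
# Entries are linear indices into the padded (hp, wp, C) array.
.conv_index1 <- function(h, w, c_in, k, pad) {
  key <- paste("i1", h, w, c_in, k, pad, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  hp <- h + 2L * pad
  wp <- w + 2L * pad
  pos_i <- rep(seq_len(h), times = w)
  pos_j <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, k * k * c_in)
  q <- 1L
  for (ch in seq_len(c_in)) for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    idx[, q] <- (pos_i + di) + (pos_j + dj - 1L) * hp + (ch - 1L) * hp * wp
    q <- q + 1L
  }
  .idx_cache[[key]] <- idx
  idx
}

# batch im2col indices: per-sample indices offset into the padded batch
.conv_index <- function(h, w, c_in, k, pad, n) {
  key <- paste("ib", h, w, c_in, k, pad, n, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  idx1 <- .conv_index1(h, w, c_in, k, pad)
  hp <- h + 2L * pad
  wp <- w + 2L * pad
  off <- rep((seq_len(n) - 1L) * hp * wp * c_in, each = h * w)
  idx <- idx1[rep(seq_len(h * w), n), , drop = FALSE] + off
  .idx_cache[[key]] <- idx
  idx
}

.pad_batch <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

#' "Same" 2D convolution over a batch
#'
#' @param x `(h, w, C_in, N)` array.
#' @param W `(k*k*C_in) x C_out` kernel matrix (rows ordered kernel-row
#'   fastest, then kernel column, then input channel).
#' @param b length-`C_out` bias.
#' @param k kernel edge; `pad` zero padding (default keeps spatial size).
#' @return list with `out` (`(h, w, C_out, N)`) and the cache needed by
#'   [conv_bwd()].
#' @keywords internal
conv_fwd <- function(x, W, b, k = 3L, pad = (k - 1L) %/% 2L) {
  d <- dim(x)
  idx <- .conv_index(d[1], d[2], d[3], k, pad, d[4])
  xp <- .pad_batch(x, pad)
  xcol <- xp[idx]                       # linear gather, no intermediate copy
  dim(xcol) <- dim(idx)
  outm <- xcol %*% W
  outm <- outm + rep(b, each = nrow(outm))
  c_out <- length(b)
  dim(outm) <- c(d[1], d[2], d[4], c_out)
  out <- aperm(outm, c(1, 2, 4, 3))
  list(out = out, xcol = xcol, dims = d, k = k, pad = pad)
}

#' Backward pass of [conv_fwd()]
#'
#' @param dout gradient of the loss in the output, `(h, w, C_out, N)`.
#' @param cache forward cache; `W` the kernel matrix.
#' @param need_dx skip the (costly) input-gradient scatter for layers that
#'   sit directly on the data.
#' @return list `dx`, `dW`, `db`.
#' @keywords internal
conv_bwd <- function(dout, cache, W, need_dx = TRUE) {
  d <- cache$dims
  doutm <- aperm(dout, c(1, 2, 4, 3))
  dim(doutm) <- c(d[1] * d[2] * d[4], ncol(W))
  dW <- crossprod(cache$xcol, doutm)
  db <- colSums(doutm)
  if (!need_dx) return(list(dx = NULL, dW = dW, db = db))
  dxcol <- tcrossprod(doutm, W)
  idx <- .conv_index(d[1], d[2], d[3], cache$k, cache$pad, d[4])
  hp <- d[1] + 2L * cache$pad
  wp <- d[2] + 2L * cache$pad
  dv <- numeric(hp * wp * d[3] * d[4])
  for (q in seq_len(ncol(idx))) {       # indices within a column are unique
    iq <- idx[, q]
    dv[iq] <- dv[iq] + dxcol[, q]
  }
  dxp <- array(dv, dim = c(hp, wp, d[3], d[4]))
  dx <- if (cache$pad > 0L)
    dxp[cache$pad + seq_len(d[1]), cache$pad + seq_len(d[2]), , , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

#' 2x2 average pooling (stride 2)
#' @keywords internal
pool_fwd <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  (x[i1, j1, , , drop = FALSE] + x[i2, j1, , , drop = FALSE] +
     x[i1, j2, , , drop = FALSE] + x[i2, j2, , , drop = FALSE]) / 4
}

#' Backward pass of [pool_fwd()]
#' @keywords internal
pool_bwd <- function(dout) {
  d <- dim(dout)
  dout[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
       drop = FALSE] / 4
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dout, x) dout * (x > 0)

#' Global average pooling of a feature-map batch
#'
#' Component `c` of each output row is the spatial mean of channel `c`.
#'
#' @param x `(h, w, C, N)` array.
#' @return `N x C` matrix of branch feature vectors.
#' @export
gap <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4])) # ordered (channel, sample)
  t(matrix(m, d[3], d[4]))
}

# spread dV (N x C) back uniformly over the spatial grid
gap_bwd <- function(dV, h, w) {
  n <- nrow(dV); c_ <- ncol(dV)
  array(rep(as.vector(t(dV)), each = h * w) / (h * w), dim = c(h, w, c_, n))
}

fc_fwd <- function(V, W, b) V %*% W + rep(b, each = nrow(V))
fc_bwd <- function(dZ, V, W)
  list(dV = tcrossprod(dZ, W), dW = crossprod(V, dZ), db = colSums(dZ))

# row-wise softmax with the usual max-shift for stability
softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# Glorot-uniform initial weight matrices (linear heads), driven by the
# current RNG
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# He-uniform initialization for kernels feeding ReLU units: preserves
# activation variance through stacked conv/ReLU blocks
he_init <- function(nin, nout) {
  lim <- sqrt(6 / nin)
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}
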