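#' DANet architecture configuration
#'
#' The DANet runs five feature pathways over a decomposed patch: `main`
#' (original image), `down` (nuclei only), `top` (non-nuclei only), and two
#' middle branches obtained by fusing main with each auxiliary branch. Each
#' base branch has its own backbone (no weight sharing); global average
#' pooling turns every branch's feature map into a length-`branch_channels`
#' vector; branch-selection attention pools the vectors; a fully connected
#' layer produces class logits.
#'
#' The shipped backbone `"cnn3"` is a compact three-block CNN — a fixed
#' 2x2 average-pool stem followed by three blocks of conv 3x3 / ReLU /
#' 2x2 average pool with channel widths `C/4, C/2, C` — that trains in
#' seconds on a CPU; any image-to-feature-map backbone with the same
#' contract can be substituted. A full-scale deployment of this
#' architecture would use an Xception-class backbone with
#' `branch_channels = 512` and 320x320 inputs (so the final maps are
#' 10x10x512); the defaults here are the CPU-scale equivalents.
#'
#' @param num_classes number of output classes.
#' @param input_size square input edge in pixels; must be divisible by 16
#'   (the backbone downsamples 16x).
#' @param branch_channels channel width `C` of the branch feature maps and
#'   length `L` of the branch vectors (default 32 for the CPU backbone).
#' @param backbone backbone family; currently `"cnn3"`.
#' @param attention_hidden hidden width of the attention scoring network
#'   (default 128; set to 5 for the minimal one-layer parameterization).
#' @param attention_hidden2 optional second hidden width (default `NULL`,
#'   i.e. a single hidden layer).
#' @param dcca a [dcca_config()] for the projection heads.
#' @return a `danet_config` list.
#' @export
danet_config <- function(num_classes,
                         input_size = 64L,
                         branch_channels = 32L,
                         backbone = "cnn3",
                         attention_hidden = 128L,
                         attention_hidden2 = NULL,
                         dcca = dcca_config(d = 8L)) {
  stopifnot(num_classes >= 2L, input_size %% 16L == 0L, branch_channels >= 4L,
            attention_hidden >= 1L)
  backbone <- match.arg(backbone, "cnn3")
  structure(list(num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 branch_channels = as.integer(branch_channels),
                 backbone = backbone,
                 attention_hidden = as.integer(attention_hidden),
                 attention_hidden2 = if (!is.null(attention_hidden2))
                   as.integer(attention_hidden2),
                 dcca = dcca),
            class = "danet_config")
}

#' Ablation switches for the DANet
#'
#' Mirrors the architecture ablations: dropping the fusion blocks (three
#' branches instead of five), dropping the DCCA penalty, replacing
#' attention pooling by mean / max / concatenation, or restricting to a
#' subset of branches (e.g. `"main"` alone for a single-backbone baseline).
#'
#' @param use_fusion_block keep the two fused middle branches?
#' @param use_dcca apply the DCCA penalty during training?
#' @param pooling `"attention"`, `"mean"`, `"max"` or `"concat"`.
#' @param active_branches subset of `c("top", "mid1", "main", "mid2",
#'   "down")`; must contain `"main"`.
#' @return an `ablation_spec` list.
#' @export
ablation_spec <- function(use_fusion_block = TRUE,
                          use_dcca = TRUE,
                          pooling = c("attention", "mean", "max", "concat"),
                          active_branches = c("top", "mid1", "main", "mid2", "down")) {
  pooling <- match.arg(pooling)
  active_branches <- match.arg(active_branches, several.ok = TRUE)
  if (!"main" %in% active_branches)
    stop("the main branch must stay active", call. = FALSE)
  structure(list(use_fusion_block = use_fusion_block,
                 use_dcca = use_dcca,
                 pooling = pooling,
                 active_branches = active_branches),
            class = "ablation_spec")
}

# canonical branch ordering used everywhere
.branch_order <- c("top", "mid1", "main", "mid2", "down")

# branches actually present under an ablation
.active_branches <- function(ablation) {
  act <- ablation$active_branches
  base <- intersect(c("top", "main", "down"), act)
  mids <- character(0)
  if (ablation$use_fusion_block) {
    if (all(c("main", "top") %in% base) && "mid1" %in% act) mids <- c(mids, "mid1")
    if (all(c("main", "down") %in% base) && "mid2" %in% act) mids <- c(mids, "mid2")
  }
  intersect(.branch_order, c(base, mids))
}

#' Build a DANet model with freshly initialized parameters
#'
#' Parameter initialization draws from the current RNG stream (He uniform
#' for convolution kernels feeding ReLU units, Glorot uniform for linear
#' heads, zeros for biases), so a `set.seed()` before the call makes the
#' model reproducible. All parameters are created in a fixed
#' order regardless of which loss terms are later enabled, so two models
#' built from the same seed are parameter-identical even if one never uses
#' its DCCA heads.
#'
#' @param config a [danet_config()].
#' @param ablation an [ablation_spec()].
#' @return a `danet_model` list with elements `params` (flat named list of
#'   arrays), `config`, `ablation`.
#' @export
danet_model <- function(config, ablation = ablation_spec()) {
  stopifnot(inherits(config, "danet_config"))
  C <- config$branch_channels
  c1 <- max(4L, C %/% 4L); c2 <- max(8L, C %/% 2L)
  L <- C
  p <- list()
  base <- intersect(c("top", "main", "down"), .active_branches(ablation))
  for (br in c("top", "main", "down")) {
    if (!br %in% base) next
    p[[paste0("bb_", br, "_c1_W")]] <- he_init(9L * 3L, c1)
    p[[paste0("bb_", br, "_c1_b")]] <- numeric(c1)
    p[[paste0("bb_", br, "_c2_W")]] <- he_init(9L * c1, c2)
    p[[paste0("bb_", br, "_c2_b")]] <- numeric(c2)
    p[[paste0("bb_", br, "_c3_W")]] <- he_init(9L * c2, C)
    p[[paste0("bb_", br, "_c3_b")]] <- numeric(C)
  }
  branches <- .active_branches(ablation)
  for (mid in intersect(c("mid1", "mid2"), branches)) {
    p[[paste0("fu_", mid, "_p_W")]] <- he_init(2L * C, C)      # 1x1 conv
    p[[paste0("fu_", mid, "_p_b")]] <- numeric(C)
    p[[paste0("fu_", mid, "_q_W")]] <- he_init(9L * C, C)      # 3x3 conv
    p[[paste0("fu_", mid, "_q_b")]] <- numeric(C)
  }
  if (ablation$pooling == "attention") {
    h1 <- config$attention_hidden
    p$att_Q <- glorot(L, h1)                                  # stored L x h1
    if (!is.null(config$attention_hidden2)) {
      h2 <- config$attention_hidden2
      p$att_W2 <- glorot(h1, h2)
      p$att_w <- stats::runif(h2, -sqrt(3 / h2), sqrt(3 / h2))
    } else {
      p$att_w <- stats::runif(h1, -sqrt(3 / h1), sqrt(3 / h1))
    }
  }
  zdim <- if (ablation$pooling == "concat") L * length(branches) else L
  p$cls_W <- glorot(zdim, config$num_classes)
  p$cls_b <- numeric(config$num_classes)
  for (br in intersect(c("main", "down", "top"), base)) {
    p[[paste0("dcca_", br, "_W")]] <- glorot(L, config$dcca$d)
    p[[paste0("dcca_", br, "_b")]] <- numeric(config$dcca$d)
  }
  structure(list(params = p, config = config, ablation = ablation),
            class = "danet_model")
}

#' Number of trainable parameters of a model
#'
#' @param model a `danet_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, integer(1)))

#' Percentage parameter reduction of one model versus a reference
#'
#' `100 * (reference - model) / reference`; e.g. a 95 M-parameter
#' triple-backbone DANet against VGG16's 139 M parameters gives 31.65,
#' which rounds to a 32 percent reduction.
#'
#' @param n_model,n_reference parameter counts.
#' @return percentage reduction (positive when the model is smaller).
#' @export
parameter_reduction_pct <- function(n_model, n_reference)
  100 * (n_reference - n_model) / n_reference

# ---- backbone ---------------------------------------------------------

.backbone_fwd <- function(p, prefix, x) {
  x <- pool_fwd(x)                      # fixed 2x2 average-pool stem
  cv1 <- conv_fwd(x, p[[paste0(prefix, "_c1_W")]], p[[paste0(prefix, "_c1_b")]])
  a1 <- relu_fwd(cv1$out); p1 <- pool_fwd(a1)
  cv2 <- conv_fwd(p1, p[[paste0(prefix, "_c2_W")]], p[[paste0(prefix, "_c2_b")]])
  a2 <- relu_fwd(cv2$out); p2 <- pool_fwd(a2)
  cv3 <- conv_fwd(p2, p[[paste0(prefix, "_c3_W")]], p[[paste0(prefix, "_c3_b")]])
  a3 <- relu_fwd(cv3$out); p3 <- pool_fwd(a3)
  list(out = p3, cv1 = cv1, cv2 = cv2, cv3 = cv3)
}

.backbone_bwd <- function(dout, cache, p, prefix, grads) {
  d3 <- relu_bwd(pool_bwd(dout), cache$cv3$out)
  b3 <- conv_bwd(d3, cache$cv3, p[[paste0(prefix, "_c3_W")]])
  d2 <- relu_bwd(pool_bwd(b3$dx), cache$cv2$out)
  b2 <- conv_bwd(d2, cache$cv2, p[[paste0(prefix, "_c2_W")]])
  d1 <- relu_bwd(pool_bwd(b2$dx), cache$cv1$out)
  # the first convolution sits on the (stem-pooled) image, so its input
  # gradient is never consumed
  b1 <- conv_bwd(d1, cache$cv1, p[[paste0(prefix, "_c1_W")]], need_dx = FALSE)
  grads[[paste0(prefix, "_c3_W")]] <- b3$dW
  grads[[paste0(prefix, "_c3_b")]] <- b3$db
  grads[[paste0(prefix, "_c2_W")]] <- b2$dW
  grads[[paste0(prefix, "_c2_b")]] <- b2$db
  grads[[paste0(prefix, "_c1_W")]] <- b1$dW
  grads[[paste0(prefix, "_c1_b")]] <- b1$db
  grads
}

#' Extract branch feature maps with a model's backbone
#'
#' Runs one branch backbone over a batch of images and returns the final
#' feature maps (spatial size `input_size / 16`, `branch_channels`
#' channels). Branch backbones share no weights.
#'
#' @param model a `danet_model`.
#' @param x `(h, w, 3, N)` image batch at the configured input size.
#' @param branch `"main"`, `"down"` or `"top"`.
#' @return `(h/16, w/16, C, N)` feature-map array.
#' @export
extract_branch_features <- function(model, x, branch = "main") {
  stopifnot(branch %in% c("top", "main", "down"))
  d <- dim(x)
  if (d[1] != model$config$input_size || d[2] != model$config$input_size)
    stop("input must be ", model$config$input_size, "x",
         model$config$input_size, call. = FALSE)
  .backbone_fwd(model$params, paste0("bb_", branch), x)$out
}

# ---- fusion block -----------------------------------------------------

.fusion_fwd <- function(xm, xa, Wp, bp, Wq, bq, activation = TRUE) {
  d <- dim(xm)
  C <- d[3]
  xcat <- array(0, dim = c(d[1], d[2], 2L * C, d[4]))
  xcat[, , seq_len(C), ] <- xm
  xcat[, , C + seq_len(C), ] <- xa
  cvp <- conv_fwd(xcat, Wp, bp, k = 1L, pad = 0L)
  ap <- if (activation) relu_fwd(cvp$out) else cvp$out
  cvq <- conv_fwd(ap, Wq, bq, k = 3L, pad = 1L)
  aq <- if (activation) relu_fwd(cvq$out) else cvq$out
  list(out = aq, cvp = cvp, cvq = cvq, activation = activation, C = C)
}

.fusion_bwd <- function(dout, cache, Wp, Wq) {
  dq <- if (cache$activation) relu_bwd(dout, cache$cvq$out) else dout
  bq <- conv_bwd(dq, cache$cvq, Wq)
  dp <- if (cache$activation) relu_bwd(bq$dx, cache$cvp$out) else bq$dx
  bp <- conv_bwd(dp, cache$cvp, Wp)
  C <- cache$C
  list(dxm = bp$dx[, , seq_len(C), , drop = FALSE],
       dxa = bp$dx[, , C + seq_len(C), , drop = FALSE],
       dWp = bp$dW, dbp = bp$db, dWq = bq$dW, dbq = bq$db)
}

#' Branch fusion block
#'
#' Concatenates a main-branch and an auxiliary-branch feature map along
#' channels (main first), fuses channels with a 1x1 convolution back to `C`
#' channels, then re-learns spatial features with a padded 3x3 convolution;
#' spatial dimensions are preserved. ReLU follows each convolution unless
#' `activation = FALSE` (useful for verifying the convolution arithmetic
#' in isolation).
#'
#' @param x_main,x_aux `(h, w, C, N)` feature maps of equal shape.
#' @param params list with `p_W` (`2C x C` 1x1 kernels), `p_b`, `q_W`
#'   (`9C x C` 3x3 kernels), `q_b`.
#' @param activation apply ReLU after each convolution?
#' @return `(h, w, C, N)` fused feature map.
#' @export
fusion_block <- function(x_main, x_aux, params, activation = TRUE) {
  if (!identical(dim(x_main), dim(x_aux)))
    stop("fusion inputs must have identical shapes", call. = FALSE)
  .fusion_fwd(x_main, x_aux, params$p_W, params$p_b, params$q_W, params$q_b,
              activation = activation)$out
}

# ---- branch selection attention ---------------------------------------

#' Initialize branch-selection attention parameters
#'
#' @param L branch vector length.
#' @param hidden hidden width of the scoring network (128 by default).
#' @param hidden2 optional second hidden width (`NULL` for one layer).
#' @return list with `Q` (`L x hidden`), optional `W2`, and `w`.
#' @export
attention_params <- function(L, hidden = 128L, hidden2 = NULL) {
  out <- list(Q = glorot(L, hidden))
  if (!is.null(hidden2)) {
    out$W2 <- glorot(hidden, hidden2)
    out$w <- stats::runif(hidden2, -sqrt(3 / hidden2), sqrt(3 / hidden2))
  } else {
    out$w <- stats::runif(hidden, -sqrt(3 / hidden), sqrt(3 / hidden))
  }
  out
}

.attention_fwd <- function(V, Q, w, W2 = NULL) {
  K <- length(V)
  n <- nrow(V[[1]])
  scores <- matrix(0, n, K)
  T1 <- vector("list", K); T2 <- if (!is.null(W2)) vector("list", K)
  for (k in seq_len(K)) {
    T1[[k]] <- tanh(V[[k]] %*% Q)                 # N x h1
    if (is.null(W2)) {
      scores[, k] <- T1[[k]] %*% w
    } else {
      T2[[k]] <- tanh(T1[[k]] %*% W2)             # N x h2
      scores[, k] <- T2[[k]] %*% w
    }
  }
  a <- softmax_rows(scores)
  z <- matrix(0, n, ncol(V[[1]]))
  for (k in seq_len(K)) z <- z + a[, k] * V[[k]]
  list(z = z, a = a, scores = scores, T1 = T1, T2 = T2)
}

# backward through attention pooling: returns dV list plus parameter grads
.attention_bwd <- function(dz, cache, V, Q, w, W2 = NULL) {
  K <- length(V)
  a <- cache$a
  dV <- vector("list", K)
  da <- matrix(0, nrow(a), K)
  for (k in seq_len(K)) {
    dV[[k]] <- a[, k] * dz
    da[, k] <- rowSums(dz * V[[k]])
  }
  ds <- a * (da - rowSums(da * a))                # softmax Jacobian rows
  dQ <- matrix(0, nrow(Q), ncol(Q))
  dw <- numeric(length(w))
  dW2 <- if (!is.null(W2)) matrix(0, nrow(W2), ncol(W2))
  for (k in seq_len(K)) {
    if (is.null(W2)) {
      dT1 <- outer(ds[, k], w)
      dw <- dw + colSums(ds[, k] * cache$T1[[k]])
    } else {
      dT2 <- outer(ds[, k], w)
      dw <- dw + colSums(ds[, k] * cache$T2[[k]])
      dU2 <- dT2 * (1 - cache$T2[[k]]^2)
      dW2 <- dW2 + crossprod(cache$T1[[k]], dU2)
      dT1 <- tcrossprod(dU2, W2)
    }
    dU1 <- dT1 * (1 - cache$T1[[k]]^2)
    dQ <- dQ + crossprod(V[[k]], dU1)
    dV[[k]] <- dV[[k]] + tcrossprod(dU1, Q)
  }
  list(dV = dV, dQ = dQ, dw = dw, dW2 = dW2)
}

#' Branch-selection attention pooling
#'
#' Scores each branch vector with a small shared network
#' (`score = w' tanh(Q' V)`, optionally with a second tanh layer), softmaxes
#' the scores across branches, and returns the attention-weighted sum. The
#' weights are strictly positive, sum to one, and are equivariant under
#' branch permutation; the pooled vector lies componentwise in the convex
#' hull of the branch vectors.
#'
#' @param branches list of branch feature vectors (each a length-`L` vector
#'   or an `N x L` matrix; all the same shape).
#' @param params an [attention_params()] list.
#' @return list with `z` (pooled vector/matrix) and `a` (attention weights,
#'   `N x K`, columns named after the branches if the input list is named).
#' @export
branch_selection_attention <- function(branches, params) {
  single <- !is.matrix(branches[[1]])
  V <- lapply(branches, function(v) if (is.matrix(v)) v else matrix(v, 1L))
  L <- ncol(V[[1]])
  if (!all(vapply(V, ncol, integer(1)) == L))
    stop("branch vectors must share one length", call. = FALSE)
  if (nrow(params$Q) != L)
    stop("attention parameters expect length-", nrow(params$Q),
         " vectors, got ", L, call. = FALSE)
  fw <- .attention_fwd(V, params$Q, params$w, params$W2)
  a <- fw$a
  colnames(a) <- names(branches)
  if (single) list(z = drop(fw$z), a = drop(a)) else list(z = fw$z, a = a)
}

# ---- full forward / backward ------------------------------------------

#' DANet forward pass
#'
#' Runs the base-branch backbones, fusion blocks, global average pooling,
#' branch pooling (attention or an ablation head) and the classifier over a
#' batch of decomposed triplets; in training mode also computes the DCCA
#' projection matrices and keeps the caches the backward pass needs.
#'
#' @param model a `danet_model`.
#' @param batch list with arrays `main`, `down`, `top` of shape
#'   `(h, w, 3, N)`, e.g. from [as_branch_batch()]; branches the ablation
#'   does not use may be omitted.
#' @param train keep caches and compute DCCA projections?
#' @return list with `logits` (`N x num_classes`), `probs`, `attention`
#'   (`N x K` weights, or `NULL` for non-attention pooling), `V` (list of
#'   branch vectors), `H` (DCCA projections, train mode with DCCA heads),
#'   and `cache` (train mode).
#' @export
danet_forward <- function(model, batch, train = FALSE) {
  p <- model$params
  abl <- model$ablation
  branches <- .active_branches(abl)
  base <- intersect(c("top", "main", "down"), branches)

  bb <- list(); X <- list()
  for (br in base) {
    if (is.null(batch[[br]]))
      stop("batch is missing the ", br, " branch images", call. = FALSE)
    bb[[br]] <- .backbone_fwd(p, paste0("bb_", br), batch[[br]])
    X[[br]] <- bb[[br]]$out
  }
  fu <- list()
  if ("mid1" %in% branches) {
    fu$mid1 <- .fusion_fwd(X$main, X$top, p$fu_mid1_p_W, p$fu_mid1_p_b,
                           p$fu_mid1_q_W, p$fu_mid1_q_b)
    X$mid1 <- fu$mid1$out
  }
  if ("mid2" %in% branches) {
    fu$mid2 <- .fusion_fwd(X$main, X$down, p$fu_mid2_p_W, p$fu_mid2_p_b,
                           p$fu_mid2_q_W, p$fu_mid2_q_b)
    X$mid2 <- fu$mid2$out
  }
  V <- lapply(X[branches], gap)

  att <- NULL; attention <- NULL
  z <- switch(abl$pooling,
    attention = {
      att <- .attention_fwd(V, p$att_Q, p$att_w, p$att_W2)
      attention <- att$a
      colnames(attention) <- branches
      att$z
    },
    mean = Reduce(`+`, V) / length(V),
    max = {
      zm <- V[[1]]
      for (k in seq_along(V)[-1]) zm <- pmax(zm, V[[k]])
      zm
    },
    concat = do.call(cbind, V)
  )
  logits <- fc_fwd(z, p$cls_W, p$cls_b)
  probs <- softmax_rows(logits)

  H <- NULL
  if (train && !is.null(p$dcca_main_W)) {
    H <- list()
    for (br in intersect(c("main", "down", "top"), base))
      H[[br]] <- fc_fwd(V[[br]], p[[paste0("dcca_", br, "_W")]],
                        p[[paste0("dcca_", br, "_b")]])
  }
  out <- list(logits = logits, probs = probs, attention = attention,
              V = V, H = H)
  if (train)
    out$cache <- list(bb = bb, fu = fu, X = X, att = att, z = z,
                      branches = branches, base = base)
  out
}

# full backward pass; returns flat gradient list matching model$params and
# the loss components. `lambda1`, `lambda2` weight CE and DCCA.
.danet_backward <- function(model, fwd, onehot, lambda1, lambda2) {
  p <- model$params
  abl <- model$ablation
  cache <- fwd$cache
  branches <- cache$branches
  n <- nrow(fwd$logits)
  K <- length(branches)
  L <- model$config$branch_channels

  grads <- list()
  eps <- 1e-12
  ce <- -mean(rowSums(onehot * log(pmax(fwd$probs, eps))))

  dlogits <- lambda1 * (fwd$probs - onehot) / n
  bcls <- fc_bwd(dlogits, cache$z, p$cls_W)
  grads$cls_W <- bcls$dW
  grads$cls_b <- bcls$db
  dz <- bcls$dV

  dV <- switch(abl$pooling,
    attention = {
      ba <- .attention_bwd(dz, cache$att, fwd$V, p$att_Q, p$att_w, p$att_W2)
      grads$att_Q <- ba$dQ
      grads$att_w <- ba$dw
      if (!is.null(ba$dW2)) grads$att_W2 <- ba$dW2
      stats::setNames(ba$dV, branches)
    },
    mean = stats::setNames(rep(list(dz / K), K), branches),
    max = {
      zm <- fwd$V[[1]]
      for (k in seq_along(fwd$V)[-1]) zm <- pmax(zm, fwd$V[[k]])
      lapply(stats::setNames(fwd$V, branches), function(v) dz * (v == zm))
    },
    concat = {
      out <- list()
      for (k in seq_len(K)) out[[branches[k]]] <- dz[, (k - 1L) * L + seq_len(L), drop = FALSE]
      out
    }
  )

  dcca_value <- 0
  use_dcca <- abl$use_dcca && lambda2 > 0 && !is.null(fwd$H) &&
    !is.null(fwd$H$main) && (!is.null(fwd$H$down) || !is.null(fwd$H$top))
  if (use_dcca) {
    cfg <- model$config$dcca
    dH <- list(main = 0)
    if (!is.null(fwd$H$down)) {
      g <- dcca_correlation_grad(fwd$H$main, fwd$H$down, cfg)
      dcca_value <- dcca_value - g$value
      dH$main <- dH$main - lambda2 * g$dH1
      dH$down <- -lambda2 * g$dH2
    }
    if (!is.null(fwd$H$top)) {
      g <- dcca_correlation_grad(fwd$H$main, fwd$H$top, cfg)
      dcca_value <- dcca_value - g$value
      dH$main <- dH$main - lambda2 * g$dH1
      dH$top <- -lambda2 * g$dH2
    }
    for (br in names(dH)) {
      bh <- fc_bwd(dH[[br]], fwd$V[[br]], p[[paste0("dcca_", br, "_W")]])
      grads[[paste0("dcca_", br, "_W")]] <- bh$dW
      grads[[paste0("dcca_", br, "_b")]] <- bh$db
      dV[[br]] <- dV[[br]] + bh$dV
    }
  }

  # branch vectors -> feature maps
  hmap <- dim(cache$X$main)[1]; wmap <- dim(cache$X$main)[2]
  dX <- lapply(dV, gap_bwd, h = hmap, w = wmap)

  # fusion blocks feed gradients back into their parent branches
  if ("mid1" %in% branches) {
    bf <- .fusion_bwd(dX$mid1, cache$fu$mid1, p$fu_mid1_p_W, p$fu_mid1_q_W)
    grads$fu_mid1_p_W <- bf$dWp; grads$fu_mid1_p_b <- bf$dbp
    grads$fu_mid1_q_W <- bf$dWq; grads$fu_mid1_q_b <- bf$dbq
    dX$main <- dX$main + bf$dxm
    dX$top <- dX$top + bf$dxa
  }
  if ("mid2" %in% branches) {
    bf <- .fusion_bwd(dX$mid2, cache$fu$mid2, p$fu_mid2_p_W, p$fu_mid2_q_W)
    grads$fu_mid2_p_W <- bf$dWp; grads$fu_mid2_p_b <- bf$dbp
    grads$fu_mid2_q_W <- bf$dWq; grads$fu_mid2_q_b <- bf$dbq
    dX$main <- dX$main + bf$dxm
    dX$down <- dX$down + bf$dxa
  }

  for (br in cache$base)
    grads <- .backbone_bwd(dX[[br]], cache$bb[[br]], p, paste0("bb_", br), grads)

  list(grads = grads, ce = ce, dcca = dcca_value,
       total = lambda1 * ce + lambda2 * dcca_value)
}

#' Assemble decomposed triplets into branch batch arrays
#'
#' Normalizes 8-bit images to the unit interval, centres them at zero
#' (`x/255 - 0.5`, so the strong stain-colour DC component does not
#' dominate the first convolution), and stacks the three decomposed views
#' into the `(h, w, 3, N)` arrays [danet_forward()] expects.
#'
#' @param triplets list of `decomposed_triplet` objects (or of samples with
#'   `image`/`mask` fields, which are decomposed on the fly).
#' @return list of arrays `main`, `down`, `top`.
#' @export
as_branch_batch <- function(triplets) {
  if (!is.null(triplets$main)) triplets <- list(triplets)
  triplets <- lapply(triplets, function(t) {
    if (inherits(t, "decomposed_triplet")) t
    else decompose_image(t$image, t$mask)
  })
  d <- dim(triplets[[1]]$main)
  n <- length(triplets)
  scale <- if (max(triplets[[1]]$main) > 1) 255 else 1
  out <- list()
  for (br in c("main", "down", "top")) {
    a <- array(0, dim = c(d[1], d[2], 3L, n))
    for (i in seq_len(n)) a[, , , i] <- triplets[[i]][[br]] / scale - 0.5
    out[[br]] <- a
  }
  out
}

#' Predict class probabilities and labels for samples
#'
#' @param model a trained `danet_model`.
#' @param samples list of samples (`image`, `mask`) or decomposed triplets.
#' @param batch_size samples per forward pass.
#' @return list with `probs` (`N x num_classes`) and `labels` (1-based).
#' @export
predict_danet <- function(model, samples, batch_size = 32L) {
  n <- length(samples)
  probs <- matrix(0, n, model$config$num_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fwd <- danet_forward(model, as_branch_batch(samples[i:j]))
    probs[i:j, ] <- fwd$probs
    i <- j + 1L
  }
  list(probs = probs, labels = max.col(probs, ties.method = "first"))
}
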