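#' Training hyperparameters
#'
#' Defaults follow the published training recipe: equal loss weights
#' `lambda1 = lambda2 = 0.5` on the cross-entropy and DCCA terms, Adam with
#' `beta1 = 0.9` and learning rate 0.001, and an 80/20 train-and-validate /
#' test split. Epoch count and batch size are not part of the recipe and
#' default to CPU-friendly values.
#'
#' @param lambda1,lambda2 weights of the cross-entropy and DCCA losses.
#' @param lr Adam learning rate.
#' @param beta1 Adam first-moment decay; `beta2` and `epsilon` use the
#'   conventional 0.999 and 1e-8.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed master seed controlling initialization, shuffling and any
#'   synthetic-data generation done by the caller.
#' @param split_fraction fraction of the dataset assigned to
#'   train-and-validate by [split_dataset()].
#' @param val_fraction fraction of the training pool held out for per-epoch
#'   validation accuracy.
#' @return a `train_config` list.
#' @export
train_config <- function(lambda1 = 0.5, lambda2 = 0.5, lr = 0.001,
                         beta1 = 0.9, batch_size = 32L, epochs = 30L,
                         seed = 1L, split_fraction = 0.8,
                         val_fraction = 0.1) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lr > 0,
            split_fraction > 0, split_fraction < 1,
            val_fraction >= 0, val_fraction < 1, batch_size >= 2L)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lr = lr,
                 beta1 = beta1, beta2 = 0.999, epsilon = 1e-8,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 split_fraction = split_fraction,
                 val_fraction = val_fraction),
            class = "train_config")
}

#' Cross-entropy loss from predicted probabilities
#'
#' Mean over the batch of `-sum_k q_k log p_k`, with probabilities clamped
#' at `1e-12` so a zero probability at the true class yields a large finite
#' loss rather than infinity.
#'
#' @param probabilities `N x K` matrix; rows must sum to 1.
#' @param one_hot `N x K` 0/1 matrix of ground truth.
#' @return nonnegative scalar.
#' @export
ce_loss <- function(probabilities, one_hot) {
  stopifnot(identical(dim(probabilities), dim(one_hot)))
  if (any(abs(rowSums(probabilities) - 1) > 1e-6))
    stop("probability rows must sum to 1", call. = FALSE)
  -mean(rowSums(one_hot * log(pmax(probabilities, 1e-12))))
}

#' Combined DANet objective
#'
#' `lambda1 * L_CE + lambda2 * L_DCCA`. With `lambda2 = 0` this is exactly
#' the weighted cross-entropy and the projections are ignored.
#'
#' @param probabilities,one_hot as in [ce_loss()].
#' @param H_main,H_down,H_top DCCA projection matrices (may be `NULL` when
#'   `lambda2 = 0`).
#' @param lambda1,lambda2 loss weights.
#' @param dcca a [dcca_config()].
#' @return scalar loss.
#' @export
combined_loss <- function(probabilities, one_hot, H_main = NULL,
                          H_down = NULL, H_top = NULL,
                          lambda1 = 0.5, lambda2 = 0.5,
                          dcca = if (!is.null(H_main)) dcca_config(d = ncol(H_main))) {
  total <- lambda1 * ce_loss(probabilities, one_hot)
  if (lambda2 > 0 && !is.null(H_main))
    total <- total + lambda2 * dcca_loss(H_main, H_down, H_top, dcca)
  total
}

#' Stratified train/test split
#'
#' Splits a labelled dataset into disjoint, exhaustive train-and-validate
#' and test subsets at `split_fraction`, stratified by class so each class
#' keeps (to rounding) the same proportion. Deterministic given the seed.
#' Classes with fewer than 2 members trigger a warning and an unstratified
#' split.
#'
#' @param dataset list of samples with a `label` field.
#' @param split_fraction fraction assigned to the first subset.
#' @param seed integer seed.
#' @return list with `train` and `test` index vectors into `dataset`.
#' @export
split_dataset <- function(dataset, split_fraction = 0.8, seed = 1L) {
  stopifnot(length(dataset) > 0)
  labels <- vapply(dataset, function(s) as.integer(s$label), integer(1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  counts <- table(labels)
  train_idx <- integer(0)
  if (any(counts < 2L)) {
    warning("a class has fewer than 2 members; splitting without stratification")
    n_train <- round(length(dataset) * split_fraction)
    train_idx <- sample(seq_along(dataset), n_train)
  } else {
    for (cl in names(counts)) {
      idx <- which(labels == as.integer(cl))
      n_train <- round(length(idx) * split_fraction)
      train_idx <- c(train_idx, sample(idx, n_train))
    }
    train_idx <- sort(train_idx)
  }
  list(train = train_idx, test = setdiff(seq_along(dataset), train_idx))
}

# one Adam step over the flat parameter list; state carries m, v, t
.adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      cfg$lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + cfg$epsilon)
  }
  list(params = params, state = state)
}

.one_hot <- function(labels, num_classes) {
  q <- matrix(0, length(labels), num_classes)
  q[cbind(seq_along(labels), labels)] <- 1
  q
}

#' Train a DANet on a labelled dataset
#'
#' Builds a model (unless one is supplied), holds out a seeded validation
#' subset of the training pool, and runs minibatch Adam on the combined
#' objective. The DCCA penalty is computed per minibatch on that batch's
#' projection matrices; minibatches smaller than 4 samples skip the
#' penalty, since canonical correlations are meaningless there. With
#' `lambda2 = 0` (or `use_dcca = FALSE` in the ablation) the DCCA machinery
#' is bypassed entirely and, from the same seed, the run is bit-identical
#' to a cross-entropy-only model.
#'
#' @param dataset list of samples (`image`, `mask`, `label`) with 1-based
#'   labels; e.g. from [generate_dataset()] or [read_dataset()].
#' @param config a [danet_config()]; `num_classes` must match the labels.
#' @param tc a [train_config()].
#' @param ablation an [ablation_spec()].
#' @param model optionally, a `danet_model` to continue training.
#' @param verbose print one line per epoch to stderr?
#' @return list with `model` and `history` (one row per epoch: mean
#'   training `ce`, `dcca`, `loss`, and `val_accuracy`).
#' @export
train_danet <- function(dataset, config, tc = train_config(),
                        ablation = ablation_spec(), model = NULL,
                        verbose = FALSE) {
  labels <- vapply(dataset, function(s) as.integer(s$label), integer(1))
  stopifnot(all(labels >= 1L), all(labels <= config$num_classes))
  set.seed(tc$seed)
  if (is.null(model)) model <- danet_model(config, ablation)

  n <- length(dataset)
  n_val <- floor(n * tc$val_fraction)
  val_idx <- if (n_val > 0) sample(seq_len(n), n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)

  # decompose, normalize and stack the whole dataset once; minibatches are
  # array slices, which keeps the per-step R overhead negligible
  full <- as_branch_batch(lapply(dataset, function(s)
    decompose_image(s$image / 255, (s$mask > 0) * 1)))
  slice <- function(idx) lapply(full, function(a) a[, , , idx, drop = FALSE])

  lambda2 <- if (ablation$use_dcca) tc$lambda2 else 0
  state <- list(m = list(), v = list(), t = 0L)
  hist <- vector("list", tc$epochs)

  for (epoch in seq_len(tc$epochs)) {
    ord <- sample(tr_idx)
    ce_sum <- dcca_sum <- loss_sum <- 0
    nb <- 0L
    i <- 1L
    while (i <= length(ord)) {
      j <- min(i + tc$batch_size - 1L, length(ord))
      idx <- ord[i:j]
      batch <- slice(idx)
      onehot <- .one_hot(labels[idx], config$num_classes)
      fwd <- danet_forward(model, batch, train = TRUE)
      l2 <- if (length(idx) >= 4L) lambda2 else 0
      bwd <- .danet_backward(model, fwd, onehot, tc$lambda1, l2)
      if (!is.finite(bwd$total))
        stop("training diverged (non-finite loss) at epoch ", epoch, call. = FALSE)
      upd <- .adam_step(model$params, bwd$grads, state, tc)
      model$params <- upd$params
      state <- upd$state
      ce_sum <- ce_sum + bwd$ce
      dcca_sum <- dcca_sum + bwd$dcca
      loss_sum <- loss_sum + bwd$total
      nb <- nb + 1L
      i <- j + 1L
    }
    val_acc <- if (length(val_idx) > 0) {
      pred <- integer(0)
      i <- 1L
      while (i <= length(val_idx)) {
        j <- min(i + tc$batch_size - 1L, length(val_idx))
        fwd <- danet_forward(model, slice(val_idx[i:j]))
        pred <- c(pred, max.col(fwd$probs, ties.method = "first"))
        i <- j + 1L
      }
      mean(pred == labels[val_idx])
    } else NA_real_
    hist[[epoch]] <- data.frame(epoch = epoch, ce = ce_sum / nb,
                                dcca = dcca_sum / nb, loss = loss_sum / nb,
                                val_accuracy = val_acc)
    if (verbose)
      message(sprintf("epoch %d: ce %.4f dcca %.4f loss %.4f val_acc %s",
                      epoch, ce_sum / nb, dcca_sum / nb, loss_sum / nb,
                      format(val_acc, digits = 3)))
  }
  history <- do.call(rbind, hist)
  attr(history, "optimizer") <- list(algorithm = "adam", lr = tc$lr,
                                     beta1 = tc$beta1, beta2 = tc$beta2,
                                     epsilon = tc$epsilon)
  list(model = model, history = history)
}

#' Mean attention weight per branch over a set of samples
#'
#' @param model a trained attention-pooling `danet_model`.
#' @param samples list of samples or triplets.
#' @param batch_size forward batch size.
#' @return named numeric vector of mean attention weights (sums to 1).
#' @export
mean_attention <- function(model, samples, batch_size = 32L) {
  stopifnot(model$ablation$pooling == "attention")
  n <- length(samples)
  acc <- NULL
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fwd <- danet_forward(model, as_branch_batch(samples[i:j]))
    s <- colSums(fwd$attention)
    acc <- if (is.null(acc)) s else acc + s
    i <- j + 1L
  }
  acc / n
}

#' Save / load a model checkpoint
#'
#' Weights go to an RDS file; a JSON sidecar (`<path>.json`) records the
#' architecture and ablation so a checkpoint is self-describing.
#'
#' @param model a `danet_model`.
#' @param path checkpoint path (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
save_danet <- function(model, path) {
  saveRDS(model, path)
  side <- list(config = model$config[setdiff(names(model$config), "dcca")],
               dcca = unclass(model$config$dcca),
               ablation = unclass(model$ablation),
               n_parameters = n_parameters(model))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_danet
#' @export
load_danet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "danet_model"))
  model
}
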