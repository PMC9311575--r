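# shared fixture builders: everything is generated in code at test time

rand_image <- function(h = 8, w = 8, seed = NULL, integer8 = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (integer8)
    array(as.numeric(sample(0:255, h * w * 3, replace = TRUE)),
          dim = c(h, w, 3))
  else array(runif(h * w * 3), dim = c(h, w, 3))
}

rand_mask <- function(h = 8, w = 8, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(as.numeric(rbinom(h * w, 1, p)), h, w)
}

# tiny trainable configuration used by the network/training smoke tests
tiny_config <- function(num_classes = 3) {
  danet_config(num_classes = num_classes, input_size = 64L,
               branch_channels = 16L, attention_hidden = 8L,
               dcca = dcca_config(d = 4L))
}

# small balanced synthetic dataset (reused across tests via a fixed seed)
tiny_dataset <- function(n_per_class = 6, carrier = "nuclei", seed = 42) {
  spec <- synthetic_task_spec(signal_carrier = carrier)
  generate_dataset(spec, n_per_class = n_per_class, seed = seed)
}

# independent classical CCA solver: canonical correlations from the
# ridge-regularized covariances via a plain eigendecomposition
cca_oracle_rho <- function(H1, H2, r) {
  n <- nrow(H1)
  H1c <- scale(H1, scale = FALSE)
  H2c <- scale(H2, scale = FALSE)
  S11 <- crossprod(H1c) / (n - 1) + r * diag(ncol(H1))
  S22 <- crossprod(H2c) / (n - 1) + r * diag(ncol(H2))
  S12 <- crossprod(H1c, H2c) / (n - 1)
  ev <- eigen(solve(S11) %*% S12 %*% solve(S22) %*% t(S12),
              only.values = TRUE)$values
  sqrt(pmax(Re(ev), 0))
}

# the desk-scale training protocol shared by the end-to-end tests:
# 300 samples split 200 train / 100 test, 10 epochs, minibatch 16
desk_run <- function(carrier, seed, ablation = ablation_spec()) {
  spec <- synthetic_task_spec(signal_carrier = carrier)
  ds <- generate_dataset(spec, n_per_class = 100, seed = seed)
  sp <- split_dataset(ds, 2 / 3, seed = seed)
  tc <- train_config(seed = seed, epochs = 10, batch_size = 16)
  fit <- train_danet(ds[sp$train], danet_config(num_classes = 3), tc, ablation)
  list(fit = fit, test = ds[sp$test],
       accuracy = evaluate_danet(fit$model, ds[sp$test])$accuracy)
}
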