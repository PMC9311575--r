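test_that("convolution and pooling backward passes match finite differences", {
  set.seed(1)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  W <- matrix(rnorm(27 * 4), 27, 4)
  b <- rnorm(4)
  R <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  cv <- danet:::conv_fwd(x, W, b)
  bk <- danet:::conv_bwd(R, cv, W)
  h <- 1e-6
  for (idx in sample(length(x), 10)) {
    xp <- x; xp[idx] <- xp[idx] + h
    xm <- x; xm[idx] <- xm[idx] - h
    fd <- (sum(danet:::conv_fwd(xp, W, b)$out * R) -
             sum(danet:::conv_fwd(xm, W, b)$out * R)) / (2 * h)
    expect_equal(bk$dx[idx], fd, tolerance = 1e-5)
  }
  for (idx in sample(length(W), 10)) {
    Wp <- W; Wp[idx] <- Wp[idx] + h
    Wm <- W; Wm[idx] <- Wm[idx] - h
    fd <- (sum(danet:::conv_fwd(x, Wp, b)$out * R) -
             sum(danet:::conv_fwd(x, Wm, b)$out * R)) / (2 * h)
    expect_equal(bk$dW[idx], fd, tolerance = 1e-5)
  }
  Rp <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  expect_equal(sum(danet:::pool_fwd(x) * Rp),
               sum(x * danet:::pool_bwd(Rp)), tolerance = 1e-10)
})

test_that("global average pooling is the spatial mean per channel", {
  expect_equal(gap(array(7, c(3, 3, 2, 1))), matrix(7, 1, 2))
  x <- array(c(1, 2, 3, 4), c(2, 2, 1, 1))
  expect_equal(gap(x), matrix(2.5, 1, 1))
  set.seed(2)
  y <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  expected <- matrix(0, 2, 3)
  for (n in 1:2) for (ch in 1:3) {
    s <- 0
    for (i in 1:4) for (j in 1:5) s <- s + y[i, j, ch, n]
    expected[n, ch] <- s / 20
  }
  expect_equal(gap(y), expected, tolerance = 1e-12)
})

test_that("fusion block preserves shape and matches direct convolution", {
  set.seed(3)
  C <- 4
  xm <- array(abs(rnorm(5 * 7 * C * 2)), c(5, 7, C, 2))
  xa <- array(abs(rnorm(5 * 7 * C * 2)), c(5, 7, C, 2))
  params <- list(p_W = matrix(rnorm(2 * C * C), 2 * C, C), p_b = rnorm(C),
                 q_W = matrix(rnorm(9 * C * C), 9 * C, C), q_b = rnorm(C))
  out <- fusion_block(xm, xa, params)
  expect_identical(dim(out), dim(xm))
  expect_error(fusion_block(xm, xa[, 1:6, , , drop = FALSE], params),
               "identical shapes")

  # constructed identity: 1x1 passes the first C channels, 3x3 is a centred
  # delta kernel, so (without activation) the block returns x_main
  pid <- matrix(0, 2 * C, C); pid[cbind(1:C, 1:C)] <- 1
  qid <- matrix(0, 9 * C, C)
  for (ch in 1:C) qid[(ch - 1) * 9 + 5, ch] <- 1 # centre of the 3x3 window
  idp <- list(p_W = pid, p_b = numeric(C), q_W = qid, q_b = numeric(C))
  expect_equal(fusion_block(xm, xa, idp, activation = FALSE), xm,
               tolerance = 1e-12)

  # hand-computed 1-channel convolution arithmetic on a 2x2 map
  x1 <- array(c(1, 3, 2, 4), c(2, 2, 1, 1)) # column-major: x[1,1]=1 x[2,1]=3
  x2 <- array(0, c(2, 2, 1, 1))
  hp <- list(p_W = matrix(c(1, 0), 2, 1), p_b = 0,
             q_W = matrix(c(rep(0, 4), 2, rep(0, 4)), 9, 1), q_b = 1)
  # 1x1 conv keeps x1; 3x3 delta kernel scales by 2 and adds bias 1
  expect_equal(fusion_block(x1, x2, hp, activation = FALSE),
               x1 * 2 + 1, tolerance = 1e-12)
})

test_that("attention weights form a proper convex combination", {
  set.seed(4)
  pars <- attention_params(6, hidden = 5)
  for (rep in 1:50) {
    V <- lapply(1:5, function(k) rnorm(6))
    out <- branch_selection_attention(V, pars)
    expect_true(all(out$a > 0))
    expect_equal(sum(out$a), 1, tolerance = 1e-6)
    lo <- do.call(pmin, V); hi <- do.call(pmax, V)
    expect_true(all(out$z >= lo - 1e-10 & out$z <= hi + 1e-10))
  }
  # equal branches: exact softmax symmetry
  v <- rnorm(6)
  eq <- branch_selection_attention(rep(list(v), 5), pars)
  expect_equal(unname(eq$a), rep(0.2, 5), tolerance = 1e-12)
  expect_equal(eq$z, v, tolerance = 1e-12)
  # permutation equivariance, exactly
  V <- lapply(1:5, function(k) rnorm(6))
  perm <- c(3, 1, 5, 2, 4)
  o1 <- branch_selection_attention(V, pars)
  o2 <- branch_selection_attention(V[perm], pars)
  expect_equal(unname(o2$a), unname(o1$a[perm]), tolerance = 1e-12)
  expect_equal(o2$z, o1$z, tolerance = 1e-12)
})

test_that("attention scoring follows w' tanh(Q v) through saturation", {
  pars <- list(Q = matrix(1, 1, 1), w = 1)
  out <- branch_selection_attention(list(0, 1000), pars)
  # scores are (tanh(0), tanh(1000)) = (0, ~1)
  expect_equal(unname(out$a), c(exp(0), exp(1)) / (exp(0) + exp(1)),
               tolerance = 1e-6)
  expect_equal(unname(out$a), c(0.2689, 0.7311), tolerance = 1e-4)
  # scores depend on (w, Q) only through the composite w' tanh(Q v)
  set.seed(5)
  V <- lapply(1:3, function(k) rnorm(4))
  p1 <- attention_params(4, hidden = 8)
  s1 <- vapply(V, function(v) sum(p1$w * tanh(as.vector(v %*% p1$Q))),
               numeric(1))
  a_direct <- exp(s1 - max(s1)) / sum(exp(s1 - max(s1)))
  expect_equal(unname(branch_selection_attention(V, p1)$a), a_direct,
               tolerance = 1e-12)
})

test_that("forward pass honours shape contracts and determinism", {
  set.seed(6)
  cfg <- tiny_config()
  model <- danet_model(cfg)
  ds <- tiny_dataset(n_per_class = 2)
  batch <- as_branch_batch(ds)
  fwd1 <- danet_forward(model, batch)
  fwd2 <- danet_forward(model, batch)
  expect_identical(fwd1$logits, fwd2$logits) # evaluation is deterministic
  expect_identical(dim(fwd1$logits), c(6L, 3L))
  expect_equal(rowSums(fwd1$probs), rep(1, 6), tolerance = 1e-12)
  expect_equal(unname(rowSums(fwd1$attention)), rep(1, 6), tolerance = 1e-6)
  expect_identical(colnames(fwd1$attention),
                   c("top", "mid1", "main", "mid2", "down"))

  fmap <- extract_branch_features(model, batch$main, "main")
  expect_identical(dim(fmap), c(4L, 4L, 16L, 6L))
  # zero input through zero-bias convolutions stays zero
  zero <- array(0, dim(batch$main))
  expect_true(all(extract_branch_features(model, zero, "down") == 0))
  expect_error(extract_branch_features(model, batch$main[1:32, , , , drop = FALSE]),
               "64")
})

test_that("ablation heads still produce valid classifiers", {
  ds <- tiny_dataset(n_per_class = 2)
  batch <- as_branch_batch(ds)
  for (pool in c("mean", "max", "concat")) {
    set.seed(7)
    model <- danet_model(tiny_config(), ablation_spec(pooling = pool))
    fwd <- danet_forward(model, batch)
    expect_identical(dim(fwd$logits), c(6L, 3L))
    expect_equal(rowSums(fwd$probs), rep(1, 6), tolerance = 1e-12)
    expect_null(fwd$attention)
  }
  set.seed(8)
  m3 <- danet_model(tiny_config(), ablation_spec(use_fusion_block = FALSE))
  fwd3 <- danet_forward(m3, batch)
  expect_identical(colnames(fwd3$attention), c("top", "main", "down"))
  set.seed(9)
  m1 <- danet_model(tiny_config(),
                    ablation_spec(active_branches = "main",
                                  use_fusion_block = FALSE, use_dcca = FALSE))
  expect_identical(dim(danet_forward(m1, batch["main"])$logits), c(6L, 3L))
  expect_error(ablation_spec(active_branches = c("top", "down")), "main")
})

test_that("checkpoints round-trip through disk", {
  set.seed(10)
  model <- danet_model(tiny_config())
  path <- tempfile(fileext = ".rds")
  save_danet(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$n_parameters, n_parameters(model))
  reloaded <- load_danet(path)
  ds <- tiny_dataset(n_per_class = 1)
  batch <- as_branch_batch(ds)
  expect_identical(danet_forward(reloaded, batch)$logits,
                   danet_forward(model, batch)$logits)
})

test_that("parameter accounting reproduces the headline reduction", {
  expect_equal(round(parameter_reduction_pct(95e6, 139e6)), 32)
  set.seed(11)
  model <- danet_model(tiny_config())
  expect_identical(n_parameters(model),
                   sum(vapply(model$params, length, integer(1))))
})
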