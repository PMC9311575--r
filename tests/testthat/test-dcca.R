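test_that("column centering is exact and idempotent", {
  set.seed(1)
  H <- matrix(rnorm(15), 5, 3)
  Hc <- center_columns(H)
  expect_lt(max(abs(colMeans(Hc))), 1e-12)
  expect_equal(center_columns(Hc), Hc)
  expect_true(all(center_columns(matrix(3, 4, 2)) == 0))
})

test_that("covariances match a brute-force oracle plus the ridge", {
  set.seed(2)
  H1 <- matrix(rnorm(150), 50, 3)
  H2 <- matrix(rnorm(150), 50, 3)
  cfg <- dcca_config(d = 3, r1 = 0.001, r2 = 0.001)
  S <- dcca_covariances(H1, H2, cfg)

  # two-loop sample covariance oracle
  mu1 <- colMeans(H1); mu2 <- colMeans(H2)
  S12o <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3)
    S12o[a, b] <- sum((H1[, a] - mu1[a]) * (H2[, b] - mu2[b])) / 49
  expect_equal(S$S12, S12o, tolerance = 1e-12)

  # ridge definition: S11 minus the sample covariance is exactly r * I
  expect_equal(S$S11 - (cov(H1) ), 0.001 * diag(3), tolerance = 1e-12)
  # self-covariance: H1 == H2 and r = 0 collapses the triple
  S0 <- dcca_covariances(H1, H1, dcca_config(d = 3, r1 = 0, r2 = 0))
  expect_equal(S0$S11, S0$S12, tolerance = 1e-12)
  expect_equal(S0$S22, S0$S12, tolerance = 1e-12)
})

test_that("identical views give sqrt(d) / d total correlation", {
  set.seed(3)
  H <- matrix(rnorm(40 * 4), 40, 4)
  frob <- dcca_config(d = 4, r1 = 0, r2 = 0)
  tn <- dcca_config(d = 4, r1 = 0, r2 = 0, correlation_mode = "trace_norm")
  expect_equal(dcca_correlation(H, H, frob), 2, tolerance = 1e-8)
  expect_equal(dcca_correlation(H, H, tn), 4, tolerance = 1e-8)
  expect_equal(dcca_loss(H, H, H, frob), -4, tolerance = 1e-8)
})

test_that("total correlation equals the classical CCA oracle", {
  set.seed(4)
  frob <- dcca_config(d = 3, r1 = 0.001, r2 = 0.001)
  tn <- dcca_config(d = 3, r1 = 0.001, r2 = 0.001,
                    correlation_mode = "trace_norm")
  for (rep in 1:20) {
    H1 <- matrix(rnorm(150), 50, 3)
    H2 <- matrix(rnorm(150), 50, 3) + runif(1, 0, 1) * H1
    rho <- cca_oracle_rho(H1, H2, 0.001)
    expect_equal(dcca_correlation(H1, H2, frob), sqrt(sum(rho^2)),
                 tolerance = 1e-6)
    expect_equal(dcca_correlation(H1, H2, tn), sum(rho), tolerance = 1e-6)
  }
})

test_that("correlation respects bounds, symmetry and rotation invariance", {
  set.seed(5)
  for (mode in c("frobenius", "trace_norm")) {
    cfg <- dcca_config(d = 3, r1 = 0.01, r2 = 0.01, correlation_mode = mode)
    for (rep in 1:10) {
      H1 <- matrix(rnorm(120), 40, 3)
      H2 <- matrix(rnorm(120), 40, 3) + 0.5 * H1
      v <- dcca_correlation(H1, H2, cfg)
      expect_gte(v, 0)
      expect_lte(v, if (mode == "frobenius") sqrt(3) + 1e-10 else 3 + 1e-10)
      expect_equal(dcca_correlation(H2, H1, cfg), v, tolerance = 1e-10)
      R1 <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
      R2 <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
      expect_equal(dcca_correlation(H1 %*% R1, H2 %*% R2, cfg), v,
                   tolerance = 1e-8)
    }
  }
})

test_that("independent views decorrelate at large N", {
  set.seed(6)
  H1 <- matrix(rnorm(2000 * 3), 2000, 3)
  H2 <- matrix(rnorm(2000 * 3), 2000, 3)
  cfg <- dcca_config(d = 3, r1 = 0.001, r2 = 0.001)
  expect_lt(dcca_correlation(H1, H2, cfg), 3 / sqrt(2000) * 3)
  expect_gt(dcca_loss(H1, H2, H2, cfg), -6 / sqrt(2000) * 3)
})

test_that("analytic gradients match central finite differences", {
  for (mode in c("frobenius", "trace_norm")) {
    set.seed(7)
    cfg <- dcca_config(d = 3, r1 = 0.001, r2 = 0.001, correlation_mode = mode)
    H1 <- matrix(rnorm(36), 12, 3)
    H2 <- matrix(rnorm(36), 12, 3) + 0.3 * H1
    H3 <- matrix(rnorm(36), 12, 3)
    g <- dcca_loss_grad(H1, H2, H3, cfg)
    expect_equal(g$value, suppressWarnings(dcca_loss(H1, H2, H3, cfg)),
                 tolerance = 1e-10)
    h <- 1e-5
    grads <- list(g$dH_main, g$dH_down, g$dH_top)
    for (m in 1:3) {
      for (idx in seq(1, 36, by = 5)) {
        Hp <- list(H1, H2, H3); Hm <- list(H1, H2, H3)
        Hp[[m]][idx] <- Hp[[m]][idx] + h
        Hm[[m]][idx] <- Hm[[m]][idx] - h
        fd <- (suppressWarnings(dcca_loss(Hp[[1]], Hp[[2]], Hp[[3]], cfg)) -
                 suppressWarnings(dcca_loss(Hm[[1]], Hm[[2]], Hm[[3]], cfg))) /
          (2 * h)
        expect_equal(grads[[m]][idx], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("correlation grows with the shared-signal fraction", {
  set.seed(8)
  cfg <- dcca_config(d = 3, r1 = 0.001, r2 = 0.001)
  H1 <- matrix(rnorm(300), 100, 3)
  noise <- matrix(rnorm(300), 100, 3)
  vals <- vapply(seq(0, 1, by = 0.1), function(alpha)
    dcca_correlation(H1, alpha * H1 + (1 - alpha) * noise, cfg), numeric(1))
  expect_true(all(diff(vals) > -1e-8))
})

test_that("projection heads and batch contracts behave", {
  set.seed(9)
  H <- matrix(rnorm(9), 3, 3)
  expect_error(dcca_loss(H, H, H), "at least 4")
  expect_warning(
    dcca_loss(matrix(rnorm(16), 4, 4), matrix(rnorm(16), 4, 4),
              matrix(rnorm(16), 4, 4), dcca_config(d = 4)),
    "rank-deficient")
  expect_error(dcca_covariances(matrix(rnorm(12), 4, 3),
                                matrix(rnorm(8), 4, 2)))
})
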