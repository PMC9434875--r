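# Forward passes, softmax head and the composite loss against hand arithmetic.

test_that("softmax head is a proper, shift-invariant probability map", {
  expect_equal(classify_logits(rbind(c(0, 0))), rbind(c(0.5, 0.5)))
  e <- exp(1)
  expect_equal(classify_logits(rbind(c(1, 0))),
               rbind(c(e / (1 + e), 1 / (1 + e))), tolerance = 1e-12)
  withr::with_seed(5, Z <- matrix(rnorm(60), 20, 3) * 10)
  P <- classify_logits(Z)
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-9)
  expect_equal(classify_logits(Z + 7), P, tolerance = 1e-12)
})

test_that("encoder matches hand arithmetic on a fixed 2-3-2 network", {
  p <- list(
    W1 = rbind(c(1, 0, -1), c(2, 1, 0)), b1 = c(0.5, -1, 0),
    W2 = rbind(c(1, 0), c(0, 1), c(1, 1)), b2 = c(0, 0.25)
  )
  mdl <- hand_model(p, d = 2, k = 2)
  x <- rbind(c(1, -1))
  # hand: pre-activations (1*1 + -1*2 + 0.5, 0*1 + 1*-1 - 1, -1*1 + 0 + 0)
  #       = (-0.5, -2, -1) -> relu -> (0, 0, 0) -> Z = (0, 0.25)
  expect_equal(encode(mdl, matrix(x, 1, 2)), rbind(c(0, 0.25)))
  x2 <- rbind(c(2, 1))
  # pre: (2 + 2 + 0.5, 1 - 1, -2) = (4.5, 0, -2) -> relu (4.5, 0, 0)
  # Z = (4.5*W2[1,1] + 0 + 0, 4.5*W2[1,2] + 0 + 0 + 0.25) = (4.5, 0.25)
  expect_equal(encode(mdl, matrix(x2, 1, 2)), rbind(c(4.5, 0.25)))
  # identical inputs give identical latent rows
  X <- rbind(c(0.3, 0.7), c(0.3, 0.7))
  Z <- encode(mdl, X)
  expect_identical(Z[1, ], Z[2, ])
})

test_that("zero-weight networks encode and decode to zero", {
  p <- list(W1 = matrix(0, 3, 4), b1 = rep(0, 4),
            W2 = matrix(0, 4, 2), b2 = rep(0, 2),
            W3 = matrix(0, 2, 4), b3 = rep(0, 4),
            W4 = matrix(0, 4, 3), b4 = rep(0, 3))
  mdl <- hand_model(p, d = 3, k = 2)
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(encode(mdl, X), matrix(0, 5, 2))
  expect_equal(decode(mdl, matrix(rnorm(10), 5, 2)), matrix(0, 5, 3))
  expect_equal(ncol(decode(mdl, encode(mdl, X))), 3)
})

test_that("decoder matches hand arithmetic on a fixed mirror network", {
  p <- list(W1 = matrix(0, 2, 2), b1 = rep(0, 2),
            W2 = matrix(0, 2, 2), b2 = rep(0, 2),
            W3 = rbind(c(1, -1), c(0, 2)), b3 = c(0, 1),
            W4 = rbind(c(1, 0), c(1, 1)), b4 = c(-1, 0))
  mdl <- hand_model(p, d = 2, k = 2)
  z <- rbind(c(2, 1))
  # hidden pre: (2*1 + 1*0, 2*-1 + 1*2 + 1) = (2, 1) -> relu (2, 1)
  # out: (2*1 + 1*1 - 1, 2*0 + 1*1) = (2, 1)
  expect_equal(decode(mdl, z), rbind(c(2, 1)))
})

test_that("composite loss decomposes correctly and matches scalar-loop arithmetic", {
  withr::with_seed(13, {
    d <- 3; h <- 4; k <- 2
    p <- list(W1 = matrix(rnorm(d * h), d, h), b1 = rnorm(h),
              W2 = matrix(rnorm(h * k), h, k), b2 = rnorm(k),
              W3 = matrix(rnorm(k * h), k, h), b3 = rnorm(h),
              W4 = matrix(rnorm(h * d), h, d), b4 = rnorm(d))
    X <- matrix(rnorm(2 * d), 2, d)
    y <- c(0L, 1L)
  })
  delta <- 0.6
  got <- total_loss(p, X, y, lambda = 0.7, recon_loss = "huber",
                    huber_delta = delta)

  # scalar-loop oracle
  ce <- 0; hub <- 0
  for (i in 1:2) {
    a1 <- numeric(4)
    for (j in 1:4) a1[j] <- max(sum(X[i, ] * p$W1[, j]) + p$b1[j], 0)
    z <- numeric(2)
    for (j in 1:2) z[j] <- sum(a1 * p$W2[, j]) + p$b2[j]
    pr <- exp(z) / sum(exp(z))
    ce <- ce - log(pr[y[i] + 1])
    a3 <- numeric(4)
    for (j in 1:4) a3[j] <- max(sum(z * p$W3[, j]) + p$b3[j], 0)
    for (j in 1:3) {
      r <- sum(a3 * p$W4[, j]) + p$b4[j] - X[i, j]
      hub <- hub + if (abs(r) <= delta) 0.5 * r^2 else delta * (abs(r) - 0.5 * delta)
    }
  }
  ce <- ce / 2; hub <- hub / 6
  expect_equal(got$classification, ce, tolerance = 1e-12)
  expect_equal(got$reconstruction, hub, tolerance = 1e-12)
  expect_equal(got$total, ce + 0.7 * hub, tolerance = 1e-12)

  # lambda = 0 collapses to the cross-entropy term
  got0 <- total_loss(p, X, y, lambda = 0)
  expect_equal(got0$total, got0$classification)
  expect_gte(got$total, 0)
  expect_error(total_loss(p, X, c(0L, 5L)), "labels")
})

test_that("perfect reconstruction has zero Huber term", {
  # all-zero input through a zero network reconstructs exactly
  p <- list(W1 = matrix(0, 2, 3), b1 = rep(0, 3), W2 = matrix(0, 3, 2),
            b2 = rep(0, 2), W3 = matrix(0, 2, 3), b3 = rep(0, 3),
            W4 = matrix(0, 3, 2), b4 = rep(0, 2))
  out <- total_loss(p, matrix(0, 4, 2), rep(0L, 4), lambda = 2)
  expect_equal(out$reconstruction, 0)
})

test_that("Huber loss is quadratic below delta and grows linearly above", {
  # zero decoder => residual is -X; compare Huber and squared-error variants
  p <- list(W1 = matrix(0, 1, 2), b1 = rep(0, 2), W2 = matrix(0, 2, 2),
            b2 = rep(0, 2), W3 = matrix(0, 2, 2), b3 = rep(0, 2),
            W4 = matrix(0, 2, 1), b4 = 0)
  small <- matrix(0.4, 1, 1)   # |r| below delta = 1
  hub <- total_loss(p, small, 0L, lambda = 1, recon_loss = "huber")$reconstruction
  sq <- total_loss(p, small, 0L, lambda = 1, recon_loss = "l2")$reconstruction
  expect_equal(hub, sq)
  expect_equal(hub, 0.5 * 0.4^2)

  big1 <- total_loss(p, matrix(10, 1, 1), 0L, lambda = 1)$reconstruction
  big2 <- total_loss(p, matrix(100, 1, 1), 0L, lambda = 1)$reconstruction
  sq1 <- total_loss(p, matrix(10, 1, 1), 0L, lambda = 1, recon_loss = "l2")$reconstruction
  sq2 <- total_loss(p, matrix(100, 1, 1), 0L, lambda = 1, recon_loss = "l2")$reconstruction
  expect_equal(big2 / big1, (100 - 0.5) / (10 - 0.5), tolerance = 1e-12)  # linear growth
  expect_equal(sq2 / sq1, 100, tolerance = 1e-12)                          # quadratic growth
  expect_lt(big2 / big1, sq2 / sq1)
})

test_that("forward passes are bitwise deterministic", {
  withr::with_seed(17, {
    p <- list(W1 = matrix(rnorm(12), 3, 4), b1 = rnorm(4),
              W2 = matrix(rnorm(8), 4, 2), b2 = rnorm(2))
    X <- matrix(rnorm(30), 10, 3)
  })
  mdl <- hand_model(p, d = 3, k = 2)
  expect_identical(encode(mdl, X), encode(mdl, X))
})
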