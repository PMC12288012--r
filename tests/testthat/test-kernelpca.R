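test_that("the lambda grid enumerates the simplex lattice in lexicographic order", {
  g <- lambda_grid(0.25)
  expect_length(g, 15)
  W <- do.call(rbind, lapply(g, unclass))
  expect_true(all(abs(rowSums(W) - 1) < 1e-12))
  expect_false(is.unsorted(W[, 1]))

  expect_equal(lapply(lambda_grid(1), as.numeric),
               list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0)))

  # brute-force enumeration oracle for step = 0.5
  vals <- c(0, 0.5, 1)
  brute <- expand.grid(l1 = vals, l2 = vals, l3 = vals)
  brute <- brute[abs(rowSums(brute) - 1) < 1e-12, ]
  expect_length(lambda_grid(0.5), nrow(brute))  # 6 triples

  expect_error(lambda_grid(0), class = "rc_invalid_step")
  expect_error(lambda_grid(0.3), class = "rc_invalid_step")
})

test_that("kernel weights enforce the simplex constraint", {
  expect_error(kernel_weights(0.5, 0.5, 0.5))
  expect_error(kernel_weights(-0.2, 0.6, 0.6))
  w <- kernel_weights(0.25, 0.25, 0.5)
  expect_equal(sum(w), 1)
})

test_that("the angular kernel matches closed forms and a scalar-loop oracle", {
  r <- 7.3
  on_x <- make_traj(array(c(r, 0, 0), dim = c(1, 1, 3)), atom_name = "CA")
  on_z <- make_traj(array(c(0, 0, r), dim = c(1, 1, 3)), atom_name = "CA")
  expect_equal(kernel_transform(on_x, kernel_weights(1, 0, 0))$values[1, 1],
               cos(1)^2, tolerance = 1e-12)   # x/r = 1 rad
  expect_equal(kernel_transform(on_z, kernel_weights(0, 0, 1))$values[1, 1],
               sin(1)^2, tolerance = 1e-12)   # z/r = 1 rad

  tr <- random_traj(10, 10, seed = 31)
  for (w in lambda_grid(0.25)) {
    k <- kernel_transform(tr, w)
    expect_true(all(k$values >= 0 & k$values <= 1))
    expect_equal(k$values, kernel_oracle(tr$coords, w), tolerance = 1e-12)
  }
})

test_that("the kernel is linear in the weights and smooth in positions", {
  tr <- random_traj(5, 8, seed = 33)
  w1 <- kernel_weights(0.75, 0, 0.25)
  w2 <- kernel_weights(0, 0.5, 0.5)
  for (alpha in c(0.2, 0.5, 0.9)) {
    mix <- kernel_weights(alpha * w1[1] + (1 - alpha) * w2[1],
                          alpha * w1[2] + (1 - alpha) * w2[2],
                          alpha * w1[3] + (1 - alpha) * w2[3])
    expect_equal(kernel_transform(tr, mix)$values,
                 alpha * kernel_transform(tr, w1)$values +
                   (1 - alpha) * kernel_transform(tr, w2)$values,
                 tolerance = 1e-12)
  }

  # Lipschitz smoke test: perturbing one atom by delta moves its feature by
  # at most ~2 * delta / r
  set.seed(34)
  w <- kernel_weights(1 / 3, 1 / 3, 1 / 3)
  for (i in 1:20) {
    p <- rnorm(3, sd = 4) + c(12, 0, 0)
    r <- sqrt(sum(p^2))
    delta <- 1e-4
    q <- p + delta * { u <- rnorm(3); u / sqrt(sum(u^2)) }
    k1 <- kernel_oracle(array(p, dim = c(1, 1, 3)), w)
    k2 <- kernel_oracle(array(q, dim = c(1, 1, 3)), w)
    expect_lte(abs(k2 - k1), 2 * delta / r * (1 + 1e-6) + 1e-12)
  }

  at_origin <- make_traj(array(0, dim = c(1, 2, 3)), atom_name = c("CA", "CA"))
  at_origin$coords[1, 2, ] <- c(5, 5, 5)
  expect_error(kernel_transform(at_origin, w), class = "rc_degenerate_position")
})

test_that("PCA embedding reproduces a diagonal-covariance construction exactly", {
  set.seed(41)
  Q <- qr.Q(qr(cbind(1, rnorm(40), rnorm(40))))  # cols 2,3: centred, orthonormal
  col1 <- Q[, 2] * 2 * sqrt(39)   # sample variance 4
  col2 <- Q[, 3] * sqrt(39)       # sample variance 1
  emb <- pca_embed(cbind(col1, col2))
  expect_equal(emb$explained_variance, c(4, 1), tolerance = 1e-9)
  expect_equal(abs(emb$pc1), abs(col1), tolerance = 1e-9)
  expect_gte(var(emb$pc1), var(emb$pc2))
})

test_that("PCA embedding agrees with a dense eigendecomposition oracle", {
  set.seed(42)
  X <- matrix(rnorm(50 * 10), 50, 10)
  emb <- pca_embed(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eig <- eigen(cov(Xc), symmetric = TRUE)
  expect_equal(emb$explained_variance, eig$values[1:2], tolerance = 1e-9)
  for (j in 1:2) {
    proj <- as.numeric(Xc %*% eig$vectors[, j])
    score <- if (j == 1) emb$pc1 else emb$pc2
    expect_equal(abs(score), abs(proj), tolerance = 1e-9)
  }
  expect_equal(crossprod(emb$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PCA variance bookkeeping identities hold", {
  set.seed(43)
  X <- matrix(rnorm(30 * 6), 30, 6)
  emb <- pca_embed(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_equal(sum(emb$eigenvalues), sum(apply(Xc, 2, var)), tolerance = 1e-10)
  # 2D reconstruction error equals the sum of discarded eigenvalues
  scores <- cbind(emb$pc1, emb$pc2)
  resid <- Xc - scores %*% t(emb$loadings)
  expect_equal(sum(resid^2) / (nrow(X) - 1), sum(emb$eigenvalues[-(1:2)]),
               tolerance = 1e-10)
})

test_that("PCA sign convention is deterministic and degenerate input errors", {
  set.seed(44)
  X <- matrix(rnorm(25 * 5), 25, 5)
  e1 <- pca_embed(X)
  e2 <- pca_embed(X)
  expect_identical(e1$pc1, e2$pc1)
  for (j in 1:2) {
    v <- e1$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  rank1 <- cbind(X[, 1], 2 * X[, 1])
  expect_error(pca_embed(rank1), class = "rc_degenerate_features")
})
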