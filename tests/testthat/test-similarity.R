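test_that("GIP kernel matches hand-evaluated profile distances", {
  Y <- rbind(c(1, 0), c(0, 1), c(1, 0))
  K <- gip_kernel(Y, "mirna", gamma = 1)
  expect_equal(K[1, 3], 1)            # identical profiles
  expect_equal(K[1, 2], exp(-2))      # squared distance 2
  expect_equal(diag(K), rep(1, 3))
  Kd <- gip_kernel(Y, "disease", gamma = 2)
  expect_equal(Kd[1, 2], exp(-2 * 3)) # columns (1,0,1) vs (0,1,0)
  expect_error(gip_kernel(Y, "mirna", gamma = 0), "positive")
})

test_that("GIP kernel is symmetric, positive and unit-diagonal on random matrices", {
  set.seed(3)
  for (rep in 1:10) {
    Y <- random_binary(sample(3:12, 1), sample(3:12, 1))
    K <- gip_kernel(Y, sample(c("mirna", "disease"), 1), gamma = runif(1, 0.2, 3))
    expect_identical(K, t(K))
    expect_true(all(K > 0 & K <= 1))
    expect_equal(diag(K), rep(1, nrow(K)))
  }
})

test_that("kernel fusion is the stated convex combination and linear in alpha", {
  S <- matrix(c(1, 0.4, 0.4, 1), 2)
  G <- matrix(c(1, 0.2, 0.2, 1), 2)
  expect_identical(fuse_kernels(S, G, 1), S)
  expect_identical(fuse_kernels(S, G, 0), G)
  expect_equal(fuse_kernels(S, G, 0.5)[1, 2], 0.3)
  a <- 0.37
  expect_equal(fuse_kernels(S, G, a),
               a * fuse_kernels(S, G, 1) + (1 - a) * fuse_kernels(S, G, 0))
  expect_error(fuse_kernels(S, matrix(0, 3, 3)), "dimensions")
  expect_error(fuse_kernels(S, G, 1.2), "\\[0, 1\\]")
})

test_that("nearest-profile matrix keeps one kernel-valued nonzero per row", {
  K <- rbind(c(1, 0.8, 0.3), c(0.8, 1, 0.5), c(0.3, 0.5, 1))
  N <- nearest_profile(K)
  expect_equal(N, rbind(c(0, 0.8, 0), c(0.8, 0, 0), c(0, 0.5, 0)))
  expect_equal(diag(N), rep(0, 3))
  expect_equal(rowSums(N != 0), rep(1, 3))

  # ties resolve to the smallest column index
  Kt <- rbind(c(1, 0.2, 0.2), c(0.2, 1, 0.2), c(0.2, 0.2, 1))
  Nt <- nearest_profile(Kt)
  expect_equal(which(Nt[1, ] != 0), 2L)
  expect_equal(which(Nt[3, ] != 0), 1L)

  expect_error(nearest_profile(matrix(1, 1, 1)), "single entity")
  Ns <- nearest_profile(K, symmetrize = TRUE)
  expect_identical(Ns, t(Ns))
  expect_equal(Ns, (N + t(N)) / 2)
})

test_that("nearest-profile prediction scales the neighbour profile by similarity", {
  K <- rbind(c(1, 0.8), c(0.8, 1))
  Y <- rbind(c(0, 0, 0), c(1, 0, 1))
  expect_equal(np_profile(K, Y, 1, "mirna"), c(0.8, 0, 0.8))

  K0 <- rbind(c(1, 0), c(0, 1))
  expect_equal(np_profile(K0, Y, 1, "mirna"), c(0, 0, 0))
  # all-zero neighbour profile stays zero
  expect_equal(np_profile(K, rbind(c(1, 1, 0), c(0, 0, 0)), 1, "mirna"),
               c(0, 0, 0))
  # disease side works over columns
  Kd <- rbind(c(1, 0.6, 0.1), c(0.6, 1, 0.1), c(0.1, 0.1, 1))
  expect_equal(np_profile(Kd, Y, 1, "disease"), 0.6 * Y[, 2])
  expect_error(np_profile(K, Y, 5, "mirna"), "not valid")
})
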