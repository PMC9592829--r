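test_that("domain fitting reproduces hand-computed toy cases", {
  # three 2-bit vectors at unit distance, k = 1: all NN distances are 1
  fps <- rbind(c(0, 0), c(1, 0), c(0, 1))
  m <- fit_ad(fps, k = 1, Z = 0.7)
  expect_equal(m$d_ave, 1)
  expect_equal(m$theta, 0)
  expect_equal(m$D_T, 1)          # any Z, since theta = 0

  # identical fingerprints collapse everything to zero
  same <- matrix(1, 4, 8)
  m0 <- fit_ad(same, k = 2, Z = 3)
  expect_equal(c(m0$d_ave, m0$theta, m0$D_T), c(0, 0, 0))

  # Z = 0 reduces the threshold to d_ave
  set.seed(2)
  fps2 <- matrix(rbinom(60, 1, 0.5), 6, 10)
  mz <- fit_ad(fps2, k = 2, Z = 0)
  expect_equal(mz$D_T, mz$d_ave)
  expect_identical(mz$D_T, mz$d_ave + mz$Z * mz$theta)

  expect_error(fit_ad(fps, k = 3, Z = 0.1), "smaller")
})

test_that("classification uses nearest-training distance with an inclusive boundary", {
  fps <- rbind(c(0, 0), c(1, 0), c(0, 1))
  m <- fit_ad(fps, k = 1, Z = 0.5)     # D_T = 1
  # a training molecule itself: distance 0, inside
  expect_equal(classify_ad(rbind(c(1, 0)), m)$domain, "ID")
  # exactly at the threshold: still inside ("exceeds" read strictly)
  at <- classify_ad(rbind(c(1, 1)), m)  # NN distance 1
  expect_equal(at$distance, 1)
  expect_equal(at$domain, "ID")
  # beyond it: outside
  far <- classify_ad(rbind(c(2, 1)), m)
  expect_equal(far$distance, sqrt(2))
  expect_equal(far$domain, "OD")
})

test_that("fit agrees with the exhaustive all-pairs oracle", {
  set.seed(5)
  for (i in 1:5) {
    n <- sample(5:10, 1)
    fps <- matrix(rbinom(n * 16, 1, 0.4), n, 16)
    for (k in 1:min(3, n - 1)) {
      want <- oracle_ad(fps, k, Z = 0.5)
      got <- fit_ad(fps, k, Z = 0.5)
      expect_lte(abs(got$d_ave - want$d_ave), 1e-12)
      expect_lte(abs(got$theta - want$theta), 1e-12)
      expect_lte(abs(got$D_T - want$D_T), 1e-12)
    }
  }
})

test_that("the threshold is monotone in Z and fitting ignores training order", {
  set.seed(6)
  fps <- matrix(rbinom(200, 1, 0.5), 20, 10)
  prev <- -Inf
  for (z in seq(0, 1, by = 0.25)) {
    m <- fit_ad(fps, k = 2, Z = z)
    expect_gte(m$D_T, prev)
    prev <- m$D_T
  }
  perm <- sample(nrow(fps))
  q <- matrix(rbinom(30, 1, 0.5), 3, 10)
  a <- classify_ad(q, fit_ad(fps, 2, 0.4))
  b <- classify_ad(q, fit_ad(fps[perm, ], 2, 0.4))
  expect_equal(a, b)
})

test_that("grid search reports monotone OD counts and subset metrics", {
  set.seed(7)
  train <- matrix(rbinom(30 * 32, 1, 0.5), 30, 32)
  test <- matrix(rbinom(10 * 32, 1, 0.5), 10, 32)
  labels <- c(rep(1, 6), rep(0, 4))
  probs <- c(runif(6, 0.6, 1), runif(4, 0, 0.4))
  grid <- ad_grid_search(train, test, k_values = 1:3,
                         Z_values = seq(0.1, 0.5, 0.2),
                         evaluator = function(rows) {
                           tibble::tibble(n = length(rows),
                                          acc = mean((probs[rows] >= 0.5) ==
                                                       labels[rows]))
                         })
  expect_equal(nrow(grid), 9L)
  for (k in 1:3) {
    sub <- grid[grid$k == k, ]
    expect_true(all(diff(sub$n_OD) <= 0))  # n_OD non-increasing in Z
  }
  # Z large enough that the threshold tops the maximal distance: no OD
  big <- ad_grid_search(train, test, k_values = 2, Z_values = 50)
  expect_equal(big$n_OD, 0L)
})

test_that("deliberately remote molecules fall outside the fitted domain", {
  bench <- make_benchmark("remote-test-AD", n_compounds = 120, seed = 3)
  ds <- bench$dataset
  fps <- compute_morgan(ds$smiles)
  model <- fit_ad(fps[ds$split == "train", ], k = 2, Z = 0.4)
  remote <- classify_ad(fps[bench$meta$remote_smiles, , drop = FALSE], model)
  expect_true(all(remote$domain == "OD"))
  expect_s3_class(glance(model), "tbl_df")
  expect_equal(glance(model)$D_T, model$D_T)
  expect_s3_class(autoplot(model), "ggplot")
})
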