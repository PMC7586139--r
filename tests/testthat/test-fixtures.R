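test_that("chainlink builds two interlocked, linearly non-separable rings", {
  ds <- make_chainlink(n = 200, noise_sd = 0, seed = 3)
  expect_equal(table(ds$labels), table(rep(1:2, each = 100)),
               ignore_attr = TRUE)
  # noiseless points lie exactly on their circles
  r1 <- ds$data[ds$labels == 1, ]
  expect_equal(sqrt(r1[, 1]^2 + r1[, 2]^2), rep(1, 100), tolerance = 1e-12)
  expect_equal(r1[, 3], rep(0, 100), tolerance = 1e-12)
  r2 <- ds$data[ds$labels == 2, ]
  expect_equal(sqrt((r2[, 1] - 1)^2 + r2[, 3]^2), rep(1, 100),
               tolerance = 1e-12)

  # no separating hyperplane exists (hard-margin linear SVM oracle)
  skip_if_not_installed("e1071")
  expect_false(oracle_linearly_separable(ds$data, ds$labels))
  # sanity: the same oracle certifies a separable control
  ctrl <- make_gaussian_mixture(k = 2, n = 100, d = 3, separation = 10,
                                seed = 3)
  expect_true(oracle_linearly_separable(ctrl$data, ctrl$labels))
})

test_that("chainlink's linear projection exhibits the cross-ring crowding", {
  # the projection failure mode the map is meant to expose: at least one
  # cross-ring pair lands closer in 2-D than the 5th percentile of
  # within-ring 2-D distances
  ds <- make_chainlink(n = 300, seed = 11)
  pr <- make_linear_projection(ds$data)
  d2 <- as.matrix(stats::dist(pr))
  same <- outer(ds$labels, ds$labels, `==`)
  diag(same) <- NA
  within <- d2[same & upper.tri(d2)]
  cross <- d2[!same & upper.tri(d2)]
  expect_lt(min(cross), stats::quantile(within, 0.05))
})

test_that("the bars-plus-outliers set has 3 clusters and exactly 4 outliers", {
  ds <- make_lsun3d_like(seed = 6)
  expect_equal(sum(ds$labels == 4), 4L)
  expect_setequal(unique(ds$labels), 1:4)
  centers <- t(sapply(1:3, function(k) colMeans(ds$data[ds$labels == k, ])))
  radii <- sapply(1:3, function(k) {
    max(sqrt(rowSums(sweep(ds$data[ds$labels == k, ], 2,
                           centers[k, ])^2)))
  })
  out <- ds$data[ds$labels == 4, , drop = FALSE]
  min_out <- min(apply(out, 1, function(o) {
    sqrt(colSums((t(centers) - o)^2))
  }))
  expect_gt(min_out, max(radii))
})

test_that("golfball points sit on the unit sphere with no distance structure", {
  ds <- make_golfball(400, seed = 2)
  expect_equal(sqrt(rowSums(ds$data^2)), rep(1, 400), tolerance = 1e-12)
  expect_equal(unique(ds$labels), 1L)
  # nearest-neighbour distances have no gap: the 95th/5th percentile ratio
  # stays near the 2-D Poisson-process value sqrt(ln(0.05)/ln(0.95)) ~ 7.6
  d <- as.matrix(stats::dist(ds$data))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  q <- stats::quantile(nn, c(0.05, 0.95))
  expect_lt(q[2] / q[1], 12)
})

test_that("gaussian mixture respects separation, sizes and the CLT bound", {
  ds <- make_gaussian_mixture(k = 3, n = 600, d = 4, separation = 7,
                              sd = 0.5, seed = 13)
  expect_equal(as.vector(table(ds$labels)), rep(200L, 3))
  centers <- t(sapply(1:3, function(k) colMeans(ds$data[ds$labels == k, ])))
  expect_true(all(stats::dist(centers) > 7 - 0.5))  # sample-mean jitter
  # per-cluster sample mean within 4*sd/sqrt(n_k) of its centre, per axis
  # (probabilistic CLT bound; fixed seed)
  for (k in 1:3) {
    dev <- abs(centers[k, ] - ds$centers[k, ])
    expect_true(all(dev < 4 * 0.5 / sqrt(200)))
  }

  one <- make_gaussian_mixture(k = 1, n = 50, d = 2, seed = 1)
  expect_equal(unique(one$labels), 1L)
  zero <- make_gaussian_mixture(k = 3, n = 90, d = 3, separation = 0,
                                sd = 1, seed = 1)
  cen0 <- t(sapply(1:3, function(k) colMeans(zero$data[zero$labels == k, ])))
  expect_true(all(stats::dist(cen0) < 1))  # centres coincide
  # k > d falls back to random placement with the separation respected
  many <- make_gaussian_mixture(k = 5, n = 250, d = 2, separation = 6,
                                sd = 0.1, seed = 4)
  cen5 <- t(sapply(1:5, function(k) colMeans(many$data[many$labels == k, ])))
  expect_true(all(stats::dist(cen5) > 6 - 0.5))
})

test_that("all generators are deterministic under a fixed seed", {
  for (gen in list(function(s) make_chainlink(100, seed = s),
                   function(s) make_lsun3d_like(seed = s),
                   function(s) make_golfball(100, seed = s),
                   function(s) make_gaussian_mixture(3, 90, 3, seed = s))) {
    a <- gen(17); b <- gen(17); c <- gen(18)
    expect_identical(a$data, b$data)
    expect_identical(a$labels, b$labels)
    expect_false(identical(a$data, c$data))
  }
})

test_that("the linear projection fixture is the leading principal plane", {
  set.seed(19)
  X <- matrix(stats::rnorm(100 * 5), 100, 5) %*% diag(c(5, 3, 1, 0.5, 0.1))
  pr <- make_linear_projection(X)
  expect_gte(stats::var(pr[, 1]), stats::var(pr[, 2]))
  # reconstruction error equals the sum of trailing eigenvalues
  Xc <- scale(X, scale = FALSE)
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)$values
  pc <- stats::prcomp(X)
  recon <- pc$x[, 1:2] %*% t(pc$rotation[, 1:2])
  err <- sum((Xc - recon)^2) / (nrow(X) - 1)
  expect_equal(err, sum(ev[3:5]), tolerance = 1e-8)
  # projection is deterministic and sign-fixed
  expect_identical(pr, make_linear_projection(X))

  # 2-D axis-aligned data comes back (centred) up to the sign convention
  X2 <- cbind(c(0, 4, 0, 4), c(0, 0, 1, 1))
  pr2 <- make_linear_projection(X2)
  expect_equal(abs(pr2[, 1]), abs(scale(X2[, 1], scale = FALSE)[, 1]))
  expect_error(make_linear_projection(matrix(1, 5, 3)), "constant")
})

test_that("dataset CSV export writes the three expected files", {
  ds <- make_gaussian_mixture(2, 40, 3, seed = 5)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("data.csv", "proj.csv", "labels.csv")))))
  back <- readr::read_csv(file.path(dir, "data.csv"), show_col_types = FALSE)
  expect_equal(as.matrix(back), ds$data, ignore_attr = TRUE,
               tolerance = 1e-12)
  lb <- readr::read_csv(file.path(dir, "labels.csv"), show_col_types = FALSE)
  expect_equal(lb$label, ds$labels)
})
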