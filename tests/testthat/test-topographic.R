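test_that("robust normalization anchors the 1st/99th percentiles at 0/1", {
  # integers 1..100 on a 10x10 grid; independent percentile routine agrees
  H <- matrix(1:100, 10, 10)
  norm <- robust_normalize(H)
  q01 <- oracle_percentile(1:100, 0.01)
  q99 <- oracle_percentile(1:100, 0.99)
  expect_equal(attr(norm, "q01"), q01)  # 1.99
  expect_equal(attr(norm, "q99"), q99)  # 99.01
  expect_equal(q01, 1.99)
  expect_equal(q99, 99.01)
  expect_equal(norm[H == 50], (50 - 1.99) / 97.02, tolerance = 1e-10)
  expect_true(all(norm >= 0 & norm <= 1))
  # values at/below q01 clamp to 0, at/above q99 clamp to 1
  expect_equal(norm[H == 1], 0)
  expect_equal(norm[H == 100], 1)

  # constant heights -> all-zero map
  expect_true(all(robust_normalize(matrix(4, 3, 3)) == 0))
  expect_error(robust_normalize(matrix(numeric(0), 0, 0)), "at least one")
})

test_that("interval count is the clamped percentile ratio", {
  expect_equal(interval_count(1, 20), 20L)
  expect_equal(interval_count(2, 21), 11L)     # ceiling of 10.5
  expect_equal(interval_count(5, 5), 8L)       # degenerate ratio -> floor clamp
  expect_equal(interval_count(0, 1), 64L)      # zero q01 -> ceiling clamp
  expect_equal(interval_count(1, 1000), 64L)
  expect_equal(interval_count(0, 0), 8L)
})

test_that("colorize bins uniformly with a monotone class and CIELab ramp", {
  m <- matrix(c(0, 0.124, 0.126, 0.5, 0.999, 1), 2, 3)
  col <- colorize(m, n_intervals = 8)
  expect_equal(col$class[m == 0], 1L)
  expect_equal(col$class[m == 1], 8L)
  expect_equal(col$class[m == 0.124], 1L)
  expect_equal(col$class[m == 0.126], 2L)
  # class is non-decreasing in height
  v <- seq(0, 1, by = 0.01)
  cl <- colorize(matrix(v, 1), n_intervals = 13)$class
  expect_true(all(diff(as.vector(cl)) >= 0))
  expect_equal(length(col$colors), 8L)

  # two-level map: exactly the first and last class survive
  two <- colorize(matrix(c(0, 1), 1), n_intervals = 8)
  expect_setequal(as.vector(two$class), c(1L, 8L))

  # ramp endpoints: sea blue at the bottom, white peaks at the top
  ramp <- cielab_ramp(hypsometric_scale(), c(0, 1))
  rgb0 <- grDevices::col2rgb(ramp[1])
  expect_gt(rgb0["blue", 1], rgb0["red", 1])
  expect_equal(as.vector(grDevices::col2rgb(ramp[2])), c(255, 255, 255),
               tolerance = 2)

  # all-zero map: a single sea class everywhere
  flat <- colorize(matrix(0, 4, 4), n_intervals = 8)
  expect_true(all(flat$class == 1L))
})

test_that("contours outline class regions", {
  # uniform class array -> nothing to outline
  expect_length(extract_contours(matrix(1L, 5, 5)), 0)

  # single differing cell -> one closed loop around it
  m <- matrix(1L, 5, 5); m[3, 3] <- 2L
  ct <- extract_contours(m)
  expect_length(ct, 1)
  expect_true(attr(ct[[1]], "closed"))
  expect_equal(nrow(ct[[1]]), 5L)  # 4 corners + repeated start
  expect_true(all(ct[[1]]$x %in% c(2.5, 3.5) & ct[[1]]$y %in% c(2.5, 3.5)))

  # half/half split -> one separating line across the array
  m2 <- rbind(matrix(1L, 3, 6), matrix(2L, 3, 6))
  ct2 <- extract_contours(m2)
  expect_length(ct2, 1)
  expect_true(all(ct2[[1]]$y == 3.5))
  expect_equal(range(ct2[[1]]$x), c(0.5, 6.5))
})

test_that("toroidal tiling is an exact 2x2 periodic replication", {
  set.seed(5)
  M <- matrix(stats::rnorm(12), 3, 4)
  Tl <- tile_toroidal(M)
  expect_equal(dim(Tl), c(6L, 8L))
  for (probe in 1:20) {
    i <- sample(3, 1); j <- sample(4, 1)
    expect_identical(Tl[i, j], Tl[i + 3, j])
    expect_identical(Tl[i, j], Tl[i, j + 4])
    expect_identical(Tl[i, j], Tl[i + 3, j + 4])
  }
})

test_that("island cut maximises border height and keeps valleys intact", {
  # flat map: first-offset tie-break
  flat <- cut_island(matrix(0, 6, 6))
  expect_equal(unname(flat$offset), c(0L, 0L))

  # a valley wrapped across the seam is re-centred away from the border
  M <- matrix(1, 8, 8)
  valley <- rbind(c(1, 1), c(1, 8), c(8, 1), c(8, 8))  # low corners = one torus valley
  M[valley] <- 0
  isl <- cut_island(M)
  # wherever the window lands, the valley's four cells must be contiguous
  # and off the border
  low <- which(isl$normalized == 0, arr.ind = TRUE)
  expect_equal(nrow(low), 4L)
  expect_true(all(low > 1 & low < 8))
  expect_lte(max(dist(low)), sqrt(2))

  # exhaustive-search oracle: returned offset attains the global maximum
  set.seed(33)
  M2 <- matrix(stats::runif(7 * 9), 7, 9)
  isl2 <- cut_island(M2)
  border_sum <- function(M, dl, dc) {
    sh <- M[(seq_len(nrow(M)) - 1 + dl) %% nrow(M) + 1,
            (seq_len(ncol(M)) - 1 + dc) %% ncol(M) + 1]
    sum(sh[1, ]) + sum(sh[nrow(M), ]) + sum(sh[, 1]) + sum(sh[, ncol(M)]) -
      sh[1, 1] - sh[1, ncol(M)] - sh[nrow(M), 1] - sh[nrow(M), ncol(M)]
  }
  all_obj <- outer(0:6, 0:8, Vectorize(function(dl, dc) border_sum(M2, dl, dc)))
  expect_equal(isl2$border_height, max(all_obj), tolerance = 1e-12)
  # dominance over random offsets
  for (r in 1:100) {
    expect_gte(isl2$border_height + 1e-12,
               border_sum(M2, sample(0:6, 1), sample(0:8, 1)))
  }
})

test_that("valley counting reads clusters off the thresholded torus", {
  lat <- esom_lattice(10, 10)
  # two anchor points pin the bounding box to the lattice corners; four
  # more land at interior cells (3,3), (4,4), (7,7), (8,8)
  line_to_y <- function(l) 1 - (l - 1) / 9
  col_to_x <- function(cc) (cc - 1) / 9
  pr <- cbind(c(0, 1, col_to_x(c(3, 4, 7, 8))),
              c(0, 1, line_to_y(c(3, 4, 7, 8))))
  bm <- map_projection_to_grid(pr, lat)
  expect_equal(bm$positions$line[3:6], c(3L, 4L, 7L, 8L))
  expect_equal(bm$positions$column[3:6], c(3L, 4L, 7L, 8L))

  # all heights above sea level -> no valleys
  expect_equal(count_valleys(matrix(0.9, 10, 10), bm), 0L)
  # one uniform basin containing the points -> 1
  expect_equal(count_valleys(matrix(0.1, 10, 10), bm), 1L)

  # two interior basins separated by a ridge, two points each -> 2
  M <- matrix(1, 10, 10)
  M[2:4, 2:4] <- 0; M[7:9, 7:9] <- 0
  expect_equal(count_valleys(M, bm), 2L)
  # low pockets without any projected point are not valleys
  M[1:2, 6] <- 0
  expect_equal(count_valleys(M, bm), 2L)
  # basins below the minimum point share are ignored
  expect_equal(count_valleys(M, bm, min_share = 0.5), 0L)  # needs 3 of 6
  expect_equal(count_valleys(M, bm, min_share = 0.33), 2L) # needs 2 of 6
  # valleys connect across the torus seam: the four corner cells are one
  # 2x2 toroidal basin holding the two anchor points
  M2 <- matrix(1, 10, 10)
  M2[c(1, 10), c(1, 10)] <- 0
  expect_equal(count_valleys(M2, bm), 1L)
})

test_that("the map object wires the stages together consistently", {
  set.seed(44)
  X <- matrix(stats::rnorm(60 * 3), 60, 3)
  pr <- cbind(stats::rnorm(60), stats::rnorm(60))
  lat <- esom_lattice(12, 14)
  bm <- map_projection_to_grid(pr, lat)
  g <- train_sesom(X, bm, lat, sesom_config(seed = 3))
  tm <- topographic_map(compute_uheights(g), bm)

  expect_s3_class(tm, "topographic_map")
  expect_equal(dim(tm$tiled$heights), c(24L, 28L))
  expect_equal(tm$n_intervals, interval_count(tm$q01, tm$q99))
  expect_true(all(tm$class >= 1 & tm$class <= tm$n_intervals))
  # colour class monotone in normalized height
  ord <- order(as.vector(tm$normalized))
  expect_true(all(diff(as.vector(tm$class)[ord]) >= 0))

  td <- tidy(tm)
  expect_equal(nrow(td), 12L * 14L)
  gl <- glance(tm)
  expect_equal(gl$n_neurons, 168L)
  expect_equal(gl$n_valleys, tm$n_valleys)

  p <- autoplot(tm)
  expect_s3_class(p, "ggplot")
  f <- withr::local_tempfile(fileext = ".png")
  render_topographic_map(tm, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
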