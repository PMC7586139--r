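# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals they check.

# minimum-image distance by brute force over all 4 image offsets per axis
oracle_toroidal_distance <- function(a, b, L, C) {
  best <- Inf
  for (ol in c(-L, 0, L)) {
    for (oc in c(-C, 0, C)) {
      d <- sqrt((a[1] - b[1] + ol)^2 + (a[2] - b[2] + oc)^2)
      best <- min(best, d)
    }
  }
  best
}

# naive double loop over cells and their 8 wrapped neighbours
oracle_umatrix <- function(W, L, C, metric = "euclidean") {
  U <- matrix(0, L, C)
  for (l in 1:L) {
    for (cc in 1:C) {
      k <- (l - 1) * C + cc
      acc <- 0
      for (dl in -1:1) {
        for (dc in -1:1) {
          if (dl == 0 && dc == 0) next
          nl <- ((l - 1 + dl) %% L) + 1
          ncc <- ((cc - 1 + dc) %% C) + 1
          kn <- (nl - 1) * C + ncc
          diff <- W[k, ] - W[kn, ]
          acc <- acc + if (metric == "euclidean") sqrt(sum(diff^2))
                       else sum(abs(diff))
        }
      }
      U[l, cc] <- acc / 8
    }
  }
  U
}

# exhaustive scan argmin with first-cell (lexicographic) tie-break
oracle_bmu <- function(x, W, L, C) {
  d <- apply(W, 1, function(w) sum((x - w)^2))
  k <- which.min(d)
  c(((k - 1) %/% C) + 1, ((k - 1) %% C) + 1)
}

# step-by-step manual simulation of the training loop, built from the
# exported single-step operations; RNG use mirrors the documented procedure
# (seeded init sample, then one shuffled order per radius step)
oracle_train <- function(X, bmus, lattice, seed, metric = "euclidean") {
  n <- nrow(X)
  nc <- lattice$L * lattice$C
  members <- cell_members(bmus)
  means <- t(vapply(members$points,
                    function(idx) colMeans(X[idx, , drop = FALSE]),
                    numeric(ncol(X))))
  withr::with_seed(seed, {
    W <- X[sample.int(n, nc, replace = TRUE), , drop = FALSE]
    W[members$cell, ] <- means
    g <- esom_grid(W, lattice)
    for (R in cooling_schedule(lattice)) {
      ord <- sample.int(n)
      for (j in ord) {
        bmu <- find_bmu(X[j, ], g, metric)
        g <- update_neighborhood(g, bmu, X[j, ], R)
      }
      g$weights[members$cell, ] <- means
    }
    g
  })
}

# quantile-anchored normalization recomputed with an independent percentile
# routine (direct linear interpolation of sorted values)
oracle_percentile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# hard-margin linear SVM as the linear-separability oracle: training error 0
# iff a separating hyperplane exists (up to numerics)
oracle_linearly_separable <- function(X, y) {
  fit <- e1071::svm(x = X, y = factor(y), kernel = "linear",
                    cost = 1e6, scale = FALSE)
  all(stats::predict(fit, X) == factor(y))
}
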