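test_that("class-weight and positivity invariants are enforced", {
  expect_error(gaussian_model(matrix(0, 2, 3), -1, 1), "widths")
  d_bad <- matrix(c(0.5, 0.2), 2, 2)
  expect_error(gaussian_model(matrix(0, 2, 3), c(1, 2), c(1, 1), d_bad),
               "unit column sums")
  m <- gaussian_model(matrix(0, 2, 3), c(1, 2), c(1, 1))
  expect_equal(colSums(m$class_weights), c(1, 1))
})

test_that("render_density matches a brute-force triple loop", {
  m <- toy_model(3, seed = 42, width = 2.5, amp = 1.3, extent = 6)
  v <- render_density(m, 8, 2.0)
  oracle <- array(0, rep(8, 3))
  for (ix in 0:7) for (iy in 0:7) for (iz in 0:7) {
    x <- (c(ix, iy, iz) - 4) * 2.0
    oracle[ix + 1, iy + 1, iz + 1] <-
      sum(1.3 * exp(-colSums((t(m$centers) - x)^2) / 2.5^2))
  }
  expect_lt(max(abs(v$data - oracle)) / max(oracle), 1e-6)
})

test_that("rendering is linear in the amplitudes", {
  m <- toy_model(4, seed = 3)
  v1 <- render_density(m, 12, 2.5)
  m$amplitudes <- m$amplitudes * 2
  v2 <- render_density(m, 12, 2.5)
  expect_equal(v2$data, 2 * v1$data, tolerance = 1e-12)
})

test_that("a single Gaussian renders its amplitude at its centre voxel", {
  # centre placed exactly on a voxel centre: value there is a * exp(0)
  m <- gaussian_model(matrix(c(2, -4, 6), 1, 3), widths = 3,
                      amplitudes = 1.7)
  v <- render_density(m, 16, 2.0)
  idx <- c(2, -4, 6) / 2 + 8 + 1
  expect_equal(v$data[idx[1], idx[2], idx[3]], 1.7, tolerance = 1e-12)
})

test_that("initialize_from_map is deterministic and respects support", {
  data <- array(1, rep(16, 3))
  v <- volume_grid(data, 2)
  m1 <- initialize_from_map(v, 0, 10, seed = 3)
  m2 <- initialize_from_map(v, 0, 10, seed = 3)
  expect_equal(m1$centers, m2$centers)
  expect_true(all(abs(m1$centers) <= 17))
  # positive only in one octant
  data2 <- array(0, rep(16, 3))
  data2[1:8, 1:8, 1:8] <- 1
  m3 <- initialize_from_map(volume_grid(data2, 2), 0, 10, seed = 4)
  expect_true(all(m3$centers < 0))
  # enclosing voxel above threshold
  vox <- floor(m3$centers / 2 + 8) + 1
  expect_true(all(data2[vox] > 0))
  expect_error(initialize_from_map(volume_grid(data2, 2), 1.5, 10, seed = 1),
               "0 voxels")
})

test_that("initialization matches the map norm on a smooth blob", {
  blob <- toy_model(1, seed = 8, width = 8, amp = 2, extent = 2)
  vol <- render_density(blob, 24, 2)
  m <- initialize_from_map(vol, 0.05 * max(vol$data), 40, seed = 5)
  rendered <- render_density(m, 24, 2)
  ratio <- sqrt(sum(rendered$data^2)) / sqrt(sum(vol$data^2))
  expect_gte(ratio, 0.99)
  expect_lte(ratio, 1.01)
})

test_that("neighbour graph matches analytic unit-square case", {
  pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0)
  g <- build_neighbor_graph(pts)
  expect_equal(g$c_mean, 1)
  expect_equal(nrow(g$edges), 6)  # sqrt(2) < 1.5 connects all pairs
  expect_equal(g$source, "knn_heuristic")
})

test_that("neighbour graph matches an O(N^2) brute-force oracle", {
  brute <- function(pts) {
    dm <- as.matrix(dist(pts)); diag(dm) <- Inf
    nn <- matrix(0L, 0, 2)
    for (i in seq_len(nrow(pts))) {
      for (j in order(dm[i, ])[1:2]) nn <- rbind(nn, sort(c(i, j)))
    }
    nn <- unique(nn)
    cm <- mean(dm[nn])
    e <- which(dm < 1.5 * cm & upper.tri(dm), arr.ind = TRUE)
    list(c_mean = cm, edges = e[order(e[, 1], e[, 2]), , drop = FALSE])
  }
  # collinear points
  pts3 <- cbind(c(0, 1, 10), 0, 0)
  g3 <- build_neighbor_graph(pts3)
  b3 <- brute(pts3)
  expect_equal(g3$c_mean, b3$c_mean)
  expect_equal(unname(g3$edges), unname(cbind(b3$edges[, 1], b3$edges[, 2])))
  # random sets
  for (seed in 1:20) {
    set.seed(seed)
    pts <- matrix(runif(150, 0, 40), 50)
    g <- build_neighbor_graph(pts)
    b <- brute(pts)
    expect_equal(g$c_mean, b$c_mean)
    expect_equal(unname(g$edges), unname(cbind(b$edges[, 1], b$edges[, 2])))
  }
})

test_that("neighbour graph is permutation-equivariant", {
  set.seed(9)
  pts <- matrix(runif(90, 0, 30), 30)
  g <- build_neighbor_graph(pts)
  perm <- sample(30)
  gp <- build_neighbor_graph(pts[perm, ])
  # map permuted edge labels back
  inv <- order(perm)
  remapped <- cbind(pmin(perm[gp$edges[, 1]], perm[gp$edges[, 2]]),
                    pmax(perm[gp$edges[, 1]], perm[gp$edges[, 2]]))
  remapped <- remapped[order(remapped[, 1], remapped[, 2]), ]
  expect_equal(unname(remapped), unname(g$edges))
  expect_equal(gp$c_mean, g$c_mean)
})

test_that("model tables round-trip through the plain-text format", {
  m <- toy_model(6, seed = 11)
  g <- build_neighbor_graph(m$centers)
  stem <- file.path(withr::local_tempdir(), "model")
  write_gaussian_model(m, stem, g)
  m2 <- read_gaussian_model(stem)
  expect_equal(m2$centers, m$centers, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(m2$widths, m$widths)
  expect_equal(m2$amplitudes, m$amplitudes)
})
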