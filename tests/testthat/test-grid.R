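test_that("single-square partition summarizes its pixels", {
  f <- raster_field(30, 30, function(x, y) rep(0.4, length(x)))
  g <- grid_partition(f, grid_spec(30, extent = c(30, 30)))
  expect_equal(nrow(g), 1)
  expect_equal(g$director_angle, 0.4, tolerance = 1e-12)
  expect_equal(g$oop, 1, tolerance = 1e-12)
  expect_equal(g$density, 900 / 900)
  expect_equal(g$n_pixels, 900L)
})

test_that("block-constant fields give block directors", {
  f <- raster_field(60, 30, function(x, y) ifelse(x < 30, 0, pi / 2))
  g <- grid_partition(f, grid_spec(30, extent = c(60, 30)))
  expect_equal(nrow(g), 2)
  expect_equal(g$director_angle, c(0, pi / 2), tolerance = 1e-12)
  expect_equal(g$oop, c(1, 1), tolerance = 1e-12)
})

test_that("partial edge squares keep their clipped area", {
  f <- raster_field(40, 30, function(x, y) rep(1, length(x)))
  g <- grid_partition(f, grid_spec(30, extent = c(40, 30)))
  expect_equal(g$area, c(900, 300))
  # edge square: 10 x 30 pixels over a 10 x 30 clipped area
  expect_equal(g$density, c(1, 1))
})

test_that("empty squares carry zero density and undefined directors", {
  f <- orientation_field(rep(0.3, 10), coords = cbind(seq(0, 9), rep(2, 10)))
  g <- grid_partition(f, grid_spec(10, extent = c(10, 30)))
  expect_equal(g$n_pixels, c(10L, 0L, 0L))
  expect_equal(g$density[1], 0.1)
  expect_true(all(is.na(g$director_angle[2:3])))
  expect_true(all(g$density[2:3] == 0))
})

test_that("out-of-extent coordinates are rejected with offenders listed", {
  f <- orientation_field(c(0.1, 0.2), coords = rbind(c(5, 5), c(50, 5)))
  expect_error(grid_partition(f, grid_spec(10, extent = c(20, 20))),
               "outside the extent")
})

test_that("per-square grid summaries match direct tensor computation", {
  set.seed(44)
  f <- raster_field(60, 60, function(x, y) stats::runif(length(x), 0, pi))
  g <- grid_partition(f, grid_spec(20, extent = c(60, 60)))
  expect_equal(nrow(g), 9)
  # recompute one square directly from its pixels
  sq <- f$coords[, 1] < 20 & f$coords[, 2] < 20
  o <- oop(f$angles[sq])
  expect_equal(g$oop[1], o$oop, tolerance = 1e-12)
  expect_lt(axial_dist(g$director_angle[1],
                       atan2(o$director[2], o$director[1])), 1e-12)
})

test_that("grid weights multiply order and density and null absent squares", {
  fp <- raster_field(20, 10, function(x, y) rep(0.2, length(x)))
  # Q occupies only the left square
  fq <- orientation_field(rep(1.2, 50),
                          coords = cbind(rep(0:9, 5), rep(0:4, each = 10)))
  spec <- grid_spec(10, extent = c(20, 10))
  w <- grid_weights(grid_partition(fp, spec), grid_partition(fq, spec))
  expect_equal(w$weight[1], 1 * 1 * 1 * 0.5)
  expect_equal(w$weight[2], 0)  # Q absent
  # direct product example
  expect_equal(0.5 * 0.8 * 1.0 * 0.5, 0.2)
})

test_that("mismatched grid geometries are rejected", {
  f <- raster_field(20, 20, function(x, y) rep(0.2, length(x)))
  g1 <- grid_partition(f, grid_spec(10, extent = c(20, 20)))
  g2 <- grid_partition(f, grid_spec(20, extent = c(20, 20)))
  expect_error(grid_weights(g1, g2), "incompatible")
})

test_that("weighted COOP reduces to the pixel COOP at one pixel per square", {
  set.seed(50)
  n <- 12
  g <- expand.grid(x = seq_len(n) - 1L, y = seq_len(n) - 1L)
  p_ang <- stats::runif(n^2, 0, pi)
  q_ang <- stats::runif(n^2, 0, pi)
  fp <- orientation_field(p_ang, coords = cbind(g$x + 0.5, g$y + 0.5))
  fq <- orientation_field(q_ang, coords = cbind(g$x + 0.5, g$y + 0.5))
  spec <- grid_spec(1, extent = c(n, n))
  w <- grid_weights(grid_partition(fp, spec), grid_partition(fq, spec))
  expect_equal(w$weight, rep(1, n^2))  # single vector: OOP 1, density 1
  expect_equal(weighted_coop(w)$coop, coop(p_ang, q_ang)$coop,
               tolerance = 1e-12)
})

test_that("down-weighting a discordant region drives the COOP to that of the rest", {
  # half the squares parallel, half perpendicular: equal weights cancel
  p <- rep(0.3, 8)
  q <- c(rep(0.3, 4), rep(0.3 + pi / 2, 4))
  equal <- coop(paired_field(p, q, weights = rep(1, 8)))
  expect_lt(equal$coop, 1e-12)
  # as the perpendicular half loses weight the parallel signal dominates
  damped <- coop(paired_field(p, q, weights = c(rep(1, 4), rep(1e-9, 4))))
  expect_equal(damped$coop, 1, tolerance = 1e-6)
})

test_that("removing zero-weight squares changes nothing", {
  set.seed(61)
  k <- 20
  dp <- stats::runif(k, 0, pi)
  dq <- stats::runif(k, 0, pi)
  w <- c(stats::runif(k - 5, 0.1, 1), rep(0, 5))
  full <- coop(paired_field(dp, dq, weights = w))
  trimmed <- coop(paired_field(dp[w > 0], dq[w > 0], weights = w[w > 0]))
  expect_equal(full$coop, trimmed$coop, tolerance = 1e-10)
})

test_that("grid origin shift leaves a constant field's COOP unchanged", {
  f <- raster_field(30, 30, function(x, y) rep(0.8, length(x)))
  fq <- raster_field(30, 30, function(x, y) rep(0.8 + pi / 3, length(x)))
  r1 <- weighted_coop(grid_weights(
    grid_partition(f, grid_spec(10, extent = c(30, 30))),
    grid_partition(fq, grid_spec(10, extent = c(30, 30)))))
  r2 <- weighted_coop(grid_weights(
    grid_partition(f, grid_spec(10, extent = c(37, 33), origin = c(-7, -3))),
    grid_partition(fq, grid_spec(10, extent = c(37, 33), origin = c(-7, -3)))))
  expect_equal(r1$coop, r2$coop, tolerance = 1e-12)
  expect_equal(r1$coop, 1, tolerance = 1e-12)
})

test_that("consistency matrices are symmetric with unit diagonal", {
  set.seed(71)
  spec <- grid_spec(10, extent = c(50, 50))
  base <- raster_field(50, 50, function(x, y) {
    atan2(y - 25, x - 25) / 2
  })
  summaries <- lapply(1:4, function(i) {
    noisy <- orientation_field(base$angles + stats::rnorm(2500, 0, 0.2),
                               coords = base$coords,
                               label = paste0("sample", i))
    grid_partition(noisy, spec)
  })
  m <- consistency_matrix(summaries)
  expect_equal(diag(m), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_true(all(m >= -1e-12 & m <= 1 + 1e-12))
  # noisy copies of one field stay strongly consistent
  expect_gt(attr(m, "off_diagonal_mean"), 0.5)
})

test_that("multi-sample angle statistics pick the wrap-safe branch", {
  deg <- function(d) c(cos(d * pi / 180), sin(d * pi / 180))
  # identical directors: zero spread
  s <- multi_sample_angle_stats(list(deg(40), deg(40), deg(40)))
  expect_equal(s$theta0_mean, 40 * pi / 180, tolerance = 1e-12)
  expect_equal(s$theta0_sd, 0, tolerance = 1e-12)
  # near-vertical: arccos branch keeps 80/90/100 contiguous
  s <- multi_sample_angle_stats(list(deg(80), deg(90), deg(100)))
  expect_equal(s$theta0_mean, pi / 2, tolerance = 1e-9)
  # near-horizontal: arcsin branch keeps -5/0/5 contiguous
  s <- multi_sample_angle_stats(list(deg(-5), deg(0), deg(5)))
  expect_equal(s$theta0_mean, 0, tolerance = 1e-9)
  expect_equal(s$theta0_sd, 5 * pi / 180, tolerance = 1e-9)
  # incoherent directors warn
  expect_warning(
    multi_sample_angle_stats(list(deg(0), deg(45), deg(90), deg(135))),
    "unstable")
})

test_that("grid-level analysis recovers the correlated bound", {
  set.seed(83)
  npx <- 90000L
  ext <- 300
  coords <- cbind(stats::runif(npx, 0, ext), stats::runif(npx, 0, ext))
  p_ang <- stats::rnorm(npx, pi / 2, 0.35)
  q_ang <- p_ang + stats::rnorm(npx, 0, 0.45)
  spec <- grid_spec(10, extent = c(ext, ext))
  gp <- grid_partition(orientation_field(p_ang, coords = coords), spec)
  gq <- grid_partition(orientation_field(q_ang, coords = coords), spec)
  r <- weighted_coop(grid_weights(gp, gq))
  # per-square mean noise makes Q's directors P's plus independent noise,
  # so the grid-level COOP tracks min/max of the grid-level OOPs
  expect_lt(abs(r$coop - r$coop_c), 3 / sqrt(900))
  expect_equal(r$regime, "normal")
})
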