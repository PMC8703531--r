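test_that("map statistics match hand values and a two-pass oracle", {
  m <- density_map(array(c(0, 0, 0, 4), dim = c(2, 2, 1)), 1)
  s <- map_stats(m)
  expect_equal(s$mean, 1)
  expect_equal(s$sd, sqrt(3))

  cm <- density_map(array(2.5, dim = c(3, 3, 3)), 1)
  expect_equal(map_stats(cm), list(mean = 2.5, sd = 0))

  r <- random_map(c(32, 32, 32), seed = 11)
  v <- as.numeric(r$values)
  mu <- sum(v) / length(v)                       # two-pass oracle
  sd2 <- sum((v - mu)^2) / length(v)
  s <- map_stats(r)
  expect_equal(s$mean, mu, tolerance = 1e-12)
  expect_equal(s$sd, sqrt(sd2), tolerance = 1e-12)
})

test_that("sd_threshold is mean + k*sd and affine-equivariant", {
  cm <- density_map(array(3, dim = c(4, 4, 4)), 1)
  expect_equal(sd_threshold(cm, 7), 3)
  expect_equal(sd_threshold(cm, 0), 3)
  r <- random_map(seed = 2)
  s <- map_stats(r)
  expect_equal(sd_threshold(r, 7), s$mean + 7 * s$sd)
  a <- 2.7
  r2 <- r; r2$values <- a * r$values
  expect_equal(sd_threshold(r2, 4) - map_stats(r2)$mean,
               a * (sd_threshold(r, 4) - s$mean), tolerance = 1e-9)
})

test_that("enclosed volume matches an exhaustive loop oracle", {
  r <- random_map(c(16, 16, 16), voxel = 1.5, seed = 4)
  expect_equal(enclosed_volume(r, min(r$values) - 1)$enclosed_volume,
               total_volume(r))
  expect_equal(enclosed_volume(r, max(r$values) + 1)$voxel_count, 0L)
  for (lev in c(-1, 0, 0.5, 2)) {
    n <- 0L
    for (v in as.numeric(r$values)) if (v >= lev) n <- n + 1L
    expect_identical(enclosed_volume(r, lev)$voxel_count, n)
  }
})

test_that("threshold_for_volume is the order statistic it claims to be", {
  set.seed(8)
  vals <- array(sample(seq(0, 1, length.out = 4 * 4 * 4)), dim = c(4, 4, 4))
  m <- density_map(vals, 2)                      # voxel volume 8
  res <- threshold_for_volume(m, 5 * 8)
  expect_equal(res$level, sort(as.numeric(vals), decreasing = TRUE)[5])
  expect_identical(res$voxel_count, 5L)
  expect_error(threshold_for_volume(m, 0), "target_volume")
  expect_error(threshold_for_volume(m, total_volume(m) * 2), "target_volume")
})

test_that("the deposited display-volume convention is reproducible on a synthetic transporter map", {
  sc <- build_scene(make_toy_transporter(60, seed = 1), seed = 1)
  target <- 153000                               # the deposited-map display volume
  expect_gt(total_volume(sc$map), target)        # box holds the envelope at 1.043 A
  vox <- voxel_volume(sc$map)
  res <- threshold_for_volume(sc$map, target)
  m_expect <- round(target / vox)
  lev <- sort(as.numeric(sc$map$values), decreasing = TRUE)[m_expect]  # full-sort oracle
  expect_equal(res$level, lev)
  expect_identical(res$voxel_count, as.integer(m_expect))
  expect_lte(abs(res$enclosed_volume - target), vox)
})

test_that("threshold level is monotone non-increasing in target volume", {
  r <- random_map(c(20, 20, 20), seed = 5)
  targets <- seq(0.05, 0.95, length.out = 20) * total_volume(r)
  levels <- vapply(targets, function(t) threshold_for_volume(r, t)$level,
                   numeric(1))
  expect_true(all(diff(levels) <= 1e-12))
})

test_that("FSC limits: identity gives 1, sign flip gives -1, symmetric args", {
  m <- random_map(c(24, 24, 24), seed = 21)
  cur <- fsc_curve(m, m)
  expect_true(all(abs(cur$fsc - 1) < 1e-9))
  neg <- m; neg$values <- -m$values
  cur2 <- fsc_curve(m, neg)
  expect_true(all(abs(cur2$fsc + 1) < 1e-9))
  m2 <- random_map(c(24, 24, 24), seed = 22)
  expect_equal(fsc_curve(m, m2)$fsc, fsc_curve(m2, m)$fsc, tolerance = 1e-12)
  bad <- random_map(c(20, 24, 24), seed = 23)
  expect_error(fsc_curve(m, bad), "mismatch")
})

test_that("independent noise maps decorrelate per shell", {
  absfsc <- c()
  min_n <- Inf
  for (seed in 1:10) {
    a <- random_map(c(32, 32, 32), seed = 100 + seed)
    b <- random_map(c(32, 32, 32), seed = 200 + seed)
    cur <- fsc_curve(a, b)
    keep <- cur$shell_radius > 0
    absfsc <- c(absfsc, abs(cur$fsc[keep]))
    min_n <- min(min_n, cur$n_voxels[keep])
  }
  expect_lt(mean(absfsc), 3 / sqrt(min_n))
})

test_that("resolution read-out interpolates the first downward crossing", {
  cur <- data.frame(shell_radius = 0:4,
                    frequency = c(0, 0.05, 0.10, 0.15, 0.20),
                    fsc = c(1, 0.9, 0.5, 0.143, 0.05),
                    n_voxels = rep(100L, 5))
  r <- resolution_at(cur, 0.143)                 # exact hit at a shell center
  expect_equal(r$resolution, 1 / 0.15)
  expect_false(r$nyquist_limited)
  cur$fsc <- c(1, 0.9, 0.6, 0.3, 0.1)            # hand-solved interpolation:
  r2 <- resolution_at(cur, 0.143)                # 0.15 + 0.05*(0.3-0.143)/0.2
  expect_equal(r2$frequency, 0.15 + 0.05 * (0.3 - 0.143) / (0.3 - 0.1))
  cur$fsc <- rep(1, 5)
  r3 <- resolution_at(cur, 0.143)
  expect_true(r3$nyquist_limited)
  expect_equal(r3$resolution, 1 / 0.2)
  expect_error(resolution_at(cur, 1.2), "criterion")
})

test_that("FSC curve exports as the stated TSV layout", {
  m <- random_map(c(16, 16, 16), seed = 31)
  cur <- fsc_curve(m, m)
  p <- tempfile(fileext = ".tsv")
  write_fsc_tsv(cur, p)
  back <- read.delim(p)
  expect_identical(names(back), c("shell_center_invA", "fsc", "n_voxels"))
  expect_equal(back$fsc, cur$fsc)
})
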