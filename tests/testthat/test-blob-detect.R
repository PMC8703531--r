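test_that("masking removes exactly the voxels a distance oracle predicts", {
  m <- random_map(c(12, 12, 12), voxel = 1, seed = 6)
  m$values <- abs(m$values) + 1                  # all positive so min is informative
  model <- trace_model(rbind(c(5, 5, 5), c(5, 5, 5.001)))
  radius <- 1.5
  masked <- mask_modeled_density(m, model, radius)
  # brute-force oracle over all voxel centers
  cnt <- 0
  for (k in 0:11) for (j in 0:11) for (i in 0:11) {
    d <- sqrt(sum((c(i, j, k) - c(5, 5, 5))^2))
    d2 <- sqrt(sum((c(i, j, k) - c(5, 5, 5.001))^2))
    if (min(d, d2) <= radius) cnt <- cnt + 1
  }
  expect_equal(attr(masked, "masked_voxels"), cnt)
  again <- mask_modeled_density(masked, model, radius)
  expect_equal(again$values, masked$values)      # idempotent

  far <- trace_model(rbind(c(500, 500, 500), c(501, 500, 500)))
  expect_equal(mask_modeled_density(m, far, 3)$values, m$values)
})

test_that("connectivity 6 vs 26 splits or joins diagonal neighbours", {
  a <- array(0, dim = c(7, 5, 5))
  a[2, 2, 2] <- 1; a[4, 2, 2] <- 1               # gap of one voxel along x
  m <- density_map(a, 1)
  expect_equal(length(find_blobs(m, 0.5, 6, 1)), 2L)
  expect_equal(length(find_blobs(m, 0.5, 26, 1)), 2L)  # still a full gap
  b <- array(0, dim = c(7, 5, 5))
  b[2, 2, 2] <- 1; b[3, 3, 3] <- 1               # diagonal adjacency
  m2 <- density_map(b, 1)
  expect_equal(length(find_blobs(m2, 0.5, 6, 1)), 2L)
  expect_equal(length(find_blobs(m2, 0.5, 26, 1)), 1L)
})

test_that("blob shape metrics match a PCA oracle on an axis-aligned rod", {
  a <- array(0, dim = c(27, 9, 9))
  a[4:24, 4:6, 4:6] <- 1                         # 21 x 3 x 3 voxel rod
  m <- density_map(a, 1)
  blobs <- find_blobs(m, 0.5, 26, 1)
  expect_equal(length(blobs), 1L)
  b <- blobs[[1]]
  expect_identical(b$voxel_count, 21L * 9L)
  # PCA oracle on the voxel-center coordinates
  idx <- which(a == 1, arr.ind = TRUE) - 1
  ev <- eigen(stats::cov(idx) * (nrow(idx) - 1) / nrow(idx))$values
  expect_equal(b$principal_extents, 2 * sqrt(ev), tolerance = 1e-6)
  expect_equal(b$elongation, sqrt(ev[1] / ev[2]), tolerance = 1e-6)
  expect_equal(b$elongation, 7, tolerance = 0.15)
  expect_equal(b$centroid, c(13, 4, 4), tolerance = 1e-9)
})

test_that("blob voxel counts partition the above-level set", {
  r <- random_map(c(20, 20, 20), seed = 13)
  for (lev in c(0.5, 1, 1.5)) {
    blobs <- find_blobs(r, lev, 26, 1)
    expect_identical(sum(vapply(blobs, `[[`, integer(1), "voxel_count")),
                     as.integer(sum(r$values >= lev)))
    idx <- unlist(lapply(blobs, `[[`, "voxel_idx"))
    expect_identical(anyDuplicated(idx), 0L)
  }
})

test_that("blob volumes are non-increasing as the level rises", {
  r <- random_map(c(16, 16, 16), seed = 14)
  lv <- c(0.5, 1.0, 1.5, 2.0)
  tot <- vapply(lv, function(l)
    sum(vapply(find_blobs(r, l, 26, 1), `[[`, numeric(1), "volume")),
    numeric(1))
  expect_true(all(diff(tot) <= 0))
})

test_that("expected ligand volume behaves like a reference envelope", {
  lig <- make_toy_ligand(seed = 9)
  p <- simulation_params()
  v7 <- expected_ligand_volume(lig, p, 7)
  v14 <- expected_ligand_volume(lig, p, 14)
  expect_gt(v7, 0)
  expect_lte(v14, v7)                            # monotone in k
  expect_identical(expected_ligand_volume(lig, p, 7), v7)  # deterministic

  # two identical well-separated atoms: the envelope splits into two equal
  # components whose volumes sum to the reported expected volume
  two <- ligand_from_coords(rbind(c(0, 0, 0), c(0, 0, 0.01),
                                  c(40, 0, 0), c(40, 0, 0.01)), "C")
  sim2 <- simulate_map(two, p)
  lev2 <- sd_threshold(sim2, 7)
  comps <- find_blobs(sim2, lev2, 26, 1)
  expect_equal(length(comps), 2L)
  vols <- vapply(comps, `[[`, numeric(1), "volume")
  expect_lte(abs(vols[1] - vols[2]), voxel_volume(sim2))
  expect_equal(sum(vols), expected_ligand_volume(two, p, 7))
})

test_that("constructed decoys fail exactly the criteria they should", {
  lig <- make_toy_ligand(seed = 3)
  p <- simulation_params()
  ref <- expected_ligand_volume(lig, p, 7)

  # spherical decoy with about the expected volume: fails rod, passes volume
  r_vox <- round((3 * ref / (4 * pi))^(1 / 3))
  n <- 2 * r_vox + 9
  a <- array(0, dim = c(n, n, n))
  ctr <- (n + 1) / 2
  for (k in 1:n) for (j in 1:n) for (i in 1:n)
    if ((i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= r_vox^2) a[i, j, k] <- 1
  sph <- find_blobs(density_map(a, 1), 0.5, 26, 1)[[1]]
  rep_s <- evaluate_criteria(sph, 0.5, lig, p)
  expect_false(rep_s$c2_rod_shaped)
  expect_true(rep_s$c3_volume_match)
  expect_true(is.na(rep_s$c4_no_serious_clashes))
  expect_false(rep_s$all_pass)

  # thin rod decoy of under half the expected volume: passes rod, fails volume
  nrod <- max(3, round(0.2 * ref))
  b <- array(0, dim = c(nrod + 6, 7, 7))
  b[4:(3 + nrod), 4, 4] <- 1
  rod <- find_blobs(density_map(b, 1), 0.5, 26, 1)[[1]]
  rep_r <- evaluate_criteria(rod, 0.5, lig, p)
  expect_true(rep_r$c2_rod_shaped)
  expect_false(rep_r$c3_volume_match)
  expect_lt(rep_r$volume_ratio, 0.5)
})

test_that("criteria flags are invariant under global map rescaling", {
  ens <- make_ensemble(seed = 4)
  s <- ens$scenes[[1]]
  lig <- s$ligand
  run_flags <- function(map, disp) {
    thr <- threshold_for_volume(map, disp)
    masked <- mask_modeled_density(map, s$model, 3)
    blobs <- find_blobs(masked, thr$level, 26, 10)
    lapply(blobs, function(b) {
      r <- evaluate_criteria(b, thr$level, lig)
      c(r$c1_visible_at_protein_level, r$c2_rod_shaped, r$c3_volume_match)
    })
  }
  f1 <- run_flags(s$map, s$truth$display_volume)
  scaled <- s$map; scaled$values <- 3.7 * s$map$values
  f2 <- run_flags(scaled, s$truth$display_volume)
  expect_identical(f1, f2)
})
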