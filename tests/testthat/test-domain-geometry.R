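test_that("center of mass matches hand computations", {
  mod <- trace_model(rbind(c(0, 0, 0), c(2, 0, 0)))
  sel <- domain_selection("all", "A", 1, 2)
  expect_equal(center_of_mass(mod, sel), c(1, 0, 0))
  expect_equal(center_of_mass(mod, sel, "geometric"),
               center_of_mass(mod, sel, "mass"))   # identical elements

  co <- trace_model(rbind(c(0, 0, 0), c(1, 0, 0)))
  co$atoms$element <- c("C", "O")
  x <- center_of_mass(co, sel)[1]
  expect_equal(x, 15.999 / (12.011 + 15.999), tolerance = 1e-9)

  expect_error(center_of_mass(mod, domain_selection("none", "Z", 1, 5)),
               "matches no atoms")
})

test_that("domain separation is a rigid-motion invariant distance", {
  modA <- trace_model(matrix(rnorm(60, 0, 3), 20, 3), chain = "A")
  comA <- colMeans(atom_coords(modA))
  shift <- sweep(atom_coords(modA), 2, comA)
  xyzB <- sweep(shift, 2, comA + c(60, 0, 0), "+")
  mod <- trace_model(rbind(atom_coords(modA), xyzB))
  mod$atoms$chain <- rep(c("A", "B"), each = 20)
  selA <- domain_selection("A", "A", 1, 40)
  selB <- domain_selection("B", "B", 1, 40)
  expect_equal(domain_separation(mod, selA, selB), 60, tolerance = 1e-9)

  R <- rotation_about_axis(c(1, 2, 3), 0.7)
  moved <- transform_model(mod, R, c(11, -4, 2))
  expect_equal(domain_separation(moved, selA, selB), 60, tolerance = 1e-9)
})

test_that("pocket volume equals the exhaustive double-loop oracle", {
  cm <- density_map(array(1, dim = c(8, 8, 8)), 1)
  ref <- matrix(c(4, 4, 4), 1, 3)
  expect_equal(pocket_volume(cm, ref, 5)$voxel_count, 0L)  # nothing < mean

  a <- array(1, dim = c(9, 9, 9)); a[5, 5, 5] <- 0
  m <- density_map(a, 1)
  pv <- pocket_volume(m, matrix(c(4, 4, 4), 1, 3), 3)
  expect_equal(pv$voxel_count, 1L)
  expect_equal(pv$volume, 1)

  for (seed in 1:3) {
    r <- random_map(c(32, 32, 32), voxel = 1.25, seed = 40 + seed)
    set.seed(seed)
    atoms <- matrix(runif(9, 5, 30), 3, 3)
    got <- pocket_volume(r, atoms, 5)$voxel_count
    mu <- mean(r$values)
    cnt <- 0L
    for (k in 0:31) for (j in 0:31) for (i in 0:31) {
      ctr <- c(i, j, k) * 1.25
      if (r$values[i + 1, j + 1, k + 1] < mu &&
          min(sqrt(rowSums(sweep(atoms, 2, ctr)^2))) <= 5)
        cnt <- cnt + 1L
    }
    expect_identical(got, cnt)
  }
})

test_that("matched RMSD removes rigid motions to numerical precision", {
  mod <- make_toy_transporter(56, seed = 2)
  expect_s3_class(matched_rmsd(mod, mod), "rmsd_report")
  same <- matched_rmsd(mod, mod)
  expect_equal(same$rmsd_all, 0, tolerance = 1e-12)
  expect_identical(same$n_retained, same$n_matched)

  R <- rotation_about_axis(c(1, 0, 2), 1.2)
  moved <- transform_model(mod, R, c(25, -10, 5))
  rep <- matched_rmsd(mod, moved)
  expect_lt(rep$rmsd_all, 1e-6)
  expect_identical(rep$n_retained, rep$n_matched)
})

test_that("iterative pruning recovers a constructed clean subset exactly", {
  set.seed(77)
  xyz <- matrix(rnorm(300, 0, 10), 100, 3)
  A <- trace_model(xyz, name = "A")
  bad <- sort(sample(100, 20))
  xyzB <- xyz
  dirs <- matrix(rnorm(60), 20, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  xyzB[bad, ] <- xyzB[bad, ] + 5 * dirs           # displace 20 points by 5 A
  B <- transform_model(trace_model(xyzB, name = "B"),
                       rotation_about_axis(c(0, 1, 1), 0.9), c(3, 3, -7))
  rep <- matched_rmsd(A, B, prune_cutoff = 2.0)
  kept <- as.integer(sub("^A (\\d+).*", "\\1", rep$retained_key))
  expect_identical(sort(kept), setdiff(1:100, bad))
  # oracle: rmsd over the clean subset after superposing on that subset
  fit <- cryomap:::.kabsch(xyz[-bad, ], xyzB[-bad, ])
  dev <- sqrt(rowSums((xyz[-bad, ] -
    cryomap:::.transform_xyz(xyzB[-bad, ], fit$R, fit$t))^2))
  expect_equal(rep$rmsd_retained, sqrt(mean(dev^2)), tolerance = 1e-6)
  expect_identical(rep$n_matched, 100L)
  expect_identical(rep$n_retained, 80L)
  expect_false(rep$pruning_failed)
})

test_that("matched RMSD is symmetric between converged arguments", {
  modA <- make_toy_transporter(60, seed = 5)
  modB <- make_toy_transporter(56, seed = 5)
  r1 <- matched_rmsd(modA, modB)
  r2 <- matched_rmsd(modB, modA)
  expect_equal(r1$rmsd_all, r2$rmsd_all, tolerance = 1e-3)
  expect_equal(r1$rmsd_retained, r2$rmsd_retained, tolerance = 1e-3)
})

test_that("the superposition engine agrees with an independent reference", {
  set.seed(9)
  A <- matrix(rnorm(90, 0, 8), 30, 3)
  B <- sweep(A %*% t(rotation_about_axis(c(2, 1, 0), 0.6)), 2, c(5, 5, 5), "+")
  B <- B + matrix(rnorm(90, 0, 0.4), 30, 3)
  fit <- cryomap:::.kabsch(A, B)
  ours <- sqrt(mean(rowSums((A - cryomap:::.transform_xyz(B, fit$R, fit$t))^2)))
  # bio3d's least-squares fit as the independent oracle
  xyzA <- as.vector(t(A)); xyzB <- as.vector(t(B))
  fitted <- bio3d::fit.xyz(fixed = xyzA, mobile = xyzB,
                           fixed.inds = 1:90, mobile.inds = 1:90)
  ref <- sqrt(mean(rowSums((A - matrix(fitted, ncol = 3, byrow = TRUE))^2)))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("selections read back from YAML reproduce the ranges", {
  p <- system.file("extdata", "pgp_nbd_selections.yaml", package = "cryomap")
  sels <- read_selections_yaml(p)
  expect_named(sels, c("NBD1", "NBD2"))
  expect_equal(sels$NBD1$ranges$start, 395)
  expect_equal(sels$NBD2$ranges$end, 1271)
})
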