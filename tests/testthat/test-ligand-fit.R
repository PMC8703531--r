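test_that("ligand_pose validates the rotation matrix", {
  expect_error(ligand_pose(diag(3) * 2, c(0, 0, 0)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(ligand_pose(refl, c(0, 0, 0)), "orthonormal")
  p <- ligand_pose(rotation_about_axis(c(0, 0, 1), 0.3), c(1, 2, 3))
  expect_s3_class(p, "ligand_pose")
})

test_that("self-correlation is 1 and anti-correlation is -1", {
  lig <- make_toy_ligand(seed = 8)
  params <- simulation_params()
  pose <- ligand_pose(diag(3), c(0, 0, 0))
  m <- simulate_map(lig, params)               # the posed ligand's own map
  sc <- correlation_score(lig, pose, m, params)
  expect_gt(sc$cc, 0.9999)
  expect_gt(sc$n_scored_voxels, 10)
  neg <- m; neg$values <- -m$values
  expect_lt(correlation_score(lig, pose, neg, params)$cc, -0.9999)
})

test_that("correlation is invariant under affine rescaling of the map", {
  lig <- make_toy_ligand(seed = 8)
  params <- simulation_params()
  pose <- ligand_pose(rotation_about_axis(c(1, 1, 0), 0.4), c(0, 0, 0))
  m <- simulate_map(lig, params)
  m$values <- m$values + array(rnorm(prod(m$dims), 0, 0.3), dim = m$dims)
  base <- correlation_score(lig, pose, m, params)$cc
  m2 <- m; m2$values <- 5.5 * m$values + 2
  expect_equal(correlation_score(lig, pose, m2, params)$cc, base,
               tolerance = 1e-9)
})

test_that("the true pose outscores a 5 A displaced pose under noise", {
  params <- simulation_params()
  wins <- 0
  for (seed in 1:5) {
    lig <- make_toy_ligand(seed = seed)
    m <- simulate_map(lig, params)
    set.seed(seed)
    m$values <- m$values + array(rnorm(prod(m$dims), 0, 0.1 * max(m$values)),
                                 dim = m$dims)
    ctr <- colMeans(atom_coords(lig))
    cc_true <- correlation_score(lig, ligand_pose(diag(3), ctr), m, params)$cc
    cc_off <- correlation_score(lig, ligand_pose(diag(3), ctr + c(5, 0, 0)),
                                m, params)$cc
    wins <- wins + (cc_true > cc_off)
  }
  expect_equal(wins, 5)
})

test_that("fitting a ligand into its own simulated map recovers the identity", {
  lig <- make_toy_ligand(seed = 12)
  params <- simulation_params()
  m <- simulate_map(lig, params)
  lev <- sd_threshold(m, 7)
  blobs <- find_blobs(m, lev, 26, 5)
  pose <- rigid_fit(lig, m, blobs[[1]], n_rotations = 144, params = params)
  expect_gte(pose$cc, 0.99)
  err <- pose_rotation_error(lig, pose$rotation, diag(3))
  expect_lte(err, rotation_grid_spacing_deg(144))
  expect_lt(sqrt(sum((pose$translation - colMeans(atom_coords(lig)))^2)), 1.1)
})

test_that("local refinement never lowers the correlation", {
  lig <- make_toy_ligand(seed = 13)
  params <- simulation_params()
  m <- simulate_map(lig, params)
  blobs <- find_blobs(m, sd_threshold(m, 7), 26, 5)
  coarse <- rigid_fit(lig, m, blobs[[1]], n_rotations = 40,
                      local_refine = FALSE, params = params)
  fine <- rigid_fit(lig, m, blobs[[1]], n_rotations = 40,
                    local_refine = TRUE, params = params)
  expect_gte(fine$cc, coarse$cc)
})

test_that("flip comparison is symmetric for a centro-symmetric ligand", {
  lig <- ligand_from_coords(rbind(c(-2, 0, 0), c(2, 0, 0)), "C")
  params <- simulation_params()
  m <- simulate_map(lig, params)
  pose <- ligand_pose(diag(3), colMeans(atom_coords(lig)))
  fc <- flip_compare(lig, m, pose, params)
  expect_lt(abs(fc$cc_pose - fc$cc_flipped), 1e-6)
})

test_that("the rocket ligand's fins pick the true end over the flip", {
  lig <- make_toy_ligand(seed = 21)
  mod <- make_toy_transporter(60, seed = 21)
  sc <- build_scene(mod, ligand = lig, seed = 21)
  tr <- sc$truth$ligand_pose
  pose <- ligand_pose(tr$rotation, tr$translation)
  fc <- flip_compare(lig, sc$map, pose)
  expect_gt(fc$cc_pose, fc$cc_flipped)
  expect_equal(fc$preferred, "pose")
})

test_that("clash detection equals the all-pairs oracle", {
  lig <- make_toy_ligand(seed = 30)
  pose <- ligand_pose(diag(3), c(0, 0, 0))
  far <- trace_model(matrix(rnorm(30, 100, 2), 10, 3))
  expect_equal(clash_check(pose, lig, far, 2)$n_serious, 0L)

  # one protein atom 1.5 A from a known ligand atom, perpendicular to the
  # shaft so no other ligand atom comes within the cutoff
  posed <- apply_pose(lig, pose)
  a1 <- as.numeric(posed$atoms[1, c("x", "y", "z")])
  near <- trace_model(rbind(a1 + c(0, 1.5, 0), a1 + c(0, 10, 0)))
  cl <- clash_check(pose, lig, near, 2)
  expect_equal(cl$n_serious, 1L)
  expect_equal(cl$pairs$distance, 1.5, tolerance = 1e-9)
  expect_equal(cl$pairs$resno, 1L)

  # random 50-atom scene vs O(n^2) brute force
  set.seed(31)
  prot <- trace_model(matrix(rnorm(150, 0, 6), 50, 3))
  cl2 <- clash_check(pose, lig, prot, 3.0)
  lx <- as.matrix(posed$atoms[, c("x", "y", "z")])
  px <- as.matrix(prot$atoms[, c("x", "y", "z")])
  brute <- 0L
  for (i in seq_len(nrow(lx))) for (j in seq_len(nrow(px)))
    if (sqrt(sum((lx[i, ] - px[j, ])^2)) < 3.0) brute <- brute + 1L
  expect_identical(cl2$n_serious, brute)
  expect_true(all(cl2$pairs$distance < 3.0))
})

test_that("contact residues list exactly the residues within the cutoff", {
  lig <- ligand_from_coords(rbind(c(0, 0, 0), c(1.5, 0, 0)), "C")
  pose <- ligand_pose(diag(3), colMeans(atom_coords(lig)))
  xyz <- rbind(c(4, 0, 0), c(30, 0, 0), c(0, 4.2, 0))
  mod <- trace_model(xyz)
  out <- contact_residues(pose, lig, mod, 4.5)
  expect_equal(sort(out$resno), c(1L, 3L))
  expect_equal(out$resno[1], 1L)                  # sorted by min distance
  expect_equal(out$min_distance, c(2.5, 4.2), tolerance = 1e-9)
  none <- contact_residues(pose, lig, mod, 0.5)
  expect_equal(nrow(none), 0L)
})
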