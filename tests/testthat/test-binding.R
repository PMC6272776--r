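test_that("pose tables parse in file order and reject malformed rows", {
  p <- write_lines_tmp(c("label,delta_g,x1,y1,z1",
                         "a,-3.0,0,0,0",
                         "b,-2.0,1,0,0",
                         "c,-1.0,2,0,0"))
  poses <- read_pose_table(p)
  expect_length(poses, 3L)
  expect_equal(sapply(poses, `[[`, "label"), c("a", "b", "c"))
  expect_equal(sapply(poses, `[[`, "delta_g"), c(-3, -2, -1))

  bad_counts <- write_lines_tmp(c("label,delta_g,x1,y1,z1,x2,y2,z2",
                                  "a,-3,0,0,0,1,1,1",
                                  "b,-2,0,0,0,,,"))
  expect_error(read_pose_table(bad_counts), "inconsistent atom counts")

  bad_energy <- write_lines_tmp(c("label,delta_g", "a,-3", "b,oops"))
  expect_error(read_pose_table(bad_energy), "row 2")
})

test_that("pose tables round-trip through write_pose_table", {
  spec <- synthetic_spec(seed = 12, poses = list(n = 5L))
  poses <- make_pose_ensemble(spec)
  p <- tempfile(fileext = ".csv")
  write_pose_table(poses, p)
  back <- read_pose_table(p)
  expect_equal(sapply(back, `[[`, "delta_g"),
               sapply(poses, `[[`, "delta_g"), tolerance = 1e-12)
  expect_equal(back[[3]]$coordinates, poses[[3]]$coordinates,
               tolerance = 1e-12)
})

test_that("pose RMSD is the unsuperposed per-atom quadratic mean", {
  xyz <- matrix(rnorm(9), ncol = 3)
  a <- toy_pose(-1, xyz)
  expect_equal(pose_rmsd(a, a), 0)
  b <- toy_pose(-1, sweep(xyz, 2, c(3, 0, 0), "+"))
  expect_equal(pose_rmsd(a, b), 3.0, tolerance = 1e-12)

  a2 <- toy_pose(-1, rbind(c(0, 0, 0), c(5, 0, 0)))
  b2 <- toy_pose(-1, rbind(c(1, 0, 0), c(5, 2, 0)))
  expect_equal(pose_rmsd(a2, b2), sqrt((1 + 4) / 2), tolerance = 1e-12)
  expect_equal(pose_rmsd(a2, b2), 1.5811, tolerance = 1e-4)

  expect_error(pose_rmsd(a, a2), "mismatch")
})

test_that("greedy clustering is energy-ordered and partitions the input", {
  xyz <- matrix(0, 2, 3)
  same <- structure(lapply(c(-3, -1, -2), toy_pose, xyz = xyz),
                    class = c("pose_ensemble", "list"))
  cl <- cluster_poses(same)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$delta_g, -3)
  expect_setequal(cl[[1]]$members, 1:3)

  apart <- list(toy_pose(-2, xyz),
                toy_pose(-4, sweep(xyz, 2, c(5, 0, 0), "+")))
  cl2 <- cluster_poses(apart, threshold = 2)
  expect_length(cl2, 2L)
  expect_equal(cl2[[1]]$delta_g, -4)   # clusters ordered by seed energy

  # three mutually close poses: the -3 pose seeds the single cluster
  near <- lapply(c(-3, -2, -1), function(dg, i)
    toy_pose(dg, xyz + (dg + 3) * 0.3), 1)
  cl3 <- cluster_poses(near, threshold = 2)
  expect_length(cl3, 1L)
  expect_equal(cl3[[1]]$representative, 1L)
})

test_that("clustering assigns every pose to exactly one cluster", {
  spec <- synthetic_spec(seed = 77, poses = list(n = 40L,
                                                 coordinate_jitter = 1.5))
  poses <- make_pose_ensemble(spec)
  cl <- cluster_poses(poses, threshold = 2)
  members <- unlist(lapply(cl, `[[`, "members"))
  expect_equal(sort(members), 1:40)
})

test_that("free energy converts to a dissociation-scale constant and back", {
  expect_equal(delta_g_to_k(0), 1)
  k <- delta_g_to_k(-1.727, 298.15)
  expect_equal(k * 1000, 54.16, tolerance = 1e-3)
  # inside the reported experimental band 53.66 +/- 9.24 mM
  expect_lt(abs(k * 1000 - 53.66), 9.24)
  expect_equal(delta_g_to_k(-6.0, 298.15), 4.00e-5, tolerance = 1e-3)

  expect_equal(k_to_delta_g(1), 0)
  expect_equal(k_to_delta_g(0.05416, 298.15), -1.727, tolerance = 1e-3)
  expect_error(k_to_delta_g(0), "domain error")
  expect_error(k_to_delta_g(-1), "domain error")

  dg <- seq(-15, 5, by = 0.25)
  expect_equal(k_to_delta_g(delta_g_to_k(dg)), dg, tolerance = 1e-12)
  expect_true(all(diff(delta_g_to_k(dg)) > 0))
})

test_that("top-pose summaries report mean/sd energies and constants", {
  xyz <- matrix(0, 1, 3)
  triple <- lapply(c(-1.769, -1.727, -1.685), toy_pose, xyz = xyz)
  s <- summarize_top_poses(triple, k = 3)
  expect_equal(s$mean_dg, -1.727, tolerance = 1e-12)
  expect_equal(s$sd_dg, 0.042, tolerance = 1e-9)
  expect_equal(s$mean_k_mM, mean(delta_g_to_k(c(-1.769, -1.727,
                                                -1.685)) * 1000),
               tolerance = 1e-12)
  expect_equal(s$affinity_class, "low")

  expect_warning(s1 <- summarize_top_poses(triple[1], k = 3), "exceeds")
  expect_equal(s1$mean_dg, -1.769)
  expect_equal(s1$sd_dg, 0)

  four <- lapply(c(-5, -1, -1, -1), toy_pose, xyz = xyz)
  s4 <- summarize_top_poses(four, k = 1)
  expect_equal(s4$mean_dg, -5)
  expect_equal(s4$sd_dg, 0)
})

test_that("summaries are invariant to pose order", {
  spec <- synthetic_spec(seed = 31, poses = list(n = 20L))
  poses <- make_pose_ensemble(spec)
  s <- summarize_top_poses(poses)
  set.seed(2)
  shuffled <- poses[sample(20)]
  s2 <- summarize_top_poses(shuffled)
  expect_equal(s2$mean_dg, s$mean_dg, tolerance = 1e-12)
  expect_equal(s2$sd_dg, s$sd_dg, tolerance = 1e-12)
  expect_equal(s2$mean_k_mM, s$mean_k_mM, tolerance = 1e-12)
})

test_that("affinity classification uses the -6 kcal/mol rule inclusively", {
  expect_equal(classify_affinity(-1.727), "low")
  expect_equal(classify_affinity(-6.5), "high")
  expect_equal(classify_affinity(-6.0), "high")
  expect_error(classify_affinity(NaN), "finite")
})
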