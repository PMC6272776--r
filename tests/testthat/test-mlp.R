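test_that("MLP at a point is the distance-weighted constant sum", {
  fs1 <- fragment_system(c(A = 1.0))
  m <- one_atom("C"); m$atoms$fragment_type <- "A"
  expect_equal(mlp_at_points(rbind(c(0, 0, 0)), m, fs1)$values, 1.0)

  # symmetric +1 / -1 pair cancels at the midpoint
  pair <- molecule(data.frame(element = "C", x = c(-2, 2), y = 0, z = 0,
                              fragment_type = c("P", "M")))
  fs2 <- fragment_system(c(P = 1, M = -1))
  expect_equal(mlp_at_points(rbind(c(0, 0, 0)), pair, fs2)$values, 0)

  # single atom at 2 A with f = 0.5, exponential weighting
  m5 <- one_atom("C"); m5$atoms$fragment_type <- "H5"
  v <- mlp_at_points(rbind(c(2, 0, 0)), m5,
                     fragment_system(c(H5 = 0.5)))$values
  expect_equal(v, 0.5 * exp(-1), tolerance = 1e-9)
  expect_equal(v, 0.18394, tolerance = 1e-4)
})

test_that("hyperbolic weighting and the cutoff behave as declared", {
  m <- one_atom("C"); m$atoms$fragment_type <- "A"
  fs <- fragment_system(c(A = 2))
  w <- distance_weight("hyperbolic", cutoff = 5)
  expect_equal(mlp_at_points(rbind(c(3, 0, 0)), m, fs, w)$values, 2 / 4)
  expect_equal(mlp_at_points(rbind(c(6, 0, 0)), m, fs, w)$values, 0)
  expect_error(distance_weight(cutoff = 0), "positive")
})

test_that("mlp_sums splits the field and conserves the total", {
  f <- mlp_field(matrix(0, 3, 3), c(1, -2, 3))
  s <- mlp_sums(f)
  expect_equal(unname(s), c(4, -2))

  z <- mlp_field(matrix(0, 2, 3), c(0, 0))
  expect_equal(unname(mlp_sums(z)), c(0, 0))

  set.seed(99)
  v <- rnorm(1000)
  s2 <- mlp_sums(mlp_field(matrix(rnorm(3000), ncol = 3), v))
  expect_equal(s2[["sum_plus"]] + s2[["sum_minus"]], sum(v),
               tolerance = 1e-12)
})

test_that("logp_mlp is the calibrated linear map of the sums", {
  fld <- function(vals) mlp_field(matrix(0, length(vals), 3), vals)
  expect_equal(logp_mlp(fld(c(2, -3)), logp_calibration(1, 1, 0)), -1)
  expect_equal(logp_mlp(fld(0), logp_calibration(0.7, -0.2, 4.2)), 4.2)
  expect_equal(logp_mlp(fld(c(5, -2)), logp_calibration(0.2, 0.3, -0.1)),
               0.3, tolerance = 1e-12)
  expect_warning(logp_mlp(fld(c(1, -1))), "calibration")
})

test_that("calibration recovers exact generating weights and flags defects", {
  set.seed(21)
  fields <- lapply(1:10, function(i)
    mlp_field(matrix(rnorm(30), ncol = 3), rnorm(10, sd = 2)))
  sums <- t(sapply(fields, mlp_sums))
  logp <- 0.4 * sums[, 1] + 0.6 * sums[, 2] + 1.2
  cal <- calibrate_logp(fields, logp)
  expect_equal(cal$w_plus, 0.4, tolerance = 1e-9)
  expect_equal(cal$w_minus, 0.6, tolerance = 1e-9)
  expect_equal(cal$intercept, 1.2, tolerance = 1e-9)

  expect_error(calibrate_logp(fields[1:2], logp[1:2]), "at least 3")
  all_pos <- lapply(1:5, function(i)
    mlp_field(matrix(rnorm(9), ncol = 3), abs(rnorm(3)) + 0.1))
  expect_error(calibrate_logp(all_pos, rnorm(5)), "rank-deficient")
})

test_that("MLP is linear in the fragment constants", {
  mol <- random_molecule(15, seed = 2)
  fs <- default_fragment_system()
  fs2 <- fragment_system(fs$constants * 2, fallback = fs$fallback * 2)
  pts <- matrix(rnorm(60, sd = 4), ncol = 3)
  v1 <- mlp_at_points(pts, mol, fs)$values
  v2 <- mlp_at_points(pts, mol, fs2)$values
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
})

test_that("finite-cutoff MLP matches the cutoff-free brute-force oracle", {
  fs <- default_fragment_system()
  for (seed in c(31, 32, 33)) {
    mol <- random_molecule(25, seed = seed)
    set.seed(seed + 500)
    pts <- matrix(rnorm(45, sd = 5), ncol = 3)
    dmax <- sqrt(max(outer(rowSums(pts^2), rowSums(coords(mol)^2), "+") -
                       2 * pts %*% t(coords(mol))))
    v <- mlp_at_points(pts, mol, fs,
                       distance_weight("exponential",
                                       cutoff = dmax + 1))$values
    expect_equal(v, mlp_brute_force(pts, mol, fs, "exponential"),
                 tolerance = 1e-9)
    vh <- mlp_at_points(pts, mol, fs,
                        distance_weight("hyperbolic",
                                        cutoff = dmax + 1))$values
    expect_equal(vh, mlp_brute_force(pts, mol, fs, "hyperbolic"),
                 tolerance = 1e-9)
  }
})

test_that("MLP values are invariant under a shared rigid motion", {
  mol <- random_molecule(18, seed = 8)
  fs <- default_fragment_system()
  set.seed(9)
  pts <- matrix(rnorm(36, sd = 4), ncol = 3)
  R <- random_rotation(3); tr <- c(-2, 5, 1)
  v0 <- mlp_at_points(pts, mol, fs)$values
  v1 <- mlp_at_points(sweep(pts %*% t(R), 2, tr, "+"),
                      transform_molecule(mol, R, tr), fs)$values
  expect_equal(v1, v0, tolerance = 1e-9)
})

test_that("MLP field CSV round-trips", {
  f <- mlp_field(matrix(rnorm(30), ncol = 3), rnorm(10), source = "t")
  p <- tempfile(fileext = ".csv")
  write_mlp_field(f, p)
  g <- read_mlp_field(p)
  expect_equal(g$points, f$points, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g$values, f$values, tolerance = 1e-12)
})

test_that("the PDB point-cloud writer emits one HETATM per point", {
  f <- mlp_field(matrix(rnorm(15), ncol = 3), rnorm(5))
  p <- tempfile(fileext = ".pdb")
  write_mlp_pdb(f, p)
  lines <- readLines(p)
  expect_equal(sum(startsWith(lines, "HETATM")), 5L)
})
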