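# Shared fixture builders. Everything is generated in code; the only
# packaged files are the small sevoflurane structures and the default
# fragment table under inst/extdata.

extdata <- function(f) system.file("extdata", f, package = "hostguest")

# a generic (asymmetric) random molecule: well-conditioned for
# principal-axis frames and free of coincident atoms
random_molecule <- function(n, seed, elements = c("C", "N", "O", "F", "S")) {
  set.seed(seed)
  repeat {
    xyz <- matrix(rnorm(3 * n, sd = 3), ncol = 3)
    if (n == 1 || min(dist(xyz)) > 0.5) break
  }
  molecule(data.frame(element = sample(elements, n, replace = TRUE),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
           name = sprintf("random-%d", seed))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

one_atom <- function(element = "C", x = 0, y = 0, z = 0, vdw = NULL) {
  df <- data.frame(element = element, x = x, y = y, z = z)
  if (!is.null(vdw)) df$vdw_radius <- vdw
  molecule(df)
}

write_lines_tmp <- function(lines, ext = ".csv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# brute-force cutoff-free MLP oracle: plain double loop, independent of
# the vectorised implementation
mlp_brute_force <- function(points, mol, fs,
                            form = c("exponential", "hyperbolic")) {
  form <- match.arg(form)
  f <- assign_constants(mol, fs)
  xyz <- coords(mol)
  vals <- numeric(nrow(points))
  for (k in seq_len(nrow(points))) {
    acc <- 0
    for (i in seq_len(nrow(xyz))) {
      d <- sqrt(sum((points[k, ] - xyz[i, ])^2))
      acc <- acc + f[i] * switch(form,
                                 exponential = exp(-d / 2),
                                 hyperbolic = 1 / (1 + d))
    }
    vals[k] <- acc
  }
  vals
}

toy_pose <- function(dg, xyz, label = "p") pose(dg, xyz, label)
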