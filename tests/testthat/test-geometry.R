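# Superposition and descriptor checks: exact rigid-motion identities plus
# brute-force and alternative-formula oracles.

test_that("kabsch recovers exact superpositions and excludes reflections", {
  set.seed(1)
  x <- matrix(rnorm(15, sd = 3), 5, 3)
  fit0 <- kabsch(x, x)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  rot90z <- euler_rotation(pi / 2, 0, 0)
  y <- sweep(x %*% t(rot90z), 2, c(5, 0, 0), `+`)
  fit <- kabsch(x, y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_transform(fit, x), y, tolerance = 1e-9)

  # a mirrored target cannot be fit to zero: the proper-rotation constraint
  # must hold and the rmsd stays positive
  ym <- x
  ym[, 1] <- -ym[, 1]
  fitm <- kabsch(x, ym)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0.1)
})

test_that("kabsch rejects mismatched and degenerate inputs", {
  x <- matrix(rnorm(12), 4, 3)
  expect_error(kabsch(x, x[1:3, ]), "equal-sized")
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch(line, line), "collinear")
  pt <- matrix(1, 3, 3)
  expect_error(kabsch(pt, pt), "coincident")
})

test_that("kabsch agrees with an exhaustive rotation-grid oracle on small sets", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(4:6, 1)
    a <- matrix(rnorm(3 * n, sd = 2), n, 3)
    b <- a %*% t(random_rotation(seed + 50)) +
      matrix(rnorm(3 * n, sd = 0.3), n, 3)
    expect_equal(kabsch(a, b)$rmsd, brute_force_rmsd(a, b), tolerance = 1e-3)
  }
})

test_that("rmsd series vanishes for static and rigidly moving trajectories", {
  d <- fix_duplex(n_bp = 4)
  static <- make_trajectory(d, motion_spec(n_frames = 5, dt = 10, seed = 1))
  ref <- frame_coords(d, 1)
  s <- rmsd_series(static, ref)
  expect_equal(s$value, rep(0, 5), tolerance = 1e-9)

  # per-frame arbitrary rigid motions
  xyz <- static$xyz
  for (f in 1:5) {
    xyz[, , f] <- sweep(xyz[, , f] %*% t(random_rotation(f)), 2, rnorm(3, sd = 10), `+`)
  }
  moved <- trajectory(static$atoms, xyz, dt = 10)
  expect_equal(rmsd_series(moved, ref)$value, rep(0, 5), tolerance = 1e-9)
  expect_error(rmsd_series(static, ref, selection(chain = "Z")), "empty selection")
})

test_that("rmsd series matches an independent superposition oracle on jittered frames", {
  d <- fix_duplex(n_bp = 6)
  tr <- make_trajectory(d, motion_spec(n_frames = 20, dt = 10, jitter_sigma = 0.5, seed = 9))
  ref <- frame_coords(d, 1)
  ours <- rmsd_series(tr, ref)$value
  oracle <- vapply(seq_len(20), function(f) {
    bio3d::rmsd(
      as.numeric(t(ref)), as.numeric(t(tr$xyz[, , f])),
      fit = TRUE
    )
  }, numeric(1))
  expect_equal(ours, oracle, tolerance = 2e-3) # oracle reports 3 decimals
})

test_that("average structure handles static, symmetric and jittered inputs", {
  d <- fix_duplex(n_bp = 3)
  static <- make_trajectory(d, motion_spec(n_frames = 4, dt = 10, seed = 1))
  expect_equal(average_structure(static), frame_coords(d, 1), tolerance = 1e-9)

  # two frames symmetric about a mean -> midpoint. The displacement is
  # projected free of net translation and torque so that superposition of
  # either frame onto the midpoint is the identity (the mean is otherwise
  # only defined up to a rigid motion).
  x0 <- frame_coords(d, 1)
  delta <- matrix(rnorm(length(x0), sd = 0.1), nrow(x0), 3)
  delta <- sweep(delta, 2, colMeans(delta))
  r <- sweep(x0, 2, colMeans(x0))
  cross <- function(u, v) {
    cbind(
      u[, 2] * v[, 3] - u[, 3] * v[, 2],
      u[, 3] * v[, 1] - u[, 1] * v[, 3],
      u[, 1] * v[, 2] - u[, 2] * v[, 1]
    )
  }
  torque <- colSums(cross(r, delta))
  inertia <- sum(rowSums(r^2)) * diag(3) - t(r) %*% r
  omega <- solve(inertia, torque)
  delta <- delta - cross(matrix(omega, nrow(r), 3, byrow = TRUE), r)
  two <- trajectory(d$atoms, array(c(x0 + delta, x0 - delta), dim = c(nrow(x0), 3, 2)), dt = 10)
  expect_equal(average_structure(two), x0, tolerance = 1e-5)

  # jittered recovery, compared in the generator frame (the iterated mean
  # carries an arbitrary small rigid offset from its seed frame)
  sigma <- 0.3
  nf <- 200
  tr <- make_trajectory(d, motion_spec(n_frames = nf, dt = 10, jitter_sigma = sigma, seed = 2))
  avg <- average_structure(tr)
  expect_lt(kabsch(avg, x0)$rmsd, 2 * sigma * sqrt(3) / sqrt(nf))
})

test_that("rmsf is zero for static input and approaches sigma*sqrt(3) for one jittered atom", {
  d <- fix_duplex(n_bp = 4)
  static <- make_trajectory(d, motion_spec(n_frames = 5, dt = 10, seed = 1))
  expect_equal(rmsf(static)$rmsf_A, rep(0, n_atoms(d)), tolerance = 1e-9)
  expect_error(rmsf(d), "at least 2 frames")

  # jitter a single atom of a large rigid scaffold (the other 179 atoms
  # pin the superposition); that atom's RMSF converges to the isotropic
  # limit sigma*sqrt(3)
  big <- fix_duplex(n_bp = 13)
  sigma <- 0.5
  nf <- 2000
  x0 <- frame_coords(big, 1)
  set.seed(5)
  xyz <- array(rep(x0, nf), dim = c(nrow(x0), 3, nf))
  xyz[1, , ] <- xyz[1, , ] + matrix(rnorm(3 * nf, sd = sigma), 3, nf)
  tr <- trajectory(big$atoms, xyz, dt = 10)
  prof <- rmsf(tr)
  expect_equal(prof$rmsf_A[1], sigma * sqrt(3), tolerance = 0.03)
  expect_lt(max(prof$rmsf_A[-1]), 0.1)
})

test_that("terminal nucleotides of an opening duplex fluctuate more than the core", {
  d <- fix_duplex()
  holo <- make_trajectory(d, motion_spec(
    n_frames = 150, dt = 100, jitter_sigma = 0.2,
    opening = default_opening_schedule(), seed = 3
  ))
  prof <- rmsf(holo, selection(name = "C5'"))
  term <- prof$rmsf_A[prof$chain == "B" & prof$resid %in% 14:16]
  core <- prof$rmsf_A[prof$resid %in% c(4:9, 18:23)]
  expect_gt(min(term), max(core))
})

test_that("radius of gyration matches analytic cases and a pairwise-formula oracle", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1.0)
  # unequal masses 1:3 at x = 0, 4 -> com at 3
  expect_equal(center_of_mass(rbind(c(0, 0, 0), c(4, 0, 0)), c(1, 3)), c(3, 0, 0))
  expect_equal(center_of_mass(matrix(c(7, 8, 9), 1, 3), 12), c(7, 8, 9))

  d <- fix_duplex()
  x <- frame_coords(d, 1)
  m <- d$atoms$mass
  rg <- radius_of_gyration(x, m)
  # independent identity: Rg^2 = sum_{i<j} m_i m_j d_ij^2 / M^2
  dm <- as.matrix(dist(x))
  oracle <- sqrt(sum(outer(m, m) * dm^2) / (2 * sum(m)^2))
  expect_equal(rg, oracle, tolerance = 1e-9)
  expect_error(radius_of_gyration(x[0, , drop = FALSE]), "empty")
})

test_that("descriptors are invariant under rigid motion and equivariant under scaling", {
  d <- fix_duplex(n_bp = 5)
  tr <- make_trajectory(d, motion_spec(n_frames = 15, dt = 10, jitter_sigma = 0.4, seed = 6))
  moved <- rigid_copy(tr, random_rotation(3), c(12, -7, 4))
  ref <- frame_coords(d, 1)

  expect_equal(rmsd_series(moved, ref)$value, rmsd_series(tr, ref)$value,
    tolerance = 1e-9
  )
  expect_equal(rmsf(moved)$rmsf_A, rmsf(tr)$rmsf_A, tolerance = 1e-5)
  expect_equal(rg_series(moved)$value, rg_series(tr)$value, tolerance = 1e-9)

  scaled <- trajectory(tr$atoms, tr$xyz * 2.5, dt = tr$dt)
  expect_equal(rg_series(scaled)$value, 2.5 * rg_series(tr)$value, tolerance = 1e-9)
  expect_equal(rmsf(scaled)$rmsf_A, 2.5 * rmsf(tr)$rmsf_A, tolerance = 1e-5)
})

test_that("rmsd after superposition is symmetric in its arguments", {
  set.seed(8)
  a <- matrix(rnorm(30, sd = 2), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
  expect_equal(kabsch(a, b)$rmsd, kabsch(b, a)$rmsd, tolerance = 1e-9)
})
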