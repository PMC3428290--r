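# Shared fixtures and independent oracles for the test suite. Oracles here
# deliberately avoid the code paths they check (brute-force loops, grid
# searches, alternative formulas).

# Random proper rotation matrix (via QR of a Gaussian matrix, det fixed).
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply one rigid motion to every frame of a trajectory.
rigid_copy <- function(traj, rot, trans) {
  xyz <- traj$xyz
  for (f in seq_len(dim(xyz)[3])) {
    xyz[, , f] <- sweep(xyz[, , f] %*% t(rot), 2, trans, `+`)
  }
  trajectory(traj$atoms, xyz, dt = traj$dt, t0 = traj$t0)
}

euler_rotation <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(a) %*% ry(b) %*% rz(c)
}

# Brute-force superposition oracle: exhaustive coarse search over ZYZ Euler
# angles (translation handled by centroid matching, which is optimal for
# least squares), refined with Nelder-Mead. Independent of the SVD path.
brute_force_rmsd <- function(mobile, reference) {
  xm <- sweep(mobile, 2, colMeans(mobile))
  yr <- sweep(reference, 2, colMeans(reference))
  score <- function(p) {
    r <- euler_rotation(p[1], p[2], p[3])
    sqrt(mean(rowSums((xm %*% t(r) - yr)^2)))
  }
  best <- Inf
  best_p <- c(0, 0, 0)
  step <- pi / 12
  for (a in seq(0, 2 * pi - step, by = step)) {
    for (b in seq(0, pi, by = step)) {
      for (cc in seq(0, 2 * pi - step, by = step)) {
        s <- score(c(a, b, cc))
        if (s < best) {
          best <- s
          best_p <- c(a, b, cc)
        }
      }
    }
  }
  opt <- optim(best_p, score, control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Minimal hand-built two-strand system for counting oracles: each "residue"
# is a single P atom, chains A and B face each other 3 A apart with 6 A
# spacing along the strand.
ladder_system <- function(k = 10, gap = 3) {
  atoms <- data.frame(
    serial = seq_len(2 * k),
    name = "P",
    resname = "A",
    resid = c(seq_len(k), seq_len(k) + k),
    chain = rep(c("A", "B"), each = k)
  )
  xyz <- rbind(
    cbind(6 * seq_len(k), 0, 0),
    cbind(6 * seq_len(k), gap, 0)
  )
  trajectory(topology(atoms), xyz, dt = 10)
}

# Standard study-sized fixtures.
fix_duplex <- function(...) make_duplex(duplex_spec(...))

fix_patch <- function(duplex, residues) {
  make_protein_patch(domain_spec(residues), duplex)
}

# Base-moiety atom indices without reaching into package internals.
.res_atoms_for_test <- function(topo, chain, resid) {
  which(topo$chain == chain & topo$resid == resid &
    !topo$name %in% c("P", "C5'"))
}
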