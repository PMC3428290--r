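# Base-pair geometry: distance traces, residue-base distances, the
# holo-apo difference landscape and opening-order detection.

test_that("pair inference is antiparallel-by-position and rejects reuse", {
  d <- fix_duplex()
  pm <- pair_map(d)
  expect_equal(nrow(pm), 13)
  expect_equal(pm$resid1, 1:13)
  expect_equal(pm$resid2, 26:14)
  # explicit declaration, e.g. the terminal pairs 13-14, 12-15, 11-16
  ex <- pair_map(pairs = data.frame(
    chain1 = "A", resid1 = 13:11, chain2 = "B", resid2 = 14:16
  ))
  expect_equal(ex$pair, 1:3)
  expect_error(
    pair_map(pairs = data.frame(
      chain1 = "A", resid1 = c(1, 1), chain2 = "B", resid2 = c(26, 25)
    )),
    "more than one pair"
  )
})

test_that("closed-duplex base pairs sit at the construction distance", {
  d <- fix_duplex() # d0 = 5.5
  bp <- basepair_distances(d)
  expect_equal(bp$distance_A, rep(5.5, 13), tolerance = 1e-6)

  static <- make_trajectory(d, motion_spec(n_frames = 8, dt = 10, seed = 1))
  bps <- basepair_distances(static)
  for (k in 1:13) {
    expect_equal(var(bps$distance_A[bps$pair == k]), 0, tolerance = 1e-20)
  }
})

test_that("a displaced pair's trace steps from baseline to baseline + displacement", {
  d <- fix_duplex()
  tr <- make_trajectory(d, motion_spec(n_frames = 10, dt = 10, seed = 1))
  pm <- pair_map(d)
  # displace strand-2 nucleotide of pair 1 along the pair axis in frames 6-10
  i1 <- select_atoms(tr, selection(chain = "A", resid = 1))
  i2 <- select_atoms(tr, selection(chain = "B", resid = 26))
  b1 <- which(!tr$atoms$name[i1] %in% c("P", "C5'"))
  b2 <- which(!tr$atoms$name[i2] %in% c("P", "C5'"))
  com1 <- center_of_mass(tr$xyz[i1[b1], , 1], tr$atoms$mass[i1[b1]])
  com2 <- center_of_mass(tr$xyz[i2[b2], , 1], tr$atoms$mass[i2[b2]])
  ax <- (com2 - com1) / sqrt(sum((com2 - com1)^2))
  for (f in 6:10) {
    tr$xyz[i2, , f] <- tr$xyz[i2, , f] + matrix(12 * ax, length(i2), 3, byrow = TRUE)
  }
  s <- basepair_distances(tr, pm)
  s1 <- s[s$pair == 1, ]
  expect_equal(s1$distance_A[1:5], rep(5.5, 5), tolerance = 1e-6)
  expect_equal(s1$distance_A[6:10], rep(17.5, 5), tolerance = 1e-6)
})

test_that("missing base atoms in a declared pair are reported by name", {
  d <- fix_duplex(n_bp = 3)
  bad <- pair_map(pairs = data.frame(
    chain1 = "A", resid1 = 1, chain2 = "B", resid2 = 99
  ))
  expect_error(basepair_distances(d, bad), "B99")
})

test_that("residue-base distance hits constructed values and degenerate base lists", {
  d <- fix_duplex()
  pat <- fix_patch(d, data.frame(
    resname = "PHE", resid = 69, anchor_chain = "A", anchor_resid = 12,
    target = "base", offset = 12.0
  ))
  one <- residue_base_distance(pat,
    list(chain = "K", resid = 69),
    data.frame(chain = "A", resid = 12)
  )
  expect_equal(one$value, 12.0, tolerance = 1e-9)
  # listing the same base twice leaves the joint COM unchanged
  twice <- residue_base_distance(pat,
    list(chain = "K", resid = 69),
    data.frame(chain = "A", resid = c(12, 12))
  )
  expect_equal(twice$value, one$value, tolerance = 1e-12)
  expect_error(
    residue_base_distance(pat, list(chain = "K", resid = 69),
      data.frame(chain = "A", resid = 99)),
    "A99"
  )
})

test_that("a programmed linear approach yields a monotone distance series", {
  d <- fix_duplex()
  pat <- fix_patch(d, data.frame(
    resname = "PHE", resid = 69, anchor_chain = "A", anchor_resid = 12,
    target = "base", offset = 18.0
  ))
  topo <- pat$atoms
  x0 <- frame_coords(pat, 1)
  res_idx <- which(topo$chain == "K")
  base_idx <- .res_atoms_for_test(topo, "A", 12)
  com_b <- center_of_mass(x0[base_idx, ], topo$mass[base_idx])
  sc_idx <- res_idx[!topo$name[res_idx] %in% c("N", "CA", "C", "O")]
  com_sc <- center_of_mass(x0[sc_idx, ], topo$mass[sc_idx])
  ax <- (com_b - com_sc) / sqrt(sum((com_b - com_sc)^2))
  nf <- 25
  xyz <- array(rep(x0, nf), dim = c(nrow(x0), 3, nf))
  for (f in seq_len(nf)) {
    step <- 6 * (f - 1) / (nf - 1) # 18 A -> 12 A
    xyz[res_idx, , f] <- xyz[res_idx, , f] +
      matrix(ax * step, length(res_idx), 3, byrow = TRUE)
  }
  tr <- trajectory(topo, xyz, dt = 10)
  s <- residue_base_distance(tr, list(chain = "K", resid = 69),
    data.frame(chain = "A", resid = 12))
  expect_equal(s$value[1], 18, tolerance = 1e-9)
  expect_equal(s$value[nf], 12, tolerance = 1e-9)
  expect_true(all(diff(s$value) < 0))
})

test_that("distance-difference landscape is zero on identical/rigid inputs and antisymmetric", {
  d <- fix_duplex(n_bp = 6)
  tr <- make_trajectory(d, motion_spec(n_frames = 12, dt = 10, jitter_sigma = 0.3, seed = 5))
  dd_same <- distance_difference_landscape(tr, tr)
  expect_equal(max(abs(dd_same)), 0)

  moved <- rigid_copy(tr, random_rotation(9), c(15, 5, -3))
  expect_lt(max(abs(distance_difference_landscape(tr, moved))), 1e-9)

  tr2 <- make_trajectory(d, motion_spec(n_frames = 12, dt = 10, jitter_sigma = 0.3, seed = 6))
  ab <- distance_difference_landscape(tr, tr2)
  ba <- distance_difference_landscape(tr2, tr)
  expect_equal(ab, -ba, tolerance = 1e-12)
  expect_equal(ab, t(ab), tolerance = 1e-12)
  expect_equal(diag(ab), setNames(rep(0, nrow(ab)), rownames(ab)))

  expect_error(
    distance_difference_landscape(tr, fix_duplex(n_bp = 5)),
    "different duplex nucleotide sets"
  )
})

test_that("opening concentrates positive distance differences at the opening terminus", {
  d <- fix_duplex()
  closed <- make_trajectory(d, motion_spec(n_frames = 60, dt = 250, jitter_sigma = 0.2, seed = 7))
  open <- make_trajectory(d, motion_spec(
    n_frames = 60, dt = 250, jitter_sigma = 0.2,
    opening = default_opening_schedule(), seed = 8
  ))
  dd <- distance_difference_landscape(open, closed)
  moved <- c("B:14", "B:15", "B:16")
  still <- setdiff(rownames(dd), moved)
  # rows of displaced nucleotides vs the static body are strongly positive
  expect_gt(min(rowMeans(dd[moved, still])), 1)
  # the static body barely changes among itself
  expect_lt(max(abs(dd[still, still])), 0.5)
})

test_that("opening detection respects the sustain rule and flags terminal-first order", {
  d <- fix_duplex()
  tr <- make_trajectory(d, motion_spec(
    n_frames = 300, dt = 100, opening = default_opening_schedule(), seed = 2
  ))
  bp <- basepair_distances(tr)
  rep0 <- detect_opening(bp, delta = 3, sustain = 10)
  tab <- rep0$pairs
  expect_true(all(tab$opened[tab$pair %in% 11:13]))
  expect_false(any(tab$opened[tab$pair %in% 1:10]))
  t_open <- tab$opening_time_ps[match(13:11, tab$pair)]
  expect_true(all(diff(t_open) > 0))
  expect_true(rep0$ordered)

  # constant series at baseline never opens
  static <- basepair_distances(make_trajectory(d, motion_spec(n_frames = 30, dt = 10, seed = 1)))
  expect_false(any(detect_opening(static, delta = 3, sustain = 5)$pairs$opened))

  # a spike shorter than `sustain` does not count ...
  one <- static[static$pair == 1, ]
  spiked <- one
  spiked$distance_A[10:12] <- spiked$distance_A[10:12] + 10
  expect_false(detect_opening(spiked, delta = 3, sustain = 5)$pairs$opened)
  # ... and appending post-opening frames never changes an opening time
  r1 <- detect_opening(bp, delta = 3, sustain = 10)
  half <- bp[bp$time_ps <= 15000, ]
  r2 <- detect_opening(half, delta = 3, sustain = 10)
  both <- r2$pairs$opened
  expect_equal(
    r1$pairs$opening_time_ps[both],
    r2$pairs$opening_time_ps[both]
  )
})
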