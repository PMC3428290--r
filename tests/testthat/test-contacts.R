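# Three-class contact census: boundary conventions, counting oracles,
# occupancy filtering and ensemble comparison.

# 50-frame fixture: a hydrophobic residue within cutoff in `n_in` frames,
# displaced outward along the residue-base axis in the rest.
blinking_patch <- function(n_frames = 50, n_in = 26, offset = 5.5, push = 3) {
  d <- fix_duplex()
  pat <- fix_patch(d, data.frame(
    resname = "ILE", resid = 304, anchor_chain = "A", anchor_resid = 7,
    target = "base", offset = offset
  ))
  topo <- pat$atoms
  x0 <- frame_coords(pat, 1)
  res_idx <- which(topo$chain == "K")
  sc_idx <- which(topo$chain == "K" & !topo$name %in% c("N", "CA", "C", "O"))
  base_idx <- which(topo$chain == "A" & topo$resid == 7 &
    !topo$name %in% c("P", "C5'"))
  dir <- center_of_mass(x0[sc_idx, ], topo$mass[sc_idx]) -
    center_of_mass(x0[base_idx, ], topo$mass[base_idx])
  dir <- dir / sqrt(sum(dir^2))
  set.seed(42)
  in_frames <- sort(sample(n_frames, n_in))
  xyz <- array(rep(x0, n_frames), dim = c(nrow(x0), 3, n_frames))
  for (f in setdiff(seq_len(n_frames), in_frames)) {
    xyz[res_idx, , f] <- xyz[res_idx, , f] +
      matrix(dir * push, length(res_idx), 3, byrow = TRUE)
  }
  list(traj = trajectory(topo, xyz, dt = 10), in_frames = in_frames,
    sc_idx = sc_idx, base_idx = base_idx)
}

test_that("hydrophobic census applies a strict distance cutoff at the side-chain/base COMs", {
  d <- fix_duplex()
  inside <- fix_patch(d, data.frame(
    resname = "ILE", resid = 1, anchor_chain = "A", anchor_resid = 7,
    target = "base", offset = 6.4
  ))
  h <- hydrophobic_contacts(inside)
  expect_equal(nrow(h), 1)
  expect_equal(h$population, 1.0)
  expect_equal(h$rna_resid, 7)

  outside <- fix_patch(d, data.frame(
    resname = "ILE", resid = 1, anchor_chain = "A", anchor_resid = 7,
    target = "base", offset = 6.6
  ))
  expect_equal(nrow(hydrophobic_contacts(outside)), 0)
  expect_error(hydrophobic_contacts(d), "protein and one RNA")
})

test_that("populations equal a brute-force per-frame recount exactly", {
  fx <- blinking_patch(n_frames = 50, n_in = 26)
  h <- hydrophobic_contacts(fx$traj)
  expect_equal(nrow(h), 1)
  expect_identical(h$population, 26 / 50)

  # independent recount: plain loops, no shared helpers
  topo <- fx$traj$atoms
  m_sc <- topo$mass[fx$sc_idx]
  m_b <- topo$mass[fx$base_idx]
  count <- 0
  for (f in seq_len(50)) {
    xyz <- fx$traj$xyz[, , f]
    com_sc <- colSums(xyz[fx$sc_idx, ] * m_sc) / sum(m_sc)
    com_b <- colSums(xyz[fx$base_idx, ] * m_b) / sum(m_b)
    if (sqrt(sum((com_sc - com_b)^2)) < 6.5) count <- count + 1
  }
  expect_identical(h$population, count / 50)
  expect_identical(h$present[[1]], seq_len(50) %in% fx$in_frames)

  # survives the 50% filter at 0.52
  expect_equal(nrow(filter_by_population(h, 0.5)), 1)
})

test_that("electrostatic census uses the charged-group COM vs phosphate rule", {
  d <- fix_duplex()
  near <- fix_patch(d, data.frame(
    resname = "ARG", resid = 315, anchor_chain = "B", anchor_resid = 15,
    target = "P", offset = 10.9
  ))
  e <- electrostatic_contacts(near)
  expect_equal(nrow(e), 1)
  expect_equal(e$rna_resid, 15)

  far <- fix_patch(d, data.frame(
    resname = "ARG", resid = 315, anchor_chain = "B", anchor_resid = 15,
    target = "P", offset = 11.1
  ))
  expect_equal(nrow(electrostatic_contacts(far)), 0)
})

test_that("14 charged residues in phosphate range give 14 filtered records", {
  d <- fix_duplex()
  anchors <- data.frame(
    resname = rep(c("ARG", "LYS"), 7),
    resid = 301:314,
    anchor_chain = rep(c("A", "B"), each = 7),
    anchor_resid = c(3:9, 16:22),
    target = "P", offset = 10.5
  )
  pat <- fix_patch(d, anchors)
  kept <- filter_by_population(electrostatic_contacts(pat), 0.5)
  expect_equal(nrow(kept), 14)
  expect_setequal(kept$protein_resid, 301:314)
  expect_true(all(kept$population == 1))
})

test_that("5'-terminal nucleotides without a phosphate are skipped", {
  d <- fix_duplex()
  # anchor via base of the 5' terminus (which has no P); census must not
  # report it even though the residue sits right next to it
  pat <- fix_patch(d, data.frame(
    resname = "LYS", resid = 1, anchor_chain = "A", anchor_resid = 1,
    target = "base", offset = 3
  ))
  e <- electrostatic_contacts(pat)
  expect_false(any(e$rna_chain == "A" & e$rna_resid == 1))
})

# Hand-built single-nucleotide + serine system with an exact OG...N7
# distance, everything else out of range.
hbond_probe <- function(og_n7, n_frames = 1, og_frames = NULL) {
  base <- rbind(
    N9 = c(0, 0, 0), C8 = c(1.2, 0, 0), N7 = c(2.4, 0, 0),
    C6 = c(0.6, 1.2, 0), N6 = c(1.8, 1.2, 0),
    P = c(-5, -5, 0), "C5'" = c(-4, -4, 0)
  )
  ser <- rbind(
    OG = c(2.4 + og_n7, 0, 0), CB = c(2.4 + og_n7 + 1.2, 0.8, 0),
    CA = c(2.4 + og_n7 + 2.4, 0, 0), N = c(2.4 + og_n7 + 3.4, 1, 0),
    C = c(2.4 + og_n7 + 3.4, -1, 0), O = c(2.4 + og_n7 + 4.4, -1, 0)
  )
  atoms <- data.frame(
    serial = 1:13,
    name = c(rownames(base), rownames(ser)),
    resname = c(rep("A", 7), rep("SER", 6)),
    resid = c(rep(1, 7), rep(2, 6)),
    chain = c(rep("R", 7), rep("Q", 6))
  )
  x0 <- rbind(base, ser)
  if (n_frames == 1) return(trajectory(topology(atoms), x0, dt = 10))
  xyz <- array(rep(x0, n_frames), dim = c(13, 3, n_frames))
  out_frames <- setdiff(seq_len(n_frames), og_frames)
  xyz[8, 1, out_frames] <- 2.4 + 3.6 # OG pushed beyond the cutoff
  trajectory(topology(atoms), xyz, dt = 10)
}

test_that("hydrogen bonds use the heavy donor-acceptor distance when no hydrogens exist", {
  close_enough <- hbond_probe(3.4)
  hb <- hydrogen_bonds(close_enough)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$population, 1.0)
  expect_equal(nrow(hydrogen_bonds(hbond_probe(3.6))), 0)
})

test_that("a 40% occupancy hydrogen bond fails the default filter", {
  tr <- hbond_probe(3.4, n_frames = 50, og_frames = 1:20)
  hb <- hydrogen_bonds(tr)
  expect_equal(hb$population, 0.40)
  expect_equal(nrow(filter_by_population(hb)), 0)
})

test_that("occupancy filtering is strictly greater-than and sorts by population", {
  tr <- hbond_probe(3.4, n_frames = 50, og_frames = 1:25)
  hb <- hydrogen_bonds(tr)
  expect_equal(hb$population, 0.50)
  expect_equal(nrow(filter_by_population(hb, 0.5)), 0) # boundary excluded
  expect_equal(nrow(filter_by_population(hb, 0.49)), 1)
  empty <- filter_by_population(hb[0, ], 0.5)
  expect_equal(nrow(empty), 0)
})

test_that("contact sets grow monotonically with the cutoff", {
  fx <- blinking_patch(n_frames = 20, n_in = 9, offset = 6.0, push = 0.7)
  tight <- hydrophobic_contacts(fx$traj, contact_config(hydrophobic_cutoff = 6.5))
  loose <- hydrophobic_contacts(fx$traj, contact_config(hydrophobic_cutoff = 7.0))
  key <- function(x) paste(x$protein_resid, x$rna_chain, x$rna_resid)
  expect_true(all(key(tight) %in% key(loose)))
  for (k in seq_len(nrow(tight))) {
    j <- match(key(tight)[k], key(loose))
    expect_true(all(loose$present[[j]] >= tight$present[[k]]))
  }
})

test_that("census is invariant under frame reordering and rigid motion", {
  fx <- blinking_patch(n_frames = 20, n_in = 11)
  h1 <- hydrophobic_contacts(fx$traj)

  set.seed(33)
  perm <- sample(20)
  shuffled <- trajectory(fx$traj$atoms, fx$traj$xyz[, , perm], dt = 10)
  h2 <- hydrophobic_contacts(shuffled)
  expect_identical(h1$population, h2$population)

  moved <- rigid_copy(fx$traj, random_rotation(17), c(30, -10, 5))
  h3 <- hydrophobic_contacts(moved)
  expect_identical(h1$population, h3$population)
  expect_identical(h1$present, h3$present)
})

test_that("census comparison flags common and unique records", {
  d <- fix_duplex()
  shared <- data.frame(
    resname = "ARG", resid = c(315, 317), anchor_chain = "B",
    anchor_resid = c(15, 17), target = "P", offset = 10.5
  )
  only_a <- data.frame(
    resname = "LYS", resid = 320, anchor_chain = "A", anchor_resid = 5,
    target = "P", offset = 10.5
  )
  only_b <- data.frame(
    resname = "LYS", resid = 321, anchor_chain = "A", anchor_resid = 9,
    target = "P", offset = 10.5
  )
  ca <- electrostatic_contacts(fix_patch(d, rbind(shared, only_a)))
  cb <- electrostatic_contacts(fix_patch(d, rbind(shared, only_b)))

  cmp <- compare_censuses(ca, cb)
  expect_equal(sum(cmp$status == "common"), 2)
  expect_equal(sum(cmp$status == "a_only"), 1)
  expect_equal(sum(cmp$status == "b_only"), 1)
  expect_true(all(cmp$protein_resid[cmp$status == "common"] %in% c(315, 317)))

  same <- compare_censuses(ca, ca)
  expect_true(all(same$status == "common"))
  expect_equal(sum(compare_censuses(ca[1:2, ], cb[3, ])$status == "common"), 0)
})
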