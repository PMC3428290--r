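# Build the synthetic stand-ins for the study systems: the apo duplex and
# the protein-bound ("holo") complex whose terminal base pairs open. Writes
# the reference structures and a short demonstration trajectory as
# multi-model PDB with JSON provenance sidecars; the longer runs used by
# the other drivers are regenerated in memory from the same seeds.

source("analysis/00_common.R")

write_system(duplex, OUT("systems", "duplex_closed.pdb"),
  provenance = list(generator = "make_duplex", n_bp = 13, d0 = 5.5,
    rise = 2.81, twist = 32.7, synthetic = TRUE)
)

complex <- make_protein_patch(domain_spec(kh_patch), duplex)
write_system(complex, OUT("systems", "complex_reference.pdb"),
  provenance = list(generator = "make_protein_patch", residues = kh_patch,
    synthetic = TRUE)
)

demo <- make_trajectory(
  complex,
  motion_spec(n_frames = 100, dt = 500, jitter_sigma = 0.4,
    opening = default_opening_schedule(), seed = SEED + 1)
)
write_system(demo, OUT("systems", "complex_opening_demo.pdb"),
  provenance = list(generator = "make_trajectory", n_frames = 100,
    dt_ps = 500, jitter_sigma = 0.4, seed = SEED + 1,
    opening = default_opening_schedule(), synthetic = TRUE)
)

cat(
  "Wrote synthetic systems:\n",
  "  duplex_closed.pdb        13-bp duplex, ", n_atoms(duplex), " atoms\n",
  "  complex_reference.pdb    duplex + ", nrow(kh_patch),
  " coarse binding residues (", n_atoms(complex), " atoms)\n",
  "  complex_opening_demo.pdb 100-frame opening demonstration (50 ns)\n",
  sep = ""
)
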