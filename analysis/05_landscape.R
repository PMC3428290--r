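# Pseudo-free-energy landscapes over C5' RMSD x Rg (8x8 bins) for the apo
# duplex and the opening complex, with their basin locations.

source("analysis/00_common.R")

sel <- selection(name = "C5'", molecule = "rna")

for (sys in list(list(name = "apo", tr = make_apo()),
                 list(name = "holo", tr = make_holo()))) {
  avg <- average_structure(sys$tr, sel)
  rmsd <- rmsd_series(sys$tr, avg, sel)
  rg <- rg_series(sys$tr, selection(molecule = "rna"))
  ls <- energy_landscape(rmsd, rg, bins_per_axis = 8)
  write_tsv(landscape_table(ls),
    OUT("landscape", paste0("landscape_", sys$name, ".tsv")),
    comments = c(
      paste0("G = -ln(P/Pmax) [kT], 8x8 bins; ", sys$name),
      "x = C5' RMSD (A), y = RNA Rg (A)"
    )
  )
  b <- ls$basin[1, ]
  cat(sprintf(
    "%-5s basin: RMSD %.2f-%.2f A, Rg %.2f-%.2f A (P = %.2f over %d cells)\n",
    sys$name, b$x_lo, b$x_hi, b$y_lo, b$y_hi, b$P, length(ls$P)
  ))
}
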