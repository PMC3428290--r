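# duplexmd

Trajectory analysis of protein-bound miRNA:mRNA duplex opening.

`duplexmd` is an R toolkit for analysing molecular dynamics trajectories of
protein–RNA complexes, built around a specific structural question: how do
RNA-binding domains — the KH domain of FXR1 and the PAZ domain of
Argonaute 2 — destabilise and open a microRNA:mRNA duplex? This is the key
structural step proposed for microRNA-mediated translation *up*-regulation
of TNFα mRNA by miR369-3 in quiescent cells, where the two strands of the
duplex must separate before the mRNA can be translated.

The package is aimed at structural bioinformaticians who have (or simulate)
multi-model PDB trajectories of such complexes and want the standard
descriptor/contact/kinetics analyses in one tested, scriptable toolbox.

## What it computes

* **Superposition descriptors** — Kabsch least-squares superposition
  (proper rotations only), per-frame RMSD relative to a reference or to the
  iterative average structure, per-atom RMSF about the mean, and the
  mass-weighted radius of gyration $R_g$.
* **Three-class contact census** between protein residues and nucleotides,
  with per-frame presence and trajectory occupancy ("population"):
  * *hydrophobic*: side-chain COM to base-moiety COM < 6.5 Å,
  * *electrostatic*: Arg/Lys charged-group COM to backbone phosphate P
    < 11 Å,
  * *hydrogen bond*: heavy donor–acceptor distance ≤ 3.5 Å (plus a
    D–H···A ≥ 135° angle check when hydrogens are present),
  filtered at population > 50% and comparable across ensembles.
* **Base-pair geometry** — per-pair inter-strand distance traces (base
  COM to base COM), residue-to-base distances, opening detection with a
  sustained-excursion rule and terminal-first ordering flag, and the
  holo-vs-apo distance-difference landscape over C5′ atoms.
* **2D pseudo-free-energy landscapes** over RMSD × $R_g$: normalized 8×8
  histograms inverted as $G = -\ln(P/P_{max})$ in kT units, with basin
  identification.
* **Native-contact kinetics** — the fraction of native inter-strand
  contacts $Q_b(t)$ (heavy-atom pairs < 4.5 Å in the reference, retained
  within 1.2× their reference distance) and the single-exponential fit
  $A\,e^{-t/\tau}+B$ of its decay.
* **A synthetic generator** (`make_duplex()`, `make_protein_patch()`,
  `make_trajectory()`, `make_qb_trace()`) producing deterministic,
  seed-reproducible idealized duplex systems with Gaussian thermal jitter
  and programmed, terminally ordered exponential strand opening — the
  validation bed for everything above.

## Worked example

A 13-bp duplex with a coarse KH-like binding patch, 50 ns of synthetic
dynamics in which the three terminal pairs open exponentially, analysed end
to end:

```r
library(duplexmd)

duplex <- make_duplex()                      # 13 bp, pairs ~5.5 A apart
complex <- make_protein_patch(domain_spec(data.frame(
  resname = c("ILE", "ARG"), resid = c(304, 315),
  anchor_chain = "B", anchor_resid = c(14, 15),
  target = c("base", "P"), offset = c(6.0, 10.5)
)), duplex)
holo <- make_trajectory(complex, motion_spec(
  n_frames = 2000, dt = 25, jitter_sigma = 0.4,
  opening = default_opening_schedule(), seed = 1
))

bp <- basepair_distances(holo)
detect_opening(bp, delta = 3, sustain = 20)$ordered
#> [1] TRUE                       # pairs open terminal-first

s13 <- bp[bp$pair == 13, ]
fit_exponential(descriptor_series(s13$time_ps, s13$distance_A))
#> <exp_fit> y = A*exp(-t/tau) + B
#>   A = -11.9933, tau = 4.94511, B = 17.492 (t_half = 3.42769)
#>   rss = 130 over 2000 points; converged: TRUE
```

The fitted time constant recovers the 4.96 ns opening schedule of the
generator, and the plateau (17.5 Å) is the closed-pair distance plus the
programmed 12 Å separation — the terminal pair ramps from ~5.5 Å to
~17.5 Å, the behaviour reported for the duplex terminus upon PAZ+KH
binding.

The numbered drivers under `analysis/` run the full study workflow
(synthetic systems → descriptors → contact census → base pairs →
landscapes → kinetics), each printing a short summary and writing TSV/JSON
tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

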