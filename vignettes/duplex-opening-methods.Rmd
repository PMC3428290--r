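---
title: "Methods: descriptors, contact census, landscapes and opening kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, contact census, landscapes and opening kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmd)
```

`duplexmd` analyses molecular dynamics trajectories of protein–RNA
complexes with one scientific target in mind: quantifying how the binding
of RNA-recognition domains (a KH domain, the Argonaute PAZ domain) changes
the conformation of a microRNA:mRNA duplex and eventually opens its
terminal base pairs. This vignette documents the methods, their
assumptions, the tunable parameters, and the design decisions taken where
the conventions of the field are not unique.

## Trajectory model and time conventions

A trajectory is a fixed topology plus an ordered stack of coordinate
frames (Å) at a constant sampling interval `dt` (ps). PDB files carry no
time axis, so `read_pdb()` takes `dt` from the caller and falls back to
10 ps — the conventional snapshot interval for this kind of simulation —
with a warning.

Frames are indexed from `t0 = dt`: a run of duration $D$ sampled every
$s$ has frames at $s, 2s, \dots, D$, so a 50 ns run at 10 ps has exactly
5000 frames and a 60 ns run 6000. We adopt this convention (rather than
starting at $t=0$) because it reproduces the snapshot counts conventional
for these run lengths exactly; `subsample()` preserves the first frame
and requires the new interval to be an integer multiple of `dt`.

Chains are classified as protein or RNA from residue-name vocabularies
(the 20 standard amino-acid codes; `A/U/G/C` with `R`-prefixed and
5′/3′-terminal variants). An unrecognised residue name is a hard error:
silently skipping atoms would bias every downstream census.

An analysis window `[t_start, t_end]` (`time_window()`, also a pipeline
configuration field) lets occupancies be computed post-equilibration. The
default is the full trajectory, because no published convention dictates
a burn-in for occupancy statistics; users who equilibrate for, say,
20 ns should set the window accordingly.

## Superposition and descriptors

Superposition uses the Kabsch algorithm: SVD of the (optionally
mass-weighted) cross-covariance matrix with the determinant sign
correction, so reflections are never returned. Collinear or coincident
point sets leave a rotation degree of freedom unconstrained and are
rejected as degenerate rather than silently resolved.

* **RMSD** is computed after superposing each frame onto the reference
  *over the same selection that is measured* (fit set = measurement set).
  RMSD/RMSF are unweighted by default because the canonical duplex
  descriptor is computed over a single atom type (C5′), where mass
  weighting is a no-op; a `mass_weighted` flag exposes the variant.
* **Average structure**: frames are iteratively superposed onto the
  running mean until the mean moves < 1e-6 Å (max per coordinate), with
  a 100-iteration cap treated as a numerical error. Iteration starts
  from frame 1; iterated means depend (weakly) on the seed frame and on
  an arbitrary global orientation, so comparisons against a reference
  should superpose first.
* **RMSF** ("variation") is the per-atom RMS deviation from the
  time-average position after superposition onto the average structure.
  The plausible alternative — fluctuation about the *first frame* — is
  not used: fluctuation about the mean is the standard estimator, and
  the distinction matters only far from equilibrium. For isotropic
  per-axis jitter $\sigma$ it converges to $\sigma\sqrt{3}$, which the
  test suite uses as an analytic anchor.
* **$R_g$** is mass-weighted (the standard convention).

## Contact census

Three interaction classes are censused between protein residues and
nucleotides; a contact's *population* is the fraction of frames in which
its geometric criterion holds.

| class | criterion | default |
|---|---|---|
| hydrophobic | side-chain COM to base-moiety COM | < 6.5 Å |
| electrostatic | charged-group COM to backbone P | < 11 Å |
| hydrogen bond | heavy donor–acceptor distance | ≤ 3.5 Å (+ angle ≥ 135° with H) |

Conventions that required a decision:

* "Side chain" of a nucleotide is its **base moiety** (ring heavy atoms
  plus exocyclic N/O; no sugar, no phosphate). Glycine's side-chain proxy
  is its Cα.
* The charged-residue set is **Arg + Lys** (His optional via
  `include_his`), and the charged-group COM uses the terminal group
  (guanidinium nitrogens for Arg, NZ for Lys) rather than the whole
  residue — the charge resides there, and the whole-residue COM would
  shift the effective cutoff by the side-chain length.
* Nucleotides lacking a phosphate (5′ termini) are skipped by the
  electrostatic census rather than approximated.
* Hydrogen-bond criteria use heavy-atom donor–acceptor tables per
  residue/base; the angular criterion applies only when the topology
  actually carries a hydrogen within 1.2 Å of the donor, so heavy-atom
  trajectories (and the synthetic fixtures) run in distance-only mode.
* Distance comparisons at the hydrophobic/electrostatic cutoffs are
  **strict** (<), and the population filter is **strict** (>) — matching
  the reading of "population higher than 50%". A contact at exactly the
  threshold is excluded; tests pin both boundaries.

Censuses from two ensembles are compared by an outer join on
(class, residue, nucleotide), flagging records `common`/`a_only`/`b_only`
with the occupancy from each side.

## Base-pair geometry and opening detection

Pair identity is declared by a `pair_map`: by default antiparallel by
position (strand 1 ascending vs strand 2 descending), with an explicit
pair table available because published pair numberings (e.g. pairs
labelled "13–14", "12–15") are not always recoverable from residue
numbering alone. Nucleotides in the default 13-bp system are numbered
continuously: mRNA-like chain A is 1–13, miRNA-like chain B is 14–26, so
pair $k$ joins A:$k$ with B:$(27-k)$ and "pair 13–14" is the terminal
pair at the mRNA 3′ end / miRNA 5′ end.

A pair's distance trace is the distance between base-moiety COMs.
`detect_opening()` declares a pair open at the first frame where its
distance exceeds `baseline + delta` for at least `sustain` consecutive
frames. Defaults: per-pair first-frame baseline, `delta = 3` Å (half the
intact-pair distance — comfortably above thermal noise, well below a
fully opened pair), `sustain = 50` frames (0.5 ns at 10 ps sampling), all
configurable. The sustain rule makes the opening time invariant to
appending later frames and insensitive to brief excursions. The report's
`ordered` flag is true when opening times are non-decreasing with pair
index counted from the declared terminus — the signature of terminal-first
unzipping.

The holo-vs-apo **distance-difference landscape** is
$\Delta_{ij} = \overline{d^{holo}_{ij}} - \overline{d^{apo}_{ij}}$ over
one atom per nucleotide (C5′ by default): symmetric, zero-diagonal,
invariant under rigid motion of either trajectory, and antisymmetric
under exchanging the ensembles. Positive blocks mark regions that moved
apart upon binding.

## Free-energy landscapes

`energy_landscape()` bins two descriptor series on an equal-width grid
(default 8 bins per axis, the conventional 64-cell layout), normalizes
counts to probabilities and Boltzmann-inverts:

$$G = -\ln\left(\frac{P}{P_{max}}\right)$$

in kT units — the temperature is factored out because only relative depths
are meaningful for basin identification. Bin ranges come from each
trajectory's own data min/max (matching per-system landscape panels), not
from fixed global ranges; landscapes from different systems therefore
share bin *counts* but not bin *edges*. Empty bins carry a `+Inf`
sentinel, exported as `inf` in TSV. The basin is the argmin-G cell of the
raw histogram (no smoothing — a smoothed argmin would depend on an
arbitrary bandwidth); exact ties are all reported. A zero-variance axis
is a degeneracy error.

## Native-contact kinetics

$Q_b(t)$ is the fraction of native inter-strand contacts retained at
time $t$. Because no single convention defines "native contact" for RNA
duplexes, the package pins one and exposes its knobs: all inter-strand
heavy-atom pairs closer than 4.5 Å in the reference frame (the first
analysis frame by default), retained while their distance stays within
1.2× the reference distance. $Q_b$ is 1 on the reference frame by
construction and invariant under rigid motion.

`fit_exponential()` fits $y = A e^{-t/\tau} + B$ by Levenberg–Marquardt
least squares, with a deterministic initialisation: $B_0$ = mean of the
last 10% of $y$; $A_0 = y(0) - B_0$; $\tau_0$ = first time at which
$|y - B_0|$ drops below $|A_0|/e$, falling back to a third of the time
range. $\tau$ is constrained positive; a constant $y$ is a degeneracy
error; non-convergence returns the best iterate flagged
`converged = FALSE`. Fits of $Q_b$ run on time in ns, and the result
reports both $\tau$ and $t_{1/2} = \tau \ln 2$, since "half time" in the
literature sometimes denotes the exponential time constant itself and
sometimes the half-life. Negative amplitudes are allowed, so the same
fitter recovers saturating ramps such as the opening pair distance
$d_0 + extra\,(1 - e^{-t/\tau})$.

## The synthetic generator: what it emulates, and what it does not

The study systems this package targets have no deposited trajectories,
so validation runs on synthetic stand-ins built by `make_duplex()`,
`make_protein_patch()` and `make_trajectory()`. These are deliberately
**coarse**: each nucleotide carries only the atoms the analysis touches
(backbone P except at 5′ termini, C5′, and a 5-atom base proxy with
standard PDB atom names), and protein residues are backbone plus
side-chain pseudo-atom clusters whose group COM is placed exactly where
a fixture needs it. Defaults describe the study system: 13 base pairs,
AU-rich sequence, A-form-like helix (rise 2.81 Å, twist 32.7°/bp), and a
closed-pair base-COM separation $d_0 = 5.5$ Å — the middle of the
intact-pair range. Base clusters extend along the pair axis so a closed
duplex genuinely interdigitates within native-contact range.

Motion is composed of: programmed opening — strand-B nucleotides of
selected pairs displaced along their pair axis by
$extra\,(1 - e^{-t/\tau})$ — plus isotropic, uncorrelated Gaussian jitter,
plus optional cumulative rigid drift. `default_opening_schedule()`
encodes the terminally ordered scenario: the three pairs at the mRNA
3′ end / miRNA 5′ end gain 12, 10.5 and 6.5 Å (endpoints ≈ 17.5, 16 and
12 Å from the 5.5 Å baseline) with time constants 4.96, 6.5 and 8.5 ns,
so the duplex unzips terminal-first with a ~5 ns leading time constant.
The jitter default in the analysis drivers (0.4 Å per axis) puts C5′
RMSF near 0.7 Å, a typical stable-nucleic-acid magnitude.

All generators are pure functions of (spec, seed): the RNG state is
saved and restored, and identical seeds give byte-identical PDB output.

What passing tests on these fixtures **does** show: the analysis layer
measures what it claims (populations equal brute-force recounts, fitted
constants equal generator constants, invariances hold exactly). What it
**does not** show: anything about force fields, solvent, correlated
motions, base-pair step geometry, or stereochemistry — the generator has
none of these, and conclusions about real systems still require real
trajectories.

## Problem sizes and orchestration

The analysis drivers (`analysis/01…06`) run the 13-bp duplex with an
8-residue binding patch over 50 ns at 25 ps sampling (2000 frames), and
the contact census over 500 frames — sizes chosen so the whole workflow
re-runs in about half a minute while keeping per-frame statistics
well-resolved. The acceptance script uses the study's own sampling scale
(5000 frames at 10 ps). `run_pipeline()` drives all stages from one
configuration (YAML/JSON or list), writes fixed-name TSVs with
provenance comments (`#`-prefixed: version, seed, cutoffs) plus a JSON
manifest of inputs, parameters and per-stage status; numeric output is
fixed to 6 significant digits so identical configurations reproduce
byte-identical tables. The first hard stage failure is recorded in the
manifest and then propagated.

## Known limitations

* No mmCIF/DCD/XTC input and no bond inference; multi-model PDB is the
  only trajectory format.
* Hydrogen-bond detection without hydrogens is distance-only and thus
  permissive; with hydrogens present, donors are associated to hydrogens
  geometrically (≤ 1.2 Å), not via connectivity records.
* π-stacking, cation–π and water-mediated interactions are out of scope
  for the census.
* The landscape uses raw histograms; basins narrower than a bin or
  split across a bin edge can shift by up to one bin width under
  re-binning (the refinement test bounds exactly this).
* The exponential fitter is single-exponential by design; multi-phase
  decays will show structured residuals rather than a warning.
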