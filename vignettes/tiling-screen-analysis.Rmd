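---
title: "From tiling-screen counts to a docking box: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tiling-screen counts to a docking box: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprtiles)
```

## The problem

A conventional depletion screen tells you that a gene is essential; a
*tiling* screen, with guides spaced every few codons along one gene's coding
exons, tells you which parts of the protein are essential. Cas9 cuts repaired
by end joining leave a mixture of frameshifts and small in-frame
insertions/deletions at the guide's cut site. Where the protein tolerates a
couple of substituted or missing residues, in-frame alleles survive and the
guide depletes only partially; where even a small in-frame lesion is lethal
— a folded core, a functional interface — nearly all alleles are lost and
the guide depletes as strongly as a knockout of a core-essential gene. The
per-residue depletion profile therefore reads out local functional
constraint, and strongly constrained surface patches are natural targets
for small molecules.

## Screen scoring

**Abundance and QC.** Raw counts per guide and sample are scaled to reads
per million after adding a pseudocount of one read (`rpm_normalize`). The
pseudocount avoids log-of-zero downstream and is standard screen practice.
A day-0 sample passes representation QC when at least 90% of guides reach
10 RPM (`library_qc`); failing libraries were bottlenecked during cloning
or infection and give unreliable fold changes.

**Fold change and filtering.** The guide-level signal is
`log10(end RPM / start RPM)`, computed per replicate pair and then averaged
(`fold_change_table`). Guides below 5% of the expected uniform frequency
(1e6 / library size RPM) in the pooled day-0 counts are dropped from all
downstream statistics; the comparison is strictly "below", so a guide
sitting exactly at the boundary survives. Pooling day 0 across replicates
for this filter is a deliberate choice: the filter targets guides that were
under-represented in the library itself, which is a property of the common
starting material, not of one replicate.

**Calibration.** Each library carries negative controls (guides against
non-essential sequence) and positive controls (guides against
core-essential genes). The normalized CRISPR score maps the raw fold change
affinely so the negative-control median lands on 0 and the positive-control
median on −1 (`calibrate_ncs`). The map uses medians, not means, so a
handful of outlier control guides cannot move the scale; the calibration is
invariant to any constant shift in fold change (e.g. global growth-rate
differences between screens). Degenerate calibrations (coinciding medians)
and control sets with fewer than three kept guides per class are rejected
outright rather than producing a meaningless scale.

## Per-residue profile

Guides are assigned to the codon containing the nucleotide immediately 5′
of the blunt Cas9 cut (between protospacer positions 17 and 18, three
nucleotides 5′ of the PAM): `codon = floor((cut_nt - 1)/3) + 1`, in 1-based
coordinates of the primary translation product, signal peptide included.
Multiple guides at one codon are averaged (`assign_guides_to_residues`).

Smoothing uses a truncated Gaussian kernel (`smooth_profile`), defaults
σ = 5 residues and support ±3σ. With a typical density of one guide per
~3 residues, σ = 5 pools roughly 10 guides per window — enough to suppress
single-guide noise (efficiency differences between guides are large) while
keeping features of 10–20 residues visible. Positions without a guide
contribute no weight and the kernel mass is renormalized over observed
neighbours; imputing zeros instead would drag scores toward "neutral" at
edges and gaps, which is exactly the wrong bias for a hypersensitivity
readout. A residue whose entire window is unobserved stays missing.

**Segment calling** (`call_segments`) takes maximal runs with smoothed
NCS ≤ −0.5 (half the positive-control depletion — deep enough to exclude
partially tolerated regions, shallow enough to keep real functional
elements whose guides are diluted by in-frame survivors), merges runs
separated by ≤ 2 residues, and discards merged runs shorter than 3
residues. The threshold, minimum length and merge gap have no published
reference values; they are exposed as parameters, recorded in the run
report, and every reported segment count is conditional on them.

## Structure mapping and the docking box

`map_profile` pairs profile position *p* with structure residue
*p + offset*; the offset accommodates author numbering that does not start
at the initiator methionine (no indel alignment is attempted — the mapping
is a constant shift or nothing). Two render-ready artifacts are written:
a UCSF Chimera `defattr` attribute file, and a copy of the structure with
each atom's B-factor replaced by its residue's smoothed NCS to two
decimals, with 99.99 as the sentinel for unmapped residues (safely outside
the plausible NCS range of roughly −2..+1).

`define_box` encloses all heavy atoms of the hypersensitive-segment
residues in an axis-aligned box with 6 Å padding on every side, cubic by
default (docking engines accept arbitrary boxes; the cube matches common
virtual-screening setups and is the shape the search-space definition
expects). The padding default is a geometry margin, not a fitted value, and
is likewise recorded in the run report.

`detect_cavity` is a deliberately lightweight pocket finder used to sanity
check that the box actually contains enclosed space: grid points (1 Å
spacing) that are clash-free (≥ probe 1.4 Å + atom radius 1.7 Å from every
heavy atom, one radius for all elements) are kept when axis rays in at
least 4 of the 6 cardinal directions hit protein. It is a surrogate for a
proper pocket-detection tool — an externally computed pocket can be used
instead via the docking-box interface — and makes no druggability claim.

## Docking-score ranking

Engine outputs (log tables or PDBQT result remarks) are parsed to the best
mode per compound. Engine-native scores are kcal/mol; selection thresholds
in the literature are often quoted in kJ/mol. The package multiplies by
exactly 4.184 and always reports *both* columns, because a kcal-labelled
number read as kJ (or vice versa) changes a selection by a factor of four
and the two conventions genuinely coexist in published work; keeping both
visible is the only safe behaviour. Selection (`select_binders`) sorts
ascending by ΔG°, breaks ties lexicographically by compound id for
determinism, and applies the top-N rule and/or an inclusive (≤) cutoff.

## Assay analytics

* **Viability:** signals as percent of the vehicle-well mean; "effective
  kill" requires strictly less than 10% residual signal in *both* an
  ATP-based and a dehydrogenase-based assay, so a compound that merely
  quenches one chemistry does not score.
* **NanoBRET:** corrected ratio = 1000·(acceptor/donor of the sample minus
  acceptor/donor of the no-ligand control), in milliBRET units.
* **Thermal shift:** the melt curve is fitted with a Boltzmann sigmoid
  `F(T) = B + (P − B)/(1 + exp((Tm − T)/s))`; Tm is the sigmoid midpoint
  (the common convention; a derivative-peak estimate differs only when the
  transition is asymmetric, in which case neither is reliable).
  Initialization: baselines from the 5th/95th signal percentiles, Tm from
  the steepest finite-difference rise, s = 2 °C; Levenberg–Marquardt least
  squares via `minpack.lm`. ΔTm is fitted-treated minus fitted-control.
* **Dose–response:** four-parameter logistic with log-scale IC50
  parameterization; a response that rises with dose triggers a warning but
  the fit is still attempted.

## What the simulators emulate — and what they do not

`simulate_screen` and `simulate_tiling` draw counts from a negative
binomial (Gamma–Poisson) around a uniform day-0 expectation; day-24
expectations multiply each guide's share by 10^(effect), with positive
controls at −1.5 log10 units and planted hypersensitive segments at a depth
expressed in NCS units (−1 ⇒ the positive-control effect), plus per-guide
Gaussian noise (sd 0.1 log10 units) mimicking guide-efficiency variation.
Defaults are one guide per 3 residues, 100 negative and 30 positive
controls, depth 1e6 reads per sample, dispersion 0.05, two replicates —
sized to the library scale and coverage of a real single-gene tiling screen
while keeping the test suite fast (a 300-residue protein rather than a
~1000-residue one; segment geometry is scale-free, so recovery behaviour
transfers).

The simulators deliberately omit: PCR amplification bias and jackpotting,
guide-sequence-dependent cutting efficiency, in-frame allele spectra (the
effect is modelled directly as depletion, not through repair outcomes),
copy-number artefacts, and inter-replicate batch effects. Passing tests
therefore show the *estimator* is correct under a faithful noise model, not
that real screens are free of these additional error sources.

`toy_structure` builds a ring of wedge-shaped atom clusters around an empty
centre — the geometry of a β-propeller's central pocket — so cavity
detection has an analytic ground truth; it is labelled synthetic and is not
a protein model. Melt-curve presets `cpdav2_control` (Tm 52.0 °C) and
`cpdav2_treated` (Tm 58.1 °C) encode a published ligand-stabilization pair
as generator parameters so the fitting path can be checked against a known
shift (6.1 °C).

## Numerical choices and degenerate inputs

Determinism throughout: a single integer seed drives each simulator through
R's default generator with state save/restore, so repeated calls are
byte-identical and never disturb the caller's RNG. Tie-breaks are always
lexicographic. Boundary conventions: QC fractions and the binder cutoff are
inclusive; the low-frequency filter and the kill rule are strict, following
the wording of their definitions. Empty segment lists, empty cavity grids
and structures missing profile residues are valid outcomes, reported rather
than errored; zero-variance dependency rows are dropped with a warning; a
flat dose–response or coinciding calibration medians are hard errors
because no meaningful estimate exists.

The tiling-resolution constant for the integrin α-V precursor (1048
residues, UniProt P06756) ships with the package so the aa-per-guide
arithmetic works without a network lookup.

## Known limitations

Segment calls carry no significance estimate (no permutation null); the
per-residue profile inherits any systematic guide biases uncorrected; the
structure mapping handles a constant offset only; the cavity surrogate is
not a pocket-quality score; and reproducing published per-gene dependency
correlations requires the specific external dependency-matrix release they
were computed on, which is out of scope here. The seven-segment count on
the real integrin α-V tiling data requires the original supplementary
count tables; the corresponding check runs only when those tables are
placed under `inst/extdata/itgav_tiling/` and is otherwise reported as
unmet, with parameters recorded.
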