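---
title: "Methods: contact networks, flexibility and groove geometry from protein-DNA trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact networks, flexibility and groove geometry from protein-DNA trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadmd)
```

# Scope and model

`dyadmd` post-processes molecular dynamics (MD) trajectories of protein-DNA
complexes, with the conventions used in studies of base-flipping reader
domains (such as the SRA domain of UHRF1) bound to CpG dyads carrying
cytosine modifications (5-methylcytosine, 5-carboxylcytosine, and their
oxidation relatives). The package does not run MD; it takes a topology
(PDB), coordinate trajectories (multi-model PDB or DCD), and a run
configuration, and produces:

1. per-frame hydrogen-bond and salt-bridge events and their time series;
2. occupancy-pruned, weighted residue/atom interaction networks;
3. RMSD traces, replica quality control, and per-residue RMSF profiles;
4. minor/major groove-width profiles of the DNA duplex;
5. binding-assay quantification (dual-colour EMSA normalization, 1:1
   isotherm K~D~ fits) for the wet-lab side of such studies.

Because real trajectories of this kind are rarely deposited, the package
treats its synthetic-data module as first-class: every analysis can be
validated against generators that plant the ground truth (contact
occupancies, fluctuation magnitudes, divergent replicas, known K~D~
values).

# Contact detection

**Hydrogen bonds.** An event is a (donor heavy atom D, bonded hydrogen H,
acceptor A) triple with d(D, A) <= 4.0 Angstrom and angle(D-H-A) >= 120
degrees. The distance is measured between heavy atoms (the convention of
the major trajectory tools), and the angle is the D-H-A angle with 180
degrees ideal. Both cutoffs are parameters (`hbond_dist`, `hbond_angle`).
Whether the original tools applied the angle test as D-H-A or H-D-A is a
known ambiguity of the 120-degree convention; D-H-A was chosen as the
standard reading, and the cutoff is configurable for sensitivity tests.

**Salt bridges.** An event is a heavy-atom pair from two oppositely
charged formal-charge groups within 5.0 Angstrom, with pairs inside one
residue excluded. Counting is deliberately per atom pair, not per group
pair: an arginine guanidinium facing both phosphate oxygens contributes up
to six simultaneous interactions, which is what makes average edge weights
greater than 2 interactions per frame possible. The charged set is the
classical force-field convention at neutral pH: Arg (NE/NH1/NH2, the NE
membership being configurable), Lys (NZ), Glu/Asp carboxylates, the
nucleotide phosphate (OP1/OP2), and the carboxylate of 5-carboxylcytosine
(O51/O52). Histidine is neutral by default and terminal charge groups are
excluded by default; both are `role_table` switches, since published
analyses rarely state those choices.

If a pair qualifies as both hydrogen bond and salt bridge in a frame, both
events are kept; removing the duplicate is a display decision made at the
network layer (`salt_bridge_precedence`), matching the figure convention
"only salt bridges are displayed".

# Networks

Contact series are recorded at atom-pair granularity and aggregated to
nodes only when a network is built: per-frame counts are summed into
node-level counts *before* statistics, so a node pair connected by two
always-present hydrogen bonds yields one edge of weight 2.0. Each edge
carries two statistics:

* `mean_count` — mean interactions per frame (the edge weight, printed to
  2 decimals only at presentation time);
* `occupancy` — fraction of frames with at least one interaction.

Pruning removes edges with occupancy less than *or equal to* the
threshold, reading "interactions occurring in <= X% of simulation time are
omitted" strictly; the package defaults are 0.15 (binding-pocket reports)
and 0.10 (finger-region reports). Occupancy, not mean count, drives
pruning; both statistics stay on every edge so the alternative reading can
be audited. Statistics are computed per kind independently; whether
published averages were computed before or after the salt-bridge/H-bond
display precedence is not documented anywhere we know of, so precedence is
applied after pruning and is switchable.

# Superposition, RMSD, RMSF, replica QC

Superposition is the closed-form Kabsch solution (SVD with a determinant
correction, proper rotations only). RMSD series use separate fit and
calculation selections: each frame is fitted to the reference on the fit
set (typically the C-alpha atoms of the structured core, e.g. residues
432-586 in SRA-domain numbering, excluding flexible termini) and the RMSD
is then computed over the calculation set (e.g. all DNA heavy atoms)
without refitting.

RMSF uses a two-pass protocol: fit all frames to the first frame, form the
mean structure, refit all frames to that mean, then compute per-atom RMSF
as the root mean squared deviation from the mean position. One iteration
of re-averaging is performed (no fixed point iteration); per-residue
values are unweighted means over the residue's heavy atoms. Mass weighting
is off by default — published methods typically state only "non-hydrogen
atoms" — and the isotopic-harmonic calibration RMSF = sqrt(3) sigma holds
for this convention.

Replica QC reproduces the divergence screen applied before merging
replicas: tail-window RMSD (protein-core fit, DNA calculation set, crystal
reference) with a 4 Angstrom exclusion threshold. Divergence screens of
this kind are usually stated as a bare threshold without naming the
statistic; we exclude on the *mean* tail RMSD and report the maximum
alongside, so the decision is auditable and the alternative statistic can
be checked from the report. Exclusions are always logged,
never silent. Merging concatenates the tails (the "last 100 ns" / "last
1000 frames" convention, resolved via the stored frame times) of all
passing replicas into one system trajectory.

# Groove widths

The El Hassan-Calladine construction is implemented as cross-strand
phosphate-phosphate distances with opposite offsets: at base-pair level i,
the minor groove pairs the strand-1 phosphate at level i+2 with the
strand-2 phosphate at level i-2, and the major groove uses the opposite
offsets. The +/-2 offset is this implementation's documented reading of
the method and is configurable (e.g. +/-3) so alternates can be compared;
a brute-force distance oracle in the test suite pins whichever convention
is configured. Raw P-P distances are reported by default; subtracting the
customary 5.8 Angstrom phosphate diameter is a flag, since published
distributions do not always state which was plotted. Positions whose
required phosphates do not exist — termini, and the gap left by the
flipped-out base — are explicitly undefined (NA), never zero-filled.
Base pairing is *declared*, not inferred, precisely because the flipped
base breaks geometric pair detection; a declared pair whose N1-N3 distance
exceeds 4 Angstrom in the reference structure triggers a warning.

# Kernel density estimates

Distance distributions (e.g. ring-centroid separations between a tyrosine
lid and the flipped base) attach a Gaussian KDE: the mean of Gaussian
kernels centred on the samples, bandwidth by Scott's rule
(sd(x) n^(-1/5), the covariance-factor convention of the scipy estimator
that typically backs such plots) or fixed. Zero-variance input is a
degenerate-input error rather than a delta spike.

# Binding assays

The dual-colour EMSA normalization is
(bound~550~ / bound~647~) x (total~647~ / total~550~): the bound-fraction
ratio of the modified probe against the unmodified internal control,
corrected for loading. It is scale-invariant per channel, so detector gain
cancels; a value of 2 is a two-fold binding preference. A zero bound
signal in the reference channel flags the lane instead of imputing.

K~D~ fitting uses the non-depleting 1:1 hyperbola
response = baseline + amplitude c / (c + K~D~), by Levenberg-Marquardt
least squares with the K~D~ start set to the concentration nearest
half-amplitude (deterministic given the data). The non-depleting
approximation is defensible when the fixed partner concentration (50 nM in
the motivating experiments) sits well below the fitted K~D~s (0.2-1.1
micromolar); a quadratic depletion model is available behind
`model = "quadratic"` for cases where it is not. A Hill coefficient is
deliberately not fitted: stoichiometry is fixed at 1:1.

# Synthetic data: what it emulates, and what it does not

The generators define the package's test conditions:

* `generate_bdna()` — a fiber-model duplex (rise 3.38 Angstrom, twist 36
  degrees, inter-strand backbone phase 154 degrees) of pseudo-nucleotides
  carrying only the atoms the analyses touch (P/OP1/OP2, C1', a
  six-membered ring with the pairing nitrogen aimed at the helix axis).
  Its helical symmetry makes interior groove widths exactly constant, and
  the phase angle makes major > minor as in B-DNA. It does not reproduce
  sugar pucker, sequence-dependent geometry, or realistic absolute groove
  widths.
* `plant_contact_trajectory()` — contacts planted with a >= 0.5 Angstrom
  margin inside the cutoff on "on" frames and 1 Angstrom outside on "off"
  frames, so floating-point jitter can never flip a detection; on-frames
  are drawn deterministically from the seed with exactly
  `round(occupancy x n_frames)` members, making recovered occupancies
  exact by construction.
* `harmonic_ensemble()` — isotropic Gaussian positional noise
  (RMSF = sqrt(3) sigma analytically). Real fluctuations are anisotropic
  and correlated; passing the calibration shows the estimator is
  unbiased, not that real proteins are harmonic.
* `make_replica_set()` — replicas with one member's DNA rigidly displaced
  (6 Angstrom by default, safely past the 4 Angstrom rule).
* `simulate_binding_curve()` — 16-point titrations at dissociation
  constants typical of SRA-domain/DNA binding (0.23 and 0.28 micromolar,
  the symmetric-carboxyl and hemi-methyl regimes) with 2%-of-amplitude
  noise for recovery tests.

Passing on these fixtures demonstrates correctness of the detectors,
statistics and conventions on planted truth. It does not demonstrate that
the published trajectory-scale numbers (specific edge weights, RMSF
differences between modification states, the 1-2 Angstrom groove shifts)
are reproduced: those derive from ~1 microsecond of undeposited
simulation and cannot be recomputed at desk scale.

# Numerical choices and problem sizes

* Distances in Angstrom, times in ps throughout; "last 100 ns" converts to
  frames via the stored frame times (nearest frame).
* Kabsch fits require >= 3 non-collinear atoms; degenerate geometry is an
  error, not a silent fallback.
* The KDE integral contract (= 1 within 1e-3) is checked over the sample
  range extended by 6 bandwidths.
* Detector-oracle equivalence is exercised on 200 random frames of a
  40-atom system; RMSF calibration uses 2000 frames of 40 noisy atoms plus
  a 12-atom static fit anchor; planted-network recovery uses 100 frames.
  These sizes give comfortable statistical margins for the stated
  tolerances (e.g. the relative standard error of a per-atom RMSF at 2000
  frames is about 1%) while keeping the default test run fast.
* Pipeline outputs are plain TSV/GraphML/JSON written with deterministic
  formatting; rerunning an identical configuration yields byte-identical
  tables, which the test suite asserts by hash.

# Known limitations

* No pi-stacking detection (not quantifiable with classical force fields,
  and deliberately out of scope), no energetic scoring, no pKa or
  protonation prediction beyond the static role table.
* Periodic-boundary minimum-image handling is not implemented; inputs are
  expected to be imaged/stripped, as is standard before this kind of
  post-processing. Synthetic fixtures are non-periodic.
* Groove analysis reports widths only — no full helicoidal parameter set.
* The replica-exclusion statistic (mean tail RMSD) is a documented choice;
  trajectories hovering exactly at the threshold deserve visual
  inspection of the reported series either way.

# A worked miniature

```{r example}
ints <- data.frame(kind = c("hbond", "saltbridge"), count = c(2, 1),
                   occupancy = c(1.0, 0.42))
tr <- plant_contact_trajectory(ints, n_frames = 100, seed = 1)
net <- build_network(contact_time_series(tr), make_node_map(tr$topology),
                     prune_occupancy = 0.15)
format_network(net)
```

The always-present pair of hydrogen bonds appears as a single edge of
weight 2.00; the salt bridge planted at occupancy 0.42 survives the
15% pruning with its exact occupancy.
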