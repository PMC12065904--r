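---
title: "Methods: integrative mapping of the CaVbeta-actin interaction and its functional readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative mapping of the CaVbeta-actin interaction and its functional readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betactin)
```

# Scope

`betactin` implements the analysis core of an integrative study of how
voltage-gated calcium channel beta subunits (CaV&beta;) bind filamentous
actin and what that binding does to L-type channel function. The pipeline
has two arms:

* **Structural**: residue-pair reports from cross-linking mass spectrometry
  (XL-MS) are normalized and consensus-filtered; the surviving C&alpha;-C&alpha;
  distance restraints are screened for self-consistency by an exhaustive
  rigid-body scan (accessible interaction space); docking-model ensembles
  built from such restraints are evaluated with CAPRI-style RMSD metrics,
  neighbour-count clustering, restraint-violation checks and residue
  contact-frequency maps; and consensus computational alanine scanning ranks
  interface hotspots.
* **Functional**: whole-cell electrophysiology (Boltzmann activation,
  gating-charge integration, stationary noise analysis, bootstrap group
  comparison) and in vitro biophysics (two-state thermal unfolding of the
  intrinsic-fluorescence spectral center of mass, F-actin cosedimentation
  bound fractions).

Search-engine identification of cross-linked spectra, the docking engine's
refinement stages, force-field energy evaluation and electrostatic-surface
computation are out of scope: energies and residue-pair tables are inputs.

A seeded synthetic-data module generates inputs with the statistical and
geometric structure each stage assumes, so the whole pipeline runs and is
testable offline.

# Structure handling

Structures are plain atom tables parsed from PDB files (via bio3d).
Alternate locations are resolved to the highest-occupancy conformer (ties to
the first encountered); hydrogens and waters are dropped; author residue
numbering is never altered. Superposition uses the closed-form Kabsch
solution with a proper-rotation correction; contacts are defined by any
selected-atom pair within a cutoff.

Relative solvent accessibility divides a Shrake-Rupley per-residue SASA by a
per-residue reference maximum. The sphere sampling is a deterministic golden
spiral (960 points/atom by default; results are reproducible and converge to
within ~2% of a 10&times; denser run on test peptides). The shipped reference
maxima are theoretical Gly-X-Gly values stored in
`inst/extdata/max_sasa_reference.csv`; they approximate, but do not
reproduce, NACCESS output, whose run parameters (probe radius, slice width)
vary between installations. Values slightly above 100% are possible and expected for
conformations more exposed than the reference context.

# Cross-link consensus

Engine exports are normalized to one row per cross-linked residue pair with
provenance (engine, linker, replicate); user-supplied column maps adapt
arbitrary delimited exports. Unique inter-protein cross-links (inter-XLs)
are unordered residue pairs; provenance is pooled over records, and pair
identity deliberately ignores the linker, so the same pair found with DSSO
(10.3 &Aring; spacer) and DSBU (12.5 &Aring;) is a single unique inter-XL.
The consensus filter keeps pairs reported by at least two distinct search
engines — the rule used to prioritize reliable contacts — and
`venn_counts()` reports the provenance partition. Construct-to-reference
(UniProt) numbering offsets are applied explicitly via a per-protein offset
table because search results are construct-local.

# Accessible interaction space and restraint filtering

Cross-linker chemistry bounds the C&alpha;-C&alpha; distance of a genuine
cross-link: restraints are set to 0-30 &Aring;, covering two lysine side
chains, the spacer and conformational dynamics. `restraint_scan()`
enumerates rigid-body poses of the scanning chain around the fixed chain —
a deterministic set of quasi-uniform rotations (Shoemake quaternions from a
seed; the identity is always included) crossed with a translation grid over
the fixed chain's bounding box plus the maximum bound as margin. A pose is
rejected if any inter-chain atom pair is closer than the clash distance; a
restraint is satisfied when the minimum anchor distance over its ambiguity
set (e.g. the equivalent residue on either of two adjacent filament
subunits) lies within its bounds.

Defaults are 576 rotations, a 2 &Aring; grid and a 2.5 &Aring; clash
distance. This direct enumeration reproduces the *behaviour* of an
FFT-accelerated exhaustive search at toy scale; it is a fidelity emulation,
not a numerical replica of any particular server, and it will not reproduce
another implementation's pose counts number-for-number. The
translation grid is pre-classified once per scan: positions farther from
every fixed atom than the ligand's bounding radius plus the clash distance
can never clash under any rotation and skip the per-atom test, which makes
the default sampling run in tens of seconds on the toy systems.

The **violated fraction** of a restraint is the fraction of non-clashing
poses at a consistency level in which it fails. The level defaults to
`n_max - 1`, one below the highest attained restraint count; because conventions differ
between implementations, the level is configurable.
`iterative_filter()` repeats the scan, discarding restraints whose violated
fraction reaches the threshold (default 0.8; what counts as a "high
probability of being a false positive" is a judgement call, so the
threshold is exposed) until a fixed point.
`interaction_fraction()` reports, for poses at the top consistency level,
how often each residue contacts the partner; the `> 0.5` selection used to
nominate docking-active residues is left to the caller.

# The planted toy complex

`make_toy_complex()` builds the geometry the structural stages assume: two
elongated pseudo-subunits (60 C&alpha; beads each on self-avoiding curves,
chains A and C, mimicking two adjacent filament subunits seen side-on) and a
50-bead ligand planted clash-free over the groove between them. True
cross-links are sampled with planted distances in 8-28 &Aring;. Planted
false positives are *geometrically impossible*: each is at least 45 &Aring;
long in the planted pose and conflicts, by triangle inequality, with at
least four true restraints (its fixed anchor is farther from theirs than
2 &times; 30 &Aring; plus the corresponding intra-ligand anchor span), so no
rigid pose can satisfy it jointly with the true set and its violated
fraction at level `n_max - 1` is exactly 1. The generator verifies this
contract on every draw with a reduced-sampling scan and re-rolls designs in
which a randomly planted *true* restraint is itself so much tighter than the
rest that it would look like a weak link (violated fraction above 0.4); this
rejection sampling is part of the generator's definition, not a tuning of
any analysis threshold.

Two design notes follow from the pseudo-atom nature of the toys. First, the
default planted anchors are unambiguous: with subunit-ambiguous anchors
(`A:i|C:i`) and 0-30 &Aring; windows on a ~75 &Aring; object, every single
restraint is satisfiable almost everywhere and planted false positives would
be undetectable at any threshold; an `ambiguous = TRUE` mode exists to
exercise the ambiguity machinery. Second, C&alpha;-only chains have no side
chains, so contact-based analyses on toys use inflated cutoffs (typically
8-10 &Aring; instead of 5 &Aring;); the analysis functions themselves
default to the real-protein values.

# Docking-ensemble evaluation

Model quality and similarity follow the CAPRI conventions:

* `global_rmsd` — C&alpha; RMSD over all residues after fitting on the same
  atoms;
* `i_rmsd` — backbone RMSD over the reference-defined interface (any heavy
  atom within 10 &Aring; of the partner), after fitting on those interfacial
  atoms;
* `l_rmsd` — backbone RMSD over the ligand after fitting on the receptor;
* `i-l-RMSD` — fit on the receptor side of the ensemble-wide *flexible
  interface* (union over models of residues in contact at 5 &Aring;),
  measured on its ligand side; this is the clustering metric.

Clustering picks the model with the most neighbours within 7.5 &Aring;
(ties resolved to the lower model index, since docking-engine internal
order is not reproducible), forms a cluster of the centre plus neighbours
when it reaches 4 members in total, removes them and repeats. The conventional
clustering parameter "number of neighbors of 4" is ambiguous between "4
neighbours" and "4 members"; the minimum-cluster-size reading is the
default and the parameter is exposed. Clusters are ranked by the mean HADDOCK score
(`1.0 E_vdw + 0.2 E_elec + 1.0 E_desol + 0.1 E_air`, lower better) of their
four best members; energies are read from the ensemble manifest, never
computed.

Restraint checks classify the per-model minimum-ambiguity C&alpha;-C&alpha;
distance as satisfied (&le; 30 &Aring;), tolerated (30-35 &Aring;, the
allowance used in the literature for cross-link flexibility) or violated
(> 35 &Aring;). Contact frequency is the fraction of models in which a
residue touches the partner within 5 &Aring;. Cross-complex comparison
(e.g. between complexes of two beta-subunit isoforms) computes l-RMSD and
interface RMSD over an explicit residue correspondence table — the package
does not embed an aligner — and reports the interface sequence identity.

# Hotspot consensus

Alanine-scanning &Delta;&Delta;G predictions (kcal/mol, positive =
destabilizing) from several predictors on several docked structures are
averaged over models first (to absorb docking flexibility) and then over
predictors (to form the consensus), exactly in that order; an unweighted
grand mean is available behind `grand_mean = TRUE` for sensitivity checks.
Raw values are averaged without per-predictor rescaling (the six common
predictors report broadly comparable kcal/mol scales); an optional
per-predictor z-score mode is deliberately not the default because it
changes the meaning of the consensus; residues covered by fewer than half the
predictors are excluded with a warning, since a consensus over one or two
tools is not a consensus. Hotspot selection takes the top-k residues
(k = 7 by default) plus explicit manual additions (the workflow's
structurally motivated extra pick), and `aid_overlap()` checks the
selection against the residues critical for binding the channel
&alpha;-subunit AID helix — disjoint sets mean actin binding and channel
anchoring use different surfaces.

# Electrophysiology

Units are pA, mV and ms throughout, so a current integral is directly in fC
and the noise-analysis axes are in nS. Inward currents are negative; all
quantities are computed with signed values, which makes both axes of the
variance-mean plot positive below the reversal potential.

* **Activation**: per-voltage peak current (most negative value in the step
  window after 2-point smoothing), normalized to the maximal magnitude
  (I/Imax) and fitted with the Boltzmann curve
  `P(V) = 1 / (1 + exp(-(V - V_half)/k))`, in its standard form (the reversal
  potential does not enter the formula). I/Imax is fitted directly, without
  a driving-force correction.
* **Gating charge**: the On gating transient recorded at the reversal
  potential is baseline-subtracted (mean of the pre-step window) and
  integrated over the step by the trapezoidal rule; pA&middot;ms &equiv; fC.
* **Stationary noise analysis**: with unitary current
  `i = gamma (Vm - Vrev)` and `n` independent binomial channels,
  `sigma^2 / (I (Vm - Vrev)) = -(1/n) (I / (Vm - Vrev)) + gamma`.
  Per voltage, the mean and unbiased variance across repeated sweeps are
  computed per time point inside the stationary window and averaged; the
  window defaults to the final 50% of the step, where macroscopic activation
  has settled. A linear fit gives `gamma` (intercept) and
  `n` (negative reciprocal slope); `Po_max = I_max / (n i)` at the voltage
  of maximal current. A non-negative slope is a hard error ("channel count
  unresolvable"). Optional sweep-drift correction and background-variance
  subtraction are off by default.
* **Bootstrap comparison**: group summaries and the two-sided p-value come
  from 500,000 resamples with replacement of the per-cell estimates (cells,
  not sweeps, are the exchangeable unit), with
  `p = 2 min(P(diff <= 0), P(diff >= 0))` and a `+1/(n_boot+1)` continuity
  correction.

The sweep simulator draws open-channel counts i.i.d. Binomial(n, Po(V)) per
time point (true stationarity) and adds Gaussian instrument noise; a
two-state Markov mode with matched stationary Po exists for robustness
checks only. Simulated currents follow `I = n gamma (Vm - Vrev) Po`, which
is negative below the reversal potential without any extra sign flip.

# Thermal unfolding and cosedimentation

The spectral center of mass `CM = sum(F lambda) / sum(F)` tracks unfolding;
the melting curve is fitted with the two-state model with sloping baselines

$$y = \frac{\alpha_n + \beta_n T}{1 + e^{4 T_m (T - T_m)/(T \Delta T)}} +
      \frac{\alpha_d + \beta_d T}{1 + e^{4 T_m (T_m - T)/(T \Delta T)}}.$$

The temperature unit inside the exponent matters because `T` appears in a
denominator; dimensional consistency favours absolute temperature, so the
fit works in Kelvin by default and reports `T_m` in &deg;C, with a
literal-Celsius mode behind `kelvin = FALSE` for comparison with fits that
use the expression verbatim in &deg;C. Both modes invert their own
noiseless forward curves to better than 0.01 &deg;C. Initialization takes
`T_m` at the steepest CM change and baselines from the terminal quarters of
the scan. CM is fitted in nm.

Cosedimentation bound fractions are `pellet / (supernatant + pellet)` per
replicate lane (band intensities arrive background-corrected; densitometry
itself is upstream). Summaries are mean &plusmn; SD per condition with Welch
two-tailed t-tests between conditions and a Kendall rank-correlation trend
report for numeric condition series such as a NaCl titration.

# What the synthetic data do and do not show

The generators reproduce the *statistical and geometric structure* each
analysis assumes: provenance-designed cross-link reports, a planted binding
pose with in-reach true and impossible false restraints, pose families with
known cluster membership and energies correlated with displacement, planted
&Delta;&Delta;G hotspots (2.0 &plusmn; 0.3 vs 0.0 &plusmn; 0.2 kcal/mol,
6 predictors &times; 4 models), binomial channel ensembles at study
magnitudes (12,000 channels, 3.9 pS, 100 sweeps, 150 ms steps, Ba2+
reversal near +70 mV), alpha-function gating transients with planted charge
(300 fC scale), two-state melts (T_m 55 &deg;C, &Delta;T 5) and log-normal
densitometry around bound fractions of 0.24/0.11/0.09. They do not emulate
real protein folds, side-chain packing, correlated gating beyond the
flagged two-state mode, spectra, or gel artefacts — so green tests
demonstrate algorithmic correctness and parameter recovery under the stated
models, not performance on any particular laboratory data set.

Problem sizes in the tests and acceptance script (60+60/50-bead toys, 576
rotations on a 2 &Aring; grid, 10-model ensembles, 100-run recovery
batches, 500,000 bootstrap resamples) were chosen as the smallest sizes at
which each statistical claim is sharp.

# Known limitations

* The rigid-body scan treats both chains as rigid and samples rotations
  quasi-uniformly; very anisotropic accessible spaces would need more
  rotations (the count is a parameter).
* Violated fractions at a consistency level are a ranking heuristic; a true
  restraint that is far tighter than the rest of its set can legitimately
  look like a weak link, which is why the discard threshold and level are
  exposed rather than fixed.
* Relative accessibility depends on the reference maxima table; users
  comparing against other software should supply that software's table.
* The ensemble evaluator assumes shared topology and numbering across
  models, as docking outputs provide; it does not renumber or align.
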