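---
title: "Models and methods behind neofold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neofold}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(neofold)
```

neofold models how structural variants (SVs) — deletions, duplications,
inversions, translocations and circular ecDNA amplicons — rewire the 3D
folding of chromatin, and provides the statistics used to characterize SV
breakpoint distributions. This vignette explains the models, the parameters
that matter, the numerical choices we made where the methods literature
leaves them open, and what the synthetic-data tests do and do not
demonstrate.

## The strings-and-binders (SBS) polymer model

Chromatin in a genomic window is a chain of beads, one per fixed-size bin
(default 5 kbp). Each bead carries non-negative integer multiplicities of
`M` *binding-site classes* (`polymer_model()`). Diffusing binder particles
of class `c` attract beads with sites of class `c`; binders bridging two
beads of a shared class fold the chain, which is how the model produces
TAD-like blocks, loops, and compartment-style patterns from a
one-dimensional binding-site annotation.

`run_sbs()` samples conformational ensembles of this system in reduced
units (bead diameter σ = 1, kT = 1, mass = 1):

* bonded beads (and the closing pair of a circular chain): harmonic bond,
  stiffness 50 kT/σ², rest length 1 σ;
* non-bonded bead pairs: WCA repulsion (excluded volume);
* bead–binder pairs of a matching class: truncated-shifted Lennard-Jones
  attraction of depth `interaction_energy × multiplicity` (default
  4 kT), cut at 2.5 σ; non-matching pairs see WCA only;
* binder–binder: ideal (no interaction);
* a soft harmonic wall confines all particles to a cube (default side
  10 σ).

The bonded/excluded-volume constants are our choices within the standard
coarse-grained polymer conventions; they are not claimed from any specific
source, and the observables we target (equilibrium contact frequencies)
are insensitive to their precise values. The pair force is clamped at
1000 kT/σ at deep core overlap — a numerical guard for startup
configurations that equilibrium states (≫ kT above the clamp radius)
never reach.

**Two integrators, one ensemble.** The default sampler is Metropolis
Monte Carlo on continuous coordinates; the alternative is Langevin
dynamics under a velocity-Verlet (BAOAB) scheme (default dt = 0.005,
friction 1). Both use exactly the same potential, so both target the same
Boltzmann distribution: the test suite verifies per-pair contact
frequencies agree within 3 Monte-Carlo standard errors on a 20-bead chain,
which is the strongest cross-validation available without an exact
solution. MC is the reference because it is simpler to verify against a
brute-force energy evaluation; Langevin additionally yields dynamics.

**Binder counts from concentration.** A molar binder concentration only
becomes a particle count through a volume. We convert via the confinement
box: with a 50 nm physical bead diameter (a conventional scale for a
5 kbp bead) and a 10-diameter box, 200 nmol/L maps to 15 binders per
class (`binders_from_concentration()`). Both the box side and the bead
diameter are configurable, and the count can be overridden directly.

**Contacts and ensemble scores.** Two beads are in contact when their
Euclidean distance is ≤ `contact_radius` (default 3.5 bead diameters;
no canonical value exists, and the package treats it as an explicit
parameter everywhere). The first 50% of recorded frames are discarded as
burn-in by default — "reaching steady state" is otherwise unquantified,
and the integrator-agreement test is the check that this suffices at the
sizes we use. From an ensemble the package computes:

* `triplet_colocalization()`: for a target bead X and regions A, B, the
  correlation-style score
  `(P_XAB − P_XA·P_XB) / sqrt(P_XA(1−P_XA)·P_XB(1−P_XB))` — 0 under
  independence, 1 under perfect co-occurrence;
* `insilico_expression()`: per conformation `log(Σ_i 1/d(target,i) / F)`
  over regulatory peak beads `i`, natural log. `F = "auto"` uses the
  ensemble mean of the inverse-distance sum, centring the mean log-ratio
  near zero; with this normalization the score is invariant to the length
  unit of the coordinates, so no physical distance calibration is needed.

## Inferring binding sites from Hi-C: regularized simulated annealing

`sa_fit()` solves the inverse problem: find the binding table whose
*mean-field* contact map best matches an experimental matrix. The
mean-field reconstruction (`reconstruct_meanfield()`) is

    P(i,j) = p0(d_eff) · (1 + κ · Σ_c s_c · min(b_ic, b_jc))

with `p0(d) = max(d,1)^(−α)` the coil-globule distance-decay baseline
(default α = 1 at TAD scale — an implementation choice, configurable),
`d_eff` the linear bin separation or, for circular loci, the minimal
distance around the ring, and κ an affinity gain (default 1). The
`min()` form counts the shared binding capacity of a pair; per-class
strengths `s_c` default to 1.

The cost is `‖normalize(target) − normalize(reconstruction)‖_L1 +
λ · (total sites)`, with both matrices scaled to unit upper-triangle sum:
the comparison is between contact-map *shapes*, not sequencing depths.
L2 is available. The target is pre-smoothed with a 0.5-bin Gaussian
filter (`smooth_matrix()`).

**Annealing scheme.** Each iteration draws several tentative single-site
modifications (add/remove/swap one site on a random bead; default 8
candidates), evaluates all, and submits the best to Metropolis acceptance
at the current temperature (geometric schedule, T0 = 0.05 on the
normalized-cost scale, cooling 0.9997, 20 000 iterations by default).
Because candidate selection is greedy, this is an optimization scheme,
not an equilibrium sampler — appropriate for annealing, where only the
final minimum matters.

Two numerical choices deserve emphasis, both driven by the `min()`
affinity being a *pair* property:

* **Initialization.** A single site on an otherwise empty chain changes no
  pairwise affinity, so an empty start gives the optimizer no gradient and
  the sparsity penalty pins it at zero sites. Worse, an iid random start
  is pure pair noise that costs *more* than the empty baseline. The
  default start is therefore spatially correlated: random contiguous runs
  (about 10 beads) of one random class each, which seeds same-class pairs
  the anneal can refine at any `M`.
* **Segment moves.** Single-site moves cannot cross the barrier between
  class-labeling optima: splitting a wrongly merged class degrades the fit
  until many beads have moved. One quarter of iterations therefore
  propose relabeling a short random run of beads from one class to
  another. With these moves, recovery of planted 3-class structures is
  seed-independent in our tests; without them, two thirds of seeds stalled
  in merged-class optima.

**Hyperparameter selection.** `select_lambda()` fits across a λ ladder and
returns the largest λ whose data-fidelity cost stays within 10% of the
low-λ plateau — the strongest sparsity that costs nothing, with the
largest qualifying λ as the tie-break. `select_n_classes()` increases `M`
until the relative fidelity gain of one more class drops below 2%
(configurable; 0 disables early stopping). `rescale_monomer()` resamples
the matrix to longer or shorter bead lengths by bilinear interpolation
(scale 2 is exactly 2×2 block averaging), so fits can be scanned across
monomer lengths to absorb persistence-length effects; the scan keeps the
scale with the best distance-corrected correlation.

Matrix similarity is always reported as the **distance-corrected Pearson
correlation** (`distance_corrected_correlation()`): subtract each
diagonal's mean from both matrices, then correlate the off-diagonal
residuals — otherwise the decay trend dominates any comparison.

## Bridging classes across chromosomes through epigenetic tracks

A fitted region tells us which binding classes co-occur with which
epigenomic signals. For an unfitted region (e.g. the partner of a
translocation on another chromosome) the package transfers classes
probabilistically through tracks (`build_transfer_model()`,
`transfer_classes()`). For indicator variables the identities
`E(1_X) = p_X`, `var(1_X) = p_X(1−p_X)` turn the observed class–track
correlation into a conditional probability:

    P(C|T) = P_C + corr(C,T) · sqrt(P_C(1−P_C)(1−P_T)/P_T)

and the target-region profile is `P_C(x) = Σ_i P(C|T_i)·P_{T_i}(x)` over
couples with correlation > 0.2 (strictly greater; the rule is one-sided
as stated, so anti-correlated couples are excluded — documented, and
configurable via the threshold). The sum neglects track-intersection
terms; the model therefore *reports* the track–track correlations and
warns when any exceeds the threshold rather than silently assuming
independence. Sums can exceed 1 when multiple couples fire; values are
clipped to [0, 1] with a warning. Binarization of raw tracks is not
dictated by the transfer algebra; defaults are peak-overlap for
peak-like tracks and a top-quartile rule for coverage tracks
(`binarize_track()`).

## Rearranged and circular loci

`assemble_hybrid()` concatenates ordered, oriented reference segments
into a hybrid locus, with 0-based half-open coordinates throughout and
boundaries snapped down to the bin grid. For circular (ecDNA-like)
topology, an inert 80 kbp buffer closes the ring by default — it carries
no binding sites and interacts only through the distance-decay baseline,
a conservative stand-in for ring closure when the complete amplicon
structure is uncertain (population heterogeneity typically prevents
resolving it). Bin-level maps to and from reference coordinates are kept
(`hybrid_to_reference()`, `reference_to_hybrid()`), and reverse-oriented
segments map order-reversed.

`predict_neo_contacts()` runs the mean-field reconstruction on the hybrid
with `d_eff` the minimal circular distance. `predict_unjoined_contacts()`
is the control: identical within-segment contacts, zero cross-segment
contacts, isolating exactly what the rearrangement creates.
`call_candidate_neoloops()` picks candidate neoloops as local maxima of
distance-stratum z-scores (observed-over-expected per effective distance,
default z ≥ 2, 3×3 local-maximum filter, buffer anchors excluded) — a
deliberately simple peak picker meant for comparing predictions, not a
replacement for loop callers on experimental data.

## SV annotation and breakpoint statistics

* `classify_intra_sv()`: duplication when the junction orientation is
  `-+`, `++` or `--` *and* the inter-breakpoint copy-ratio exceeds 1.35;
  deletion when the orientation is `+-` and the ratio is below 0.65;
  otherwise unclassified. The thresholds sit well below the clonal
  1.5/0.5 to allow for allelic and population heterogeneity.
* `shuffle_svs()`: the enrichment null — every shuffled SV keeps its
  chromosome(s) and exact breakpoint separation, placed uniformly among
  valid positions.
* `breakpoint_enrichment()`: one side of each real junction is sampled
  (seeded) to reduce within-junction dependence; the same side is read
  from every null copy. Real and null property values are pooled and
  rank-transformed to (0, 1) with average ranks on ties, and the real
  ranks are tested against Uniform(0,1) with a one-sided
  Kolmogorov–Smirnov test. Testing pooled ranks against the uniform
  reference (rather than a two-sample test against the empirical null) is
  the cleaner reading of the procedure; with 100+ null sets the pooled
  rank distribution is dominated by the null and the two variants
  coincide in practice. The "greater" direction tests for breakpoints in
  *high* property values; it is configurable per property.
* `adjust_by()` applies Benjamini–Yekutieli FDR control (valid under
  arbitrary dependence) across a suite; significance is reported at
  q < 0.01.
* `match_loops()` / `match_svs()` / `jaccard_similarity()`: two loops are
  the same when both anchor midpoints lie strictly within 50 kbp; pairs
  are resolved greedily nearest-first into a one-to-one matching. Reusing
  the 50 kbp rule for SV sets (both breakpoints within tolerance, same
  type) is a package convention, not an external definition, and the
  tolerance is an argument.

## The synthetic-data generator

`synthetic_spec()` and the `make_*()` generators produce every input with
known ground truth: block or interleaved class layouts on a polymer;
contact maps from either the mean-field forward model or a full SBS
ensemble; tracks equal to class indicators plus Gaussian noise (noise 0
gives correlation exactly 1, the planted couple); SV sets with the
orientation conventions above on a toy genome of two 10 Mbp chromosomes
at 5 kbp bins (big enough for stable rank statistics, small enough that
the 200-repetition type-I-error simulation runs in about a minute); and
CNV profiles painted at ratio 2.0 / 0.5 inside duplications / deletions —
far beyond the 1.35/0.65 thresholds so planted labels are unambiguous.
Duplication and deletion intervals are kept disjoint by rejection
sampling for the same reason. Intrachromosomal spans default to
50–500 kbp, keeping dozens of disjoint CNV intervals placeable on the toy
genome.

What passing these tests shows: the algebra is exact, the optimizer
recovers planted structure generated by its own forward model, the
samplers agree with each other, and the statistics control error rates
under their stated null. What it does not show: robustness to the
mismatch between the mean-field model and real Hi-C (ligation noise, CNV
distortion, unbalanced coverage, heterogeneous cell populations), nor
sequencing-level artefacts — the generator deliberately emulates none of
these.

## Problem sizes and runtimes

The shipped tests and the acceptance script use: 100-bead, 3-class
polymers for annealing recovery (three independent seeds, 30 000
iterations each, seconds per fit); 20-bead chains for the
integrator cross-check; 200 simulated enrichment suites of 30 SVs against
100 shuffled null sets each; and the 121-bin circular hybrid (70 kbp +
455 kbp segments + 80 kbp buffer) for neoloop prediction. These sizes were
chosen so the full suite completes in a few minutes on one CPU while
leaving each statistical check adequately powered.

## Known limitations

* The mean-field reconstruction is a first-order model: it ignores
  binder competition, cooperative globule formation, and
  loop-extrusion-style mechanisms.
* SA hyperparameters (T0, cooling) are tuned for matrices normalized to
  unit sum; grossly different problem scales may need retuning.
* The transfer model is linear in tracks by construction and cannot
  represent class–track relationships that require track interactions.
* Heterogeneous sub-population mixtures (multiple amplicon structures in
  one sample) are out of scope; predictions describe a single assembly.
* `call_candidate_neoloops()` is a comparison heuristic; use dedicated
  loop callers for discovery on experimental matrices.
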