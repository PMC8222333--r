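---
title: "Models and methods behind SpecProfiler"
author: "SpecProfiler authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind SpecProfiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

SpecProfiler analyzes sorted-library sequencing experiments that probe the
sequence specificity of CRISPR–Cas12a nucleases, plus the companion readouts
such experiments travel with: directed-evolution enrichment screens,
amplicon editing quantification, and concentration/time-course curve fits.
This vignette is the package's own account of the models it fits, the
parameters that matter, and the design decisions taken where the methods
literature leaves room.

## Coordinate frame

Everything hangs off one coordinate frame, fixed in `TargetSite`: the
sequencing construct is 5'-flank–PAM–protospacer–flank-3' on the displayed
strand, with PAM positions labelled P1..P4 (5'→3') and protospacer positions
1..21 numbered from the PAM-proximal base. Cas12a places its PAM 5' of the
protospacer; the "seed" is protospacer positions 1–7, and positions 9–11 are
the characteristic low-specificity centre of the protospacer. All library
variants, penalty matrices and simulators share these labels, which is what
makes variant IDs (`"mP2A+m5C"`, consensus `"WT"`) stable join keys across
modules.

## Library design

`buildMismatchLibrary()` enumerates every sequence whose mismatched
positions fit in at least one contiguous window of `windowWidth` (default
4 nt) tiled across PAM plus protospacer. Overlapping windows generate the
same sequence more than once; duplicates are removed by exact sequence
identity — pooled physical oligos would instead inflate the consensus, a
nuisance the analysis modules must not inherit. Emission order is
deterministic (first window offset, then lexicographic), so identical calls
give byte-identical libraries. Whether the randomized windows should also
tile the PAM is genuinely open; the default tiles both, and
`region = "protospacer"` restricts to the protospacer.

`enumerateMismatchLibrary()` exposes the same enumeration over a bare
consensus of any length. This matters because the estimator-identity
experiments below use a 6-nt frame (640 variants), which is smaller than any
biologically valid target site; the enumeration and the fits are agnostic to
the frame, so small exhaustive frames double as cross-check territory
(brute-force span filtering reproduces the enumerator exactly for all
lengths ≤ 8).

## From reads to counts

Fraction reads are anchored by both constant flanks (exact match by default;
`maxFlankMismatches` relaxes it) and the variable region is assigned to a
library variant by exact sequence match only. Library members can differ by
a single base, so error-tolerant assignment would cross-assign variants;
sequencing errors instead land in an audited "unmatched" tally. Reads with
ambiguous bases never match. The cost of this choice is depth, the benefit
is an assignment with no mismatch-dependent bias — which is the quantity the
whole analysis is about.

Frequencies use a Jeffreys-style pseudocount, f_i = (c_i + α)/Σ(c_j + α)
with α = 0.5, applied at normalization time so stored counts remain raw.

## The two estimators

Binding: lnK_A(i) = ln[(f_bound,i/f_bound,WT)/(f_unbound,i/f_unbound,WT)].
Under a single-site Boltzmann partition — bound probability
f_i = 1/(1 + exp(E_i − μ)) with a global chemical potential μ — the
bound/unbound odds are exp(μ − E_i), so the ratio-of-ratios has expectation
exactly −E_i. The estimator is invariant to depth differences between
fractions, which is also why no depth matching is attempted. Standard
errors come from the delta method: sqrt of summed reciprocal pseudocounted
counts over the four cells involved.

Cleavage: Δd(i) = ln[(f_uncut,i/f_uncut,WT)/(f_input,i/f_input,WT)], with
the mock digest as input. Under first-order kinetics with
k_i = k_ref·exp(−E^c_i), E[Δd] = C·(1 − exp(−E^c_i)), C = k_ref·t.

Sign conventions are chosen once and used everywhere: lnK_A is
affinity-positive (mismatches are negative), penalties ε are
positive-is-worse, Δd is positive-is-less-cleaved. Both logos then read
"penalty of mismatches".

## Penalty-matrix fits

The binding model is linear in its parameters: −lnK_A regressed on
per-(position, base) mismatch indicators, weights 1/SE², no intercept (the
consensus anchors zero). Linearity is not an approximation — the log-odds
identity makes the additive model exact under the partition model — so
"fitting" reduces to weighted least squares, and noiseless data is recovered
to machine precision.

The cleavage model is genuinely nonlinear: Δd_i = C·(1 − exp(−Σ_p ε^c)).
It is fit by Levenberg–Marquardt with an analytic Jacobian, initialized by
profiling: for any fixed C the model linearizes through
−log(1 − Δd/C), so a grid of C candidates each yields a closed-form start,
and the best seeds the refinement. C is parameterized on the log scale
(positivity), and when replicates are fit jointly each replicate gets its
own C — exposure times may differ between replicates; energies may not.
Pre-averaging replicates (inverse-variance) is available behind
`preAverage = TRUE` but the joint fit is the default.

Identifiability is treated explicitly rather than silently:

- A (position, base) never observed in the measures is flagged
  `"unidentifiable"`, not reported as 0.
- Penalties estimated at or above `satBound` (default 8 natural-log units)
  are flagged `"saturated"`: the data only bound them from below.
- When all Δd are zero, penalties are zero and C is *unidentifiable*,
  reported as NA.
- Single-mismatch-only data cannot identify (ε, C) jointly — every pair
  with the same C(1 − e^{−ε}) fits identically. Multi-mismatch variants
  supply the curvature that pins C, which is one reason the windowed
  library design (up to 4 contiguous mismatches) is analytically
  convenient and why the tests exercise exactly that configuration.

`matrixToPwm()` converts penalties to per-position Boltzmann probabilities
exp(−ε/τ)/Σexp(−ε/τ); saturated entries act as infinite penalties
(probability 0), unidentifiable entries are excluded from the normalization
and returned as NA.

## PAM profiling

The exhaustive 256-member PAM library is scored with the same estimators;
scores are oriented larger-is-more-active (lnK_A as-is, Δd negated) and
anchored at the consensus PAM. Ranks 1..256 break ties lexicographically so
output is deterministic. Degenerate classes (TTTV etc.) are summarized by
averaging member scores. Comparison against external activity tables uses
Spearman correlation over the shared PAMs, which makes the comparison
invariant to any monotone transform of either scale — appropriate since
external assays report on arbitrary activity scales.

## Directed-evolution enrichment

Per-round amplicon reads are compared to the reference coding segment;
substitutions are counted per position and normalized by per-position depth.
Reads whose length differs from the reference carry indels; the bacterial
survival assay selects frameshifts out, so such reads count toward depth but
never toward mutation calls. Positions with zero depth report missing — not
zero — frequencies. Fold enrichment of round r uses a frequency floor of
1/depth at round 0, so mutations unobserved in the input still get finite
folds. Residue labels (e.g. M537R) come from translating the single-base
change within its codon, with the codon numbering offset of the mutagenized
segment.

Dominance calling uses two thresholds the assay itself does not define, so
they are explicit arguments: final-round frequency ≥ 0.1 and a
non-decreasing run of ≥ 3 consecutive rounds. Setting them to 0 and 1
degenerates to "all observed mutations".

## Amplicon editing

Reads (merged amplicons) are aligned to the reference by global
Needleman–Wunsch with affine gaps (match +2, mismatch −2, gap open −10,
gap extend −1), with strand rescue via the reverse complement. Among
score-equivalent indel placements in repeat context, the indel is slid to
the placement whose midpoint is nearest the predicted cut — the
re-alignment convention that concentrates indels at the cut site, where the
scoring window lives. Reads scoring below 40% of the perfect score are
discarded as "no alignment" and reported as such.

Window geometry, with 0-based half-open coordinates throughout: Cas9 cuts
3 nt 5' of its PAM and indels are scored over cut ± 4 (8 nt); Cas12a
nominally cuts PAM-distal after protospacer position 18 and is scored over
[cut − 3, cut + 6) (9 nt, strand-mirrored on the minus strand). Published
descriptions of both windows are ambiguous about anchoring, so both the cut
offset and the window are config overrides. Insertions exactly on a window
boundary count as inside — a one-sided choice documented here rather than
hidden.

Classification order is HDR first (when a donor is configured), and strict:
the read's implied sequence over the full donor interval must equal the
expected allele exactly; donor-matching reads with extra window indels fall
through to NHEJ. Substitution-only reads are unedited, because editing here
is an indel phenomenon. This makes the HDR calls conservative — sequencing
errors inside the donor interval (≈1.6% of reads for a 16-nt interval at
0.1%/base) demote true HDR reads to unedited/NHEJ, a bias visible in, and
bounded by, the simulator round-trips.

## Curve fits

Concentration–response uses the 4-parameter logistic
r(c) = bottom + (top − bottom)/(1 + (EC50/c)^h) — the standard reading of a
concentration-response curve — with h free by default and fixable to 1.
EC50 is multi-start initialized on a log grid across the dose range; doses
of 0 are handled by the (EC50/c)^h → ∞ limit so no log(0) is ever taken.
Constant responses are flagged "no transition" rather than fit; EC50
estimates outside [min dose/10, max dose×10] are flagged as extrapolation.
Cleavage kinetics fits F(t) = A(1 − e^{−kt}) with log-scale parameters and
an implied (0, 0) point when absent.

## The synthetic-data module

Simulators generate every input the pipeline consumes, with ground truth
serialized next to the data so integration tests read truth only from the
file. What they emulate, and what they deliberately do not:

- **Binding sort**: single-site Boltzmann partition, global chemical
  potential, equimolar input, multinomial sequencing sampling. No protein
  depletion, no PCR amplification bias, no chimeras.
- **Cleavage assay**: first-order kinetics with energy-scaled rates —
  chosen so the nonlinear regression has an exact generative counterpart.
- **Error-prone PCR**: i.i.d. per-base substitutions at 0.005/base
  (5 mutations/kb), uniform among alternatives. Real mutagenesis has
  transition/transversion bias; the enrichment analysis is insensitive
  to it, so it is not modelled.
- **Selection**: per-round Bernoulli survival, σ = baseline × product of
  per-mutation multipliers (capped at 1), resampling to constant
  population. No recombination — a consequential simplification: without
  recombination, beneficial mutations on different backgrounds compete
  (clonal interference), so two planted mutations co-dominate only when
  their fitness effects are comparable.
- **Amplicon reads**: HDR/NHEJ/unedited outcomes, truncated-geometric
  indel sizes (1–10 nt), indel midpoints jittered ±1 nt around the cut,
  optional off-window indel fraction, per-base substitution errors,
  constant Q30 qualities.

Sequencing reads are emitted as full-length merged amplicons (the paired-end
merge step is out of scope and assumed done upstream); default read length
for construct reads is 83 nt.

Passing round-trip tests on these simulators shows the estimators invert
the models they assume. It does not validate the models against real data:
real sorts leak, real digestion is not single-exponential for every variant,
and real libraries are not equimolar. The estimators' depth-invariance and
the exact-match tally are designed so the first-order departures show up as
noise and unmatched counts, not as bias, but that claim is only as good as
the model class.

## Study conditions and problem sizes

The validation experiments use these conditions, chosen once:

- **Estimator identities**: the 640-variant exhaustive frame (6-nt
  consensus, window 4) at column depth 10^6, default truth penalties
  ~0.8–1.2 per position. Reported "bias" is the mean of lnK_A + E over the
  library: per-variant deviations at this depth have SE 0.05–0.16, so a
  per-variant maximum is noise-dominated by construction, while the mean
  isolates the systematic component (empirically ~0.01).
- **Parameter recovery**: planted penalties at 0.4–0.6 per position,
  exposure C = 1, two replicates fit jointly, depth 10^6. These sit in the
  well-identified regime: at C = 1 the consensus retains e^{−1} ≈ 37% uncut
  reads (C's precision is limited by the reference's uncut counts), and
  4-mismatch variants stay inside the depletion dynamic range rather than
  saturating. Deeper digests or larger penalties push either C or ε toward
  their identifiability boundaries — exactly the regimes the saturation
  flags exist for.
- **Selection**: 10^5 clones over a 300-nt test region, planted multipliers
  10 and 8 at baseline survival 0.05, 5 rounds, depth 10^5. The library
  size matters: with ~170 independent carrier lineages per beneficial
  mutation, passengers are diluted across backgrounds and stay below the
  dominance threshold; at ≤10^4 clones hitchhikers reach it.
- **Editing quantification**: 10^4 reads per condition at editing rates
  0.1/0.5/0.9, HDR 0.1, 0.1%/base error.
- **Exposure default**: C = 1 (~63% consensus cleavage), the partial-digest
  operating point that maximizes log-ratio dynamic range.

## Known limitations

- The additive (position-independent) penalty model carries no pairwise
  interaction terms; the binding fit's residual SD is the lack-of-additivity
  diagnostic, not a repair.
- Energies are relative (consensus-anchored), never absolute affinities.
- The amplicon module assumes one editing site per amplicon and does not
  detect translocations, large deletions or vector integration.
- The enrichment module scores substitutions only and accepts pre-merged
  reads; fragment tiling works (depth is per-position) but codon labels
  need full-codon coverage.
- Dominance thresholds, alignment score floors and window anchors are
  conventions, exposed as arguments; changing them changes calls, and the
  defaults documented here are the ones the tests pin.
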