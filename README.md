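# SpecProfiler

Computational toolkit for characterizing CRISPR–Cas12a nucleases from
sorted-library sequencing experiments. It is aimed at groups running in
vitro specificity assays (Spec-seq–style binding sorts, SEAM-seq–style
cleavage depletion), PAM profiling, bacterial directed-evolution selections,
and amplicon-based editing readouts, who need the full analysis path — from
library design to fitted mismatch-penalty models — as tested, scriptable R
code.

## What it computes

**Relative binding affinity.** A designed library of target-site variants is
sorted into protein-bound and unbound fractions. For variant *i* with
pseudocount-normalized frequencies *f*,

  lnK_A(i) = ln[(f_bound,i / f_bound,WT) / (f_unbound,i / f_unbound,WT)]

Under a single-site Boltzmann partition with per-variant energy *E_i* (in
units of kT) this estimator has expectation −*E_i*, independent of
sequencing depth per fraction.

**Relative cleavage depletion.** The uncut fraction of a digested library is
compared with a mock-digest input:

  Δd(i) = ln[(f_uncut,i / f_uncut,WT) / (f_input,i / f_input,WT)]

Positive Δd means slower cleavage. Under first-order kinetics with rate
k_i = k_ref·exp(−E^c_i), its expectation is C·(1 − exp(−E^c_i)) with
exposure C = k_ref·t.

**Energy matrices.** Both measures are reduced to additive per-position,
per-base mismatch penalties ε(p, b) with the consensus base anchored at 0:
binding by weighted least squares on mismatch indicators (exact under the
partition model), cleavage by nonlinear least squares of the saturating form
above with a shared C per replicate. Penalties convert to motif logos via
per-position Boltzmann probabilities.

The same machinery drives exhaustive 256-PAM preference ranking,
round-by-round mutation-enrichment analysis of directed-evolution selections
(per-position substitution frequencies normalized by sequencing depth),
amplicon indel/HDR classification with enzyme-specific cut-site windows
(8 bp for Cas9, 9 bp for Cas12a), and EC50 / cleavage-kinetics curve fits.
A synthetic-data module generates every input with serialized ground truth.

## Worked example

Design the 4-nt sliding-window mismatch library for a Cas12a target,
simulate a two-replicate binding sort at depth 10^6, and fit the binding
energy matrix:

```r
library(SpecProfiler)

ts <- TargetSite(protospacer = "GACGCATAAAGATGAGACGCT", pam = "TTTA")
lib <- buildMismatchLibrary(ts, windowWidth = 4)
lib
#> VariantLibrary (mismatch) with 4288 variants
#>   variable region: TTTAGACGCATAAAGATGAGACGCT
#>   mismatch counts: 0x:1  1x:75  2x:621  3x:1809  4x:1782

truth <- simTruth(depth = 1e6, seed = 42)
fc <- simulateSpecSeq(truth, lib, nReplicates = 2)
measures <- computeLnKA(fc)
em <- fitBindingEnergyMatrix(measures, lib)
em
#> EnergyMatrix (binding) over 25 positions
#>   mean mismatch penalty: 1.250 (range 0.146..2.898)

round(penalties(em)[, c("P2", "1", "10")], 2)
#>     P2    1   10
#> A 1.93 1.58 0.00
#> C 2.43 1.98 0.24
#> G 2.90 0.00 0.30
#> T 0.00 2.32 0.36
```

The columns read directly as biology: PAM position 2 and seed position 1
carry strong penalties (~2–3 kT per mismatch), while position 10 — in the
protospacer's characteristic low-specificity centre — is nearly neutral.
The zero in each column is the consensus base. `matrixToPwm()` and
`plotEnergyLogo()` turn the matrix into a motif logo;
`compareEnergyMatrices()` contrasts two enzymes position by position.

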