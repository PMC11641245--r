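---
title: "Quantifying cardiac progenitor cell-division defects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac progenitor cell-division defects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiodiv)
```

## The biological model

The embryonic *Drosophila* heart is metameric: in each abdominal hemisegment
A2–A7 the stereotyped wild-type pattern is two Seven-up-expressing cardial
cells (Svp-CCs), each paired with a Seven-up pericardial sister cell
(Svp-PC), followed by four Tinman-expressing cardial cells (Tin-CCs); A8 is
truncated, with only two Tin-CCs. This pattern is produced by an invariant
series of progenitor divisions:

* an **earlier-stage division** yields exactly two Svp progenitors;
* each Svp progenitor divides **asymmetrically** into one Svp-CC and one
  Svp-PC;
* two Tin progenitors (one in A8) divide **symmetrically** into two Tin-CCs
  each.

Because the wild-type outcome is deterministic, observed cell counts per
hemisegment carry information about which division failed. `cardiodiv`
mechanizes that inference, simulates cohorts under parameterized error
rates, and tests genotype effects with permutation regression.

## The synthetic cohort generator

`simulate_hemisegment()` draws one hemisegment from the lineage model. Under
`division_error_rates()` the perturbations are:

| parameter | meaning | default |
|---|---|---|
| `r_early` | earlier-stage division yields 1 or 3 progenitors (equal odds) | 0 |
| `r_asym` | an Svp progenitor's asymmetric division fails | 0 |
| `asym_mode_weights` | failure mode: both-CC / both-PC / karyokinesis failure | 1/3 each |
| `r_sym` | a Tin progenitor's symmetric division fails | 0 |
| `sym_mode_weights` | failure mode: 1 cell / 3 cells | 1/2 each |
| `r_dropout` | a hemisegment is unscoreable | 0 |

All rates are per-division probabilities, so the induced per-hemisegment
defect probabilities follow analytically: the earlier-defect probability is
`r_early` exactly, and with two independent progenitors the probability of
at least one asymmetric (or symmetric) failure is `1 - (1 - r)^2`. These
closed forms anchor the round-trip tests between the simulator and the
classifier.

Design choices worth making explicit:

* **Scored region.** Only A2–A8 × left/right is generated (14 hemisegments
  per embryo), matching the denominators used when hearts are scored; the
  anterior aorta is not modeled.
* **A8 pericardial complement.** The truncation of A8 is defined for
  Tin-CCs; we assume the Svp side of A8 is the standard two CC/PC pairs.
* **Independence.** Progenitors fail independently, so both Tin progenitors
  can fail in one hemisegment; failure modes are drawn independently of each
  other.
* **Dropout.** Unscoreable hemisegments are uniform at random, carry no
  counts, and are excluded from every denominator. Real unscoreability may
  be systematic (orientation, staining quality); the generator does not
  emulate that, so tests passing here say nothing about informative
  missingness.
* **Reproducibility.** `simulate_cohort()` derives one RNG substream per
  embryo from `(seed, genotype, embryo index)`, so cohorts are reproducible
  and invariant to genotype order.

What the generator deliberately does not emulate: progenitor specification
defects (the FGF/Wnt receptor pathway acting upstream), cell fate switching
between Svp and Tin identities, spatial misplacement of correctly-counted
cells, and image-level noise. Passing tests therefore demonstrate correct
bookkeeping and inference over counts, not robustness to segmentation or
staining artifacts.

## The defect classifier

With pericardial cells visualized, `classify_hemisegment_full()` scores:

* **symmetric**: `n_tin_cc` differs from the segment expectation (4, or 2 in
  A8);
* **Svp-lineage categories**: by exhaustive enumeration
  (`enumerate_consistent_explanations()`) of progenitor counts k ∈ {1, 2, 3}
  and per-progenitor outcomes (normal, both-CC, both-PC, karyokinesis
  failure) that reproduce the observed
  `(n_svp_cc, n_svp_pc, n_enlarged_svp_cc)` triple.

Among consistent explanations, those positing the fewest errors
(`|k - 2|` + number of failed divisions) are retained. If every minimal
explanation requires `k != 2` the hemisegment is an **earlier** defect; if
every minimal explanation contains a failed asymmetric division it is an
**asymmetric** defect; both can hold at once (e.g. a single enlarged CC with
no PC: one progenitor, karyokinesis failure). When minimal explanations
disagree the specific flag is recorded as unknown (`NA`) rather than
guessed, while `svp_lineage` — any deviation from the error-free lineage —
remains `TRUE`. Observations no lineage can produce (e.g. `(2, 1, 0)` when
the enlarged-nucleus marker is trusted) are flagged `inconsistent`.

This minimal-error rule is the most conservative mechanization of what is
otherwise expert judgment: it attributes to the hemisegment no more
division errors than the data force. Two switches matter:

* `enlarged_marker_reliable = FALSE` admits karyokinesis failures without an
  observed enlarged nucleus (nuclear size is easy to miss), which makes
  `(2, 1, 0)` explainable as a missed karyokinesis failure.
* k is capped at 3, mirroring the one-or-three-progenitor phenotype;
  configurations needing k ≥ 4 are reported as inconsistent rather than
  extrapolated.

Without pericardial information (`mask_pericardial()`, or field data scored
with CC markers only), `classify_hemisegment_cc_only()` collapses the Svp
side to a single rule — any deviation from two Svp-CCs is an Svp-lineage
defect of unknown subtype — because asymmetric and earlier defects are
genuinely confounded in that regime.

Per-embryo summaries (`summarize_embryos()`) divide flagged hemisegments by
scoreable hemisegments. A hemisegment can contribute to both the Svp and Tin
numerators; categories are counted independently. Unknown flags count toward
`svp_lineage` but never toward `asymmetric` or `earlier`, so those two
category proportions are lower bounds under masking.

## Permutation inference

The response is the per-embryo defect proportion, which is bounded,
non-normal, and heteroscedastic — hence permutation rather than parametric
tests.

**Two-group comparison.** `Y_j = β0 + β1 I_j + ε_j`, where `I_j` indicates
the mutant. The observed `β1` (difference of group means) is compared with
its distribution under `n_perm` random relabelings of the embryos (group
sizes preserved), and

p = (n + 1) / (N + 1),

where `n` counts permutation estimates that **equal or exceed** the observed
one. Ties count toward `n`; the p-value is floored at `1/(N + 1)` and can
never be 0. The default `N = 10^6` gives highly reproducible p-values;
smaller `N` is appropriate for simulation studies. `exhaustive_two_group()`
enumerates all `choose(n, n1)` assignments on small designs and is the
testing oracle for the sampled version. One numerical subtlety: the observed
statistic is computed through the same sum-based arithmetic as the permuted
ones, so floating-point ties are detected exactly — the exceedance rule is
tie-sensitive and the test must be invariant to affine rescaling of the
response.

**Synergy.** For two mutations p and q the no-intercept model

`Y_j = β1 Ip_j + β2 Iq_j + β3 Ip_j Iq_j + ε_j`

is saturated on the usual three-group design (p-only, q-only, double
heterozygotes): `β3` is the double-heterozygote mean minus the additive
expectation `β1 + β2`, so `β3 > 0` is synergy. The no-intercept form pins
the unmutated baseline at zero; an `intercept = TRUE` mode exists for
sensitivity analysis (with a wild-type group present the no-intercept model
would otherwise absorb baseline defects into the coefficients). Testing
`H0: β3 = 0` in a multiple regression requires care: we use the Smith
orthogonalization strategy, residualizing the interaction column against
`(Ip, Iq)` (`smith_orthogonalize()`) and permuting the entries of the
residualized column while the response and nuisance columns stay fixed. The
coefficient on the residualized column equals `β3` from the full model
(Frisch–Waugh), and the permutation preserves the nuisance structure.
Alternative Smith-family variants permute residualized responses; we
permute the orthogonalized covariate because it keeps the observed response
vector intact and matches the orthogonalization label. The default
alternative is `"greater"` for both tests (synergy and worse-than-control
are the directional hypotheses of interest); `"less"` and `"two.sided"`
(absolute-value exceedance) are available.

Calibration is verified by simulation in the test suite at two levels. On
continuous responses, both tests reject at a 0.05 level at the nominal rate
(within Monte-Carlo error). On simulated cohorts (14 vs 14 embryos, 500
replicate cohorts, 2000 permutations per test), the realized rejection rate
falls *below* nominal: per-embryo proportions are counts out of 14
hemisegments, so at low error rates the response — and hence the
permutation distribution of the coefficient — is highly discrete, and under
the equals-or-exceeds tie rule every atom at the observed statistic counts
toward `n`. Discrete permutation tests with this tie handling are valid but
conservative (the type-I error never exceeds α, it undershoots it), and the
effect is strongest exactly in the low-rate, small-count regime a null
cohort occupies. Users should read borderline p-values in that regime as
conservative. The power check is unaffected: an asymmetric-division rate of
0.25 vs 0.02 is detected with power above 0.8 at the same design. These
problem sizes were chosen to estimate a 5% rejection rate with a standard
error near 1%.

## Expression screening

`gate_de()` applies strict fold-change/FDR thresholds to a
mutant-vs-wild-type differential-expression table: activated means
`log2FC < -threshold` with `FDR < 0.1`, repressed means
`log2FC > threshold`; `"stringent"` sets the threshold at 1,
`"relaxed"` at 0.5. Inequalities are strict, and the FDR cutoff is strict
at 0.1; boundary genes are excluded. `low_expression_filter()` removes the
bottom 30% of genes by log2CPM before gating (floor of `fraction × n`
records, ties broken by input order). The package ships the published
21-gene table of Jumu-activated cell-division genes
(`jumu_mesoderm_de()`) as a worked fixture: all 21 pass the relaxed
activation gate, 9 also pass the stringent gate.

`ddct_relative_expression()` implements 2^−ΔΔCT relative quantification
(technical replicates averaged on the CT scale before differencing — a
common convention), and `welch_one_tailed()` provides the matching
one-tailed unequal-variance t-test. `analyze_qpcr()` combines both over a
long-format CT table, testing per-replicate ΔCT values between conditions.

## Direct-target triage

Cardiac cis-regulatory modules are typically clustered binding sites of
multiple cardiogenic transcription factors in introns or flanking
intergenic DNA. `gene_territory()` builds that search region: the gene span
minus its exons, plus the intervals up to the immediately adjacent 5' and 3'
neighbor genes. `classify_direct_target()` then calls a gene

* `direct` if a Jumu ChIP peak in the territory is clustered with a peak of
  at least one partner cardiogenic TF (Myb, Tin, Tup, Twi, Su(H), Pnt, Mad,
  Hand),
* `jumu_only` if Jumu binds but no partner peak is within range, and
* `no_jumu_peak` if Jumu does not bind the territory at all (regulation
  presumed indirect).

"Clustered" has no canonical distance; we define it as gap ≤ `max_gap`
with default 0 (overlapping or abutting peaks) and report the setting in
the output, so users can relax it explicitly. Coordinates are handled as
`GRanges` (1-based inclusive internally, BED's 0-based half-open on disk via
`rtracklayer`); strand is ignored; peaks partially overlapping a territory
boundary count as inside; when no exon structure is available the whole
gene body is used as the intronic proxy, with a warning, as a conservative
superset. Shrinking `max_gap` can only demote calls (direct → jumu_only),
never promote them — a monotonicity the tests check on random fixtures.

## The pipeline

`run_pipeline()` chains the stages — simulate (or read) counts, classify,
summarize per embryo and per genotype, and run the configured permutation
tests — from a YAML (or list) configuration, writing every stage table as
TSV plus a run log. Runs are deterministic given `(config, seed)`; the
permutation seed stream is derived from the cohort seed. The per-genotype
summary reports pooled percentages (total flagged hemisegments over total
scoreable), i.e. the hemisegment-weighted mean of per-embryo proportions.

```{r pipeline-example, eval = FALSE}
config <- list(
  cohort = list(genotypes = list(
    wild_type = list(n_embryos = 14, rates = list()),
    rx_mut = list(n_embryos = 14, rates = list(r_asym = 0.2, r_sym = 0.15))
  )),
  categories = c("svp_lineage", "symmetric"),
  comparisons = list(two_group = list(list(ref = "wild_type",
                                           alt = "rx_mut"))),
  n_perm = 1e6
)
report <- run_pipeline(config, seed = 17, out_dir = "results")
report$tests
```

## Known limitations

* The classifier's unknown (`NA`) mechanism records ambiguous count
  configurations but cannot resolve them; under heavy masking the specific
  asymmetric/earlier proportions are lower bounds.
* The simulator's dropout is non-informative; inference under systematic
  unscoreability is untested.
* Multiple-testing correction across many genotype comparisons is out of
  scope; p-values are reported per comparison.
* The triage stage ranks plausibility of direct regulation from ChIP
  colocation only; it does not validate enhancers or binding-site function.
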