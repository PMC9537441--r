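---
title: "Clonal barcoding with capturable cassettes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal barcoding with capturable cassettes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capturekit)
```

This vignette is the package's own account of the science it implements:
the barcode cassette model and its design rules, the single-replicate
enrichment statistic, the binomial preexistence model, the editing-outcome
and reporter logic, the multi-evidence variant priority score, and the
clonal-evolution simulator that generates all test data. It also records
the numerical conventions and the design choices that were genuinely open.

## 1. The cassette model and design rules

A barcode cassette is the fixed-flank construct

```
CGTCCG  (N20, site A)  GCCACCATGGTCGAC  (N20, site B)  CGGTAG
```

fused in-frame inside a fluorescent reporter. The two N20 segments are
guide target sites for a Cas9 nickase in PAM-out orientation: the
plus-strand NGG PAM for site B is the start of the 3' flank (`CGG`), and
the minus-strand PAM for site A is the `CCN` at the end of the 5' flank
(`CCG`, i.e. `CGG` on the minus strand). The linker length equals the
inter-nick offset; 15 bp is the default (9 bp is supported), because the
paired-nickase geometry works best with a short offset between
reverse-oriented sites. `cassette_spec()` validates all of this, and
`assemble_cassette()` re-checks the PAM geometry at assembly time.

**Frame rules.** Because the cassette is translated as part of the
reporter fusion, no accepted candidate may introduce a stop codon into any
in-frame codon that overlaps it — including codons that straddle the
junctions with the flank or linker. The cassette motif itself does not
state the codon phase of the surrounding vector, so the phase of the first
flank base is a parameter (`frame_phase`, default 0); a `strict_frames`
mode excludes stops in all three forward frames for users who do not know
their vector phase. This was a genuinely open choice: the cassette motif
alone does not pin down the phase, and the default is the phase in which
the flanks themselves are stop-free.

**Forbidden motifs** default to the MluI (`ACGCGT`) and BamHI (`GGATCC`)
cloning sites used to insert the cassette. SalI (`GTCGAC`) is *not*
forbidden even though it is a common cloning site, because the default
linker itself contains it; forbidding it would reject every candidate whose
junction recreates the linker's own sequence.

**On-target scores.** Published designs select guides by on-target
activity models. Re-implementing such a model is out of scope here; scores
are accepted as an external column, and a deliberately simple built-in
heuristic (`heuristic_guide_score()`: GC fraction in [0.3, 0.8], no
homopolymer of length ≥ 5) is available as a fallback so the filtering
pipeline is runnable without external tools.

**Combinatorics.** The library is the full cross of a top and a bottom
pool: `enumerate_library()` reports |top| × |bottom| and iterates each pair
exactly once; barcode keys are position-deterministic (site A then
site B), so key → (site A, site B) is a bijection whenever the pools have
no internal duplicates (checked). The even 6,000/6,000 split used in the
acceptance computation is the natural reading of a ~12,000-oligo,
36-million-barcode design; the split is a free parameter of
`emit_oligos()`, which also models the synthesis strategy — top and bottom
single-strand oligos sharing a complementary 3' pairing region centred in
the linker, such that anneal + extend reconstructs the cassette exactly
(tested string-exactly for all pairs of small pools).

**v2 frame safety.** The v2 reporter chains GFP, a blasticidin marker and
an HA-tagged puromycin marker so that a −1 frameshift switches selection
markers. `check_frames_v2()` verifies that a region has no stop codon in
the design frame, none in the −1-shifted frame, and no −1 programmed
ribosomal frameshifting heptamer. The slippery-site pattern defaults to the
canonical X₁X₁X₁ X₂X₂X₂ N with X₂ ∈ {A, T}; the pattern is configurable
because published designs state the goal ("no slippery sites") rather than
the exact pattern screened.

## 2. Barcode extraction and counting

Amplicon reads carry the cassette at a variable offset (the sequencing
library uses a 0–8 nt stagger for diversity), so `extract_barcodes()`
searches all offsets and takes the leftmost plus-strand hit; the reverse
complement is searched when the plus strand misses (on by default; a
strict single-strand motif grep is the `search_revcomp = FALSE` special
case). Exact mode (default) requires all
three fixed segments verbatim, matching 100%-match counting; an optional
per-segment mismatch budget exists for degraded data. Counting against the
reference is exact by default; `hamming_rescue = d` optionally rescues keys
within Hamming distance d of a *unique* reference key, with ties left
unassigned.

Two bookkeeping invariants are asserted throughout: assigned + unassigned
reads equal reads-in per sample, and fractions are computed over assigned
totals. Quality trimming is reduced to an optional mean-quality filter
(default off): the motif match itself rejects corrupt reads, and wrapping
an external trimmer would add a dependency without changing the counts.

## 3. The enrichment statistic

For a barcode with counts k in a treated sample (assigned total N_t) and
k' in the control (total N_c), the abundance rates get independent Gamma
posteriors λ ~ Gamma(k + α)/N with pseudocount α = 1, and the statistic is
the c-quantile (default c = 0.01) of the posterior of log₂(λ_t/λ_c) — the
generalized-fold-change construction for unreplicated count data. A value
above the threshold (default 4) means even the conservative lower edge of
the posterior fold change exceeds 2⁴.

The `numeric` method is exact: since
λ_t/λ_c = (N_c/N_t) · B/(1 − B) with B ~ Beta(k + α, k' + α) and log₂ is
monotone, the c-quantile is `log2((N_c/N_t) * qbeta(c, a, b) / (1 - qbeta(c, a, b)))`.
The `monte_carlo` method draws from the two Gamma posteriors; the two
routes agree within 0.05 across a (k, k') grid in the acceptance suite,
and the statistic is monotone in k (increasing) and k' (decreasing).

Normalisation uses per-sample assigned totals rather than median-of-ratio
size factors: post-selection barcode pools are dominated by a few clones,
which violates the "most features unchanged" assumption behind
median-of-ratios. Enrichment is one-sided (treatment over control), the
primary use case; depletion calling is available behind a flag. The
re-implementation is faithful by construction (same posterior family, same
quantile convention) but is not a byte-identical port of the original
implementation, whose exact version and normalisation options are not
stated; the
threshold, α and c are all configurable for that reason.

**Ranking convention.** "Top n most enriched" ranks by statistic value
descending, ties broken by treated count, then lexicographic key — a
deterministic rule chosen because no canonical convention exists.

## 4. The preexistence model

Let P be the probability that a detected barcode becomes enriched in one
replicate (estimated as enriched-union / detected complexity). Under
independence across R replicates, the chance probability of the same
barcode being enriched in exactly r replicates is C(R, r) Pʳ (1−P)^(R−r);
multiplying by the detected complexity gives the expected number of such
barcodes (a Bonferroni-style adjustment). The adjustment is the plain
(uncapped) product — it is an expected count, and can exceed 1 for large
P; a `cap = TRUE` variant clamps it for users who want a probability. At
a representative full-scale operating point (P = 0.0007, R = r = 5, complexity 230,000)
the unadjusted and adjusted values are 1.68 × 10⁻¹⁶ and 3.86 × 10⁻¹¹, which
the acceptance suite reproduces to printed precision.

The model's practical reading gives the origin labels in
`dynamics_summary()`: enriched in all R replicates — far beyond chance —
is a *preexisting candidate*; enriched in exactly one replicate is
*late-emerging* (acquired); anything else is *intermediate*.

## 5. Editing outcomes, reporter states, purity

`align_to_cassette()` performs global alignment with defaults
(match +1, mismatch −1, gap open −4, gap extend −1) suited to short
indel-dominated amplicons, then derives a CIGAR-like edit list with gap
runs left-normalised for determinism. The cut window defaults to 3 nt
inside each protospacer plus the whole offset — the region where
paired-nick repair products concentrate — and is configurable because the
region where edits "count" is an analysis choice, not a published
constant. An indel op counts with its full length when it overlaps the
window; net length mod 3 sets the frame class, and `reporter_state()` maps
class to phenotype (v1: any frameshift silences eGFP; v2: only the −1
class frames in PuroR-HA). Under a uniform indel-size model on 1..30 the
frameshift fraction is exactly 2/3; the model is swappable and is treated
as a design-time prediction, not data.

`purity_report()` assigns reads by exact motif first; reads whose motif was
destroyed by editing are assigned by best alignment against the library
cassettes, accepted only if both N20 remnants outside the cut window are
edit-free — the explicit competitor-aware version of assigning reads to a
single amplicon. Both purity-style statistics are reported:
`composition_purity` (share of assignable reads on the intended barcode)
and `targeted_fraction` (edited share among target reads), because reported purity figures in
this field sometimes count edited reads only and sometimes all reads on
the target barcode.

## 6. The clonal-evolution simulator

The simulator is the package's synthetic-data generator and the ground
truth for validating origin inference. It emulates, at desk scale:

1. **Barcoding** (`barcode_founders()`): founders draw Poisson(MOI)
   integrations (MOI 0.3); zero-integration cells are removed; barcodes are
   drawn with lognormal skew from the library. Multi-integration cells
   (~14% of barcoded cells at MOI 0.3, the closed-form conditional
   fraction) are tracked rather than ignored so the single-barcode
   assumption can be stress-tested.
2. **Expansion** (`expand_pool()`): Galton–Watson doubling with a small
   death probability until mean cells per clone reach coverage ×
   (replicates + 1), with barcode dropout reported.
3. **Treatment** (`treat()`): a multinomial split into control + R
   replicates, then daily dynamics — sensitive cells die with probability
   0.3/day; persisters (1% of sensitive cells) survive, divide at 0.1/day
   and convert to stable resistance with probability 2 × 10⁻⁴ per division;
   resistant clones (preexisting fraction 2 × 10⁻³, or converted
   persisters) grow by a per-clone factor ~ Normal(1.45, 0.1) per day
   (truncated at 1.05). Pools are passaged by binomial thinning back to
   10⁶ cells whenever they exceed 2 × 10⁶, in both arms — the in-silico
   version of "passaged as needed". The control arm grows neutrally at
   1.6/day under the same passaging.
4. **Sequencing** (`sequence_pools()`): multinomial reads over barcode
   templates weighted by final cells; FASTQ mode embeds each barcode in the
   full cassette motif with a random 0–8 nt stagger, pads to 100 nt and
   applies substitution errors at 10⁻³ per base (so ~(1 − 10⁻³)⁶⁷ ≈ 93.5%
   of reads survive exact-motif counting, which the tests verify).

**Default scale.** 10⁴ founder cells against a 10⁵-barcode library, five
treated replicates plus control, 40 days, 10⁵ reads per sample. These are
the conditions of a full-scale selection experiment shrunk to desk size: the simulations in the test and
acceptance suites run in under a second each (counts mode) and the full
FASTQ pipeline in about a minute, which is what makes 200-run calibration
experiments affordable. One parameter is deliberately *not* scaled
proportionally: the preexisting fraction. At full scale,
all-replicate shared barcodes are a handful per hundreds of thousands
detected (~10⁻⁵); that rate would give ~0.03
preexisting clones at 10⁴ founders — the preexisting arm of the model would
simply never appear. The default `rho_pre = 2e-3` (~5 preexisting clones)
keeps both origins represented; the quantitative growth, death and
acquisition rates have no published values at all and are stated defaults
chosen to reproduce the qualitative selection regime (a few dominant
clones, top-10 share above ~75% in treated pools, a mix of shared and
replicate-private enriched barcodes).

**What the simulator does not model** — and hence what passing tests do
not certify about real data: spatial structure and microenvironment,
pharmacokinetics, cell-cycle structure (time is discretised in days),
reversibility of the persister state, PCR amplification bias and chimeras,
and indel sequencing errors (substitutions only). Conclusions about the
pipeline's behaviour under those effects require real amplicon data.

**Calibration property.** With `rho_pre = 0`, every resistant clone is
replicate-private by construction, so barcodes enriched in all R
replicates should occur at (at most) the rate the adjusted binomial model
predicts. The acceptance suite runs 200 simulations and checks the
observed all-replicate count against the summed adjusted expectation with
a one-sided Poisson test at α = 0.01. Clone-size heterogeneity makes
acquisition probabilities vary across clones, which the binomial model
ignores (a Jensen-gap underestimate); at the default rates the effect is
far below one expected event in 200 runs, so the test is a genuine, if
coarse, consistency check.

## 7. The variant priority score

For each candidate somatic alteration the score averages five 0–100
components: **AS** = allele frequency × 100; **DS** = mean of the scaled
CADD/SIFT/PROVEAN deleteriousness scores; **CS** = scaled CRISPR-screen
fold change; **GS**/**MS** = 100 iff the gene / the exact mutation appears
in the clinical resistance landscape. Variants in genes with FPKM < 0.1 in
every sample score 0 outright (likely passengers in silent genes).

Conventions that are genuinely open in this scoring scheme, and the
choices made here (all configurable):

* **Tool orientation**: CADD raw scores rise with deleteriousness
  (`higher_is_deleterious`); SIFT and PROVEAN fall
  (`lower_is_deleterious`) and are sign-flipped before scaling.
* **Scaling domain**: min–max over the analysis run's scored candidate
  set. Global theoretical ranges do not exist for PROVEAN, so per-run
  scaling is the only option that is always defined.
* **Imputation**: frameshift deletions, stop gains and splicing variants —
  which the tools cannot score — get the maximum (100), reflecting their
  typically larger effect; other unscored variants get the median of the
  scaled scored set, computed *before* imputation so imputed values cannot
  move it.
* **Degenerate spread** (all scored values equal): everything maps to 50
  with a warning rather than an error, so a single-gene run still ranks.

The invariants — every component and PS in [0, 100], PS = mean of the five
when expressed and 0 otherwise, monotonicity in each component — are
property-tested on 10⁴ random records.

## 8. Numerical conventions and degenerate inputs

* Counts are integers; totals use per-sample assigned reads; fraction
  matrices guard against zero totals.
* `gfold_statistic()` requires 0 < c < 0.5 and positive totals; k = 0 is
  fine (the pseudocount keeps the posterior proper).
* Alignment tie-breaks: gaps left-normalised; deletions preferred by the
  scoring defaults over mismatch runs for indels ≥ 2 nt.
* Empty candidate lists, empty read sets, zero-complexity references and
  r > R all raise errors; whole-replicate extinction in the simulator is
  reported, not raised.
* All stochastic code paths take explicit seeds; identical config + seed
  gives identical output, byte-for-byte in the count tables.

## 9. Problem sizes used in the shipped checks

The test and acceptance suites run entirely on synthetic data: guide pools
of a few hundred candidates (the 6,000 × 6,000 complexity computation
enumerates only slices of the 36-million library); simulated experiments
at the default desk scale above; a 25-point (k, k') grid with 10⁶
Monte-Carlo draws per point for the statistic cross-check; ~1,200
single-indel perturbations of a 67-nt cassette for the alignment oracle;
10⁴ random variant records for the score invariants; and 200 simulation
runs for the preexistence calibration. These sizes were chosen as the
smallest at which each property is statistically meaningful.

## 10. Known limitations

* The enrichment statistic is a faithful re-derivation, not a port; exact
  numeric equality with any particular release of the original tool is not
  guaranteed (and not needed for threshold-level calls at the margins seen
  here).
* The built-in guide score is a placeholder heuristic, not an activity
  model; real designs should supply external scores.
* Off-target search across a genome is out of scope; the design controls
  off-targets structurally (fully designed sites, nickase chemistry).
* `purity_report()`'s alignment fallback is O(reads × library) and meant
  for captured pools (small libraries), not whole-library searches.
* The preexistence model assumes replicate independence and a common P
  per barcode; clone-size heterogeneity violates the latter mildly (see
  §6).
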