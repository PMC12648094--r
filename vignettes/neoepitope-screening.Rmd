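---
title: "Methods: neoepitope screening and clonotype tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neoepitope screening and clonotype tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscreen)
```

# The screening model

`neoscreen` formalizes the computational core of a neoantigen screening
study: from a tumor's somatic missense variants to a per-patient verdict on
whether spontaneous neoepitope-specific CD8+ T cells are detectable, and
from single-cell TCR repertoires to per-clonotype frequency dynamics across
treatment. This vignette records the statistical conventions, parameter
defaults, and design decisions, with the reasoning behind each.

## Variant consensus

Somatic variant callers disagree; requiring support from at least
`min_callers` of a configured caller universe (default 2 of
{mutect2, strelka2, varscan2}) trades sensitivity for precision. Only
missense variants are retained: they are the class that yields single
amino-acid-substituted peptides. The rule is exposed as *k*-of-*n* rather
than hard-wired at 2-of-3 so that pipelines with different caller sets can
reuse it. Where the same amino-acid change is reported twice, the caller
sets are unioned — the only lossless merge. Ingestion is at protein level
(annotated consequences), not genomic VCF: annotation is an upstream tool's
job, and accepting its output keeps the package self-contained. When a
study mixes pipelines with and without a stated consensus rule, we apply
this rule uniformly; it is the conservative common denominator.

## Peptide windows and enumeration

Around each variant a 25-residue window is built (12 flanking residues each
side), so that every peptide of length ≤ 13 containing the variant lies
inside it. Windows are clipped at protein termini and *kept* with
truncation flags — dropping terminal variants would silently lose
candidates. Enumeration emits every 8–11-mer containing the mutated
position, paired with the wild-type sequence at the same offset: for an
untruncated window, exactly *k* peptides of length *k*, hence
8+9+10+11 = 38 pairs. Wild-type partners are emitted for *all* candidates
(not only confirmed ones): they cost nothing computationally and the
mutant-vs-WT comparison needs them. Peptides containing non-standard
residues (X, U, ...) are dropped with a warning because binding predictors
cannot score them. Internally indices are 0-based; protein positions at
I/O boundaries are 1-based, matching annotation conventions.

## Binding ranks and candidate selection

Binding prediction engines are external binaries; the package defines a
*rank provider* interface instead: any function mapping (peptide, allele)
pairs to percentile ranks in (0, 100], lower = stronger. Three providers
ship: a table lookup over precomputed predictor output, a deterministic
seeded surrogate (a keyed hash mapped to (0, 100], platform-independent by
construction — it carries no biology and exists so the pipeline is
exercisable and reproducible without predictions), and a planted wrapper
that forces designated peptides to a strong rank for ground-truth
simulations.

Two selection modes reflect two screening designs:

* **threshold** — keep peptide–allele pairs with `%Rank < 0.5` *and*
  source-gene expression `> 1 TPM`. Both inequalities are strict, taken
  literally from the stated cutoffs. Genes absent from the expression
  table count as 0 TPM and are therefore filtered.
* **top_n** — rank all unique mutant peptides by their best `%Rank` across
  alleles and keep the first `n_top` (default 150). Selection counts
  unique *sequences* because synthesis does; the best allele represents
  each peptide. By default this mode applies no TPM filter: screens without
  tumor RNA-seq have nothing to filter on, and imposing one silently would
  drop candidates. Ties break by (rank, peptide, allele) lexicographically:
  the paperless tie-break is arbitrary, but determinism of the synthesized
  list is not negotiable.

TPM normalization is the standard length-normalized rate
(`count / kb`, scaled to sum to 1e6); fractional counts are accepted
because multi-mapper fractionation produces them.

## ELISPOT calling

The positivity rule is: a condition is positive within one experiment when
the *mean* spot count of its replicate wells strictly exceeds
`mean(neg) + 3 * sd(neg)`. The standard deviation is read as the sample SD
(n−1) of the negative-control replicate wells on the same plate — the only
replicate set the rule can refer to — so at least two negative wells are
required, and an `sd_floor` argument (default 0) is available for plates
whose negative wells are all identical. No minimum absolute spot count is
imposed by default; common practice sometimes adds one, but it is not part
of the rule as stated. An antigen is *confirmed* when positive in at least
two independent experiments; experiments in which the antigen was not
plated are skipped, not counted as failures — exclusion is the conservative
reading of "confirmed".

Pools are deterministic chunks (optionally seed-shuffled) of the candidate
list, default 15 peptides, warning outside 10–20; a trailing pool of fewer
than 2 peptides merges into its predecessor. Deconvolution attributes each
confirmed pool to its members with confirmed single-peptide calls; a
confirmed pool whose members were all tested and all negative is reported
`unresolved_pool` — a real outcome in screens limited by material, not an
error. Mutant-vs-WT recognition uses the paired Wilcoxon signed-rank test
(a "Wilcoxon t-test" on paired assays can only mean the signed-rank test),
exact up to 25 non-zero pairs.

## Clonotype tracking

Clonotypes are keyed on V gene, J gene and CDR3 amino-acid junction, at
gene rather than allele resolution: bulk DNA repertoires and single-cell
assemblies disagree at allele level, and gene-level keys maximize valid
joins. Keys are TRB-anchored; a paired TRA refines the key when present.
Cells carrying only a TRB merge into the unique paired clonotype sharing
that TRB, if there is exactly one — otherwise they remain a separate,
flagged clonotype rather than being guessed into a pairing. Cells with two
distinct TRBs are dropped as suspected doublets; TRA-only cells are
excluded (they cannot be joined to bulk TRB data).

A clonotype is *detected* in a sample at ≥ 2 cells; frequency is
`count / n_cells` with detection floor `1 / n_cells` (the smallest
observable non-zero frequency; `2 / n` would be the smallest *detectable*
one under the 2-cell rule — we expose `1 / n` and note the alternative).
Pre/post comparisons use the two-sided Fisher exact test on
`[[k_pre, n_pre − k_pre], [k_post, n_post − k_post]]` at nominal
α = 0.05 without multiple-testing correction — per-clonotype tests are
reported the way repertoire figures conventionally show them; a correction
can be applied downstream. When a clonotype is absent post-treatment its
fold change is computed against the detection floor and flagged
`fold_is_bound`: "decreased at least x-fold" is itself a bound, and the
package reports it as one. Enrichment requires detection in the tumor and
a tumor frequency strictly above *every* reference sample.

## Exact 2×2 statistics

`fisher_exact_2x2()` implements the minimum-likelihood two-sided
convention: conditioning on both margins, sum the hypergeometric
probabilities of all tables as-or-less probable than the observed one.
This convention — not tail-doubling — reproduces the cohort-table values
`1/56 = 0.0179`, `8/35 = 0.229` and `1.0` exactly. Probabilities are
compared with a relative tie tolerance of `1e-7` so that tables tied up to
floating rounding are counted together; hypergeometric masses come from
`dhyper`, and the test suite verifies the implementation against an
independent exhaustive enumeration using exact binomial-coefficient
products for every table with N ≤ 40. `mann_whitney_u()` enumerates the
exact null for combined n ≤ 12 without ties and otherwise uses the normal
approximation with tie and continuity corrections.
`wilcoxon_signed_rank()` drops zero differences, uses an exact
convolution over observed (mid)ranks up to 25 pairs — exact even with
tied ranks — and the corrected normal approximation above that. Exact
two-sided p-values use the doubling convention capped at 1.

# The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture dump: it
emulates every input the pipeline consumes, with planted ground truth.

* **Variant burden**: uniform in 2–57 per patient — the published
  per-tumor range of 20–567 nonsynonymous substitutions scaled down
  tenfold so full cohorts run in seconds. Caller support is Bernoulli per
  caller (defaults 0.90/0.85/0.80), plus caller-private false positives at
  rate 0.05 per true variant, plus a couple of non-missense rows so the
  class filter is exercised.
* **Expression**: log-normal TPM (meanlog 1, sdlog 1.5) — a heavy-tailed
  shape typical of bulk RNA-seq, with roughly a quarter of genes under the
  1 TPM cutoff.
* **Binding ranks**: the surrogate hash provides pseudo-uniform ranks;
  planted epitopes (3 per patient, chosen among consensus variants on
  genes above 1 TPM) are forced to rank 0.1.
* **ELISPOT**: negative wells Poisson with mean 10 spots (an optional
  negative-binomial overdispersion stresses the 3-SD rule); responder
  wells Poisson at 3× background; 3 replicate wells and 2 independent
  experiments per condition. Replicate count is not standardized across
  laboratories; triplicates are the common desk choice.
* **Repertoire**: 48 clonotypes; planted enriched clonotypes at fixed
  tumor frequencies `0.12 × 0.8^i`, absent from adjacent tissue, dropped
  10-fold post-treatment; background frequencies Dirichlet(0.5);
  multinomial cell sampling at depths 266 (tumor), 158 (adjacent), 48
  (post-treatment) — the depths of the most deeply sampled published
  patient; blood is a bulk TRB frequency table with planted clonotypes
  diluted 50-fold.
* **Reproducibility**: one root seed fans out to per-patient streams via a
  fixed Lehmer-step counter scheme, so patient *k* is reproducible in
  isolation and identical seeds give byte-identical bundles.

`uc1_like_fixture()` is the deterministic complement: counts are
*constructed*, not sampled, so its guarantees hold by design — 48
clonotypes over 222 tumor cells, six planted enriched clonotypes each with
≥ 2 tumor cells and dominated nowhere else, every non-planted
tumor-detected clonotype at least as frequent in adjacent tissue, planted
clonotypes absent post-treatment.

What the generator does *not* emulate: read-level noise, mutational
signatures, linkage between expression and mutation, HLA allele population
frequencies, true peptide–HLA binding chemistry, ELISPOT plate effects and
counting artifacts, or V(D)J recombination biases. Passing tests therefore
demonstrate that the *rules and statistics* behave as specified under
controlled noise — not that the pipeline's biological inputs (predictors,
callers) are accurate on real data.

# Operating characteristics

Three simulation helpers expose the pipeline's own error rates, used by
the acceptance checks and reusable for assay design:

* `elispot_null_fpr()` — all-background screens (defaults: 200 screens ×
  100 antigens × 2 experiments, triplicate wells, Poisson mean 10)
  measuring the single-experiment false-positive rate against the ≥ 2-
  experiment confirmed rate. Confirmation squares a small per-experiment
  rate, so the confirmed rate is far smaller — the purpose of the rule.
* `elispot_recovery()` — screens with one planted responder (pool and
  single wells at background + 6 background SD) processed through the full
  `screen_antigens()` → `deconvolute()` chain. Note that recovery requires
  *four* positivity events (pool and single peptide, each in two
  experiments), and with triplicate wells the sample SD of the negative
  control is itself noisy; the conjunction therefore caps recovery
  materially below the per-condition positive rate. This is an inherent
  property of the 3-SD/≥2-experiment rule at these replicate numbers, not
  an implementation artifact; more negative-control wells would tighten
  the threshold estimate.
* `clonotype_drop_power()` — exact predicted power of the Fisher test for
  planted 10-fold frequency drops at the fixture depths (266 pre, 48
  post), summed over binomial count probabilities, against the empirical
  flag rate over 200 multinomial repertoires. Because multinomial
  marginals are binomial, prediction and simulation must agree up to
  Monte-Carlo noise; the acceptance check asserts agreement within 5
  percentage points.

Problem sizes throughout (200 simulated screens, 100 antigens, 40-gene
desk proteomes, 10-fold scaled burden) are the package's chosen desk
scale: large enough for stable rates, small enough that the full suite
runs in well under a minute.

# Known limitations

* The Fisher test's exact enumeration is O(min margin) per table; it is
  exhaustive-tested to N ≤ 40 and spot-checked against a log-space oracle
  to margins of 500, but for very deep tables (N ≫ 10⁴) a mid-p or
  asymptotic alternative would be preferable.
* The 3-SD ELISPOT rule assumes replicate wells are exchangeable within a
  plate; plate-edge and day effects are not modeled.
* Clonotype merging cannot rescue TRB-only cells when one TRB pairs with
  several TRAs; such cells form a flagged, separate clonotype.
* The surrogate rank provider is deliberately biology-free; conclusions
  about real binding require a real predictor behind the provider
  interface.
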