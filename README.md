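# neoscreen

Detecting spontaneous anti-neoepitope CD8+ T-cell responses in tumor
cohorts — in idiomatic, fully-tested R.

Tumors with a high mutational burden (bladder cancer among them) present
mutant peptides — *neoepitopes* — on HLA class I molecules, and a fraction
of patients mount spontaneous CD8+ T-cell responses against them.
Quantifying that fraction, and following the responding T-cell clones
through therapy, takes a long chain of computational steps that is usually
re-implemented ad hoc for every study. `neoscreen` packages that chain as
reusable, unit-tested functions for immunologists running neoantigen
screens:

1. **Variant consensus** — keep somatic *missense* variants supported by at
   least *k* of *n* callers (default 2 of {Mutect2, Strelka2, VarScan2}):
   `read_variants()`, `consensus_filter()`.
2. **Peptide enumeration** — build the 25-residue window centered on each
   variant (clipped at protein termini) and emit every 8–11-mer containing
   the mutated residue, paired with its wild-type counterpart:
   `build_window()`, `enumerate_peptides()`. An interior variant yields
   exactly 8+9+10+11 = 38 mutant/WT pairs.
3. **Candidate prioritization** — score each unique mutant peptide against
   the patient's HLA-A/B/C alleles through a pluggable `%Rank` provider
   (precomputed NetMHCpan/PRIME tables, or a deterministic surrogate) and
   select either by thresholds (`%Rank < 0.5` **and** gene expression
   `> 1 TPM`, both strict) or the top-N best-ranked unique peptides
   (default 150): `score_candidates()`, `select_candidates()`,
   `counts_to_tpm()`.
4. **ELISPOT screening** — pool peptides (10–20 per pool), call a condition
   positive when its mean spot count exceeds the negative control by more
   than three negative-control standard deviations (sample SD), confirm an
   antigen when positive in ≥ 2 independent experiments, and deconvolute
   confirmed pools to single peptides: `assign_pools()`, `call_antigen()`,
   `deconvolute()`, `compare_mut_wt()`.
5. **Clonotype tracking** — group single-cell TCR rearrangements into
   clonotypes (gene-level V/J + CDR3, TRB-anchored), require detection in
   ≥ 2 cells, screen for tumor enrichment, test pre/post-treatment
   frequency shifts with an exact Fisher test, and cross-reference bulk
   blood TRB repertoires: `build_clonotype_table()`,
   `compare_timepoints()`, `enrichment_screen()`, `match_bulk_trb()`.
6. **Exact statistics** — a two-sided 2×2 Fisher exact test under the
   minimum-likelihood convention
   (p = Σ {P(T) : P(T) ≤ P(observed)} over tables with fixed margins),
   Mann–Whitney U, and a paired Wilcoxon signed-rank test exact up to 25
   pairs: `fisher_exact_2x2()`, `mann_whitney_u()`,
   `wilcoxon_signed_rank()`.
7. **Synthetic cohorts** — `generate_cohort()` emits a complete,
   seed-reproducible patient bundle (proteome FASTA, multi-caller variant
   TSV, TPM table, HLA genotype, rank table, ELISPOT plates, single-cell
   TCR tables, bulk blood TRB) with planted ground truth, so every stage
   runs and is testable without controlled-access patient data;
   `run_pipeline()` drives all stages end to end.

## Worked example

```r
library(neoscreen)

# the exact Fisher test used for cohort contingency tables:
# 3/0 non-progressors vs 0/5 progressors with/without detectable
# neoantigen-specific T cells
p <- fisher_exact_2x2(3, 0, 0, 5)
sprintf("Fisher exact P = %.4f", p)
#> "Fisher exact P = 0.0179"

# a synthetic two-patient cohort, screened end to end
d <- tempfile()
generate_cohort(cohort_config(seed = 42, n_patients = 2,
  proteome = list(n_genes = 40, mean_length_aa = 120),
  variants = list(mutations_range = c(8, 20))), d)
s <- run_pipeline(run_config(d, tempfile()))
#> [neoscreen] P01: variants 13 -> consensus 11
#> [neoscreen] P01: peptide pairs 344 -> scored 2064 -> selected 23
#> [neoscreen] P01: 8 antigens tested, 2 confirmed
#> [neoscreen] P01: 45 clonotypes, 4 significant frequency shifts
#> ...
cat("cohort responders:", s$n_response_detected, "/", s$n_patients, "\n")
#> cohort responders: 2 / 2
```

Reading the log: of 13 called variants, 11 pass the 2-of-3 missense
consensus; they yield 344 mutant/WT peptide pairs, scored against 6 HLA
alleles (2064 peptide–allele scores); 23 pass the `%Rank < 0.5` + `> 1 TPM`
selection; pooled screening confirms 2 antigens in ≥ 2 experiments, so the
patient is classified as having a detectable anti-neoepitope response; the
single-cell repertoire resolves into 45 clonotypes of which 4 shift
significantly in frequency after treatment (Fisher exact, P < 0.05).

## Scope

The package starts from *protein-level* annotated variants, precomputed (or
surrogate) binding percentile ranks, counted ELISPOT wells and extracted
TCR rearrangements. Read alignment, variant calling itself, VEP/Funcotator
annotation, HLA typing, the neural binding predictors, and single-cell
expression clustering are upstream tools, out of scope by design. See the
methods vignette (`vignettes/neoepitope-screening.Rmd`) for the statistical
conventions and their rationale.
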