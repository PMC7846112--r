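---
title: "Family-based rare-variant prioritization under a dominant model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare-variant prioritization under a dominant model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

## The analysis famvar implements

famvar reproduces, as reusable components, the discovery strategy used to
find a private thrombophilia-causing variant in a single extended family
with multiple relatives affected by unprovoked venous thromboembolism
(VTE): whole-exome sequencing (WES) of a handful of relatives, a
five-stage variant-filtering cascade under an autosomal-dominant
full-penetrance model, co-segregation checking in the fully genotyped
pedigree, carrier screening in external cohorts and reference panels, and
exact nonparametric comparison of plasma coagulation phenotypes between
affected and unaffected members. The family in question carries a MAST2
missense variant (Arg89Gln); affected members show decreased free TFPI,
increased PAI-1 and a prolonged euglobulin clot lysis time (ECLT).

The package ships a synthetic-study generator with the same statistical
structure, so every stage can be exercised and tested without access to
the (undeposited) study data.

## The dominant full-penetrance model

The genetic model behind the cascade is: one copy of a rare allele
suffices to cause disease, and every carrier is affected. Under that
model, a causal variant must be

1. carried by **every** affected relative (heterozygous is enough),
2. carried by **no** unaffected relative,
3. plausibly functional (stop gain/loss, frameshift indel, nonsynonymous,
   splicing),
4. rare in every reference panel (< 1 per mille by default), and
5. predicted deleterious in silico (SIFT, PolyPhen, CADD).

`run_cascade()` applies these five filters in that order and records an
auditable per-stage report (`cascade_report`). The last three filters are
pure per-variant predicates and commute; the order is kept for the
report's narrative value only.

### Policy choices the model does not fix

*Missing genotypes.* The source strategy is silent on them. The default
(`missing_genotype_policy = "strict"`) reads the two genotype filters
literally: a missing case genotype cannot *confirm* sharing, so the
variant is dropped; a missing control genotype cannot confirm carriage,
so it never excludes. `"permissive"` instead ignores missing case calls.

*Variants absent from all panels.* They are **kept** by the rarity filter.
The archetypal causal variant is exactly the one the panels have never
seen; absence of evidence of commonness must not exclude.

*Unknown predictions.* `unknown_prediction_policy = "keep"` (default)
lets an unknown SIFT/PolyPhen/CADD value pass its criterion; `"drop"`
fails it. The deleteriousness criteria are conjunctive but individually
toggleable, because the original analysis used the predictors jointly
without stating an exact rule.

## Kinship and the sequencing design

The study sequenced the four "most genealogically distant" affected
relatives and two unaffected relatives "as close as possible" to the
cases. No quantitative criterion was published; famvar operationalizes
both with Wright's kinship coefficient $\varphi(i,j)$, the probability
that two alleles sampled one from each individual are identical by
descent, computed by the standard recursion with founders assumed
unrelated ($\varphi(i,i) = \tfrac12(1+\varphi(f_i,m_i))$;
$\varphi(i,j) = \tfrac12(\varphi(i,f_j)+\varphi(i,m_j))$ for the
later-generation member $j$). `select_cases_for_sequencing()` minimizes
the summed pairwise kinship of the chosen cases; controls maximize summed
kinship to those cases. Both search exhaustively (the affected and
unaffected sets here are far below the enumeration limit) and break ties
by lexicographic order of the sorted ids, for determinism. Inbred
pedigrees are supported by the recursion even though the study family is
treated as outbred.

## The synthetic study generator

`simulate_study()` emulates the study conditions:

* **Pedigree** — `template_pedigree()`: 15 members over 3 generations,
  5 affected (an index case, her mother, maternal uncle and aunt, and a
  first cousin), matching the published family structure.
* **Causal variant** — one allele copy planted in the earliest-generation
  founder ancestral to all affected members and gene-dropped, re-drawing
  until at least 3 carriers span at least 2 generations; carriers are
  affected with probability `penetrance` (default 1) and non-carriers
  with probability `phenocopy_rate` (default 0), so by default carriers
  and affected coincide. Its annotation (nonsynonymous, SIFT deleterious,
  PolyPhen probably damaging, CADD 30, panel frequency ~3e-6) satisfies
  every cascade criterion by construction.
* **Background variants** — 20,000 by default, gene-dropped independently
  (no linkage disequilibrium) from a Beta(0.2, 2) population allele
  frequency spectrum truncated to [1e-5, 0.5], a rare-skewed spectrum
  typical of exome data. Functional classes are assigned with probability
  `functional_fraction = 0.094`, calibrated to the published cascade
  proportion (108 likely functional among 1,153 candidate variants);
  `rare_fraction_of_functional = 0.02` of functional variants receive a
  fully deleterious prediction profile, echoing the 108-to-2 reduction.
  Panel frequencies are the true frequency under multiplicative
  log-normal noise (sigma = 0.2) — panels approximate but do not equal
  the cohort frequency.
* **Plasma values** — Normal(group mean, group SD) per parameter and
  affection status. Only means and SDs are recoverable from the published
  table, hence the Normal model. f-TFPI and PAI-1 moments are the sample
  moments of the measured 10-subject panel; ECLT moments come from the
  published mean ± SEM summaries (1200 ± 300 vs 458 ± 90 minutes,
  SEM converted to SD with n = 3 and 7); uPA and thrombomodulin showed no
  group difference, so both groups share one plausible mean/SD.

All randomness derives from `sim_config(seed = ...)`; identical configs
give byte-identical written studies. Because a simulated replicate
re-assigns status from the planted drop, it can have as few as 3 affected
members; `run_full_study()` therefore sequences `min(4, affected)` cases
and `min(2, unaffected)` controls.

What the generator does **not** emulate: linkage disequilibrium,
sequencing error, X-linked inheritance, population structure in the
external cohort, and relatedness between reference panels. Passing tests
on synthetic data therefore validate the *logic* of the pipeline, not its
robustness to artifacts of real sequencing data.

## Co-segregation and screening

`check_cosegregation()` re-examines each candidate in the *fully*
genotyped pedigree (the replication step that genotyped one further case
and eight controls in the study): a variant co-segregates perfectly when
every status-known, genotyped case carries it and no control does;
members with unknown status or missing genotypes are excluded from the
totals and counted separately. This is the step that eliminates a
candidate that survived the WES cascade but is not carried by a
later-genotyped case — replayed in the test suite with the published
discordant individual (305012). No formal segregation statistic (e.g. a
Bayes factor) is computed: the source analysis reports only the boolean
pattern, and a statistic would be an extension rather than a
reproduction.

`screen_cohort()` counts carriers in an external case/control cohort, and
`aggregate_panels()` sums reference-panel allele counts with a diploid
denominator: 2 alternate alleles among 345,939 individuals give
$2/691{,}878 \approx 2.89\times10^{-6}$. The published rounded figure
("~0.0004 %") is not reproduced; the exact computed frequency is
reported. "Total sequences" is read as *individuals*, following the
panels' own description of genetically independent individuals.

## Exact small-sample phenotype comparison

With 3 cases and 7 controls, asymptotic rank tests are not trustworthy,
so `mann_whitney_exact()` enumerates. U is computed from mid-rank sums;
when $\binom{n_1+n_2}{n_1} \le 10^6$ the two-sided p-value is the exact
permutation probability $P(|U - n_1 n_2/2| \ge$ observed$)$ over all
assignments of the pooled values — tie-correct by construction, and equal
to symmetric tail doubling capped at 1 because the permutation
distribution of U is symmetric under label swap. Larger problems fall
back to a normal approximation with tie-corrected variance and continuity
correction, flagged in the `method` field.

On the measured panel both f-TFPI and PAI-1 separate completely (3 vs 7),
so the exact two-sided p is $2/\binom{10}{3} = 1/60 \approx 0.0167$ — the
smallest two-sided value attainable at these group sizes. The published
"p = 0.01" is convention-dependent (one-sided enumeration or an
asymptotic approximation would yield it) and is documented here rather
than asserted.

The "±" in the published group summaries is interpreted as **SEM**, not
SD: recomputing from the printed individual values gives SEMs 1.95 / 1.22
(f-TFPI cases/controls) and 6.17 / 0.75 (PAI-1), matching the printed
1.9 / 1.2 / 6.1 / 0.7 at one decimal. `summarize_group()` uses the
sample (n − 1) SD and SEM = SD/√n, with both undefined at n = 1.

## Numerical and problem-size choices

* Exact enumeration is capped at $10^6$ assignments (`combn`-based);
  beyond that the flagged normal approximation is used.
* Subset selection enumerates exhaustively whenever the candidate pool
  allows (≤ 20 members is comfortable; the study family has 5 affected
  and 10 unaffected).
* The test suite validates kinship against Monte-Carlo gene dropping with
  200,000 labelled-allele drops (3-standard-error agreement on all 105
  pairs of the template pedigree), and the cascade against a single-pass
  brute-force predicate on 1,000-variant fixtures.
* The end-to-end recovery check runs 50 independent simulated studies at
  the default 20,000 background variants; the planted causal variant
  survives all five stages and co-segregation in every replicate, with a
  median final-candidate count of 1.

## A worked run

```{r, eval = FALSE}
library(famvar)
report <- run_full_study(sim_config(seed = 1), verbose = TRUE)
print(report)
```

The report bundles the cascade audit trail, the ranked segregation
results, the replication-cohort screen, the reference-panel aggregate and
the plasma comparisons, plus provenance (seed, package and R versions).
`write_report_json()` serializes it; `write_study()` writes the
simulated PED/VCF/TSV/CSV inputs for use with any other tool.

## Known limitations

* The published cascade counts (14,406 shared variants, 1,153 after
  control exclusion, 108 functional, 2 rare candidates) depend on the
  undeposited WES data; the simulator is calibrated to their
  *proportions*, not their absolute values.
* The composite rule by which the original analysis combined rarity and
  deleteriousness evidence was not stated (one of its two final
  candidates had panel frequency ~0.005 and benign predictions); famvar
  exposes the two filters independently rather than guessing the
  composite.
* Hemizygous male X genotypes, variant normalization/left-alignment and
  liftover are out of scope; sites are assumed bi-allelic after
  decomposition and coordinates are 1-based VCF throughout.
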