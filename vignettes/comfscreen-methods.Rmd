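---
title: "Screening somatic mutation catalogs for change-of-metabolic-function enzyme mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening somatic mutation catalogs for change-of-metabolic-function enzyme mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comfscreen)
```

## The problem

A change-of-metabolic-function (COMF) mutation gives an enzyme a new or
altered catalytic activity, as IDH1 p.R132H does when it converts the
enzyme into an R-2-hydroxyglutarate producer. Such mutations are rare
among the bulk of passenger and loss-of-function events, but they share a
recognizable genetic signature: the *identical* protein-level change
recurs independently across many patients' tumours (positive selection
concentrated at one residue), in a gene encoding an enzyme, at a
conserved residue close to the active site. `comfscreen` operationalizes
that signature as a filter funnel over a somatic mutation catalog and
adds the statistical machinery used to validate candidates downstream.

## The recurrence model

The null hypothesis for a single protein site is independent mutation:
across `n` tumours, each mutates the site with a small per-sample
probability `mu`, so the patient count at the site is
`X ~ Binomial(n, mu)` and the chance of recurrence at level `k` is the
upper tail `P(X >= k)`, computed exactly by
`recurrence_null_pvalue()`. For a catalog of roughly 10^4 samples and
per-site rates near 10^-6, three independent hits at one site already
have a chance probability around 2 × 10^-7:

```{r}
recurrence_null_pvalue(11000, 1e-6, 3)
```

Multiplied by the number of sites in the coding exome this still leaves
recurrence at 3+ a strong (if not individually conclusive) selection
signal in a catalog of that size; a catalog two orders of magnitude
larger needs the floor raised — hence the two generations of thresholds.

The recurrence filter couples the patient floor to a *gene-fraction*
condition, which captures the oncogene-style concentration of mutations
at one residue: the variant must account for more than 5% of the gene's
mutation burden (first generation), or more than 25% of the gene's
*recurrent* burden (second generation; the denominator counts only
observations of variants that themselves reach 9+ patients). Patient
floors are non-strict (`>=`), fractions strict (`>`), mirroring the way
the thresholds are stated. The fraction denominator counts all
deduplicated coding observations in the gene, not only missense ones —
the wording "of all mutations in a given gene" does not restrict the
class, so the inclusive reading is the default and the basis is
configurable (`recurrence_config()`).

The second generation adds a pathogenicity cutoff (FATHMM score at or
below −3; scores are consumed from the catalog, never computed). A
variant with no score is retained and flagged `fathmm_missing` by
default: absence of a score is not evidence of benignity. A `drop`
policy is available.

## Annotation triage

Each post-recurrence filter is a subset operation with a machine-readable
reason code, so the pipeline funnel reconstructs its input exactly:

- **Germline exclusion** removes variants whose minor allele frequency in
  a population table exceeds 0.01 (strict). Matching is by
  (gene, protein change); an entry absent from the table passes.
- **Enzyme restriction** keeps genes with an EC number (wildcard classes
  like `1.1.-.-` count).
- **Known gain-of-function exclusion** removes genes whose recurrent
  mutations are already established drivers; the shipped list
  (IDH1, IDH2, EZH2, PIK3CA, BRAF, RAS-family, ...) is a plain-text file
  users can edit.
- **Length** keeps proteins strictly under 1500 residues — a
  practical bound on what downstream biochemistry can express and purify.
- **Conservation**: the mutated residue's alignment column must carry the
  reference residue in at least 90% of non-gap homolog sequences. No
  published figure pins this number; 0.9 is this package's default,
  exposed in `filter_conserved()` and recorded in reports. Gap characters
  are excluded from numerator and denominator, and position-to-column
  mapping is strictly 1-based on the ungapped reference.

## Structure proximity

Candidates are classified by the minimum Euclidean distance between any
atom of the mutated residue and any atom of the active/ligand site:
within 10 Å is a hit, 10–15 Å marginal, beyond 15 Å distant. Both
boundaries are inclusive ("within 10 Å" reads naturally as ≤ 10). All
atoms of the residue are used because proximity is a residue-level
statement and side chains matter; a Cα-only mode exists for coarse
models. In `ligand_auto` mode the site is every hetero group except
waters, ions and buffer components; apo models (most predicted
structures) must supply an explicit residue list — the error message says
so rather than silently measuring against nothing. Construct numbering
rarely matches protein numbering (a short transcript variant can place
protein residue 400 at construct residue 191), so a constant per-structure
offset is part of the structure map. Alternate locations resolve to the
highest-occupancy conformer; multi-model files keep model 1; mmCIF input
is out of scope.

## The metabolomic screen

The validation arm profiles cells expressing each candidate mutant, its
wild-type control and vector controls — the reference design is 10
groups × 3 replicates over ~277 semi-quantified metabolites as
normalized ion counts. Two contrasts are computed per metabolite with
Welch's unequal-variances t-test (two-tailed throughout, since effects in
both directions are real):

- **group-vs-rest**: one group's replicates against all remaining samples
  pooled, Bonferroni-adjusted with family size `m` = the number of
  metabolites in the matrix. The printed q/p ratios of the reference
  analysis imply `m ≈ 277`, i.e. the family is metabolites within one
  contrast, not metabolites × contrasts.
- **mutant-vs-wild-type**: the named control group only, reported
  *uncorrected* for the volcano view.

Fold change is the ratio of group means on the imputed normalized counts
(not log scale, matching how ion-count fold changes are conventionally
reported). Missing values are treated as left-censored and imputed with
the per-metabolite minimum; the mask is retained and the step can be
skipped when a matrix arrives complete. Degenerate inputs follow a fixed
convention: two constant equal groups give t = 0, p = 1; constant unequal
groups give p = 0 with a `degenerate` flag.

## Evaluation

The screen's operating point is scored against a curated gold-standard
panel inside an a-priori universe of enzymes plausibly involved in
cancer metabolism (reference scale: a 42-entry panel, 300-enzyme
universe). Matching is at (gene, protein change) granularity, falling
back to gene level for panel entries without a residue. With 48
predictions of which 36 hit the panel, the matrix is tp 36, fp 12, fn 6,
tn 246: sensitivity 36/42 = 85.7%, specificity 246/258 = 95.3%, accuracy
282/300 = 94.0%. The package always reports the exact fractions next to
rounded percentages; a historically printed accuracy of 93% is
inconsistent with its own fraction, and this implementation stands by
the fraction.

## Synthetic data: what it does and does not emulate

The generators produce every input format the pipeline consumes, each on
its own explicitly seeded RNG stream (the caller's random state is
restored on exit, and equal seeds give byte-identical files):

- `gen_catalog()`: per-site background counts drawn
  `Binomial(n_samples, background_rate)` — exactly the recurrence null —
  plus hotspots planted with exact patient counts. Defaults (1000
  samples, 20 genes × 500 sites, rate 10^-4) are sized so background
  recurrence is rare but observable. It does *not* model mutational
  signatures, gene-level covariates of mutation rate, or multi-sample
  patients.
- `gen_alignment()`: homologs derived from a reference with independent
  per-position substitutions and optional gaps; conserved positions are
  held identical. No phylogenetic correlation structure.
- `gen_structure()`: a Cα chain on a line plus one ligand atom placed so
  a designated residue sits at an exactly known distance — constructed
  truth for the distance code, not a plausible fold.
- `gen_metabolite_matrix()`: log-normal baselines (location drawn per
  metabolite, scale from a 10% replicate coefficient of variation,
  matching tight transfection-replicate spread), multiplicative planted
  group effects, optional missingness. It does not model correlated
  metabolite blocks, batch effects, or platform drift.

Passing tests on these simulations show the *machinery* is correct —
counting, thresholds, distances, test statistics; they do not show that
real catalogs or metabolomes satisfy the generators' independence
assumptions.

## Numerical choices and known limitations

- The binomial tail is delegated to R's `pbinom`, which is stable in the
  small-rate regime; tests verify agreement with direct log-space pmf
  summation to 10^-9 relative error over the grid n ≤ 10^4, rate ≤ 10^-3,
  k ≤ 20.
- Tie-breaks in `top_variant_per_gene` are deterministic: most patients,
  then smallest residue position, then alphabetical alternate residue.
- Problem sizes in the test suite are chosen for a laptop-class single
  core: catalogs of a few hundred samples, 50-metabolite matrices,
  50-atom structures, 100-replicate simulation loops.
- **Small-n Welch behaviour.** At n = 3 per group the t approximation is
  coarse in both directions: the realized type-I error at the 0.05 level
  runs slightly conservative (~0.03 in our null simulations), while the
  extreme tail is anti-conservative — a null metabolite occasionally
  draws three nearly identical replicates, collapsing the Welch degrees
  of freedom to ~2 and producing very small p-values by chance. Two
  practical consequences, both visible in our simulations and worth
  remembering when reading real screens at this design size: (i) with
  hundreds of metabolites, a Bonferroni-corrected group-vs-rest null can
  still yield a handful of q < 0.05 false calls; (ii) a genuine
  multiplicative effect (whose own replicate spread scales with the
  fold) is *not* guaranteed the smallest p in its contrast — in
  repeated simulations at the reference design the planted effect ranks
  first only in a minority of draws at the 277-metabolite scale. Fold
  changes, by contrast, are re-estimated accurately (within a few
  percent at CV 10%). Significance rankings at n = 3 should therefore be
  read alongside effect sizes, not instead of them.
- The screen consumes the metabolite matrix as delivered and applies no
  further normalization; whether the upstream platform median-scaled the
  data is outside its visibility.
- Manual steps of the historical pipeline — literature triage of
  candidates, pseudogene curation — are intentionally out of scope; the
  reason-coded outputs are designed to make that curation auditable
  rather than to replace it.

## Command line

`inst/cli/comfscreen` is a thin Rscript wrapper exposing the stages as
subcommands (`catalog-normalize`, `screen-run`, `structure-classify`,
`metabolomics-run`, `evaluate`, `simulate-catalog`) for shell pipelines;
every subcommand is a direct call into the exported functions documented
above.
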