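# comfscreen

Most somatic mutations in cancer inactivate proteins or do nothing. A
small, interesting minority do the opposite: they confer a *new* or
*altered* enzymatic activity — a change of metabolic function (COMF). The
archetype is IDH1 p.R132H, which turns isocitrate dehydrogenase into an
R-2-hydroxyglutarate producer. `comfscreen` mines COSMIC-style somatic
mutation catalogs for candidate COMF enzyme mutations and provides the
statistical machinery to validate them: hotspot recurrence filtering,
structure-based active-site proximity classification, a metabolomic
differential-abundance screen, and a gold-standard confusion-matrix
evaluation.

The screen comes in two generations of stringency, sized to the catalog:

| stage | first generation (`metis1`) | second generation (`metis2`) |
|---|---|---|
| recurrence | ≥ 3 unique patients | ≥ 9 unique patients |
| gene fraction | > 5% of all gene mutations | > 25% of the gene's recurrent (9+) mutations |
| pathogenicity | — | FATHMM score ≤ −3 |
| structure | PDB entries, ≤ 10 Å to ligand | PDB or predicted models, 10 Å and 10–15 Å bins |

Shared downstream triage: duplicate/germline removal (dbSNP-style MAF >
0.01), enzyme (EC number) restriction, known gain-of-function exclusion,
most-frequent-variant-per-gene, protein length < 1500 residues, and
residue conservation across a homolog alignment.

## The statistics at the core

**Recurrence null model.** If a fixed protein site mutates independently
in each of *n* tumours with per-site probability *μ*, the chance of seeing
it in at least *k* patients is the binomial upper tail

  P(X ≥ k), X ~ Binomial(n, μ),

computed exactly (`recurrence_null_pvalue`). This is the argument that a
recurrence floor of 3 (small catalog) or 9 (large catalog) patients marks
positive selection rather than chance.

**Active-site proximity.** For a candidate's mutated residue, the minimum
Euclidean distance from any of its atoms to any atom of the
ligand/active-site selection, binned as ≤ 10 Å (hit), 10–15 Å
(marginal), > 15 Å (distant). Both boundaries are inclusive.

**Metabolomic screen.** Per metabolite, Welch's unequal-variances t-test
on normalized ion counts: each group versus all other samples pooled
(Bonferroni-adjusted over the metabolite family, q = min(1, p·m)) and
mutant versus its wild-type control (uncorrected, volcano-style). Missing
values are left-censored and imputed with the per-metabolite minimum.

**Evaluation.** Against a gold-standard COMF panel inside a fixed
enzyme universe: tp/fp/tn/fn with sensitivity, specificity, accuracy as
exact fractions and rounded percentages.

## Worked example

Simulate a catalog with one planted hotspot (9 patients at GENE1 residue
40), a toy structure with a ligand 5 Å from that residue, and run the
first-generation screen end to end:

```r
library(comfscreen)

pdb <- tempfile(fileext = ".pdb")
gen_structure(n_residues = 60, target_residue = 40, ligand_distance = 5,
              seed = 1, path = pdb)
cat_df <- gen_catalog(n_samples = 400, n_genes = 4, sites_per_gene = 60,
                      background_rate = 2e-4,
                      hotspots = data.frame(gene = "GENE1", position = 40,
                                            ref_aa = "A", alt_aa = "T",
                                            n_patients = 9),
                      seed = 1)
ann <- data.frame(gene = sprintf("GENE%d", 1:4),
                  ec_number = c("1.1.1.1", "2.7.1.1", NA, NA),
                  protein_length = c(600L, 700L, 800L, 900L),
                  known_gof = FALSE)
res <- run_comf_screen(cat_df, pipeline_config(
  mode = "metis1", annotations = ann, gof_genes = character(0),
  conservation = data.frame(gene = "GENE1", position = 40,
                            fraction_identical = 1),
  structure_map = list(GENE1 = list(path = pdb, chain = "A", offset = 0))))
res$candidates[, c("gene", "protein_change", "n_patients", "min_distance", "bin")]
#>    gene protein_change n_patients min_distance      bin
#> 1 GENE1         p.A40T          9            5 hit_le10
res$funnel
#>                 stage n_in n_out n_removed
#> 1         deduplicate   33    33         0
#> 2            missense   33    33         0
#> 3  summarize_variants   33    25         8
#> 4          recurrence   25     1        24
#> 5              enzyme    1     1         0
#> 6        top_per_gene    1     1         0
#> 7              length    1     1         0
#> 8        conservation    1     1         0
#> 9 structure_proximity    1     1         0
```

The planted hotspot is the only variant that survives: 9 unique patients
(≥ 3), a dominant share of its gene's mutations (> 5%), an EC-annotated
gene, a fully conserved residue, and 5 Å from the ligand (≤ 10 Å). The
funnel rows telescope — each stage's input count is the previous stage's
output — so every removal is attributed to exactly one stage.

The exact binomial null underlying the recurrence floor:

```r
recurrence_null_pvalue(11000, 1e-6, 3)
#> [1] 2.199517e-07
```

## Replicating a full-catalog screen

The historical full-catalog run (210,354 missense mutations in, 735
recurrent mutations across 125 genes, 48 recurrent enzyme candidates)
used a licensed, version-pinned COSMIC export and cannot be bundled or
re-run offline. To replicate it with your own licensed download:

1. Export all coding mutations with gene symbol, sample and tumour IDs,
   mutation description, and HGVS-p change; describe the headers with
   `catalog_dialect()`.
2. `parse_catalog()` → `deduplicate()` → `summarize_variants()` →
   `apply_recurrence_filter()` with `metis1_config()` (or
   `metis2_config()` plus FATHMM scores for a current-scale export).
3. Supply an EC/length annotation table, a dbSNP-derived MAF table, and
   per-gene structures (`pipeline_config()`), then `run_comf_screen()`.
4. Score against your gold-standard panel with `evaluation_config()`,
   `build_confusion()` and `metrics()`.

The funnel JSON (`write_funnel()`) records the counts at every stage for
comparison with the published figures.
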