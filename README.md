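# wsdecipher

Multi-data integration for candidate disease genes, candidate disease-causing
variants, and genotype–phenotype association in Waardenburg syndrome (WS).

WS is an autosomal-dominant auditory–pigmentary syndrome with seven confirmed
causative genes (*PAX3*, *MITF*, *SOX10*, *SNAI2*, *EDNRB*, *EDN3*, *KITLG*),
yet a substantial fraction of clinically diagnosed patients remains molecularly
unexplained. `wsdecipher` implements, as a tested R pipeline, a three-stage
strategy for deciphering those undiagnosed cases:

1. **Candidate gene prioritization.** Map the seed genes into several
   protein–protein interaction (PPI) sources and keep the one-hop partners
   supported by *every* source (set A). Independently, pool the seed genes'
   phenotype annotations into a disease phenotype set P<sub>ws</sub> of size
   N<sub>ws</sub> and score every annotated gene *g* by its
   phenotype-similarity weight

   &nbsp;&nbsp;&nbsp;&nbsp;W<sub>g</sub> = N<sub>g</sub> / N<sub>ws</sub>,

   where N<sub>g</sub> = |P<sub>g</sub> ∩ P<sub>ws</sub>|; genes with
   W<sub>g</sub> > 0.2 form set B (with N<sub>ws</sub> = 70 this is exactly
   "more than 14 shared phenotypes"). Preliminary candidates are A ∩ B, and an
   optional evidence filter (e.g. hearing impairment in knockout mice) yields
   high-priority candidates.
2. **Candidate variant nomination.** A consensus deleteriousness filter keeps
   a variant only if all five predictors agree: SIFT ≤ 0.001,
   PolyPhen2-HVAR > 0.957, MutationTaster = 1, CADD-phred > 25 and
   GERP++ RS > 4 (missing scores fail closed). Survivors are cross-referenced
   against known pathogenic variants, checked for per-residue conservation in
   a cross-species protein alignment, and located within protein domains;
   final candidates must pass all four stages.
3. **Genotype–phenotype association.** On a curated patient cohort with
   ternary phenotype coding (present / absent / not recorded), the package
   computes missing-aware prevalences, two-sided Pearson chi-square or Fisher
   exact tests per phenotype across gene strata (Fisher when any expected
   count is below 5; Freeman–Halton enumeration for 2×3 tables), pairwise
   tests, phi-coefficient phenotype co-occurrence with significance masking,
   sex-difference tests, and gene/subtype/variant-type distribution summaries.

A seeded synthetic-data module (`simulation_config()`, `generate_all()`)
emulates every input — PPI trios with planted consensus partners, annotations
with planted overlap counts, variant bundles with planted survivors and
per-stage decoys, and cohorts drawn from per-gene prevalence matrices with
controlled missingness — so the whole pipeline runs and is verified offline
with retained ground truth.

## Worked example

```r
library(wsdecipher)
config <- simulation_config(seed = 7)     # study-scale defaults
truth  <- generate_all(config, "ws_demo") # writes every input + ground truth

## Stage 1: gene prioritization
seeds    <- c("PAX3","MITF","SOX10","SNAI2","EDNRB","EDN3","KITLG")
networks <- lapply(truth$ppi$files, read_edge_list)
set_A    <- consensus_partners(lapply(networks, direct_partners, seeds = seeds))
annotations <- read_gene_phenotype_map(truth$phenotypes$file)
p_ws     <- ws_phenotype_union(seeds, annotations)
weights  <- phenotype_weights(names(annotations$annotations), p_ws, annotations)
set_B    <- select_set_B(weights, threshold = 0.2, seeds = seeds)
candidates <- prioritize(set_A, set_B, seeds)
candidates
#> Candidate gene sets: |A| = 4, |B| = 4, preliminary = 4
#>   preliminary: CHD7, EP300, KIT, SIN3A
subset(weights, gene %in% candidates$preliminary)[, 1:3]
#>       gene n_overlap    weight
#> 4697  CHD7        15 0.2142857
#> 4700 EP300        16 0.2285714
#> 4701   KIT        15 0.2142857
#> 4705 SIN3A        17 0.2428571
```

Each candidate shares more than 14 of the 70 pooled disease phenotype terms,
so its weight exceeds the 0.2 cutoff, and each interacts with a seed gene in
all three PPI sources — exactly the planted signal, recovered.

```r
## Stage 2: variant nomination
variants   <- read_variant_table(truth$variants$variants_file)
alignments <- lapply(truth$variants$msa_files, read_alignment,
                     reference_id = "Homo_sapiens")
report <- build_variant_report(variants,
                               known      = readLines(truth$variants$known_file)[-1],
                               alignments = alignments,
                               domains    = read_domain_table(truth$variants$domains_file))
report$gene_counts
#>    gene n_filter_pass n_novel n_conserved n_final
#> 1  MITF            13       9           8       7
#> 2  PAX3            30      22          21      20
#> 3 SOX10            11       7           6       5
```

The staged counts shrink monotonically (filter → novel → conserved →
in-domain); the 20/7/5 final candidates are the generator's planted variants.

```r
## Stage 3: genotype-phenotype association
cohort  <- read_cohort_table(truth$cohort$file, truth$cohort$phenotypes)
hearing <- group_association_test(cohort, "hearing_impairment")
hearing
#> Association of 'hearing_impairment' across PAX3/MITF/SOX10: pearson_chi2 p = 3.159e-05
hearing$prevalence
#>    gene n_present n_recorded proportion
#> 1  PAX3        92        116  0.7931034
#> 2  MITF       126        147  0.8571429
#> 3 SOX10       118        120  0.9833333
```

Hearing impairment is markedly more prevalent in the *SOX10* stratum of this
simulated cohort (98.3% vs 79.3% / 85.7%), and the group chi-square flags the
difference; denominators are recorded patients only, so they fall short of
the stratum sizes.

The same stages are scriptable from a shell via the thin CLI in
`inst/cli/ws-decipher.R` (subcommands `simulate`, `prioritize`,
`filter-variants`, `associate`, `run --config file.yaml`), and
`run_pipeline()` orchestrates everything from one configuration with
fail-fast input validation and a combined JSON report.

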