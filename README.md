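# neoscape

Neoepitope discovery from somatic missense mutations and gene fusions.

Tumor-specific somatic alterations can create peptides absent from the
normal proteome; those predicted to bind a patient's HLA class I
molecules are candidate *neoepitopes* — potential immunotherapy targets.
`neoscape` implements the full discovery workflow for the two alteration
classes that dominate pediatric cancers:

* **Missense SNVs** — every substitution at protein position *p* is
  expanded into the tiling nonamers covering *p* (nine for an interior
  mutation), each paired with its wild-type counterpart.
* **Gene fusions** — a junction retaining *n₅* coding nucleotides of the
  5′ partner and joining the 3′ partner at coding offset *n₃* is
  in-frame iff (*n₅* − *n₃*) mod 3 = 0; in-frame junctions are
  translated to the first stop and the nonamers overlapping the
  breakpoint are extracted.

Candidates are scored against the sample's HLA class I alleles through a
pluggable predictor contract (an output-file adapter for external
predictors, plus a deterministic built-in position-weight scorer with
the IC50 = 50000^(1−s) transform) and kept when **IC50 ≤ 500 nM**
(inclusive).  RNA-seq expression evidence requires at least one
mutant-supporting read spanning the full **27 bases** encoding the
nonamer.  Companion modules score WGS-vs-clinical HLA typing concordance
(homozygous loci count two correct alleles when called homozygous, one
when called heterozygous with a match; heterozygous loci use maximum
matching), compute cohort allele carrier frequencies, and aggregate
per-sample / per-subtype landscape summaries with half-up rounding at
the printed precision.

A deterministic synthetic-fixture module (`fixtureBundle`) generates
toy references, variants, fusions, reads, genotypes and binding
matrices with *planted ground truth*, so the whole pipeline is testable
offline with no data download.

## Worked example

The KRAS G13D hotspot, from substitution to filtered candidate:

```r
library(neoscape)

v <- list(sample = "SJ001", gene = "KRAS", aa_change = "G13D",
          aa_pos = 13L, aa_ref = "G", aa_mut = "D")
peptideWindows(missenseCandidates(referenceContexts()["KRAS"], v))
#>   offset aa_start       mut        wt scorable
#> 1      0        5 KLVVVGAGD KLVVVGAGG     TRUE
#> 2      1        6 LVVVGAGDV LVVVGAGGV     TRUE
#> 3      2        7 VVVGAGDVG VVVGAGGVG     TRUE
#> 4      3        8 VVGAGDVGK VVGAGGVGK     TRUE
#> 5      4        9 VGAGDVGKS VGAGGVGKS     TRUE
#> 6      5       10 GAGDVGKSA GAGGVGKSA     TRUE
#> 7      6       11 AGDVGKSAL AGGVGKSAL     TRUE
#> 8      7       12 GDVGKSALT GGVGKSALT     TRUE
#> 9      8       13 DVGKSALTI GVGKSALTI     TRUE
```

Nine tiling nonamers, each differing from its wild-type partner only at
the mutated residue.  Feeding an external predictor's output through the
adapter and filtering at the inclusive 500 nM cutoff:

```r
sc <- parsePredictorTable(text = c(
  "allele peptide affinity_nM",
  "HLA-A11:01 VVGAGDVGK 285.24",
  "HLA-A11:01 VVVGAGDVG 6204.10",
  "HLA-A02:01 KLVVVGAGD 1044.95"))
filterBinders(sc)
#>     peptide      allele ic50_nM predictor_tag
#> 1 VVGAGDVGK HLA-A*11:01  285.24         table
```

Only the 285.24 nM nonamer survives: a predicted HLA-A\*11:01-restricted
G13D neoepitope.  Concordance arithmetic works the same way — 288
correct alleles over 51 samples × 6 alleles prints as:

```r
formatPercent(288, 306)$label
#> [1] "94.1% (288/306)"
```

For an end-to-end run, `fixtureBundle()` + `writeFixtureBundle()` emit a
complete input directory and `runPipeline(runConfig(...))` produces
`candidates.tsv`, `sample_summary.tsv` and a run log; the
`inst/scripts/neoscape` wrapper exposes the same as `simulate` and `run`
subcommands.

## Package layout

| Area | Files |
| --- | --- |
| Domain classes (S4) | `R/AllClasses.R` |
| Readers/writers (FASTA, SAM, TSV dialects) | `R/io-*.R` |
| Missense windows | `R/peptide-windows.R` |
| Fusion junctions | `R/fusion-junction.R` |
| Binding prediction + filter | `R/mhc-binding.R` |
| Expression evidence | `R/expression.R` |
| HLA concordance | `R/hla-concordance.R` |
| Landscape reporting | `R/landscape.R` |
| Synthetic fixtures | `R/fixtures.R` |
| Orchestration + CLI | `R/pipeline.R`, `inst/scripts/neoscape` |

See `vignettes/neoscape-methods.Rmd` for the model, parameter and design
discussion.
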