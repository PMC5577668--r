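---
title: "Neoepitope discovery from missense mutations and gene fusions: methods and design"
author: "neoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoepitope discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscape)
```

## The problem

Tumor-specific somatic alterations can create peptides absent from the
normal proteome.  When such a peptide binds one of the patient's HLA
class I molecules it may be presented to CD8+ T cells — a *neoepitope*,
and a candidate target for immunotherapy.  In pediatric cancers two
alteration classes dominate: missense single-nucleotide variants, and
oncogenic gene fusions, whose chimeric junctions are sequence-novel by
construction.  `neoscape` implements the discovery workflow for both
classes: candidate peptide generation, MHC binding filtering, RNA-seq
expression evidence, HLA-typing concordance scoring, and cohort-level
landscape reporting.

## Candidate peptide generation

**Missense windows.** MHC class I ligands are canonically nine residues
long.  A substitution at protein position $p$ can appear in any 9-mer
that covers $p$: the windows starting at $p-8, \dots, p$.  An interior
mutation therefore yields exactly **nine tiling nonamers**; a mutation
within eight residues of a terminus yields fewer.  We report the reduced
count rather than padding — padding would fabricate sequence that does
not exist in the protein.  Each mutant window is paired with the
wild-type window at the same offset; the pair differs at exactly one
position, which is checked as a class invariant.  Wild-type windows are
carried for reference but no wild-type-based filter (e.g. differential
agretopicity) is applied.

```{r}
v <- list(aa_pos = 13L, aa_ref = "G", aa_mut = "D")
head(peptideWindows(missenseCandidates(referenceContexts()["KRAS"], v)), 3)
```

**Fusion junctions.** A junction retains $n_5$ coding nucleotides of the
5' partner and joins the 3' partner at coding offset $n_{3}$ from its
CDS start.  The 3' partner's native codons stay in register exactly when
$(n_5 - n_3) \bmod 3 = 0$; only such in-frame junctions are translated
into junction peptides, and translation halts at the first stop codon.
Out-of-frame events yield no candidates by default (a configuration flag
can translate the frameshifted tail for exploratory use, but it is off
because frameshift products are a different biological object).  When
the breakpoint splits a codon, the chimeric residue is assigned to
*both* sides for window-overlap purposes — it is encoded partly by each
partner.  Junction windows are exactly the 9-mers containing at least
one residue from each side, equivalently the set of all 9-mers minus
those wholly 5' minus those wholly 3'; the test suite checks this
set-algebra identity against brute-force enumeration.

## Binding prediction and the IC50 filter

Binding strength is expressed as a predicted IC50 in nM; lower is
stronger, and $\le 500$ nM is the conventional moderate-to-high affinity
cutoff.  The threshold is **inclusive** and applies to every (window,
allele) pair formed from the sample's up-to-six distinct class I
alleles; a homozygous locus contributes its allele once.  Windows are
never collapsed across alleles — one mutation can yield several
candidates by binding different alleles or in different registers.  No
percentile-rank filter is applied: the nanomolar cutoff is the sole
selection rule.

Real binding predictors are external, licensed tools, so the package
defines a predictor *contract* (peptide, allele → nM) with two
implementations:

* an **output-file adapter** (`parsePredictorTable`) for tabular output
  of an external run, tolerant of banner/separator decoration; and
* a **built-in position-weight scorer** (`matrixScore`): a 9 × 20
  per-allele weight table in $[0,1]$; a peptide's score $s$ is the
  positional mean and is mapped to nM by the community-standard
  transform $\mathrm{IC50} = 50000^{1-s}$.

The built-in scorer is deterministic plumbing for testing and for
planted-truth simulation; it is not a trained binding model and makes no
claim about real alleles.  Windows containing a non-standard residue
(X) are non-scorable — weight matrices cover the 20 standard residues —
and are excluded with a logged count, never silently scored.

## Expression evidence: the 27-base span rule

A candidate nonamer is called **expressed** when at least one RNA-seq
read (i) supports the mutant allele at the variant position and (ii)
spans all $3k = 27$ genomic bases encoding the window.  Two readings of
rule (ii) are possible; we adopt the strict one — the spanning read must
itself be a mutant-supporting read — because it is the only reading that
ties the expression evidence to the mutant peptide rather than to the
locus.  `strict = FALSE` relaxes this for sensitivity analysis.  Each of
the nine windows has its own 27 bases, so one mutation can have some
windows expressed and others not.

Coordinate mapping honors exon structure and strand: window bases may be
split across introns, and splice gaps (CIGAR `N`) in a read do *not*
break spanning because they are transcript-consistent, whereas a
deletion (`D`) overlapping any window base does.  Duplicate-marked,
secondary, supplementary and QC-failed alignments are excluded.  Minimum
base quality (default 20) and mapping quality (default 1) are exposed in
the configuration; read-level quality thresholds are not part of the
published rule, so they default to conventional values and are logged.
For fusion candidates the junction contig itself is the variant, so the
mutant-allele test is vacuous: any contig-aligned read spanning the 27
contig bases counts.  Samples without RNA-seq yield `NA` (unknown) for
every candidate — never `FALSE`.

## HLA typing concordance

Genotypes are compared at two-field (protein-level) resolution;
higher-resolution input is truncated with a warning.  Per locus, the
correct-allele count follows the homozygous rule — two correct if a
homozygous truth locus is called homozygous for that allele, one if
called heterozygous with one matching allele — and, for heterozygous
truth, maximum bipartite matching (each called allele credits at most
one truth allele).  The matching rule subsumes the homozygous rule and
makes the score independent of within-pair order; the case of a
called-homozygous locus against heterozygous truth (credited 1) is our
decision, as only the homozygous-truth direction is conventionally
specified.  Cohort accuracy is $100 \times \sum \mathrm{correct} / (2
\times \mathrm{loci})$, rounded half-up to one decimal.  Carrier
frequencies count a sample once per allele regardless of zygosity.

## Reporting conventions

Percentages are `100 * numerator / denominator` rounded **half-up** at
the printed precision (one decimal for percentages, two for per-subtype
means); base R's banker's rounding disagrees on exact ties, hence
`roundHalfUp`.  Per-sample summaries report both "mutations with at
least one passing candidate" and "distinct (peptide, allele) pairs" —
cohort tables in this field are ambiguous between the two, so emitting
both removes the ambiguity downstream.  Candidates arising from several
transcripts of one gene are de-duplicated per (sample, peptide, allele)
at reporting time with provenance retained.  Relapse samples are
excluded from primary per-subtype averages and reported in companion
(`*_incl_relapse`) columns.  The mutation-burden/epitope-count
relationship is summarized by ordinary least squares (`stats::lm`) with
$R^2$; a constant response is defined to have $R^2 = 0$.

## The synthetic-fixture world

Real patient WGS/RNA-seq is protected and the landscape statistics of a
540-patient cohort are not reproducible at desk scale, so correctness is
demonstrated by **planted-truth recovery**: `fixtureBundle(seed)`
generates a toy reference (single- and multi-exon transcripts, both
strands), missense and fusion cases with reads placed to make specific
windows expressed or not, genotypes, and binding matrices built so that
*exactly* the planted (peptide, allele) pairs pass the 500 nM filter
(planted cells weight 0.9 ≈ 2.95 nM; everything else weight 0, 50000
nM).  If a randomly drawn decoy window would collide with a planted
peptide the plant is infeasible; the bundle then redraws its cases from
the next derived seed, keeping the bundle a pure function of the seed.
All generators are deterministic in the seed and regenerate
byte-identically.

What the fixtures do *not* emulate: sequencing error, coverage
variation, tumor purity and clonality, alignment artifacts, and real
binding motifs.  Passing tests therefore demonstrate the combinatorial
and arithmetic correctness of the workflow — window enumeration, frame
arithmetic, span checking, filtering, counting — not predictive accuracy
on real tumors, which is inherited from whichever external predictor and
aligner the user supplies.

The default problem sizes keep the whole suite fast: bundles hold two
samples with one variant and one fusion each, and the randomized oracle
batteries run 1000 instances per property (window enumeration, junction
set algebra, CIGAR span checks, locus concordance), each instance a few
dozen residues or bases.

## Numerical and degenerate-input choices

* Genomic coordinates are 1-based inclusive end to end (IRanges
  convention); tabular inputs already use 1-based inclusive coordinates,
  so no conversion happens at the file boundary.  Protein positions are
  1-based.
* Coordinates are treated as belonging to a single assembly per run; no
  liftover is attempted.
* Sequences shorter than the window length yield an empty window list
  with a warning, not an error.
* A stop codon at or before a fusion junction yields zero candidates
  with a logged reason, not an error; likewise junctions in non-coding
  context.
* Reference-residue mismatches (annotation vs protein database, i.e.
  transcript-version drift) are hard errors reporting expected vs found.
* Candidate tables are sorted deterministically (sample, source, key,
  offset, allele) so identical runs are byte-identical.
* `k` is configurable for 8–11-mer extensions; all defaults use 9, and
  the expression span is always $3k$.

## Known limitations

* No indel/frameshift peptides, splice-variant peptides, or class II
  15-mers; fusion detection and HLA calling from reads are upstream
  tools, consumed via their outputs.
* The built-in scorer shares no statistical power with trained
  predictors; use the adapter for real analyses.
* Expression evidence is qualitative (spanning-read presence), not
  quantitative (no FPKM/TPM, no allele-specific expression statistics).
* BAM/CRAM are not parsed natively; convert to SAM text (e.g.
  `samtools view`) or extend the reader.
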