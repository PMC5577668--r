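#' @import methods
NULL

## ---------------------------------------------------------------------------
## HlaGenotype
## ---------------------------------------------------------------------------

#' HLA class I genotype of one sample
#'
#' Six two-field class I alleles (two each at HLA-A, HLA-B, HLA-C),
#' normalized to the \code{"HLA-A*02:01"} form.  Homozygous loci carry the
#' same allele twice.
#'
#' @slot sample sample identifier.
#' @slot alleles named character vector of length 6 with names
#'   \code{A1, A2, B1, B2, C1, C2}.
#' @export
setClass("HlaGenotype",
    representation(sample = "character", alleles = "character"))

setValidity("HlaGenotype", function(object) {
    a <- object@alleles
    if (length(a) != 6L)
        return("exactly six alleles (two per locus) required")
    if (!identical(names(a), c("A1", "A2", "B1", "B2", "C1", "C2")))
        return("alleles must be named A1, A2, B1, B2, C1, C2")
    pat <- "^HLA-[ABC]\\*[0-9]{2,3}:[0-9]{2,3}$"
    if (!all(grepl(pat, a)))
        return(paste0("malformed allele name(s): ",
                      paste(a[!grepl(pat, a)], collapse = ", ")))
    locus <- unname(substr(sub("^HLA-", "", a), 1, 1))
    want <- c("A", "A", "B", "B", "C", "C")
    if (!identical(locus, want))
        return("allele loci do not match slots (need A,A,B,B,C,C)")
    TRUE
})

#' Construct an HlaGenotype
#'
#' @param sample sample identifier.
#' @param alleles character vector of six class I alleles in locus order
#'   (A, A, B, B, C, C); any accepted input form (see
#'   \code{\link{normalizeHlaAllele}}).
#' @return an \linkS4class{HlaGenotype}.
#' @examples
#' HlaGenotype("S1", c("A*02:01", "A*11:01", "B*07:02", "B*08:01",
#'                     "C*04:01", "C*07:01"))
#' @export
HlaGenotype <- function(sample, alleles) {
    alleles <- vapply(alleles, normalizeHlaAllele, character(1),
                      USE.NAMES = FALSE)
    names(alleles) <- c("A1", "A2", "B1", "B2", "C1", "C2")
    new("HlaGenotype", sample = as.character(sample), alleles = alleles)
}

setMethod("show", "HlaGenotype", function(object) {
    cat("HlaGenotype for sample", object@sample, "\n")
    for (l in c("A", "B", "C"))
        cat("  HLA-", l, ": ",
            paste(object@alleles[paste0(l, 1:2)], collapse = " / "),
            "\n", sep = "")
})

#' @rdname HlaGenotype
#' @param object,x an \code{HlaGenotype}.
#' @param locus optional locus letter (\code{"A"}, \code{"B"} or \code{"C"})
#'   to restrict \code{hlaAlleles} to one locus pair.
#' @export
hlaAlleles <- function(x, locus = NULL) {
    stopifnot(is(x, "HlaGenotype"))
    if (is.null(locus)) return(x@alleles)
    x@alleles[paste0(match.arg(locus, c("A", "B", "C")), 1:2)]
}

#' @rdname HlaGenotype
#' @export
sampleId <- function(x) {
    if (is(x, "HlaGenotype")) return(x@sample)
    stop("no sampleId method for class ", class(x))
}

## ---------------------------------------------------------------------------
## TranscriptModel
## ---------------------------------------------------------------------------

#' Transcript model with exon structure
#'
#' Carries the exon intervals and CDS boundaries needed to map a peptide
#' window's codons to genomic positions.  All coordinates are 1-based
#' inclusive genomic positions (IRanges convention); tabular input files
#' use the same convention so no conversion occurs at the boundary.
#'
#' @slot txId transcript accession.
#' @slot gene gene symbol.
#' @slot chrom chromosome / contig name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons \link[IRanges]{IRanges} of exon intervals, sorted,
#'   non-overlapping.
#' @slot cdsStart,cdsEnd genomic CDS boundaries (within the exon span).
#' @export
setClass("TranscriptModel",
    representation(txId = "character", gene = "character",
                   chrom = "character", strand = "character",
                   exons = "IRanges",
                   cdsStart = "integer", cdsEnd = "integer"))

setValidity("TranscriptModel", function(object) {
    ex <- object@exons
    if (length(ex) == 0L) return("at least one exon required")
    st <- IRanges::start(ex); en <- IRanges::end(ex)
    if (is.unsorted(st)) return("exons must be sorted by start")
    if (length(ex) > 1L && any(st[-1] <= en[-length(ex)]))
        return("exons must be non-overlapping")
    if (!object@strand %in% c("+", "-")) return("strand must be + or -")
    if (object@cdsStart > object@cdsEnd)
        return("cdsStart must be <= cdsEnd")
    if (object@cdsStart < min(st) || object@cdsEnd > max(en))
        return("CDS boundaries outside the exon span")
    TRUE
})

#' Construct a TranscriptModel
#'
#' @param txId transcript accession.
#' @param gene gene symbol.
#' @param chrom chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exonStarts,exonEnds integer vectors of exon boundaries
#'   (1-based inclusive).
#' @param cdsStart,cdsEnd genomic CDS boundaries.  Default: the full exon
#'   span.
#' @return a \linkS4class{TranscriptModel}.  A message flags transcripts
#'   whose CDS length is not divisible by 3 (incomplete models).
#' @export
TranscriptModel <- function(txId, gene, chrom, strand, exonStarts, exonEnds,
                            cdsStart = min(exonStarts),
                            cdsEnd = max(exonEnds)) {
    tm <- new("TranscriptModel", txId = txId, gene = gene, chrom = chrom,
              strand = strand,
              exons = IRanges::IRanges(as.integer(exonStarts),
                                       as.integer(exonEnds)),
              cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd))
    if (cdsLength(tm) %% 3L != 0L)
        message("transcript ", txId, ": CDS length ", cdsLength(tm),
                " not divisible by 3 (incomplete model?)")
    tm
}

#' @rdname TranscriptModel
#' @param x a \code{TranscriptModel}.
#' @export
txId <- function(x) x@txId

#' @rdname TranscriptModel
#' @export
cdsLength <- function(x) {
    sum(pmin(IRanges::end(x@exons), x@cdsEnd) -
        pmax(IRanges::start(x@exons), x@cdsStart) + 1L)
}

setMethod("show", "TranscriptModel", function(object) {
    cat("TranscriptModel ", object@txId, " (", object@gene, ") ",
        object@chrom, ":", object@cdsStart, "-", object@cdsEnd,
        " (", object@strand, "), ", length(object@exons), " exon(s), CDS ",
        cdsLength(object), " nt\n", sep = "")
})

## ---------------------------------------------------------------------------
## ScoringMatrix
## ---------------------------------------------------------------------------

#' Position-weight binding matrix for one HLA allele
#'
#' The deterministic built-in predictor: a 9 x 20 table of per-position
#' residue scores in [0, 1].  A peptide's score is the positional mean,
#' mapped to a nanomolar IC50 by the standard \eqn{50000^{1-s}} transform
#' (see \code{\link{scoreToIC50}}).
#'
#' @slot allele two-field HLA allele name.
#' @slot weights numeric 9 x 20 matrix; columns named by the 20 standard
#'   residues.
#' @export
setClass("ScoringMatrix",
    representation(allele = "character", weights = "matrix"))

setValidity("ScoringMatrix", function(object) {
    w <- object@weights
    if (!is.numeric(w) || nrow(w) != 9L || ncol(w) != 20L)
        return("weights must be a numeric 9 x 20 matrix")
    if (!identical(colnames(w), AA20))
        return("weight columns must be the 20 standard residues (ACDEFGHIKLMNPQRSTVWY)")
    if (any(!is.finite(w))) return("weights must be finite")
    TRUE
})

#' Construct a ScoringMatrix
#'
#' @param allele HLA allele name (any accepted form).
#' @param weights 9 x 20 numeric matrix with residue column names.
#' @return a \linkS4class{ScoringMatrix}.
#' @export
ScoringMatrix <- function(allele, weights) {
    weights <- as.matrix(weights)[, AA20, drop = FALSE]
    new("ScoringMatrix", allele = normalizeHlaAllele(allele),
        weights = weights)
}

setMethod("show", "ScoringMatrix", function(object) {
    cat("ScoringMatrix for", object@allele, "- 9 positions x 20 residues,",
        "weight range", sprintf("[%.2f, %.2f]\n", min(object@weights),
                                max(object@weights)))
})

## ---------------------------------------------------------------------------
## WindowSet
## ---------------------------------------------------------------------------

#' Tiling nonamer windows around one missense mutation
#'
#' Pairs each mutant window with the wild-type window at the same offset.
#' Interior mutations yield nine windows for the default window length 9;
#' mutations close to a terminus yield fewer (never padded).
#'
#' @slot variantKey identifier of the source variant.
#' @slot mutantContext the mutated peptide context (mutation +/- k-1
#'   residues, clipped to the termini).
#' @slot contextStart 1-based protein position of the first context residue.
#' @slot windows data.frame with columns \code{offset} (0-based start of
#'   the window within the context), \code{aa_start} (1-based protein
#'   position of the window start), \code{mut} and \code{wt} (the paired
#'   peptides), and \code{scorable} (FALSE when the window contains a
#'   non-standard residue such as X).
#' @export
setClass("WindowSet",
    representation(variantKey = "character", mutantContext = "character",
                   contextStart = "integer", windows = "data.frame"))

setValidity("WindowSet", function(object) {
    w <- object@windows
    need <- c("offset", "aa_start", "mut", "wt", "scorable")
    if (!all(need %in% names(w)))
        return(paste("windows needs columns:", paste(need, collapse = ", ")))
    if (nrow(w)) {
        diffs <- mapply(function(m, wt) {
            sum(strsplit(m, "")[[1]] != strsplit(wt, "")[[1]])
        }, w$mut, w$wt)
        if (any(diffs != 1L))
            return("each mutant/wild-type window pair must differ at exactly one position")
    }
    TRUE
})

#' @rdname WindowSet
#' @param x a \code{WindowSet}.
#' @export
peptideWindows <- function(x) x@windows

setMethod("show", "WindowSet", function(object) {
    cat("WindowSet for", object@variantKey, "-", nrow(object@windows),
        "window(s), context", object@mutantContext, "\n")
})

## ---------------------------------------------------------------------------
## JunctionPeptide
## ---------------------------------------------------------------------------

#' Translated fusion-junction peptide
#'
#' The chimeric coding sequence across a fusion breakpoint, its
#' translation (truncated at the first stop codon), and the 1-based
#' peptide positions whose codons touch both partners: a single chimeric
#' codon when the break splits a codon, or the boundary residue pair when
#' the break falls between codons.
#'
#' @slot fusionKey fusion identifier.
#' @slot junctionCds chimeric nucleotide sequence.
#' @slot peptide translated peptide (up to the first stop).
#' @slot junctionSpan integer(2): first and last junction residue.
#'   Positions may exceed the peptide length when a stop codon truncates
#'   translation before the junction (in which case no junction window
#'   exists).
#' @slot inFrame TRUE when the 3' partner stays in native codon register.
#' @export
setClass("JunctionPeptide",
    representation(fusionKey = "character", junctionCds = "character",
                   peptide = "character", junctionSpan = "integer",
                   inFrame = "logical"))

setValidity("JunctionPeptide", function(object) {
    if (length(object@junctionSpan) != 2L)
        return("junctionSpan must have length 2")
    if (object@junctionSpan[1] > object@junctionSpan[2])
        return("junctionSpan must be ordered")
    if (nchar(object@peptide) &&
        !identical(object@peptide, translateCds(object@junctionCds)))
        return("peptide must be the translation of junctionCds")
    TRUE
})

setMethod("show", "JunctionPeptide", function(object) {
    cat("JunctionPeptide ", object@fusionKey,
        if (object@inFrame) " (in-frame)" else " (out-of-frame)",
        ": ", nchar(object@peptide), " aa, junction residues ",
        object@junctionSpan[1], "-", object@junctionSpan[2], "\n", sep = "")
})

## ---------------------------------------------------------------------------
## CandidateSet
## ---------------------------------------------------------------------------

.CANDIDATE_COLS <- c("sample", "peptide", "wt_peptide", "allele", "ic50_nM",
                     "source", "source_key", "window_offset", "aa_start",
                     "expressed")

#' Set of candidate neoepitopes
#'
#' One row per retained (sample, peptide, HLA allele) combination that
#' passed the IC50 filter, with provenance (source variant or fusion,
#' window offset) and a tri-state expression flag (TRUE / FALSE / NA for
#' unknown, e.g. samples without RNA-seq).
#'
#' @slot candidates data.frame with columns \code{sample}, \code{peptide},
#'   \code{wt_peptide} (empty string for fusions), \code{allele},
#'   \code{ic50_nM}, \code{source} ("missense" or "fusion"),
#'   \code{source_key}, \code{window_offset} (0-based within the source
#'   peptide context), \code{aa_start} (1-based start within the source
#'   protein or junction peptide), \code{expressed} (logical, NA =
#'   unknown).
#' @export
setClass("CandidateSet", representation(candidates = "data.frame"))

setValidity("CandidateSet", function(object) {
    df <- object@candidates
    if (!all(.CANDIDATE_COLS %in% names(df)))
        return(paste("candidates needs columns:",
                     paste(.CANDIDATE_COLS, collapse = ", ")))
    if (!nrow(df)) return(TRUE)
    if (length(unique(nchar(df$peptide))) > 1L)
        return("all candidate peptides must share one length")
    if (any(!is.na(df$ic50_nM) & df$ic50_nM <= 0))
        return("ic50_nM must be positive")
    if (!all(df$source %in% c("missense", "fusion")))
        return("source must be 'missense' or 'fusion'")
    mis <- df$source == "missense"
    if (any(mis)) {
        diffs <- mapply(function(m, wt) {
            if (!nzchar(wt)) return(NA_integer_)
            sum(strsplit(m, "")[[1]] != strsplit(wt, "")[[1]])
        }, df$peptide[mis], df$wt_peptide[mis])
        if (any(is.na(diffs)) || any(diffs != 1L))
            return("missense candidates must differ from wild type at exactly one position")
    }
    TRUE
})

#' Construct a CandidateSet
#'
#' @param candidates data.frame with the candidate columns (see the class
#'   description); missing \code{expressed} is filled with NA.
#' @return a \linkS4class{CandidateSet}.
#' @export
CandidateSet <- function(candidates = .emptyCandidates()) {
    if (!"expressed" %in% names(candidates))
        candidates$expressed <- NA
    rownames(candidates) <- NULL
    new("CandidateSet", candidates = candidates[, .CANDIDATE_COLS])
}

.emptyCandidates <- function() {
    data.frame(sample = character(), peptide = character(),
               wt_peptide = character(), allele = character(),
               ic50_nM = numeric(), source = character(),
               source_key = character(), window_offset = integer(),
               aa_start = integer(), expressed = logical())
}

#' @rdname CandidateSet
#' @param x a \code{CandidateSet}.
#' @export
candidates <- function(x) x@candidates

setMethod("length", "CandidateSet", function(x) nrow(x@candidates))

setMethod("as.data.frame", "CandidateSet",
          function(x, ...) x@candidates)

setMethod("show", "CandidateSet", function(object) {
    df <- object@candidates
    cat("CandidateSet:", nrow(df), "candidate(s),",
        length(unique(df$sample)), "sample(s);",
        sum(df$source == "missense"), "missense /",
        sum(df$source == "fusion"), "fusion;",
        sum(df$expressed %in% TRUE), "expressed,",
        sum(is.na(df$expressed)), "unknown\n")
    if (nrow(df)) print(utils::head(df, 6))
})

## ---------------------------------------------------------------------------
## FixtureBundle
## ---------------------------------------------------------------------------

#' Deterministic synthetic test world with planted ground truth
#'
#' Everything the pipeline consumes -- toy reference, transcript models,
#' variants, fusions, reads, HLA genotypes, binding matrices -- generated
#' as a pure function of a seed, together with the expected outputs
#' (window peptides, passing binders, expression flags, summary counts)
#' known by construction.
#'
#' @slot seed integer seed the bundle was generated from.
#' @slot proteome \link[Biostrings]{AAStringSet} of reference proteins.
#' @slot cds \link[Biostrings]{DNAStringSet} of coding sequences
#'   (transcript space, stop codon included).
#' @slot genome \link[Biostrings]{DNAStringSet} of synthetic contigs
#'   (one per transcript, plus fusion junction contigs).
#' @slot transcripts named list of \linkS4class{TranscriptModel}.
#' @slot variants missense variant data.frame (the data-matrix layout).
#' @slot fusions fusion event data.frame.
#' @slot samText character vector of SAM lines (header + alignments).
#' @slot genotypes named list of \linkS4class{HlaGenotype}.
#' @slot matrices named list of \linkS4class{ScoringMatrix} keyed by allele.
#' @slot truth list of planted expected outputs.
#' @export
setClass("FixtureBundle",
    representation(seed = "integer", proteome = "AAStringSet",
                   cds = "DNAStringSet", genome = "DNAStringSet",
                   transcripts = "list", variants = "data.frame",
                   fusions = "data.frame", samText = "character",
                   genotypes = "list", matrices = "list", truth = "list"))

setMethod("show", "FixtureBundle", function(object) {
    cat("FixtureBundle (seed ", object@seed, "): ",
        length(object@proteome), " proteins, ",
        nrow(object@variants), " variants, ",
        nrow(object@fusions), " fusions, ",
        length(object@genotypes), " genotyped sample(s), ",
        sum(!startsWith(object@samText, "@")), " reads\n", sep = "")
})
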