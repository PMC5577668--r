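#' Reading-frame phase of a fusion junction
#'
#' A fusion junction retains \code{n5} coding nucleotides of the 5'
#' partner (from its CDS start to the breakpoint) and joins the 3'
#' partner at coding offset \code{n3off} from its CDS start.  The 3'
#' partner's native codons remain in register downstream of the junction
#' exactly when \code{(n5 - n3off) mod 3 == 0}.
#'
#' @param n5 retained coding nucleotides of the 5' partner.
#' @param n3off coding-nucleotide offset of the 3' breakpoint.
#' @return logical: TRUE for an in-frame junction.
#' @examples
#' isInFrame(9, 0)   # codon-aligned join
#' isInFrame(10, 0)  # +1 shift: out of frame
#' isInFrame(10, 1)  # phases cancel: in frame
#' @export
isInFrame <- function(n5, n3off) {
    stopifnot(n5 >= 0, n3off >= 0)
    (n5 - n3off) %% 3 == 0
}

#' Assemble the chimeric coding sequence across a junction
#'
#' Prefix of the 5' partner CDS (first \code{n5} nucleotides) followed by
#' the 3' partner CDS from offset \code{n3off} onward.  This consumes a
#' junction already resolved to transcript coordinates; fusion detection
#' and contig assembly are upstream of this package.
#'
#' @param cds5,cds3 coding nucleotide sequences of the partners.
#' @param n5,n3off see \code{\link{isInFrame}}.
#' @return the chimeric nucleotide string, of length
#'   \code{n5 + nchar(cds3) - n3off}.
#' @export
buildJunctionCds <- function(cds5, n5, cds3, n3off) {
    cds5 <- as.character(cds5); cds3 <- as.character(cds3)
    if (n5 > nchar(cds5))
        stop("n5 (", n5, ") exceeds 5' CDS length (", nchar(cds5), ")",
             call. = FALSE)
    if (n3off > nchar(cds3))
        stop("n3off (", n3off, ") exceeds 3' CDS length (", nchar(cds3),
             ")", call. = FALSE)
    paste0(substr(cds5, 1, n5), substr(cds3, n3off + 1, nchar(cds3)))
}

#' Translate a coding sequence
#'
#' Standard genetic code; translation stops at the first stop codon and
#' a trailing incomplete codon is dropped.  Codons containing N translate
#' to X.
#'
#' @param cds nucleotide string over the alphabet ACGTN.
#' @return the peptide string (possibly empty).
#' @examples
#' translateCds("ATGAAATAGGGG")  # "MK": translation halts at TAG
#' @export
translateCds <- function(cds) {
    cds <- toupper(as.character(cds))
    if (grepl("[^ACGTN]", cds))
        stop("CDS contains characters outside ACGTN", call. = FALSE)
    ncod <- nchar(cds) %/% 3
    if (ncod == 0L) return("")
    codons <- substring(cds, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    aa <- Biostrings::GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"                         # codons containing N
    stop_at <- which(aa == "*")
    if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
    paste(aa, collapse = "")
}

#' Junction residue span of a fusion peptide
#'
#' The 1-based peptide positions whose codons contain nucleotides from
#' both partners.  When the breakpoint splits a codon, that single
#' chimeric residue is assigned to both sides; when it falls between
#' codons, the span is the boundary pair (last wholly-5' residue, first
#' wholly-3' residue).
#'
#' @param n5 retained coding nucleotides of the 5' partner.
#' @return integer(2): first and last junction residue position.
#' @export
junctionResidueSpan <- function(n5) {
    stopifnot(n5 >= 0)
    if (n5 %% 3 == 0) {
        c(as.integer(n5 / 3), as.integer(n5 / 3 + 1))   # boundary pair
    } else {
        chim <- as.integer(n5 %/% 3 + 1)                # chimeric codon
        c(chim, chim)
    }
}

#' Build a JunctionPeptide from partner coding sequences
#'
#' @param fusionKey identifier for the event.
#' @param cds5,cds3 partner coding sequences (5' partner without, 3'
#'   partner with, its stop codon).
#' @param n5,n3off junction phase parameters (see \code{\link{isInFrame}}).
#' @return a \linkS4class{JunctionPeptide}.  For out-of-frame events the
#'   peptide is still the translation to the first stop, but
#'   \code{inFrame} is FALSE and \code{\link{junctionWindows}} returns
#'   no windows.
#' @export
junctionPeptide <- function(fusionKey, cds5, n5, cds3, n3off) {
    jcds <- buildJunctionCds(cds5, n5, cds3, n3off)
    new("JunctionPeptide", fusionKey = fusionKey, junctionCds = jcds,
        peptide = translateCds(jcds),
        junctionSpan = junctionResidueSpan(n5),
        inFrame = isInFrame(n5, n3off))
}

#' Tiling windows overlapping a fusion junction
#'
#' Every length-\code{k} window of the junction peptide containing at
#' least one residue encoded on each side of the breakpoint (a chimeric
#' codon counts as both sides).  Equivalently: all k-mers of the peptide
#' minus those wholly 5' of the junction minus those wholly 3' of it.
#' Out-of-frame junctions yield no windows -- only in-frame coding
#' regions are translated into junction peptides.
#'
#' @param jp a \linkS4class{JunctionPeptide}.
#' @param k window length (default 9).
#' @return data.frame with columns \code{start} (1-based start within
#'   the junction peptide) and \code{peptide}.
#' @export
junctionWindows <- function(jp, k = 9) {
    empty <- data.frame(start = integer(0), peptide = character(0))
    if (!jp@inFrame) return(empty)
    L <- nchar(jp@peptide)
    span <- jp@junctionSpan
    if (L < k || span[2] > L) return(empty)      # stop before/at junction
    sMin <- max(1L, span[2] - k + 1L)
    sMax <- min(span[1], L - k + 1L)
    if (sMin > sMax) return(empty)
    starts <- sMin:sMax
    data.frame(start = starts,
               peptide = substring(jp@peptide, starts, starts + k - 1L),
               stringsAsFactors = FALSE)
}

#' Candidate-epitope precursors for one fusion event
#'
#' Composes the junction operations: frame check, chimeric CDS assembly,
#' translation, and junction-overlapping window extraction.  Out-of-frame
#' events, junctions in non-coding context (\code{n5 = 0} leaves no 5'
#' residue) and stop codons at or before the junction all yield zero
#' precursors, with the reason attached as the \code{"reason"} attribute.
#'
#' @param event one fusion row (see \code{\link{readFusionTable}}).
#' @param cds5,cds3 partner coding sequences.
#' @param k window length (default 9).
#' @return data.frame of precursors with columns \code{sample},
#'   \code{peptide}, \code{wt_peptide} (empty), \code{source},
#'   \code{source_key}, \code{window_offset} (0-based within the junction
#'   peptide), \code{aa_start}, \code{scorable}.
#' @export
fusionCandidates <- function(event, cds5, cds3, k = 9) {
    key <- fusionKey(event)
    empty <- data.frame(sample = character(0), peptide = character(0),
                        wt_peptide = character(0), source = character(0),
                        source_key = character(0),
                        window_offset = integer(0), aa_start = integer(0),
                        scorable = logical(0))
    jp <- junctionPeptide(key, cds5, event$n5, cds3, event$n3off)
    if (!jp@inFrame) {
        attr(empty, "reason") <- "out-of-frame junction"
        return(empty)
    }
    win <- junctionWindows(jp, k)
    if (!nrow(win)) {
        attr(empty, "reason") <- "no junction-overlapping window (short ORF or non-coding breakpoint)"
        return(empty)
    }
    data.frame(sample = event$sample, peptide = win$peptide,
               wt_peptide = "", source = "fusion", source_key = key,
               window_offset = win$start - 1L, aa_start = win$start,
               scorable = !grepl("[^ACDEFGHIKLMNPQRSTVWY]", win$peptide),
               stringsAsFactors = FALSE)
}
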