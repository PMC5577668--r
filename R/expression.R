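#' Genomic positions of the bases encoding a peptide window
#'
#' Maps a k-residue window starting at protein position \code{aaStart}
#' to the 3k genomic coordinates of its codons, in transcript order:
#' ascending along the genome for plus-strand transcripts, descending
#' for minus-strand ones.  Windows straddling exon junctions produce
#' positions split across the intron.
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @param aaStart 1-based protein position of the window's first residue.
#' @param k window length in residues (default 9, hence 27 bases).
#' @return integer vector of 3k genomic positions (1-based).
#' @export
windowGenomicPositions <- function(tx, aaStart, k = 9) {
    stopifnot(is(tx, "TranscriptModel"), aaStart >= 1)
    st <- IRanges::start(tx@exons); en <- IRanges::end(tx@exons)
    cdsPos <- unlist(lapply(seq_along(st), function(i) {
        a <- max(st[i], tx@cdsStart); b <- min(en[i], tx@cdsEnd)
        if (a > b) integer(0) else a:b
    }))
    if (tx@strand == "-") cdsPos <- rev(cdsPos)
    idx <- (3L * (aaStart - 1L) + 1L):(3L * (aaStart + k - 1L))
    if (max(idx) > length(cdsPos))
        stop("window [", aaStart, ", ", aaStart + k - 1L,
             "] extends past the CDS of ", tx@txId, " (",
             length(cdsPos) %/% 3L, " codons)", call. = FALSE)
    cdsPos[idx]
}

## flags excluded from expression counting: unmapped (0x4), QC fail
## (0x200), secondary (0x100), duplicate (0x400), supplementary (0x800)
.EXCLUDE_FLAGS <- 0x4L + 0x100L + 0x200L + 0x400L + 0x800L

.usableReads <- function(reads, chrom, mapqMin = 1) {
    reads[reads$chrom == chrom & reads$mapq >= mapqMin &
          bitwAnd(reads$flag, .EXCLUDE_FLAGS) == 0L, , drop = FALSE]
}

#' Does a read support the mutant allele?
#'
#' TRUE when the read's aligned base at the variant's genomic position
#' equals the mutant allele (with base quality at or above
#' \code{baseQualMin} when qualities are present).  Reads not covering
#' the position -- including reads whose deletion spans it -- return
#' FALSE.  The comparison is on the reference/plus strand as aligned,
#' matching how the variant alleles are recorded.
#'
#' @param read one row of a \code{\link{readSamSubset}} table (or an
#'   equivalent list with \code{blocks}, \code{seq}, \code{qual}).
#' @param variant one variant row with \code{pos} and \code{mut_allele}.
#' @param baseQualMin minimum Phred base quality (default 20).
#' @return logical.
#' @export
readSupportsMutant <- function(read, variant, baseQualMin = 20) {
    blocks <- if (is.data.frame(read)) read$blocks[[1]] else read$blocks
    pos <- as.integer(variant$pos)
    hit <- which(blocks[, "rstart"] <= pos & blocks[, "rend"] >= pos)
    if (!length(hit)) return(FALSE)
    q <- blocks[hit[1], "qstart"] + (pos - blocks[hit[1], "rstart"])
    seq <- if (is.data.frame(read)) read$seq else read$seq
    if (substr(seq, q, q) != variant$mut_allele) return(FALSE)
    qual <- if (is.data.frame(read)) read$qual else read$qual
    ph <- .phred(qual)
    is.null(ph) || ph[q] >= baseQualMin
}

#' Does a read span every base of a window?
#'
#' TRUE when all supplied genomic positions fall inside the read's
#' aligned match blocks.  Splice gaps (CIGAR N) between blocks are
#' transcript-consistent and do not break spanning; a deletion (D)
#' overlapping any window position does.
#'
#' @param read one row of a \code{\link{readSamSubset}} table.
#' @param positions integer vector of genomic positions (the 3k window
#'   bases from \code{\link{windowGenomicPositions}}).
#' @return logical.
#' @export
readSpansWindow <- function(read, positions) {
    blocks <- if (is.data.frame(read)) read$blocks[[1]] else read$blocks
    all(vapply(positions, function(p)
        any(blocks[, "rstart"] <= p & blocks[, "rend"] >= p), logical(1)))
}

#' Expression call for one missense candidate
#'
#' A candidate window counts as expressed when at least one RNA-seq read
#' both supports the mutant allele and spans the full 3k bases (27 for
#' nonamers) encoding the window.  Under the default strict rule the
#' spanning read must itself be a mutant-supporting read, which is what
#' ties expression evidence to the mutant peptide rather than the locus;
#' \code{strict = FALSE} relaxes the span requirement to any usable read
#' for sensitivity analysis.  Each window is evaluated against its own
#' 3k bases, so one mutation can have some windows expressed and others
#' not.
#'
#' @param candidate one candidate row with \code{aa_start}.
#' @param variant the source variant row.
#' @param tx the \linkS4class{TranscriptModel} the variant is annotated
#'   on.
#' @param reads alignment table from \code{\link{readSamSubset}}, or
#'   NULL when the sample has no RNA-seq (expression unknown, not
#'   FALSE).  Secondary, supplementary, duplicate-marked and QC-failed
#'   alignments are excluded.
#' @param k window length (default 9).
#' @param strict require the spanning read to support the mutant allele
#'   (default TRUE).
#' @param baseQualMin,mapqMin quality cutoffs for supporting reads
#'   (defaults 20 and 1).
#' @return list with \code{mutant_read_count},
#'   \code{spanning_mutant_read_count} and \code{expressed} (logical,
#'   NA when \code{reads} is NULL).
#' @export
callExpression <- function(candidate, variant, tx, reads, k = 9,
                           strict = TRUE, baseQualMin = 20, mapqMin = 1) {
    if (is.null(reads))
        return(list(mutant_read_count = NA_integer_,
                    spanning_mutant_read_count = NA_integer_,
                    expressed = NA))
    reads <- .usableReads(reads, variant$chrom, mapqMin)
    positions <- windowGenomicPositions(tx, candidate$aa_start, k)
    supports <- logical(nrow(reads)); spans <- logical(nrow(reads))
    for (i in seq_len(nrow(reads))) {
        supports[i] <- readSupportsMutant(reads[i, ], variant, baseQualMin)
        spans[i] <- readSpansWindow(reads[i, ], positions)
    }
    nMut <- sum(supports)
    nSpan <- if (strict) sum(supports & spans) else sum(spans)
    list(mutant_read_count = as.integer(nMut),
         spanning_mutant_read_count = as.integer(min(nSpan, nMut)),
         expressed = nSpan >= 1L)
}

#' Expression call for one fusion-junction candidate
#'
#' For fusion candidates the junction contig itself is the variant, so
#' the mutant-allele test is vacuous: any read aligned to the contig is
#' junction-derived.  A window is expressed when at least one usable
#' read spans the full 3k contig bases encoding it.
#'
#' @param candidate one candidate row with \code{aa_start} (1-based
#'   start within the junction peptide; codon c of the peptide occupies
#'   contig bases 3c-2..3c).
#' @param contig name of the junction contig the reads are aligned to.
#' @param reads alignment table (alignments to the junction contig), or
#'   NULL for no RNA (unknown).
#' @param k window length (default 9).
#' @param mapqMin minimum mapping quality (default 1).
#' @return list as for \code{\link{callExpression}};
#'   \code{mutant_read_count} counts usable reads overlapping the
#'   window at all.
#' @export
fusionWindowExpression <- function(candidate, contig, reads, k = 9,
                                   mapqMin = 1) {
    if (is.null(reads))
        return(list(mutant_read_count = NA_integer_,
                    spanning_mutant_read_count = NA_integer_,
                    expressed = NA))
    reads <- .usableReads(reads, contig, mapqMin)
    aaStart <- candidate$aa_start
    positions <- (3L * (aaStart - 1L) + 1L):(3L * (aaStart + k - 1L))
    overlaps <- logical(nrow(reads)); spans <- logical(nrow(reads))
    for (i in seq_len(nrow(reads))) {
        blocks <- reads$blocks[[i]]
        overlaps[i] <- any(vapply(positions, function(p)
            any(blocks[, "rstart"] <= p & blocks[, "rend"] >= p),
            logical(1)))
        spans[i] <- readSpansWindow(reads[i, ], positions)
    }
    list(mutant_read_count = as.integer(sum(overlaps)),
         spanning_mutant_read_count = as.integer(sum(spans)),
         expressed = sum(spans) >= 1L)
}

#' Attach expression calls to a candidate table
#'
#' Fills the \code{expressed} column of a candidate table by dispatching
#' each row to \code{\link{callExpression}} (missense) or
#' \code{\link{fusionWindowExpression}} (fusion).  Samples without
#' RNA-seq keep \code{expressed = NA} throughout.
#'
#' @param candidateDf candidate data.frame (the \code{candidates()} of a
#'   \linkS4class{CandidateSet}).
#' @param variants variant table keyed by \code{\link{variantKey}}.
#' @param transcripts named list of \linkS4class{TranscriptModel}.
#' @param reads alignment table, or NULL.
#' @param contigOf named character: junction contig name per fusion key.
#' @param rnaSamples character vector of samples with RNA-seq; rows from
#'   other samples stay NA regardless of \code{reads}.
#' @param k,strict,baseQualMin,mapqMin see \code{\link{callExpression}}.
#' @return the candidate data.frame with \code{expressed},
#'   \code{mutant_read_count} and \code{spanning_mutant_read_count}
#'   filled.
#' @export
attachExpression <- function(candidateDf, variants, transcripts, reads,
                             contigOf = character(0),
                             rnaSamples = unique(candidateDf$sample),
                             k = 9, strict = TRUE, baseQualMin = 20,
                             mapqMin = 1) {
    vkeys <- variantKey(variants)
    candidateDf$mutant_read_count <- NA_integer_
    candidateDf$spanning_mutant_read_count <- NA_integer_
    candidateDf$expressed <- NA
    for (i in seq_len(nrow(candidateDf))) {
        row <- candidateDf[i, ]
        rds <- if (row$sample %in% rnaSamples) reads else NULL
        if (row$source == "missense") {
            v <- variants[match(row$source_key, vkeys), ]
            cl <- callExpression(row, v, transcripts[[v$mrna_accession]],
                                 rds, k = k, strict = strict,
                                 baseQualMin = baseQualMin,
                                 mapqMin = mapqMin)
        } else {
            cl <- fusionWindowExpression(row, contigOf[[row$source_key]],
                                         rds, k = k, mapqMin = mapqMin)
        }
        candidateDf$mutant_read_count[i] <- cl$mutant_read_count
        candidateDf$spanning_mutant_read_count[i] <-
            cl$spanning_mutant_read_count
        candidateDf$expressed[i] <- cl$expressed
    }
    candidateDf
}
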