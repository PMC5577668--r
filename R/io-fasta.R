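#' @importFrom Biostrings readAAStringSet readDNAStringSet writeXStringSet
#'   AAStringSet DNAStringSet DNAString reverseComplement GENETIC_CODE
NULL

#' Read a protein FASTA with pipe-delimited record metadata
#'
#' Headers of the form \code{">P001|KRAS|NM_004985|12345"} carry protein
#' accession, gene symbol, mRNA accession and protein GI (the GI field
#' may be empty).  Plain headers are accepted; missing fields are empty
#' strings.  Sequences are validated against the amino-acid alphabet
#' (20 standard residues plus X) and must contain no internal stop.
#'
#' @param path FASTA path.
#' @return \link[Biostrings]{AAStringSet} named by protein accession with
#'   \code{mcols} columns \code{gene}, \code{mrna_accession},
#'   \code{protein_gi}.
#' @export
readProteinFasta <- function(path) {
    aa <- Biostrings::readAAStringSet(path)
    parts <- strsplit(sub(" .*$", "", names(aa)), "|", fixed = TRUE)
    get <- function(i) vapply(parts, function(p)
        if (length(p) >= i) p[i] else "", character(1))
    names(aa) <- get(1)
    S4Vectors::mcols(aa) <- S4Vectors::DataFrame(
        gene = get(2), mrna_accession = get(3), protein_gi = get(4))
    for (i in seq_along(aa)) {
        s <- as.character(aa[[i]])
        if (!nzchar(s))
            stop("empty protein sequence: ", names(aa)[i], call. = FALSE)
        if (grepl("\\*", s))
            stop("internal stop symbol in protein ", names(aa)[i],
                 call. = FALSE)
        .checkProteinAlphabet(s, paste0("protein ", names(aa)[i]))
    }
    aa
}

#' Write a protein set in the pipe-delimited FASTA layout
#'
#' @param proteins \link[Biostrings]{AAStringSet} with the \code{mcols}
#'   produced by \code{\link{readProteinFasta}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeProteinFasta <- function(proteins, path) {
    mc <- S4Vectors::mcols(proteins)
    out <- proteins
    names(out) <- paste(names(proteins), mc$gene, mc$mrna_accession,
                        mc$protein_gi, sep = "|")
    Biostrings::writeXStringSet(out, path)
    invisible(path)
}

#' Export candidate windows as a peptide FASTA
#'
#' Hand-off format for external binding predictors: one record per
#' unique peptide occurrence, headers encoding
#' \code{sample|source_key|offset}.
#'
#' @param windows data.frame with columns \code{sample},
#'   \code{source_key}, \code{window_offset}, \code{peptide} (the mutant
#'   window table produced by the pipeline, or \code{candidates()} of a
#'   \linkS4class{CandidateSet}).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePeptideFasta <- function(windows, path) {
    u <- unique(windows[, c("sample", "source_key", "window_offset",
                            "peptide")])
    aa <- Biostrings::AAStringSet(u$peptide)
    names(aa) <- paste(u$sample, u$source_key, u$window_offset, sep = "|")
    Biostrings::writeXStringSet(aa, path)
    invisible(path)
}

.TX_COLS <- c("tx_id", "gene", "chrom", "strand", "exon_starts",
              "exon_ends", "cds_start", "cds_end")

#' Read transcript models from a GenePred-like table
#'
#' Tab-separated layout with one transcript per row: \code{tx_id},
#' \code{gene}, \code{chrom}, \code{strand}, comma-separated
#' \code{exon_starts} / \code{exon_ends} (1-based inclusive), and
#' genomic \code{cds_start} / \code{cds_end}.
#'
#' @param path path to the table.
#' @return named list of \linkS4class{TranscriptModel}.
#' @export
readTranscriptModels <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
    miss <- setdiff(.TX_COLS, names(df))
    if (length(miss))
        stop("transcript table is missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    tms <- lapply(seq_len(nrow(df)), function(i) {
        TranscriptModel(
            txId = df$tx_id[i], gene = df$gene[i], chrom = df$chrom[i],
            strand = df$strand[i],
            exonStarts = as.integer(strsplit(as.character(df$exon_starts[i]),
                                             ",")[[1]]),
            exonEnds = as.integer(strsplit(as.character(df$exon_ends[i]),
                                           ",")[[1]]),
            cdsStart = df$cds_start[i], cdsEnd = df$cds_end[i])
    })
    names(tms) <- df$tx_id
    tms
}

#' @rdname readTranscriptModels
#' @param transcripts list of \linkS4class{TranscriptModel}.
#' @export
writeTranscriptModels <- function(transcripts, path) {
    rows <- do.call(rbind, lapply(transcripts, function(tm)
        data.frame(tx_id = tm@txId, gene = tm@gene, chrom = tm@chrom,
                   strand = tm@strand,
                   exon_starts = paste(IRanges::start(tm@exons),
                                       collapse = ","),
                   exon_ends = paste(IRanges::end(tm@exons), collapse = ","),
                   cds_start = tm@cdsStart, cds_end = tm@cdsEnd,
                   stringsAsFactors = FALSE)))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read per-allele binding matrices
#'
#' Long tab-separated layout: columns \code{allele}, \code{pos} (1--9)
#' and one column per standard residue; nine rows per allele.
#'
#' @param path path to the table.
#' @return named list of \linkS4class{ScoringMatrix}, keyed by allele.
#' @export
readScoringMatrices <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE, comment.char = "#")
    miss <- setdiff(c("allele", "pos", AA20), names(df))
    if (length(miss))
        stop("matrix table is missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    out <- lapply(split(df, df$allele), function(d) {
        d <- d[order(d$pos), ]
        w <- as.matrix(d[, AA20])
        rownames(w) <- NULL
        ScoringMatrix(d$allele[1], w)
    })
    names(out) <- vapply(out, function(m) m@allele, character(1))
    out
}

#' @rdname readScoringMatrices
#' @param matrices list of \linkS4class{ScoringMatrix}.
#' @export
writeScoringMatrices <- function(matrices, path) {
    rows <- do.call(rbind, lapply(matrices, function(m)
        data.frame(allele = m@allele, pos = 1:9, m@weights,
                   check.names = FALSE, stringsAsFactors = FALSE)))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
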