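.VARIANT_COLS <- c("sample", "gene", "chrom", "pos", "ref_allele",
                   "mut_allele", "mutation_class", "aa_change",
                   "mrna_accession", "protein_gi",
                   "mutant_reads_tumor", "total_reads_tumor",
                   "mutant_reads_normal", "total_reads_normal")

.parseAaChange <- function(aa_change, line = NA) {
    m <- regmatches(aa_change,
                    regexec("^([A-Z])([0-9]+)([A-Z\\*])$", aa_change))[[1]]
    if (length(m) == 0L)
        stop("malformed amino-acid change '", aa_change, "'",
             if (!is.na(line)) paste0(" at line ", line), call. = FALSE)
    list(aa_ref = m[2], aa_pos = as.integer(m[3]), aa_mut = m[4])
}

#' Read the somatic variant data matrix
#'
#' Reads the per-sample variant table: sample, gene, genomic coordinate
#' (1-based), reference and mutant alleles, mutation class, amino-acid
#' change, transcript/protein accessions, and mutant/total read counts in
#' tumor and normal.  Only missense rows are in scope; rows of any other
#' mutation class are skipped and counted (reported via a message and the
#' \code{"skipped"} attribute).  The amino-acid change string (e.g.
#' \code{"G13D"}) is parsed into \code{aa_ref}, \code{aa_pos},
#' \code{aa_mut} columns.
#'
#' @param path path to a tab-separated file with the columns above.
#' @return data.frame of missense variants with parsed amino-acid change
#'   columns; attributes \code{rows_in} (input data rows) and
#'   \code{skipped} (non-missense rows dropped).
#' @seealso \code{\link{writeVariantMatrix}}
#' @export
readVariantMatrix <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
    miss <- setdiff(.VARIANT_COLS, names(df))
    if (length(miss))
        stop("variant matrix is missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    rowsIn <- nrow(df)
    keep <- df$mutation_class == "missense"
    nskip <- sum(!keep)
    if (nskip)
        message(nskip, " non-missense row(s) skipped (out of scope)")
    df <- df[keep, , drop = FALSE]

    parsed <- lapply(seq_len(nrow(df)), function(i)
        .parseAaChange(df$aa_change[i], line = which(keep)[i] + 1L))
    df$aa_ref <- vapply(parsed, `[[`, character(1), "aa_ref")
    df$aa_pos <- vapply(parsed, `[[`, integer(1), "aa_pos")
    df$aa_mut <- vapply(parsed, `[[`, character(1), "aa_mut")

    bad <- df$aa_ref == df$aa_mut
    if (any(bad))
        stop("reference and mutant residues identical (not missense) for: ",
             paste(df$aa_change[bad], collapse = ", "), call. = FALSE)
    for (col in c("mutant_reads_tumor", "total_reads_tumor",
                  "mutant_reads_normal", "total_reads_normal")) {
        df[[col]] <- as.integer(df[[col]])
        if (any(df[[col]] < 0, na.rm = TRUE))
            stop("negative read count in column ", col, call. = FALSE)
    }
    if (any(df$mutant_reads_tumor > df$total_reads_tumor) ||
        any(df$mutant_reads_normal > df$total_reads_normal))
        stop("mutant read count exceeds total read count", call. = FALSE)
    df$pos <- as.integer(df$pos)
    rownames(df) <- NULL
    attr(df, "rows_in") <- rowsIn
    attr(df, "skipped") <- nskip
    df
}

#' Write a variant table in the data-matrix layout
#'
#' @param variants data.frame as returned by
#'   \code{\link{readVariantMatrix}} (parsed columns are dropped; the
#'   \code{aa_change} string is authoritative).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeVariantMatrix <- function(variants, path) {
    utils::write.table(variants[, .VARIANT_COLS], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Key identifying one variant row
#'
#' \code{"sample|gene|aa_change"} -- the provenance key carried through
#' candidate tables.
#'
#' @param variants one or more variant rows.
#' @return character vector of keys.
#' @export
variantKey <- function(variants) {
    paste(variants$sample, variants$gene, variants$aa_change, sep = "|")
}

.FUSION_COLS <- c("sample", "gene5", "tx5", "bp5", "gene3", "tx3", "bp3",
                  "n5", "n3off", "junction_read_count")

#' Read a fusion event table
#'
#' BEDPE-like tab-separated layout with one row per fusion: sample, 5'
#' and 3' partner genes / transcripts / genomic breakpoints, the retained
#' coding length of the 5' partner (\code{n5}, nucleotides from its CDS
#' start to the breakpoint), the coding offset of the 3' breakpoint from
#' the 3' partner's CDS start (\code{n3off}), and the junction-spanning
#' read count.  \code{n5} and \code{n3off} determine the reading-frame
#' phase of the junction (see \code{\link{isInFrame}}).
#'
#' @param path path to the tab-separated file.
#' @return data.frame of fusion events.
#' @export
readFusionTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
    miss <- setdiff(.FUSION_COLS, names(df))
    if (length(miss))
        stop("fusion table is missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    for (col in c("n5", "n3off", "junction_read_count")) {
        df[[col]] <- as.integer(df[[col]])
        if (any(df[[col]] < 0, na.rm = TRUE))
            stop("negative value in column ", col, call. = FALSE)
    }
    rownames(df) <- NULL
    df
}

#' @rdname readFusionTable
#' @param fusions data.frame of fusion events.
#' @export
writeFusionTable <- function(fusions, path) {
    utils::write.table(fusions[, .FUSION_COLS], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Key identifying one fusion event
#'
#' @param fusions one or more fusion rows.
#' @return \code{"sample|gene5-gene3|tx5|tx3"} keys.
#' @export
fusionKey <- function(fusions) {
    paste(fusions$sample, paste0(fusions$gene5, "-", fusions$gene3),
          fusions$tx5, fusions$tx3, sep = "|")
}
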