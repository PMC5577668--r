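#' Aligned reference blocks of a CIGAR string
#'
#' Walks a CIGAR string and returns the reference intervals covered by
#' reference-consuming match operations (M, =, X).  Deletions (D) and
#' splice gaps (N) advance the reference and break the current block;
#' insertions (I) and soft clips (S) advance the query only; hard clips
#' (H) consume neither.
#'
#' @param cigar CIGAR string, e.g. \code{"20M100N30M"}.
#' @param pos 1-based leftmost reference position of the alignment.
#' @return integer matrix with one row per block and columns
#'   \code{rstart}, \code{rend} (1-based inclusive reference interval) and
#'   \code{qstart} (1-based offset of the block's first base in the query
#'   sequence).
#' @examples
#' cigarBlocks("20M100N30M", 100)  # two blocks across a splice gap
#' @export
cigarBlocks <- function(cigar, pos) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cigar))
        stop("malformed CIGAR string: '", cigar, "'", call. = FALSE)
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    rpos <- as.integer(pos)
    qpos <- 1L
    blocks <- NULL
    for (i in seq_along(op)) {
        if (op[i] %in% c("M", "=", "X")) {
            blocks <- rbind(blocks,
                            c(rstart = rpos, rend = rpos + n[i] - 1L,
                              qstart = qpos))
            rpos <- rpos + n[i]
            qpos <- qpos + n[i]
        } else if (op[i] %in% c("D", "N")) {
            rpos <- rpos + n[i]                  # block break
        } else if (op[i] %in% c("I", "S")) {
            qpos <- qpos + n[i]
        } else if (op[i] == "P" || op[i] == "H") {
            ## consumes neither reference nor query
        } else {
            stop("unsupported CIGAR operation '", op[i], "'", call. = FALSE)
        }
    }
    if (is.null(blocks))
        blocks <- matrix(integer(0), ncol = 3,
                         dimnames = list(NULL, c("rstart", "rend", "qstart")))
    blocks
}

## query length implied by a CIGAR (SEQ-consuming ops)
.cigarQueryLength <- function(cigar) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "=", "X", "I", "S")])
}

#' Read a SAM text file into an alignment table
#'
#' A minimal SAM reader sufficient for the expression-evidence stage:
#' header lines are skipped and each alignment line is reduced to the
#' fields the mutant-support and window-span rules need.  Aligned
#' reference blocks are precomputed from the CIGAR with
#' \code{\link{cigarBlocks}}.  Unmapped reads (flag 0x4 or \code{rname}
#' \code{"*"}) are dropped.
#'
#' @param path path to a SAM text file.
#' @return data.frame with columns \code{read_id}, \code{flag},
#'   \code{chrom}, \code{pos} (1-based leftmost), \code{mapq},
#'   \code{cigar}, \code{seq}, \code{qual}, and a list column
#'   \code{blocks} of \code{cigarBlocks} matrices.
#' @export
readSamSubset <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    recs <- lapply(lines, function(ln) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(f) < 11L)
            stop("SAM line with fewer than 11 fields: ",
                 substr(ln, 1, 50), call. = FALSE)
        list(read_id = f[1], flag = as.integer(f[2]), chrom = f[3],
             pos = as.integer(f[4]), mapq = as.integer(f[5]), cigar = f[6],
             seq = f[10], qual = f[11])
    })
    mapped <- vapply(recs, function(r)
        r$chrom != "*" && bitwAnd(r$flag, 4L) == 0L, logical(1))
    recs <- recs[mapped]
    for (r in recs) {
        if (r$seq != "*" && .cigarQueryLength(r$cigar) != nchar(r$seq))
            stop("read ", r$read_id, ": CIGAR (", r$cigar,
                 ") and sequence length (", nchar(r$seq),
                 ") are inconsistent", call. = FALSE)
    }
    data.frame(
        read_id = vapply(recs, `[[`, character(1), "read_id"),
        flag = vapply(recs, `[[`, integer(1), "flag"),
        chrom = vapply(recs, `[[`, character(1), "chrom"),
        pos = vapply(recs, `[[`, integer(1), "pos"),
        mapq = vapply(recs, `[[`, integer(1), "mapq"),
        cigar = vapply(recs, `[[`, character(1), "cigar"),
        seq = vapply(recs, `[[`, character(1), "seq"),
        qual = vapply(recs, `[[`, character(1), "qual"),
        blocks = I(lapply(recs, function(r) cigarBlocks(r$cigar, r$pos))),
        stringsAsFactors = FALSE)
}

## assemble one SAM alignment line (fixture side)
.samLine <- function(read_id, flag, chrom, pos, mapq, cigar, seq,
                     qual = strrep("I", nchar(seq))) {
    paste(read_id, flag, chrom, pos, mapq, cigar, "*", 0, 0, seq, qual,
          sep = "\t")
}
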