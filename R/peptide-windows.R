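#' Apply a missense substitution to a protein sequence
#'
#' Replaces the residue at \code{aaPos} with \code{aaMut} after checking
#' that the reference residue matches \code{aaRef}.  A mismatch is
#' reported with both residues, which is the symptom of transcript-version
#' drift between the variant annotation and the protein database.
#'
#' @param sequence protein sequence (character or
#'   \link[Biostrings]{AAString}).
#' @param aaPos 1-based protein position of the substitution.
#' @param aaRef expected reference residue at \code{aaPos}.
#' @param aaMut mutant residue.
#' @return the mutated sequence as a character string.
#' @examples
#' applyMissense("MTEYKLVVVGAGGVGKSALT", 13, "G", "D")
#' @export
applyMissense <- function(sequence, aaPos, aaRef, aaMut) {
    sequence <- as.character(sequence)
    if (aaPos < 1L || aaPos > nchar(sequence))
        stop("aaPos ", aaPos, " outside sequence of length ",
             nchar(sequence), call. = FALSE)
    found <- substr(sequence, aaPos, aaPos)
    if (found != aaRef)
        stop("reference residue mismatch at position ", aaPos,
             ": expected ", aaRef, ", found ", found,
             " (transcript-version drift?)", call. = FALSE)
    if (aaRef == aaMut)
        stop("reference and mutant residues are identical (", aaRef, ")",
             call. = FALSE)
    substr(sequence, aaPos, aaPos) <- aaMut
    sequence
}

#' Tiling k-mer windows containing a position
#'
#' Every length-\code{k} substring of \code{sequence} that contains the
#' 1-based position \code{pos}, in ascending start order.  An interior
#' position of a long enough sequence yields exactly \code{k} windows
#' (nine tiling nonamers for the default \code{k = 9}); positions within
#' \code{k - 1} residues of a terminus yield fewer, and a sequence
#' shorter than \code{k} yields none (with a warning).
#'
#' @param sequence peptide string.
#' @param pos 1-based position every window must contain.
#' @param k window length (default 9, the canonical MHC class I length).
#' @return data.frame with columns \code{start} (1-based window start)
#'   and \code{peptide}.
#' @examples
#' tilingWindows("MTEYKLVVVGAGDVGKSALT", 13)  # the nine G13D nonamers
#' @export
tilingWindows <- function(sequence, pos, k = 9) {
    sequence <- as.character(sequence)
    L <- nchar(sequence)
    k <- as.integer(k); pos <- as.integer(pos)
    stopifnot(k >= 1, pos >= 1, pos <= L)
    if (L < k) {
        warning("sequence of length ", L, " has no windows of length ", k,
                call. = FALSE)
        return(data.frame(start = integer(0), peptide = character(0)))
    }
    starts <- max(1L, pos - k + 1L):min(pos, L - k + 1L)
    data.frame(start = starts,
               peptide = substring(sequence, starts, starts + k - 1L),
               stringsAsFactors = FALSE)
}

#' Mutant/wild-type window pairs for one missense variant
#'
#' Applies the substitution, extracts every tiling window containing the
#' mutant residue, and pairs each with the wild-type window at the same
#' offset.  Windows containing a non-standard residue (X) are flagged
#' non-scorable: position-weight matrices cover the 20 standard residues
#' only.
#'
#' @param protein the protein sequence (character,
#'   \link[Biostrings]{AAString}, or a single-record
#'   \link[Biostrings]{AAStringSet}).
#' @param variant a one-row variant data.frame (or list) with fields
#'   \code{aa_pos}, \code{aa_ref}, \code{aa_mut} and the identifying
#'   fields used by \code{\link{variantKey}}.
#' @param k window length (default 9).
#' @return a \linkS4class{WindowSet}.
#' @examples
#' v <- list(sample = "S1", gene = "KRAS", aa_change = "G13D",
#'           aa_pos = 13L, aa_ref = "G", aa_mut = "D")
#' missenseCandidates("MTEYKLVVVGAGGVGKSALT", v)
#' @export
missenseCandidates <- function(protein, variant, k = 9) {
    if (is(protein, "AAStringSet")) {
        stopifnot(length(protein) == 1L)
        protein <- as.character(protein[[1]])
    }
    protein <- as.character(protein)
    pos <- as.integer(variant$aa_pos)
    mutseq <- applyMissense(protein, pos, variant$aa_ref, variant$aa_mut)
    k <- as.integer(k)
    ctxStart <- max(1L, pos - (k - 1L))
    ctxEnd <- min(nchar(mutseq), pos + (k - 1L))
    mutWin <- tilingWindows(mutseq, pos, k)
    windows <- data.frame(
        offset = mutWin$start - ctxStart,
        aa_start = mutWin$start,
        mut = mutWin$peptide,
        wt = substring(protein, mutWin$start, mutWin$start + k - 1L),
        stringsAsFactors = FALSE)
    windows$scorable <- !grepl("[^ACDEFGHIKLMNPQRSTVWY]", windows$mut)
    key <- if (!is.null(variant$sample)) variantKey(variant)
           else paste0(variant$aa_ref, pos, variant$aa_mut)
    new("WindowSet", variantKey = key,
        mutantContext = substr(mutseq, ctxStart, ctxEnd),
        contextStart = ctxStart, windows = windows)
}
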