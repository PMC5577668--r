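#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (half-up for positive values), the convention used by every printed
#' percentage and cohort mean in this package's reports.  Base R's
#' `round()` uses banker's rounding, which disagrees on exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' roundHalfUp(0.125, 2)   # 0.13, where round() gives 0.12
#' roundHalfUp(94.1176, 1) # 94.1
#' @export
roundHalfUp <- function(x, digits = 0) {
    f <- 10^digits
    sign(x) * floor(abs(x) * f + 0.5) / f
}

## single-letter alphabet used by the binding matrices (20 standard residues)
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## residues legal in a protein sequence: the 20 plus the unknown marker
AA_OK <- c(AA20, "X")

.assertScalarString <- function(x, what) {
    if (!is.character(x) || length(x) != 1L || is.na(x))
        stop(what, " must be a single character string", call. = FALSE)
    invisible(x)
}

.checkProteinAlphabet <- function(seq, what = "sequence") {
    bad <- setdiff(strsplit(seq, "")[[1]], AA_OK)
    if (length(bad))
        stop(what, " contains characters outside the amino-acid alphabet: ",
             paste(unique(bad), collapse = ", "), call. = FALSE)
    invisible(seq)
}

## Phred qualities from a SAM QUAL string ("*" means unavailable)
.phred <- function(qual) {
    if (identical(qual, "*")) return(NULL)
    as.integer(charToRaw(qual)) - 33L
}
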