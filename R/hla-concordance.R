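#' Correct-allele count at one HLA locus
#'
#' Compares a called allele pair against the clinical-typing truth pair
#' at two-field resolution.  A homozygous truth locus counts as two
#' correct alleles if called homozygous for that allele, or one if
#' called heterozygous with one matching allele.  A heterozygous truth
#' locus is scored by maximum matching: each called allele credits at
#' most one truth allele, so the count is the multiset intersection size
#' and is independent of within-pair order on either side.
#'
#' @param truth character(2): the clinically typed allele pair.
#' @param called character(2): the sequencing-derived pair.
#' @return integer in 0..2.
#' @examples
#' scoreLocus(c("A*02:01", "A*02:01"), c("A*02:01", "A*01:01"))  # 1
#' scoreLocus(c("A*02:01", "A*03:01"), c("A*03:01", "A*02:01"))  # 2
#' @export
scoreLocus <- function(truth, called) {
    stopifnot(length(truth) == 2L, length(called) == 2L)
    truth <- vapply(truth, normalizeHlaAllele, character(1),
                    USE.NAMES = FALSE)
    called <- vapply(called, normalizeHlaAllele, character(1),
                     USE.NAMES = FALSE)
    if (length(unique(.hlaLocus(c(truth, called)))) != 1L)
        stop("truth and called pairs are not at the same locus: ",
             paste(c(truth, called), collapse = ", "), call. = FALSE)
    tt <- table(truth); tc <- table(called)
    shared <- intersect(names(tt), names(tc))
    as.integer(sum(pmin(tt[shared], tc[shared])))
}

#' Per-sample, per-locus concordance table
#'
#' @param truthGenotypes,calledGenotypes named lists of
#'   \linkS4class{HlaGenotype} keyed by sample; samples present in both
#'   lists are scored.
#' @return data.frame with one row per (sample, locus): columns
#'   \code{sample}, \code{locus}, \code{correct_alleles},
#'   \code{truth_pair}, \code{called_pair}.
#' @export
concordanceTable <- function(truthGenotypes, calledGenotypes) {
    samples <- intersect(names(truthGenotypes), names(calledGenotypes))
    if (!length(samples))
        stop("no samples shared between truth and called genotypes",
             call. = FALSE)
    rows <- list()
    for (s in samples) {
        for (l in c("A", "B", "C")) {
            tp <- hlaAlleles(truthGenotypes[[s]], l)
            cp <- hlaAlleles(calledGenotypes[[s]], l)
            rows[[length(rows) + 1L]] <- data.frame(
                sample = s, locus = l,
                correct_alleles = scoreLocus(tp, cp),
                truth_pair = paste(tp, collapse = "/"),
                called_pair = paste(cp, collapse = "/"),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' Cohort typing accuracy
#'
#' Percentage of correctly called alleles over all scored loci:
#' \eqn{100 \times \sum correct / (2 \times loci)}, rounded half-up to
#' one decimal.
#'
#' @param concordance data.frame from \code{\link{concordanceTable}} (or
#'   any table with a \code{correct_alleles} column, one row per locus).
#' @return numeric percentage.
#' @export
cohortAccuracy <- function(concordance) {
    if (is.null(concordance) || nrow(concordance) == 0L)
        stop("cannot compute accuracy of an empty concordance table",
             call. = FALSE)
    roundHalfUp(100 * sum(concordance$correct_alleles) /
                (2 * nrow(concordance)), 1)
}

#' Cohort allele carrier frequencies
#'
#' For every allele observed in the cohort, the number of samples
#' carrying it on at least one chromosome (a homozygous carrier counts
#' once) and the carrier percentage of the cohort, rounded half-up to
#' one decimal.
#'
#' @param genotypes list of \linkS4class{HlaGenotype}.
#' @return data.frame with columns \code{allele}, \code{locus},
#'   \code{carriers}, \code{pct}, sorted by descending carrier count.
#' @export
carrierFrequencies <- function(genotypes) {
    if (!length(genotypes))
        stop("empty cohort", call. = FALSE)
    n <- length(genotypes)
    perSample <- lapply(genotypes, function(g) unique(hlaAlleles(g)))
    counts <- table(unlist(perSample))
    df <- data.frame(allele = names(counts), locus = .hlaLocus(names(counts)),
                     carriers = as.integer(counts),
                     pct = roundHalfUp(100 * as.integer(counts) / n, 1),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$carriers, df$allele), ]
    rownames(df) <- NULL
    df
}
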