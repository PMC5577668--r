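#' Normalize an HLA class I allele name to two-field form
#'
#' Accepts the common spellings -- \code{"HLA-A*02:01"}, \code{"A*02:01"},
#' \code{"HLA-A02:01"}, \code{"A02:01"} -- and returns the canonical
#' \code{"HLA-A*02:01"} form.  Resolution beyond two fields (e.g.
#' \code{"A*02:01:01"}) is truncated with a warning; typing in this
#' package is validated at two-field (protein-level) resolution.
#' Expression suffixes (L, S, C, A, Q, N) are dropped.
#'
#' @param allele a single allele name.
#' @return canonical two-field name, e.g. \code{"HLA-A*02:01"}.
#' @examples
#' normalizeHlaAllele("A*02:01")     # "HLA-A*02:01"
#' normalizeHlaAllele("HLA-B07:02")  # "HLA-B*07:02"
#' @export
normalizeHlaAllele <- function(allele) {
    .assertScalarString(allele, "allele")
    x <- trimws(allele)
    m <- regmatches(x, regexec(
        "^(?:HLA-)?([ABC])\\*?([0-9]{2,3}):([0-9]{2,3})((?::[0-9]+)*)[LSCAQN]?$",
        x))[[1]]
    if (length(m) == 0L)
        stop("cannot parse HLA allele name: '", allele, "'", call. = FALSE)
    if (nzchar(m[5]))
        warning("allele '", allele, "' truncated to two-field resolution",
                call. = FALSE)
    sprintf("HLA-%s*%s:%s", m[2], m[3], m[4])
}

.hlaLocus <- function(allele) substr(sub("^HLA-", "", allele), 1, 1)

## expand per-locus allele lists to homozygous pairs; error on > 2
.lociToGenotype <- function(sample, byLocus) {
    out <- character(0)
    for (l in c("A", "B", "C")) {
        a <- byLocus[[l]]
        if (is.null(a) || length(a) == 0L)
            stop("sample ", sample, ": no allele reported at HLA-", l,
                 call. = FALSE)
        if (length(a) == 1L) a <- rep(a, 2L)       # homozygous expansion
        if (length(a) > 2L)
            stop("sample ", sample, ": more than two alleles at HLA-", l,
                 ": ", paste(a, collapse = ", "), call. = FALSE)
        out <- c(out, a)
    }
    HlaGenotype(sample, out)
}

#' Read HLA class I genotype calls
#'
#' Two tabular layouts are supported and auto-detected from the header:
#' \itemize{
#'   \item wide (OptiType-style result table): columns \code{sample},
#'     \code{A1}, \code{A2}, \code{B1}, \code{B2}, \code{C1}, \code{C2}
#'     (extra columns such as \code{Reads} / \code{Objective} ignored);
#'   \item long: two columns \code{sample} and \code{alleles}
#'     (comma-separated list of 3--6 alleles).
#' }
#' Allele names are normalized with \code{\link{normalizeHlaAllele}}; a
#' locus reported with a single allele is expanded to a homozygous pair.
#'
#' @param path path to a tab-separated file.
#' @return named list of \linkS4class{HlaGenotype}, keyed by sample.
#' @seealso \code{\link{writeHlaCalls}}
#' @export
readHlaCalls <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE, comment.char = "#")
    wide <- all(c("A1", "B1", "C1") %in% names(df))
    gts <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
        sample <- as.character(df$sample[i])
        if (wide) {
            byLocus <- list()
            for (l in c("A", "B", "C")) {
                a <- unlist(df[i, intersect(paste0(l, 1:2), names(df))])
                a <- a[!is.na(a) & nzchar(a)]
                byLocus[[l]] <- vapply(a, normalizeHlaAllele, character(1),
                                       USE.NAMES = FALSE)
            }
        } else {
            a <- trimws(strsplit(as.character(df$alleles[i]), ",")[[1]])
            a <- vapply(a[nzchar(a)], normalizeHlaAllele, character(1),
                        USE.NAMES = FALSE)
            byLocus <- split(a, .hlaLocus(a))
        }
        gts[[i]] <- .lociToGenotype(sample, byLocus)
    }
    names(gts) <- vapply(gts, sampleId, character(1))
    gts
}

#' Write HLA genotypes in the wide tabular layout
#'
#' @param genotypes list of \linkS4class{HlaGenotype}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeHlaCalls <- function(genotypes, path) {
    rows <- do.call(rbind, lapply(genotypes, function(g)
        data.frame(sample = sampleId(g), as.list(hlaAlleles(g)),
                   stringsAsFactors = FALSE)))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
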