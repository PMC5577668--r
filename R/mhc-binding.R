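#' Score-to-affinity transform
#'
#' The community-standard mapping between a normalized binding score
#' \eqn{s \in [0, 1]} and a nanomolar IC50: \eqn{IC50 = 50000^{1-s}}.
#' A score of 1 maps to 1 nM (strong binder), 0 to 50000 nM.
#'
#' @param s normalized score(s) in [0, 1].
#' @return predicted IC50 in nM.
#' @export
scoreToIC50 <- function(s) 50000^(1 - s)

#' @rdname scoreToIC50
#' @param ic50 affinity in nM.
#' @export
ic50ToScore <- function(ic50) 1 - log(ic50) / log(50000)

#' Score peptides against a position-weight matrix
#'
#' The built-in deterministic predictor: a nonamer's score is the mean
#' of the matrix weights at its nine (position, residue) cells, mapped
#' to nM by \code{\link{scoreToIC50}}.  Peptides containing a residue
#' outside the 20 standard amino acids are non-scorable and get NA
#' affinity; downstream filtering drops them.
#'
#' @param peptides character vector of 9-mers.
#' @param m a \linkS4class{ScoringMatrix}.
#' @return data.frame with columns \code{peptide}, \code{allele},
#'   \code{score}, \code{ic50_nM}, \code{predictor_tag}.
#' @examples
#' m <- ScoringMatrix("HLA-A*02:01",
#'                    matrix(0.5, 9, 20, dimnames = list(NULL,
#'                    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])))
#' matrixScore("SIINFEKLV", m)  # s = 0.5 -> 50000^0.5 ~ 223.6 nM
#' @export
matrixScore <- function(peptides, m) {
    stopifnot(is(m, "ScoringMatrix"))
    scores <- vapply(peptides, function(p) {
        if (nchar(p) != 9L)
            stop("matrixScore requires 9-mers, got '", p, "'",
                 call. = FALSE)
        res <- strsplit(p, "")[[1]]
        idx <- match(res, AA20)
        if (anyNA(idx)) return(NA_real_)         # non-scorable (X etc.)
        mean(m@weights[cbind(1:9, idx)])
    }, numeric(1), USE.NAMES = FALSE)
    data.frame(peptide = peptides, allele = m@allele, score = scores,
               ic50_nM = ifelse(is.na(scores), NA_real_,
                                scoreToIC50(scores)),
               predictor_tag = "matrix", stringsAsFactors = FALSE)
}

#' Parse a predictor output table
#'
#' Adapter for NetMHC-style whitespace-delimited output from an external
#' binding predictor.  Decoration lines (blank, \code{#}-comments, dashed
#' separators, \code{pos ...} banners) are skipped.  If a header line
#' names the columns (\code{peptide}, \code{allele}/\code{HLA}/\code{MHC},
#' and an affinity column matching \code{affinity}/\code{aff(nM)}/
#' \code{ic50}), those positions are used; otherwise the default
#' three-column layout \code{allele peptide affinity_nM} is assumed.
#' Allele names are normalized (e.g. \code{"HLA-A02:01"} to
#' \code{"HLA-A*02:01"}).
#'
#' @param path path to the predictor output (or a character vector of
#'   lines via \code{text}).
#' @param text optional character vector of lines, used instead of
#'   \code{path}.
#' @return data.frame with columns \code{peptide}, \code{allele},
#'   \code{ic50_nM}, \code{predictor_tag = "table"}.
#' @export
parsePredictorTable <- function(path, text = NULL) {
    lines <- if (is.null(text)) readLines(path) else text
    keep <- !grepl("^\\s*$|^\\s*#|^-{2,}|^\\s*pos\\b", lines,
                   ignore.case = TRUE)
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines))
        stop("predictor table contains no data rows", call. = FALSE)
    toks <- strsplit(trimws(lines), "\\s+")

    ## header detection
    h <- tolower(toks[[1]])
    pepCol <- which(h == "peptide")
    allCol <- which(h %in% c("allele", "hla", "mhc"))
    affCol <- grep("^(affinity.*|aff\\(nm\\)|ic50.*|affinity_nm)$", h)
    if (length(pepCol)) {
        if (!length(affCol))
            stop("predictor table header has no affinity column",
                 call. = FALSE)
        toks <- toks[-1]; lineNo <- lineNo[-1]
        cols <- c(allele = allCol[1], peptide = pepCol[1], aff = affCol[1])
    } else {
        cols <- c(allele = 1L, peptide = 2L, aff = 3L)
    }
    rows <- lapply(seq_along(toks), function(i) {
        tk <- toks[[i]]
        if (length(tk) < max(cols))
            stop("predictor table row at line ", lineNo[i],
                 " has too few columns", call. = FALSE)
        aff <- suppressWarnings(as.numeric(tk[cols["aff"]]))
        if (is.na(aff))
            stop("non-numeric affinity '", tk[cols["aff"]], "' at line ",
                 lineNo[i], call. = FALSE)
        data.frame(peptide = tk[cols["peptide"]],
                   allele = normalizeHlaAllele(tk[cols["allele"]]),
                   ic50_nM = aff, predictor_tag = "table",
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Render binding scores in the tabular predictor layout
#'
#' Writes the layout \code{\link{parsePredictorTable}} reads back
#' (round-trip safe), including decoration lines.
#'
#' @param scores data.frame with columns \code{allele}, \code{peptide},
#'   \code{ic50_nM}.
#' @param path output path; omit to return the lines.
#' @return invisibly the path, or the character lines when \code{path}
#'   is missing.
#' @export
renderPredictorTable <- function(scores, path) {
    lines <- c("# predictor output (tabular adapter layout)",
               "----------------------------------------",
               "allele  peptide  affinity_nM",
               sprintf("%s  %s  %.4f", scores$allele, scores$peptide,
                       scores$ic50_nM),
               "----------------------------------------")
    if (missing(path)) return(lines)
    writeLines(lines, path)
    invisible(path)
}

#' Filter binding scores at an IC50 threshold
#'
#' Retains scores with \code{ic50_nM <= thresholdNM}; the bound is
#' inclusive (an IC50 of exactly 500 nM indicates moderate-to-high
#' affinity and is kept under the default).  Non-scorable rows (NA
#' affinity) are dropped.  Input order is preserved and the operation is
#' idempotent and monotone in the threshold.
#'
#' @param scores data.frame with an \code{ic50_nM} column.
#' @param thresholdNM inclusive affinity cutoff in nM (default 500).
#' @return the retained rows.
#' @export
filterBinders <- function(scores, thresholdNM = 500) {
    stopifnot(thresholdNM > 0)
    out <- scores[!is.na(scores$ic50_nM) & scores$ic50_nM <= thresholdNM, ,
                  drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Score candidate windows against a sample's HLA alleles
#'
#' Forms the Cartesian product of the unique candidate peptides with the
#' sample's distinct class I alleles (a homozygous locus contributes its
#' allele once), scores every pair through the backend, and applies the
#' IC50 filter.  Windows are never collapsed across alleles: one
#' mutation can yield multiple candidates by binding diverse alleles or
#' in distinct registers, and each surviving (peptide, allele) pair is
#' reported.
#'
#' @param peptides character vector of candidate 9-mers.
#' @param genotype an \linkS4class{HlaGenotype}.
#' @param backend either a named list of \linkS4class{ScoringMatrix}
#'   (keyed by allele) or a parsed predictor table (data.frame from
#'   \code{\link{parsePredictorTable}}).  Alleles the backend cannot
#'   score are reported with a warning and skipped, never silently
#'   scored.
#' @param thresholdNM inclusive IC50 cutoff (default 500 nM).
#' @return data.frame of passing pairs: \code{sample}, \code{peptide},
#'   \code{allele}, \code{ic50_nM}, \code{predictor_tag}.
#' @export
scoreCandidates <- function(peptides, genotype, backend,
                            thresholdNM = 500) {
    stopifnot(is(genotype, "HlaGenotype"))
    peptides <- unique(peptides)
    alleles <- unique(hlaAlleles(genotype))
    if (!length(peptides))
        return(data.frame(sample = character(0), peptide = character(0),
                          allele = character(0), ic50_nM = numeric(0),
                          predictor_tag = character(0)))
    if (is.data.frame(backend)) {
        scored <- backend[backend$allele %in% alleles &
                          backend$peptide %in% peptides, , drop = FALSE]
        unsupported <- setdiff(alleles, unique(backend$allele))
    } else {
        have <- vapply(backend, function(m) m@allele, character(1))
        unsupported <- setdiff(alleles, have)
        scored <- do.call(rbind, lapply(intersect(alleles, have),
            function(a) matrixScore(peptides, backend[[match(a, have)]])))
        if (is.null(scored)) scored <- data.frame(peptide = character(0),
            allele = character(0), ic50_nM = numeric(0),
            predictor_tag = character(0))
    }
    if (length(unsupported))
        warning("sample ", sampleId(genotype),
                ": no predictor support for allele(s) ",
                paste(unsupported, collapse = ", "), "; skipped",
                call. = FALSE)
    passing <- filterBinders(scored, thresholdNM)
    if (!nrow(passing))
        return(data.frame(sample = character(0), peptide = character(0),
                          allele = character(0), ic50_nM = numeric(0),
                          predictor_tag = character(0)))
    data.frame(sample = sampleId(genotype), peptide = passing$peptide,
               allele = passing$allele, ic50_nM = passing$ic50_nM,
               predictor_tag = passing$predictor_tag,
               stringsAsFactors = FALSE)
}
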