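#' Percentage in the reporting convention
#'
#' \eqn{100 \times numerator / denominator}, rounded half-up to
#' \code{decimals} places -- the convention behind every printed cohort
#' proportion in this package's reports.
#'
#' @param numerator,denominator counts; the denominator must be positive.
#' @param decimals decimal places (default 1).
#' @return list with \code{value} (numeric) and \code{label} (e.g.
#'   \code{"37.4\% (441/1180)"}).
#' @examples
#' formatPercent(441, 1180)$value  # 37.4
#' @export
formatPercent <- function(numerator, denominator, decimals = 1) {
    if (denominator <= 0)
        stop("denominator must be positive", call. = FALSE)
    value <- roundHalfUp(100 * numerator / denominator, decimals)
    list(value = value,
         label = sprintf("%.*f%% (%s/%s)", decimals, value,
                         format(numerator, scientific = FALSE),
                         format(denominator, scientific = FALSE)))
}

#' Per-sample neoepitope summary
#'
#' Counts for one sample: missense mutations, mutations with at least
#' one passing candidate, distinct candidate (peptide, allele) pairs
#' (duplicates arising from multiple transcripts collapse per
#' sample/peptide/allele), and expressed candidates.  Samples without
#' RNA-seq report unknown (NA) expression counts, never zero.
#'
#' @param candidateDf candidate rows (see \linkS4class{CandidateSet});
#'   all rows must belong to one sample.
#' @param variants the sample's missense variant rows.
#' @param sample sample identifier (inferred when inputs are non-empty).
#' @param subtype disease subtype label.
#' @param rnaAvailable does the sample have RNA-seq?
#' @param relapse is this a relapse sample?
#' @return one-row data.frame with columns \code{sample},
#'   \code{subtype}, \code{relapse}, \code{rna_available},
#'   \code{n_missense}, \code{n_neoepitope_mutations},
#'   \code{n_candidates}, \code{n_expressed_candidates}.
#' @export
summarizeSample <- function(candidateDf, variants, sample = NULL,
                            subtype = "", rnaAvailable = TRUE,
                            relapse = FALSE) {
    seen <- unique(c(candidateDf$sample, variants$sample))
    if (length(seen) > 1L)
        stop("summarizeSample received rows from multiple samples: ",
             paste(seen, collapse = ", "), call. = FALSE)
    if (is.null(sample)) sample <- if (length(seen)) seen else NA_character_
    vk <- if (nrow(variants)) variantKey(variants) else character(0)
    mis <- candidateDf[candidateDf$source == "missense", , drop = FALSE]
    dedup <- unique(candidateDf[, c("peptide", "allele")])
    dedupExpr <- candidateDf[!duplicated(candidateDf[, c("peptide",
                                                         "allele")]), ,
                             drop = FALSE]
    nExpr <- if (!rnaAvailable) NA_integer_
             else sum(dedupExpr$expressed %in% TRUE)
    data.frame(sample = sample, subtype = subtype, relapse = relapse,
               rna_available = rnaAvailable,
               n_missense = nrow(variants),
               n_neoepitope_mutations =
                   length(intersect(vk, unique(mis$source_key))),
               n_candidates = nrow(dedup),
               n_expressed_candidates = nExpr,
               stringsAsFactors = FALSE)
}

#' Cohort landscape summary
#'
#' Aggregates per-sample summaries into the cohort reporting layout:
#' per-subtype averages of mutation, neoepitope-candidate and expressed
#' counts (half-up, two decimals), computed over primary samples with
#' the relapse-included value carried in companion columns (the
#' parenthetical convention), plus overall cohort proportions.
#'
#' @param summaries data.frame of rows from
#'   \code{\link{summarizeSample}}.
#' @return list with \code{perSubtype} (data.frame of averages),
#'   \code{overall} (list: \code{pct_mutations_with_neoepitope},
#'   \code{pct_samples_with_neoepitope}, and when any sample has RNA,
#'   \code{pct_samples_with_expressed_neoepitope}).
#' @export
summarizeCohort <- function(summaries) {
    if (!nrow(summaries)) stop("empty cohort", call. = FALSE)
    avg <- function(x) if (all(is.na(x))) NA_real_
                       else roundHalfUp(mean(x, na.rm = TRUE), 2)
    perSubtype <- do.call(rbind, lapply(split(summaries,
                                              summaries$subtype),
        function(d) {
            p <- d[!d$relapse, , drop = FALSE]   # primary samples
            data.frame(subtype = d$subtype[1],
                       n_samples = nrow(p), n_relapse = sum(d$relapse),
                       avg_mutations = avg(p$n_missense),
                       avg_mutations_incl_relapse = avg(d$n_missense),
                       avg_neoepitope_mutations =
                           avg(p$n_neoepitope_mutations),
                       avg_candidates = avg(p$n_candidates),
                       avg_candidates_incl_relapse = avg(d$n_candidates),
                       avg_expressed = avg(p$n_expressed_candidates),
                       avg_expressed_incl_relapse =
                           avg(d$n_expressed_candidates),
                       stringsAsFactors = FALSE)
        }))
    rownames(perSubtype) <- NULL
    prim <- summaries[!summaries$relapse, , drop = FALSE]
    overall <- list(
        pct_mutations_with_neoepitope =
            formatPercent(sum(prim$n_neoepitope_mutations),
                          sum(prim$n_missense))$value,
        pct_samples_with_neoepitope =
            formatPercent(sum(prim$n_candidates > 0), nrow(prim))$value)
    rna <- prim[prim$rna_available, , drop = FALSE]
    if (nrow(rna))
        overall$pct_samples_with_expressed_neoepitope <-
            formatPercent(sum(rna$n_expressed_candidates > 0,
                              na.rm = TRUE), nrow(rna))$value
    list(perSubtype = perSubtype, overall = overall)
}

#' Mutation-burden vs neoepitope-count regression
#'
#' Ordinary least squares of per-sample candidate count on mutation
#' count, the relationship summarized cohort-wide by its R squared.
#'
#' @param mutations,epitopes numeric vectors (same length, >= 3 finite
#'   pairs), e.g. \code{n_missense} and \code{n_candidates} columns of a
#'   summary table.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_value}.
#' @export
mutationEpitopeRegression <- function(mutations, epitopes) {
    ok <- is.finite(mutations) & is.finite(epitopes)
    if (sum(ok) < 3L)
        stop("need at least three samples with finite counts",
             call. = FALSE)
    x <- mutations[ok]; y <- epitopes[ok]
    if (stats::var(x) == 0)
        stop("mutation counts have zero variance; regression undefined",
             call. = FALSE)
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    ## constant response: no variance to explain, define R^2 = 0
    r2 <- if (stats::var(y) == 0) 0 else sm$r.squared
    pval <- if (stats::var(y) == 0) NA_real_
            else sm$coefficients["x", "Pr(>|t|)"]
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, p_value = pval)
}

#' Recurrent-lesion epitope table
#'
#' For each recurrent lesion (a normalized protein change such as
#' \code{"KRAS:G13D"}, or a fusion partner pair such as
#' \code{"ETV6-RUNX1"}), the number of cohort samples carrying it and
#' the number in which it is predicted to encode at least one
#' neoepitope.  A sample contributing the same lesion through several
#' transcripts counts once.
#'
#' @param carriers data.frame with columns \code{lesion}, \code{sample}:
#'   one row per (lesion, carrier sample), duplicates tolerated.
#' @param positives data.frame with columns \code{lesion},
#'   \code{sample}: samples where the lesion has at least one passing
#'   candidate.
#' @return data.frame with columns \code{lesion},
#'   \code{n_samples_total}, \code{n_samples_with_epitope}, \code{pct}
#'   (half-up, whole percent).
#' @export
recurrenceTable <- function(carriers, positives) {
    carriers <- unique(carriers[, c("lesion", "sample")])
    positives <- unique(positives[, c("lesion", "sample")])
    out <- do.call(rbind, lapply(split(carriers, carriers$lesion),
        function(d) {
            lesion <- d$lesion[1]
            nTot <- nrow(d)
            nPos <- sum(positives$lesion == lesion &
                        positives$sample %in% d$sample)
            data.frame(lesion = lesion, n_samples_total = nTot,
                       n_samples_with_epitope = nPos,
                       pct = formatPercent(nPos, nTot, 0)$value,
                       stringsAsFactors = FALSE)
        }))
    rownames(out) <- NULL
    out
}
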