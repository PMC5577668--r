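#' Pipeline run configuration
#'
#' Collects input paths and parameters for \code{\link{runPipeline}}.
#' The defaults are the workflow's standard operating point: nonamer
#' windows (\code{k = 9}, hence a 27-base expression span), an inclusive
#' 500 nM IC50 cutoff, strict mutant-read spanning, base quality >= 20
#' and mapping quality >= 1.
#'
#' @param proteins protein FASTA (see \code{\link{readProteinFasta}}).
#' @param variants missense variant table
#'   (\code{\link{readVariantMatrix}}).
#' @param hla HLA genotype table (\code{\link{readHlaCalls}}).
#' @param transcripts transcript model table
#'   (\code{\link{readTranscriptModels}}); required for expression.
#' @param cds CDS FASTA; required when \code{fusions} is given.
#' @param fusions optional fusion event table
#'   (\code{\link{readFusionTable}}).
#' @param matrices optional binding-matrix table
#'   (\code{\link{readScoringMatrices}}).
#' @param predictorTable optional external predictor output
#'   (\code{\link{parsePredictorTable}}); exactly one of
#'   \code{matrices} / \code{predictorTable} must be given.
#' @param sam optional RNA-seq alignments in SAM text
#'   (\code{\link{readSamSubset}}); absent means expression status is
#'   unknown for every candidate.
#' @param sampleInfo optional data.frame with columns \code{sample},
#'   \code{subtype}, \code{relapse}, \code{rna_available}.
#' @param outDir output directory.
#' @param k window length in residues (default 9).
#' @param thresholdNM inclusive IC50 cutoff in nM (default 500).
#' @param strictSpanning must the 27-base-spanning read itself carry the
#'   mutant allele (default TRUE)?
#' @param baseQualMin,mapqMin quality cutoffs (defaults 20, 1).
#' @return a validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(proteins, variants, hla, transcripts = NULL,
                      cds = NULL, fusions = NULL, matrices = NULL,
                      predictorTable = NULL, sam = NULL,
                      sampleInfo = NULL, outDir = tempfile("neoscape_run"),
                      k = 9, thresholdNM = 500, strictSpanning = TRUE,
                      baseQualMin = 20, mapqMin = 1) {
    cfg <- list(proteins = proteins, variants = variants, hla = hla,
                transcripts = transcripts, cds = cds, fusions = fusions,
                matrices = matrices, predictorTable = predictorTable,
                sam = sam, sampleInfo = sampleInfo, outDir = outDir,
                k = as.integer(k), thresholdNM = thresholdNM,
                strictSpanning = isTRUE(strictSpanning),
                baseQualMin = baseQualMin, mapqMin = mapqMin)
    class(cfg) <- "RunConfig"
    for (stage in c("proteins", "variants", "hla")) {
        if (is.null(cfg[[stage]]) || !file.exists(cfg[[stage]]))
            stop("required input for stage '", stage, "' missing: ",
                 cfg[[stage]], call. = FALSE)
    }
    if (is.null(matrices) == is.null(predictorTable))
        stop("exactly one scoring backend required: 'matrices' or ",
             "'predictorTable'", call. = FALSE)
    if (!is.null(fusions) && is.null(cds))
        stop("stage 'fusion windows' needs the 'cds' FASTA", call. = FALSE)
    if (!is.null(sam) && is.null(transcripts))
        stop("stage 'expression' needs 'transcripts'", call. = FALSE)
    if (cfg$thresholdNM <= 0 || cfg$k < 1)
        stop("invalid parameters: thresholdNM must be positive, k >= 1",
             call. = FALSE)
    cfg
}

## deterministic candidate ordering for byte-identical re-runs
.orderCandidates <- function(df) {
    df[order(df$sample, df$source, df$source_key, df$window_offset,
             df$allele), , drop = FALSE]
}

#' Run the neoepitope discovery pipeline end to end
#'
#' Stages, in order: mutant window extraction around each missense
#' variant; junction window extraction for each in-frame fusion; binding
#' prediction of every window against the sample's HLA alleles with the
#' IC50 filter; expression evidence from RNA-seq (when provided);
#' per-sample and cohort landscape summaries.  Outputs are pure
#' functions of inputs and configuration -- re-running the same
#' configuration reproduces byte-identical files.
#'
#' @param config a \code{"RunConfig"} from \code{\link{runConfig}}.
#' @return invisibly, a list with \code{candidates}
#'   (\linkS4class{CandidateSet}), \code{summaries} (per-sample
#'   data.frame), \code{cohort} (from \code{\link{summarizeCohort}}),
#'   \code{skipped} (named counts of skipped records) and \code{paths}
#'   of the written TSVs (\code{candidates.tsv},
#'   \code{sample_summary.tsv}, \code{run.log}).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    log <- character(0)
    say <- function(...) log <<- c(log, paste0(...))
    say("neoscape pipeline run")
    say("parameters: k=", config$k, " thresholdNM=", config$thresholdNM,
        " strictSpanning=", config$strictSpanning,
        " baseQualMin=", config$baseQualMin, " mapqMin=", config$mapqMin)

    proteome <- readProteinFasta(config$proteins)
    variants <- readVariantMatrix(config$variants)
    genotypes <- readHlaCalls(config$hla)
    say("inputs: ", nrow(variants), " missense variant(s) (",
        attr(variants, "skipped"), " skipped), ",
        length(genotypes), " genotype(s)")
    transcripts <- if (!is.null(config$transcripts))
        readTranscriptModels(config$transcripts) else NULL
    cds <- if (!is.null(config$cds))
        Biostrings::readDNAStringSet(config$cds) else NULL
    fusions <- if (!is.null(config$fusions))
        readFusionTable(config$fusions) else NULL
    backend <- if (!is.null(config$matrices))
        readScoringMatrices(config$matrices)
        else parsePredictorTable(config$predictorTable)
    reads <- if (!is.null(config$sam)) readSamSubset(config$sam) else NULL

    ## --- stage: missense windows -------------------------------------
    mrna <- S4Vectors::mcols(proteome)$mrna_accession
    winRows <- list()
    for (i in seq_len(nrow(variants))) {
        v <- variants[i, ]
        hit <- which(names(proteome) == v$mrna_accession |
                     mrna == v$mrna_accession)
        if (!length(hit)) {
            say("variant ", variantKey(v),
                ": no protein for accession ", v$mrna_accession,
                "; skipped")
            next
        }
        ws <- missenseCandidates(as.character(proteome[[hit[1]]]), v,
                                 k = config$k)
        w <- peptideWindows(ws)
        if (nrow(w))
            winRows[[length(winRows) + 1L]] <- data.frame(
                sample = v$sample, peptide = w$mut, wt_peptide = w$wt,
                source = "missense", source_key = variantKey(v),
                window_offset = w$offset, aa_start = w$aa_start,
                scorable = w$scorable, stringsAsFactors = FALSE)
    }
    ## --- stage: fusion junction windows ------------------------------
    nOutOfFrame <- 0L
    for (i in seq_len(NROW(fusions))) {
        ev <- fusions[i, ]
        fc <- fusionCandidates(ev, cds[[ev$tx5]], cds[[ev$tx3]],
                               k = config$k)
        if (!nrow(fc)) {
            nOutOfFrame <- nOutOfFrame + 1L
            say("fusion ", fusionKey(ev), ": ",
                attr(fc, "reason") %||% "no windows")
        } else winRows[[length(winRows) + 1L]] <- fc
    }
    windows <- if (length(winRows)) do.call(rbind, winRows) else
        .emptyCandidates()[, c("sample", "peptide", "wt_peptide",
                               "source", "source_key", "window_offset",
                               "aa_start")]

    ## --- stage: binding prediction + IC50 filter ---------------------
    candRows <- list()
    for (s in unique(windows$sample)) {
        gt <- genotypes[[s]]
        if (is.null(gt)) {
            say("sample ", s, ": no HLA genotype; windows not scored")
            next
        }
        sw <- windows[windows$sample == s & windows$scorable, ,
                      drop = FALSE]
        nonsc <- sum(windows$sample == s & !windows$scorable)
        if (nonsc) say("sample ", s, ": ", nonsc,
                       " non-scorable window(s) excluded")
        scored <- scoreCandidates(sw$peptide, gt, backend,
                                  thresholdNM = config$thresholdNM)
        if (!nrow(scored)) next
        merged <- merge(sw, scored[, c("sample", "peptide", "allele",
                                       "ic50_nM")],
                        by = c("sample", "peptide"))
        candRows[[length(candRows) + 1L]] <- merged
    }
    cand <- if (length(candRows)) do.call(rbind, candRows) else NULL

    ## --- stage: expression evidence ----------------------------------
    rnaSamples <- character(0)
    if (!is.null(reads)) {
        rnaSamples <- unique(c(variants$sample, fusions$sample))
        if (!is.null(config$sampleInfo) &&
            "rna_available" %in% names(config$sampleInfo))
            rnaSamples <- config$sampleInfo$sample[
                config$sampleInfo$rna_available]
    }
    if (!is.null(cand)) {
        contigOf <- character(0)
        if (NROW(fusions)) {
            fk <- fusionKey(fusions)
            contigOf <- stats::setNames(paste0("ctg|", fk), fk)
        }
        cand <- attachExpression(cand, variants, transcripts, reads,
                                 contigOf = contigOf,
                                 rnaSamples = rnaSamples,
                                 k = config$k,
                                 strict = config$strictSpanning,
                                 baseQualMin = config$baseQualMin,
                                 mapqMin = config$mapqMin)
        cand <- .orderCandidates(cand)
        candidateSet <- CandidateSet(cand)
    } else {
        candidateSet <- CandidateSet()
    }

    ## --- stage: landscape report -------------------------------------
    allSamples <- unique(c(variants$sample, fusions$sample,
                           names(genotypes)))
    info <- config$sampleInfo
    summaries <- do.call(rbind, lapply(sort(allSamples), function(s) {
        subtype <- ""; relapse <- FALSE
        if (!is.null(info) && s %in% info$sample) {
            r <- info[info$sample == s, ]
            subtype <- r$subtype %||% ""
            relapse <- isTRUE(r$relapse)
        }
        summarizeSample(
            candidates(candidateSet)[candidates(candidateSet)$sample == s,
                                     , drop = FALSE],
            variants[variants$sample == s, , drop = FALSE],
            sample = s, subtype = subtype,
            rnaAvailable = s %in% rnaSamples, relapse = relapse)
    }))
    cohort <- summarizeCohort(summaries)
    say("candidates: ", length(candidateSet), " passing pair(s); ",
        nOutOfFrame, " fusion(s) yielded no windows")

    ## --- outputs ------------------------------------------------------
    header <- "# neoscape\tschema=1"
    paths <- list(candidates = file.path(config$outDir, "candidates.tsv"),
                  summary = file.path(config$outDir, "sample_summary.tsv"),
                  log = file.path(config$outDir, "run.log"))
    writeTsv <- function(df, path) {
        con <- file(path, "w")
        writeLines(header, con)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
    }
    writeTsv(candidates(candidateSet), paths$candidates)
    writeTsv(summaries, paths$summary)
    writeLines(log, paths$log)
    invisible(list(candidates = candidateSet, summaries = summaries,
                   cohort = cohort,
                   skipped = c(non_missense = attr(variants, "skipped"),
                               fusions_without_windows = nOutOfFrame),
                   paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
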