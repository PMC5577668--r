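## Deterministic synthetic test world: toy reference, variants, fusions,
## reads, genotypes and binding matrices with planted ground truth.  All
## generators are pure functions of (seed, parameters).

## one fixed codon per residue (common human codons) for reverse translation
.REV_CODON <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
                G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
                M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "CGC",
                S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")

.reverseTranslate <- function(peptide) {
    paste(.REV_CODON[strsplit(peptide, "")[[1]]], collapse = "")
}

#' Canonical worked-example context fragments
#'
#' N-terminal 40-residue fragments of KRAS and of histone H3.1 / H3.3
#' (mature histone numbering, initiator methionine removed), embedded so
#' the hotspot worked examples -- KRAS G13D and histone H3 K27M -- need
#' no database fetch.  H3.1 and H3.3 differ at residue 31 (A vs S) within
#' this fragment.
#'
#' @return named character vector with elements \code{KRAS},
#'   \code{H3.1}, \code{H3.3}.
#' @examples
#' substr(referenceContexts()["KRAS"], 13, 13)  # "G", the G13 hotspot
#' @export
referenceContexts <- function() {
    c(KRAS = "MTEYKLVVVGAGGVGKSALTIQLIQNHFVDEYDPTIEDSY",
      H3.1 = "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHR",
      H3.3 = "ARTKQTARKSTGGKAPRKQLATKAARKSAPSTGGVKKPHR")
}

## genomic positions of the CDS in transcript order (shared with the
## expression module's window mapping)
.cdsGenomicPositions <- function(tx) {
    st <- IRanges::start(tx@exons); en <- IRanges::end(tx@exons)
    pos <- unlist(lapply(seq_along(st), function(i) {
        a <- max(st[i], tx@cdsStart); b <- min(en[i], tx@cdsEnd)
        if (a > b) integer(0) else a:b
    }))
    if (tx@strand == "-") rev(pos) else pos
}

.randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

.revcomp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## build a contig holding one transcript's CDS split over nExons exons
.placeTranscript <- function(txId, gene, cds, nExons, strand,
                             pad = 50L, intron = 30L) {
    chunkLen <- rep(nchar(cds) %/% nExons, nExons)
    chunkLen[nExons] <- chunkLen[nExons] + nchar(cds) %% nExons
    ends <- cumsum(chunkLen)
    chunks <- substring(cds, ends - chunkLen + 1L, ends)   # transcript order
    genomicChunks <- if (strand == "+") chunks
                     else rev(vapply(chunks, .revcomp, character(1)))
    seqParts <- character(0)
    exonStarts <- integer(0); exonEnds <- integer(0)
    cursor <- 0L
    seqParts <- .randomDna(pad); cursor <- pad
    for (i in seq_len(nExons)) {
        if (i > 1L) {
            seqParts <- c(seqParts, .randomDna(intron))
            cursor <- cursor + intron
        }
        exonStarts <- c(exonStarts, cursor + 1L)
        exonEnds <- c(exonEnds, cursor + nchar(genomicChunks[i]))
        seqParts <- c(seqParts, genomicChunks[i])
        cursor <- cursor + nchar(genomicChunks[i])
    }
    seqParts <- c(seqParts, .randomDna(pad))
    list(tm = TranscriptModel(txId, gene, paste0("chr_", txId), strand,
                              exonStarts, exonEnds),
         contig = paste(seqParts, collapse = ""))
}

#' Generate a toy reference proteome and transcript set
#'
#' Random genes (single- and multi-exon, both strands) plus the fixed
#' KRAS / H3.1 / H3.3 context fragments as named entries.  Coding
#' sequences carry a terminal stop codon and translate without internal
#' stops by construction.  Byte-identical for a given seed.
#'
#' @param seed integer seed.
#' @param nGenes number of random genes (default 4; generated as
#'   single-exon +, single-exon +, two-exon +, three-exon -).
#' @param aaLengths protein lengths of the random genes (recycled;
#'   default 40).
#' @return list with \code{proteome} (\link[Biostrings]{AAStringSet},
#'   named by transcript, with gene metadata), \code{cds}
#'   (\link[Biostrings]{DNAStringSet}, stop codon included),
#'   \code{transcripts} (named list of \linkS4class{TranscriptModel}),
#'   \code{genome} (\link[Biostrings]{DNAStringSet} of per-transcript
#'   contigs).
#' @export
makeReference <- function(seed, nGenes = 4, aaLengths = 40) {
    stopifnot(nGenes >= 1, all(aaLengths >= 9))
    set.seed(seed)
    aaLengths <- rep_len(aaLengths, nGenes)
    structure_of <- function(i)            # deterministic exon layout cycle
        list(c(1L, "+"), c(1L, "+"), c(2L, "+"), c(3L, "-"))[[
            (i - 1L) %% 4L + 1L]]
    genes <- paste0("GENE", seq_len(nGenes))
    peptides <- vapply(seq_len(nGenes), function(i)
        paste0("M", paste(sample(AA20, aaLengths[i] - 1L, replace = TRUE),
                          collapse = "")), character(1))
    ctx <- referenceContexts()
    genes <- c(genes, "KRAS", "HIST1H3B", "H3F3A")
    peptides <- c(peptides, unname(ctx))
    txIds <- paste0("TX_", genes)
    layouts <- c(lapply(seq_len(nGenes), structure_of),
                 list(c(1L, "+"), c(1L, "+"), c(1L, "+")))

    transcripts <- list(); contigs <- character(0)
    cds <- character(0)
    for (i in seq_along(genes)) {
        cdsSeq <- paste0(.reverseTranslate(peptides[i]), "TAA")
        pl <- .placeTranscript(txIds[i], genes[i], cdsSeq,
                               as.integer(layouts[[i]][1]),
                               layouts[[i]][2])
        transcripts[[txIds[i]]] <- pl$tm
        contigs[paste0("chr_", txIds[i])] <- pl$contig
        cds[txIds[i]] <- cdsSeq
    }
    proteome <- Biostrings::AAStringSet(peptides)
    names(proteome) <- txIds
    S4Vectors::mcols(proteome) <- S4Vectors::DataFrame(
        gene = genes, mrna_accession = txIds,
        protein_gi = as.character(seq_along(genes) + 1000L))
    list(proteome = proteome,
         cds = Biostrings::DNAStringSet(cds),
         transcripts = transcripts,
         genome = Biostrings::DNAStringSet(contigs))
}

## choose a single-base codon change producing a missense substitution
.pickMissenseEdit <- function(codon) {
    oldAa <- Biostrings::GENETIC_CODE[codon]
    for (cpos in 1:3) {
        for (alt in c("A", "C", "G", "T")) {
            if (substr(codon, cpos, cpos) == alt) next
            newCodon <- codon
            substr(newCodon, cpos, cpos) <- alt
            newAa <- Biostrings::GENETIC_CODE[newCodon]
            if (newAa != oldAa && newAa != "*")
                return(list(cpos = cpos, alt = alt, aaMut = unname(newAa)))
        }
    }
    stop("no missense edit available for codon ", codon)   # cannot happen
}

#' Generate a missense test case with planted truth
#'
#' Plants a single-nucleotide missense variant on a (plus-strand,
#' single-exon) transcript of the reference, generates tumor RNA-seq
#' reads, and records the expected tiling windows and per-window
#' expression flags.  \code{position = "interior"} places the mutation
#' at least 8 residues from both termini (nine expected windows);
#' \code{"edge"} places it at residue 1 (one window).  With
#' \code{expressed = "expressed"} one mutant read spans the full peptide
#' context, so every window has a 27-base-spanning mutant read; with
#' \code{"silent"} mutant reads cover the variant but are 20 bases long,
#' too short to span any window.
#'
#' @param seed integer seed.
#' @param ref reference from \code{\link{makeReference}}.
#' @param txId transcript to mutate (default \code{"TX_GENE1"}).
#' @param position \code{"interior"} or \code{"edge"}.
#' @param expressed \code{"expressed"} or \code{"silent"}.
#' @param sample sample identifier.
#' @return list with \code{variant} (one-row data.frame), \code{reads}
#'   (SAM alignment lines), \code{mutPeptide}, and \code{truth}
#'   (expected window count, window peptides, per-window expression).
#' @export
makeMissenseCase <- function(seed, ref, txId = "TX_GENE1",
                             position = c("interior", "edge"),
                             expressed = c("expressed", "silent"),
                             sample = "S1") {
    position <- match.arg(position); expressed <- match.arg(expressed)
    set.seed(seed)
    tx <- ref$transcripts[[txId]]
    stopifnot(tx@strand == "+", length(tx@exons) == 1L)
    pep <- as.character(ref$proteome[[txId]])
    L <- nchar(pep)
    aaPos <- if (position == "interior") base::sample(9:(L - 8), 1) else 1L
    cdsSeq <- as.character(ref$cds[[txId]])
    codon <- substr(cdsSeq, 3L * (aaPos - 1L) + 1L, 3L * aaPos)
    edit <- .pickMissenseEdit(codon)
    cdsIdx <- 3L * (aaPos - 1L) + edit$cpos
    gmap <- .cdsGenomicPositions(tx)
    gpos <- gmap[cdsIdx]
    chrom <- tx@chrom
    contig <- as.character(ref$genome[[chrom]])
    aaRef <- substr(pep, aaPos, aaPos)
    mutPep <- pep
    substr(mutPep, aaPos, aaPos) <- edit$aaMut

    ## expected windows by explicit enumeration (independent of the
    ## window-count formula)
    wins <- character(0)
    for (s in seq_len(max(L - 8L, 0L)))
        if (s <= aaPos && aaPos <= s + 8L)
            wins <- c(wins, substr(mutPep, s, s + 8L))

    ## reads
    ctxG <- range(gmap[(3L * (max(1L, aaPos - 8L) - 1L) + 1L):
                       (3L * min(L, aaPos + 8L))])
    mkRead <- function(id, start, end, mutant) {
        s <- substr(contig, start, end)
        if (mutant) substr(s, gpos - start + 1L, gpos - start + 1L) <- edit$alt
        .samLine(id, 0L, chrom, start, 60L,
                 paste0(end - start + 1L, "M"), s)
    }
    if (expressed == "expressed") {
        reads <- c(mkRead(paste0(sample, "_mut1"), ctxG[1] - 3L,
                          ctxG[2] + 3L, TRUE),
                   mkRead(paste0(sample, "_wt1"), ctxG[1] - 3L,
                          ctxG[2] + 3L, FALSE),
                   mkRead(paste0(sample, "_wt2"), ctxG[1], ctxG[2], FALSE))
        exprFlags <- rep(TRUE, length(wins))
        nMut <- 1L
    } else {
        reads <- c(mkRead(paste0(sample, "_mut1"), gpos - 10L, gpos + 9L,
                          TRUE),
                   mkRead(paste0(sample, "_mut2"), gpos - 9L, gpos + 10L,
                          TRUE),
                   mkRead(paste0(sample, "_wt1"), ctxG[1] - 3L,
                          ctxG[2] + 3L, FALSE))
        exprFlags <- rep(FALSE, length(wins))
        nMut <- 2L
    }
    variant <- data.frame(
        sample = sample, gene = tx@gene, chrom = chrom, pos = gpos,
        ref_allele = substr(codon, edit$cpos, edit$cpos),
        mut_allele = edit$alt, mutation_class = "missense",
        aa_change = paste0(aaRef, aaPos, edit$aaMut),
        mrna_accession = txId, protein_gi = "",
        mutant_reads_tumor = nMut, total_reads_tumor = length(reads),
        mutant_reads_normal = 0L, total_reads_normal = 30L,
        aa_ref = aaRef, aa_pos = aaPos, aa_mut = edit$aaMut,
        stringsAsFactors = FALSE)
    list(variant = variant, reads = reads, mutPeptide = mutPep,
         truth = list(n_windows = length(wins), windows = wins,
                      window_expressed = exprFlags))
}

#' Generate a fusion test case with planted truth
#'
#' Joins the coding sequences of two reference transcripts at a random
#' breakpoint, assembles the junction contig, tiles 30-base reads across
#' it, and records the expected junction windows (empty for out-of-frame
#' events) with per-window expression flags from a brute-force read
#' sweep.  Window truth is computed by side-labelling every residue's
#' codon, not by the window-range arithmetic under test.
#'
#' @param seed integer seed.
#' @param ref reference from \code{\link{makeReference}}.
#' @param inFrame generate an in-frame (TRUE) or frameshifting (FALSE)
#'   junction.
#' @param tx5,tx3 partner transcripts.
#' @param sample sample identifier.
#' @return list with \code{fusion} (one-row data.frame), \code{contig}
#'   (named junction contig sequence), \code{reads} (SAM lines),
#'   \code{truth} (window peptides, starts, expression flags).
#' @export
makeFusionCase <- function(seed, ref, inFrame = TRUE, tx5 = "TX_GENE1",
                           tx3 = "TX_GENE2", sample = "S1") {
    set.seed(seed)
    cds5 <- as.character(ref$cds[[tx5]])
    cds5 <- substr(cds5, 1L, nchar(cds5) - 3L)       # drop 5' stop
    cds3 <- as.character(ref$cds[[tx3]])
    phase <- base::sample(0:2, 1)
    n5 <- 3L * base::sample(6:10, 1) + phase
    n3off <- if (inFrame) phase else (phase + 1L) %% 3L + 3L
    stopifnot(isInFrame(n5, n3off) == inFrame)

    ev <- data.frame(sample = sample,
                     gene5 = ref$transcripts[[tx5]]@gene, tx5 = tx5,
                     bp5 = .cdsGenomicPositions(ref$transcripts[[tx5]])[n5],
                     gene3 = ref$transcripts[[tx3]]@gene, tx3 = tx3,
                     bp3 = .cdsGenomicPositions(
                         ref$transcripts[[tx3]])[n3off + 1L],
                     n5 = n5, n3off = n3off, junction_read_count = 0L,
                     stringsAsFactors = FALSE)
    key <- fusionKey(ev)
    contigName <- paste0("ctg|", key)
    contigSeq <- buildJunctionCds(cds5, n5, cds3, n3off)

    ## truth windows by residue side-labelling
    wins <- character(0); starts <- integer(0)
    if (inFrame) {
        pep <- translateCds(contigSeq)
        Lp <- nchar(pep)
        if (Lp >= 9L) {
            touches5 <- vapply(1:Lp, function(r) 3L * r - 2L <= n5,
                               logical(1))
            touches3 <- vapply(1:Lp, function(r) 3L * r > n5, logical(1))
            for (s in 1:(Lp - 8L)) {
                rr <- s:(s + 8L)
                if (any(touches5[rr]) && any(touches3[rr])) {
                    wins <- c(wins, substr(pep, s, s + 8L))
                    starts <- c(starts, s)
                }
            }
        }
    }

    ## tiled 30-base reads across the contig (stride 5, tail-anchored)
    rStarts <- unique(c(seq(1L, max(nchar(contigSeq) - 29L, 1L), by = 5L),
                        max(nchar(contigSeq) - 29L, 1L)))
    reads <- vapply(seq_along(rStarts), function(i) {
        st <- rStarts[i]
        en <- min(st + 29L, nchar(contigSeq))
        .samLine(paste0(sample, "_jr", i), 0L, contigName, st, 60L,
                 paste0(en - st + 1L, "M"), substr(contigSeq, st, en))
    }, character(1))
    exprFlags <- vapply(starts, function(s) {
        b1 <- 3L * (s - 1L) + 1L; b2 <- 3L * (s + 8L)
        any(rStarts <= b1 & rStarts + 29L >= b2)
    }, logical(1))
    ev$junction_read_count <- length(rStarts)
    list(fusion = ev, contig = stats::setNames(contigSeq, contigName),
         reads = reads,
         truth = list(n_windows = length(wins), windows = wins,
                      starts = starts, window_expressed = exprFlags))
}

#' Construct binding matrices guaranteeing a planted binder set
#'
#' Builds one position-weight matrix per allele in the genotypes such
#' that exactly the planted (peptide, allele) pairs pass the 500 nM
#' filter among all candidate peptides: planted cells get weight 0.9
#' (IC50 = 50000^0.1, about 2.9 nM) over a zero baseline.  If any
#' non-planted pair from the peptide universe would also pass (peptides
#' sharing too many positional residues with a planted one), the plant
#' is infeasible and an error is raised.
#'
#' @param seed integer seed (reserved for future stochastic baselines;
#'   the construction is deterministic).
#' @param genotypes list of \linkS4class{HlaGenotype}.
#' @param planted data.frame with columns \code{peptide}, \code{allele}.
#' @param peptideUniverse all candidate peptides the matrices will ever
#'   score (used for the feasibility check).
#' @return named list of \linkS4class{ScoringMatrix} keyed by allele.
#' @export
makeBindingWorld <- function(seed, genotypes, planted,
                             peptideUniverse = planted$peptide) {
    alleles <- unique(unlist(lapply(genotypes, hlaAlleles)))
    planted$allele <- vapply(planted$allele, normalizeHlaAllele,
                             character(1), USE.NAMES = FALSE)
    matrices <- lapply(alleles, function(a) {
        w <- matrix(0, 9, 20, dimnames = list(NULL, AA20))
        for (p in planted$peptide[planted$allele == a])
            w[cbind(1:9, match(strsplit(p, "")[[1]], AA20))] <- 0.9
        ScoringMatrix(a, w)
    })
    names(matrices) <- alleles
    universe <- unique(c(peptideUniverse, planted$peptide))
    universe <- universe[!grepl("[^ACDEFGHIKLMNPQRSTVWY]", universe)]
    for (a in alleles) {
        sc <- matrixScore(universe, matrices[[a]])
        pass <- sc$peptide[!is.na(sc$ic50_nM) & sc$ic50_nM <= 500]
        want <- planted$peptide[planted$allele == a]
        if (!setequal(pass, want))
            stop("infeasible plant for ", a, ": unintended binder(s) ",
                 paste(setdiff(pass, want), collapse = ", "),
                 call. = FALSE)
    }
    matrices
}

#' Assemble a complete fixture bundle
#'
#' The end-to-end test world: two samples, one interior expressed
#' missense variant (S1), one interior silent missense variant (S2), an
#' in-frame fusion with tiled junction reads (S1), an out-of-frame
#' fusion (S2), six-allele genotypes (S2 homozygous at HLA-A), and
#' binding matrices planting one missense binder per sample plus one
#' junction binder for S1.  The \code{truth} slot carries the expected
#' windows, binder set, expression flags and per-sample summary counts,
#' all known by construction.
#'
#' @param seed integer seed (default 20170831).
#' @return a \linkS4class{FixtureBundle}.
#' @export
fixtureBundle <- function(seed = 20170831) {
    seed <- as.integer(seed)
    ref <- makeReference(seed)
    genotypes <- list(
        S1 = HlaGenotype("S1", c("A*02:01", "A*11:01", "B*07:02",
                                 "B*08:01", "C*04:01", "C*07:01")),
        S2 = HlaGenotype("S2", c("A*02:01", "A*02:01", "B*15:17",
                                 "B*40:01", "C*03:04", "C*12:03")))

    ## planted binders: the centre window of each missense variant and a
    ## mid-junction window of the in-frame fusion.  In the (rare) event
    ## that a random case makes the plant infeasible (a decoy window
    ## collides with a planted peptide), the cases are redrawn from the
    ## next derived seed -- still a pure function of `seed`.
    centre <- function(mc, txId) {
        ws <- missenseCandidates(as.character(ref$proteome[[txId]]),
                                 mc$variant)
        w <- peptideWindows(ws)
        w$mut[which.min(abs(w$aa_start - (mc$variant$aa_pos - 4L)))]
    }
    allWindows <- function(mc, txId)
        peptideWindows(missenseCandidates(
            as.character(ref$proteome[[txId]]), mc$variant))$mut
    matrices <- NULL
    for (attempt in 0:24) {
        off <- seed + 101L * attempt
        m1 <- makeMissenseCase(off + 1L, ref, "TX_GENE1", "interior",
                               "expressed", sample = "S1")
        m2 <- makeMissenseCase(off + 2L, ref, "TX_GENE2", "interior",
                               "silent", sample = "S2")
        f1 <- makeFusionCase(off + 3L, ref, inFrame = TRUE,
                             tx5 = "TX_GENE1", tx3 = "TX_GENE2",
                             sample = "S1")
        f2 <- makeFusionCase(off + 4L, ref, inFrame = FALSE,
                             tx5 = "TX_GENE2", tx3 = "TX_GENE1",
                             sample = "S2")
        p1 <- centre(m1, "TX_GENE1")
        p2 <- centre(m2, "TX_GENE2")
        jmid <- f1$truth$windows[ceiling(length(f1$truth$windows) / 2)]
        planted <- data.frame(
            peptide = c(p1, jmid, p2),
            allele = c("HLA-A*02:01", "HLA-B*07:02", "HLA-B*15:17"),
            sample = c("S1", "S1", "S2"), stringsAsFactors = FALSE)
        universe <- c(allWindows(m1, "TX_GENE1"),
                      allWindows(m2, "TX_GENE2"), f1$truth$windows)
        matrices <- tryCatch(
            makeBindingWorld(off + 5L, genotypes,
                             planted[, c("peptide", "allele")], universe),
            error = function(e) NULL)
        if (!is.null(matrices)) break
    }
    if (is.null(matrices))
        stop("could not construct a feasible fixture bundle from seed ",
             seed, call. = FALSE)

    contigs <- c(f1$contig, f2$contig)
    genome <- c(ref$genome, Biostrings::DNAStringSet(contigs))
    samHeader <- c("@HD\tVN:1.6\tSO:unsorted",
                   paste0("@SQ\tSN:", names(genome), "\tLN:",
                          Biostrings::width(genome)))
    samText <- c(samHeader, m1$reads, m2$reads, f1$reads, f2$reads)

    variants <- rbind(m1$variant, m2$variant)
    fusions <- rbind(f1$fusion, f2$fusion)

    ## expected expression of the planted candidates
    jIdx <- match(jmid, f1$truth$windows)
    expectedExpr <- data.frame(
        sample = c("S1", "S1", "S2"),
        peptide = c(p1, jmid, p2),
        allele = c("HLA-A*02:01", "HLA-B*07:02", "HLA-B*15:17"),
        expressed = c(TRUE, f1$truth$window_expressed[jIdx], FALSE),
        stringsAsFactors = FALSE)

    truth <- list(
        windows = stats::setNames(
            list(m1$truth$windows, m2$truth$windows),
            variantKey(variants)),
        window_counts = stats::setNames(
            c(m1$truth$n_windows, m2$truth$n_windows),
            variantKey(variants)),
        junction_windows = stats::setNames(
            list(f1$truth$windows, f2$truth$windows), fusionKey(fusions)),
        binders = data.frame(planted,
                             ic50_nM = scoreToIC50(0.9),
                             stringsAsFactors = FALSE),
        expressed = expectedExpr,
        summaries = list(
            S1 = list(n_missense = 1L, n_neoepitope_mutations = 1L,
                      n_candidates = 2L,
                      n_expressed = sum(expectedExpr$expressed[
                          expectedExpr$sample == "S1"])),
            S2 = list(n_missense = 1L, n_neoepitope_mutations = 1L,
                      n_candidates = 1L, n_expressed = 0L)))

    new("FixtureBundle", seed = seed, proteome = ref$proteome,
        cds = ref$cds, genome = genome, transcripts = ref$transcripts,
        variants = variants, fusions = fusions, samText = samText,
        genotypes = genotypes, matrices = matrices, truth = truth)
}

#' Write a fixture bundle to a directory of standard-format files
#'
#' Emits everything \code{\link{runPipeline}} reads: protein / CDS /
#' genome FASTA, transcript models, variant and fusion tables, HLA
#' calls, binding matrices, SAM reads, plus the planted truth as JSON.
#'
#' @param bundle a \linkS4class{FixtureBundle}.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
writeFixtureBundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
        proteins = file.path(dir, "proteins.fasta"),
        cds = file.path(dir, "cds.fasta"),
        genome = file.path(dir, "genome.fasta"),
        transcripts = file.path(dir, "transcripts.tsv"),
        variants = file.path(dir, "variants.tsv"),
        fusions = file.path(dir, "fusions.tsv"),
        hla = file.path(dir, "hla.tsv"),
        matrices = file.path(dir, "matrices.tsv"),
        sam = file.path(dir, "reads.sam"),
        truth = file.path(dir, "truth.json"))
    writeProteinFasta(bundle@proteome, paths$proteins)
    Biostrings::writeXStringSet(bundle@cds, paths$cds)
    Biostrings::writeXStringSet(bundle@genome, paths$genome)
    writeTranscriptModels(bundle@transcripts, paths$transcripts)
    writeVariantMatrix(bundle@variants, paths$variants)
    writeFusionTable(bundle@fusions, paths$fusions)
    writeHlaCalls(bundle@genotypes, paths$hla)
    writeScoringMatrices(bundle@matrices, paths$matrices)
    writeLines(bundle@samText, paths$sam)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
        jsonlite::write_json(bundle@truth, paths$truth, auto_unbox = TRUE,
                             digits = NA)
    } else {
        paths$truth <- NULL
    }
    invisible(paths)
}
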