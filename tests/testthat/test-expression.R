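## a tiny hand-built world: one plus-strand single-exon transcript
plusTx <- TranscriptModel("TXP", "G1", "chr1", "+", 101, 160)

samRead <- function(id, pos, cigar, seq, flag = 0, mapq = 60,
                    qual = strrep("I", nchar(seq))) {
    data.frame(read_id = id, flag = flag, chrom = "chr1", pos = pos,
               mapq = mapq, cigar = cigar, seq = seq, qual = qual,
               blocks = I(list(cigarBlocks(cigar, pos))),
               stringsAsFactors = FALSE)
}

test_that("window coordinates honor exon structure and strand", {
    ## contiguous single-exon window: 27 consecutive bases
    p <- windowGenomicPositions(plusTx, 1)
    expect_equal(p, 101:127)
    expect_equal(length(p), 27L)

    ## exon-straddling window on a two-exon transcript
    tx2 <- TranscriptModel("TX2", "G2", "chr1", "+", c(101, 161),
                           c(130, 190))
    p2 <- windowGenomicPositions(tx2, 3)         # CDS nt 7..33
    expect_equal(length(p2), 27L)
    expect_equal(p2, c(107:130, 161:163))        # two runs summing to 27
    expect_error(windowGenomicPositions(tx2, 13), "extends past the CDS")

    ## minus strand: genomically descending, transcript-order ascending
    txm <- TranscriptModel("TXM", "G3", "chr1", "-", 201, 260)
    pm <- windowGenomicPositions(txm, 1)
    expect_equal(pm, 260:234)
    expect_true(all(diff(pm) == -1))
})

test_that("minus-strand window bases reverse-complement to the CDS", {
    ref <- makeReference(42)
    txm <- ref$transcripts[["TX_GENE4"]]          # three-exon, minus strand
    expect_equal(txm@strand, "-")
    contig <- as.character(ref$genome[[txm@chrom]])
    pos <- windowGenomicPositions(txm, 3, k = 9)
    cds <- as.character(ref$cds[["TX_GENE4"]])
    ## reverse-complement oracle: reading the genomic bases in ascending
    ## order and reverse-complementing recovers the transcript-order window
    ascBases <- paste(vapply(sort(pos), function(p) substr(contig, p, p),
                             character(1)), collapse = "")
    oracle <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ascBases)))
    expect_equal(oracle, substr(cds, 7, 33))
    ## equivalently: complementing each base in transcript (descending
    ## genomic) order gives the CDS window directly
    bases <- paste(vapply(pos, function(p) substr(contig, p, p),
                          character(1)), collapse = "")
    expect_equal(chartr("ACGT", "TGCA", bases), substr(cds, 7, 33))
})

test_that("mutant support requires the alt base at sufficient quality", {
    v <- list(chrom = "chr1", pos = 120L, mut_allele = "T")
    seqA <- paste0(strrep("A", 19), "T", strrep("A", 10))   # alt at 120
    r <- samRead("r1", 101, "30M", seqA)
    expect_true(readSupportsMutant(r, v))
    seqRef <- strrep("A", 30)
    expect_false(readSupportsMutant(samRead("r2", 101, "30M", seqRef), v))
    ## deletion spanning the site
    rd <- samRead("r3", 115, "4M3D23M", strrep("T", 27))
    expect_false(readSupportsMutant(rd, v))
    ## low base quality at the variant site
    qual <- paste0(strrep("I", 19), "#", strrep("I", 10))
    expect_false(readSupportsMutant(samRead("r4", 101, "30M", seqA,
                                            qual = qual), v))
})

test_that("window spanning needs every base; splices ok, deletions not", {
    pos27 <- 110:136
    expect_true(readSpansWindow(samRead("r1", 101, "50M",
                                        strrep("A", 50)), pos27))
    ## covers 26 of 27
    r26 <- samRead("r2", 111, "40M", strrep("A", 40))
    expect_false(readSpansWindow(r26, pos27))
    expect_true(bfSpans(r26$blocks[[1]], 111:136))
    ## spliced read covering an intron-straddling window
    posSplit <- c(107:130, 161:163)
    rs <- samRead("r3", 101, "30M30N20M", strrep("A", 50))
    expect_true(readSpansWindow(rs, posSplit))
    expect_equal(readSpansWindow(rs, posSplit),
                 bfSpans(rs$blocks[[1]], posSplit))
    ## deletion inside the window breaks spanning
    rdel <- samRead("r4", 101, "15M2D35M", strrep("A", 50))
    expect_false(readSpansWindow(rdel, 110:136))
})

test_that("CIGAR span checks agree with brute force on random reads", {
    set.seed(1234)
    for (i in 1:300) {
        nOps <- sample(1:4, 1)
        lens <- sample(5:40, nOps, replace = TRUE)
        gapT <- sample(c("", "D", "N"), nOps, replace = TRUE)
        gapL <- sample(2:50, nOps, replace = TRUE)
        cig <- ""
        for (j in 1:nOps) {
            cig <- paste0(cig, lens[j], "M")
            if (j < nOps && gapT[j] != "")
                cig <- paste0(cig, gapL[j], gapT[j])
        }
        start <- sample(1:500, 1)
        qlen <- sum(lens)
        r <- samRead(paste0("rr", i), start, cig, strrep("A", qlen))
        wStart <- sample(start + (-5:40), 1)
        positions <- wStart:(wStart + 26)
        expect_equal(readSpansWindow(r, positions),
                     bfSpans(r$blocks[[1]], positions))
    }
})

test_that("expression calls combine mutant support with 27-base spanning", {
    ## transcript protein positions 1..9 occupy bases 101..127
    v <- list(chrom = "chr1", pos = 113L, mut_allele = "G",
              sample = "S1")
    cand <- list(aa_start = 1L)
    mutSeq <- function(len, start) {
        s <- strrep("A", len)
        if (start <= 113 && 113 <= start + len - 1)
            substr(s, 113 - start + 1, 113 - start + 1) <- "G"
        s
    }
    spanning <- samRead("m1", 101, "30M", mutSeq(30, 101))
    short1 <- samRead("m2", 105, "18M", mutSeq(18, 105))
    short2 <- samRead("m3", 106, "18M", mutSeq(18, 106))
    wt <- samRead("w1", 101, "30M", strrep("A", 30))

    cl <- callExpression(cand, v, plusTx, rbind(spanning, wt))
    expect_equal(cl$mutant_read_count, 1L)
    expect_equal(cl$spanning_mutant_read_count, 1L)
    expect_true(cl$expressed)

    cl2 <- callExpression(cand, v, plusTx,
                          rbind(short1, short2,
                                samRead("m4", 107, "18M", mutSeq(18, 107)),
                                wt))
    expect_equal(cl2$mutant_read_count, 3L)
    expect_equal(cl2$spanning_mutant_read_count, 0L)
    expect_false(cl2$expressed)

    cl0 <- callExpression(cand, v, plusTx, rbind(spanning, wt)[0, ])
    expect_equal(cl0$mutant_read_count, 0L)
    expect_false(cl0$expressed)

    ## no RNA at all: unknown, not FALSE
    clNA <- callExpression(cand, v, plusTx, NULL)
    expect_true(is.na(clNA$expressed))

    ## strict rule: a wild-type read spanning does not rescue; relaxed does
    clStrict <- callExpression(cand, v, plusTx, rbind(short1, wt))
    expect_false(clStrict$expressed)
    clRelax <- callExpression(cand, v, plusTx, rbind(short1, wt),
                              strict = FALSE)
    expect_true(clRelax$expressed)

    ## duplicate-marked and secondary alignments never count
    dup <- spanning; dup$flag <- 1024L
    sec <- spanning; sec$flag <- 256L
    clDup <- callExpression(cand, v, plusTx, rbind(dup, sec))
    expect_equal(clDup$mutant_read_count, 0L)
})

test_that("junction window expression matches a brute-force read sweep", {
    fc <- makeFusionCase(7, makeReference(7), inFrame = TRUE,
                         sample = "SX")
    contig <- names(fc$contig)
    reads <- readSamSubset(tmpWrite(c("@HD\tVN:1.6", fc$reads), ".sam"))
    for (j in seq_along(fc$truth$starts)) {
        cl <- fusionWindowExpression(list(aa_start = fc$truth$starts[j]),
                                     contig, reads)
        expect_equal(cl$expressed, fc$truth$window_expressed[j])
        expect_lte(cl$spanning_mutant_read_count, cl$mutant_read_count)
    }
    ## reads covering only the 5' side never span
    r5 <- readSamSubset(tmpWrite(c("@HD\tVN:1.6",
        paste("five", 0, contig, 1, 60, "12M", "*", 0, 0,
              substr(unname(fc$contig), 1, 12), strrep("I", 12),
              sep = "\t")), ".sam"))
    cl5 <- fusionWindowExpression(list(aa_start = fc$truth$starts[1]),
                                  contig, r5)
    expect_false(cl5$expressed)
})

test_that("expression is monotone in the read set", {
    set.seed(88)
    v <- list(chrom = "chr1", pos = 113L, mut_allele = "G", sample = "S")
    cand <- list(aa_start = 1L)
    mkR <- function(i) {
        start <- sample(90:125, 1); len <- sample(15:40, 1)
        s <- strrep("A", len)
        if (start <= 113 && 113 <= start + len - 1 && runif(1) < 0.7)
            substr(s, 113 - start + 1, 113 - start + 1) <- "G"
        samRead(paste0("x", i), start, paste0(len, "M"), s)
    }
    for (rep in 1:20) {
        pool <- do.call(rbind, lapply(1:6, mkR))
        full <- callExpression(cand, v, plusTx, pool)$expressed
        sub <- callExpression(cand, v, plusTx,
                              pool[sample(6, 3), ])$expressed
        if (sub) expect_true(full)               # adding reads never unsets
    }
})
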