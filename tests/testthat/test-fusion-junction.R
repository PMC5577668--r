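test_that("frame arithmetic follows the codon-register rule", {
    expect_true(isInFrame(9, 0))
    expect_false(isInFrame(10, 0))
    expect_true(isInFrame(10, 1))
    expect_false(isInFrame(0, 1))
    expect_true(isInFrame(0, 0))
})

test_that("in-frame junctions preserve the 3' partner's native register", {
    ## n5 = 10, n3off = 1: chimeric codon, then native 3' codons
    pep3 <- "HQWKDEN"
    cds3 <- paste0(vapply(strsplit(pep3, "")[[1]], function(a)
        c(H = "CAC", Q = "CAG", W = "TGG", K = "AAG", D = "GAC",
          E = "GAG", N = "AAC")[a], character(1)), collapse = "")
    cds5 <- "ATGGCCGCCGT"                         # 11 nt; take n5 = 10
    jcds <- buildJunctionCds(cds5, 10, cds3, 1)
    pep <- translateCds(jcds)
    ## after the chimeric 4th codon, translation is pure 3' native frame
    expect_equal(substr(pep, 5, nchar(pep)), substr(pep3, 2, 7))
})

test_that("junction CDS assembly is plain prefix+suffix with length arithmetic", {
    expect_equal(buildJunctionCds("ATGGAA", 6, "GATTAA", 0), "ATGGAAGATTAA")
    expect_equal(buildJunctionCds("ATGGAA", 0, "GATTAA", 2), "TTAA")
    expect_error(buildJunctionCds("ATG", 4, "GAT", 0), "exceeds")
    set.seed(11)
    for (i in 1:100) {
        l5 <- sample(0:30, 1); l3 <- sample(0:30, 1)
        c5 <- paste(sample(c("A", "C", "G", "T"), l5, TRUE), collapse = "")
        c3 <- paste(sample(c("A", "C", "G", "T"), l3, TRUE), collapse = "")
        n5 <- sample(0:l5, 1); n3 <- sample(0:l3, 1)
        expect_equal(nchar(buildJunctionCds(c5, n5, c3, n3)),
                     n5 + l3 - n3)
    }
})

test_that("translation truncates at stop, drops partial codons, N gives X", {
    expect_equal(translateCds("ATGAAATAGGGG"), "MK")
    expect_equal(translateCds("ATGGA"), "M")
    expect_equal(translateCds("ATGANAAAA"), "MXK")
    expect_equal(translateCds(""), "")
    expect_error(translateCds("ATGRAA"), "outside ACGTN")
    ## random codon strings against the Biostrings translation oracle
    set.seed(5)
    for (i in 1:50) {
        n <- sample(1:30, 1)
        cds <- paste(sample(c("A", "C", "G", "T"), 3 * n, TRUE),
                     collapse = "")
        oracle <- as.character(Biostrings::translate(
            Biostrings::DNAString(cds), no.init.codon = TRUE))
        oracle <- sub("\\*.*$", "", oracle)       # stop-truncation contract
        expect_equal(translateCds(cds), oracle)
    }
})

test_that("junction windows are exactly the k-mers touching both sides", {
    ## 20-aa peptide, break between residues 10 and 11 (n5 = 30)
    pep <- randomPeptide(20)
    cds <- paste(vapply(strsplit(pep, "")[[1]], function(a)
        neoscape:::.REV_CODON[a], character(1)), collapse = "")
    jp <- junctionPeptide("F", substr(cds, 1, 30), 30,
                          paste0(substr(cds, 31, 60), "TAA"), 0)
    w <- junctionWindows(jp)
    expect_equal(w$start, 3:10)                  # 8 windows
    expect_identical(w$peptide, bfJunctionWindows(pep, 30))
})

test_that("junction window set-algebra matches brute force on random events", {
    set.seed(99)
    for (i in 1:200) {
        aa5 <- sample(2:14, 1); aa3 <- sample(2:14, 1)
        p5 <- randomPeptide(aa5); p3 <- randomPeptide(aa3)
        mk <- function(p) paste(vapply(strsplit(p, "")[[1]], function(a)
            neoscape:::.REV_CODON[a], character(1)), collapse = "")
        phase <- sample(0:2, 1)
        n5 <- 3 * sample(1:aa5, 1) - phase       # may split a codon
        n3off <- if (runif(1) < 0.5) (n5 %% 3) else (n5 + 1) %% 3
        jp <- junctionPeptide("F", mk(p5), n5, paste0(mk(p3), "TAA"),
                              n3off)
        w <- junctionWindows(jp)
        if (!isInFrame(n5, n3off)) {
            expect_equal(nrow(w), 0L)
        } else {
            expect_identical(w$peptide,
                             bfJunctionWindows(jp@peptide, n5))
            expect_false(any(grepl("\\*", w$peptide)))
        }
    }
})

test_that("fusion candidates are junction-novel and respect degeneracies", {
    b <- fixtureBundle(101)
    ev <- b@fusions[1, ]                          # the in-frame event
    cds5 <- as.character(b@cds[[ev$tx5]])
    cds5 <- substr(cds5, 1, nchar(cds5) - 3)
    cds3 <- as.character(b@cds[[ev$tx3]])
    fc <- fusionCandidates(ev, cds5, cds3)
    expect_gt(nrow(fc), 0L)
    ## no junction nonamer is a contiguous 9-mer of either parent protein
    pep5 <- translateCds(paste0(cds5, "TAA"))
    pep3 <- translateCds(cds3)
    expect_false(any(vapply(fc$peptide, function(p)
        grepl(p, pep5, fixed = TRUE) || grepl(p, pep3, fixed = TRUE),
        logical(1))))

    ## frameshifting event: zero candidates
    ev2 <- b@fusions[2, ]
    c5b <- as.character(b@cds[[ev2$tx5]])
    fc2 <- fusionCandidates(ev2, substr(c5b, 1, nchar(c5b) - 3),
                            as.character(b@cds[[ev2$tx3]]))
    expect_equal(nrow(fc2), 0L)
    expect_match(attr(fc2, "reason"), "out-of-frame")

    ## stop codon right at the junction: no windows, no error
    ev3 <- ev; ev3$n5 <- 9; ev3$n3off <- 0
    fc3 <- fusionCandidates(ev3, "ATGGCCGCC", "TAACCCGGGTTT")
    expect_equal(nrow(fc3), 0L)
})
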