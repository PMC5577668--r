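test_that("fixture generation is a pure function of the seed", {
    b1 <- fixtureBundle(4242)
    b2 <- fixtureBundle(4242)
    expect_identical(b1@samText, b2@samText)
    expect_identical(as.character(b1@proteome), as.character(b2@proteome))
    expect_identical(as.character(b1@genome), as.character(b2@genome))
    expect_identical(b1@variants, b2@variants)
    expect_identical(b1@truth, b2@truth)
    d1 <- tempfile(); d2 <- tempfile()
    writeFixtureBundle(b1, d1); writeFixtureBundle(b2, d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    b3 <- fixtureBundle(4243)
    expect_false(identical(b1@samText, b3@samText))
})

test_that("every reference CDS translates to its protein", {
    ref <- makeReference(2024)
    for (tx in names(ref$cds))
        expect_equal(translateCds(as.character(ref$cds[[tx]])),
                     as.character(ref$proteome[[tx]]))
    ## worked-example fragments are present verbatim
    expect_equal(as.character(ref$proteome[["TX_KRAS"]]),
                 unname(referenceContexts()["KRAS"]))
})

test_that("transcript placement round-trips through the genome, both strands", {
    ref <- makeReference(31)
    for (tx in c("TX_GENE1", "TX_GENE3", "TX_GENE4")) {
        tm <- ref$transcripts[[tx]]
        contig <- as.character(ref$genome[[tm@chrom]])
        exSeq <- paste(vapply(seq_along(tm@exons), function(i)
            substr(contig, IRanges::start(tm@exons)[i],
                   IRanges::end(tm@exons)[i]), character(1)),
            collapse = "")
        spliced <- if (tm@strand == "-")
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(exSeq))) else exSeq
        expect_equal(spliced, as.character(ref$cds[[tx]]), info = tx)
    }
})

test_that("planted missense cases carry consistent window and read truth", {
    ref <- makeReference(55)
    mi <- makeMissenseCase(56, ref, "TX_GENE1", "interior", "expressed")
    expect_equal(mi$truth$n_windows, 9L)
    expect_true(all(mi$truth$window_expressed))
    ## the planted windows are what the window module derives
    ws <- peptideWindows(missenseCandidates(
        as.character(ref$proteome[["TX_GENE1"]]), mi$variant))
    expect_identical(ws$mut, mi$truth$windows)

    me <- makeMissenseCase(57, ref, "TX_GENE2", "edge", "expressed")
    expect_equal(me$truth$n_windows, 1L)
    expect_equal(me$variant$aa_pos, 1L)

    ## silent: mutant reads exist but none spans 27 bases
    ms <- makeMissenseCase(58, ref, "TX_GENE1", "interior", "silent")
    reads <- readSamSubset(tmpWrite(c("@HD\tVN:1.6", ms$reads), ".sam"))
    tx <- ref$transcripts[["TX_GENE1"]]
    cl <- callExpression(list(aa_start = max(1L, ms$variant$aa_pos - 4L)),
                         ms$variant, tx, reads)
    expect_gt(cl$mutant_read_count, 0L)
    expect_equal(cl$spanning_mutant_read_count, 0L)
    expect_false(cl$expressed)
})

test_that("binding worlds recover exactly the planted binder set", {
    gt <- HlaGenotype("S", c("A*02:01", "A*11:01", "B*07:02", "B*08:01",
                             "C*04:01", "C*07:01"))
    set.seed(9)
    decoys <- replicate(8, randomPeptide(9))
    planted <- data.frame(peptide = randomPeptide(9), allele = "A*11:01")
    world <- makeBindingWorld(1, list(gt), planted,
                              peptideUniverse = decoys)
    got <- scoreCandidates(c(decoys, planted$peptide), gt, world)
    expect_equal(got$peptide, planted$peptide)
    expect_equal(got$allele, "HLA-A*11:01")
    expect_equal(got$ic50_nM, 50000^0.1, tolerance = 1e-9)

    ## plant none: nothing passes
    world0 <- makeBindingWorld(1, list(gt),
                               data.frame(peptide = character(0),
                                          allele = character(0)),
                               peptideUniverse = decoys)
    expect_equal(nrow(scoreCandidates(decoys, gt, world0)), 0L)

    ## an infeasible plant (near-duplicate peptide in the universe) errors
    clash <- planted$peptide
    substr(clash, 1, 1) <- setdiff(AA, substr(clash, 1, 1))[1]
    expect_error(makeBindingWorld(1, list(gt), planted,
                                  peptideUniverse = c(decoys, clash)),
                 "infeasible plant")

    ## the text rendering parses back to the same scores
    sc <- matrixScore(c(decoys, planted$peptide), world[["HLA-A*11:01"]])
    back <- parsePredictorTable(text = renderPredictorTable(sc))
    expect_equal(back$ic50_nM, round(sc$ic50_nM, 4), tolerance = 1e-8)
})
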