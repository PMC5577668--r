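mkCand <- function(sample, peptide, allele, source = "missense",
                   key = "k1", expressed = NA, offset = 0L) {
    data.frame(sample = sample, peptide = peptide,
               wt_peptide = "", allele = allele, ic50_nM = 50,
               source = source, source_key = key, window_offset = offset,
               aa_start = offset + 1L, expressed = expressed,
               stringsAsFactors = FALSE)
}

oneVariant <- function(sample = "S1", gene = "KRAS", aa = "G13D") {
    data.frame(sample = sample, gene = gene, aa_change = aa,
               stringsAsFactors = FALSE)
}

test_that("per-sample summaries count mutations, pairs, and expression", {
    ## 1 mutation, 3 windows on 2 alleles -> 6 candidate pairs
    v <- oneVariant()
    cand <- do.call(rbind, lapply(0:2, function(o) rbind(
        mkCand("S1", paste0("PEP", o), "HLA-A*02:01",
               key = "S1|KRAS|G13D", offset = o, expressed = TRUE),
        mkCand("S1", paste0("PEP", o), "HLA-B*07:02",
               key = "S1|KRAS|G13D", offset = o, expressed = FALSE))))
    s <- summarizeSample(cand, v)
    expect_equal(s$n_missense, 1L)
    expect_equal(s$n_neoepitope_mutations, 1L)
    expect_equal(s$n_candidates, 6L)
    expect_equal(s$n_expressed_candidates, 3L)

    ## zero candidates
    s0 <- summarizeSample(cand[0, ], v)
    expect_equal(s0$n_candidates, 0L)
    expect_equal(s0$n_neoepitope_mutations, 0L)

    ## no RNA: unknown, not zero
    sNA <- summarizeSample(cand, v, rnaAvailable = FALSE)
    expect_true(is.na(sNA$n_expressed_candidates))

    ## duplicate transcript provenance collapses per (peptide, allele)
    sDup <- summarizeSample(rbind(cand, cand), v)
    expect_equal(sDup$n_candidates, 6L)

    expect_error(summarizeSample(rbind(mkCand("S1", "P", "HLA-A*02:01"),
                                       mkCand("S2", "P", "HLA-A*02:01")),
                                 v), "multiple samples")
})

test_that("percentage formatting reproduces printed cohort proportions", {
    expect_equal(formatPercent(441, 1180)$value, 37.4)
    expect_equal(formatPercent(2336, 5619)$value, 41.6)
    expect_equal(formatPercent(0, 10)$value, 0)
    expect_equal(formatPercent(32, 47, 0)$value, 68)
    expect_equal(formatPercent(441, 1180)$label, "37.4% (441/1180)")
    expect_error(formatPercent(1, 0), "positive")
})

test_that("cohort summaries average per subtype with relapse set aside", {
    sm <- rbind(
        summarizeSample(mkCand("A1", "P1", "HLA-A*02:01", expressed = TRUE),
                        oneVariant("A1"), subtype = "BALL"),
        summarizeSample(rbind(mkCand("A2", "P2", "HLA-A*02:01",
                                     expressed = TRUE),
                              mkCand("A2", "P3", "HLA-A*02:01",
                                     key = "k2", expressed = FALSE)),
                        rbind(oneVariant("A2"),
                              oneVariant("A2", "NRAS", "Q61K"),
                              oneVariant("A2", "TP53", "R175H")),
                        subtype = "BALL"),
        summarizeSample(mkCand("A3", "P4", "HLA-A*02:01",
                               expressed = TRUE),
                        oneVariant("A3"), subtype = "BALL",
                        relapse = TRUE))
    cs <- summarizeCohort(sm)
    row <- cs$perSubtype[cs$perSubtype$subtype == "BALL", ]
    expect_equal(row$n_samples, 2L)
    expect_equal(row$n_relapse, 1L)
    expect_equal(row$avg_mutations, 2)            # (1 + 3) / 2
    expect_equal(row$avg_candidates, 1.5)
    expect_equal(row$avg_mutations_incl_relapse,
                 roundHalfUp((1 + 3 + 1) / 3, 2)) # parenthetical column
    ## single-sample cohort: averages equal its counts
    cs1 <- summarizeCohort(sm[1, ])
    expect_equal(cs1$perSubtype$avg_mutations, 1)
    expect_equal(cs1$perSubtype$avg_candidates, 1)
})

test_that("mutation-epitope regression matches the closed form", {
    ## collinear points (summary.lm warns about the perfect fit)
    r <- suppressWarnings(mutationEpitopeRegression(1:5, 2 * (1:5) + 3))
    expect_equal(r$r_squared, 1)
    expect_equal(r$slope, 2)
    expect_equal(r$intercept, 3)
    ## constant response
    r0 <- suppressWarnings(mutationEpitopeRegression(1:5, rep(4, 5)))
    expect_equal(r0$r_squared, 0)
    ## 5-point hand case against explicit least-squares algebra
    x <- c(2, 5, 9, 14, 20); y <- c(1, 4, 3, 9, 10)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    icpt <- mean(y) - slope * mean(x)
    r2 <- sum((icpt + slope * x - mean(y))^2) / sum((y - mean(y))^2)
    fit <- mutationEpitopeRegression(x, y)
    expect_equal(fit$slope, slope)
    expect_equal(fit$intercept, icpt)
    expect_equal(fit$r_squared, r2)
    expect_error(mutationEpitopeRegression(rep(3, 5), 1:5),
                 "zero variance")
    expect_error(mutationEpitopeRegression(1:2, 1:2), "at least three")
})

test_that("recurrence tables count carriers and epitope-positive samples", {
    carriers <- data.frame(lesion = "ETV6-RUNX1",
                           sample = paste0("P", 1:47))
    positives <- data.frame(lesion = "ETV6-RUNX1",
                            sample = paste0("P", 1:32))
    rt <- recurrenceTable(carriers, positives)
    expect_equal(rt$n_samples_total, 47L)
    expect_equal(rt$n_samples_with_epitope, 32L)
    expect_equal(rt$pct, 68)

    ## no positives
    rt0 <- recurrenceTable(carriers, positives[0, ])
    expect_equal(rt0$n_samples_with_epitope, 0L)

    ## one sample with two transcripts of the same lesion counts once
    dup <- rbind(carriers, carriers[1, ])
    dupPos <- rbind(positives, positives[1, ])
    rtd <- recurrenceTable(dup, dupPos)
    expect_equal(rtd$n_samples_total, 47L)
    expect_equal(rtd$n_samples_with_epitope, 32L)
})
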