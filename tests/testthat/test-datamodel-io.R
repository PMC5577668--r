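vmHeader <- paste(c("sample", "gene", "chrom", "pos", "ref_allele",
                    "mut_allele", "mutation_class", "aa_change",
                    "mrna_accession", "protein_gi",
                    "mutant_reads_tumor", "total_reads_tumor",
                    "mutant_reads_normal", "total_reads_normal"),
                  collapse = "\t")

vmRow <- function(sample = "S1", gene = "KRAS", pos = 100,
                  cls = "missense", aa = "G13D", mrna = "TX1",
                  counts = c(12, 40, 0, 35)) {
    paste(c(sample, gene, "chr1", pos, "G", "A", cls, aa, mrna, "999",
            counts), collapse = "\t")
}

test_that("variant matrix reading filters classes and parses amino-acid changes", {
    path <- tmpWrite(c(vmHeader, vmRow(),
                       vmRow(gene = "TP53", aa = "R196*",
                             cls = "nonsense")))
    expect_message(v <- readVariantMatrix(path), "1 non-missense")
    expect_equal(nrow(v), 1L)
    expect_equal(attr(v, "skipped"), 1L)
    expect_equal(attr(v, "rows_in"), nrow(v) + attr(v, "skipped"))
    ## the KRAS G13D row of the data matrix
    expect_equal(v$aa_ref, "G")
    expect_equal(v$aa_pos, 13L)
    expect_equal(v$aa_mut, "D")
    expect_equal(v$mutant_reads_tumor, 12L)
})

test_that("variant matrix round-trips and rejects malformed rows", {
    path <- tmpWrite(c(vmHeader, vmRow(), vmRow(gene = "NRAS",
                                                aa = "Q61K", pos = 222)))
    v <- readVariantMatrix(path)
    out <- tempfile()
    writeVariantMatrix(v, out)
    v2 <- readVariantMatrix(out)
    attributes(v) <- attributes(v2) <- NULL
    expect_identical(v, v2)

    expect_error(readVariantMatrix(tmpWrite(c(vmHeader,
                                              vmRow(aa = "13D")))),
                 "malformed amino-acid change.*line")
    expect_error(readVariantMatrix(tmpWrite(c(vmHeader,
                                              vmRow(aa = "G13G")))),
                 "identical")
    expect_error(readVariantMatrix(tmpWrite(c(vmHeader,
                      vmRow(counts = c(50, 40, 0, 35))))),
                 "exceeds total")
})

test_that("HLA allele names normalize across input spellings", {
    expect_equal(normalizeHlaAllele("A*02:01"), "HLA-A*02:01")
    expect_equal(normalizeHlaAllele("HLA-B07:02"), "HLA-B*07:02")
    expect_equal(normalizeHlaAllele("C04:01"), "HLA-C*04:01")
    expect_warning(x <- normalizeHlaAllele("A*02:01:01:02"), "truncated")
    expect_equal(x, "HLA-A*02:01")
    expect_error(normalizeHlaAllele("D*01:01"), "cannot parse.*D\\*01:01")
})

test_that("HLA call reading expands homozygotes and bounds locus arity", {
    long <- tmpWrite(c("sample\talleles",
                       "S1\tA*02:01,A*11:01,B*07:02,B*08:01,C*04:01"))
    g <- readHlaCalls(long)[["S1"]]
    expect_s4_class(g, "HlaGenotype")
    ## single HLA-C allele duplicated to a homozygous pair
    expect_equal(unname(hlaAlleles(g, "C")),
                 c("HLA-C*04:01", "HLA-C*04:01"))
    expect_equal(length(hlaAlleles(g)), 6L)

    wide <- tmpWrite(c("sample\tA1\tA2\tB1\tB2\tC1\tC2",
                       "S2\tA*01:01\tA*02:01\tB*07:02\tB*08:01\tC*04:01\tC*07:01"))
    g2 <- readHlaCalls(wide)[["S2"]]
    expect_equal(unname(hlaAlleles(g2, "A")),
                 c("HLA-A*01:01", "HLA-A*02:01"))

    three <- tmpWrite(c("sample\talleles",
                        "S3\tA*01:01,A*02:01,A*03:01,B*07:02,C*04:01"))
    expect_error(readHlaCalls(three), "more than two alleles at HLA-A")
})

test_that("HLA genotypes round-trip through the wide layout", {
    gts <- list(S1 = HlaGenotype("S1", c("A*02:01", "A*02:01", "B*07:02",
                                         "B*40:01", "C*04:01", "C*07:01")))
    path <- tempfile()
    writeHlaCalls(gts, path)
    back <- readHlaCalls(path)
    expect_identical(hlaAlleles(back[["S1"]]), hlaAlleles(gts[["S1"]]))
})

test_that("CIGAR walking produces the reference-consuming blocks", {
    b <- cigarBlocks("50M", 100)
    expect_equal(unname(b[, c("rstart", "rend"), drop = FALSE]),
                 matrix(c(100L, 149L), 1))

    b <- cigarBlocks("20M100N30M", 100)          # splice gap
    expect_equal(unname(b[, "rstart"]), c(100L, 220L))
    expect_equal(unname(b[, "rend"]), c(119L, 249L))
    expect_equal(unname(b[, "qstart"]), c(1L, 21L))

    b <- cigarBlocks("10M2D10M", 100)            # deletion: abutting blocks
    expect_equal(unname(b[, "rstart"]), c(100L, 112L))
    expect_equal(unname(b[, "rend"]), c(109L, 121L))
    expect_equal(unname(b[, "qstart"]), c(1L, 11L))

    b <- cigarBlocks("5S10M3I10M5S", 50)         # clips/insertions: query only
    expect_equal(unname(b[, "qstart"]), c(6L, 19L))
})

test_that("SAM reading validates lengths and drops unmapped reads", {
    sam <- c("@HD\tVN:1.6",
             "@SQ\tSN:chr1\tLN:1000",
             paste("r1", 0, "chr1", 100, 60, "10M", "*", 0, 0,
                   "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
             paste("r2", 4, "*", 0, 0, "*", "*", 0, 0, "*", "*",
                   sep = "\t"))
    reads <- readSamSubset(tmpWrite(sam, ".sam"))
    expect_equal(nrow(reads), 1L)
    expect_equal(reads$read_id, "r1")
    expect_equal(reads$blocks[[1]][1, "rend"], c(rend = 109L))

    bad <- c("@HD\tVN:1.6",
             paste("r3", 0, "chr1", 100, 60, "12M", "*", 0, 0,
                   "ACGTACGTAC", "IIIIIIIIII", sep = "\t"))
    expect_error(readSamSubset(tmpWrite(bad, ".sam")),
                 "r3.*inconsistent")
})
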