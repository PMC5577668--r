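## Independent brute-force oracles used across the suite.  These stay
## deliberately naive (explicit enumeration) so they cannot share a bug
## with the vectorized implementations they check.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomPeptide <- function(n) paste(sample(AA, n, replace = TRUE),
                                   collapse = "")

## every k-mer of seq containing 1-based position pos, by full enumeration
bfWindows <- function(seq, pos, k = 9) {
    L <- nchar(seq)
    out <- character(0)
    if (L < k) return(out)
    for (s in 1:(L - k + 1)) {
        if (s <= pos && pos <= s + k - 1)
            out <- c(out, substr(seq, s, s + k - 1))
    }
    out
}

## junction k-mers by residue side-labelling: a residue touches the 5'
## partner iff its codon starts within the first n5 nucleotides, and the
## 3' partner iff its codon ends past them
bfJunctionWindows <- function(peptide, n5, k = 9) {
    L <- nchar(peptide)
    out <- character(0)
    if (L < k) return(out)
    t5 <- vapply(1:L, function(r) 3 * r - 2 <= n5, logical(1))
    t3 <- vapply(1:L, function(r) 3 * r > n5, logical(1))
    for (s in 1:(L - k + 1)) {
        rr <- s:(s + k - 1)
        if (any(t5[rr]) && any(t3[rr]))
            out <- c(out, substr(peptide, s, s + k - 1))
    }
    out
}

## per-position coverage check against a block matrix
bfSpans <- function(blocks, positions) {
    for (p in positions) {
        covered <- FALSE
        for (i in seq_len(nrow(blocks)))
            if (blocks[i, "rstart"] <= p && p <= blocks[i, "rend"])
                covered <- TRUE
        if (!covered) return(FALSE)
    }
    TRUE
}

## maximum bipartite matching between two allele pairs, by enumerating
## both assignments
bfScoreLocus <- function(truth, called) {
    max(sum(truth == called), sum(truth == rev(called)))
}

## small helper: write lines to a temp file and return the path
tmpWrite <- function(lines, ext = ".tsv") {
    path <- tempfile(fileext = ext)
    writeLines(lines, path)
    path
}
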