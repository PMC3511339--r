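test_that("reverse complement is IUPAC-aware, case-preserving, and an involution", {
    expect_equal(revcompIupac("tgtgactcagc"), "gctgagtcaca")
    expect_equal(revcompIupac("N"), "N")
    expect_equal(revcompIupac("GGGRNNYYCC"), "GGRRNNYCCC")
    expect_equal(revcompIupac("tgGACTca"), "tgAGTCca")  # case survives
    expect_error(revcompIupac("ACGX!"), "invalid character")
    set.seed(31)
    for (rep in 1:20) {
        x <- paste(sample(strsplit("ACGTRYSWKMBDHVNacgt", "")[[1]],
                          sample(1:30, 1), replace = TRUE), collapse = "")
        expect_equal(revcompIupac(revcompIupac(x)), x)
    }
})

test_that("motif library read/write round-trips both representations", {
    motifs <- list(
        consensusMotif("V$AP-1F", "V$AP-1.01", "TGASTCA", core = c(3, 6)),
        consensusMotif("V$NFKB", "V$NFKAPPAB.01", "GGGRNNYYCC", core = c(1, 4)),
        matrixMotif("V$TEST", "V$TEST.01",
                    matrix(c(10, 0, 0, 0,  0, 8, 2, 0,  1, 1, 1, 7), 4, 3),
                    core = c(1, 2), threshold = 0.9))
    f <- withr::local_tempfile(fileext = ".txt")
    writeMotifLibrary(motifs, f)
    back <- readMotifLibrary(f)
    expect_length(back, 3)
    expect_equal(vapply(back, motifName, character(1)),
                 vapply(motifs, motifName, character(1)))
    expect_equal(back[[1]]@consensus, "TGASTCA")
    expect_equal(motifCore(back[[2]]), c(1L, 4L))
    expect_equal(back[[3]]@matrix, motifs[[3]]@matrix,
                 ignore_attr = TRUE)
    expect_equal(back[[3]]@threshold, 0.9)

    # a consensus entry parses to the stated width
    f2 <- withr::local_tempfile()
    writeLines("AP1\tV$AP-1.01\tTGASTCA\tcore=1-7", f2)
    m <- readMotifLibrary(f2)[[1]]
    expect_equal(motifWidth(m), 7)

    writeLines(c("AP1\tV$X\tTGASTCA", "AP2\tV$X\tTGASTCA"), f2)
    expect_error(readMotifLibrary(f2), "duplicate")
    writeLines("AP1\tV$Y\tTGAZTCA", f2)
    expect_error(readMotifLibrary(f2), "IUPAC")
})

test_that("consensus scanning matches the per-window enumeration oracle", {
    lib <- coreMotifLibrary()
    set.seed(32)
    for (rep in 1:25) {
        seq <- randomDna(sample(30:80, 1))
        for (m in lib) {
            hits <- scanMotifs(seq, list(m))
            hits <- hits[order(hits$start, hits$strand), ]
            orc <- oracleConsensusHits(seq, m@consensus)
            orc <- orc[order(orc$start, orc$strand), ]
            expect_equal(hits$start, orc$start, info = seq)
            expect_equal(hits$strand, orc$strand, info = seq)
        }
    }
    expect_equal(nrow(scanMotifs(randomDna(50), list())), 0)
})

test_that("consensus scanning agrees with Biostrings degenerate matching", {
    lib <- coreMotifLibrary()
    set.seed(33)
    for (rep in 1:10) {
        seq <- randomDna(200)
        for (m in lib) {
            hits <- scanMotifs(seq, list(m))
            plus <- sort(hits$start[hits$strand == "+"])
            ref <- Biostrings::matchPattern(m@consensus,
                                            Biostrings::DNAString(seq),
                                            fixed = FALSE)
            expect_equal(plus, IRanges::start(IRanges::ranges(ref)))
        }
    }
})

test_that("strand symmetry: minus-strand hits mirror plus-strand hits of the revcomp", {
    lib <- coreMotifLibrary()
    set.seed(34)
    for (rep in 1:10) {
        seq <- randomDna(120)
        rc <- revcompIupac(seq)
        L <- nchar(seq)
        hits <- scanMotifs(seq, lib)
        rcHits <- scanMotifs(rc, lib)
        for (m in lib) {
            w <- motifWidth(m)
            minus <- sort(hits$start[hits$strand == "-" & hits$matrixName == motifName(m)])
            plusOnRc <- rcHits$start[rcHits$strand == "+" & rcHits$matrixName == motifName(m)]
            expect_equal(minus, sort(L - (plusOnRc + w - 1) + 1))
        }
    }
})

test_that("matrix scanning scores by observed counts over per-position maxima", {
    counts <- matrix(c(10, 0, 0, 0,   # A
                       0, 10, 0, 0,   # C
                       5, 0, 5, 0,    # A or G
                       0, 0, 0, 10), 4, 4,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    m <- matrixMotif("F", "M1", counts, threshold = 0.8)
    hits <- scanMotifs("ACAT", list(m))
    h <- hits[hits$strand == "+", ]
    expect_equal(h$score, 1.0)  # 35/35
    # one suboptimal base: ACTT gives (10+10+0+10)/35
    m2 <- matrixMotif("F", "M1", counts, threshold = 0.5)
    h2 <- scanMotifs("ACTT", list(m2))
    h2 <- h2[h2$strand == "+", ]
    expect_equal(h2$score, 30 / 35)
    # below threshold: no hit
    m3 <- matrixMotif("F", "M1", counts, threshold = 0.9)
    h3 <- scanMotifs("ACTT", list(m3))
    expect_false(any(h3$strand == "+"))
    # consensus scanning is the threshold-1 special case of its indicator matrix
    ind <- matrix(0, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
    cons <- strsplit("TGACTCA", "")[[1]]
    for (p in seq_along(cons)) ind[cons[p], p] <- 1
    mi <- matrixMotif("F", "IND", ind, threshold = 1.0)
    mc <- consensusMotif("F", "CONS", "TGACTCA")
    set.seed(35)
    for (rep in 1:10) {
        s <- randomDna(60)
        expect_equal(scanMotifs(s, list(mi))[, c("start", "strand")],
                     scanMotifs(s, list(mc))[, c("start", "strand")])
    }
})

test_that("hits report plus-strand coordinates with upper-cased cores", {
    fix <- makeTable2Fixture()
    lib <- coreMotifLibrary()
    f1 <- fix$fragments[fix$fragments$name == "ap1_site1", ]
    hits <- scanMotifs(f1$sequence, lib, offset = f1$offset)
    expect_setequal(hits$strand, c("+", "-"))
    plus <- hits[hits$strand == "+", ]
    minus <- hits[hits$strand == "-", ]
    expect_equal(plus$matchedSequence, "tgACTCa")
    expect_equal(minus$matchedSequence, "tGACTca")
    # the site as read on the minus strand is the printed (-) word
    expect_equal(revcompIupac(minus$matchedSequence), "tgAGTCa")
    expect_equal(plus$start, minus$start)  # inverted-repeat double listing
    # offset shifts coordinates into the report frame
    expect_true(all(hits$start >= 122 & hits$end <= 132))
})

test_that("core deletion excises the core and abolishes rescan hits there", {
    lib <- coreMotifLibrary()
    ap1 <- lib[[1]]
    seq <- "AAAATGACTCAAAAA"
    hits <- scanMotifs(seq, list(ap1))
    h <- hits[hits$strand == "+", ][1, ]
    mut <- deleteCore(seq, h)
    expect_equal(nchar(mut), nchar(seq) - (h$coreEnd - h$coreStart + 1))
    re <- scanMotifs(mut, list(ap1))
    expect_equal(nrow(re), 0)

    # two disjoint cores: deleting one leaves exactly the other
    two <- "TGACTCATTTTTTTTTGAGTCA"
    hits2 <- scanMotifs(two, list(ap1))
    first <- hits2[hits2$start == 1 & hits2$strand == "+", ]
    mut2 <- deleteCore(two, first)
    re2 <- scanMotifs(mut2, list(ap1))
    expect_true(all(re2$start > 1))
    expect_equal(length(unique(re2$start)), 1)

    # deletion at the sequence edge
    edge <- "TGACTCA"
    he <- scanMotifs(edge, list(ap1))
    expect_no_error(deleteCore(edge, he[1, ]))
    expect_error(deleteCore("ACGT", data.frame(coreStart = 10, coreEnd = 12)),
                 "outside")
})

test_that("variant disruption classifies core vs flank-only overlap", {
    lib <- coreMotifLibrary()
    seq <- paste0(strrep("T", 20), "TGACTCA", strrep("T", 20))
    hits <- scanMotifs(seq, lib)
    # variant away from all hits: all clear
    far <- disruptedSites(IRanges::IRanges(1, 5), hits)
    expect_equal(nrow(far$core), 0)
    expect_equal(nrow(far$flankOnly), 0)
    # variant equal to a core: that hit returned
    h <- hits[hits$strand == "+", ][1, ]
    onCore <- disruptedSites(IRanges::IRanges(h$coreStart, h$coreEnd), hits)
    expect_true(nrow(onCore$core) >= 1)
    # variant on the flank only (clear of every hit's core on either strand)
    minCore <- min(hits$coreStart)
    flank <- disruptedSites(IRanges::IRanges(h$start, minCore - 1), hits)
    expect_equal(nrow(flank$core), 0)
    expect_true(nrow(flank$flankOnly) >= 1)
    # random variants agree with a brute-force interval-intersection oracle
    set.seed(36)
    for (rep in 1:20) {
        vs <- sample(45, 1); ve <- min(47, vs + sample(0:6, 1))
        d <- disruptedSites(IRanges::IRanges(vs, ve), hits)
        coreOracle <- hits[pmax(hits$coreStart, vs) <= pmin(hits$coreEnd, ve), ]
        expect_equal(d$core$start, coreOracle$start)
        expect_equal(d$core$strand, coreOracle$strand)
    }
})
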