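test_that("insert-size model estimation follows the mean + 2 sd rule", {
    m <- estimateInsertModel(c(300, 300, 300, 300))
    expect_equal(m@meanFragment, 300)
    expect_equal(m@sdFragment, 0)
    expect_equal(discordantDistance(m), 300)

    ## mean 300, sd 100 -> threshold 500
    x <- c(200, 300, 400)
    expect_equal(mean(x), 300)
    expect_equal(sd(x), 100)
    expect_equal(discordantDistance(estimateInsertModel(x)), 500)

    expect_error(estimateInsertModel(numeric()), "insufficient")
    expect_error(estimateInsertModel(300), "insufficient")
    expect_error(estimateInsertModel(c(300, -1, 300)), "positive")
    expect_error(insertSizeModel(-10, 5), "positive")
})

test_that("alignment classification applies the three discordance criteria", {
    m <- insertSizeModel(300, 100, 500)
    ## concordant +/- within distance
    expect_identical(
        classifyAlignment(makeAln(start = 1000, end = 1100,
                                  mate_start = 1200, mate_end = 1300), m),
        character(0))
    ## outer distance 600 > 500
    expect_identical(
        classifyAlignment(makeAln(start = 1000, end = 1100,
                                  mate_start = 1500, mate_end = 1600), m),
        "pairend")
    ## -/+ configuration, distance 200
    expect_identical(
        classifyAlignment(makeAln(start = 1000, end = 1100, strand = -1L,
                                  mate_start = 1100, mate_end = 1200,
                                  mate_strand = 1L), m),
        "pairend")
    ## interchromosomal mates
    expect_identical(
        classifyAlignment(makeAln(chrom = "1", mate_chrom = "5"), m),
        "pairend")
    ## concordant pair carrying a supplementary segment
    expect_identical(
        classifyAlignment(makeAln(start = 1000, end = 1100,
                                  mate_start = 1200, mate_end = 1300,
                                  has_split = TRUE,
                                  split_chrom = "chr1",
                                  split_start = 5000L, split_end = 5040L,
                                  split_strand = 1L), m),
        "split")
    ## discordant and split
    expect_setequal(
        classifyAlignment(makeAln(start = 1000, end = 1100,
                                  mate_start = 1500, mate_end = 1600,
                                  has_split = TRUE,
                                  split_chrom = "chr1",
                                  split_start = 5000L, split_end = 5040L,
                                  split_strand = 1L), m),
        c("pairend", "split"))
    ## unpaired, no split -> empty set, not an error
    expect_identical(
        classifyAlignment(makeAln(paired = FALSE,
                                  mate_chrom = NA_character_,
                                  mate_start = NA, mate_end = NA,
                                  mate_strand = NA), m),
        character(0))
})

test_that("pairend records are breakpoint-padded and genome-ordered", {
    m <- insertSizeModel(300, 100, 500)
    aln <- makeAln(start = 1000, end = 1100, strand = 1L,
                   mate_start = 2000, mate_end = 2100, mate_strand = -1L)
    rec <- makeEvidenceRecords(aln, "pairend", m)
    ## + end extended downstream to start + 500, - end upstream to
    ## end - 500
    expect_equal(rec$left_start, 1000)
    expect_equal(rec$left_end, 1500)
    expect_equal(rec$right_start, 1600)
    expect_equal(rec$right_end, 2100)
    expect_equal(rec$left_strand, 1L)
    expect_equal(rec$right_strand, -1L)
    expect_equal(rec$class, "pairend")

    ## ends given right-before-left come out genome-ordered
    rev <- makeAln(start = 2000, end = 2100, strand = -1L,
                   mate_start = 1000, mate_end = 1100, mate_strand = 1L)
    rec2 <- makeEvidenceRecords(rev, "pairend", m)
    expect_equal(rec2, rec)

    ## padding clamps at zero
    low <- makeAln(start = 10, end = 110, strand = -1L,
                   mate_chrom = "chr2", mate_start = 500, mate_end = 600,
                   mate_strand = 1L)
    rl <- makeEvidenceRecords(low, "pairend", m)
    expect_equal(rl$left_start, 0)

    ## split records use exact spans, no padding
    sp <- makeAln(start = 1000, end = 1060, strand = 1L,
                  has_split = TRUE, split_chrom = "chr1",
                  split_start = 5000L, split_end = 5040L,
                  split_strand = 1L)
    recS <- makeEvidenceRecords(sp, "split", m)
    expect_equal(recS$left_start, 1000)
    expect_equal(recS$left_end, 1060)
    expect_equal(recS$right_start, 5000)
    expect_equal(recS$right_end, 5040)
    expect_equal(recS$class, "split")

    expect_error(makeEvidenceRecords(makeAln(), "split", m), "split")
})

test_that("evidence sort is bytewise, numeric and stable", {
    r <- emptyEvidence()
    recs <- data.frame(
        left_chrom = c("X", "2", "10", "2", "2"),
        left_start = c(5L, 9L, 1L, 3L, 3L),
        left_end = c(10L, 12L, 8L, 9L, 7L),
        left_strand = 1L,
        right_chrom = c("X", "2", "10", "2", "2"),
        right_start = 100L, right_end = 200L, right_strand = -1L,
        class = c("pairend", "pairend", "split", "pairend", "split"),
        stringsAsFactors = FALSE)
    s <- sortEvidence(recs)
    ## bytewise collation: "10" < "2" < "X"
    expect_equal(s$left_chrom, c("10", "2", "2", "2", "X"))
    expect_equal(s$left_start, c(1L, 3L, 3L, 9L, 5L))
    ## numeric end as third key
    expect_equal(s$left_end, c(8L, 7L, 9L, 12L, 10L))
    ## already-sorted input is unchanged; stability on exact ties
    expect_equal(sortEvidence(s), s)
    tie <- recs[c(2, 2), ]
    tie$class <- c("pairend", "split")
    expect_equal(sortEvidence(tie)$class, c("pairend", "split"))
})

test_that("evidence dialect round-trips and rejects malformed lines", {
    recs <- data.frame(
        left_chrom = c("chr1", "chr1", "chr2"),
        left_start = c(100L, 200L, 5L),
        left_end = c(600L, 700L, 105L),
        left_strand = c(1L, -1L, 1L),
        right_chrom = c("chr1", "chr5", "chr2"),
        right_start = c(900L, 0L, 400L),
        right_end = c(1400L, 500L, 440L),
        right_strand = c(-1L, 1L, 1L),
        class = c("pairend", "pairend", "split"),
        stringsAsFactors = FALSE)
    for (ext in c(".bed", ".bed.gz")) {
        f <- tempfile(fileext = ext)
        writeEvidence(recs, f)
        expect_equal(readEvidence(f), recs)
    }
    ## class column: 1 means split
    f <- tempfile(fileext = ".bed")
    writeLines("chr1\t1\t10\t1\tchr1\t20\t30\t-1\t1", f)
    expect_equal(readEvidence(f)$class, "split")
    ## 8 columns -> error naming the line
    writeLines(c("chr1\t1\t10\t1\tchr1\t20\t30\t-1\t0",
                 "chr1\t1\t10\t1\tchr1\t20\t30\t-1"), f)
    expect_error(readEvidence(f), "line 2")
    ## invalid strand
    writeLines("chr1\t1\t10\t2\tchr1\t20\t30\t-1\t0", f)
    expect_error(readEvidence(f), "strand")
    ## empty file -> zero records
    writeLines(character(), f)
    expect_equal(nrow(readEvidence(f)), 0L)
})

test_that("extraction over a SAM file matches in-memory classification", {
    spec <- miniCohort(seed = 3L, coverage = 8)
    sim <- simulateFragments(spec, samples = 2L)   # s2: DEL + DUP carrier
    tm <- sim$templates[["s2"]]
    model <- insertSizeModel(300, 50, 500)
    inMem <- extractEvidenceFromTemplates(tm, model)
    expect_gt(nrow(inMem), 0L)

    sam <- tempfile(fileext = ".sam")
    emitAlignments(tm, sam, spec$chromLengths)
    out <- tempfile(fileext = ".bed")
    extractEvidence(sam, model, out = out)
    fromSam <- readEvidence(out)
    ## two-path equivalence as multisets of records
    key <- function(r) sort(do.call(paste, r))
    expect_equal(key(fromSam), key(inMem))

    ## determinism: re-running is byte-identical
    out2 <- tempfile(fileext = ".bed")
    extractEvidence(sam, model, out = out2)
    expect_identical(readLines(out), readLines(out2))
})

test_that("concordant-only input yields an empty evidence file", {
    n <- 50
    start <- seq(1000, by = 500, length.out = n)
    tm <- data.frame(
        r1_chrom = "chr1", r1_start = start, r1_end = start + 100,
        r1_strand = 1L, r2_chrom = "chr1", r2_start = start + 200,
        r2_end = start + 300, r2_strand = -1L,
        stringsAsFactors = FALSE)
    model <- insertSizeModel(300, 50, 500)
    expect_equal(nrow(extractEvidenceFromTemplates(tm, model)), 0L)
    sam <- tempfile(fileext = ".sam")
    emitAlignments(tm, sam, c(chr1 = 100000L))
    out <- tempfile(fileext = ".bed")
    extractEvidence(sam, model, out = out)
    expect_equal(nrow(readEvidence(out)), 0L)
})

test_that("every zero-noise deletion record flanks the true breakpoints", {
    svs <- data.frame(sv_id = "del", type = "DEL", chrom = "c1",
                      start = 100000L, end = 101000L,
                      chrom2 = NA_character_, pos2 = NA_integer_,
                      stringsAsFactors = FALSE)
    g <- matrix(1L, 1L, 1L, dimnames = list("A", "del"))
    spec <- cohortSpec(1L, c(c1 = 200000L), svs, g, coverage = 20,
                       noiseRate = 0, seed = 9L)
    tm <- simulateFragments(spec)$templates[["A"]]
    recs <- extractEvidenceFromTemplates(tm, insertSizeModel(300, 50, 500))
    expect_gt(nrow(recs), 0L)
    ## left ends at or before the left breakpoint, right ends at or after
    ## the right breakpoint (padding included), for every record
    expect_true(all(recs$left_start < 100000L + 1L))
    expect_true(all(recs$right_end > 101000L - 1L))
    ## pairend evidence is +/- and distance-discordant by construction
    pe <- recs[recs$class == "pairend", ]
    expect_true(all(pe$left_strand == 1L & pe$right_strand == -1L))
})
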