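test_that("region strings parse as 1-based inclusive coordinates", {
    r <- parseRegion("14:68603030-68603035")
    expect_equal(r, list(chrom = "14", start = 68603029, end = 68603035))
    ## single-base region
    expect_equal(parseRegion("1:5-5"), list(chrom = "1", start = 4, end = 5))
    expect_error(parseRegion("chr1:10"), "malformed")
    expect_error(parseRegion("chr1:10-5"), "bounds")
    expect_error(parseRegion("chr1:0-5"), "bounds")
})

test_that("PED files load with all metadata preserved", {
    ped <- writeExamplePed(tempfile(fileext = ".ped"))
    samples <- loadPed(ped, 5L)
    expect_equal(nrow(samples), 4L)
    expect_equal(names(samples)[1:5],
                 c("Sample", "Sex", "Population", "Super_Population",
                   "Alt_File"))
    expect_setequal(samples$evidence_file,
                    c("NA12812.bed.gz", "HG00672.bed.gz", "NA12878.bed.gz",
                      "HG00674.bed.gz"))
    expect_equal(attr(samples, "bed_column"), "Alt_File")
    expect_error(loadPed(ped, 99L), "out of range")
    ## duplicate sample names
    bad <- tempfile()
    writeLines(c("Sample\tAlt_File", "a\ta.bed", "a\tb.bed"), bad)
    expect_error(loadPed(bad, 2L), "duplicate")
    ## header only -> empty sample list
    empty <- tempfile()
    writeLines("Sample\tAlt_File", empty)
    expect_equal(nrow(loadPed(empty, 2L)), 0L)
})

test_that("query extension follows the SV-type rules", {
    q <- SVQuery("DEL", "14", 68603030, 68603035,
                 rightStart = 68603238, rightEnd = 68603743, window = 500)
    ## DEL: left downstream, right upstream
    e <- extendQuery(q)
    expect_length(e, 1L)
    expect_equal(e[[1]]$left$start, 68603030)
    expect_equal(e[[1]]$left$end, 68603535)
    expect_equal(e[[1]]$right$start, 68602738)
    expect_equal(e[[1]]$right$end, 68603743)

    ## DUP: left upstream, right downstream
    d <- extendQuery(SVQuery("DUP", "14", 68603030, 68603035,
                             rightStart = 68603738, rightEnd = 68603743,
                             window = 500))
    expect_equal(d[[1]]$left$start, 68602530)
    expect_equal(d[[1]]$left$end, 68603035)
    expect_equal(d[[1]]$right$start, 68603738)
    expect_equal(d[[1]]$right$end, 68604243)

    ## BND: unmodified, any window
    b <- extendQuery(SVQuery("BND", "1", 100, 110, rightChrom = "5",
                             rightStart = 900, rightEnd = 910,
                             window = 999))
    expect_equal(b[[1]]$left, list(chrom = "1", start = 100, end = 110))
    expect_equal(b[[1]]$right, list(chrom = "5", start = 900, end = 910))

    ## INV: two sub-queries, downstream for + and upstream for -
    v <- extendQuery(SVQuery("INV", "2", 100, 110, rightStart = 900,
                             rightEnd = 910, window = 50))
    expect_length(v, 2L)
    plus <- v[[which(vapply(v, `[[`, "", "sign") == "+")]]
    minus <- v[[which(vapply(v, `[[`, "", "sign") == "-")]]
    expect_equal(c(plus$left$start, plus$left$end), c(100, 160))
    expect_equal(c(plus$right$start, plus$right$end), c(900, 960))
    expect_equal(c(minus$left$start, minus$left$end), c(50, 110))
    expect_equal(c(minus$right$start, minus$right$end), c(850, 910))

    ## extension clamps at zero
    z <- extendQuery(SVQuery("DUP", "1", 100, 110, rightStart = 900,
                             rightEnd = 910, window = 500))
    expect_equal(z[[1]]$left$start, 0)
})

test_that("query construction validates and normalizes breakpoints", {
    expect_error(SVQuery("XXX", "1", 1, 2, rightStart = 5, rightEnd = 6))
    expect_error(SVQuery("DEL", "1", 1, 2, rightChrom = "2",
                         rightStart = 5, rightEnd = 6), "intrachromosomal")
    expect_warning(
        q <- SVQuery("BND", "5", 900, 910, rightChrom = "1",
                     rightStart = 100, rightEnd = 110),
        "reverse")
    expect_equal(q@leftChrom, "1")
    expect_equal(q@rightChrom, "5")
})

test_that("strand-configuration matching reproduces the per-type rules", {
    combos <- expand.grid(ls = c(1L, -1L), rs = c(1L, -1L),
                          class = c("pairend", "split"),
                          stringsAsFactors = FALSE)
    recs <- data.frame(left_strand = combos$ls, right_strand = combos$rs,
                       class = combos$class, stringsAsFactors = FALSE)
    lab <- paste0(ifelse(combos$ls == 1, "+", "-"),
                  ifelse(combos$rs == 1, "+", "-"), ".", combos$class)
    got <- sapply(c("DEL", "DUP", "INV", "BND"),
                  function(t) setNames(matchStrandConfig(recs, t), lab))
    ## deletions: +/- pairend; +/+ or -/- split
    expect_equal(names(which(got[, "DEL"])),
                 c("+-.pairend", "++.split", "--.split"))
    ## duplications: -/+ pairend; +/+ or -/- split
    expect_equal(names(which(got[, "DUP"])),
                 c("-+.pairend", "++.split", "--.split"))
    ## inversions: +/+ or -/- pairend; +/- or -/+ split
    expect_equal(names(which(got[, "INV"])),
                 c("++.pairend", "--.pairend", "-+.split", "+-.split"))
    ## break ends: everything
    expect_true(all(got[, "BND"]))
})

test_that("queries count matching records once per sample, zeros included", {
    ## one pairend +/- record spanning both DEL probes in one sample
    files <- vapply(1:3, function(i) {
        f <- tempfile(fileext = ".bed")
        writeEvidence(if (i == 1L) data.frame(
            left_chrom = "c1", left_start = 1000L, left_end = 1500L,
            left_strand = 1L, right_chrom = "c1", right_start = 1600L,
            right_end = 2100L, right_strand = -1L, class = "pairend",
            stringsAsFactors = FALSE) else emptyEvidence(), f)
        f
    }, character(1))
    idx <- buildCohortIndex(files, c("sampleA", "sampleB", "sampleC"))
    samples <- data.frame(Sample = c("sampleA", "sampleB", "sampleC"),
                          evidence_file = basename(files),
                          stringsAsFactors = FALSE)
    q <- SVQuery("DEL", "c1", 1400, 1401, rightStart = 1700,
                 rightEnd = 1701, window = 500)
    res <- runQuery(idx, samples, q)
    expect_equal(nrow(res), 3L)
    expect_equal(res$Pairend, c(1L, 0L, 0L))
    expect_equal(res$Split, c(0L, 0L, 0L))
    expect_equal(res$Id, 0:2)

    ## the same locus queried as DUP finds nothing (strand configs
    ## disjoint)
    dup <- runQuery(idx, samples,
                    SVQuery("DUP", "c1", 1400, 1401, rightStart = 1700,
                            rightEnd = 1701, window = 500))
    expect_equal(sum(dup$Pairend + dup$Split), 0L)

    ## PED row order only permutes the output rows
    res2 <- runQuery(idx, samples[c(3, 1, 2), ], q)
    expect_equal(res2$Pairend[res2$Sample == "sampleA"], 1L)
    expect_equal(sum(res2$Pairend), 1L)

    ## a PED sample without an indexed file is an error naming it
    bad <- rbind(samples,
                 data.frame(Sample = "ghost", evidence_file = "ghost.bed"))
    expect_error(runQuery(idx, bad, q), "ghost")
})

test_that("both query paths agree and window growth is monotone", {
    pipe <- miniPipeline(miniCohort(seed = 21L, noiseRate = 0.02))
    qs <- svQueries(pipe$spec)
    for (q in qs) {
        a <- runQuery(pipe$idx, pipe$sim$ped, q, method = "index")
        b <- runQuery(pipe$idx, pipe$sim$ped, q, method = "bruteforce")
        expect_equal(a, b)
    }
    ## monotonicity in the window
    q <- qs[["del1"]]
    counts <- sapply(c(100, 300, 500, 800), function(w) {
        qw <- SVQuery("DEL", q@leftChrom, q@leftStart, q@leftEnd,
                      rightStart = q@rightStart, rightEnd = q@rightEnd,
                      window = w)
        r <- runQuery(pipe$idx, pipe$sim$ped, qw)
        r$Pairend + r$Split
    })
    expect_true(all(apply(counts, 1, function(x) all(diff(x) >= 0))))
})

test_that("result formatting matches the tabular and summary dialects", {
    res <- data.frame(Id = 0:1, Sample = c("a", "b"), Sex = c("1", "2"),
                      Population = "P", Super_Population = "SP",
                      Alt_File = c("a.bed", "b.bed"),
                      Pairend = c(8L, 0L), Split = c(1L, 0L),
                      stringsAsFactors = FALSE)
    txt <- formatResult(res)
    expect_length(txt, 3L)
    expect_equal(txt[1],
                 "Id\tSample\tSex\tPopulation\tSuper_Population\tAlt_File\tPairend\tSplit")
    expect_equal(length(strsplit(txt[2], "\t")[[1]]), 8L)
    ## summary mode
    expect_equal(formatResult(res, summary = TRUE),
                 "n_samples_with_evidence\t1\ttotal_pairend\t8\ttotal_split\t1")
    ## empty cohort: header only
    expect_equal(formatResult(res[0, ]), txt[1])
})
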