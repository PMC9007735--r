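## Shared fixtures: a small fast cohort, an alignment-view row builder,
## and the worked 4-sample PED table.

## a compact cohort that still exercises every SV type: 4 samples, two
## 400-kb chromosomes, one DEL/DUP/INV plus one interchromosomal BND,
## hand-set genotypes so every SV has carriers and non-carriers
miniCohort <- function(seed = 11L, noiseRate = 0, coverage = 20) {
    svs <- data.frame(
        sv_id = c("del1", "dup1", "inv1", "bnd1"),
        type = c("DEL", "DUP", "INV", "BND"),
        chrom = c("cA", "cA", "cB", "cA"),
        start = c(50000L, 150000L, 120000L, 300000L),
        end = c(51500L, 152000L, 123000L, 300001L),
        chrom2 = c(NA, NA, NA, "cB"),
        pos2 = c(NA, NA, NA, 250000L),
        stringsAsFactors = FALSE)
    genotypes <- matrix(
        c(1L, 2L, 0L, 0L,    # del1 carriers: s1, s2
          0L, 1L, 1L, 0L,    # dup1 carriers: s2, s3
          2L, 0L, 0L, 1L,    # inv1 carriers: s1, s4
          0L, 0L, 2L, 0L),   # bnd1 carrier:  s3
        nrow = 4L,
        dimnames = list(c("s1", "s2", "s3", "s4"),
                        c("del1", "dup1", "inv1", "bnd1")))
    cohortSpec(4L, c(cA = 400000L, cB = 400000L), svs, genotypes,
               fragmentMean = 300, fragmentSd = 50, readLength = 100L,
               coverage = coverage, noiseRate = noiseRate, seed = seed)
}

## one AlignmentView row for classifyAlignment / makeEvidenceRecords
makeAln <- function(chrom = "chr1", start = 1000, end = 1100, strand = 1L,
                    mate_chrom = chrom, mate_start = 2000,
                    mate_end = 2100, mate_strand = -1L, paired = TRUE,
                    has_split = FALSE, split_chrom = NA_character_,
                    split_start = NA_integer_, split_end = NA_integer_,
                    split_strand = NA_integer_) {
    data.frame(chrom = chrom, start = start, end = end, strand = strand,
               paired = paired, mate_chrom = mate_chrom,
               mate_start = mate_start, mate_end = mate_end,
               mate_strand = mate_strand, has_split = has_split,
               split_chrom = split_chrom, split_start = split_start,
               split_end = split_end, split_strand = split_strand,
               stringsAsFactors = FALSE)
}

## the worked 4-sample PED layout (header + sample/sex/population/
## super-population/evidence-file columns)
writeExamplePed <- function(path) {
    writeLines(c(
        "Sample\tSex\tPopulation\tSuper_Population\tAlt_File",
        "NA12812\t1\tCEU\tEUR\tNA12812.bed.gz",
        "HG00672\t2\tCHS\tEAS\tHG00672.bed.gz",
        "NA12878\t2\tCEU\tEUR\tNA12878.bed.gz",
        "HG00674\t1\tCHS\tEAS\tHG00674.bed.gz"), path)
    path
}

## sorted canonical form of a hit frame for multiset comparison
canonicalHits <- function(h) {
    h <- h[order(h$rid, h$matched_end, method = "radix"), , drop = FALSE]
    rownames(h) <- NULL
    h
}

## simulate a mini cohort, extract evidence and build the index once
miniPipeline <- function(spec = miniCohort(), dir = tempfile("mini")) {
    sim <- simulateCohortEvidence(spec, dir)
    idx <- buildCohortIndex(sim$evidenceFiles, sim$sampleIds)
    list(spec = spec, sim = sim, idx = idx)
}
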