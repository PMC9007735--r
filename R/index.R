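## Multi-sample evidence index: pooled record table plus a GRanges over
## both end-intervals of every record; search is interval overlap on the
## half-open record/probe coordinates.

#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
NULL

.INDEX_FORMAT_VERSION <- 1L

.endsGRanges <- function(records) {
    if (nrow(records) == 0L)
        return(GenomicRanges::GRanges())
    ## 0-based half-open -> 1-based closed keeps overlap semantics exact
    gr <- GenomicRanges::GRanges(
        seqnames = c(records$left_chrom, records$right_chrom),
        ranges = IRanges::IRanges(
            start = c(records$left_start, records$right_start) + 1L,
            end = c(records$left_end, records$right_end)))
    S4Vectors::mcols(gr)$rid <- rep(records$rid, 2L)
    S4Vectors::mcols(gr)$side <- rep(c("left", "right"),
                                     each = nrow(records))
    gr
}

#' Build a unified cohort evidence index
#'
#' Pools the records of per-sample evidence files into one searchable
#' index. Each record is attributed to its sample and entered under both
#' of its end-intervals, so interchromosomal records are findable from
#' either side; search results are independent of file order.
#'
#' @param evidenceFiles character vector of evidence file paths (the
#'   dialect of [writeEvidence()]).
#' @param sampleIds parallel character vector of unique sample ids;
#'   defaults to the file base names stripped of extensions.
#' @return A [CohortIndex-class].
#' @export
buildCohortIndex <- function(evidenceFiles,
                             sampleIds = sub("\\.bed(\\.gz)?$", "",
                                             basename(evidenceFiles))) {
    if (length(evidenceFiles) != length(sampleIds))
        stop("evidenceFiles and sampleIds must be parallel")
    if (anyDuplicated(sampleIds))
        stop("duplicate sample ids: ",
             paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
    recs <- lapply(evidenceFiles, readEvidence)
    n <- vapply(recs, nrow, integer(1))
    records <- do.call(rbind, c(recs, list(emptyEvidence())))
    records$sample_id <- rep(sampleIds, n)
    records$rid <- seq_len(nrow(records))
    manifest <- data.frame(sample_id = as.character(sampleIds),
                           file = as.character(evidenceFiles),
                           n_records = n, stringsAsFactors = FALSE)
    new("CohortIndex", records = records, ends = .endsGRanges(records),
        manifest = manifest,
        params = list(version = .INDEX_FORMAT_VERSION))
}

.hitFrame <- function(records, idx, side) {
    out <- records[idx, c("rid", "sample_id", .EVIDENCE_COLS), drop = FALSE]
    out$matched_end <- side
    o <- order(out$rid, out$matched_end, method = "radix")
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Search the index with a probe interval
#'
#' Returns one hit per record end whose interval overlaps the probe under
#' half-open semantics (`a.start < b.end && b.start < a.end`); a record
#' whose two ends both overlap yields two hits, distinguished by
#' `matched_end`. Unknown chromosomes give an empty result.
#'
#' @param index a [CohortIndex-class].
#' @param chrom probe chromosome.
#' @param start,end probe interval, 0-based half-open, `start < end`.
#' @return data.frame of hits: `rid`, `sample_id`, the nine record
#'   columns, and `matched_end`.
#' @seealso [bruteForceSearch()] for the oracle equivalent.
#' @export
searchHits <- function(index, chrom, start, end) {
    stopifnot(is(index, "CohortIndex"), start < end)
    records <- index@records
    if (nrow(records) == 0L ||
        !(chrom %in% GenomeInfoDb::seqlevels(index@ends)))
        return(.hitFrame(records, integer(), character()))
    probe <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(start + 1L, end))
    ov <- GenomicRanges::findOverlaps(probe, index@ends)
    j <- S4Vectors::subjectHits(ov)
    side <- S4Vectors::mcols(index@ends)$side[j]
    idx <- match(S4Vectors::mcols(index@ends)$rid[j], records$rid)
    .hitFrame(records, idx, side)
}

## Plain-arithmetic overlap scan over a pooled record table; the
## independent twin of searchHits used for oracle testing and as the
## brute-force query path.
.bruteScan <- function(records, chrom, start, end) {
    hitL <- which(records$left_chrom == chrom &
                  records$left_start < end & start < records$left_end)
    hitR <- which(records$right_chrom == chrom &
                  records$right_start < end & start < records$right_end)
    .hitFrame(records, c(hitL, hitR),
              c(rep("left", length(hitL)), rep("right", length(hitR))))
}

#' Brute-force evidence search (oracle)
#'
#' Linearly scans every record of every evidence file and applies the same
#' half-open overlap predicate as [searchHits()], by direct arithmetic
#' comparison. For all probes the hit multiset equals the indexed search;
#' the scan exists as the independent correctness oracle.
#'
#' @inheritParams buildCohortIndex
#' @inheritParams searchHits
#' @param records optional pre-pooled record table from
#'   [poolEvidence()], to avoid re-reading the files on every probe of a
#'   repeated oracle comparison.
#' @return data.frame of hits with the same columns as [searchHits()].
#' @export
bruteForceSearch <- function(evidenceFiles, chrom, start, end,
                             sampleIds = sub("\\.bed(\\.gz)?$", "",
                                             basename(evidenceFiles)),
                             records = NULL) {
    stopifnot(start < end)
    if (is.null(records))
        records <- poolEvidence(evidenceFiles, sampleIds)
    .bruteScan(records, chrom, start, end)
}

#' @rdname bruteForceSearch
#' @export
poolEvidence <- function(evidenceFiles,
                         sampleIds = sub("\\.bed(\\.gz)?$", "",
                                         basename(evidenceFiles))) {
    recs <- lapply(evidenceFiles, readEvidence)
    n <- vapply(recs, nrow, integer(1))
    records <- do.call(rbind, c(recs, list(emptyEvidence())))
    records$sample_id <- rep(sampleIds, n)
    records$rid <- seq_len(nrow(records))
    records
}

#' Persist / reload a cohort index
#'
#' The on-disk layout is a directory holding a JSON manifest
#' (format version, per-sample files and record counts) and one
#' tab-separated record shard per left-end chromosome. The format is
#' versioned and self-contained; a reloaded index searches identically to
#' the in-memory original.
#'
#' @param index a [CohortIndex-class].
#' @param dir index directory (created if needed).
#' @return `saveCohortIndex` returns `dir` invisibly; `loadCohortIndex`
#'   returns the reloaded [CohortIndex-class].
#' @export
saveCohortIndex <- function(index, dir) {
    stopifnot(is(index, "CohortIndex"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    records <- index@records
    chroms <- sort(unique(records$left_chrom), method = "radix")
    shards <- sprintf("shard-%s.tsv", chroms)
    for (i in seq_along(chroms)) {
        shard <- records[records$left_chrom == chroms[i],
                         c("rid", "sample_id", .EVIDENCE_COLS), drop = FALSE]
        utils::write.table(shard, file.path(dir, shards[i]), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    meta <- list(format = "svidx-cohort-index",
                 version = .INDEX_FORMAT_VERSION,
                 shards = as.list(shards),
                 manifest = index@manifest)
    jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' @rdname saveCohortIndex
#' @export
loadCohortIndex <- function(dir) {
    metaPath <- file.path(dir, "manifest.json")
    if (!file.exists(metaPath))
        stop("not an index directory (no manifest.json): ", dir)
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    if (!identical(meta$format, "svidx-cohort-index"))
        stop("unrecognized index format in ", dir)
    if (meta$version > .INDEX_FORMAT_VERSION)
        stop("index format version ", meta$version, " is newer than supported")
    shards <- lapply(meta$shards, function(s) {
        utils::read.table(file.path(dir, s), sep = "\t", header = TRUE,
                          colClasses = c("integer", "character",
                                         "character", "integer", "integer",
                                         "integer", "character", "integer",
                                         "integer", "integer", "character"),
                          stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, shards)
    if (is.null(records)) {
        records <- emptyEvidence()
        records$sample_id <- character()
        records$rid <- integer()
    }
    records <- records[order(records$rid), , drop = FALSE]
    rownames(records) <- NULL
    records <- records[, c(.EVIDENCE_COLS, "sample_id", "rid")]
    manifest <- as.data.frame(meta$manifest, stringsAsFactors = FALSE)
    new("CohortIndex", records = records, ends = .endsGRanges(records),
        manifest = manifest, params = list(version = meta$version))
}
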