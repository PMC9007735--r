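## Query semantics: PED sample database, SV-type-specific breakpoint
## extension, strand-configuration matching, both-end overlap, and
## per-sample counting with zero-count samples reported.

#' Parse a region string
#'
#' Regions are given as `chrom:start-end`, 1-based inclusive (the usual
#' command-line convention), and converted to 0-based half-open.
#'
#' @param text region string, e.g. `"14:68603030-68603035"`.
#' @return list with `chrom`, `start` and `end` (0-based half-open).
#' @examples
#' parseRegion("14:68603030-68603035")  # start 68603029, end 68603035
#' @export
parseRegion <- function(text) {
    m <- regmatches(text, regexec("^(.+):([0-9]+)-([0-9]+)$", text))[[1L]]
    if (length(m) != 4L)
        stop("malformed region (expected chrom:start-end): ", text)
    start1 <- as.numeric(m[3L]); end1 <- as.numeric(m[4L])
    if (start1 < 1 || start1 > end1)
        stop("invalid region bounds (need 1 <= start <= end): ", text)
    list(chrom = m[2L], start = start1 - 1, end = end1)
}

#' Load a PED sample database
#'
#' The PED file is tab-separated with a header row and one row per
#' sample; the first column is the sample name and `bedColumn` names the
#' 1-based column holding the sample's evidence file. All columns are
#' preserved as metadata.
#'
#' @param path PED file path.
#' @param bedColumn 1-based index of the evidence-file column.
#' @return data.frame with one row per sample, all PED columns, plus an
#'   `evidence_file` column (a copy of column `bedColumn`); the attribute
#'   `"bed_column"` records the chosen column name.
#' @export
loadPed <- function(path, bedColumn) {
    if (!file.exists(path)) stop("cannot read PED file: ", path)
    ped <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(ped) < 2L)
        stop("PED file must have a header and at least 2 columns: ", path)
    if (bedColumn < 1L || bedColumn > ncol(ped))
        stop(sprintf("bedColumn %d out of range (PED has %d columns)",
                     bedColumn, ncol(ped)))
    if (anyDuplicated(ped[[1L]]))
        stop("duplicate sample names in PED: ",
             paste(unique(ped[[1L]][duplicated(ped[[1L]])]), collapse = ", "))
    ped$evidence_file <- ped[[bedColumn]]
    attr(ped, "bed_column") <- names(ped)[bedColumn]
    ped
}

#' Extend query breakpoints by SV type
#'
#' Applies the type-specific search-window extension: deletions extend the
#' left coordinate downstream and the right coordinate upstream;
#' duplications the left upstream and the right downstream; inversions
#' produce two probe pairs, both coordinates extended downstream for +
#' strand evidence and upstream for - strand evidence; break-end
#' coordinates are not modified. Starts are clamped at 0.
#'
#' @param q an [SVQuery-class].
#' @return list of probe triples; each has `left` and `right`
#'   (`list(chrom, start, end)`, 0-based half-open) and `sign` (`"+"`/
#'   `"-"` for the two inversion sub-queries, `NA` otherwise).
#' @export
extendQuery <- function(q) {
    stopifnot(is(q, "SVQuery"))
    w <- q@window
    probe <- function(chrom, s, e) list(chrom = chrom, start = max(0, s),
                                        end = e)
    L <- function(ds, de) probe(q@leftChrom, q@leftStart + ds,
                                q@leftEnd + de)
    R <- function(ds, de) probe(q@rightChrom, q@rightStart + ds,
                                q@rightEnd + de)
    switch(q@svType,
        DEL = list(list(left = L(0, w), right = R(-w, 0), sign = NA)),
        DUP = list(list(left = L(-w, 0), right = R(0, w), sign = NA)),
        INV = list(list(left = L(0, w), right = R(0, w), sign = "+"),
                   list(left = L(-w, 0), right = R(-w, 0), sign = "-")),
        BND = list(list(left = L(0, 0), right = R(0, 0), sign = NA)))
}

#' Match an evidence record's strand configuration to an SV type
#'
#' Strand requirements per type, with strands taken in genome order:
#' deletions need +/- paired-end and +/+ or -/- split alignments;
#' duplications -/+ paired-end and +/+ or -/- split; inversions +/+ or
#' -/- paired-end and +/- or -/+ split; break ends accept any
#' configuration (overlap of both query coordinates is their only
#' requirement).
#'
#' @param records evidence data.frame rows (needs `left_strand`,
#'   `right_strand`, `class`).
#' @param svType `"DEL"`, `"DUP"`, `"INV"` or `"BND"`.
#' @return logical vector, one element per record.
#' @export
matchStrandConfig <- function(records, svType) {
    ls <- records$left_strand; rs <- records$right_strand
    pe <- records$class == "pairend"
    same <- ls == rs
    switch(svType,
        DEL = ifelse(pe, ls == 1L & rs == -1L, same),
        DUP = ifelse(pe, ls == -1L & rs == 1L, same),
        INV = ifelse(pe, same, !same),
        BND = rep(TRUE, nrow(records)),
        stop("unknown SV type: ", svType))
}

## half-open interval overlap of one record end against a probe
.overlapsProbe <- function(chrom, start, end, probe) {
    chrom == probe$chrom & start < probe$end & probe$start < end
}

## the +/- inversion sub-queries select records by orientation: +/+
## pairend and +- split evidence belong to the downstream (+) probe pair,
## -/- pairend and -+ split to the upstream (-) pair
.invSignMatch <- function(records, sign) {
    if (is.na(sign)) return(rep(TRUE, nrow(records)))
    if (sign == "+") records$left_strand == 1L else records$left_strand == -1L
}

#' Query the cohort for SV evidence
#'
#' Implements the full query semantics: the index is searched with the
#' (type-extended) left coordinate; hits are retained when the record's
#' other end also overlaps the right coordinate and its strand
#' configuration matches the SV type; each evidence record is counted at
#' most once per query; counts are split by evidence class and reported
#' for every sample of the database, zeros included.
#'
#' @param index a [CohortIndex-class].
#' @param samples PED data.frame from [loadPed()] (or any data.frame whose
#'   first column is the sample name and that carries an `evidence_file`
#'   column naming the indexed file).
#' @param q an [SVQuery-class].
#' @param method `"index"` (default) searches the built index;
#'   `"bruteforce"` runs the identical retention logic over a linear scan
#'   of all records, as an independent path for verification.
#' @return A `QueryResult` data.frame: `Id` (0-based row id), all PED
#'   metadata columns, `Pairend` and `Split` support counts.
#' @export
runQuery <- function(index, samples, q, method = c("index", "bruteforce")) {
    method <- match.arg(method)
    stopifnot(is(index, "CohortIndex"), is(q, "SVQuery"))
    man <- index@manifest
    sampleNames <- samples[[1L]]
    evFiles <- if ("evidence_file" %in% names(samples))
        samples$evidence_file else samples[[ncol(samples)]]
    sampleKey <- match(basename(evFiles), basename(man$file))
    if (anyNA(sampleKey))
        stop("PED samples without indexed evidence files: ",
             paste(sampleNames[is.na(sampleKey)], collapse = ", "))
    indexIds <- man$sample_id[sampleKey]
    records <- index@records
    triples <- extendQuery(q)
    keepRid <- integer()
    for (tr in triples) {
        cand <- if (method == "index")
            searchHits(index, tr$left$chrom, tr$left$start, tr$left$end)
        else
            .bruteScan(records, tr$left$chrom, tr$left$start, tr$left$end)
        if (nrow(cand) == 0L) next
        cand <- cand[!duplicated(cand$rid), , drop = FALSE]
        ok <- .overlapsProbe(cand$left_chrom, cand$left_start,
                             cand$left_end, tr$left) &
            .overlapsProbe(cand$right_chrom, cand$right_start,
                           cand$right_end, tr$right) &
            matchStrandConfig(cand, q@svType) &
            .invSignMatch(cand, tr$sign)
        keepRid <- c(keepRid, cand$rid[ok])
    }
    keepRid <- unique(keepRid)
    kept <- records[match(keepRid, records$rid), , drop = FALSE]
    peCount <- table(factor(kept$sample_id[kept$class == "pairend"],
                            levels = man$sample_id))
    spCount <- table(factor(kept$sample_id[kept$class == "split"],
                            levels = man$sample_id))
    meta <- samples[, setdiff(names(samples), "evidence_file"),
                    drop = FALSE]
    out <- cbind(data.frame(Id = seq_along(sampleNames) - 1L), meta,
                 data.frame(
                     Pairend = as.integer(peCount[match(indexIds,
                                                        man$sample_id)]),
                     Split = as.integer(spCount[match(indexIds,
                                                      man$sample_id)])))
    rownames(out) <- NULL
    out
}

#' Format a query result
#'
#' Tab-separated text: a header then one row per sample with the metadata
#' columns followed by `Pairend` and `Split`. In summary mode a single
#' line reports `n_samples_with_evidence`, `total_pairend` and
#' `total_split`.
#'
#' @param result a `QueryResult` data.frame from [runQuery()].
#' @param summary emit the one-line aggregate instead of the table.
#' @return character vector of output lines.
#' @export
formatResult <- function(result, summary = FALSE) {
    if (summary) {
        nWith <- sum(result$Pairend + result$Split > 0)
        return(sprintf("n_samples_with_evidence\t%d\ttotal_pairend\t%d\ttotal_split\t%d",
                       nWith, sum(result$Pairend), sum(result$Split)))
    }
    header <- paste(names(result), collapse = "\t")
    if (nrow(result) == 0L) return(header)
    c(header,
      do.call(paste, c(unname(as.list(result)), sep = "\t")))
}
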