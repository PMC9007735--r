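## Evidence extraction: scan per-sample alignments, classify discordant
## pairs and split reads as SV evidence, and read/write the sorted
## per-sample evidence dialect.

.EVIDENCE_COLS <- c("left_chrom", "left_start", "left_end", "left_strand",
                    "right_chrom", "right_start", "right_end", "right_strand",
                    "class")

#' An empty evidence record table
#'
#' Evidence records are data.frames with nine columns: the two genome-ordered
#' end intervals (`left_*`, `right_*`; 0-based half-open, strands coded
#' +1/-1) and `class` (`"pairend"` or `"split"`).
#'
#' @return A zero-row evidence data.frame.
#' @export
emptyEvidence <- function() {
    data.frame(left_chrom = character(), left_start = integer(),
               left_end = integer(), left_strand = integer(),
               right_chrom = character(), right_start = integer(),
               right_end = integer(), right_strand = integer(),
               class = character(), stringsAsFactors = FALSE)
}

## vectorized bytewise (C-locale) comparison: a strictly before b
.bytewiseLt <- function(a, b) {
    lv <- sort(unique(c(a, b)), method = "radix")
    match(a, lv) < match(b, lv)
}

#' Estimate the insert-size model from concordant fragment lengths
#'
#' Computes the sample mean and standard deviation of the supplied outer
#' fragment spans and sets the discordant distance to
#' `round(mean + 2 * sd)`: the recommended threshold beyond which a
#' same-chromosome +/- pair is treated as discordant.
#'
#' @param fragmentLengths integer vector of outer spans of concordant
#'   pairs, in bp; at least two values.
#' @return An [InsertSizeModel-class].
#' @examples
#' estimateInsertModel(c(280, 300, 320))
#' @export
estimateInsertModel <- function(fragmentLengths) {
    fragmentLengths <- as.numeric(fragmentLengths)
    if (length(fragmentLengths) < 2L)
        stop("insufficient data: need at least 2 concordant fragment lengths")
    if (any(fragmentLengths <= 0))
        stop("fragment lengths must be positive")
    m <- mean(fragmentLengths)
    s <- stats::sd(fragmentLengths)
    insertSizeModel(m, s, round(m + 2 * s))
}

## Pair-level discordance: not +/- in genome order, interchromosomal, or
## outer span beyond the discordant distance. Vectorized over templates.
.pairendCriterion <- function(c1, s1, e1, st1, c2, s2, e2, st2, dd) {
    inter <- c1 != c2
    ## genome order of the two reads
    lt <- .bytewiseLt(c1, c2) |
        (c1 == c2 & (s1 < s2 | (s1 == s2 & e1 <= e2)))
    firstStrand <- ifelse(lt, st1, st2)
    secondStrand <- ifelse(lt, st2, st1)
    badStrand <- !(firstStrand == 1L & secondStrand == -1L)
    outer <- pmax(e1, e2) - pmin(s1, s2)
    farApart <- !inter & outer > dd
    inter | badStrand | farApart
}

## Breakpoint padding for pairend ends: a + end is extended downstream to
## start + discordantDistance, a - end upstream to end - discordantDistance
## (clamped at 0), so a breakpoint anywhere the fragment could span
## overlaps the record. The read's own span is always retained.
.padEnd <- function(start, end, strand, dd) {
    ps <- ifelse(strand == 1L, start, pmax(0, pmin(start, end - dd)))
    pe <- ifelse(strand == 1L, pmax(end, start + dd), end)
    list(start = ps, end = pe)
}

## Build genome-ordered pairend records from two read spans (vectorized).
.pairendRecords <- function(c1, s1, e1, st1, c2, s2, e2, st2, dd) {
    lt <- .bytewiseLt(c1, c2) |
        (c1 == c2 & (s1 < s2 | (s1 == s2 & e1 <= e2)))
    lc <- ifelse(lt, c1, c2); ls <- ifelse(lt, s1, s2)
    le <- ifelse(lt, e1, e2); lst <- ifelse(lt, st1, st2)
    rc <- ifelse(lt, c2, c1); rs <- ifelse(lt, s2, s1)
    re <- ifelse(lt, e2, e1); rst <- ifelse(lt, st2, st1)
    lp <- .padEnd(ls, le, lst, dd)
    rp <- .padEnd(rs, re, rst, dd)
    ## keep the genome ordering of the record ends intact under padding
    same <- lc == rc
    rpStart <- ifelse(same, pmax(rp$start, lp$start), rp$start)
    data.frame(left_chrom = lc, left_start = as.integer(lp$start),
               left_end = as.integer(lp$end), left_strand = as.integer(lst),
               right_chrom = rc, right_start = as.integer(rpStart),
               right_end = as.integer(rp$end), right_strand = as.integer(rst),
               class = rep("pairend", length(lc)),
               stringsAsFactors = FALSE)
}

## Split records: exact spans of the two aligned segments, genome-ordered,
## never padded.
.splitRecords <- function(c1, s1, e1, st1, c2, s2, e2, st2) {
    lt <- .bytewiseLt(c1, c2) |
        (c1 == c2 & (s1 < s2 | (s1 == s2 & e1 <= e2)))
    data.frame(left_chrom = ifelse(lt, c1, c2),
               left_start = as.integer(ifelse(lt, s1, s2)),
               left_end = as.integer(ifelse(lt, e1, e2)),
               left_strand = as.integer(ifelse(lt, st1, st2)),
               right_chrom = ifelse(lt, c2, c1),
               right_start = as.integer(ifelse(lt, s2, s1)),
               right_end = as.integer(ifelse(lt, e2, e1)),
               right_strand = as.integer(ifelse(lt, st2, st1)),
               class = rep("split", length(c1)),
               stringsAsFactors = FALSE)
}

#' Classify one alignment as SV evidence
#'
#' Applies the discordance criteria to an alignment view: the record is
#' pair-level evidence (`"pairend"`) when its strand configuration in
#' genome order is not +/-, its mate maps to another chromosome, or the
#' outer span of the pair exceeds the model's discordant distance; it
#' additionally (or solely) carries `"split"` evidence when the read has a
#' supplementary (split) segment. Concordant, non-split alignments yield
#' the empty set.
#'
#' @param aln a one-or-more-row alignment view data.frame with columns
#'   `chrom,start,end,strand` (0-based half-open, strand +1/-1), `paired`
#'   (logical), `mate_chrom,mate_start,mate_end,mate_strand` (NA when
#'   unpaired; `mate_end` may be NA, in which case the mate is assumed to
#'   span the read's own length), `has_split` and, when split,
#'   `split_chrom,split_start,split_end,split_strand`.
#' @param model an [InsertSizeModel-class].
#' @return For a single-row `aln`, a character vector (subset of
#'   `c("pairend", "split")`); for multiple rows, a list of such vectors.
#' @export
classifyAlignment <- function(aln, model) {
    stopifnot(is(model, "InsertSizeModel"))
    n <- nrow(aln)
    if (n == 0L) return(list())
    mateEnd <- aln$mate_end
    if (is.null(mateEnd)) mateEnd <- rep(NA_real_, n)
    mateEnd <- ifelse(is.na(mateEnd),
                      aln$mate_start + (aln$end - aln$start), mateEnd)
    hasMate <- !is.na(aln$mate_chrom) &
        (if (is.null(aln$paired)) TRUE else aln$paired)
    pe <- rep(FALSE, n)
    if (any(hasMate))
        pe[hasMate] <- .pairendCriterion(
            aln$chrom[hasMate], aln$start[hasMate], aln$end[hasMate],
            aln$strand[hasMate], aln$mate_chrom[hasMate],
            aln$mate_start[hasMate], mateEnd[hasMate],
            aln$mate_strand[hasMate], discordantDistance(model))
    sp <- if (is.null(aln$has_split)) rep(FALSE, n) else
        !is.na(aln$has_split) & aln$has_split
    out <- lapply(seq_len(n), function(i)
        c("pairend"[pe[i]], "split"[sp[i]]))
    if (n == 1L) out[[1L]] else out
}

#' Build evidence records for a classified alignment
#'
#' Produces one [emptyEvidence()]-schema record per evidence class. Pairend
#' records carry the two read spans, genome-ordered and breakpoint-padded:
#' a + end is extended downstream to `start + discordantDistance`, a - end
#' upstream to `end - discordantDistance` (clamped at 0), so the record
#' overlaps any breakpoint the fragment could span. Split records use the
#' exact spans of the two aligned segments, unpadded.
#'
#' @param aln a single-row alignment view (see [classifyAlignment()]).
#' @param classes character vector of classes to emit (non-empty subset of
#'   `c("pairend", "split")`).
#' @param model an [InsertSizeModel-class].
#' @return An evidence data.frame with one row per class.
#' @export
makeEvidenceRecords <- function(aln, classes, model) {
    stopifnot(nrow(aln) == 1L, length(classes) >= 1L,
              all(classes %in% c("pairend", "split")))
    dd <- discordantDistance(model)
    out <- emptyEvidence()
    if ("pairend" %in% classes) {
        if (is.na(aln$mate_chrom))
            stop("pairend record requested for an alignment without a mate")
        mateEnd <- if (!is.null(aln$mate_end) && !is.na(aln$mate_end))
            aln$mate_end else aln$mate_start + (aln$end - aln$start)
        out <- rbind(out, .pairendRecords(
            aln$chrom, aln$start, aln$end, aln$strand,
            aln$mate_chrom, aln$mate_start, mateEnd, aln$mate_strand, dd))
    }
    if ("split" %in% classes) {
        if (is.null(aln$split_chrom) || is.na(aln$split_chrom))
            stop("split record requested for an alignment without a split segment")
        out <- rbind(out, .splitRecords(
            aln$chrom, aln$start, aln$end, aln$strand,
            aln$split_chrom, aln$split_start, aln$split_end,
            aln$split_strand))
    }
    out
}

#' Extract evidence records from a template table
#'
#' Template-level core of the extractor: one row per sequenced template
#' (read pair), with optional split-segment columns per read. A template
#' that is both distance-discordant and split yields one pairend and one
#' split record; when both reads are split only the genome-leftmost split
#' read is emitted, so no template is double-counted.
#'
#' @param templates data.frame with columns `r1_chrom,r1_start,r1_end,
#'   r1_strand` and the same for `r2` (NA when the template has a single
#'   mapped read), plus optional `r1_schrom,r1_sstart,r1_send,r1_sstrand`
#'   (supplementary segment of read 1; NA when absent) and the `r2_s*`
#'   equivalents.
#' @param model an [InsertSizeModel-class].
#' @return A sorted evidence data.frame (see [sortEvidence()]).
#' @export
extractEvidenceFromTemplates <- function(templates, model) {
    stopifnot(is(model, "InsertSizeModel"))
    dd <- discordantDistance(model)
    n <- nrow(templates)
    if (n == 0L) return(emptyEvidence())
    col <- function(nm) if (nm %in% names(templates)) templates[[nm]] else
        rep(NA, n)
    r2c <- col("r2_chrom")
    paired <- !is.na(r2c)
    pe <- rep(FALSE, n)
    if (any(paired))
        pe[paired] <- .pairendCriterion(
            templates$r1_chrom[paired], templates$r1_start[paired],
            templates$r1_end[paired], templates$r1_strand[paired],
            r2c[paired], col("r2_start")[paired], col("r2_end")[paired],
            col("r2_strand")[paired], dd)
    out <- list()
    if (any(pe))
        out$pairend <- .pairendRecords(
            templates$r1_chrom[pe], templates$r1_start[pe],
            templates$r1_end[pe], templates$r1_strand[pe],
            r2c[pe], col("r2_start")[pe], col("r2_end")[pe],
            col("r2_strand")[pe], dd)
    s1 <- !is.na(col("r1_schrom"))
    s2 <- !is.na(col("r2_schrom"))
    ## one split record per template: when both reads are split, keep the
    ## read whose primary alignment is genome-leftmost
    r1First <- rep(TRUE, n)
    both <- which(s1 & s2)
    if (length(both))
        r1First[both] <-
            .bytewiseLt(templates$r1_chrom[both], r2c[both]) |
            (templates$r1_chrom[both] == r2c[both] &
             templates$r1_start[both] <= col("r2_start")[both])
    useR1 <- s1 & (!s2 | r1First)
    useR2 <- s2 & !useR1
    sp <- list()
    if (any(useR1))
        sp$r1 <- .splitRecords(
            templates$r1_chrom[useR1], templates$r1_start[useR1],
            templates$r1_end[useR1], templates$r1_strand[useR1],
            col("r1_schrom")[useR1], col("r1_sstart")[useR1],
            col("r1_send")[useR1], col("r1_sstrand")[useR1])
    if (any(useR2))
        sp$r2 <- .splitRecords(
            r2c[useR2], col("r2_start")[useR2], col("r2_end")[useR2],
            col("r2_strand")[useR2],
            col("r2_schrom")[useR2], col("r2_sstart")[useR2],
            col("r2_send")[useR2], col("r2_sstrand")[useR2])
    out <- c(out, sp)
    if (!length(out)) return(emptyEvidence())
    sortEvidence(do.call(rbind, unname(out)))
}

#' Sort evidence records
#'
#' Orders records by (left chromosome bytewise, left start, left end), the
#' C-collation sort the evidence dialect requires. The sort is stable:
#' records with equal keys keep their input order.
#'
#' @param records an evidence data.frame.
#' @return The reordered data.frame.
#' @export
sortEvidence <- function(records) {
    if (nrow(records) == 0L) return(records)
    o <- order(records$left_chrom, records$left_start, records$left_end,
               method = "radix")
    out <- records[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write / read the per-sample evidence dialect
#'
#' Nine tab-separated columns per record: `left_chrom, left_start,
#' left_end, left_strand, right_chrom, right_start, right_end,
#' right_strand, class`, with coordinates 0-based half-open, strands coded
#' `1`/`-1` and class coded `0` (pairend) / `1` (split). Files ending in
#' `.gz` are compressed transparently. The round trip is lossless.
#'
#' @param records an evidence data.frame (see [emptyEvidence()]).
#' @param path output (input) file path.
#' @return `writeEvidence` returns `path` invisibly; `readEvidence`
#'   returns the evidence data.frame.
#' @export
writeEvidence <- function(records, path) {
    stopifnot(all(.EVIDENCE_COLS %in% names(records)))
    out <- records[, .EVIDENCE_COLS]
    out$class <- ifelse(out$class == "split", 1L, 0L)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    if (nrow(out)) {
        lines <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
        writeLines(lines, con)
    }
    invisible(path)
}

#' @rdname writeEvidence
#' @export
readEvidence <- function(path) {
    if (!file.exists(path)) stop("cannot read evidence file: ", path)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
    lines <- readLines(con)
    close(con)
    if (!length(lines)) return(emptyEvidence())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 9L))
        stop(sprintf("%s: malformed evidence line %d (%d columns, expected 9)",
                     path, which(nf != 9L)[1L], nf[nf != 9L][1L]))
    m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
    strandL <- suppressWarnings(as.integer(m[, 4L]))
    strandR <- suppressWarnings(as.integer(m[, 8L]))
    bad <- which(is.na(strandL) | is.na(strandR) |
                 !(strandL %in% c(1L, -1L)) | !(strandR %in% c(1L, -1L)))
    if (length(bad))
        stop(sprintf("%s: invalid strand on line %d (must be 1 or -1)",
                     path, bad[1L]))
    cls <- suppressWarnings(as.integer(m[, 9L]))
    bad <- which(is.na(cls) | !(cls %in% c(0L, 1L)))
    if (length(bad))
        stop(sprintf("%s: invalid class on line %d (must be 0 or 1)",
                     path, bad[1L]))
    data.frame(left_chrom = m[, 1L], left_start = as.integer(m[, 2L]),
               left_end = as.integer(m[, 3L]), left_strand = strandL,
               right_chrom = m[, 5L], right_start = as.integer(m[, 6L]),
               right_end = as.integer(m[, 7L]), right_strand = strandR,
               class = ifelse(cls == 1L, "split", "pairend"),
               stringsAsFactors = FALSE)
}

#' Extract SV evidence from an alignment file
#'
#' Runs the full extraction stage over a SAM or BAM file: alignments are
#' filtered (secondary, duplicate and QC-fail records dropped; optional
#' mapping-quality threshold), primaries are paired by template name,
#' supplementary segments are attached to their reads, each template is
#' classified by the discordance criteria, and the resulting records are
#' sorted and written in the evidence dialect. The output is a pure
#' function of the input file, model and filters.
#'
#' @param alignmentFile path to a SAM or BAM file (mate information
#'   required for paired records).
#' @param model an [InsertSizeModel-class].
#' @param out output evidence file path (`.gz` for compressed); defaults
#'   to `<alignmentFile>.evidence.bed`.
#' @param minMapq optional minimum mapping quality; `NULL` (default)
#'   applies no threshold.
#' @return The output path, invisibly.
#' @export
extractEvidence <- function(alignmentFile, model,
                            out = paste0(alignmentFile, ".evidence.bed"),
                            minMapq = NULL) {
    templates <- .readTemplates(alignmentFile, minMapq = minMapq)
    records <- extractEvidenceFromTemplates(templates, model)
    writeEvidence(records, out)
    invisible(out)
}

#' Estimate the insert-size model from an alignment file
#'
#' Measures outer spans of the first `maxPairs` concordant (same
#' chromosome, +/- in genome order) primary pairs and calls
#' [estimateInsertModel()].
#'
#' @inheritParams extractEvidence
#' @param maxPairs maximum number of concordant pairs to measure
#'   (default 100000).
#' @return An [InsertSizeModel-class].
#' @export
estimateInsertModelFromFile <- function(alignmentFile, maxPairs = 100000L) {
    tm <- .readTemplates(alignmentFile)
    ok <- !is.na(tm$r2_chrom) & tm$r1_chrom == tm$r2_chrom
    tm <- tm[ok, , drop = FALSE]
    lt <- tm$r1_start <= tm$r2_start
    firstStrand <- ifelse(lt, tm$r1_strand, tm$r2_strand)
    secondStrand <- ifelse(lt, tm$r2_strand, tm$r1_strand)
    conc <- firstStrand == 1L & secondStrand == -1L
    spans <- (pmax(tm$r1_end, tm$r2_end) - pmin(tm$r1_start, tm$r2_start))[conc]
    estimateInsertModel(utils::head(spans, maxPairs))
}
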