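## Cohort-level evaluation: sample-classification confusion counts and
## derived metrics, reciprocal-overlap set operations, germline filtering
## of a tumor call set against a panel of normals, query-resolution
## sweeps, and per-SV evidence summaries.

#' Sample-level confusion counts
#'
#' Given the set of samples with supporting evidence, the set of true
#' carrier (non-reference) samples, and the full cohort, computes
#' P = number of carriers, N = cohort size minus P,
#' TP = evidence-and-carrier, FP = evidence-not-carrier,
#' FN = carrier-without-evidence, TN = N - FP.
#'
#' @param evidenceSamples character vector of samples with evidence.
#' @param truthSamples character vector of carrier samples.
#' @param cohort character vector of all cohort samples; both sets must
#'   be subsets of it.
#' @return A [ConfusionCounts-class].
#' @examples
#' confusionCounts(c("a","b","c","e"), c("a","b","c","d"), letters[1:10])
#' @export
confusionCounts <- function(evidenceSamples, truthSamples, cohort) {
    evidenceSamples <- unique(evidenceSamples)
    truthSamples <- unique(truthSamples)
    cohort <- unique(cohort)
    if (!all(evidenceSamples %in% cohort) || !all(truthSamples %in% cohort))
        stop("evidence and truth samples must be subsets of the cohort")
    P <- length(truthSamples)
    N <- length(cohort) - P
    TP <- length(intersect(evidenceSamples, truthSamples))
    FP <- length(setdiff(evidenceSamples, truthSamples))
    FN <- length(setdiff(truthSamples, evidenceSamples))
    new("ConfusionCounts", P = as.integer(P), N = as.integer(N),
        TP = as.integer(TP), TN = as.integer(N - FP), FP = as.integer(FP),
        FN = as.integer(FN))
}

#' Sum confusion counts
#'
#' Aggregates per-SV confusion counts into per-type totals.
#'
#' @param ... [ConfusionCounts-class] objects (or a single list of them).
#' @return A [ConfusionCounts-class] of the summed counts.
#' @export
sumConfusion <- function(...) {
    xs <- list(...)
    if (length(xs) == 1L && is.list(xs[[1L]])) xs <- xs[[1L]]
    tot <- function(slot) sum(vapply(xs, function(x) methods::slot(x, slot),
                                     integer(1)))
    new("ConfusionCounts", P = tot("P"), N = tot("N"), TP = tot("TP"),
        TN = tot("TN"), FP = tot("FP"), FN = tot("FN"))
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP + TN) / (P + N); precision = TP / (TP + FP);
#' sensitivity = TP / P; specificity = TN / N;
#' F1 = 2 TP / (2 TP + FP + FN). A zero denominator yields `NA`
#' (undefined), never a silent 0.
#'
#' @param cc a [ConfusionCounts-class].
#' @return named numeric vector `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `f1`, each in `[0, 1]` or `NA`.
#' @export
svMetrics <- function(cc) {
    stopifnot(is(cc, "ConfusionCounts"))
    div <- function(num, den) if (den == 0) NA_real_ else num / den
    c(accuracy = div(cc@TP + cc@TN, cc@P + cc@N),
      precision = div(cc@TP, cc@TP + cc@FP),
      sensitivity = div(cc@TP, cc@P),
      specificity = div(cc@TN, cc@N),
      f1 = div(2 * cc@TP, 2 * cc@TP + cc@FP + cc@FN))
}

#' Reciprocal overlap of two intervals
#'
#' `min(overlap / length(a), overlap / length(b))` where `overlap` is the
#' shared length; intervals on different chromosomes overlap 0. The
#' measure is symmetric. Vectorized with recycling.
#'
#' @param chromA,startA,endA first interval(s), 0-based half-open.
#' @param chromB,startB,endB second interval(s).
#' @return numeric fraction(s) in `[0, 1]`.
#' @examples
#' reciprocalOverlap("1", 0, 100, "1", 10, 110)  # 0.9
#' @export
reciprocalOverlap <- function(chromA, startA, endA, chromB, startB, endB) {
    ov <- pmax(0, pmin(endA, endB) - pmax(startA, startB))
    ifelse(chromA == chromB,
           pmin(ov / (endA - startA), ov / (endB - startB)), 0)
}

#' Read an SV call set from BED / BEDPE
#'
#' `readSVBed` reads 3+ column BED with the SV type in column 4 (intervals
#' are taken as the left/right breakpoint span of an intrachromosomal SV).
#' `readBedpe` reads minimal BEDPE: chrom1, start1, end1, chrom2, start2,
#' end2 and the SV type in column 7.
#'
#' @param path input file.
#' @return data.frame of SV intervals: `chrom`, `start`, `end`,
#'   `sv_type` (BED) or additionally `chrom2`, `start2`, `end2` (BEDPE).
#' @export
readSVBed <- function(path) {
    if (!file.exists(path)) stop("cannot read BED file: ", path)
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 3L) stop("BED needs at least 3 columns: ", path)
    data.frame(chrom = as.character(raw[[1L]]),
               start = as.integer(raw[[2L]]), end = as.integer(raw[[3L]]),
               sv_type = if (ncol(raw) >= 4L) as.character(raw[[4L]]) else
                   NA_character_,
               stringsAsFactors = FALSE)
}

#' @rdname readSVBed
#' @export
readBedpe <- function(path) {
    if (!file.exists(path)) stop("cannot read BEDPE file: ", path)
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 6L) stop("BEDPE needs at least 6 columns: ", path)
    data.frame(chrom = as.character(raw[[1L]]),
               start = as.integer(raw[[2L]]), end = as.integer(raw[[3L]]),
               chrom2 = as.character(raw[[4L]]),
               start2 = as.integer(raw[[5L]]), end2 = as.integer(raw[[6L]]),
               sv_type = if (ncol(raw) >= 7L) as.character(raw[[7L]]) else
                   NA_character_,
               stringsAsFactors = FALSE)
}

#' Reciprocal-overlap intersection and subtraction of SV sets
#'
#' An element of `A` is in the intersection when any element of `B` of the
#' same SV type reaches the reciprocal-overlap threshold (many-to-one
#' matching, the bedtools `-f x -r` convention); the subtraction is its
#' complement within `A`.
#'
#' @param A,B SV interval data.frames (`chrom`, `start`, `end`,
#'   `sv_type`).
#' @param threshold reciprocal-overlap threshold (default 0.9); matching
#'   uses `>=`.
#' @return list with `intersect` and `subtract`, both row subsets of `A`,
#'   and `inB`, the logical membership vector.
#' @export
intersectSVSets <- function(A, B, threshold = 0.9) {
    inB <- vapply(seq_len(nrow(A)), function(i) {
        cand <- B[is.na(A$sv_type[i]) | is.na(B$sv_type) |
                  B$sv_type == A$sv_type[i], , drop = FALSE]
        if (nrow(cand) == 0L) return(FALSE)
        any(reciprocalOverlap(A$chrom[i], A$start[i], A$end[i],
                              cand$chrom, cand$start, cand$end) >= threshold)
    }, logical(1))
    list(intersect = A[inB, , drop = FALSE],
         subtract = A[!inB, , drop = FALSE], inB = inB)
}

#' Per-SV evidence summary
#'
#' Condenses a query result into the two cohort-level summary statistics:
#' the number of samples with any supporting evidence and the maximum
#' per-sample evidence count (pairend + split).
#'
#' @param result a `QueryResult` data.frame from [runQuery()].
#' @return named numeric vector `n_samples_with_evidence`,
#'   `max_per_sample_evidence`.
#' @export
evidenceSummary <- function(result) {
    tot <- result$Pairend + result$Split
    c(n_samples_with_evidence = sum(tot > 0),
      max_per_sample_evidence = if (length(tot)) max(tot) else 0)
}

#' Germline filtering of a tumor call set against a panel of normals
#'
#' Each tumor call is queried against the cohort evidence index; calls
#' supported in at least `minSamples` cohort samples are filtered out as
#' (likely) germline, the rest pass. Against the somatic truth set, at the
#' reciprocal-overlap threshold: false positives are calls that passed but
#' are not in the truth, true positives passed and in the truth, false
#' negatives truth calls present in the tumor set that did not pass.
#'
#' @param tumorCalls SV interval data.frame (`chrom`, `start`, `end`,
#'   `sv_type`) of tumor-sample calls.
#' @param index a [CohortIndex-class] over the panel of normals.
#' @param samples PED data.frame for the panel.
#' @param truthCalls SV interval data.frame of true somatic SVs.
#' @param window query window in bp (default 500).
#' @param minSamples minimum number of supporting cohort samples for a
#'   call to be filtered (default 1).
#' @param threshold reciprocal-overlap threshold for the truth comparison
#'   (default 0.9).
#' @return list with `counts` (`FP`, `TP`, `FN`), `calls` (the tumor
#'   calls with `n_support_samples` and `passed` columns) and `passed`
#'   (the passed subset).
#' @export
germlineFilterEval <- function(tumorCalls, index, samples, truthCalls,
                               window = 500, minSamples = 1L,
                               threshold = 0.9) {
    nSupport <- vapply(seq_len(nrow(tumorCalls)), function(i) {
        ## 2-bp breakpoint confidence intervals straddling each junction,
        ## so exactly-abutting split segments are overlapped too
        q <- SVQuery(tumorCalls$sv_type[i], tumorCalls$chrom[i],
                     max(0, tumorCalls$start[i] - 1),
                     tumorCalls$start[i] + 1,
                     rightStart = tumorCalls$end[i] - 1,
                     rightEnd = tumorCalls$end[i] + 1, window = window)
        res <- runQuery(index, samples, q)
        sum(res$Pairend + res$Split > 0)
    }, numeric(1))
    passed <- nSupport < minSamples
    calls <- tumorCalls
    calls$n_support_samples <- nSupport
    calls$passed <- passed
    passedCalls <- calls[passed, , drop = FALSE]
    passVsTruth <- intersectSVSets(passedCalls, truthCalls, threshold)
    tumorInTruth <- intersectSVSets(calls, truthCalls, threshold)$inB
    counts <- c(FP = nrow(passVsTruth$subtract),
                TP = nrow(passVsTruth$intersect),
                FN = sum(tumorInTruth & !passed))
    list(counts = counts, calls = calls, passed = passedCalls)
}

#' Query-resolution sweep
#'
#' Shifts both breakpoint coordinates of each query jointly up- and
#' downstream in `step`-bp increments to `maxShift`, reruns the query at
#' every shift, and reports the proportion of supporting samples relative
#' to the unshifted query. Queries with no support at shift 0 are
#' undefined and excluded from the median curve.
#'
#' @param index a [CohortIndex-class].
#' @param samples PED data.frame.
#' @param queries list of [SVQuery-class] objects.
#' @param maxShift maximum shift in bp (default 500).
#' @param step shift increment in bp (default 50).
#' @return list with `shifts` (integer vector), `proportions` (matrix,
#'   queries x shifts; `NA` rows for zero-support queries) and `median`
#'   (per-shift median proportion across defined queries).
#' @export
resolutionSweep <- function(index, samples, queries, maxShift = 500,
                            step = 50) {
    shifts <- seq(-maxShift, maxShift, by = step)
    prop <- matrix(NA_real_, nrow = length(queries), ncol = length(shifts),
                   dimnames = list(NULL, as.character(shifts)))
    for (i in seq_along(queries)) {
        q <- queries[[i]]
        counts <- vapply(shifts, function(s) {
            qs <- SVQuery(q@svType, q@leftChrom,
                          max(0, q@leftStart + s), max(1, q@leftEnd + s),
                          rightChrom = q@rightChrom,
                          rightStart = max(0, q@rightStart + s),
                          rightEnd = max(1, q@rightEnd + s),
                          window = q@window)
            res <- runQuery(index, samples, qs)
            sum(res$Pairend + res$Split > 0)
        }, numeric(1))
        n0 <- counts[shifts == 0]
        if (n0 > 0) prop[i, ] <- counts / n0
    }
    med <- apply(prop, 2L, stats::median, na.rm = TRUE)
    list(shifts = shifts, proportions = prop, median = med)
}
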