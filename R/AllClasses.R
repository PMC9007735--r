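#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Fragment-size model for discordance calling
#'
#' Holds the insert-size distribution of a library (mean and standard
#' deviation of the outer fragment span of concordant pairs) together with
#' the discordant distance: the outer-span threshold beyond which a
#' same-chromosome +/- pair is deemed discordant. When estimated from data
#' the threshold is `round(mean + 2 * sd)`.
#'
#' @slot meanFragment mean outer fragment span in base pairs.
#' @slot sdFragment standard deviation of the fragment span in base pairs.
#' @slot discordantDistance discordance threshold in base pairs.
#'
#' @seealso [estimateInsertModel()], [classifyAlignment()]
#' @export
setClass("InsertSizeModel",
    representation(meanFragment = "numeric", sdFragment = "numeric",
                   discordantDistance = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@meanFragment) != 1L || object@meanFragment <= 0)
            msg <- c(msg, "meanFragment must be a single positive number")
        if (length(object@sdFragment) != 1L || object@sdFragment < 0)
            msg <- c(msg, "sdFragment must be a single non-negative number")
        if (length(object@discordantDistance) != 1L ||
            object@discordantDistance <= 0)
            msg <- c(msg, "discordantDistance must be a single positive number")
        if (is.null(msg)) TRUE else msg
    })

#' Construct an InsertSizeModel
#'
#' @param meanFragment mean fragment span (bp).
#' @param sdFragment standard deviation of the fragment span (bp).
#' @param discordantDistance discordance threshold (bp); defaults to
#'   `round(meanFragment + 2 * sdFragment)`.
#' @return An [InsertSizeModel-class] object.
#' @examples
#' insertSizeModel(300, 50)      # discordant distance 400
#' insertSizeModel(300, 50, 500) # explicit threshold
#' @export
insertSizeModel <- function(meanFragment, sdFragment,
                            discordantDistance =
                                round(meanFragment + 2 * sdFragment)) {
    new("InsertSizeModel", meanFragment = as.numeric(meanFragment),
        sdFragment = as.numeric(sdFragment),
        discordantDistance = as.numeric(discordantDistance))
}

#' @describeIn InsertSizeModel-class discordance threshold in base pairs.
#' @param object,x an `InsertSizeModel`.
#' @export
discordantDistance <- function(x) x@discordantDistance

#' @export
setMethod("show", "InsertSizeModel", function(object) {
    cat(sprintf("InsertSizeModel: fragment %.1f +/- %.1f bp, discordant distance %d bp\n",
                object@meanFragment, object@sdFragment,
                as.integer(object@discordantDistance)))
})

.SV_TYPES <- c("DEL", "DUP", "INV", "BND")

#' A structural-variant query
#'
#' An SV query names the SV type and its two breakpoints. Breakpoints are a
#' pair of left and right coordinates, each a chromosome plus a 0-based
#' half-open interval (the breakpoint confidence region). The left
#' coordinate is the genome-ordered smaller one: its chromosome compares
#' bytewise less than or equal to the right chromosome and, on the same
#' chromosome, its start is not greater. DEL/DUP/INV queries are
#' intrachromosomal; BND queries may join two chromosomes and are
#' normalized (with a warning) into genome order when supplied reversed.
#'
#' @slot svType one of `"DEL"`, `"DUP"`, `"INV"`, `"BND"`.
#' @slot leftChrom,leftStart,leftEnd left breakpoint (0-based half-open).
#' @slot rightChrom,rightStart,rightEnd right breakpoint.
#' @slot window search window in bp added around each breakpoint according
#'   to the SV type; use the extraction discordant distance (default 500).
#'
#' @seealso [extendQuery()], [runQuery()]
#' @export
setClass("SVQuery",
    representation(svType = "character",
                   leftChrom = "character", leftStart = "numeric",
                   leftEnd = "numeric",
                   rightChrom = "character", rightStart = "numeric",
                   rightEnd = "numeric", window = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (!(object@svType %in% .SV_TYPES))
            msg <- c(msg, sprintf("svType must be one of %s",
                                  paste(.SV_TYPES, collapse = ", ")))
        if (object@leftStart > object@leftEnd ||
            object@rightStart > object@rightEnd)
            msg <- c(msg, "breakpoint intervals need start <= end")
        if (object@leftStart < 0 || object@rightStart < 0)
            msg <- c(msg, "coordinates must be non-negative")
        if (object@window < 0)
            msg <- c(msg, "window must be non-negative")
        if (object@svType %in% c("DEL", "DUP", "INV") &&
            object@leftChrom != object@rightChrom)
            msg <- c(msg, "DEL/DUP/INV queries must be intrachromosomal")
        ord <- .chromLt(object@leftChrom, object@rightChrom) ||
            (object@leftChrom == object@rightChrom &&
             object@leftStart <= object@rightStart)
        if (!ord)
            msg <- c(msg, "left breakpoint must be genome-ordered before right")
        if (is.null(msg)) TRUE else msg
    })

## bytewise (C-locale) chromosome comparison, the collation the evidence
## files are sorted under
.chromLt <- function(a, b) {
    if (a == b) return(FALSE)
    order(c(a, b), method = "radix")[1L] == 1L
}

#' Construct an SVQuery
#'
#' @param svType `"DEL"`, `"DUP"`, `"INV"` or `"BND"`.
#' @param leftChrom,leftStart,leftEnd left breakpoint interval, 0-based
#'   half-open.
#' @param rightChrom,rightStart,rightEnd right breakpoint interval; for
#'   intrachromosomal types `rightChrom` defaults to `leftChrom`.
#' @param window search window in bp (default 500).
#' @return An [SVQuery-class] object, breakpoints normalized to genome
#'   order (BND queries given right-before-left are swapped with a
#'   warning).
#' @examples
#' SVQuery("DEL", "14", 68603029, 68603035,
#'         rightStart = 68603737, rightEnd = 68603743)
#' @export
SVQuery <- function(svType, leftChrom, leftStart, leftEnd,
                    rightChrom = leftChrom, rightStart, rightEnd,
                    window = 500) {
    leftChrom <- as.character(leftChrom)
    rightChrom <- as.character(rightChrom)
    swapped <- .chromLt(rightChrom, leftChrom) ||
        (leftChrom == rightChrom && rightStart < leftStart)
    if (swapped) {
        if (svType == "BND")
            warning("BND breakpoints given in reverse genome order; swapping")
        tmp <- list(leftChrom, leftStart, leftEnd)
        leftChrom <- rightChrom; leftStart <- rightStart; leftEnd <- rightEnd
        rightChrom <- tmp[[1L]]; rightStart <- tmp[[2L]]; rightEnd <- tmp[[3L]]
    }
    new("SVQuery", svType = svType, leftChrom = leftChrom,
        leftStart = as.numeric(leftStart), leftEnd = as.numeric(leftEnd),
        rightChrom = rightChrom, rightStart = as.numeric(rightStart),
        rightEnd = as.numeric(rightEnd), window = as.numeric(window))
}

#' @export
setMethod("show", "SVQuery", function(object) {
    cat(sprintf("SVQuery %s  left %s:[%d,%d)  right %s:[%d,%d)  window %d\n",
                object@svType, object@leftChrom,
                as.integer(object@leftStart), as.integer(object@leftEnd),
                object@rightChrom, as.integer(object@rightStart),
                as.integer(object@rightEnd), as.integer(object@window)))
})

#' Multi-sample evidence index
#'
#' A unified, searchable store of SV evidence records pooled across the
#' samples of a cohort. Every record of every input evidence file appears
#' exactly once, attributed to its sample; both end-intervals of each
#' record are indexed so interchromosomal records are findable from either
#' side. Search is backed by the interval-overlap machinery of
#' GenomicRanges; an independent brute-force scan ([bruteForceSearch()])
#' serves as the correctness oracle.
#'
#' @slot records data.frame of all evidence records with columns `rid`
#'   (record id), `sample_id` and the nine evidence columns (see
#'   [readEvidence()]).
#' @slot ends a [GenomicRanges::GRanges] with one range per record end
#'   (1-based closed, converted from the 0-based half-open records) and
#'   metadata columns `rid` and `side` (`"left"`/`"right"`).
#' @slot manifest data.frame with one row per indexed file: `sample_id`,
#'   `file`, `n_records`.
#' @slot params list of build parameters (format version).
#'
#' @seealso [buildCohortIndex()], [searchHits()], [runQuery()]
#' @export
setClass("CohortIndex",
    representation(records = "data.frame", ends = "ANY",
                   manifest = "data.frame", params = "list"),
    validity = function(object) {
        msg <- NULL
        if (nrow(object@manifest) &&
            anyDuplicated(object@manifest$sample_id))
            msg <- c(msg, "duplicate sample ids in manifest")
        if (sum(object@manifest$n_records) != nrow(object@records))
            msg <- c(msg, "manifest counts do not sum to the record count")
        if (is.null(msg)) TRUE else msg
    })

#' @describeIn CohortIndex-class per-file manifest (sample_id, file,
#'   n_records).
#' @param x a `CohortIndex`.
#' @export
manifest <- function(x) x@manifest

#' @describeIn CohortIndex-class all indexed records as a data.frame.
#' @export
indexRecords <- function(x) x@records

#' @export
setMethod("show", "CohortIndex", function(object) {
    cat(sprintf("CohortIndex: %d samples, %d evidence records on %d chromosome(s)\n",
                nrow(object@manifest), nrow(object@records),
                length(unique(c(object@records$left_chrom,
                                object@records$right_chrom)))))
})

#' Confusion counts for sample-level SV classification
#'
#' Positives are the non-reference (carrier) samples of the truth catalog;
#' negatives the remaining cohort samples. True positives are samples with
#' supporting evidence that are carriers in the truth set, and so on.
#'
#' @slot P,N,TP,TN,FP,FN non-negative integer counts with `TP + FN == P`
#'   and `TN + FP == N`.
#'
#' @seealso [confusionCounts()], [svMetrics()]
#' @export
setClass("ConfusionCounts",
    representation(P = "integer", N = "integer", TP = "integer",
                   TN = "integer", FP = "integer", FN = "integer"),
    validity = function(object) {
        v <- c(object@P, object@N, object@TP, object@TN, object@FP, object@FN)
        if (any(v < 0)) return("counts must be non-negative")
        if (object@TP + object@FN != object@P) return("TP + FN must equal P")
        if (object@TN + object@FP != object@N) return("TN + FP must equal N")
        TRUE
    })

#' @export
setMethod("show", "ConfusionCounts", function(object) {
    cat(sprintf("ConfusionCounts: P=%d N=%d TP=%d TN=%d FP=%d FN=%d\n",
                object@P, object@N, object@TP, object@TN, object@FP,
                object@FN))
})
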