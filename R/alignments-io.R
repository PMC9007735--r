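## SAM/BAM input for the extractor and SAM output for the simulator.
## Alignments are represented internally at template level: one row per
## read pair with optional supplementary (split) segment per read.

#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments readGAlignments
NULL

## Read a SAM/BAM file into the template table consumed by
## extractEvidenceFromTemplates(). Secondary, duplicate and QC-fail
## records are dropped (record filters); unmapped records never appear.
.readTemplates <- function(alignmentFile, minMapq = NULL) {
    if (!file.exists(alignmentFile))
        stop("cannot read alignment file: ", alignmentFile)
    bam <- alignmentFile
    if (grepl("\\.sam$", alignmentFile, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        bam <- tryCatch(
            Rsamtools::asBam(alignmentFile, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE),
            error = function(e)
                stop("failed to parse alignment file ", alignmentFile, ": ",
                     conditionMessage(e)))
    }
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "mapq"),
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE,
                                      isDuplicate = FALSE,
                                      isNotPassingQualityControls = FALSE))
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    raw <- as.data.frame(ga)
    df <- data.frame(
        qname = raw$qname,
        flag = raw$flag,
        mapq = raw$mapq,
        chrom = as.character(raw$seqnames),
        start = raw$start - 1L,   # to 0-based half-open
        end = raw$end,
        strand = ifelse(as.character(raw$strand) == "-", -1L, 1L),
        stringsAsFactors = FALSE)
    if (!is.null(minMapq))
        df <- df[is.na(df$mapq) | df$mapq >= minMapq, , drop = FALSE]
    supp <- bitwAnd(df$flag, 2048L) > 0L
    first <- bitwAnd(df$flag, 128L) == 0L   # read 1 (or unpaired)
    qn <- unique(df$qname)
    blank <- function() rep(NA_integer_, length(qn))
    blankc <- function() rep(NA_character_, length(qn))
    tm <- data.frame(qname = qn,
                     r1_chrom = blankc(), r1_start = blank(),
                     r1_end = blank(), r1_strand = blank(),
                     r1_schrom = blankc(), r1_sstart = blank(),
                     r1_send = blank(), r1_sstrand = blank(),
                     r2_chrom = blankc(), r2_start = blank(),
                     r2_end = blank(), r2_strand = blank(),
                     r2_schrom = blankc(), r2_sstart = blank(),
                     r2_send = blank(), r2_sstrand = blank(),
                     stringsAsFactors = FALSE)
    fill <- function(tm, rows, prefix) {
        ## first occurrence per template wins (one primary / one supp each)
        rows <- rows[!duplicated(df$qname[rows])]
        i <- match(df$qname[rows], qn)
        tm[[paste0(prefix, "chrom")]][i] <- df$chrom[rows]
        tm[[paste0(prefix, "start")]][i] <- df$start[rows]
        tm[[paste0(prefix, "end")]][i] <- df$end[rows]
        tm[[paste0(prefix, "strand")]][i] <- df$strand[rows]
        tm
    }
    tm <- fill(tm, which(!supp & first), "r1_")
    tm <- fill(tm, which(!supp & !first), "r2_")
    tm <- fill(tm, which(supp & first), "r1_s")
    tm <- fill(tm, which(supp & !first), "r2_s")
    ## orphan read-2 templates (mate filtered/unmapped): promote to r1 so
    ## their split evidence is still considered
    orphan <- is.na(tm$r1_chrom) & !is.na(tm$r2_chrom)
    if (any(orphan)) {
        for (suf in c("chrom", "start", "end", "strand",
                      "schrom", "sstart", "send", "sstrand")) {
            tm[[paste0("r1_", suf)]][orphan] <- tm[[paste0("r2_", suf)]][orphan]
            tm[[paste0("r2_", suf)]][orphan] <- NA
        }
    }
    tm[!is.na(tm$r1_chrom), , drop = FALSE]
}

#' Write simulated templates as a SAM file
#'
#' Emits one primary record per mapped read (paired flags, strands and
#' mate fields set) and one supplementary record per split segment, so the
#' file round-trips through [extractEvidence()] to the same evidence the
#' in-memory template classification produces. Sequences and qualities are
#' omitted (`*`), CIGARs cover the mapped span.
#'
#' @param templates a template data.frame (see
#'   [extractEvidenceFromTemplates()]); a `qname` column is used when
#'   present.
#' @param path output SAM path.
#' @param chromLengths named integer vector of reference chromosome
#'   lengths for the header.
#' @return `path`, invisibly.
#' @export
emitAlignments <- function(templates, path, chromLengths) {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(chromLengths),
                        as.integer(chromLengths)))
    n <- nrow(templates)
    lines <- header
    if (n) {
        qname <- if ("qname" %in% names(templates)) templates$qname else
            sprintf("t%06d", seq_len(n))
        col <- function(nm) if (nm %in% names(templates)) templates[[nm]] else
            rep(NA, n)
        paired <- !is.na(col("r2_chrom"))
        rec <- function(prefix, firstFlag, mprefix, suppl = FALSE) {
            chrom <- col(paste0(prefix, if (suppl) "schrom" else "chrom"))
            ok <- !is.na(chrom)
            if (!any(ok)) return(character())
            s <- col(paste0(prefix, if (suppl) "sstart" else "start"))[ok]
            e <- col(paste0(prefix, if (suppl) "send" else "end"))[ok]
            st <- col(paste0(prefix, if (suppl) "sstrand" else "strand"))[ok]
            isPaired <- paired[ok]
            mchrom <- col(paste0(mprefix, "chrom"))[ok]
            mstart <- col(paste0(mprefix, "start"))[ok]
            mstrand <- col(paste0(mprefix, "strand"))[ok]
            flag <- ifelse(isPaired, 1L + firstFlag, 0L) +
                ifelse(st == -1L, 16L, 0L) +
                ifelse(isPaired & !is.na(mstrand) & mstrand == -1L, 32L, 0L) +
                if (suppl) 2048L else 0L
            sprintf("%s\t%d\t%s\t%d\t60\t%dM\t%s\t%d\t0\t*\t*",
                    qname[ok], flag, chrom[ok], as.integer(s) + 1L,
                    as.integer(e - s),
                    ifelse(isPaired & !is.na(mchrom),
                           ifelse(mchrom == chrom[ok], "=", mchrom), "*"),
                    ifelse(isPaired & !is.na(mstart),
                           as.integer(mstart) + 1L, 0L))
        }
        lines <- c(lines,
                   rec("r1_", 64L, "r2_"),
                   rec("r2_", 128L, "r1_"),
                   rec("r1_", 64L, "r2_", suppl = TRUE),
                   rec("r2_", 128L, "r1_", suppl = TRUE))
    }
    writeLines(lines, path)
    invisible(path)
}
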