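## Coordinate-level paired-end cohort simulator. Haplotypes are piecewise
## maps of reference segments (with orientation); fragments are drawn on
## the haplotype and their reads mapped back to reference coordinates, so
## junction-spanning templates produce exactly the discordant geometry an
## aligner would report: distance-discordant +/- pairs over deletions,
## -/+ pairs over tandem-duplication junctions, +/+ and -/- pairs over
## inversion junctions, interchromosomal pairs over translocation break
## ends, and split reads where a read crosses a junction. No sequence is
## generated and no aligner is involved.

.SPLIT_MIN_OVERLAP <- 20L   # bp a read must have on both junction sides

#' Define a simulated cohort
#'
#' Bundles and validates the study conditions of a simulated cohort:
#' sample count, reference chromosome lengths, the implanted SVs with
#' per-sample genotypes, the fragment-size model of the library, read
#' length, coverage, the background rate of nonspecific discordant
#' templates, and the master seed.
#'
#' @param nSamples number of samples.
#' @param chromLengths named integer vector of reference chromosome
#'   lengths (bp).
#' @param svs data.frame with columns `sv_id`, `type` (`DEL`/`DUP`/`INV`/
#'   `BND`), `chrom`, `start`, `end` (0-based half-open; for `BND`,
#'   `start` is the junction point and `end = start + 1`) and, for `BND`
#'   only, `chrom2`, `pos2` (the partner junction point).
#' @param genotypes integer matrix (samples x SVs, values 0/1/2) of SV
#'   genotypes; rownames are sample ids, colnames SV ids.
#' @param fragmentMean,fragmentSd fragment-length model (bp).
#' @param readLength read length (bp).
#' @param coverage haploid-pair (sample) coverage, e.g. 10 for 10x.
#' @param noiseRate fraction of templates emitted as random nonspecific
#'   discordant pairs; must be below 0.05.
#' @param seed master seed; per-sample streams are derived from it so a
#'   cohort can be extended without perturbing existing samples.
#' @return A validated `CohortSpec` list.
#' @export
cohortSpec <- function(nSamples, chromLengths, svs, genotypes,
                       fragmentMean = 300, fragmentSd = 50,
                       readLength = 100, coverage = 10,
                       noiseRate = 0, seed = 1L) {
    spec <- structure(list(
        nSamples = as.integer(nSamples), chromLengths = chromLengths,
        svs = svs, genotypes = genotypes,
        fragmentMean = fragmentMean, fragmentSd = fragmentSd,
        readLength = as.integer(readLength), coverage = coverage,
        noiseRate = noiseRate, seed = as.integer(seed)),
        class = "CohortSpec")
    validateCohortSpec(spec)
    spec
}

#' @rdname cohortSpec
#' @param spec a `CohortSpec`.
#' @export
validateCohortSpec <- function(spec) {
    svs <- spec$svs
    L <- spec$chromLengths
    if (is.null(names(L)) || anyDuplicated(names(L)))
        stop("chromLengths must be uniquely named")
    if (!all(svs$type %in% .SV_TYPES))
        stop("unknown SV type in spec")
    if (!all(svs$chrom %in% names(L)))
        stop("SV chromosome not in chromLengths")
    if (any(svs$start < 0) || any(svs$end > L[svs$chrom]))
        stop("SV breakpoints outside chromosome bounds")
    if (any(svs$start >= svs$end))
        stop("SV intervals need start < end")
    bnd <- svs$type == "BND"
    if (any(bnd)) {
        if (!all(svs$chrom2[bnd] %in% names(L)))
            stop("BND partner chromosome not in chromLengths")
        if (any(svs$pos2[bnd] < 0) ||
            any(svs$pos2[bnd] >= L[svs$chrom2[bnd]]))
            stop("BND partner position outside chromosome bounds")
    }
    ## SVs must not overlap on any haplotype; they are globally
    ## non-overlapping by construction here
    intra <- svs[!bnd, , drop = FALSE]
    if (nrow(intra) > 1L) {
        o <- order(intra$chrom, intra$start, method = "radix")
        s <- intra[o, ]
        sameChrom <- s$chrom[-1L] == s$chrom[-nrow(s)]
        if (any(sameChrom & s$start[-1L] < s$end[-nrow(s)]))
            stop("SVs overlap on a haplotype")
    }
    if (spec$noiseRate < 0 || spec$noiseRate >= 0.05)
        stop("noiseRate must be in [0, 0.05)")
    if (!is.matrix(spec$genotypes) ||
        nrow(spec$genotypes) != spec$nSamples ||
        ncol(spec$genotypes) != nrow(svs))
        stop("genotypes must be an nSamples x nSVs matrix")
    if (!all(spec$genotypes %in% 0:2))
        stop("genotypes must be 0, 1 or 2")
    if (spec$fragmentMean <= 0 || spec$fragmentSd < 0 ||
        spec$readLength <= 0 || spec$coverage <= 0)
        stop("fragment model, read length and coverage must be positive")
    invisible(TRUE)
}

## per-sample RNG stream derived from the master seed
.deriveSeed <- function(seed, sampleIdx) {
    as.integer((as.numeric(seed) * 48271 + sampleIdx * 16807) %% 2147483647)
}

#' Default simulated test cohort
#'
#' The standard study conditions for pipeline evaluation: 20 samples, two
#' 2-Mb chromosomes, 30 implanted SVs (10 deletions and 10 tandem
#' duplications of 200-5000 bp, 8 inversions of 500-5000 bp, 2 reciprocal
#' interchromosomal break ends), per-SV allele frequencies drawn
#' uniformly from 0.05-0.5 with Binomial(2, AF) genotypes, 10x coverage,
#' 300 +/- 50 bp fragments, 100 bp reads. SVs are laid out in shuffled
#' slots with 20-kb chromosome margins so no two events come within 10 kb
#' of each other.
#'
#' @param seed master seed.
#' @param noiseRate background discordant-template rate (default 0.04,
#'   in line with the expectation that alignment files carry under 5%
#'   discordant alignments).
#' @return A `CohortSpec`.
#' @export
defaultTestCohort <- function(seed = 1L, noiseRate = 0.04) {
    set.seed(.deriveSeed(seed, 0L))
    chromLengths <- c(chr1 = 2000000L, chr2 = 2000000L)
    nDel <- 10L; nDup <- 10L; nInv <- 8L; nBnd <- 2L
    sizes <- c(round(exp(stats::runif(nDel, log(200), log(5000)))),
               round(exp(stats::runif(nDup, log(200), log(5000)))),
               round(exp(stats::runif(nInv, log(500), log(5000)))))
    types <- c(rep("DEL", nDel), rep("DUP", nDup), rep("INV", nInv))
    ## shuffled equal slots, 20 kb margins; slot width ~130 kb >> max SV
    ## size + 10 kb spacing
    nIntra <- length(sizes)
    perChrom <- ceiling((nIntra + nBnd) / 2L)
    slotW <- floor((2000000L - 40000L) / perChrom)
    slots <- data.frame(
        chrom = rep(c("chr1", "chr2"), each = perChrom),
        lo = 20000L + rep(seq_len(perChrom) - 1L, 2L) * slotW)
    slots <- slots[sample.int(nrow(slots)), ]
    starts <- slots$lo[seq_len(nIntra)] +
        floor(stats::runif(nIntra, 0, slotW - sizes - 10000L))
    ## break-end junctions take the two leftover slots; their partner
    ## points sit on the opposite chromosome inside the 20-kb margins,
    ## clear of every implanted SV
    bndSlots <- slots[nIntra + seq_len(nBnd), ]
    bndPos1 <- bndSlots$lo +
        floor(stats::runif(nBnd, 1000, slotW - 11000L))
    bndChrom2 <- ifelse(bndSlots$chrom == "chr1", "chr2", "chr1")
    bndPos2 <- c(10000L, 1995000L)
    svs <- data.frame(
        sv_id = sprintf("sv%02d", seq_len(nIntra + nBnd)),
        type = c(types, rep("BND", nBnd)),
        chrom = c(slots$chrom[seq_len(nIntra)], bndSlots$chrom),
        start = c(starts, bndPos1),
        end = c(starts + sizes, bndPos1 + 1L),
        chrom2 = c(rep(NA_character_, nIntra), bndChrom2),
        pos2 = c(rep(NA_integer_, nIntra), bndPos2),
        stringsAsFactors = FALSE)
    af <- stats::runif(nrow(svs), 0.05, 0.5)
    sampleIds <- sprintf("S%02d", seq_len(20L))
    genotypes <- matrix(stats::rbinom(20L * nrow(svs), 2L,
                                      rep(af, each = 20L)),
                        nrow = 20L,
                        dimnames = list(sampleIds, svs$sv_id))
    ## one reciprocal translocation per haplotype at most: samples drawn
    ## as carriers of both break ends keep only the first
    bndCols <- which(svs$type == "BND")
    both <- genotypes[, bndCols[1L]] > 0L & genotypes[, bndCols[2L]] > 0L
    genotypes[both, bndCols[2L]] <- 0L
    cohortSpec(20L, chromLengths, svs, genotypes,
               fragmentMean = 300, fragmentSd = 50, readLength = 100L,
               coverage = 10, noiseRate = noiseRate, seed = seed)
}

#' Truth table of a cohort spec
#'
#' @param spec a `CohortSpec`.
#' @return data.frame with one row per (sample, SV): `sample_id`,
#'   `sv_id`, `type`, `genotype`, `carrier`, and the expected breakpoint
#'   coordinates (`chrom`, `left_pos`, `right_chrom`, `right_pos`).
#' @export
truthTable <- function(spec) {
    svs <- spec$svs
    g <- spec$genotypes
    data.frame(
        sample_id = rep(rownames(g), times = ncol(g)),
        sv_id = rep(colnames(g), each = nrow(g)),
        type = rep(svs$type, each = nrow(g)),
        genotype = as.vector(g),
        carrier = as.vector(g) > 0L,
        chrom = rep(svs$chrom, each = nrow(g)),
        left_pos = rep(svs$start, each = nrow(g)),
        right_chrom = rep(ifelse(svs$type == "BND", svs$chrom2, svs$chrom),
                          each = nrow(g)),
        right_pos = rep(ifelse(svs$type == "BND", svs$pos2, svs$end),
                        each = nrow(g)),
        stringsAsFactors = FALSE)
}

#' SV queries for the implanted variants
#'
#' One [SVQuery-class] per SV of the spec. Breakpoint confidence
#' intervals are the 2-bp windows straddling each implanted junction
#' (`[b-1, b+1)` for junction coordinate `b`): the junction falls between
#' two reference bases, and an interval containing both flanking bases
#' overlaps split-read segments that abut the junction exactly from
#' either side.
#'
#' @param spec a `CohortSpec`.
#' @param window query window in bp (default 500).
#' @return named list of [SVQuery-class] objects (names are SV ids).
#' @export
svQueries <- function(spec, window = 500) {
    svs <- spec$svs
    qs <- lapply(seq_len(nrow(svs)), function(i) {
        if (svs$type[i] == "BND") {
            ## hand the constructor genome-ordered breakpoints
            aFirst <- .chromLt(svs$chrom[i], svs$chrom2[i]) ||
                (svs$chrom[i] == svs$chrom2[i] &&
                 svs$start[i] <= svs$pos2[i])
            if (aFirst)
                SVQuery("BND", svs$chrom[i], max(0, svs$start[i] - 1),
                        svs$start[i] + 1, rightChrom = svs$chrom2[i],
                        rightStart = max(0, svs$pos2[i] - 1),
                        rightEnd = svs$pos2[i] + 1, window = window)
            else
                SVQuery("BND", svs$chrom2[i], max(0, svs$pos2[i] - 1),
                        svs$pos2[i] + 1, rightChrom = svs$chrom[i],
                        rightStart = max(0, svs$start[i] - 1),
                        rightEnd = svs$start[i] + 1, window = window)
        }
        else
            SVQuery(svs$type[i], svs$chrom[i],
                    max(0, svs$start[i] - 1), svs$start[i] + 1,
                    rightStart = svs$end[i] - 1,
                    rightEnd = svs$end[i] + 1, window = window)
    })
    names(qs) <- svs$sv_id
    qs
}

## ---- haplotype construction -------------------------------------------

## Segment chains: per chromosome unit a data.frame of reference pieces
## (ref_chrom, rs, re, orient) in haplotype order.
.hapSegments <- function(spec, carriedIds) {
    svs <- spec$svs[match(carriedIds, spec$svs$sv_id), , drop = FALSE]
    chains <- lapply(names(spec$chromLengths), function(ch) {
        L <- spec$chromLengths[[ch]]
        here <- svs[svs$chrom == ch & svs$type != "BND", , drop = FALSE]
        here <- here[order(here$start), , drop = FALSE]
        segs <- list()
        cur <- 0L
        for (i in seq_len(nrow(here))) {
            a <- here$start[i]; b <- here$end[i]
            if (a > cur)
                segs[[length(segs) + 1L]] <- c(a0 = cur, b0 = a, o = 1L)
            if (here$type[i] == "DUP") {
                segs[[length(segs) + 1L]] <- c(a0 = a, b0 = b, o = 1L)
                segs[[length(segs) + 1L]] <- c(a0 = a, b0 = b, o = 1L)
            } else if (here$type[i] == "INV") {
                segs[[length(segs) + 1L]] <- c(a0 = a, b0 = b, o = -1L)
            }                                  # DEL: skip the segment
            cur <- b
        }
        if (cur < L)
            segs[[length(segs) + 1L]] <- c(a0 = cur, b0 = L, o = 1L)
        m <- do.call(rbind, segs)
        data.frame(ref_chrom = ch, rs = as.integer(m[, "a0"]),
                   re = as.integer(m[, "b0"]), orient = as.integer(m[, "o"]),
                   stringsAsFactors = FALSE)
    })
    names(chains) <- names(spec$chromLengths)
    ## reciprocal translocations rearrange whole chain prefixes/suffixes;
    ## one exchange per haplotype keeps the surgery unambiguous
    bnds <- svs[svs$type == "BND", , drop = FALSE]
    if (nrow(bnds) > 1L)
        stop("a haplotype cannot carry more than one reciprocal translocation")
    for (i in seq_len(nrow(bnds))) {
        chA <- bnds$chrom[i]; posA <- bnds$start[i]
        chB <- bnds$chrom2[i]; posB <- bnds$pos2[i]
        sA <- .splitChainAt(chains[[chA]], posA)
        sB <- .splitChainAt(chains[[chB]], posB)
        chains[[chA]] <- rbind(sA$prefix, sB$suffix)
        chains[[chB]] <- rbind(sB$prefix, sA$suffix)
    }
    chains
}

.splitChainAt <- function(chain, refPos) {
    idx <- which(chain$orient == 1L & chain$rs <= refPos & refPos < chain$re)
    if (length(idx) != 1L)
        stop("translocation point falls inside another SV")
    idx <- idx[1L]
    pre <- chain[seq_len(idx - 1L), , drop = FALSE]
    post <- chain[-seq_len(idx), , drop = FALSE]
    seg <- chain[idx, , drop = FALSE]
    segA <- seg; segA$re <- refPos
    segB <- seg; segB$rs <- refPos
    list(prefix = rbind(pre, if (segA$rs < segA$re) segA),
         suffix = rbind(if (segB$rs < segB$re) segB, post))
}

## ---- read mapping ------------------------------------------------------

## Map haplotype read intervals [h1, h2) with haplotype-strand hapStrand
## through a segment chain. Returns primary span plus an optional split
## segment per read; reads crossing a junction with < .SPLIT_MIN_OVERLAP
## bp on one side are truncated to their larger piece.
.mapReads <- function(h1, h2, hapStrand, chain) {
    hs <- cumsum(c(0L, chain$re - chain$rs))
    segStart <- hs[-length(hs)]
    iS <- findInterval(h1, segStart)
    iE <- findInterval(h2 - 1L, segStart)
    ## a read never spans more than two segments under the minimum SV
    ## size; clamp defensively if it ever would
    iE <- pmin(iE, iS + 1L)
    mapPiece <- function(a, b, i) {
        o <- chain$orient[i]
        rs <- ifelse(o == 1L, chain$rs[i] + (a - segStart[i]),
                     chain$re[i] - (b - segStart[i]))
        re <- ifelse(o == 1L, chain$rs[i] + (b - segStart[i]),
                     chain$re[i] - (a - segStart[i]))
        list(chrom = chain$ref_chrom[i], start = rs, end = re,
             strand = as.integer(o * hapStrand))
    }
    n <- length(h1)
    out <- data.frame(chrom = character(n), start = integer(n),
                      end = integer(n), strand = integer(n),
                      schrom = NA_character_, sstart = NA_integer_,
                      send = NA_integer_, sstrand = NA_integer_,
                      stringsAsFactors = FALSE)
    same <- iS == iE
    if (any(same)) {
        p <- mapPiece(h1[same], h2[same], iS[same])
        out$chrom[same] <- p$chrom; out$start[same] <- p$start
        out$end[same] <- p$end; out$strand[same] <- p$strand
    }
    cross <- which(!same)
    if (length(cross)) {
        cut <- hs[iS[cross] + 1L]
        wA <- cut - h1[cross]; wB <- h2[cross] - cut
        pA <- mapPiece(h1[cross], cut, iS[cross])
        pB <- mapPiece(cut, h2[cross], iE[cross])
        ## pieces that are reference-contiguous on the same strand (e.g.
        ## a read crossing the second junction of a tandem duplication)
        ## would be reported by an aligner as one contiguous alignment
        contig <- pA$chrom == pB$chrom & pA$strand == pB$strand &
            (pA$end == pB$start | pB$end == pA$start)
        split <- !contig & pmin(wA, wB) >= .SPLIT_MIN_OVERLAP
        aPrim <- wA >= wB             # larger piece is the primary
        pick <- function(fld, useA) ifelse(useA, pA[[fld]], pB[[fld]])
        out$chrom[cross] <- pick("chrom", aPrim)
        out$start[cross] <- ifelse(contig, pmin(pA$start, pB$start),
                                   pick("start", aPrim))
        out$end[cross] <- ifelse(contig, pmax(pA$end, pB$end),
                                 pick("end", aPrim))
        out$strand[cross] <- pick("strand", aPrim)
        sup <- cross[split]
        if (length(sup)) {
            useA <- !aPrim[split]     # supplementary is the other piece
            out$schrom[sup] <- pick("chrom", useA)[split]
            out$sstart[sup] <- pick("start", useA)[split]
            out$send[sup] <- pick("end", useA)[split]
            out$sstrand[sup] <- pick("strand", useA)[split]
        }
    }
    out
}

## ---- per-sample simulation ---------------------------------------------

.simulateSampleTemplates <- function(spec, sampleIdx) {
    set.seed(.deriveSeed(spec$seed, sampleIdx))
    rl <- spec$readLength
    sampleId <- rownames(spec$genotypes)[sampleIdx]
    g <- stats::setNames(spec$genotypes[sampleIdx, ],
                         colnames(spec$genotypes))
    parts <- list()
    for (hap in 1:2) {
        carried <- names(g)[g == 2L | (g == 1L & hap == 1L)]
        chains <- .hapSegments(spec, carried)
        for (chain in chains) {
            len <- sum(chain$re - chain$rs)
            nFrag <- round((spec$coverage / 2) * len / (2 * rl))
            if (nFrag < 1L) next
            ## fragment lengths: Gaussian truncated to
            ## [2*readLength, mean + 4*sd]; the upper bound keeps the
            ## concordant library inside its own discordance threshold,
            ## so a zero-noise all-reference sample yields zero evidence
            fl <- pmax(2L * rl,
                       round(stats::rnorm(nFrag, spec$fragmentMean,
                                          spec$fragmentSd)))
            fl <- pmin(fl, round(spec$fragmentMean + 4 * spec$fragmentSd),
                       len)
            p <- floor(stats::runif(nFrag, 0, len - fl + 1))
            r1 <- .mapReads(p, p + rl, 1L, chain)
            r2 <- .mapReads(p + fl - rl, p + fl, -1L, chain)
            parts[[length(parts) + 1L]] <- data.frame(
                r1_chrom = r1$chrom, r1_start = r1$start, r1_end = r1$end,
                r1_strand = r1$strand, r1_schrom = r1$schrom,
                r1_sstart = r1$sstart, r1_send = r1$send,
                r1_sstrand = r1$sstrand,
                r2_chrom = r2$chrom, r2_start = r2$start, r2_end = r2$end,
                r2_strand = r2$strand, r2_schrom = r2$schrom,
                r2_sstart = r2$sstart, r2_send = r2$send,
                r2_sstrand = r2$sstrand,
                stringsAsFactors = FALSE)
        }
    }
    tm <- do.call(rbind, parts)
    nNoise <- round(spec$noiseRate * nrow(tm))
    if (nNoise > 0L) {
        chroms <- names(spec$chromLengths)
        rchrom <- function(n) chroms[sample.int(length(chroms), n,
                                                replace = TRUE)]
        rpos <- function(ch) floor(stats::runif(length(ch), 0,
                                                spec$chromLengths[ch] - rl))
        rstrand <- function(n) sample(c(1L, -1L), n, replace = TRUE)
        c1 <- rchrom(nNoise); p1 <- rpos(c1)
        c2 <- rchrom(nNoise); p2 <- rpos(c2)
        noise <- data.frame(
            r1_chrom = c1, r1_start = p1, r1_end = p1 + rl,
            r1_strand = rstrand(nNoise), r1_schrom = NA_character_,
            r1_sstart = NA_integer_, r1_send = NA_integer_,
            r1_sstrand = NA_integer_,
            r2_chrom = c2, r2_start = p2, r2_end = p2 + rl,
            r2_strand = rstrand(nNoise), r2_schrom = NA_character_,
            r2_sstart = NA_integer_, r2_send = NA_integer_,
            r2_sstrand = NA_integer_,
            stringsAsFactors = FALSE)
        tm <- rbind(tm, noise)
    }
    tm$qname <- sprintf("%s.t%07d", sampleId, seq_len(nrow(tm)))
    rownames(tm) <- NULL
    tm
}

#' Simulate the cohort's paired-end alignment streams
#'
#' Draws fragments along each haplotype at the requested coverage with
#' Gaussian fragment lengths (truncated at twice the read length) and
#' maps them back to reference coordinates; adds the configured fraction
#' of random nonspecific discordant templates. Fully reproducible from
#' the spec's seed; each sample has its own derived stream.
#'
#' @param spec a `CohortSpec`.
#' @param samples integer indices of the samples to simulate (default
#'   all).
#' @return list with `templates` (named list of per-sample template
#'   data.frames, see [extractEvidenceFromTemplates()]) and `truth` (the
#'   [truthTable()]).
#' @export
simulateFragments <- function(spec, samples = seq_len(spec$nSamples)) {
    validateCohortSpec(spec)
    templates <- lapply(samples, function(i)
        .simulateSampleTemplates(spec, i))
    names(templates) <- rownames(spec$genotypes)[samples]
    list(templates = templates, truth = truthTable(spec))
}

#' Simulate, extract and write a cohort evidence set
#'
#' Runs the extraction stage over each simulated sample in turn (keeping
#' only the evidence records in memory) and writes per-sample evidence
#' files, a PED sample table and the truth table to a directory, ready
#' for [buildCohortIndex()] and [runQuery()].
#'
#' @param spec a `CohortSpec`.
#' @param dir output directory (created).
#' @param model an [InsertSizeModel-class]; default is the spec's
#'   fragment model with a 500-bp discordant distance.
#' @return list with `evidenceFiles`, `sampleIds`, `ped` (data.frame),
#'   `pedFile`, `truth`, and `nTemplates` (per-sample template counts).
#' @export
simulateCohortEvidence <- function(spec, dir,
                                   model = insertSizeModel(
                                       spec$fragmentMean, spec$fragmentSd,
                                       500)) {
    validateCohortSpec(spec)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ids <- rownames(spec$genotypes)
    files <- file.path(dir, paste0(ids, ".bed"))
    nTemplates <- integer(spec$nSamples)
    for (i in seq_len(spec$nSamples)) {
        tm <- .simulateSampleTemplates(spec, i)
        nTemplates[i] <- nrow(tm)
        records <- extractEvidenceFromTemplates(tm, model)
        writeEvidence(records, files[i])
    }
    ped <- data.frame(Sample = ids,
                      Sex = rep_len(c("1", "2"), length(ids)),
                      Population = "SIM", Super_Population = "SIM",
                      Alt_File = basename(files),
                      stringsAsFactors = FALSE)
    pedFile <- file.path(dir, "cohort.ped")
    utils::write.table(ped, pedFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ped$evidence_file <- ped$Alt_File
    attr(ped, "bed_column") <- "Alt_File"
    list(evidenceFiles = files, sampleIds = ids, ped = ped,
         pedFile = pedFile, truth = truthTable(spec),
         nTemplates = nTemplates)
}
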