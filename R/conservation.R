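#' Conservation-calling parameters
#'
#' Defaults follow the identity criterion used for conserved-region calling:
#' more than 70 percent identity over a 100 bp span.
#'
#' @param minIdentity minimum percent identity, strict (default 70).
#' @param minSpan minimum region length in baseline bp (default 100).
#' @param window sliding-window width in baseline bp (default 100).
#' @param step window step in baseline bp (default 1).
#' @return a named list of class `ConservationParams`.
#' @export
conservationParams <- function(minIdentity = 70, minSpan = 100, window = 100,
                               step = 1) {
    if (minIdentity <= 0 || minIdentity > 100)
        stop("minIdentity must be in (0, 100]")
    if (window < 1 || minSpan < window)
        stop("require minSpan >= window >= 1")
    if (step < 1) stop("step must be >= 1")
    structure(list(minIdentity = minIdentity, minSpan = minSpan,
                   window = window, step = step),
              class = "ConservationParams")
}

# Per-window identity machinery shared by identityProfile and
# callConservedRegions. Identity of a baseline residue span [s, e] is
# 100 * (matching columns) / (columns spanned), where a column matches when
# baseline and target residues are equal and neither is a gap or N. Gap and N
# columns therefore count in the denominator and never as matches.
.identityMachinery <- function(aln) {
    maps <- .alnMaps(aln)
    list(maps = maps, cummatch = c(0, cumsum(maps$match)))
}

.spanIdentity <- function(mach, s, e) {
    c1 <- mach$maps$b2c[s]
    c2 <- mach$maps$b2c[e]
    100 * (mach$cummatch[c2 + 1L] - mach$cummatch[c1]) / (c2 - c1 + 1L)
}

#' Sliding-window identity profile
#'
#' Percent identity over each window of `window` consecutive baseline
#' residues, stepped by `step`.
#'
#' @param aln an \linkS4class{OrthologAlignment}.
#' @param params a [conservationParams()] list.
#' @return a data.frame with columns `start` (baseline window start, 1-based)
#'   and `identity` (percent).
#' @export
identityProfile <- function(aln, params = conservationParams()) {
    blen <- length(.alnMaps(aln)$b2c)
    w <- params$window
    if (blen < w)
        stop("baseline ungapped length (", blen, ") is shorter than the window (", w, ")")
    starts <- seq.int(1L, blen - w + 1L, by = params$step)
    mach <- .identityMachinery(aln)
    data.frame(start = starts,
               identity = .spanIdentity(mach, starts, starts + w - 1L))
}

#' Call conserved regions from an alignment
#'
#' Windows with identity strictly above `minIdentity` are merged when their
#' baseline spans overlap or abut; each merged run becomes one candidate
#' region whose percent identity is recomputed over the merged column span.
#' Regions shorter than `minSpan` (baseline bp) or failing the identity
#' threshold after recomputation are dropped. Emitted regions are disjoint on
#' the baseline and sorted by coordinate.
#'
#' @param aln an \linkS4class{OrthologAlignment}.
#' @param params a [conservationParams()] list.
#' @return a \linkS4class{GRanges} on the baseline with metadata columns
#'   `targetStart`, `targetEnd`, `length` (baseline bp), `pident`, `score`
#'   (pident + length/60) and `coverage` (fraction of baseline residues with
#'   an aligned target partner).
#' @export
callConservedRegions <- function(aln, params = conservationParams()) {
    prof <- identityProfile(aln, params)
    w <- params$window
    pass <- prof$start[prof$identity > params$minIdentity]
    empty <- GenomicRanges::GRanges()
    if (!length(pass)) return(empty)
    merged <- IRanges::reduce(IRanges::IRanges(pass, pass + w - 1L))
    mach <- .identityMachinery(aln)
    s <- IRanges::start(merged); e <- IRanges::end(merged)
    pid <- .spanIdentity(mach, s, e)
    len <- e - s + 1L
    keep <- len >= params$minSpan & pid > params$minIdentity
    if (!any(keep)) return(empty)
    s <- s[keep]; e <- e[keep]; pid <- pid[keep]; len <- len[keep]
    proj <- lapply(seq_along(s), function(i)
        projectInterval(aln, IRanges::IRanges(s[i], e[i]), from = "baseline"))
    tgt <- t(vapply(proj, function(p) {
        if (length(p$interval)) c(IRanges::start(p$interval), IRanges::end(p$interval))
        else c(NA_integer_, NA_integer_)
    }, integer(2)))
    gr <- GenomicRanges::GRanges(aln@baselineName, IRanges::IRanges(s, e))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        targetStart = tgt[, 1], targetEnd = tgt[, 2],
        length = len, pident = pid,
        score = scoreRegion(pid, len),
        coverage = vapply(proj, `[[`, numeric(1), "coverage"))
    gr  # reduce() already yields baseline coordinate order
}

#' Conservation score of a region
#'
#' `score = percent identity + length / 60`, with length in baseline bp.
#' On the printed statistics of a 715 bp region at 78 percent identity this
#' gives 78 + 715/60 = 89.9167.
#'
#' @param percentIdentity percent identity (0-100), vectorised.
#' @param length region length in baseline bp, vectorised.
#' @return numeric score(s).
#' @examples
#' scoreRegion(78, 715)
#' @export
scoreRegion <- function(percentIdentity, length) {
    if (any(percentIdentity < 0) || any(length < 0))
        stop("percentIdentity and length must be nonnegative")
    percentIdentity + length / 60
}

#' Rank conserved regions by score
#'
#' Descending by score; ties broken by greater length, then by smaller
#' baseline start.
#'
#' @param regions a \linkS4class{GRanges} as from [callConservedRegions()].
#' @param topK number of regions to keep (default all).
#' @return the ranked (possibly truncated) \linkS4class{GRanges}, with a
#'   `name` metadata column `CR1`, `CR2`, ... in rank order.
#' @export
rankRegions <- function(regions, topK = Inf) {
    if (!length(regions)) return(regions)
    ord <- order(-regions$score, -regions$length, GenomicRanges::start(regions))
    out <- regions[ord]
    if (is.finite(topK)) out <- out[seq_len(min(length(out), topK))]
    out$name <- paste0("CR", seq_along(out))
    out
}

#' Write conserved regions as BED6
#'
#' Name is the CR rank, the BED score column is the conservation score times
#' ten, rounded; strand is ".".
#'
#' @param regions ranked regions from [rankRegions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
    gr <- regions
    if (length(gr)) {
        if (is.null(gr$name)) gr$name <- paste0("CR", seq_along(gr))
        gr$score <- as.integer(round(gr$score * 10))
    }
    writeBed(gr, path)
}

#' Write conserved regions as TSV
#'
#' One row per region with per-species intervals (1-based closed), length,
#' percent identity and score.
#'
#' @param regions ranked regions from [rankRegions()].
#' @param path output path.
#' @param targetName target sequence name for the header.
#' @return `path`, invisibly.
#' @export
writeRegionsTsv <- function(regions, path, targetName = "target") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# conserved regions; coordinates 1-based inclusive", con)
    df <- data.frame(
        name = if (length(regions)) regions$name else character(0),
        baseline_seq = as.character(GenomicRanges::seqnames(regions)),
        baseline_from = GenomicRanges::start(regions),
        baseline_to = GenomicRanges::end(regions),
        target_seq = rep(targetName, length(regions)),
        target_from = if (length(regions)) regions$targetStart else integer(0),
        target_to = if (length(regions)) regions$targetEnd else integer(0),
        length_bp = if (length(regions)) regions$length else integer(0),
        percent_identity = if (length(regions)) round(regions$pident, 4) else numeric(0),
        score = if (length(regions)) round(regions$score, 4) else numeric(0),
        stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
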