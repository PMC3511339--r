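#' Pair motif hits across species through the alignment
#'
#' For each matrix, every baseline hit is paired with the same-matrix target
#' hit whose alignment projection overlaps it best. Reciprocal overlap is
#' `min(overlap / baseline hit width, overlap / target hit width)` with the
#' overlap measured on the baseline after projecting the target hit. Pairing
#' is greedy by descending reciprocal overlap (ties: smaller baseline start,
#' then smaller target start); each hit joins at most one pair.
#'
#' @param baseHits [scanMotifs()] data.frame on the baseline sequence, in the
#'   alignment's baseline coordinate frame.
#' @param targHits likewise for the target.
#' @param aln the \linkS4class{OrthologAlignment} of the two sequences.
#' @param minOverlap minimum reciprocal overlap (default 0.5).
#' @param requireStrand require equal strand (default TRUE).
#' @return a data.frame, one row per conserved site, sorted by baseline
#'   start: `family`, `matrixName`, `baseStart`, `baseEnd`, `strand`,
#'   `baseSequence`, `targStart`, `targEnd`, `targStrand`, `targSequence`,
#'   `reciprocalOverlap`, `baseScore`, `targScore`.
#' @export
pairConservedHits <- function(baseHits, targHits, aln, minOverlap = 0.5,
                              requireStrand = TRUE) {
    empty <- data.frame(family = character(0), matrixName = character(0),
                        baseStart = integer(0), baseEnd = integer(0),
                        strand = character(0), baseSequence = character(0),
                        targStart = integer(0), targEnd = integer(0),
                        targStrand = character(0), targSequence = character(0),
                        reciprocalOverlap = numeric(0),
                        baseScore = numeric(0), targScore = numeric(0),
                        stringsAsFactors = FALSE)
    if (!nrow(baseHits) || !nrow(targHits)) return(empty)
    blen <- nchar(ungappedSequence(aln, "baseline"))
    tlen <- nchar(ungappedSequence(aln, "target"))
    if (any(baseHits$start < 1L | baseHits$end > blen))
        stop("baseline hits lie outside the aligned baseline frame [1, ", blen, "]")
    if (any(targHits$start < 1L | targHits$end > tlen))
        stop("target hits lie outside the aligned target frame [1, ", tlen, "]")

    # project every target hit onto the baseline once
    projs <- lapply(seq_len(nrow(targHits)), function(j)
        projectInterval(aln, IRanges::IRanges(targHits$start[j], targHits$end[j]),
                        from = "target"))

    cand <- list()
    for (i in seq_len(nrow(baseHits))) {
        for (j in seq_len(nrow(targHits))) {
            if (baseHits$matrixName[i] != targHits$matrixName[j]) next
            if (requireStrand && baseHits$strand[i] != targHits$strand[j]) next
            p <- projs[[j]]
            if (!length(p$interval)) next
            ov <- min(baseHits$end[i], IRanges::end(p$interval)) -
                  max(baseHits$start[i], IRanges::start(p$interval)) + 1L
            if (ov <= 0L) next
            ro <- min(ov / (baseHits$end[i] - baseHits$start[i] + 1L),
                      ov / (targHits$end[j] - targHits$start[j] + 1L))
            if (ro >= minOverlap)
                cand[[length(cand) + 1L]] <- c(i = i, j = j, ro = ro)
        }
    }
    if (!length(cand)) return(empty)
    cm <- do.call(rbind, cand)
    ord <- order(-cm[, "ro"], baseHits$start[cm[, "i"]], targHits$start[cm[, "j"]])
    cm <- cm[ord, , drop = FALSE]
    usedB <- logical(nrow(baseHits)); usedT <- logical(nrow(targHits))
    keep <- logical(nrow(cm))
    for (k in seq_len(nrow(cm))) {
        i <- cm[k, "i"]; j <- cm[k, "j"]
        if (!usedB[i] && !usedT[j]) { keep[k] <- TRUE; usedB[i] <- TRUE; usedT[j] <- TRUE }
    }
    cm <- cm[keep, , drop = FALSE]
    i <- cm[, "i"]; j <- cm[, "j"]
    out <- data.frame(
        family = baseHits$family[i], matrixName = baseHits$matrixName[i],
        baseStart = baseHits$start[i], baseEnd = baseHits$end[i],
        strand = baseHits$strand[i], baseSequence = baseHits$matchedSequence[i],
        targStart = targHits$start[j], targEnd = targHits$end[j],
        targStrand = targHits$strand[j], targSequence = targHits$matchedSequence[j],
        reciprocalOverlap = cm[, "ro"],
        baseScore = baseHits$score[i], targScore = targHits$score[j],
        stringsAsFactors = FALSE)
    out <- out[order(out$baseStart, out$strand, out$matrixName), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write a conserved-TFBS table
#'
#' Emits the five printed columns — `Family`, `Matrix`, `From-to` (1-based
#' inclusive, relative to the conserved-region start), `Str.` as `(+)`/`(-)`,
#' and `Sequence` with core upper-cased (minus-strand rows print the
#' reverse-complemented word, i.e. the site as read on the minus strand) —
#' plus machine columns with absolute coordinates, overlap fraction and
#' scores.
#'
#' @param pairs a [pairConservedHits()] data.frame.
#' @param path output path.
#' @param frameOffset absolute coordinate of the position before the region
#'   start (default 0): printed `From-to` = absolute - frameOffset.
#' @return `path`, invisibly.
#' @seealso [readConservedTable()]
#' @export
writeConservedTable <- function(pairs, path, frameOffset = 0L) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(
        "# conserved TFBS; From-to 1-based inclusive, frame offset %d (absolute coords in abs_from/abs_to)",
        frameOffset), con)
    df <- data.frame(
        Family = pairs$family, Matrix = pairs$matrixName,
        From.to = sprintf("%d-%d", pairs$baseStart - frameOffset,
                          pairs$baseEnd - frameOffset),
        Str. = ifelse(pairs$strand == "+", "(+)", "(-)"),
        Sequence = ifelse(pairs$strand == "+", pairs$baseSequence,
                          revcompIupac(pairs$baseSequence)),
        abs_from = pairs$baseStart, abs_to = pairs$baseEnd,
        targ_from = pairs$targStart, targ_to = pairs$targEnd,
        reciprocal_overlap = round(pairs$reciprocalOverlap, 4),
        base_score = round(pairs$baseScore, 4),
        targ_score = round(pairs$targScore, 4),
        stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Parse a conserved-TFBS table written by [writeConservedTable()]
#'
#' @param path file path.
#' @return a data.frame with the table's columns plus parsed `from`, `to` and
#'   `strand`.
#' @export
readConservedTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (!nrow(df)) {
        df$from <- integer(0); df$to <- integer(0); df$strand <- character(0)
        return(df)
    }
    iv <- parseReportCoords(df$From.to)
    df$from <- IRanges::start(iv)
    df$to <- IRanges::end(iv)
    df$strand <- ifelse(df$Str. == "(+)", "+", "-")
    df
}
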