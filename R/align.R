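#' Alignment parameters
#'
#' Parameters of the global affine-gap aligner. A gap run of length k costs
#' `gapOpen + k * gapExtend`; matches score `+match`, mismatches `-mismatch`
#' (an N never scores as a match).
#'
#' @param match match reward (default 1).
#' @param mismatch mismatch penalty, as a positive number (default 1).
#' @param gapOpen gap-open penalty (default 4).
#' @param gapExtend gap-extension penalty per gap column (default 1).
#' @param band band half-width in residues, or `Inf` for unbanded (default).
#'   The band must be at least the length difference of the two sequences.
#' @return a named list of class `AlignParams`.
#' @export
alignParams <- function(match = 1, mismatch = 1, gapOpen = 4, gapExtend = 1,
                        band = Inf) {
    if (gapOpen < gapExtend || gapExtend < 0)
        stop("require gapOpen >= gapExtend >= 0")
    if (mismatch < 0) stop("mismatch penalty must be nonnegative")
    structure(list(match = match, mismatch = mismatch, gapOpen = gapOpen,
                   gapExtend = gapExtend, band = band),
              class = "AlignParams")
}

#' Globally align two sequences
#'
#' Optimal global alignment under affine gap penalties (Gotoh dynamic
#' programming), optionally banded around the diagonal. Deterministic:
#' traceback ties prefer match/mismatch over gap-in-target over
#' gap-in-baseline.
#'
#' @param a baseline sequence: character string or
#'   \linkS4class{AnnotatedSequence}.
#' @param b target sequence, likewise.
#' @param params an [alignParams()] list.
#' @return an \linkS4class{OrthologAlignment}.
#' @examples
#' aln <- alignPair("ACGT", "AGT")
#' alignedBaseline(aln); alignedTarget(aln); alignmentScore(aln)
#' @export
alignPair <- function(a, b, params = alignParams()) {
    aname <- if (is(a, "AnnotatedSequence")) seqName(a) else "baseline"
    bname <- if (is(b, "AnnotatedSequence")) seqName(b) else "target"
    sa <- if (is(a, "AnnotatedSequence")) seqResidues(a) else normalizeDna(a)
    sb <- if (is(b, "AnnotatedSequence")) seqResidues(b) else normalizeDna(b)
    if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be nonempty")
    band <- if (is.infinite(params$band)) -1L else as.integer(params$band)
    res <- align_affine_cpp(sa, sb, params$match, params$mismatch,
                            params$gapOpen, params$gapExtend, band)
    orthologAlignment(res$aligned_a, res$aligned_b,
                      baselineName = aname, targetName = bname,
                      score = res$score)
}

#' Recompute an alignment's score from its gapped strings
#'
#' Used for self-consistency checks: the score reported by [alignPair()]
#' equals the score recomputed here under the same parameters.
#'
#' @param aln an \linkS4class{OrthologAlignment}.
#' @param params an [alignParams()] list.
#' @return numeric score.
#' @export
scoreAlignment <- function(aln, params = alignParams()) {
    bs <- strsplit(alignedBaseline(aln), "")[[1]]
    ts <- strsplit(alignedTarget(aln), "")[[1]]
    sc <- 0
    ingapB <- FALSE; ingapT <- FALSE
    for (k in seq_along(bs)) {
        if (bs[k] == "-") {
            sc <- sc - params$gapExtend - if (ingapB) 0 else params$gapOpen
            ingapB <- TRUE; ingapT <- FALSE
        } else if (ts[k] == "-") {
            sc <- sc - params$gapExtend - if (ingapT) 0 else params$gapOpen
            ingapT <- TRUE; ingapB <- FALSE
        } else {
            sc <- sc + if (bs[k] == ts[k] && bs[k] != "N") params$match else -params$mismatch
            ingapB <- FALSE; ingapT <- FALSE
        }
    }
    sc
}

# residue->column and column->residue maps for one species of an alignment
.alnMaps <- function(aln) {
    bs <- strsplit(alignedBaseline(aln), "")[[1]]
    ts <- strsplit(alignedTarget(aln), "")[[1]]
    bng <- bs != "-"
    tng <- ts != "-"
    list(
        b2c = which(bng),                    # baseline residue index -> column
        t2c = which(tng),                    # target residue index -> column
        c2b = ifelse(bng, cumsum(bng), NA_integer_),  # column -> baseline residue (NA at gaps)
        c2t = ifelse(tng, cumsum(tng), NA_integer_),
        match = bng & tng & bs == ts & bs != "N"
    )
}

#' Column index of a residue
#'
#' @param aln an \linkS4class{OrthologAlignment}.
#' @param species `"baseline"` or `"target"`.
#' @param residueIndex 1-based residue index (vectorised).
#' @return integer column index/indices.
#' @export
columnOf <- function(aln, species = c("baseline", "target"), residueIndex) {
    species <- match.arg(species)
    maps <- .alnMaps(aln)
    v <- if (species == "baseline") maps$b2c else maps$t2c
    if (any(residueIndex < 1L | residueIndex > length(v)))
        stop("residue index out of range [1, ", length(v), "]")
    v[residueIndex]
}

#' Residue index at a column
#'
#' Inverse of [columnOf()] wherever the column is not a gap.
#'
#' @param aln an \linkS4class{OrthologAlignment}.
#' @param species `"baseline"` or `"target"`.
#' @param column 1-based column index (vectorised).
#' @return integer residue index, NA at gap columns.
#' @export
residueAt <- function(aln, species = c("baseline", "target"), column) {
    species <- match.arg(species)
    maps <- .alnMaps(aln)
    v <- if (species == "baseline") maps$c2b else maps$c2t
    if (any(column < 1L | column > length(v)))
        stop("column index out of range [1, ", length(v), "]")
    v[column]
}

#' Project an interval through the alignment
#'
#' Maps an interval in one species onto the minimal interval in the other
#' species spanning all residues aligned (not gapped) opposite it.
#'
#' @param aln an \linkS4class{OrthologAlignment}.
#' @param iv an \linkS4class{IRanges} of length 1, in `from` coordinates.
#' @param from `"baseline"` (project onto target) or `"target"`.
#' @return a list with `interval` (an \linkS4class{IRanges}, length 0 when no
#'   residue of `iv` has an aligned partner) and `coverage` (fraction of
#'   `iv`'s residues aligned to a residue rather than a gap).
#' @export
projectInterval <- function(aln, iv, from = c("baseline", "target")) {
    from <- match.arg(from)
    maps <- .alnMaps(aln)
    r2c <- if (from == "baseline") maps$b2c else maps$t2c
    c2o <- if (from == "baseline") maps$c2t else maps$c2b
    s <- IRanges::start(iv); e <- IRanges::end(iv)
    if (length(iv) != 1L) stop("projectInterval expects a single interval")
    if (s < 1L || e > length(r2c))
        stop("interval outside the aligned sequence [1, ", length(r2c), "]")
    partners <- c2o[r2c[s:e]]
    cov <- mean(!is.na(partners))
    if (all(is.na(partners)))
        return(list(interval = IRanges::IRanges(), coverage = 0))
    list(interval = IRanges::IRanges(min(partners, na.rm = TRUE),
                                     max(partners, na.rm = TRUE)),
         coverage = cov)
}

#' Import a pairwise alignment
#'
#' Reads aligned FASTA (exactly two gapped records) or MAF (two sequences per
#' block; blocks are concatenated in baseline order).
#'
#' @param path file path.
#' @param dialect `"aligned-FASTA"` or `"MAF"`.
#' @return an \linkS4class{OrthologAlignment}.
#' @seealso [writeAlignment()]
#' @export
importAlignment <- function(path, dialect = c("aligned-FASTA", "MAF")) {
    dialect <- match.arg(dialect)
    if (dialect == "aligned-FASTA") {
        set <- Biostrings::readBStringSet(path)
        if (length(set) != 2L)
            stop("aligned-FASTA must contain exactly two records, found ", length(set))
        a <- as.character(set[[1]]); b <- as.character(set[[2]])
        if (nchar(a) != nchar(b))
            stop("format error: aligned records have unequal lengths (",
                 nchar(a), " vs ", nchar(b), ")")
        orthologAlignment(a, b,
                          baselineName = strsplit(names(set)[1], "[ \t]")[[1]][1],
                          targetName = strsplit(names(set)[2], "[ \t]")[[1]][1])
    } else {
        lines <- readLines(path)
        lines <- lines[!grepl("^#", lines)]
        blockStarts <- which(grepl("^a( |$)", lines))
        if (!length(blockStarts)) stop("no alignment blocks found in MAF file")
        pieces <- lapply(blockStarts, function(bs) {
            k <- bs + 1L
            srows <- character(0)
            while (k <= length(lines) && grepl("^s ", lines[k])) {
                srows <- c(srows, lines[k]); k <- k + 1L
            }
            if (length(srows) != 2L)
                stop("MAF block starting at line ", bs, " must have exactly two 's' rows, found ",
                     length(srows))
            f1 <- strsplit(srows[1], "[ \t]+")[[1]]
            f2 <- strsplit(srows[2], "[ \t]+")[[1]]
            if (nchar(f1[7]) != nchar(f2[7]))
                stop("format error: unequal aligned lengths in MAF block at line ", bs)
            list(names = c(f1[2], f2[2]), start = as.numeric(f1[3]),
                 a = f1[7], b = f2[7])
        })
        ord <- order(vapply(pieces, `[[`, numeric(1), "start"))
        pieces <- pieces[ord]
        orthologAlignment(paste(vapply(pieces, `[[`, character(1), "a"), collapse = ""),
                          paste(vapply(pieces, `[[`, character(1), "b"), collapse = ""),
                          baselineName = pieces[[1]]$names[1],
                          targetName = pieces[[1]]$names[2])
    }
}

#' Write a pairwise alignment
#'
#' @param aln an \linkS4class{OrthologAlignment}.
#' @param path output path.
#' @param dialect `"aligned-FASTA"` or `"MAF"` (single block).
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path, dialect = c("aligned-FASTA", "MAF")) {
    dialect <- match.arg(dialect)
    if (dialect == "aligned-FASTA") {
        set <- Biostrings::BStringSet(c(alignedBaseline(aln), alignedTarget(aln)))
        names(set) <- c(aln@baselineName, aln@targetName)
        Biostrings::writeXStringSet(set, path)
    } else {
        blen <- nchar(ungappedSequence(aln, "baseline"))
        tlen <- nchar(ungappedSequence(aln, "target"))
        lines <- c("##maf version=1",
                   sprintf("a score=%s", format(alignmentScore(aln))),
                   sprintf("s %s 0 %d + %d %s", aln@baselineName, blen, blen,
                           alignedBaseline(aln)),
                   sprintf("s %s 0 %d + %d %s", aln@targetName, tlen, tlen,
                           alignedTarget(aln)),
                   "")
        writeLines(lines, path)
    }
    invisible(path)
}
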