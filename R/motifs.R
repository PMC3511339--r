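#' IUPAC-aware, case-preserving reverse complement
#'
#' Complements all IUPAC DNA codes and reverses the sequence, preserving
#' letter case (lower-case flanks / upper-case cores survive the operation).
#' An involution: `revcompIupac(revcompIupac(x)) == x`.
#'
#' @param x character vector of DNA strings (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @examples
#' revcompIupac("tgtgactcagc")  # "gctgagtcaca"
#' @export
revcompIupac <- function(x) {
    fwd <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"
    rev <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn"
    bad <- grepl(paste0("[^", fwd, "-]"), x)
    if (any(bad))
        stop("invalid character in sequence: ", x[bad][1])
    vapply(chartr(fwd, rev, x), function(s)
        paste(rev(strsplit(s, "")[[1]]), collapse = ""),
        character(1), USE.NAMES = FALSE)
}

# IUPAC code -> allowed observed bases. The code N matches anything,
# including an observed N; an observed N never satisfies a more specific
# code (ambiguity in the sequence is treated conservatively).
.iupacAllowed <- local({
    m <- NULL
    function() {
        if (is.null(m)) {
            mm <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
            mm[["N"]] <- c("A", "C", "G", "T", "N")
            m <<- mm
        }
        m
    }
})

#' Read a motif library
#'
#' Two plain-text formats are supported and may be mixed across files:
#' a 4-column consensus TSV (`family`, `matrix_name`, IUPAC word,
#' `core=a-b`), and a minimal TRANSFAC-like count-matrix format
#' (`ID`/`FA` header lines, numbered rows of four counts, `CO a-b` core,
#' `TH x` threshold, `//` terminator). Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a list of \linkS4class{Motif}; duplicate matrix names are an error.
#' @seealso [writeMotifLibrary()]
#' @export
readMotifLibrary <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    motifs <- list()
    i <- 1L
    while (i <= length(lines)) {
        line <- lines[i]
        if (grepl("^ID\\s", line)) {
            id <- trimws(sub("^ID\\s+", "", line))
            fam <- id; core <- NULL; th <- 0.85
            rows <- list()
            i <- i + 1L
            while (i <= length(lines) && !grepl("^//", lines[i])) {
                l <- lines[i]
                if (grepl("^FA\\s", l)) fam <- trimws(sub("^FA\\s+", "", l))
                else if (grepl("^CO\\s", l)) {
                    co <- strsplit(trimws(sub("^CO\\s+", "", l)), "-")[[1]]
                    core <- as.integer(co)
                } else if (grepl("^TH\\s", l)) th <- as.numeric(trimws(sub("^TH\\s+", "", l)))
                else if (grepl("^[0-9]+\\s", l)) {
                    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]][-1])
                    if (length(v) != 4L || any(is.na(v)))
                        stop("motif format error in ", path, ": ragged matrix row '", l,
                             "' for motif ", id)
                    rows[[length(rows) + 1L]] <- v
                }
                i <- i + 1L
            }
            if (!length(rows))
                stop("motif format error in ", path, ": matrix ", id, " has no count rows")
            counts <- t(do.call(rbind, rows))  # 4 x width, rows A C G T
            motifs[[length(motifs) + 1L]] <-
                matrixMotif(fam, id, counts, core = core, threshold = th)
            i <- i + 1L
        } else {
            f <- strsplit(line, "\t")[[1]]
            if (length(f) < 3L)
                stop("motif format error in ", path, ": expected >= 3 tab-separated fields: '",
                     line, "'")
            core <- NULL
            if (length(f) >= 4L && grepl("^core=", f[4])) {
                core <- as.integer(strsplit(sub("^core=", "", f[4]), "-")[[1]])
            }
            motifs[[length(motifs) + 1L]] <-
                consensusMotif(f[1], f[2], f[3], core = core)
            i <- i + 1L
        }
    }
    nms <- vapply(motifs, motifName, character(1))
    if (anyDuplicated(nms))
        stop("duplicate matrix_name in ", path, ": ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
    motifs
}

#' Write a motif library
#'
#' Consensus motifs are written as the 4-column TSV; matrix motifs in the
#' minimal TRANSFAC-like block format. [readMotifLibrary()] on the result
#' reproduces the library.
#'
#' @param motifs list of \linkS4class{Motif}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMotifLibrary <- function(motifs, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# motif library: consensus rows (family<TAB>matrix<TAB>IUPAC<TAB>core=a-b)", con)
    writeLines("# and TRANSFAC-like count-matrix blocks (ID/FA/CO/TH, rows pos A C G T, //)", con)
    for (m in motifs) {
        if (m@kind == "consensus") {
            writeLines(sprintf("%s\t%s\t%s\tcore=%d-%d", m@family, m@matrixName,
                               m@consensus, m@core[1], m@core[2]), con)
        } else {
            writeLines(sprintf("ID %s", m@matrixName), con)
            writeLines(sprintf("FA %s", m@family), con)
            for (p in seq_len(ncol(m@matrix)))
                writeLines(paste(c(p, m@matrix[, p]), collapse = " "), con)
            writeLines(sprintf("CO %d-%d", m@core[1], m@core[2]), con)
            writeLines(sprintf("TH %g", m@threshold), con)
            writeLines("//", con)
        }
    }
    invisible(path)
}

# scan one motif on the plus strand of seq (character, already normalized);
# returns integer start positions and scores
.scanPlus <- function(chars, motif) {
    w <- motifWidth(motif)
    L <- length(chars)
    if (L < w) return(list(starts = integer(0), scores = numeric(0)))
    starts <- seq_len(L - w + 1L)
    if (motif@kind == "consensus") {
        allowed <- .iupacAllowed()
        ok <- rep(TRUE, length(starts))
        cons <- strsplit(motif@consensus, "")[[1]]
        for (p in seq_len(w)) {
            obs <- chars[starts + p - 1L]
            ok <- ok & obs %in% allowed[[cons[p]]]
        }
        list(starts = starts[ok], scores = rep(1.0, sum(ok)))
    } else {
        counts <- rbind(motif@matrix, N = 0)  # observed N contributes 0
        idx <- match(chars, c("A", "C", "G", "T", "N"))
        best <- sum(apply(motif@matrix, 2, max))
        sc <- numeric(length(starts))
        for (p in seq_len(w))
            sc <- sc + counts[cbind(idx[starts + p - 1L], p)]
        sc <- sc / best
        keep <- sc >= motif@threshold
        list(starts = starts[keep], scores = sc[keep])
    }
}

# reverse-complement a motif model (for minus-strand scanning)
.revcompMotif <- function(motif) {
    if (motif@kind == "consensus") {
        consensusMotif(motif@family, motif@matrixName,
                       revcompIupac(motif@consensus), core = motif@core)
    } else {
        m <- motif@matrix[c("T", "G", "C", "A"), rev(seq_len(ncol(motif@matrix))), drop = FALSE]
        rownames(m) <- c("A", "C", "G", "T")
        matrixMotif(motif@family, motif@matrixName, m, core = motif@core,
                    threshold = motif@threshold)
    }
}

#' Scan a sequence for motif hits on both strands
#'
#' Every window of each motif's width is evaluated on both strands. Consensus
#' motifs hit when every position is IUPAC-compatible (the code N matches any
#' base, but an observed N never satisfies a more specific code); matrix
#' motifs hit when the matrix-similarity score
#' (sum of observed-base counts over the sum of per-position maxima) reaches
#' the motif's threshold. Hit coordinates are always reported on the plus
#' strand, shifted by `offset`; `matchedSequence` is the plus-strand word with
#' core positions upper-cased.
#'
#' @param seq character DNA string (or \linkS4class{AnnotatedSequence}).
#' @param motifs list of \linkS4class{Motif}.
#' @param offset integer added to local 1-based coordinates in the output
#'   (default 0).
#' @return a data.frame with columns `family`, `matrixName`, `start`, `end`,
#'   `strand`, `matchedSequence`, `score`, `coreStart`, `coreEnd` (core in the
#'   same plus-strand frame), sorted by start, then strand, then matrixName.
#' @export
scanMotifs <- function(seq, motifs, offset = 0L) {
    if (is(seq, "AnnotatedSequence")) seq <- seqResidues(seq)
    sequ <- toupper(seq)
    chars <- strsplit(sequ, "")[[1]]
    rows <- list()
    for (motif in motifs) {
        w <- motifWidth(motif)
        co <- motifCore(motif)
        for (str in c("+", "-")) {
            mo <- if (str == "+") motif else .revcompMotif(motif)
            hit <- .scanPlus(chars, mo)
            if (!length(hit$starts)) next
            # core positions in the plus-strand frame
            if (str == "+") {
                cs <- hit$starts + co[1] - 1L; ce <- hit$starts + co[2] - 1L
            } else {
                ends <- hit$starts + w - 1L
                cs <- ends - co[2] + 1L; ce <- ends - co[1] + 1L
            }
            word <- tolower(substring(sequ, hit$starts, hit$starts + w - 1L))
            # upper-case the core within the word
            word <- vapply(seq_along(word), function(k) {
                a <- cs[k] - hit$starts[k] + 1L; b <- ce[k] - hit$starts[k] + 1L
                paste0(substring(word[k], 1, a - 1),
                       toupper(substring(word[k], a, b)),
                       substring(word[k], b + 1, w))
            }, character(1))
            rows[[length(rows) + 1L]] <- data.frame(
                family = motif@family, matrixName = motif@matrixName,
                start = hit$starts + offset, end = hit$starts + w - 1L + offset,
                strand = str, matchedSequence = word, score = hit$scores,
                coreStart = cs + offset, coreEnd = ce + offset,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(family = character(0), matrixName = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), matchedSequence = character(0),
                          score = numeric(0), coreStart = integer(0),
                          coreEnd = integer(0), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out <- out[order(out$start, out$strand, out$matrixName), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Delete a motif hit's core from a sequence
#'
#' Excises the core positions of the hit (the in-silico counterpart of
#' site-directed core deletion); the sequence shortens by the core length.
#' Rescanning the mutant yields no hit of that motif overlapping the excision
#' point.
#'
#' @param seq character DNA string.
#' @param hit one row of a [scanMotifs()] data.frame.
#' @param offset the offset the hits were scanned with (default 0), so the
#'   hit's coordinates can be mapped back onto `seq`.
#' @return the mutated sequence.
#' @export
deleteCore <- function(seq, hit, offset = 0L) {
    if (is(seq, "AnnotatedSequence")) seq <- seqResidues(seq)
    cs <- hit$coreStart - offset; ce <- hit$coreEnd - offset
    if (length(cs) != 1L) stop("deleteCore expects a single hit row")
    if (cs < 1L || ce > nchar(seq))
        stop("hit core [", cs, ", ", ce, "] lies outside the sequence")
    paste0(substring(seq, 1, cs - 1L), substring(seq, ce + 1L, nchar(seq)))
}

#' Motif hits disrupted by a sequence variant
#'
#' Classifies hits by whether the variant interval intersects the hit's core
#' (\code{core}) or only its non-core flanks (\code{flankOnly}). Hits not
#' touched at all are omitted. The all-clear outcome — a variant in a region
#' with no motif cores — is an empty \code{core} element.
#'
#' @param variant an \linkS4class{IRanges} of length 1 (same coordinate frame
#'   as the hits).
#' @param hits a [scanMotifs()] data.frame.
#' @return a list with data.frames `core` and `flankOnly`.
#' @export
disruptedSites <- function(variant, hits) {
    stopifnot(length(variant) == 1L)
    vs <- IRanges::start(variant); ve <- IRanges::end(variant)
    coreHit <- hits$coreStart <= ve & hits$coreEnd >= vs
    anyHit <- hits$start <= ve & hits$end >= vs
    list(core = hits[coreHit, , drop = FALSE],
         flankOnly = hits[anyHit & !coreHit, , drop = FALSE])
}

#' Write motif hits as TSV
#'
#' @param hits a [scanMotifs()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHitsTsv <- function(hits, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# motif hits; coordinates 1-based inclusive, plus strand", con)
    utils::write.table(hits, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
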