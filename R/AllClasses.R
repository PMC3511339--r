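#' @useDynLib CNEscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom IRanges IRanges start end width reduce setdiff findOverlaps
#'   pintersect overlapsAny
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
#' @importFrom GenomicRanges GRanges seqnames strand
#' @importFrom Biostrings DNAString DNAStringSet readBStringSet writeXStringSet
#'   BStringSet IUPAC_CODE_MAP
#' @importFrom stats runif rgeom
#' @importFrom utils read.table write.table
NULL

#' Annotated DNA sequence for one species
#'
#' A single locus sequence from one species together with its coding/exon
#' intervals, the unit on which noncoding extraction operates. Residues are
#' upper-case over the alphabet A, C, G, T, N. All coordinates in this
#' package are 1-based closed \linkS4class{IRanges}; conversion to 0-based
#' half-open happens only when writing BED.
#'
#' @slot species single character, species identifier.
#' @slot seqname single character, sequence/locus name.
#' @slot residues a \linkS4class{DNAString}.
#' @slot coding an \linkS4class{IRanges} of coding/exon intervals, each within
#'   the sequence bounds.
#'
#' @export
setClass("AnnotatedSequence",
    representation(species = "character", seqname = "character",
                   residues = "DNAString", coding = "IRanges"))

setValidity("AnnotatedSequence", function(object) {
    msg <- character()
    if (length(object@species) != 1L) msg <- c(msg, "'species' must be a single string")
    if (length(object@seqname) != 1L) msg <- c(msg, "'seqname' must be a single string")
    bad <- setdiff(unique(strsplit(as.character(object@residues), "")[[1]]),
                   c("A", "C", "G", "T", "N"))
    if (length(bad))
        msg <- c(msg, paste0("residues contain disallowed characters: ",
                             paste(bad, collapse = ", ")))
    L <- length(object@residues)
    if (length(object@coding)) {
        if (any(IRanges::start(object@coding) < 1L) ||
            any(IRanges::end(object@coding) > L))
            msg <- c(msg, "coding intervals must lie within the sequence")
        if (any(IRanges::width(object@coding) < 1L))
            msg <- c(msg, "coding intervals must have positive width")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedSequence
#'
#' @param residues DNA sequence as a character string or
#'   \linkS4class{DNAString}. Lower case is upper-cased and U is mapped to T.
#' @param species species identifier.
#' @param seqname sequence name.
#' @param coding an \linkS4class{IRanges} of coding intervals (1-based closed).
#' @return an \linkS4class{AnnotatedSequence}.
#' @examples
#' annotatedSequence("acgtACGT", species = "mouse", seqname = "locus1")
#' @export
annotatedSequence <- function(residues, species = "unknown", seqname = "seq",
                              coding = IRanges::IRanges()) {
    res <- normalizeDna(as.character(residues))
    new("AnnotatedSequence", species = as.character(species),
        seqname = as.character(seqname),
        residues = Biostrings::DNAString(res), coding = coding)
}

# Upper-case, map U->T, validate the A/C/G/T/N alphabet.
normalizeDna <- function(x) {
    x <- chartr("u", "t", toupper(x))
    x <- chartr("U", "T", x)
    bad <- regmatches(x, regexpr("[^ACGTN]", x))
    if (length(bad) && nzchar(bad))
        stop("disallowed residue '", bad, "' in sequence", call. = FALSE)
    x
}

#' @describeIn AnnotatedSequence-class species accessor
#' @param x an \code{AnnotatedSequence}.
#' @export
seqSpecies <- function(x) x@species

#' @describeIn AnnotatedSequence-class sequence name accessor
#' @export
seqName <- function(x) x@seqname

#' @describeIn AnnotatedSequence-class residues as a character string
#' @export
seqResidues <- function(x) as.character(x@residues)

#' @describeIn AnnotatedSequence-class coding intervals accessor
#' @export
codingIntervals <- function(x) x@coding

setMethod("show", "AnnotatedSequence", function(object) {
    cat("AnnotatedSequence:", object@species, "/", object@seqname,
        "|", length(object@residues), "bp |",
        length(object@coding), "coding interval(s)\n")
})

#' Gapped pairwise alignment of orthologous sequences
#'
#' A global alignment of a baseline and a target sequence, stored as two
#' equal-length gapped strings plus bidirectional residue/column maps used for
#' coordinate projection between species.
#'
#' @slot baselineName,targetName sequence identifiers.
#' @slot alignedBaseline,alignedTarget gapped aligned strings (equal length).
#' @slot score alignment score (NA for imported alignments without one).
#'
#' @export
setClass("OrthologAlignment",
    representation(baselineName = "character", targetName = "character",
                   alignedBaseline = "character", alignedTarget = "character",
                   score = "numeric"))

setValidity("OrthologAlignment", function(object) {
    msg <- character()
    if (nchar(object@alignedBaseline) != nchar(object@alignedTarget))
        msg <- c(msg, "aligned strings must have equal length")
    bs <- strsplit(object@alignedBaseline, "")[[1]]
    ts <- strsplit(object@alignedTarget, "")[[1]]
    if (any(bs == "-" & ts == "-"))
        msg <- c(msg, "no column may be gap in both sequences")
    if (length(msg)) msg else TRUE
})

#' Construct an OrthologAlignment from two gapped strings
#'
#' @param alignedBaseline,alignedTarget equal-length gapped strings
#'   ('-' is the gap character).
#' @param baselineName,targetName identifiers.
#' @param score optional alignment score.
#' @return an \linkS4class{OrthologAlignment}.
#' @export
orthologAlignment <- function(alignedBaseline, alignedTarget,
                              baselineName = "baseline", targetName = "target",
                              score = NA_real_) {
    new("OrthologAlignment",
        baselineName = baselineName, targetName = targetName,
        alignedBaseline = toupper(alignedBaseline),
        alignedTarget = toupper(alignedTarget),
        score = as.numeric(score))
}

#' @describeIn OrthologAlignment-class number of alignment columns
#' @param x an \code{OrthologAlignment}.
#' @export
alignmentColumns <- function(x) nchar(x@alignedBaseline)

#' @describeIn OrthologAlignment-class gapped baseline string
#' @export
alignedBaseline <- function(x) x@alignedBaseline

#' @describeIn OrthologAlignment-class gapped target string
#' @export
alignedTarget <- function(x) x@alignedTarget

#' @describeIn OrthologAlignment-class alignment score
#' @export
alignmentScore <- function(x) x@score

#' @describeIn OrthologAlignment-class ungapped sequence of one species
#' @param species \code{"baseline"} or \code{"target"}.
#' @export
ungappedSequence <- function(x, species = c("baseline", "target")) {
    species <- match.arg(species)
    s <- if (species == "baseline") x@alignedBaseline else x@alignedTarget
    gsub("-", "", s, fixed = TRUE)
}

setMethod("show", "OrthologAlignment", function(object) {
    cat("OrthologAlignment:", object@baselineName, "vs", object@targetName,
        "|", nchar(object@alignedBaseline), "columns | score",
        format(object@score), "\n")
})

#' Transcription factor binding-site motif
#'
#' A binding-site model, either an IUPAC consensus word or a position-count
#' matrix (4 x width, rows A/C/G/T), with a designated core interval (the most
#' informative positions, rendered upper-case in reports).
#'
#' @slot family motif family identifier (e.g. \code{"V$AP-1F"}).
#' @slot matrixName unique matrix identifier (e.g. \code{"V$AP-1.01"}).
#' @slot kind \code{"consensus"} or \code{"matrix"}.
#' @slot consensus IUPAC consensus string (consensus motifs).
#' @slot matrix position-count matrix (matrix motifs; 0-column otherwise).
#' @slot core integer length-2 vector, first and last core position.
#' @slot threshold matrix-similarity threshold in [0, 1] for matrix scanning.
#'
#' @export
setClass("Motif",
    representation(family = "character", matrixName = "character",
                   kind = "character", consensus = "character",
                   matrix = "matrix", core = "integer",
                   threshold = "numeric"))

setValidity("Motif", function(object) {
    msg <- character()
    if (!object@kind %in% c("consensus", "matrix"))
        msg <- c(msg, "kind must be 'consensus' or 'matrix'")
    w <- motifWidth(object)
    if (object@kind == "consensus") {
        codes <- names(Biostrings::IUPAC_CODE_MAP)
        bad <- setdiff(strsplit(object@consensus, "")[[1]], codes)
        if (length(bad))
            msg <- c(msg, paste0("unknown IUPAC code(s): ", paste(bad, collapse = ", ")))
    } else {
        if (nrow(object@matrix) != 4L)
            msg <- c(msg, "count matrix must have 4 rows (A, C, G, T)")
        if (any(colSums(object@matrix) <= 0))
            msg <- c(msg, "every matrix column must have positive total count")
        if (any(object@matrix < 0))
            msg <- c(msg, "matrix counts must be nonnegative")
    }
    if (length(object@core) != 2L || any(is.na(object@core)))
        msg <- c(msg, "core must be two positions")
    else if (object@core[1] < 1L || object@core[2] > w || object@core[1] > object@core[2])
        msg <- c(msg, "core must lie within the motif width")
    if (object@threshold < 0 || object@threshold > 1)
        msg <- c(msg, "threshold must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn Motif-class motif width in bp
#' @param x a \code{Motif}.
#' @export
motifWidth <- function(x) {
    if (x@kind == "consensus") nchar(x@consensus) else ncol(x@matrix)
}

#' @describeIn Motif-class core positions (length-2 integer)
#' @export
motifCore <- function(x) x@core

#' @describeIn Motif-class matrix name accessor
#' @export
motifName <- function(x) x@matrixName

#' Construct a consensus motif
#'
#' @param family family identifier.
#' @param matrixName unique matrix identifier.
#' @param consensus IUPAC consensus word.
#' @param core integer length-2, first and last core position
#'   (default: the whole motif).
#' @return a \linkS4class{Motif}.
#' @examples
#' consensusMotif("V$AP-1F", "V$AP-1.01", "TGASTCA", core = c(3, 6))
#' @export
consensusMotif <- function(family, matrixName, consensus, core = NULL) {
    consensus <- toupper(consensus)
    if (is.null(core)) core <- c(1L, nchar(consensus))
    new("Motif", family = family, matrixName = matrixName, kind = "consensus",
        consensus = consensus, matrix = matrix(0, 4, 0, dimnames = list(c("A","C","G","T"), NULL)),
        core = as.integer(core), threshold = 1.0)
}

#' Construct a position-count-matrix motif
#'
#' @param family family identifier.
#' @param matrixName unique matrix identifier.
#' @param counts 4 x width numeric matrix with rows A, C, G, T.
#' @param core integer length-2 core interval (default whole width).
#' @param threshold matrix-similarity threshold in [0, 1]; a window is a hit
#'   when (sum of counts of observed bases) / (sum of per-position maxima)
#'   is at least this value. Default 0.85.
#' @return a \linkS4class{Motif}.
#' @export
matrixMotif <- function(family, matrixName, counts, core = NULL, threshold = 0.85) {
    counts <- as.matrix(counts)
    rownames(counts) <- c("A", "C", "G", "T")
    if (is.null(core)) core <- c(1L, ncol(counts))
    new("Motif", family = family, matrixName = matrixName, kind = "matrix",
        consensus = "", matrix = counts, core = as.integer(core),
        threshold = threshold)
}

setMethod("show", "Motif", function(object) {
    cat("Motif:", object@family, object@matrixName,
        sprintf("(%s, width %d, core %d-%d)\n", object@kind,
                motifWidth(object), object@core[1], object@core[2]))
    if (object@kind == "consensus") cat("  consensus:", object@consensus, "\n")
})
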