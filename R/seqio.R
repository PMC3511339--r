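#' Read DNA sequences from FASTA
#'
#' Reads a multi-record FASTA file into a list of
#' \linkS4class{AnnotatedSequence} objects (without annotations). Residues are
#' upper-cased and U is mapped to T; only A/C/G/T/N are accepted.
#'
#' @param path path to a FASTA file.
#' @param species species label attached to every record (default: the file
#'   name without extension).
#' @return a list of \linkS4class{AnnotatedSequence}, in file order.
#' @seealso [writeFasta()]
#' @export
readFasta <- function(path, species = NULL) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    first <- readLines(path, n = 1L)
    if (length(first) == 0L)
        stop("FASTA format error in ", path, ": file is empty")
    if (!startsWith(first, ">"))
        stop("FASTA format error in ", path, ": first line is not a header: ", first)
    set <- Biostrings::readBStringSet(path)
    if (is.null(species))
        species <- sub("\\.[^.]*$", "", basename(path))
    lapply(seq_along(set), function(i) {
        nm <- strsplit(names(set)[i], "[ \t]")[[1]][1]
        annotatedSequence(as.character(set[[i]]), species = species, seqname = nm)
    })
}

#' Write AnnotatedSequence records to FASTA
#'
#' @param seqs a list of \linkS4class{AnnotatedSequence} (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
    if (is(seqs, "AnnotatedSequence")) seqs <- list(seqs)
    set <- Biostrings::DNAStringSet(vapply(seqs, seqResidues, character(1)))
    names(set) <- vapply(seqs, seqName, character(1))
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}

#' Read coding/exon annotation as intervals
#'
#' Reads BED (0-based half-open on disk) or GFF3 (1-based closed) and returns
#' 1-based closed intervals. GFF3 features are filtered to types CDS and exon;
#' BED rows are taken as-is.
#'
#' @param path annotation file path.
#' @param dialect `"BED"` or `"GFF3"`.
#' @param seqname optional sequence name to filter to.
#' @return a \linkS4class{GRanges} of coding intervals.
#' @export
readAnnotation <- function(path, dialect = c("BED", "GFF3"), seqname = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("annotation file not found: ", path)
    gr <- if (dialect == "BED") {
        rtracklayer::import(path, format = "bed")
    } else {
        g <- rtracklayer::import(path, format = "gff3")
        g[!is.na(g$type) & as.character(g$type) %in% c("CDS", "exon")]
    }
    if (length(gr) && any(GenomicRanges::width(gr) < 1L)) {
        bad <- which(GenomicRanges::width(gr) < 1L)[1]
        stop("annotation validation error: interval ", bad, " (",
             GenomicRanges::seqnames(gr)[bad], ":",
             GenomicRanges::start(gr)[bad], "-", GenomicRanges::end(gr)[bad],
             ") has end before start")
    }
    if (!is.null(seqname))
        gr <- gr[as.character(GenomicRanges::seqnames(gr)) == seqname]
    gr
}

#' Attach coding annotation to a sequence
#'
#' @param seq an \linkS4class{AnnotatedSequence}.
#' @param annotation a \linkS4class{GRanges} or \linkS4class{IRanges} of coding
#'   intervals. Strand is ignored: coding sequence is masked on both strands.
#' @return the sequence with coding intervals set.
#' @export
setCoding <- function(seq, annotation) {
    iv <- if (is(annotation, "GRanges")) {
        keep <- as.character(GenomicRanges::seqnames(annotation)) == seqName(seq)
        IRanges::ranges(annotation[keep])
    } else {
        annotation
    }
    annotatedSequence(seqResidues(seq), species = seqSpecies(seq),
                      seqname = seqName(seq), coding = iv)
}

#' Extract noncoding sequence
#'
#' Returns the complement of the union of coding intervals over the sequence,
#' as maximal intervals with their subsequences. Overlapping or adjacent
#' coding intervals are merged before complementing.
#'
#' @param seq an \linkS4class{AnnotatedSequence}.
#' @return a list with elements `intervals` (\linkS4class{IRanges}) and
#'   `sequences` (character vector of the corresponding subsequences).
#' @examples
#' s <- annotatedSequence(strrep("ACGT", 25), coding = IRanges::IRanges(11, 40))
#' extractNoncoding(s)$intervals
#' @export
extractNoncoding <- function(seq) {
    L <- nchar(seqResidues(seq))
    merged <- IRanges::reduce(codingIntervals(seq))
    nc <- IRanges::setdiff(IRanges::IRanges(1L, L), merged)
    res <- seqResidues(seq)
    list(intervals = nc,
         sequences = if (length(nc))
             substring(res, IRanges::start(nc), IRanges::end(nc))
         else character(0))
}

#' Render an interval in report coordinates
#'
#' Internal intervals are 1-based closed, so the "From-to" rendering used in
#' conserved-site tables is the identity on start/end.
#'
#' @param iv an \linkS4class{IRanges} (possibly of length > 1).
#' @return a two-column integer matrix with columns `from`, `to`.
#' @seealso [parseReportCoords()]
#' @export
reportCoords <- function(iv) {
    cbind(from = IRanges::start(iv), to = IRanges::end(iv))
}

#' Parse "from-to" report coordinates back into intervals
#'
#' @param x character vector like `"122-132"` (en dash also accepted).
#' @return an \linkS4class{IRanges}.
#' @export
parseReportCoords <- function(x) {
    x <- gsub("–", "-", x)
    parts <- strsplit(x, "-", fixed = TRUE)
    from <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    to <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    if (any(is.na(from) | is.na(to) | to < from))
        stop("malformed report coordinates: ", paste(x[is.na(from) | is.na(to) | to < from], collapse = ", "))
    IRanges::IRanges(from, to)
}

#' Write intervals as BED
#'
#' Starts are converted to the 0-based half-open convention on output.
#'
#' @param gr a \linkS4class{GRanges} (uses mcols `name` and `score` if present).
#' @param path output path.
#' @param header logical; write a coordinate-convention comment line.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path, header = TRUE) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = if (!is.null(gr$name)) gr$name else rep(".", length(gr)),
        score = if (!is.null(gr$score)) gr$score else rep(0L, length(gr)),
        strand = {
            s <- as.character(GenomicRanges::strand(gr))
            ifelse(s == "*", ".", s)
        },
        stringsAsFactors = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    if (header)
        writeLines("# BED: 0-based half-open coordinates", con)
    if (nrow(df))
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    invisible(path)
}
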