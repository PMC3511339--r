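#' Pipeline configuration
#'
#' Collects every parameter of the end-to-end run. Accepts either in-memory
#' \linkS4class{AnnotatedSequence} objects or file paths (FASTA, with
#' optional BED/GFF3 coding annotation).
#'
#' @param baseline baseline \linkS4class{AnnotatedSequence} or FASTA path.
#' @param target target \linkS4class{AnnotatedSequence} or FASTA path.
#' @param baselineAnnotation,targetAnnotation optional annotation file paths
#'   (BED or GFF3, by extension) whose coding intervals are masked before
#'   alignment.
#' @param motifs list of \linkS4class{Motif}, or a motif-library file path;
#'   default [coreMotifLibrary()].
#' @param alignParams an [alignParams()] list.
#' @param consParams a [conservationParams()] list.
#' @param minOverlap reciprocal-overlap threshold for TFBS pairing
#'   (default 0.5).
#' @param requireStrand require strand agreement in pairing (default TRUE).
#' @param topK number of top-scoring regions to scan for motifs
#'   (default all).
#' @param outDir output directory.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(baseline, target,
                           baselineAnnotation = NULL, targetAnnotation = NULL,
                           motifs = NULL,
                           alignParams = CNEscan::alignParams(),
                           consParams = conservationParams(),
                           minOverlap = 0.5, requireStrand = TRUE,
                           topK = Inf, outDir = tempfile("cnescan_run_")) {
    structure(list(baseline = baseline, target = target,
                   baselineAnnotation = baselineAnnotation,
                   targetAnnotation = targetAnnotation,
                   motifs = motifs, alignParams = alignParams,
                   consParams = consParams, minOverlap = minOverlap,
                   requireStrand = requireStrand, topK = topK,
                   outDir = outDir),
              class = "PipelineConfig")
}

.loadSeq <- function(x, annotationPath = NULL, what = "sequence") {
    s <- if (is(x, "AnnotatedSequence")) x
         else if (is.character(x) && length(x) == 1L) readFasta(x)[[1]]
         else stop("cannot interpret ", what, " input")
    if (!is.null(annotationPath)) {
        dialect <- if (grepl("\\.gff3?$", annotationPath, ignore.case = TRUE))
            "GFF3" else "BED"
        s <- setCoding(s, readAnnotation(annotationPath, dialect))
    }
    s
}

# mask coding intervals to N so they can neither count as identity matches
# nor carry motif hits, while keeping one coordinate frame
.maskCoding <- function(seq) {
    iv <- IRanges::reduce(codingIntervals(seq))
    if (!length(iv)) return(seq)
    chars <- strsplit(seqResidues(seq), "")[[1]]
    for (k in seq_along(iv))
        chars[IRanges::start(iv)[k]:IRanges::end(iv)[k]] <- "N"
    annotatedSequence(paste(chars, collapse = ""), species = seqSpecies(seq),
                      seqname = seqName(seq), coding = iv)
}

#' Run the conserved-element discovery pipeline end to end
#'
#' Noncoding masking, global alignment, conserved-region calling and
#' ranking, per-region motif scanning on both species, cross-species TFBS
#' pairing, and deterministic file output (`regions.bed`, `regions.tsv`,
#' `alignment.fasta`, `hits_baseline.tsv`, `hits_target.tsv`,
#' `tfbs_conserved.tsv`, `tfbs_conserved.bed`, `report.yaml`).
#'
#' @param cfg a [pipelineConfig()].
#' @param quiet suppress progress messages (default TRUE).
#' @return invisibly, a report list: `regions` (ranked
#'   \linkS4class{GRanges}), `baseHits`, `targHits`, `pairs`, `alignment`,
#'   `counts` (per-stage record counts) and `files`.
#' @export
runPipeline <- function(cfg, quiet = TRUE) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    say <- function(...) if (!quiet) message("[cnescan] ", ...)
    stage <- "input"
    report <- tryCatch({
        base <- .loadSeq(cfg$baseline, cfg$baselineAnnotation, "baseline")
        targ <- .loadSeq(cfg$target, cfg$targetAnnotation, "target")
        motifs <- if (is.null(cfg$motifs)) coreMotifLibrary()
                  else if (is.character(cfg$motifs)) readMotifLibrary(cfg$motifs)
                  else cfg$motifs
        dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)

        stage <- "noncoding-mask"
        baseM <- .maskCoding(base)
        targM <- .maskCoding(targ)

        stage <- "align"
        say("aligning ", seqName(base), " vs ", seqName(targ))
        aln <- alignPair(baseM, targM, cfg$alignParams)
        writeAlignment(aln, file.path(cfg$outDir, "alignment.fasta"))

        stage <- "conservation"
        regions <- callConservedRegions(aln, cfg$consParams)
        regions <- rankRegions(regions, cfg$topK)
        say(length(regions), " conserved region(s)")
        writeRegionsBed(regions, file.path(cfg$outDir, "regions.bed"))
        writeRegionsTsv(regions, file.path(cfg$outDir, "regions.tsv"),
                        targetName = seqName(targ))

        stage <- "motif-scan"
        baseHits <- list(); targHits <- list()
        for (k in seq_along(regions)) {
            bs <- GenomicRanges::start(regions)[k]
            be <- GenomicRanges::end(regions)[k]
            ts <- regions$targetStart[k]; te <- regions$targetEnd[k]
            baseHits[[k]] <- scanMotifs(
                substring(seqResidues(baseM), bs, be), motifs, offset = bs - 1L)
            if (!is.na(ts))
                targHits[[k]] <- scanMotifs(
                    substring(seqResidues(targM), ts, te), motifs, offset = ts - 1L)
        }
        bh <- if (length(baseHits)) do.call(rbind, baseHits) else scanMotifs("A", list())
        th <- if (length(targHits)) do.call(rbind, targHits) else scanMotifs("A", list())
        writeHitsTsv(bh, file.path(cfg$outDir, "hits_baseline.tsv"))
        writeHitsTsv(th, file.path(cfg$outDir, "hits_target.tsv"))

        stage <- "tfbs-pairing"
        pairs <- pairConservedHits(bh, th, aln, minOverlap = cfg$minOverlap,
                                   requireStrand = cfg$requireStrand)
        writeConservedTable(pairs, file.path(cfg$outDir, "tfbs_conserved.tsv"))
        if (nrow(pairs)) {
            pgr <- GenomicRanges::GRanges(
                seqName(base),
                IRanges::IRanges(pairs$baseStart, pairs$baseEnd),
                strand = pairs$strand)
            pgr$name <- pairs$matrixName
            pgr$score <- as.integer(round(pairs$reciprocalOverlap * 1000))
        } else {
            pgr <- GenomicRanges::GRanges()
        }
        writeBed(pgr, file.path(cfg$outDir, "tfbs_conserved.bed"))

        stage <- "report"
        counts <- list(regions = length(regions), baselineHits = nrow(bh),
                       targetHits = nrow(th), conservedTfbs = nrow(pairs))
        yaml::write_yaml(list(
            baseline = seqName(base), target = seqName(targ),
            parameters = list(
                align = unclass(cfg$alignParams),
                conservation = unclass(cfg$consParams),
                minOverlap = cfg$minOverlap,
                requireStrand = cfg$requireStrand),
            counts = counts), file.path(cfg$outDir, "report.yaml"))
        list(regions = regions, baseHits = bh, targHits = th, pairs = pairs,
             alignment = aln, counts = counts,
             files = list.files(cfg$outDir, full.names = TRUE))
    }, error = function(e) {
        stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
             call. = FALSE)
    })
    invisible(report)
}

#' One-command synthetic demo
#'
#' Simulates an ortholog pair with the default [simulationConfig()], runs the
#' full pipeline, evaluates recovery of the planted blocks against truth,
#' and writes everything (plus `truth_blocks.bed`, `metrics.tsv` and the
#' simulated FASTAs) to `outDir`.
#'
#' @param outDir output directory.
#' @param seed simulation seed (default 1).
#' @param quiet suppress progress messages.
#' @return invisibly, the [runPipeline()] report extended with `truth` and
#'   `metrics`.
#' @export
runDemo <- function(outDir = tempfile("cnescan_demo_"), seed = 1L, quiet = TRUE) {
    sim <- simulateOrthologPair(simulationConfig(seed = seed))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFasta(sim$baseline, file.path(outDir, "baseline.fasta"))
    writeFasta(sim$target, file.path(outDir, "target.fasta"))
    tgr <- GenomicRanges::GRanges(seqName(sim$baseline), sim$truth$blocksBaseline)
    tgr$name <- paste0("truth", seq_along(tgr))
    writeBed(tgr, file.path(outDir, "truth_blocks.bed"))

    cfg <- pipelineConfig(sim$baseline, sim$target, outDir = outDir)
    report <- runPipeline(cfg, quiet = quiet)
    metrics <- evaluateRecovery(sim$truth, report$regions,
                                tolerance = cfg$consParams$window)
    mdf <- data.frame(metric = c("precision", "recall", "mean_boundary_error_bp",
                                 "n_matched", "n_called", "n_truth"),
                      value = c(metrics$precision, metrics$recall,
                                metrics$meanBoundaryError, metrics$nMatched,
                                metrics$nCalled, metrics$nTruth))
    utils::write.table(mdf, file.path(outDir, "metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$truth <- sim$truth
    report$metrics <- metrics
    invisible(report)
}
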