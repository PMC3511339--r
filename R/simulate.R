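#' Simulation configuration for synthetic ortholog pairs
#'
#' Describes a pair of orthologous loci: a neutral divergence background with
#' planted high-identity blocks (candidate conserved elements) and planted
#' motif instances. The defaults emulate the regime conserved-element
#' detection assumes: a diverged background near 50 percent alignable
#' identity carrying blocks of 70-95 percent identity and 100-800 bp, with
#' AP-1-like words on both strands and an NFkB-like decamer inside the first
#' block.
#'
#' @param seed integer RNG seed; one stream drives all randomness.
#' @param baselineLength baseline locus length in bp (default 3000).
#' @param backgroundIdentity background per-base identity fraction
#'   (default 0.5).
#' @param indelRate per-base indel probability outside planted motif
#'   footprints (default 0.02; half insertions, half deletions).
#' @param indelMeanLength mean of the geometric indel length distribution
#'   (default 2).
#' @param plantedBlocks data.frame with columns `start`, `length`,
#'   `identity`; blocks must be disjoint, in bounds, with identity in
#'   (backgroundIdentity, 1].
#' @param plantedMotifs data.frame with columns `name`, `word` (the concrete
#'   instance written verbatim), `start` (baseline position) and `scope`
#'   (`"both"` or `"baseline-only"`).
#' @param codingIntervals \linkS4class{IRanges} of coding intervals on the
#'   baseline (default none).
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             baselineLength = 3000L,
                             backgroundIdentity = 0.5,
                             indelRate = 0.02,
                             indelMeanLength = 2,
                             plantedBlocks = data.frame(
                                 start = c(501L, 1501L, 2401L),
                                 length = c(300L, 250L, 400L),
                                 identity = c(0.85, 0.90, 0.80)),
                             plantedMotifs = data.frame(
                                 name = c("V$AP-1.01", "V$AP-1.01", "V$NFKAPPAB.01"),
                                 word = c("TGACTCA", "TGAGTCA", "GGGAAATTCC"),
                                 start = c(560L, 620L, 700L),
                                 scope = "both",
                                 stringsAsFactors = FALSE),
                             codingIntervals = IRanges::IRanges()) {
    cfg <- list(seed = as.integer(seed), baselineLength = as.integer(baselineLength),
                backgroundIdentity = backgroundIdentity, indelRate = indelRate,
                indelMeanLength = indelMeanLength, plantedBlocks = plantedBlocks,
                plantedMotifs = plantedMotifs, codingIntervals = codingIntervals)
    class(cfg) <- "SimulationConfig"
    if (backgroundIdentity < 0 || backgroundIdentity > 1 ||
        indelRate < 0 || indelRate > 1)
        stop("probabilities must lie in [0, 1]")
    if (nrow(plantedBlocks)) {
        iv <- IRanges::IRanges(plantedBlocks$start,
                               width = plantedBlocks$length)
        if (min(IRanges::start(iv)) < 1L || max(IRanges::end(iv)) > baselineLength)
            stop("planted blocks must lie within the baseline sequence")
        if (length(IRanges::reduce(iv, min.gapwidth = 0L)) < length(iv))
            stop("planted blocks must be disjoint")
        if (any(plantedBlocks$identity <= backgroundIdentity) ||
            any(plantedBlocks$identity > 1))
            stop("block identities must lie in (backgroundIdentity, 1]")
    }
    if (nrow(plantedMotifs)) {
        mv <- IRanges::IRanges(plantedMotifs$start,
                               width = nchar(plantedMotifs$word))
        if (min(IRanges::start(mv)) < 1L || max(IRanges::end(mv)) > baselineLength)
            stop("planted motifs must lie within the baseline sequence")
        if (length(IRanges::reduce(mv, min.gapwidth = 0L)) < length(mv))
            stop("planted motifs must not overlap one another")
    }
    cfg
}

#' Simulate an orthologous sequence pair with known truth
#'
#' The baseline is drawn uniformly over A/C/G/T; planted motif words are then
#' written verbatim. The target copies each baseline base with probability
#' equal to the enclosing block's identity (background identity elsewhere),
#' substituting uniformly over the three alternatives otherwise, and suffers
#' insertions/deletions at `indelRate` outside planted motif footprints
#' (motifs with scope `"both"` are copied verbatim and indel-free, so truth
#' coordinates stay exact). Fully reproducible from the seed.
#'
#' @param cfg a [simulationConfig()].
#' @return a list with `baseline` and `target`
#'   (\linkS4class{AnnotatedSequence}) and `truth`, a list holding
#'   `blocksBaseline`/`blocksTarget` (\linkS4class{IRanges}),
#'   `motifsBaseline`/`motifsTarget` (data.frames with `name`, `start`,
#'   `end`), the baseline->target coordinate `map` (NA at deleted bases) and
#'   the generating `config`.
#' @export
simulateOrthologPair <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(cfg$seed)
    L <- cfg$baselineLength
    bases <- c("A", "C", "G", "T")
    bl <- sample(bases, L, replace = TRUE)

    # plant motif instances into the baseline
    motifFootprint <- logical(L)
    pm <- cfg$plantedMotifs
    if (nrow(pm)) {
        for (k in seq_len(nrow(pm))) {
            w <- strsplit(toupper(pm$word[k]), "")[[1]]
            idx <- pm$start[k]:(pm$start[k] + length(w) - 1L)
            bl[idx] <- w
            if (pm$scope[k] == "both") motifFootprint[idx] <- TRUE
        }
    }

    # per-position identity
    p <- rep(cfg$backgroundIdentity, L)
    pb <- cfg$plantedBlocks
    if (nrow(pb)) {
        for (k in seq_len(nrow(pb))) {
            idx <- pb$start[k]:(pb$start[k] + pb$length[k] - 1L)
            p[idx] <- pb$identity[k]
        }
    }

    # substitutions (suppressed inside both-species motif footprints)
    sub <- runif(L) >= p & !motifFootprint
    tchars <- bl
    if (any(sub)) {
        shift <- sample.int(3L, sum(sub), replace = TRUE)
        tchars[sub] <- bases[((match(bl[sub], bases) - 1L + shift) %% 4L) + 1L]
    }

    # indels outside motif footprints
    ev <- runif(L) < cfg$indelRate & !motifFootprint
    isDel <- ev & runif(L) < 0.5
    isIns <- ev & !isDel
    insLen <- integer(L)
    if (any(isIns))
        insLen[isIns] <- rgeom(sum(isIns), prob = 1 / cfg$indelMeanLength) + 1L
    insSeq <- character(L)
    if (any(isIns))
        insSeq[isIns] <- vapply(insLen[isIns], function(n)
            paste(sample(bases, n, replace = TRUE), collapse = ""), character(1))

    emitted <- ifelse(isDel, "", tchars)
    pieces <- paste0(emitted, insSeq)
    lens <- nchar(emitted) + nchar(insSeq)
    endPos <- cumsum(lens)
    map <- ifelse(isDel, NA_integer_, endPos - lens + 1L)
    target <- paste(pieces, collapse = "")

    truthBlocksB <- IRanges::IRanges(pb$start, width = pb$length)
    mapRange <- function(s, e) {
        m <- map[s:e]
        if (all(is.na(m))) c(NA_integer_, NA_integer_)
        else c(min(m, na.rm = TRUE), max(m, na.rm = TRUE))
    }
    tb <- if (nrow(pb)) t(mapply(mapRange, pb$start, pb$start + pb$length - 1L))
          else matrix(integer(0), 0, 2)
    truthBlocksT <- IRanges::IRanges(tb[, 1], tb[, 2])

    motB <- data.frame(name = character(0), start = integer(0), end = integer(0))
    motT <- motB
    if (nrow(pm)) {
        motB <- data.frame(name = pm$name, start = pm$start,
                           end = pm$start + nchar(pm$word) - 1L,
                           stringsAsFactors = FALSE)
        both <- pm$scope == "both"
        if (any(both)) {
            ts <- map[pm$start[both]]
            motT <- data.frame(name = pm$name[both], start = ts,
                               end = ts + nchar(pm$word[both]) - 1L,
                               stringsAsFactors = FALSE)
        }
    }

    list(baseline = annotatedSequence(paste(bl, collapse = ""),
                                      species = "baseline", seqname = "locus_baseline",
                                      coding = cfg$codingIntervals),
         target = annotatedSequence(target, species = "target",
                                    seqname = "locus_target"),
         truth = list(blocksBaseline = truthBlocksB, blocksTarget = truthBlocksT,
                      motifsBaseline = motB, motifsTarget = motT,
                      map = map, config = cfg))
}

#' Score recovery of planted conserved blocks
#'
#' A called region matches a truth block when their reciprocal overlap is at
#' least 0.5 (each matched greedily, best overlap first). Precision and
#' recall are computed over that matching; boundary error is the mean
#' absolute start/end difference of matched pairs.
#'
#' @param truth the `truth` element of [simulateOrthologPair()] output (or an
#'   \linkS4class{IRanges} of truth blocks on the baseline).
#' @param called a \linkS4class{GRanges} from [callConservedRegions()], or an
#'   \linkS4class{IRanges}.
#' @param tolerance boundary tolerance in bp used for the
#'   `boundaryWithinTol` fraction (default 100).
#' @return a list: `precision`, `recall`, `meanBoundaryError`,
#'   `boundaryWithinTol`, `nMatched`, `nCalled`, `nTruth`.
#' @export
evaluateRecovery <- function(truth, called, tolerance = 100) {
    tb <- if (is(truth, "IRanges")) truth else truth$blocksBaseline
    cb <- if (is(called, "GRanges")) IRanges::ranges(called) else called
    nT <- length(tb); nC <- length(cb)
    if (nC == 0L)
        return(list(precision = NA_real_, recall = 0, meanBoundaryError = NA_real_,
                    boundaryWithinTol = NA_real_, nMatched = 0L,
                    nCalled = 0L, nTruth = nT))
    cand <- list()
    for (i in seq_len(nT)) for (j in seq_len(nC)) {
        ov <- min(IRanges::end(tb)[i], IRanges::end(cb)[j]) -
              max(IRanges::start(tb)[i], IRanges::start(cb)[j]) + 1L
        if (ov <= 0L) next
        ro <- min(ov / IRanges::width(tb)[i], ov / IRanges::width(cb)[j])
        if (ro >= 0.5) cand[[length(cand) + 1L]] <- c(i, j, ro)
    }
    if (!length(cand))
        return(list(precision = 0, recall = 0, meanBoundaryError = NA_real_,
                    boundaryWithinTol = NA_real_, nMatched = 0L,
                    nCalled = nC, nTruth = nT))
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, 3]), , drop = FALSE]
    usedT <- logical(nT); usedC <- logical(nC); pairs <- list()
    for (k in seq_len(nrow(cm))) {
        i <- cm[k, 1]; j <- cm[k, 2]
        if (!usedT[i] && !usedC[j]) {
            usedT[i] <- TRUE; usedC[j] <- TRUE
            pairs[[length(pairs) + 1L]] <- c(i, j)
        }
    }
    pm <- do.call(rbind, pairs)
    errS <- abs(IRanges::start(tb)[pm[, 1]] - IRanges::start(cb)[pm[, 2]])
    errE <- abs(IRanges::end(tb)[pm[, 1]] - IRanges::end(cb)[pm[, 2]])
    be <- (errS + errE) / 2
    list(precision = nrow(pm) / nC, recall = nrow(pm) / nT,
         meanBoundaryError = mean(be),
         boundaryWithinTol = mean(errS <= tolerance & errE <= tolerance),
         nMatched = nrow(pm), nCalled = nC, nTruth = nT)
}

#' Printed conserved-site fixtures for the motif scanner
#'
#' Sequence fragments of the mouse CR1 element as printed in the
#' conserved-TFBS table, each with its printed start offset, and the printed
#' spans of the AP-1 and NFkB rows. Used as a regression fixture: scanning
#' each fragment with the bundled consensus motifs must yield hits contained
#' in the printed spans.
#'
#' @return a list with `fragments` (data.frame: `name`, `offset`,
#'   `sequence`) and `expected` (data.frame: `fragment`, `matrixName`,
#'   `strand`, `from`, `to` — the printed spans).
#' @export
makeTable2Fixture <- function() {
    fragments <- data.frame(
        name = c("ap1_site1", "ap1_site2", "nfkb_site"),
        offset = c(121L, 614L, 724L),
        sequence = c("tgtgactcagc", "cctgactcact", "ctgggaaatccct"),
        stringsAsFactors = FALSE)
    expected <- data.frame(
        fragment = c("ap1_site1", "ap1_site1", "ap1_site2", "ap1_site2", "nfkb_site"),
        matrixName = c("V$AP-1.01", "V$AP-1.01", "V$AP-1.01", "V$AP-1.01",
                       "V$NFKAPPAB.01"),
        strand = c("+", "-", "+", "-", "+"),
        from = c(122L, 122L, 615L, 615L, 725L),
        to = c(132L, 132L, 625L, 625L, 737L),
        stringsAsFactors = FALSE)
    list(fragments = fragments, expected = expected)
}

#' The motif library bundled with the package
#'
#' Consensus models for the near-palindromic AP-1 heptamer TGASTCA (core
#' rendered as the central ACTC/AGTC tetramer) and the NFkB decamer
#' GGGRNNYYCC (core GGGR).
#'
#' @return a list of \linkS4class{Motif}.
#' @export
coreMotifLibrary <- function() {
    readMotifLibrary(system.file("extdata", "motifs_core.tsv",
                                 package = "CNEscan", mustWork = TRUE))
}
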