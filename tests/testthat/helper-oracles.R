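# Independent brute-force oracles. These deliberately re-derive results by
# enumeration or per-element counting, sharing no code with the package paths
# they check.

# --- alignment: exhaustive enumeration of all global alignments -------------
# Scores an explicit gapped alignment: +match / -mismatch per residue column
# (N never matches), and each maximal gap run of length k costs
# open + k * extend.
oracleScoreGapped <- function(ga, gb, match = 1, mismatch = 1, open = 4, extend = 1) {
    a <- strsplit(ga, "")[[1]]; b <- strsplit(gb, "")[[1]]
    sc <- 0
    for (s in list(a, b)) {
        r <- rle(s == "-")
        runs <- r$lengths[r$values]
        if (length(runs)) sc <- sc - sum(open + runs * extend)
    }
    res <- a != "-" & b != "-"
    sc + sum(ifelse(a[res] == b[res] & a[res] != "N", match, -mismatch))
}

# Best score over every global alignment of a and b, by recursive enumeration
# of the three column types. Feasible for nchar <= 6.
oracleBestScore <- function(a, b, match = 1, mismatch = 1, open = 4, extend = 1) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    best <- -Inf
    recurse <- function(i, j, ga, gb) {
        if (i > length(ca) && j > length(cb)) {
            sc <- oracleScoreGapped(paste(ga, collapse = ""),
                                    paste(gb, collapse = ""),
                                    match, mismatch, open, extend)
            if (sc > best) best <<- sc
            return(invisible())
        }
        if (i <= length(ca) && j <= length(cb))
            recurse(i + 1, j + 1, c(ga, ca[i]), c(gb, cb[j]))
        if (i <= length(ca))
            recurse(i + 1, j, c(ga, ca[i]), c(gb, "-"))
        if (j <= length(cb))
            recurse(i, j + 1, c(ga, "-"), c(gb, cb[j]))
    }
    recurse(1, 1, character(0), character(0))
    best
}

# --- conservation: per-column recount and window merge ----------------------
# Window identity by direct per-column counting on the gapped strings.
oracleProfile <- function(ga, gb, window) {
    a <- strsplit(ga, "")[[1]]; b <- strsplit(gb, "")[[1]]
    bpos <- which(a != "-")
    n <- length(bpos) - window + 1
    vapply(seq_len(n), function(s) {
        cols <- bpos[s]:bpos[s + window - 1]
        m <- sum(a[cols] == b[cols] & a[cols] != "-" & b[cols] != "-" &
                 a[cols] != "N" & b[cols] != "N")
        100 * m / length(cols)
    }, numeric(1))
}

# Merged passing-window runs on the baseline, by per-base membership.
oracleRegionSpans <- function(identities, window, minIdentity, minSpan) {
    pass <- which(identities > minIdentity)
    if (!length(pass)) return(matrix(integer(0), 0, 2))
    covered <- sort(unique(unlist(lapply(pass, function(s) s:(s + window - 1)))))
    breaks <- c(0, which(diff(covered) > 1), length(covered))
    spans <- do.call(rbind, lapply(seq_len(length(breaks) - 1), function(k)
        c(covered[breaks[k] + 1], covered[breaks[k + 1]])))
    spans[spans[, 2] - spans[, 1] + 1 >= minSpan, , drop = FALSE]
}

# --- random gapped alignment generator --------------------------------------
randomGappedPair <- function(len, pGap = 0.15, pMismatch = 0.3) {
    bases <- c("A", "C", "G", "T")
    a <- character(len); b <- character(len)
    for (k in seq_len(len)) {
        r <- runif(1)
        if (r < pGap / 2) { a[k] <- "-"; b[k] <- sample(bases, 1) }
        else if (r < pGap) { a[k] <- sample(bases, 1); b[k] <- "-" }
        else {
            a[k] <- sample(bases, 1)
            b[k] <- if (runif(1) < pMismatch)
                sample(setdiff(bases, a[k]), 1) else a[k]
        }
    }
    # forbid all-gap baseline / target and gap-in-both (none generated)
    if (all(a == "-")) a[1] <- "A"
    if (all(b == "-")) b[1] <- "A"
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# --- motifs: per-window IUPAC check independent of the scanner --------------
iupacTable <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T", "N"))

# all (start, strand) consensus matches by sliding a window and checking
# every position, with the reverse complement handled by explicitly reading
# the minus strand
oracleConsensusHits <- function(seq, consensus) {
    seq <- toupper(seq)
    sc <- strsplit(seq, "")[[1]]
    cons <- strsplit(consensus, "")[[1]]
    w <- length(cons)
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    out <- list()
    for (s in seq_len(max(0, nchar(seq) - w + 1))) {
        win <- sc[s:(s + w - 1)]
        okP <- all(mapply(function(o, c) {
            if (o == "N") c == "N" else o %in% iupacTable[[c]]
        }, win, cons))
        minus <- rev(unname(comp[win]))
        okM <- all(mapply(function(o, c) {
            if (o == "N") c == "N" else o %in% iupacTable[[c]]
        }, minus, cons))
        if (okP) out[[length(out) + 1]] <- c(start = s, strand = "+")
        if (okM) out[[length(out) + 1]] <- c(start = s, strand = "-")
    }
    if (!length(out)) return(data.frame(start = integer(0), strand = character(0)))
    df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
    df$start <- as.integer(df$start)
    df
}
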