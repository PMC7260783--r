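# Metric kernel: binary similarity indices, MAX group fusion, retrieval
# metrics (ROC AUC, enrichment factor) and the exact paired Wilcoxon
# machinery used to compare fingerprint schemes.

.checkBits <- function(x, y) {
    if (length(x) != length(y)) stop("vectors differ in length")
    if (length(x) == 0L) stop("vectors must be non-empty")
    invisible(NULL)
}

#' Rogot-Goldberg similarity of two bit vectors
#'
#' \eqn{s = a/(2a+b+c) + d/(2d+b+c)} where \eqn{a} counts shared on-bits,
#' \eqn{d} shared off-bits and \eqn{b}, \eqn{c} the two mismatch kinds.
#' Credits agreement on both on- and off-bits, which suits binary affinity
#' fingerprints where inactivity is as informative as activity. Symmetric,
#' bounded in [0, 1], and equal to 1 iff the vectors are identical (terms
#' with a zero denominator take their limiting value 1/2).
#'
#' @param x,y 0/1 vectors of equal length.
#' @return The similarity.
#' @export
rogotGoldberg <- function(x, y) {
    .checkBits(x, y)
    a <- sum(x == 1 & y == 1)
    b <- sum(x == 1 & y == 0)
    c <- sum(x == 0 & y == 1)
    d <- sum(x == 0 & y == 0)
    t1 <- if (2 * a + b + c == 0) 0.5 else a / (2 * a + b + c)
    t2 <- if (2 * d + b + c == 0) 0.5 else d / (2 * d + b + c)
    t1 + t2
}

#' Tanimoto similarity of two bit vectors
#'
#' \eqn{a / (a + b + c)}; the conventional index for substructure
#' fingerprints. Two all-zero vectors are defined to have similarity 0
#' (with a warning).
#'
#' @param x,y 0/1 vectors of equal length.
#' @return The similarity.
#' @export
tanimoto <- function(x, y) {
    .checkBits(x, y)
    a <- sum(x == 1 & y == 1)
    u <- sum(x == 1 | y == 1)
    if (u == 0) {
        warning("both vectors all-zero; Tanimoto defined as 0")
        return(0)
    }
    a / u
}

# all-pairs similarity between the rows of two bit matrices, vectorized
# through the cross-product of on-bit indicators
.similarityMatrix <- function(X, Y, method = c("tanimoto",
                                               "rogot_goldberg")) {
    method <- match.arg(method)
    storage.mode(X) <- "double"; storage.mode(Y) <- "double"
    A <- X %*% t(Y)                       # shared on-bits
    onX <- rowSums(X); onY <- rowSums(Y)
    L <- ncol(X)
    B <- matrix(onX, nrow(X), nrow(Y)) - A
    C <- matrix(onY, nrow(X), nrow(Y), byrow = TRUE) - A
    if (method == "tanimoto") {
        U <- A + B + C
        S <- ifelse(U == 0, 0, A / U)
    } else {
        D <- L - A - B - C
        den1 <- 2 * A + B + C
        den2 <- 2 * D + B + C
        S <- ifelse(den1 == 0, 0.5, A / pmax(den1, 1)) +
             ifelse(den2 == 0, 0.5, D / pmax(den2, 1))
        # pmax only guards the masked zero-denominator entries
    }
    S
}

#' MAX group fusion scores
#'
#' Scores every pool member by its maximum similarity over the query
#' fingerprints (the MAX fusion rule of group similarity searching).
#'
#' @param queries fingerprint matrix of the query actives (rows).
#' @param pool fingerprint matrix of the compounds to score (rows).
#' @param sim \code{"tanimoto"} or \code{"rogot_goldberg"}.
#' @return Numeric vector of length \code{nrow(pool)}.
#' @export
maxFusionScores <- function(queries, pool,
                            sim = c("tanimoto", "rogot_goldberg")) {
    sim <- match.arg(sim)
    if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1L)
    if (nrow(queries) == 0L) stop("need at least one query")
    if (is.null(dim(pool))) {
        if (length(pool) == 0L) return(numeric(0))
        pool <- matrix(pool, nrow = 1L)
    }
    if (nrow(pool) == 0L) return(numeric(0))
    S <- .similarityMatrix(pool, queries, method = sim)
    apply(S, 1L, max)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random active is ranked above
#' a random inactive, with ties credited 1/2.
#'
#' @param scores numeric ranking scores (higher = more active-like).
#' @param labels 0/1 (or logical) activity labels.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.integer(as.logical(labels))
    stopifnot(length(scores) == length(labels))
    nP <- sum(labels == 1L); nN <- sum(labels == 0L)
    if (nP == 0L || nN == 0L)
        stop("AUC undefined: need both actives and inactives")
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1L]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Enrichment factor at a top fraction
#'
#' \eqn{EF(\chi) = (P_\chi / N_\chi) / (P_{total} / N_{total})} with the
#' top-segment size \eqn{N_\chi = \lceil \chi N_{total} \rceil}. Scores
#' tied at the segment boundary are broken by a random pre-shuffle (drawn
#' from the current RNG stream) ahead of the stable sort, so EF never
#' depends on input order. Values above 1 beat random selection;
#' \code{chi = 1} always gives 1.
#'
#' @param scores numeric ranking scores (higher = better).
#' @param labels 0/1 (or logical) activity labels.
#' @param chi top fraction (default 0.05: the EF5 of virtual screening).
#' @return The enrichment factor.
#' @export
enrichmentFactor <- function(scores, labels, chi = 0.05) {
    labels <- as.integer(as.logical(labels))
    stopifnot(length(scores) == length(labels), chi > 0, chi <= 1)
    nTot <- length(scores)
    pTot <- sum(labels)
    if (pTot == 0L) stop("EF undefined: no actives")
    nChi <- ceiling(chi * nTot)
    shuffle <- sample.int(nTot)
    ord <- order(-scores[shuffle])
    topLabels <- labels[shuffle][ord][seq_len(nChi)]
    (sum(topLabels) / nChi) / (pTot / nTot)
}

## ---- exact paired Wilcoxon ----------------------------------------------

# Exact null distribution of the signed-rank statistic for given ranks
# (doubled to stay integral under midranks): returns counts over achievable
# doubled-statistic values 0..sum(r2). Equivalent to enumerating all 2^n
# sign assignments.
.signedRankCounts <- function(r2) {
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (r in r2) {
        g <- f
        g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] +
            f[1L:(total + 1L - r)]
        f <- g
    }
    f
}

#' Exact paired Wilcoxon signed-rank test
#'
#' P-values from the exact null distribution of the signed-rank statistic,
#' obtained by exhaustive enumeration of all \eqn{2^n} sign assignments
#' (computed as an equivalent convolution, so midranks from tied
#' differences are handled exactly). Zero differences are dropped with a
#' message. Limited to \eqn{n \le 25} pairs after zero removal; larger
#' samples should use a normal approximation instead.
#'
#' @param x,y paired measurement vectors of equal length.
#' @param alternative \code{"two_sided"}, \code{"greater"} (x tends larger
#'   than y) or \code{"less"}.
#' @return list with elements \code{statistic} (signed-rank sum W),
#'   \code{pValue}, \code{nUsed} and \code{nZero}.
#' @export
wilcoxonExactPaired <- function(x, y,
                                alternative = c("two_sided", "greater",
                                                "less")) {
    alternative <- match.arg(alternative)
    stopifnot(length(x) == length(y))
    d <- x - y
    nZero <- sum(d == 0)
    if (nZero > 0)
        message("dropping ", nZero, " zero difference(s)")
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L) stop("degenerate test: all differences are zero")
    if (n > 25L)
        stop("exact enumeration limited to 25 pairs; ",
             "use a normal-approximation test for larger samples")
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    r2 <- as.integer(round(2 * r))
    w2 <- as.integer(round(2 * w))
    counts <- .signedRankCounts(r2)
    totalMass <- 2^n
    pGE <- sum(counts[(w2 + 1L):length(counts)]) / totalMass
    pLE <- sum(counts[1L:(w2 + 1L)]) / totalMass
    p <- switch(alternative,
                greater = pGE,
                less = pLE,
                two_sided = min(1, 2 * min(pGE, pLE)))
    list(statistic = w, pValue = p, nUsed = n, nZero = nZero)
}

#' Exact signed-rank confidence interval for paired differences
#'
#' Hodges-Lehmann-style interval: order statistics of the Walsh averages
#' \eqn{(d_i + d_j)/2, i \le j} at the exact signed-rank critical values
#' (via \code{qsignrank}). The point estimate is the median Walsh average.
#'
#' @param diffs paired differences (n >= 6).
#' @param level confidence level (default 0.95).
#' @return list with \code{low}, \code{high} and \code{estimate}.
#' @export
pairedDifferenceCI <- function(diffs, level = 0.95) {
    n <- length(diffs)
    if (n < 6L) stop("need at least 6 pairs for a useful exact interval")
    stopifnot(level > 0, level < 1)
    pairsIdx <- which(upper.tri(matrix(0, n, n), diag = TRUE),
                      arr.ind = TRUE)
    walsh <- sort((diffs[pairsIdx[, 1L]] + diffs[pairsIdx[, 2L]]) / 2)
    M <- length(walsh)
    qu <- stats::qsignrank((1 - level) / 2, n)
    if (qu == 0) qu <- 1
    list(low = walsh[qu], high = walsh[M - qu + 1L],
         estimate = stats::median(walsh))
}
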