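# Independent brute-force oracles: explicit loops, no shared code with
# the implementation under test.

# the seven first-order statistics by elementwise loops
bfFirstOrder <- function(px, nBins, pixelRange) {
    n <- length(px)
    s <- 0
    for (v in px) s <- s + v
    mu <- s / n
    m2 <- m3 <- m4 <- 0
    for (v in px) {
        d <- v - mu
        m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
    }
    m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
    sigma <- sqrt(m2)
    mn <- px[1]; mx <- px[1]
    for (v in px) { if (v < mn) mn <- v; if (v > mx) mx <- v }
    counts <- rep(0, nBins)
    if (mx > mn) {
        for (v in px) {
            b <- floor((v - mn) / ((mx - mn) / nBins)) + 1
            if (b > nBins) b <- nBins
            counts[b] <- counts[b] + 1
        }
    }
    ent <- 0
    for (cnt in counts) {
        if (cnt > 0) {
            p <- cnt / n
            ent <- ent - p * log2(p)
        }
    }
    sn <- sigma / (pixelRange[2] - pixelRange[1])
    c(Mean = mu,
      VC = if (sigma == 0) NA_real_ else sigma / mu,
      "Max-Min" = mx - mn,
      Skewness = if (sigma == 0) NA_real_ else m3 / sigma^3,
      Entropy = ent,
      RelativeSmoothness = 1 - 1 / (1 + sn^2),
      Kurtosis = if (sigma == 0) NA_real_ else m4 / sigma^4)
}

# exact two-sided Mann-Whitney p by full enumeration of labelings
bfMannWhitneyP <- function(a, b) {
    pooled <- c(a, b)
    n <- length(pooled); n1 <- length(a)
    r <- rank(pooled)
    uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
    uObs <- uOf(seq_len(n1))
    combos <- utils::combn(n, n1)
    us <- apply(combos, 2, uOf)
    mid <- n1 * (n - n1) / 2
    # two-sided: as or more extreme in distance from the null mean
    mean(abs(us - mid) >= abs(uObs - mid) - 1e-9)
}

# AUC by explicit positive/negative pair comparison
bfAucPairs <- function(scores, y) {
    pos <- scores[y == 1]; neg <- scores[y == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

# disc rasterization by per-pixel test
bfDiscCount <- function(size, radius) {
    ctr <- (size + 1) / 2
    cnt <- 0
    for (i in seq_len(size)) for (j in seq_len(size))
        if ((i - ctr)^2 + (j - ctr)^2 <= radius^2) cnt <- cnt + 1
    cnt
}

# small valid image pair around a given ROI pixel vector (>= 16 values)
makePair <- function(roiPixels, id = "L001", rc = NULL) {
    n <- length(roiPixels)
    side <- ceiling(sqrt(n)) + 2
    # fill row-major so roiPixels order matches extractRoiPixels
    mask <- matrix(FALSE, side, side)
    k <- 0
    le <- matrix(0, side, side)
    rcm <- matrix(0, side, side)
    for (i in seq_len(side)) for (j in seq_len(side)) {
        k <- k + 1
        if (k <= n) {
            mask[i, j] <- TRUE
            le[i, j] <- roiPixels[k]
            rcm[i, j] <- if (is.null(rc)) roiPixels[k] else rc[k]
        }
    }
    CesmImagePair(id, le = le, rc = rcm, mask = mask)
}
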