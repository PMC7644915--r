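# Independent oracles, written from the published definitions, never from
# the package code paths they check.

# Trimmed mean of M-values (Robinson-Oshlack): reference = sample whose
# 75th-percentile count fraction is closest to the mean across samples;
# per-gene M and A against the reference over genes nonzero in both;
# double-trim (most extreme trim_m of M, trim_a of A, rank-based); factor =
# 2^(weighted mean of surviving M), weights = inverse asymptotic binomial
# variance; factors rescaled to geometric mean 1.
tmmOracle <- function(counts, trim_m = 0.30, trim_a = 0.05) {
    lib <- colSums(counts)
    f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
    ref <- which.min(abs(f75 - mean(f75)))
    f <- numeric(ncol(counts))
    for (j in seq_len(ncol(counts))) {
        o <- counts[, j]; r <- counts[, ref]
        nO <- lib[j]; nR <- lib[ref]
        M <- log2((o / nO) / (r / nR))
        A <- (log2(o / nO) + log2(r / nR)) / 2
        v <- (nO - o) / nO / o + (nR - r) / nR / r
        fin <- is.finite(M) & is.finite(A) & (A > -1e10)
        M <- M[fin]; A <- A[fin]; v <- v[fin]
        if (max(abs(M)) < 1e-6) {
            f[j] <- 1
            next
        }
        n <- length(M)
        loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
        loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
        keep <- rank(M) >= loM & rank(M) <= hiM &
                rank(A) >= loA & rank(A) <= hiA
        fj <- sum(M[keep] / v[keep], na.rm = TRUE) /
              sum(1 / v[keep], na.rm = TRUE)
        if (is.na(fj)) fj <- 0
        f[j] <- 2^fj
    }
    f / exp(mean(log(f)))
}

# Pearson product-moment correlation by the direct sum formula.
pccOracle <- function(x, y) {
    n <- length(x)
    num <- sum(x * y) - n * mean(x) * mean(y)
    den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    num / den
}

# Direct predicate evaluation of the response rule.
classifyOracle <- function(fc, threshold = 2) {
    up <- any(fc > threshold, na.rm = TRUE)
    down <- any(fc < -threshold, na.rm = TRUE)
    c(up = up, down = down)
}

# Sample standard deviation by the explicit n-1 formula.
sdOracle <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))
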