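## Between-sample normalization: trimmed mean of M-values (TMM) against a
## reference sample, then library-size scaling to counts per million.

## Reference sample: the one whose 75th-percentile count fraction is closest
## to the mean 75th-percentile across samples (deterministic; ties go to the
## lowest sample index via which.min).
.tmmReference <- function(counts, lib_size) {
    f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib_size
    which.min(abs(f75 - mean(f75)))
}

#' TMM scaling factors
#'
#' Computes the trimmed-mean-of-M-values scaling factor for every sample of a
#' count matrix: per-gene log ratios (M) and average log abundances (A)
#' against the reference sample are doubly trimmed (the most extreme
#' `trim_m` of M and `trim_a` of A), and the factor is 2 to the weighted mean
#' of the surviving M values, weights being inverse asymptotic binomial
#' variances. Factors are rescaled to geometric mean 1. The computation is
#' delegated to [edgeR::calcNormFactors()] with the reference chosen by the
#' 75th-percentile rule.
#'
#' @param x a [CountMatrix-class] (at least two samples).
#' @param trim_m fraction of extreme M values trimmed (default 0.30).
#' @param trim_a fraction of extreme A values trimmed (default 0.05).
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmmFactors <- function(x, trim_m = 0.30, trim_a = 0.05) {
    counts <- SummarizedExperiment::assay(x, "counts")
    if (ncol(counts) < 2)
        stop("TMM needs at least 2 samples, got ", ncol(counts))
    lib_size <- colSums(counts)
    if (any(lib_size == 0))
        stop("zero library size for sample(s): ",
             paste(colnames(counts)[lib_size == 0], collapse = ", "))
    ref <- .tmmReference(counts, lib_size)
    for (j in seq_len(ncol(counts))) {
        if (j == ref) next
        if (!any(counts[, j] > 0 & counts[, ref] > 0))
            stop(sprintf(
                "no gene with nonzero counts in both samples '%s' and '%s'",
                colnames(counts)[j], colnames(counts)[ref]))
    }
    f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                                logratioTrim = trim_m, sumTrim = trim_a,
                                doWeighting = TRUE)
    if (any(!is.finite(f)) || any(f <= 0))
        stop("degenerate TMM factors (non-finite or non-positive)")
    names(f) <- colnames(counts)
    f
}

#' TMM-scaled counts per million
#'
#' `value(g, s) = count(g, s) / (lib_size(s) * factor(s)) * 1e6`.
#'
#' @param x a [CountMatrix-class].
#' @param factors per-sample positive factors (geometric mean 1); computed
#'   with [tmmFactors()] when `NULL`.
#' @return a [NormalizedMatrix-class].
#' @export
normalizeCounts <- function(x, factors = NULL) {
    counts <- SummarizedExperiment::assay(x, "counts")
    lib_size <- colSums(counts)
    if (any(lib_size == 0))
        stop("zero library size for sample(s): ",
             paste(colnames(counts)[lib_size == 0], collapse = ", "))
    if (is.null(factors)) factors <- tmmFactors(x)
    if (length(factors) != ncol(counts))
        stop("need one factor per sample")
    if (any(factors <= 0)) stop("factors must be positive")
    values <- sweep(counts, 2, lib_size * factors, "/") * 1e6
    cd <- SummarizedExperiment::colData(x)
    cd$norm_factor <- unname(factors)
    cd$lib_size <- unname(lib_size)
    new("NormalizedMatrix",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(normcounts = values), colData = cd))
}

#' Low-abundance gene mask
#'
#' A gene is kept (TRUE) iff its normalized abundance is `>= cutoff` in at
#' least `min_samples` samples.
#'
#' @param norm a [NormalizedMatrix-class].
#' @param cutoff normalized-abundance cutoff (default 1).
#' @param min_samples minimum number of samples at or above the cutoff
#'   (default 2).
#' @return named logical vector per gene.
#' @export
lowAbundanceMask <- function(norm, cutoff = 1, min_samples = 2) {
    stopifnot(cutoff > 0)
    v <- SummarizedExperiment::assay(norm, "normcounts")
    rowSums(v >= cutoff) >= min_samples
}

#' Temporal log2 fold-change tensor
#'
#' For each gene, genotype and stress time:
#' `fc = log2(mean_reps(value at t) + pseudocount) -
#'       log2(mean_reps(value at 0 h) + pseudocount)`;
#' replicates are averaged on the normalized scale before the log transform.
#' The 0 h replicate mean is kept as the baseline. Genotype x time cells with
#' no samples yield `NA` (flagged missing).
#'
#' @param norm a [NormalizedMatrix-class]; every genotype must have a 0 h
#'   sample.
#' @param pseudocount added before each log (default 1 normalized unit).
#' @return a [FoldChangeTensor-class].
#' @export
foldChangeTensor <- function(norm, pseudocount = 1) {
    v <- SummarizedExperiment::assay(norm, "normcounts")
    si <- sampleInfo(norm)
    genos <- unique(si$genotype)
    noctrl <- genos[!vapply(genos, function(g)
        any(si$genotype == g & si$time_h == 0), logical(1))]
    if (length(noctrl) > 0)
        stop("genotype(s) without a 0 h control: ",
             paste(noctrl, collapse = ", "))
    times <- sort(unique(si$time_h[si$time_h > 0]))
    genes <- rownames(v)
    fc <- array(NA_real_, dim = c(length(genes), length(genos),
                                  length(times)),
                dimnames = list(genes, genos, as.character(times)))
    baseline <- matrix(NA_real_, length(genes), length(genos),
                       dimnames = list(genes, genos))
    for (g in genos) {
        sel0 <- si$genotype == g & si$time_h == 0
        m0 <- rowMeans(v[, sel0, drop = FALSE])
        baseline[, g] <- m0
        for (t in times) {
            selt <- si$genotype == g & si$time_h == t
            if (!any(selt)) next
            mt <- rowMeans(v[, selt, drop = FALSE])
            fc[, g, as.character(t)] <-
                log2(mt + pseudocount) - log2(m0 + pseudocount)
        }
    }
    FoldChangeTensor(fc, baseline)
}

#' Read and write a fold-change tensor as long-format TSV
#'
#' Columns: `gene_id`, `genotype`, `time_h`, `log2fc`, `baseline`. Missing
#' fold-changes are written as `NA` and read back as flagged-missing (never
#' as 0).
#'
#' @param tensor a [FoldChangeTensor-class].
#' @param path TSV path.
#' @export
writeFoldChanges <- function(tensor, path) {
    fc <- foldChanges(tensor)
    b <- baselines(tensor)
    dn <- dimnames(fc)
    long <- expand.grid(gene_id = dn[[1]], genotype = dn[[2]],
                        time_h = dn[[3]], KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    long$log2fc <- as.vector(fc)
    long$baseline <- as.vector(b[cbind(long$gene_id, long$genotype)])
    long$log2fc <- sprintf("%.12g", long$log2fc)
    long$log2fc[long$log2fc == "NA"] <- "NA"
    long$baseline <- sprintf("%.12g", long$baseline)
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeFoldChanges
#' @export
readFoldChanges <- function(path) {
    long <- utils::read.delim(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE,
                              na.strings = "NA", check.names = FALSE)
    genes <- unique(long$gene_id)
    genos <- unique(long$genotype)
    times <- sort(unique(as.numeric(long$time_h)))
    fc <- array(NA_real_, dim = c(length(genes), length(genos),
                                  length(times)),
                dimnames = list(genes, genos, as.character(times)))
    fc[cbind(long$gene_id, long$genotype, as.character(long$time_h))] <-
        long$log2fc
    baseline <- matrix(NA_real_, length(genes), length(genos),
                       dimnames = list(genes, genos))
    baseline[cbind(long$gene_id, long$genotype)] <- long$baseline
    FoldChangeTensor(fc, baseline)
}
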