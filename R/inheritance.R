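## Parental-inheritance tracing: each RIL gene is compared against both
## parents through per-time discretized response codes, reusing the same
## +/- log2-FC granularity as the response classification.

#' Discretize a temporal fold-change profile into response codes
#'
#' Per stress time: `+1` if `fc > threshold`, `-1` if `fc < -threshold`,
#' else `0` (strict inequalities; a value at exactly the threshold codes 0).
#' Missing stays missing.
#'
#' @param fc numeric log2 fold-change vector.
#' @param threshold positive log2 threshold (default 2).
#' @return integer vector of codes in `{-1, 0, +1}` (with `NA` preserved).
#' @export
discretizeProfile <- function(fc, threshold = 2) {
    stopifnot(threshold > 0)
    as.integer((fc > threshold) - (fc < -threshold))
}

.codesMatch <- function(a, b) all(a == b)

#' Trace one gene's parental origin from discretized codes
#'
#' Time points with a missing code in any of the three profiles are dropped;
#' if none remain the gene is excluded (`low_abundance`). Otherwise, with
#' `match(x, y)` meaning identical codes at every compared time:
#' match both parents -> `complete` (which forces the parents to match each
#' other); match only parent A -> `parentA_like`; only parent B ->
#' `parentB_like`; neither -> `non_parental`.
#'
#' @param ril_codes,parentA_codes,parentB_codes integer code vectors of
#'   equal length (values in `{-1, 0, +1}` or `NA`).
#' @param excluded exclusion reason applied before matching (`"none"`,
#'   `"low_abundance"`, `"outlier"`).
#' @return list with `category` and `exclusion_reason`.
#' @export
traceGene <- function(ril_codes, parentA_codes, parentB_codes,
                      excluded = c("none", "low_abundance", "outlier")) {
    excluded <- match.arg(excluded)
    n <- length(ril_codes)
    if (length(parentA_codes) != n || length(parentB_codes) != n)
        stop("code vectors must share length")
    if (excluded != "none")
        return(list(category = "excluded", exclusion_reason = excluded))
    ok <- !is.na(ril_codes) & !is.na(parentA_codes) & !is.na(parentB_codes)
    if (!any(ok))
        return(list(category = "excluded",
                    exclusion_reason = "low_abundance"))
    mA <- .codesMatch(ril_codes[ok], parentA_codes[ok])
    mB <- .codesMatch(ril_codes[ok], parentB_codes[ok])
    category <- if (mA && mB) "complete"
        else if (mA) "parentA_like"
        else if (mB) "parentB_like"
        else "non_parental"
    list(category = category, exclusion_reason = "none")
}

#' Trace parental inheritance for every gene in every RIL
#'
#' Exclusion is applied first: `low_abundance` if the gene fails the
#' low-abundance rule within the trio's (RIL + both parents) samples;
#' `outlier` if any absolute fold-change in the trio exceeds the outlier
#' cap. Remaining genes are traced via [traceGene()] on codes discretized at
#' the response threshold.
#'
#' @param tensor a [FoldChangeTensor-class].
#' @param norm the [NormalizedMatrix-class] the tensor came from (for the
#'   low-abundance exclusion).
#' @param parentA,parentB parent genotype labels.
#' @param rils RIL genotype labels (must not include a parent).
#' @param thresholds a [Thresholds-class] bundle.
#' @param min_samples minimum samples at/above the low-abundance cutoff
#'   within the trio (default 2).
#' @param match_rule `"codes"` (default: identical discretized response
#'   codes at every compared time) or `"chebyshev"` (continuous
#'   alternative: the largest absolute fold-change difference across
#'   compared times is at most `delta`).
#' @param delta Chebyshev tolerance in log2 units (default 1; only used by
#'   `match_rule = "chebyshev"`).
#' @param baseline_delta optional additional requirement that the RIL and
#'   parent 0 h baselines agree:
#'   `|log2(baseline_ril + 1) - log2(baseline_parent + 1)| <=
#'   baseline_delta`. `NULL` (default) disables the check: the categories
#'   describe response patterns, not absolute levels.
#' @return data.frame `gene_id`, `ril`, `category`, `exclusion_reason`, with
#'   attributes `counts` (per-RIL category counts; rows sum to the gene
#'   total) and `shared` (RIL x RIL matrix of genes assigned the same
#'   category in both).
#' @export
traceAll <- function(tensor, norm, parentA, parentB, rils,
                     thresholds = Thresholds(), min_samples = 2,
                     match_rule = c("codes", "chebyshev"), delta = 1,
                     baseline_delta = NULL) {
    match_rule <- match.arg(match_rule)
    genos <- genotypeNames(tensor)
    missing_g <- setdiff(c(parentA, parentB, rils), genos)
    if (length(missing_g) > 0)
        stop("genotype(s) absent from tensor: ",
             paste(missing_g, collapse = ", "))
    if (parentA %in% rils || parentB %in% rils)
        stop("a parent label cannot also be a RIL")
    fc <- foldChanges(tensor)
    thr <- thresholds@fc_threshold
    codes <- (fc > thr) - (fc < -thr)   # NA preserved
    v <- SummarizedExperiment::assay(norm, "normcounts")
    si <- sampleInfo(norm)
    genes <- geneIDs(tensor)
    v <- v[genes, , drop = FALSE]
    cutoff <- thresholds@low_abundance_cutoff
    cap <- thresholds@outlier_cap
    res <- vector("list", length(rils))
    for (k in seq_along(rils)) {
        ril <- rils[k]
        trio_samples <- si$genotype %in% c(ril, parentA, parentB)
        low <- rowSums(v[, trio_samples, drop = FALSE] >= cutoff) <
            min_samples
        trio_fc <- abs(fc[, c(ril, parentA, parentB), , drop = FALSE])
        outlier <- apply(trio_fc > cap, 1, function(z) any(z, na.rm = TRUE))
        cr <- codes[, ril, ]
        ca <- codes[, parentA, ]
        cb <- codes[, parentB, ]
        ok <- !is.na(cr) & !is.na(ca) & !is.na(cb)
        none_ok <- rowSums(ok) == 0
        if (match_rule == "codes") {
            eq <- function(x, y) {
                d <- x == y
                d[!ok] <- TRUE       # dropped times never break a match
                rowSums(d) == ncol(d)
            }
            mA <- eq(cr, ca)
            mB <- eq(cr, cb)
        } else {
            cheb <- function(p) {
                d <- abs(fc[, ril, ] - fc[, p, ]) <= delta
                d[!ok] <- TRUE
                rowSums(d) == ncol(d)
            }
            mA <- cheb(parentA)
            mB <- cheb(parentB)
        }
        if (!is.null(baseline_delta)) {
            b <- baselines(tensor)
            bdiff <- function(p)
                abs(log2(b[, ril] + 1) - log2(b[, p] + 1)) <=
                    baseline_delta
            mA <- mA & bdiff(parentA)
            mB <- mB & bdiff(parentB)
        }
        category <- ifelse(mA & mB, "complete",
                    ifelse(mA, "parentA_like",
                    ifelse(mB, "parentB_like", "non_parental")))
        reason <- rep("none", length(genes))
        reason[outlier] <- "outlier"
        reason[low | none_ok] <- "low_abundance"
        category[reason != "none"] <- "excluded"
        res[[k]] <- data.frame(gene_id = genes, ril = ril,
                               category = category,
                               exclusion_reason = reason,
                               stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, res)
    lev <- c("complete", "parentA_like", "parentB_like", "non_parental",
             "excluded")
    counts <- table(ril = calls$ril,
                    category = factor(calls$category, levels = lev))
    shared <- matrix(0L, length(rils), length(rils),
                     dimnames = list(rils, rils))
    for (i in seq_along(rils)) for (j in seq_along(rils)) {
        ci <- calls$category[calls$ril == rils[i]]
        cj <- calls$category[calls$ril == rils[j]]
        shared[i, j] <- sum(ci == cj)
    }
    attr(calls, "counts") <- counts
    attr(calls, "shared") <- shared
    calls
}
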