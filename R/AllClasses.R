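#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.SAMPLE_COLS <- c("sample_id", "genotype", "time_h", "replicate", "assay")

.validSampleData <- function(cd) {
    miss <- setdiff(.SAMPLE_COLS, colnames(cd))
    if (length(miss) > 0)
        return(sprintf("sample annotation lacks column(s): %s",
                       paste(miss, collapse = ", ")))
    if (anyDuplicated(cd$sample_id))
        return("duplicated sample_id")
    if (!all(cd$assay %in% c("mrna", "mirna")))
        return("assay must be 'mrna' or 'mirna'")
    if (any(cd$time_h < 0)) return("time_h must be non-negative")
    if (any(cd$replicate < 1)) return("replicate must be a positive integer")
    key <- paste(cd$genotype, cd$time_h, cd$replicate, cd$assay)
    if (anyDuplicated(key))
        return("(genotype, time_h, replicate, assay) tuples must be unique")
    ## a genotype without a 0 h control is legal here: validateDesign()
    ## flags it and foldChangeTensor() refuses it
    TRUE
}

#' Gene-by-sample count container
#'
#' `CountMatrix` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `counts` assay of non-negative values and a sample annotation
#' (`colData`) carrying `sample_id`, `genotype`, `time_h`, `replicate` and
#' `assay` (one of `"mrna"`, `"mirna"`). Validity requires unique gene ids,
#' unique design tuples, and a 0 h control sample for every genotype.
#'
#' @aliases CountMatrix-class
#' @exportClass CountMatrix
setClass("CountMatrix", contains = "SummarizedExperiment")

setValidity("CountMatrix", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("no 'counts' assay")
    m <- SummarizedExperiment::assay(object, "counts")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("gene ids (rownames) must be present and unique")
    if (any(!is.finite(m)) || any(m < 0))
        return("counts must be finite and non-negative")
    .validSampleData(SummarizedExperiment::colData(object))
})

#' Construct a CountMatrix
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @param samples data.frame with columns `sample_id`, `genotype`, `time_h`,
#'   `replicate`, `assay`, one row per count column and in the same order.
#' @param check_integer require whole-number counts (default `TRUE`; family
#'   averaging may legitimately produce fractional abundances).
#' @return a [CountMatrix-class] object.
#' @export
CountMatrix <- function(counts, samples, check_integer = TRUE) {
    counts <- as.matrix(counts)
    samples <- as.data.frame(samples)
    if (ncol(counts) != nrow(samples))
        stop("count columns (", ncol(counts), ") and sample rows (",
             nrow(samples), ") differ")
    if (check_integer) {
        bad <- which(counts != floor(counts), arr.ind = TRUE)
        if (nrow(bad) > 0)
            stop(sprintf("non-integer count at (%s, %s)",
                         rownames(counts)[bad[1, 1]],
                         samples$sample_id[bad[1, 2]]))
    }
    neg <- which(counts < 0, arr.ind = TRUE)
    if (nrow(neg) > 0)
        stop(sprintf("negative count at (%s, %s)",
                     rownames(counts)[neg[1, 1]],
                     samples$sample_id[neg[1, 2]]))
    colnames(counts) <- samples$sample_id
    storage.mode(counts) <- "double"
    samples$time_h <- as.integer(samples$time_h)
    samples$replicate <- as.integer(samples$replicate)
    cd <- S4Vectors::DataFrame(samples, row.names = samples$sample_id)
    new("CountMatrix",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts), colData = cd))
}

#' TMM-scaled counts-per-million container
#'
#' Holds the normalized abundance matrix (assay `normcounts`) together with
#' the per-sample TMM factors (`colData$norm_factor`, geometric mean 1) and
#' library sizes (`colData$lib_size`).
#'
#' @aliases NormalizedMatrix-class
#' @exportClass NormalizedMatrix
setClass("NormalizedMatrix", contains = "SummarizedExperiment")

setValidity("NormalizedMatrix", function(object) {
    if (!"normcounts" %in% SummarizedExperiment::assayNames(object))
        return("no 'normcounts' assay")
    v <- SummarizedExperiment::assay(object, "normcounts")
    if (any(!is.finite(v)) || any(v < 0))
        return("normalized values must be finite and non-negative")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("norm_factor", "lib_size") %in% colnames(cd)))
        return("colData must carry norm_factor and lib_size")
    f <- cd$norm_factor
    if (any(f <= 0)) return("norm factors must be positive")
    if (abs(mean(log(f))) > 1e-8)
        return("norm factors must have geometric mean 1")
    if (any(cd$lib_size <= 0)) return("library sizes must be positive")
    .validSampleData(cd)
})

#' Per-gene, per-genotype temporal log2 fold-change tensor
#'
#' The pipeline's central object: a gene x genotype x stress-time array of
#' log2 fold-changes relative to each genotype's own 0 h control, plus the
#' gene x genotype matrix of 0 h baseline abundances (normalized units).
#' Missing fold-changes are `NA` (flagged missing, never 0).
#'
#' @slot fc three-dimensional numeric array `[gene, genotype, time]` with
#'   dimnames; third dimension named by the stress times in hours.
#' @slot baseline numeric gene x genotype matrix of 0 h replicate-mean
#'   abundances.
#' @aliases FoldChangeTensor-class
#' @exportClass FoldChangeTensor
setClass("FoldChangeTensor",
         representation(fc = "array", baseline = "matrix"))

setValidity("FoldChangeTensor", function(object) {
    d <- dim(object@fc)
    if (length(d) != 3) return("fc must be a 3-d array")
    dn <- dimnames(object@fc)
    if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
        return("fc must have complete dimnames")
    tt <- suppressWarnings(as.numeric(dn[[3]]))
    if (any(is.na(tt)) || any(tt <= 0) || is.unsorted(tt, strictly = TRUE))
        return("stress times must be strictly ascending positive numbers")
    if (!identical(dim(object@baseline), d[1:2]))
        return("baseline dimensions must match fc gene x genotype")
    if (!identical(dimnames(object@baseline), dn[1:2]))
        return("baseline dimnames must match fc")
    if (any(object@baseline < 0, na.rm = TRUE))
        return("baselines must be non-negative")
    if (any(is.infinite(object@fc)))
        return("fc entries must be finite or NA")
    TRUE
})

#' Construct a FoldChangeTensor from its components
#'
#' @param fc gene x genotype x stress-time array of log2 fold-changes with
#'   complete dimnames (times as the third dimension's names, in hours).
#' @param baseline gene x genotype matrix of 0 h abundances.
#' @return a [FoldChangeTensor-class].
#' @export
FoldChangeTensor <- function(fc, baseline) {
    new("FoldChangeTensor", fc = fc, baseline = baseline)
}

#' Threshold bundle for the classification stages
#'
#' Groups the tunable cut-offs: the +/- log2-FC response threshold, the two
#' Pearson-correlation edge thresholds (responsive and constitutive module
#' networks), the low-abundance cutoff (normalized units) and the outlier cap
#' (absolute log2-FC beyond which a gene is excluded from inheritance
#' tracing).
#'
#' @slot fc_threshold positive, log2 units (default 2).
#' @slot pcc_responsive in (0, 1] (default 0.95).
#' @slot pcc_constitutive in (0, 1] (default 0.8).
#' @slot low_abundance_cutoff positive, normalized units (default 1).
#' @slot outlier_cap positive, log2 units (default 12).
#' @aliases Thresholds-class
#' @exportClass Thresholds
setClass("Thresholds",
         representation(fc_threshold = "numeric",
                        pcc_responsive = "numeric",
                        pcc_constitutive = "numeric",
                        low_abundance_cutoff = "numeric",
                        outlier_cap = "numeric"))

setValidity("Thresholds", function(object) {
    v <- c(object@fc_threshold, object@pcc_responsive,
           object@pcc_constitutive, object@low_abundance_cutoff,
           object@outlier_cap)
    if (length(v) != 5 || any(!is.finite(v)) || any(v <= 0))
        return("all thresholds must be single strictly positive numbers")
    if (object@pcc_responsive > 1 || object@pcc_constitutive > 1)
        return("PCC thresholds must be <= 1")
    TRUE
})

#' @param fc_threshold,pcc_responsive,pcc_constitutive,low_abundance_cutoff,outlier_cap
#'   see the class slots.
#' @return a [Thresholds-class] object.
#' @rdname Thresholds-class
#' @export
Thresholds <- function(fc_threshold = 2, pcc_responsive = 0.95,
                       pcc_constitutive = 0.8, low_abundance_cutoff = 1,
                       outlier_cap = 12) {
    new("Thresholds", fc_threshold = fc_threshold,
        pcc_responsive = pcc_responsive,
        pcc_constitutive = pcc_constitutive,
        low_abundance_cutoff = low_abundance_cutoff,
        outlier_cap = outlier_cap)
}

#' Selected gene module
#'
#' An ordered, duplicate-free gene set selected for a focal genotype, with
#' the structured rule that produced it (re-applying the rule to the same
#' tensor is idempotent).
#'
#' @slot label character, e.g. `"steady_upregulated"`.
#' @slot focalGenotype character.
#' @slot rule named list of the applied criteria and parameters.
#' @slot members character vector of gene ids.
#' @aliases GeneModule-class
#' @exportClass GeneModule
setClass("GeneModule",
         representation(label = "character", focalGenotype = "character",
                        rule = "list", members = "character"))

setValidity("GeneModule", function(object) {
    if (anyDuplicated(object@members)) return("module members must be unique")
    TRUE
})

GeneModule <- function(label, focalGenotype, rule, members) {
    new("GeneModule", label = label, focalGenotype = focalGenotype,
        rule = rule, members = as.character(members))
}

#' Signed, thresholded Pearson co-expression network
#'
#' Undirected graph over a gene module for one genotype. Edges carry the
#' Pearson correlation `r` between the two genes' temporal fold-change
#' profiles and exist only where `r >= pos_threshold` or
#' `r <= neg_threshold` (both inclusive). Edge endpoints are stored with
#' `gene_a < gene_b` lexicographically; all module genes appear as nodes even
#' when isolated.
#'
#' @slot genotype character.
#' @slot nodes character vector of gene ids.
#' @slot edges data.frame with columns `gene_a`, `gene_b`, `r`, `sign`.
#' @slot posThreshold,negThreshold numeric edge thresholds.
#' @aliases CoexpressionNetwork-class
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
         representation(genotype = "character", nodes = "character",
                        edges = "data.frame", posThreshold = "numeric",
                        negThreshold = "numeric"))

setValidity("CoexpressionNetwork", function(object) {
    e <- object@edges
    if (!identical(colnames(e), c("gene_a", "gene_b", "r", "sign")))
        return("edges must have columns gene_a, gene_b, r, sign")
    if (nrow(e) > 0) {
        if (any(e$gene_a == e$gene_b)) return("self-edges are not allowed")
        if (any(e$gene_a >= e$gene_b))
            return("edges must satisfy gene_a < gene_b")
        if (anyDuplicated(paste(e$gene_a, e$gene_b)))
            return("duplicate edges")
        if (!all(e$gene_a %in% object@nodes) ||
            !all(e$gene_b %in% object@nodes))
            return("edge endpoints must be nodes")
        okr <- e$r >= object@posThreshold | e$r <= object@negThreshold
        if (!all(okr)) return("edge r outside thresholds")
        sgn <- ifelse(e$r >= object@posThreshold, "positive", "negative")
        if (!identical(as.character(e$sign), sgn))
            return("edge sign inconsistent with r")
    }
    if (anyDuplicated(object@nodes)) return("duplicate nodes")
    TRUE
})
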