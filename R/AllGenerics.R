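#' Accessors for transegR classes
#'
#' `geneIDs()` returns the gene identifiers; `sampleInfo()` the sample
#' annotation as a data.frame; `genotypeNames()` and `stressTimes()` the
#' genotype labels and the ascending stress times (hours); `foldChanges()`
#' the gene x genotype x time log2-FC array; `baselines()` the 0 h baseline
#' matrix; `normFactors()` / `librarySizes()` the per-sample TMM factors and
#' library sizes; `moduleMembers()` a module's gene ids; `networkEdges()` /
#' `networkNodes()` a network's edge table and node list.
#'
#' @param x a transegR object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIDs", function(x) standardGeneric("geneIDs"))
#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname accessors
#' @export
setGeneric("genotypeNames", function(x) standardGeneric("genotypeNames"))
#' @rdname accessors
#' @export
setGeneric("stressTimes", function(x) standardGeneric("stressTimes"))
#' @rdname accessors
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))
#' @rdname accessors
#' @export
setGeneric("baselines", function(x) standardGeneric("baselines"))
#' @rdname accessors
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))
#' @rdname accessors
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))
#' @rdname accessors
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
setMethod("geneIDs", "SummarizedExperiment", function(x) rownames(x))
#' @rdname accessors
setMethod("geneIDs", "FoldChangeTensor", function(x) dimnames(x@fc)[[1]])
#' @rdname accessors
setMethod("sampleInfo", "SummarizedExperiment",
          function(x) as.data.frame(SummarizedExperiment::colData(x)))
#' @rdname accessors
setMethod("genotypeNames", "SummarizedExperiment",
          function(x) unique(SummarizedExperiment::colData(x)$genotype))
#' @rdname accessors
setMethod("genotypeNames", "FoldChangeTensor",
          function(x) dimnames(x@fc)[[2]])
#' @rdname accessors
setMethod("stressTimes", "FoldChangeTensor",
          function(x) as.numeric(dimnames(x@fc)[[3]]))
#' @rdname accessors
setMethod("foldChanges", "FoldChangeTensor", function(x) x@fc)
#' @rdname accessors
setMethod("baselines", "FoldChangeTensor", function(x) x@baseline)
#' @rdname accessors
setMethod("normFactors", "NormalizedMatrix",
          function(x) {
              f <- SummarizedExperiment::colData(x)$norm_factor
              names(f) <- colnames(x)
              f
          })
#' @rdname accessors
setMethod("librarySizes", "NormalizedMatrix",
          function(x) {
              n <- SummarizedExperiment::colData(x)$lib_size
              names(n) <- colnames(x)
              n
          })
#' @rdname accessors
setMethod("moduleMembers", "GeneModule", function(x) x@members)
#' @rdname accessors
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("networkNodes", "CoexpressionNetwork", function(x) x@nodes)

#' Subset a FoldChangeTensor by gene and/or genotype
#'
#' @param x a [FoldChangeTensor-class].
#' @param i gene ids or indices.
#' @param j genotype labels or indices.
#' @param ... ignored.
#' @param drop ignored (dimensions are always kept).
#' @export
setMethod("[", "FoldChangeTensor", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(dim(x@fc)[1])
    if (missing(j)) j <- seq_len(dim(x@fc)[2])
    new("FoldChangeTensor",
        fc = x@fc[i, j, , drop = FALSE],
        baseline = x@baseline[i, j, drop = FALSE])
})

setMethod("show", "FoldChangeTensor", function(object) {
    d <- dim(object@fc)
    cat("FoldChangeTensor:", d[1], "genes x", d[2], "genotypes x",
        d[3], "stress times (", paste(dimnames(object@fc)[[3]],
                                      collapse = ", "), "h )\n")
    cat("  genotypes:", paste(dimnames(object@fc)[[2]], collapse = ", "),
        "\n")
    cat("  missing fc entries:", sum(is.na(object@fc)), "\n")
})

setMethod("show", "Thresholds", function(object) {
    cat("Thresholds: |log2-FC| >", object@fc_threshold,
        "; |r| >=", object@pcc_responsive, "(responsive) /",
        object@pcc_constitutive, "(constitutive)",
        "; low-abundance <", object@low_abundance_cutoff,
        "; outlier cap", object@outlier_cap, "\n")
})

setMethod("show", "GeneModule", function(object) {
    cat("GeneModule '", object@label, "' (focal ", object@focalGenotype,
        "): ", length(object@members), " genes\n", sep = "")
})

setMethod("show", "CoexpressionNetwork", function(object) {
    e <- object@edges
    cat("CoexpressionNetwork [", object@genotype, "]: ",
        length(object@nodes), " nodes, ", nrow(e), " edges (",
        sum(e$sign == "positive"), " positive, ",
        sum(e$sign == "negative"), " negative) at r >= ",
        object@posThreshold, " / r <= ", object@negThreshold, "\n", sep = "")
})
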