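## Response classification at the +/- fc_threshold rule (strict
## inequalities): a gene is "up" in a genotype if any stress time exceeds
## the threshold, "down" if any falls below its negative, "constant"
## otherwise; genes both up and down are "mixed".

#' Classify one temporal fold-change vector
#'
#' `up` iff any fold-change is strictly greater than `threshold`; `down` iff
#' any is strictly less than `-threshold` (a value at exactly the threshold
#' counts as unchanged). Missing entries are ignored; a vector that is all
#' missing is unclassifiable (not an error).
#'
#' @param fc numeric log2 fold-changes over the stress times.
#' @param threshold positive log2 threshold (default 2).
#' @return list with `up`, `down`, `category` (one of `constant`, `up_only`,
#'   `down_only`, `mixed`, or `NA` when unclassifiable) and `unclassifiable`.
#' @export
classifyGene <- function(fc, threshold = 2) {
    stopifnot(length(fc) > 0, threshold > 0)
    if (all(is.na(fc)))
        return(list(up = NA, down = NA, category = NA_character_,
                    unclassifiable = TRUE))
    up <- any(fc > threshold, na.rm = TRUE)
    down <- any(fc < -threshold, na.rm = TRUE)
    category <- if (up && down) "mixed"
        else if (up) "up_only"
        else if (down) "down_only"
        else "constant"
    list(up = up, down = down, category = category, unclassifiable = FALSE)
}

#' Classify every gene x genotype slice of a tensor
#'
#' @param tensor a [FoldChangeTensor-class].
#' @param threshold positive log2 threshold (default 2).
#' @return data.frame `gene_id`, `genotype`, `up`, `down`, `category`
#'   (`NA` category for all-missing slices), with a `summary` attribute of
#'   per-genotype category counts.
#' @export
classifyAll <- function(tensor, threshold = 2) {
    fc <- foldChanges(tensor)
    up <- apply(fc > threshold, c(1, 2), function(z) any(z, na.rm = TRUE))
    down <- apply(fc < -threshold, c(1, 2), function(z) any(z, na.rm = TRUE))
    allna <- apply(is.na(fc), c(1, 2), all)
    category <- ifelse(up & down, "mixed",
                ifelse(up, "up_only",
                ifelse(down, "down_only", "constant")))
    category[allna] <- NA_character_
    up[allna] <- NA
    down[allna] <- NA
    dn <- dimnames(fc)
    calls <- data.frame(
        gene_id = rep(dn[[1]], times = length(dn[[2]])),
        genotype = rep(dn[[2]], each = length(dn[[1]])),
        up = as.vector(up), down = as.vector(down),
        category = as.vector(category), stringsAsFactors = FALSE)
    summary <- as.data.frame(table(genotype = calls$genotype,
                                   category = calls$category))
    names(summary)[3] <- "n"
    attr(calls, "summary") <- summary
    calls
}

#' Exclusive (UpSet-style) set intersections across genotypes
#'
#' For the queried response set (`up` = any-time upregulated including mixed,
#' `down` likewise, `constant`), counts for every non-empty genotype subset
#' the genes belonging to exactly those genotypes' sets. Unclassifiable
#' genes are excluded and reported separately. Exclusive counts over all
#' subsets sum to the size of the union of the per-genotype sets.
#'
#' @param calls output of [classifyAll()] covering at least two genotypes.
#' @param which one of `"up"`, `"down"`, `"constant"`.
#' @return list of class `IntersectionTable`: `category`; `exclusive`, a
#'   data.frame with one logical column per genotype plus `count`, one row
#'   per non-empty subset; `totals`, named per-genotype set sizes;
#'   `n_union`; `n_unclassifiable`.
#' @export
setIntersections <- function(calls, which = c("up", "down", "constant")) {
    which <- match.arg(which)
    genos <- unique(calls$genotype)
    if (length(genos) < 2)
        stop("set intersections need at least 2 genotypes")
    ok <- !is.na(calls$category)
    member <- switch(which,
        up = calls$up & ok,
        down = calls$down & ok,
        constant = ok & calls$category == "constant")
    unclass_genes <- unique(calls$gene_id[!ok])
    genes <- unique(calls$gene_id)
    m <- matrix(FALSE, length(genes), length(genos),
                dimnames = list(genes, genos))
    m[cbind(calls$gene_id[member], calls$genotype[member])] <- TRUE
    subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(genos)),
                           KEEP.OUT.ATTRS = FALSE)
    names(subsets) <- genos
    subsets <- subsets[rowSums(subsets) > 0, , drop = FALSE]
    pattern <- apply(m, 1, paste, collapse = "")
    key <- apply(subsets, 1, function(r) paste(r, collapse = ""))
    tab <- table(pattern[rowSums(m) > 0])
    subsets$count <- as.integer(tab[key])
    subsets$count[is.na(subsets$count)] <- 0L
    rownames(subsets) <- NULL
    structure(list(category = which, exclusive = subsets,
                   totals = colSums(m), n_union = sum(rowSums(m) > 0),
                   n_unclassifiable = length(unclass_genes)),
              class = "IntersectionTable")
}

#' @export
print.IntersectionTable <- function(x, ...) {
    cat("IntersectionTable (", x$category, "): union of ", x$n_union,
        " genes across ", length(x$totals), " genotypes\n", sep = "")
    print(x$exclusive[x$exclusive$count > 0, , drop = FALSE])
    invisible(x)
}

#' Write an IntersectionTable as TSV
#'
#' One row per non-empty genotype subset (logical membership columns plus
#' `count`); per-genotype totals appended as a trailing comment-free block is
#' avoided — totals go to a second file when `totals_path` is given.
#'
#' @param x an `IntersectionTable`.
#' @param path TSV path for the exclusive counts.
#' @param totals_path optional TSV path for per-genotype totals.
#' @export
writeIntersections <- function(x, path, totals_path = NULL) {
    utils::write.table(x$exclusive, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    if (!is.null(totals_path)) {
        df <- data.frame(genotype = names(x$totals),
                         total = as.integer(x$totals))
        utils::write.table(df, totals_path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE)
    }
    invisible(path)
}
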