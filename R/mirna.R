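## miRNA integration: collapse annotated miRNAs into families, compare the
## spread of family fold-changes across genotypes, and screen supplied
## miRNA-target pairs for repression-consistent anti-correlation.

#' Collapse miRNA counts into family-level counts
#'
#' @param mirna_counts a [CountMatrix-class] of miRNA counts.
#' @param map data.frame with columns `mirna_id`, `family`; every id maps to
#'   exactly one family.
#' @param mode `"sum"` (default; conserves per-sample totals) or `"mean"`.
#' @param drop_unmapped drop matrix ids absent from the map with a warning
#'   (default `FALSE`: unmapped ids are an error).
#' @return a [CountMatrix-class] keyed by family (fractional values allowed
#'   in mean mode).
#' @export
collapseFamilies <- function(mirna_counts, map,
                             mode = c("sum", "mean"),
                             drop_unmapped = FALSE) {
    mode <- match.arg(mode)
    map <- as.data.frame(map)
    if (nrow(map) == 0) stop("empty family map")
    if (!all(c("mirna_id", "family") %in% colnames(map)))
        stop("family map needs columns mirna_id, family")
    if (anyDuplicated(map$mirna_id))
        stop("mirna_id mapped to more than one family: ",
             paste(unique(map$mirna_id[duplicated(map$mirna_id)]),
                   collapse = ", "))
    m <- SummarizedExperiment::assay(mirna_counts, "counts")
    unmapped <- setdiff(rownames(m), map$mirna_id)
    if (length(unmapped) > 0) {
        if (!drop_unmapped)
            stop("miRNA id(s) missing from the family map: ",
                 paste(unmapped, collapse = ", "))
        warning("dropping ", length(unmapped), " unmapped miRNA id(s)")
        m <- m[setdiff(rownames(m), unmapped), , drop = FALSE]
    }
    fam <- map$family[match(rownames(m), map$mirna_id)]
    collapsed <- rowsum(m, group = fam, reorder = TRUE)
    if (mode == "mean")
        collapsed <- collapsed / as.vector(table(fam)[rownames(collapsed)])
    CountMatrix(collapsed, sampleInfo(mirna_counts),
                check_integer = FALSE)
}

#' Write and read a miRNA family map TSV
#'
#' Columns `mirna_id`, `family`.
#'
#' @param map data.frame with columns `mirna_id`, `family`.
#' @param path TSV path.
#' @export
writeFamilyMap <- function(map, path) {
    utils::write.table(map[, c("mirna_id", "family")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeFamilyMap
#' @export
readFamilyMap <- function(path) {
    .readTSV(path)
}

#' Per-genotype spread of family fold-changes
#'
#' Pools all family x stress-time log2-FC values within each genotype and
#' reports the min, max, range, interquartile range (linear-interpolation
#' quartiles) and standard deviation (denominator n - 1; `NA` for a single
#' value).
#'
#' @param family_fc a [FoldChangeTensor-class] keyed by miRNA family.
#' @return data.frame `genotype`, `n_values`, `min`, `max`, `range`, `iqr`,
#'   `sd`.
#' @export
familyRangeStats <- function(family_fc) {
    fc <- foldChanges(family_fc)
    stopifnot(dim(fc)[1] >= 1, dim(fc)[3] >= 1)
    genos <- genotypeNames(family_fc)
    do.call(rbind, lapply(genos, function(g) {
        vals <- as.vector(fc[, g, ])
        vals <- vals[!is.na(vals)]
        data.frame(genotype = g, n_values = length(vals),
                   min = min(vals), max = max(vals),
                   range = max(vals) - min(vals),
                   iqr = unname(stats::quantile(vals, 0.75, type = 7) -
                                stats::quantile(vals, 0.25, type = 7)),
                   sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
                   stringsAsFactors = FALSE)
    }))
}

#' Screen miRNA family / target pairs for repression-consistent profiles
#'
#' For every supplied (family, target gene) pair and every genotype,
#' computes the Pearson correlation between the family's and the target's
#' temporal fold-change profiles and flags the pair repression-consistent
#' where `r <= -rho`. Zero-variance profiles yield a missing `r` and a
#' `FALSE` flag. Pairs naming an unknown family or gene are collected into
#' an error report (attribute `errors`); the remaining pairs are still
#' processed.
#'
#' @param family_fc family-level [FoldChangeTensor-class].
#' @param target_fc gene-level [FoldChangeTensor-class] (same genotypes).
#' @param pairs data.frame with columns `family`, `gene_id`.
#' @param rho anti-correlation magnitude (default 0.8).
#' @param include_control_zero prefix the exact 0 control point (default
#'   `TRUE`).
#' @return data.frame `family`, `gene_id`, `genotype`, `r`,
#'   `repression_consistent`, with attribute `errors` listing skipped pairs.
#' @export
pairCorrelation <- function(family_fc, target_fc, pairs, rho = 0.8,
                            include_control_zero = TRUE) {
    pairs <- as.data.frame(pairs)
    stopifnot(all(c("family", "gene_id") %in% colnames(pairs)))
    genos <- intersect(genotypeNames(family_fc), genotypeNames(target_fc))
    bad <- !(pairs$family %in% geneIDs(family_fc)) |
           !(pairs$gene_id %in% geneIDs(target_fc))
    errors <- pairs[bad, , drop = FALSE]
    ok_pairs <- pairs[!bad, , drop = FALSE]
    rows <- vector("list", nrow(ok_pairs) * length(genos))
    k <- 0
    for (i in seq_len(nrow(ok_pairs))) {
        fam <- ok_pairs$family[i]
        gene <- ok_pairs$gene_id[i]
        for (g in genos) {
            pf <- temporalProfiles(family_fc, fam, g,
                                   include_control_zero)[1, ]
            pt <- temporalProfiles(target_fc, gene, g,
                                   include_control_zero)[1, ]
            r <- if (any(is.na(pf)) || any(is.na(pt))) NA_real_
                 else pcc(pf, pt)
            k <- k + 1
            rows[[k]] <- data.frame(
                family = fam, gene_id = gene, genotype = g, r = r,
                repression_consistent = !is.na(r) && r <= -rho,
                stringsAsFactors = FALSE)
        }
    }
    out <- if (k > 0) do.call(rbind, rows[seq_len(k)])
           else data.frame(family = character(0), gene_id = character(0),
                           genotype = character(0), r = numeric(0),
                           repression_consistent = logical(0))
    attr(out, "errors") <- errors
    out
}
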