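## Transgressive module selection for a focal genotype: the steadily
## upregulated set (above threshold at every stress time) and the
## constitutive-high set (elevated 0 h baseline vs the parents, bounded
## fold-changes under stress).

#' Select genes steadily upregulated in a focal genotype
#'
#' Members are the genes with `fc > threshold` at every stress time in the
#' focal genotype; a missing fold-change at any time disqualifies the gene.
#'
#' @param tensor a [FoldChangeTensor-class].
#' @param focal focal genotype label.
#' @param threshold positive log2 threshold (default 2, strict).
#' @return a [GeneModule-class] labelled `"steady_upregulated"`.
#' @export
selectSteadyUp <- function(tensor, focal, threshold = 2) {
    if (!focal %in% genotypeNames(tensor))
        stop("unknown genotype: ", focal)
    fcm <- foldChanges(tensor)[, focal, , drop = TRUE]
    if (is.null(dim(fcm))) fcm <- matrix(fcm, ncol = 1,
                                         dimnames = list(geneIDs(tensor)))
    keep <- rowSums(fcm > threshold) == ncol(fcm)   # NA -> NA -> dropped
    keep[is.na(keep)] <- FALSE
    GeneModule("steady_upregulated", focal,
               rule = list(type = "steady_upregulated",
                           threshold = threshold,
                           times = stressTimes(tensor)),
               members = geneIDs(tensor)[keep])
}

#' Refine a steady module by the early contrast in inferior genotypes
#'
#' Keeps members whose fold-change at `early_time` is downregulated in every
#' inferior genotype: `fc < 0` under the lenient rule, `fc <= -strict_fc`
#' under the strict one. A missing early fold-change drops the gene.
#'
#' @param module a [GeneModule-class].
#' @param tensor the [FoldChangeTensor-class] it was selected from.
#' @param inferior non-empty character vector of inferior genotypes.
#' @param early_time stress time in hours (default 24; must be in the
#'   tensor).
#' @param down_rule `"lenient"` (`fc < 0`, default) or `"strict"`
#'   (`fc <= -strict_fc`).
#' @param strict_fc magnitude for the strict rule (default 2).
#' @return a [GeneModule-class]; always a subset of the input module.
#' @export
refineByEarlyContrast <- function(module, tensor, inferior,
                                  early_time = 24,
                                  down_rule = c("lenient", "strict"),
                                  strict_fc = 2) {
    down_rule <- match.arg(down_rule)
    if (length(inferior) == 0) stop("inferior genotype list must be non-empty")
    if (!all(inferior %in% genotypeNames(tensor)))
        stop("unknown genotype(s): ",
             paste(setdiff(inferior, genotypeNames(tensor)), collapse = ", "))
    if (!early_time %in% stressTimes(tensor))
        stop("early_time ", early_time, " absent from tensor times")
    members <- moduleMembers(module)
    fce <- foldChanges(tensor)[members, inferior, as.character(early_time),
                               drop = FALSE]
    fce <- matrix(fce, nrow = length(members), ncol = length(inferior),
                  dimnames = list(members, inferior))
    okm <- if (down_rule == "lenient") fce < 0 else fce <= -strict_fc
    keep <- rowSums(okm) == ncol(okm)
    keep[is.na(keep)] <- FALSE
    rule <- module@rule
    rule$early_contrast <- list(inferior = inferior,
                                early_time = early_time,
                                down_rule = down_rule,
                                strict_fc = strict_fc)
    GeneModule(paste0(module@label, "_early_contrast"),
               module@focalGenotype, rule, members[keep])
}

#' Select constitutively high genes in a focal genotype
#'
#' Members satisfy both: (i) an elevated control baseline,
#' `log2((baseline_focal + pseudocount) / (parental baseline +
#' pseudocount)) > base_threshold`, where the parental baseline is their
#' mean (`parent_rule = "mean"`) or the criterion must hold against each
#' parent (`"both"`); and (ii) stability under stress, `|fc| <
#' stability_threshold` at every stress time in the focal genotype. Genes
#' with a missing baseline are skipped with a warning.
#'
#' @param tensor a [FoldChangeTensor-class].
#' @param focal focal genotype label.
#' @param parents character vector of the two parent labels.
#' @param base_threshold log2 baseline-ratio threshold (default 2, strict).
#' @param stability_threshold log2 stability band (default 2, strict).
#' @param pseudocount added to baselines before the ratio (default 1).
#' @param parent_rule `"mean"` (default) or `"both"`.
#' @return a [GeneModule-class] labelled `"constitutive_high"`.
#' @export
selectConstitutive <- function(tensor, focal, parents, base_threshold = 2,
                               stability_threshold = 2, pseudocount = 1,
                               parent_rule = c("mean", "both")) {
    parent_rule <- match.arg(parent_rule)
    stopifnot(length(parents) == 2)
    genos <- genotypeNames(tensor)
    missing_g <- setdiff(c(focal, parents), genos)
    if (length(missing_g) > 0)
        stop("unknown genotype(s): ", paste(missing_g, collapse = ", "))
    b <- baselines(tensor)
    bf <- b[, focal]
    bp <- b[, parents, drop = FALSE]
    skipped <- is.na(bf) | apply(is.na(bp), 1, any)
    if (any(skipped))
        warning(sum(skipped), " gene(s) skipped: missing baseline")
    ratio_ok <- if (parent_rule == "mean") {
        log2((bf + pseudocount) / (rowMeans(bp) + pseudocount)) >
            base_threshold
    } else {
        rowSums(log2((bf + pseudocount) /
                     (bp + pseudocount)) > base_threshold) == 2
    }
    fcm <- foldChanges(tensor)[, focal, , drop = TRUE]
    if (is.null(dim(fcm))) fcm <- matrix(fcm, ncol = 1)
    stable <- rowSums(abs(fcm) < stability_threshold) == ncol(fcm)
    keep <- ratio_ok & stable & !skipped
    keep[is.na(keep)] <- FALSE
    GeneModule("constitutive_high", focal,
               rule = list(type = "constitutive_high",
                           parents = parents,
                           base_threshold = base_threshold,
                           stability_threshold = stability_threshold,
                           pseudocount = pseudocount,
                           parent_rule = parent_rule),
               members = geneIDs(tensor)[keep])
}
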