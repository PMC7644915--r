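## Signed, thresholded Pearson co-expression networks over a gene module,
## and the cohesion/fragmentation metrics used to compare genotypes.

#' Temporal fold-change profiles for a gene module
#'
#' Extracts each gene's log2-FC vector over the stress times for one
#' genotype, optionally prefixed with an exact 0 for the control point
#' (default; lengthens 4-point profiles to 5 and guarantees nonzero variance
#' for any responsive gene).
#'
#' @param tensor a [FoldChangeTensor-class].
#' @param genes module gene ids (must all be in the tensor).
#' @param genotype genotype label.
#' @param include_control_zero prefix a 0 for 0 h (default `TRUE`).
#' @return numeric matrix, genes x profile points.
#' @export
temporalProfiles <- function(tensor, genes, genotype,
                             include_control_zero = TRUE) {
    absent <- setdiff(genes, geneIDs(tensor))
    if (length(absent) > 0)
        stop("gene(s) absent from tensor: ", paste(absent, collapse = ", "))
    if (!genotype %in% genotypeNames(tensor))
        stop("unknown genotype: ", genotype)
    p <- foldChanges(tensor)[genes, genotype, , drop = TRUE]
    if (is.null(dim(p)))
        p <- matrix(p, nrow = length(genes),
                    dimnames = list(genes, dimnames(foldChanges(tensor))[[3]]))
    if (include_control_zero)
        p <- cbind(`0` = 0, p)
    p
}

#' Pearson product-moment correlation of two profiles
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return `r` in `[-1, 1]`; `NA` when either profile has zero variance
#'   (no edge can be formed from it).
#' @export
pcc <- function(x, y) {
    if (length(x) != length(y)) stop("profiles must share length")
    if (length(x) < 3) stop("profiles must have length >= 3")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    as.numeric(stats::cor(x, y))
}

#' Build a signed, thresholded co-expression network
#'
#' Computes all pairwise Pearson correlations between profile rows and keeps
#' edges with `r >= pos_threshold` or `r <= neg_threshold` (both inclusive:
#' "at least" the threshold). Zero-variance profiles yield no edges and are
#' logged once. All genes appear as nodes even when isolated; the edge set
#' is independent of gene order.
#'
#' @param profiles genes x points matrix (see [temporalProfiles()]).
#' @param pos_threshold positive edge threshold (default 0.95).
#' @param neg_threshold negative edge threshold (default -0.95).
#' @param genotype label stored on the network.
#' @return a [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(profiles, pos_threshold = 0.95,
                         neg_threshold = -0.95, genotype = "") {
    stopifnot(neg_threshold < 0, pos_threshold > 0)
    genes <- rownames(profiles)
    sds <- apply(profiles, 1, stats::sd)
    flat <- genes[is.na(sds) | sds == 0 |
                  apply(is.na(profiles), 1, any)]
    if (length(flat) > 0)
        message("zero-variance or incomplete profile(s), no edges for: ",
                paste(flat, collapse = ", "))
    r <- suppressWarnings(stats::cor(t(profiles),
                                     use = "pairwise.complete.obs"))
    r[flat, ] <- NA
    r[, flat] <- NA
    idx <- which(upper.tri(r) & !is.na(r) &
                 (r >= pos_threshold | r <= neg_threshold), arr.ind = TRUE)
    if (nrow(idx) > 0) {
        a <- genes[idx[, 1]]
        b <- genes[idx[, 2]]
        swap <- a > b
        tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
        rv <- r[idx]
        edges <- data.frame(gene_a = a, gene_b = b, r = rv,
                            sign = ifelse(rv >= pos_threshold,
                                          "positive", "negative"),
                            stringsAsFactors = FALSE)
        edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
        rownames(edges) <- NULL
    } else {
        edges <- data.frame(gene_a = character(0), gene_b = character(0),
                            r = numeric(0), sign = character(0),
                            stringsAsFactors = FALSE)
    }
    new("CoexpressionNetwork", genotype = genotype, nodes = genes,
        edges = edges, posThreshold = pos_threshold,
        negThreshold = neg_threshold)
}

.asIgraph <- function(network, signs = c("positive", "negative")) {
    e <- network@edges
    e <- e[e$sign %in% signs, , drop = FALSE]
    igraph::graph_from_data_frame(
        e[, c("gene_a", "gene_b", "r", "sign")], directed = FALSE,
        vertices = data.frame(name = network@nodes))
}

#' Cohesion/fragmentation metrics of a co-expression network
#'
#' Quantifies how cohesive a genotype's network is: component counts over
#' all edges and over positive edges only, the fraction of nodes in the
#' largest positive component (1/n for an edgeless graph: each node its own
#' component), isolated ("straggler") nodes, the negative-edge fraction, and
#' the degree of any supplied hub genes (0, with a warning, for hubs absent
#' from the node list).
#'
#' @param network a [CoexpressionNetwork-class].
#' @param hub_genes optional gene ids whose degrees to report.
#' @return list with `genotype`, `n_nodes`, `n_pos_edges`, `n_neg_edges`,
#'   `negative_edge_fraction`, `n_components_all`, `n_components_positive`,
#'   `largest_positive_component_fraction`, `n_isolated_nodes`,
#'   `hub_degrees`.
#' @export
fragmentationMetrics <- function(network, hub_genes = NULL) {
    e <- network@edges
    n_pos <- sum(e$sign == "positive")
    n_neg <- sum(e$sign == "negative")
    g_all <- .asIgraph(network)
    g_pos <- .asIgraph(network, signs = "positive")
    comp_all <- igraph::components(g_all)
    comp_pos <- igraph::components(g_pos)
    n_nodes <- length(network@nodes)
    deg <- igraph::degree(g_all)
    hub_degrees <- numeric(0)
    if (!is.null(hub_genes)) {
        hub_degrees <- stats::setNames(numeric(length(hub_genes)), hub_genes)
        present <- hub_genes %in% network@nodes
        if (any(!present))
            warning("hub gene(s) not in network: ",
                    paste(hub_genes[!present], collapse = ", "))
        hub_degrees[hub_genes[present]] <- deg[hub_genes[present]]
    }
    list(genotype = network@genotype,
         n_nodes = n_nodes,
         n_pos_edges = n_pos,
         n_neg_edges = n_neg,
         negative_edge_fraction =
             if (n_pos + n_neg == 0) 0 else n_neg / (n_pos + n_neg),
         n_components_all = comp_all$no,
         n_components_positive = comp_pos$no,
         largest_positive_component_fraction =
             max(comp_pos$csize) / n_nodes,
         n_isolated_nodes = sum(deg == 0),
         hub_degrees = hub_degrees)
}

#' Rank genotype networks from cohesive to fragmented
#'
#' Orders fragmentation reports by largest positive-component fraction
#' (descending), ties broken by negative-edge fraction (ascending); the sort
#' is stable, so identical reports keep input order.
#'
#' @param reports list of [fragmentationMetrics()] outputs, one per
#'   genotype, genotypes unique.
#' @return data.frame of the metrics, one row per genotype, in rank order.
#' @export
compareNetworks <- function(reports) {
    if (length(reports) < 2) stop("need at least 2 reports to compare")
    genos <- vapply(reports, function(r) r$genotype, character(1))
    if (anyDuplicated(genos))
        stop("duplicate genotype in reports: ",
             paste(unique(genos[duplicated(genos)]), collapse = ", "))
    df <- do.call(rbind, lapply(reports, function(r)
        data.frame(genotype = r$genotype, n_nodes = r$n_nodes,
                   n_pos_edges = r$n_pos_edges, n_neg_edges = r$n_neg_edges,
                   negative_edge_fraction = r$negative_edge_fraction,
                   n_components_all = r$n_components_all,
                   n_components_positive = r$n_components_positive,
                   largest_positive_component_fraction =
                       r$largest_positive_component_fraction,
                   n_isolated_nodes = r$n_isolated_nodes,
                   stringsAsFactors = FALSE)))
    ord <- order(-df$largest_positive_component_fraction,
                 df$negative_edge_fraction)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Write a network as edge-list TSV and GraphML
#'
#' The edge list has columns `gene_a`, `gene_b`, `r` (12 decimal places),
#' `sign`; the GraphML file (written via igraph) retains isolated nodes.
#' Output is byte-stable given identical inputs.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param edge_path edge-list TSV path.
#' @param graphml_path optional GraphML path.
#' @export
writeNetwork <- function(network, edge_path, graphml_path = NULL) {
    e <- network@edges
    out <- data.frame(gene_a = e$gene_a, gene_b = e$gene_b,
                      r = sprintf("%.12f", e$r), sign = e$sign,
                      stringsAsFactors = FALSE)
    utils::write.table(out, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    if (!is.null(graphml_path))
        igraph::write_graph(.asIgraph(network), graphml_path,
                            format = "graphml")
    invisible(edge_path)
}

#' Re-read an edge-list TSV written by [writeNetwork()]
#'
#' @param edge_path edge-list TSV.
#' @param pos_threshold,neg_threshold the thresholds the network was built
#'   with.
#' @param genotype label to store.
#' @param nodes node list (edge endpoints when `NULL`; isolated nodes are
#'   not recoverable from an edge list alone).
#' @return a [CoexpressionNetwork-class].
#' @export
readNetworkEdges <- function(edge_path, pos_threshold = 0.95,
                             neg_threshold = -0.95, genotype = "",
                             nodes = NULL) {
    e <- utils::read.delim(edge_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    e$r <- as.numeric(e$r)
    if (is.null(nodes)) nodes <- sort(unique(c(e$gene_a, e$gene_b)))
    new("CoexpressionNetwork", genotype = genotype, nodes = nodes,
        edges = e[, c("gene_a", "gene_b", "r", "sign")],
        posThreshold = pos_threshold, negThreshold = neg_threshold)
}
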