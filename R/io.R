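## TSV interchange: tab-delimited, UTF-8, '.' decimal, header row mandatory.
## Gene ids are opaque strings; no normalization is attempted.

.readTSV <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path)
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character")
}

#' Read a count matrix and its sample sheet
#'
#' The count file is a TSV whose header row holds sample ids and whose first
#' column holds gene ids; the sample sheet is a TSV with columns exactly
#' `sample_id`, `genotype`, `time_h`, `replicate`, `assay`. Sample order
#' follows the count-file header; a sheet row without a matching count
#' column is an error.
#'
#' @param path count matrix TSV.
#' @param sample_sheet_path sample sheet TSV.
#' @return a validated [CountMatrix-class].
#' @export
readCountMatrix <- function(path, sample_sheet_path) {
    tab <- .readTSV(path)
    sheet <- .readTSV(sample_sheet_path)
    need <- c("sample_id", "genotype", "time_h", "replicate", "assay")
    miss <- setdiff(need, colnames(sheet))
    if (length(miss) > 0)
        stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
    gene_ids <- tab[[1]]
    dup <- gene_ids[duplicated(gene_ids)]
    if (length(dup) > 0)
        stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
    sample_ids <- colnames(tab)[-1]
    missing_cols <- setdiff(sheet$sample_id, sample_ids)
    if (length(missing_cols) > 0)
        stop("sample sheet row(s) without a count column: ",
             paste(missing_cols, collapse = ", "))
    extra <- setdiff(sample_ids, sheet$sample_id)
    if (length(extra) > 0)
        stop("count column(s) missing from the sample sheet: ",
             paste(extra, collapse = ", "))
    counts <- matrix(NA_real_, nrow = length(gene_ids),
                     ncol = length(sample_ids),
                     dimnames = list(gene_ids, sample_ids))
    for (j in seq_along(sample_ids)) {
        raw <- tab[[j + 1L]]
        val <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(val) | val < 0 | val != floor(val))
        if (length(bad) > 0)
            stop(sprintf("non-integer or negative count at (%s, %s): '%s'",
                         gene_ids[bad[1]], sample_ids[j], raw[bad[1]]))
        counts[, j] <- val
    }
    sheet <- sheet[match(sample_ids, sheet$sample_id), , drop = FALSE]
    sheet$time_h <- as.integer(sheet$time_h)
    sheet$replicate <- as.integer(sheet$replicate)
    CountMatrix(counts, sheet)
}

#' Write a count matrix and its sample sheet
#'
#' Inverse of [readCountMatrix()]; output is byte-stable for identical input.
#'
#' @param x a [CountMatrix-class].
#' @param path count matrix TSV to write.
#' @param sample_sheet_path optional sample sheet TSV to write.
#' @export
writeCountMatrix <- function(x, path, sample_sheet_path = NULL) {
    m <- SummarizedExperiment::assay(x, "counts")
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    if (!is.null(sample_sheet_path)) {
        si <- sampleInfo(x)[, .SAMPLE_COLS]
        utils::write.table(si, sample_sheet_path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE)
    }
    invisible(path)
}

#' Report the genotype x time design of a count matrix
#'
#' Report-only (never mutates its input): one row per genotype x time cell
#' with its replicate count, plus flags for genotypes lacking a 0 h control
#' and for cells absent from the design.
#'
#' @param x a [CountMatrix-class].
#' @return a data.frame `genotype`, `time_h`, `n_replicates` covering every
#'   genotype x time combination, with attributes `flags` (character vector)
#'   and `missing_cells`.
#' @export
validateDesign <- function(x) {
    si <- sampleInfo(x)
    genos <- unique(si$genotype)
    times <- sort(unique(si$time_h))
    grid <- expand.grid(genotype = genos, time_h = times,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$n_replicates <- mapply(function(g, t)
        sum(si$genotype == g & si$time_h == t), grid$genotype, grid$time_h)
    flags <- character(0)
    noctrl <- genos[!vapply(genos, function(g)
        any(si$genotype == g & si$time_h == 0), logical(1))]
    if (length(noctrl) > 0)
        flags <- c(flags, paste0("no control sample: ", noctrl))
    missing_cells <- grid[grid$n_replicates == 0, c("genotype", "time_h")]
    attr(grid, "flags") <- flags
    attr(grid, "missing_cells") <- missing_cells
    grid
}

#' Read and write plain-text gene lists
#'
#' One gene id per line, no header; an empty module yields an empty file.
#'
#' @param genes character vector of gene ids.
#' @param path file path.
#' @export
writeGeneList <- function(genes, path) {
    writeLines(as.character(genes), path)
    invisible(path)
}

#' @rdname writeGeneList
#' @export
readGeneList <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path)
    readLines(path)
}
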