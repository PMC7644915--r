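## One-command orchestration: simulate (optional) -> normalize -> classify
## -> trace -> select -> network -> mirna, with a machine-readable run
## report embedding every parameter and output checksum so a run is
## reproducible from the report alone.

#' Assemble a run configuration
#'
#' Either `sim` (a [simConfig()]; the study is generated) or the four input
#' paths (`counts`, `samples`, plus optionally `mirna_counts`,
#' `mirna_samples`, `family_map`, `pairs`) must be provided. Genotype roles
#' must be disjoint.
#'
#' @param out_dir output directory.
#' @param sim optional [simConfig()] for a synthetic run.
#' @param counts,samples,mirna_counts,mirna_samples,family_map,pairs input
#'   TSV paths for a run on real data.
#' @param parents,focal,inferior genotype roles (defaulted from `sim`).
#' @param thresholds a [Thresholds-class].
#' @param pseudocount,cpm_cutoff,min_samples normalization parameters.
#' @param down_rule early-contrast rule for [refineByEarlyContrast()].
#' @param include_control_zero include the exact 0 control point in network
#'   profiles (default `TRUE`).
#' @param seed integer seed (overrides `sim$seed` when given).
#' @return list of class `runConfig`.
#' @export
runConfig <- function(out_dir, sim = NULL, counts = NULL, samples = NULL,
                      mirna_counts = NULL, mirna_samples = NULL,
                      family_map = NULL, pairs = NULL,
                      parents = NULL, focal = NULL, inferior = NULL,
                      thresholds = Thresholds(), pseudocount = 1,
                      cpm_cutoff = 1, min_samples = 2,
                      down_rule = "lenient",
                      include_control_zero = TRUE, seed = NULL) {
    if (is.null(sim) && (is.null(counts) || is.null(samples)))
        stop("provide either a simConfig or counts + samples paths")
    if (!is.null(sim)) {
        if (!is.null(seed)) sim$seed <- seed
        if (is.null(parents)) parents <- sim$parents
        if (is.null(focal)) focal <- sim$focal
        if (is.null(inferior)) inferior <- sim$inferior
    }
    if (is.null(parents) || is.null(focal) || is.null(inferior))
        stop("genotype roles (parents, focal, inferior) are required")
    roles <- c(parents, focal, inferior)
    if (anyDuplicated(roles))
        stop("genotype roles must be disjoint (focal/inferior/parents)")
    structure(list(out_dir = out_dir, sim = sim, counts = counts,
                   samples = samples, mirna_counts = mirna_counts,
                   mirna_samples = mirna_samples, family_map = family_map,
                   pairs = pairs, parents = parents, focal = focal,
                   inferior = inferior, thresholds = thresholds,
                   pseudocount = pseudocount, cpm_cutoff = cpm_cutoff,
                   min_samples = min_samples, down_rule = down_rule,
                   include_control_zero = include_control_zero),
              class = "runConfig")
}

#' Read a run configuration from YAML
#'
#' Schema: top-level keys matching the arguments of [runConfig()];
#' `thresholds` is a mapping of [Thresholds()] arguments and `sim` a mapping
#' of [simConfig()] arguments.
#'
#' @param path YAML file.
#' @return a `runConfig`.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$thresholds))
        y$thresholds <- do.call(Thresholds, y$thresholds)
    if (!is.null(y$sim)) {
        if (!is.null(y$sim$mirna_range_scales))
            y$sim$mirna_range_scales <- unlist(y$sim$mirna_range_scales)
        y$sim <- do.call(simConfig, y$sim)
    }
    do.call(runConfig, y)
}

.stageFail <- function(out_dir, stage, err) {
    file.create(file.path(out_dir, paste0(stage, ".partial")))
    stop("pipeline stage '", stage, "' failed: ",
         conditionMessage(err), call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when configured) -> normalize -> classify -> trace ->
#' select -> network -> mirna, writing every stage's outputs under
#' `config$out_dir` and a `run_report.json` embedding the parameters,
#' output file list with MD5 checksums, and summary counts. Stages are
#' deterministic given the configuration, so re-running reproduces
#' byte-identical outputs. A failing stage aborts with the stage name and
#' leaves a `<stage>.partial` marker.
#'
#' @param config a [runConfig()].
#' @param verbose log stage progress to stderr (default `TRUE`).
#' @return the run report, invisibly.
#' @export
runPipeline <- function(config, verbose = TRUE) {
    stopifnot(inherits(config, "runConfig"))
    out_dir <- config$out_dir
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    note <- function(...) if (verbose) message("[transegR] ", ...)
    thr <- config$thresholds
    stages <- character(0)
    summary <- list()

    ## simulate
    stages <- c(stages, "simulate")
    sim <- NULL
    tryCatch({
        if (!is.null(config$sim)) {
            note("simulate: seed ", config$sim$seed)
            sim <- simulateStudy(config$sim)
            writeStudy(sim, file.path(out_dir, "sim"))
            mrna <- sim$mrna
            mirna <- sim$mirna
            family_map <- sim$family_map
            pairs <- sim$pairs
        } else {
            note("reading inputs")
            mrna <- readCountMatrix(config$counts, config$samples)
            mirna <- if (!is.null(config$mirna_counts))
                readCountMatrix(config$mirna_counts, config$mirna_samples)
            family_map <- if (!is.null(config$family_map))
                readFamilyMap(config$family_map)
            pairs <- if (!is.null(config$pairs)) .readTSV(config$pairs)
        }
    }, error = function(e) .stageFail(out_dir, "simulate", e))

    ## normalize
    stages <- c(stages, "normalize")
    tryCatch({
        note("normalize: TMM + CPM, pseudocount ", config$pseudocount)
        norm <- normalizeCounts(mrna)
        tensor <- foldChangeTensor(norm, pseudocount = config$pseudocount)
        writeFoldChanges(tensor, file.path(out_dir, "fold_changes.tsv"))
        summary$n_genes <- length(geneIDs(tensor))
        summary$n_genotypes <- length(genotypeNames(tensor))
    }, error = function(e) .stageFail(out_dir, "normalize", e))

    ## classify
    stages <- c(stages, "classify")
    tryCatch({
        note("classify at |log2-FC| > ", thr@fc_threshold)
        calls <- classifyAll(tensor, threshold = thr@fc_threshold)
        utils::write.table(calls, file.path(out_dir, "response_calls.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        for (w in c("up", "down", "constant")) {
            it <- setIntersections(calls, w)
            writeIntersections(it,
                file.path(out_dir, paste0("upset_", w, ".tsv")))
        }
        summary$response_counts <-
            stats::setNames(as.list(attr(calls, "summary")$n),
                            paste(attr(calls, "summary")$genotype,
                                  attr(calls, "summary")$category,
                                  sep = ":"))
    }, error = function(e) .stageFail(out_dir, "classify", e))

    ## trace
    stages <- c(stages, "trace")
    rils <- setdiff(genotypeNames(tensor), config$parents)
    tryCatch({
        note("trace inheritance for RILs: ", paste(rils, collapse = ", "))
        inh <- traceAll(tensor, norm, config$parents[1], config$parents[2],
                        rils, thresholds = thr,
                        min_samples = config$min_samples)
        utils::write.table(inh, file.path(out_dir, "inheritance.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        cnt <- as.data.frame(attr(inh, "counts"))
        utils::write.table(cnt, file.path(out_dir,
                                          "inheritance_counts.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }, error = function(e) .stageFail(out_dir, "trace", e))

    ## select
    stages <- c(stages, "select")
    tryCatch({
        note("select modules for focal ", config$focal)
        steady <- selectSteadyUp(tensor, config$focal,
                                 threshold = thr@fc_threshold)
        steady_refined <- refineByEarlyContrast(steady, tensor,
                                                config$inferior,
                                                down_rule = config$down_rule)
        consti <- selectConstitutive(tensor, config$focal, config$parents,
                                     base_threshold = thr@fc_threshold,
                                     stability_threshold = thr@fc_threshold,
                                     pseudocount = config$pseudocount)
        writeGeneList(moduleMembers(steady),
                      file.path(out_dir, "module_steady.txt"))
        writeGeneList(moduleMembers(steady_refined),
                      file.path(out_dir, "module_steady_refined.txt"))
        writeGeneList(moduleMembers(consti),
                      file.path(out_dir, "module_constitutive.txt"))
        summary$steady_module_size <- length(moduleMembers(steady))
        summary$constitutive_module_size <- length(moduleMembers(consti))
    }, error = function(e) .stageFail(out_dir, "select", e))

    ## network
    stages <- c(stages, "network")
    tryCatch({
        note("networks at |r| >= ", thr@pcc_responsive, " / ",
             thr@pcc_constitutive)
        mods <- list(steady = list(module = steady,
                                   pos = thr@pcc_responsive),
                     constitutive = list(module = consti,
                                         pos = thr@pcc_constitutive))
        reports <- list()
        for (mn in names(mods)) {
            genes <- moduleMembers(mods[[mn]]$module)
            if (length(genes) < 2) next
            reps <- lapply(genotypeNames(tensor), function(g) {
                prof <- temporalProfiles(tensor, genes, g,
                                         config$include_control_zero)
                net <- suppressMessages(buildNetwork(
                    prof, mods[[mn]]$pos, -mods[[mn]]$pos, genotype = g))
                writeNetwork(net,
                    file.path(out_dir, sprintf("net_%s_%s.edges.tsv",
                                               mn, g)),
                    file.path(out_dir, sprintf("net_%s_%s.graphml",
                                               mn, g)))
                fragmentationMetrics(net)
            })
            cmp <- compareNetworks(reps)
            utils::write.table(cmp,
                file.path(out_dir, sprintf("fragmentation_%s.tsv", mn)),
                sep = "\t", quote = FALSE, row.names = FALSE)
            reports[[mn]] <- cmp
        }
        summary$network_modules <- names(reports)
    }, error = function(e) .stageFail(out_dir, "network", e))

    ## mirna
    stages <- c(stages, "mirna")
    tryCatch({
        if (!is.null(mirna) && !is.null(family_map)) {
            note("miRNA family collapse and target screen")
            famc <- collapseFamilies(mirna, family_map, mode = "sum")
            fam_tensor <- foldChangeTensor(normalizeCounts(famc),
                                           pseudocount = config$pseudocount)
            rng <- familyRangeStats(fam_tensor)
            utils::write.table(rng,
                file.path(out_dir, "mirna_family_ranges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
            if (!is.null(pairs)) {
                pc <- pairCorrelation(fam_tensor, tensor, pairs,
                                      rho = thr@pcc_constitutive,
                                      include_control_zero =
                                          config$include_control_zero)
                utils::write.table(pc,
                    file.path(out_dir, "mirna_target_pairs.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
                summary$repression_consistent_focal <-
                    sum(pc$repression_consistent[pc$genotype ==
                                                 config$focal])
            }
        } else note("miRNA stage skipped (no miRNA inputs)")
    }, error = function(e) .stageFail(out_dir, "mirna", e))

    outputs <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                            "run_report.json"))
    checksums <- as.list(tools::md5sum(file.path(out_dir, outputs)))
    names(checksums) <- outputs
    params <- list(
        parents = config$parents, focal = config$focal,
        inferior = config$inferior,
        fc_threshold = thr@fc_threshold,
        pcc_responsive = thr@pcc_responsive,
        pcc_constitutive = thr@pcc_constitutive,
        low_abundance_cutoff = thr@low_abundance_cutoff,
        outlier_cap = thr@outlier_cap,
        pseudocount = config$pseudocount,
        cpm_cutoff = config$cpm_cutoff,
        min_samples = config$min_samples,
        down_rule = config$down_rule,
        include_control_zero = config$include_control_zero,
        sim = if (!is.null(config$sim)) {
            s <- unclass(config$sim)
            s$mirna_range_scales <- as.list(s$mirna_range_scales)
            s
        })
    report <- list(stages = stages, parameters = params,
                   outputs = checksums, summary = summary)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}
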