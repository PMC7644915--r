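## Seeded synthetic-study generator. Emulates the study design the pipeline
## targets: 6 genotypes (2 parents, 4 RILs, one focal "super-tolerant", two
## inferior), stress times 24/48/72/144 h plus the 0 h control, 2 replicates,
## parallel mRNA and miRNA libraries. Structure is planted on the log2 scale
## and exponentiated into negative-binomial count means, so the fold-change
## tensor the pipeline recovers converges to the planted templates as noise
## goes to 0.

#' Generator configuration
#'
#' All sizes, rates and genotype roles of the synthetic study. Defaults
#' reproduce the reference design: 200 genes per inheritance class, a
#' 50-gene co-expression module (split 25+25 in the fragmented regime), a
#' 40-gene steadily-upregulated and a 30-gene constitutive module, 12 miRNA
#' families of 3 members, 10 repressive miRNA-target pairs, fold-change
#' noise sd 0.25 log2 units, planted codes at `fc_threshold + margin` with
#' margin 0.75, and negative-binomial counts at dispersion 0.01
#' (`nb_dispersion = 0` yields deterministic rounded counts).
#'
#' @param seed integer RNG seed.
#' @param parents,focal,inferior,other_rils genotype roles; parents first
#'   (parent A, parent B).
#' @param stress_times ascending stress times in hours.
#' @param n_replicates replicates per genotype x time x assay.
#' @param n_per_class genes per inheritance class.
#' @param coherent_size,fragmented_block_sizes co-expression module size and
#'   its two sign-blocks in the fragmented regime.
#' @param steady_size,constitutive_size planted module sizes.
#' @param n_background,n_low_abundance unstructured filler genes and
#'   near-zero genes.
#' @param n_families,members_per_family,n_pairs miRNA design.
#' @param n_mirna_background unresponsive miRNAs (singleton families); real
#'   small-RNA libraries are dominated by invariant miRNAs, and the TMM
#'   reference majority relies on them.
#' @param noise_sd planted fold-change noise, log2 units.
#' @param module_noise_sd noise on co-expression-module and target profiles.
#' @param nb_dispersion negative-binomial dispersion (0 = deterministic).
#' @param baseline_log2_mean,baseline_log2_sd control log2-abundance
#'   distribution.
#' @param low_abundance_log2_mean control log2-abundance of near-zero genes.
#' @param margin minimum distance of planted fc values from the
#'   classification thresholds, log2 units.
#' @param fc_threshold,base_threshold,stability_threshold the classification
#'   thresholds the structure is planted against.
#' @param module_amplitude scale applied to the latent module trajectory.
#' @param lambda latent trajectory over the stress times (monotone ramp).
#' @param zero_code_prob probability a planted response code is 0 at a
#'   given time (the panel's transcriptome is mostly unresponsive).
#' @param mirna_range_scales named per-genotype amplitude scales for family
#'   fold-changes (the focal genotype gets the narrowest spread).
#' @param depth_mrna,depth_mirna target library depths.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(seed = 42,
                      parents = c("IR29", "Pokkali"),
                      focal = "FL510",
                      inferior = c("FL454", "FL499"),
                      other_rils = "FL478",
                      stress_times = c(24, 48, 72, 144),
                      n_replicates = 2,
                      n_per_class = 200,
                      coherent_size = 50,
                      fragmented_block_sizes = c(25, 25),
                      steady_size = 40,
                      constitutive_size = 30,
                      n_background = 200,
                      n_low_abundance = 20,
                      n_families = 12,
                      members_per_family = 3,
                      n_mirna_background = 120,
                      n_pairs = 10,
                      noise_sd = 0.25,
                      module_noise_sd = 0.05,
                      nb_dispersion = 0.01,
                      baseline_log2_mean = 8,
                      baseline_log2_sd = 1,
                      low_abundance_log2_mean = -4,
                      margin = 0.75,
                      fc_threshold = 2,
                      base_threshold = 2,
                      stability_threshold = 2,
                      module_amplitude = 1.5,
                      lambda = c(0.5, 1, 1.5, 2),
                      zero_code_prob = 0.5,
                      mirna_range_scales = c(IR29 = 1.5, Pokkali = 1.5,
                                             FL478 = 1.2, FL454 = 1.3,
                                             FL510 = 0.8, FL499 = 1.4),
                      depth_mrna = 2e6,
                      depth_mirna = 1e6) {
    cfg <- as.list(environment())
    stopifnot(length(cfg$lambda) == length(cfg$stress_times),
              cfg$noise_sd >= 0, cfg$module_noise_sd >= 0,
              cfg$nb_dispersion >= 0, cfg$margin >= 0,
              cfg$n_replicates >= 1,
              sum(cfg$fragmented_block_sizes) == cfg$coherent_size,
              cfg$n_pairs <= cfg$n_families)
    roles <- c(cfg$parents, cfg$focal, cfg$inferior, cfg$other_rils)
    if (anyDuplicated(roles)) stop("genotype roles must be disjoint")
    structure(cfg, class = "simConfig")
}

.simGenotypes <- function(cfg)
    c(cfg$parents, cfg$other_rils, cfg$inferior[1], cfg$focal,
      cfg$inferior[2])

.simRils <- function(cfg) c(cfg$other_rils, cfg$inferior[1], cfg$focal,
                            cfg$inferior[2])

## Draw a response-code template over the stress times; the all-(+1)
## pattern is excluded so no unstructured gene can mimic the planted
## steadily-upregulated module in the focal genotype.
.drawTemplate <- function(nt, p0, avoid = list()) {
    repeat {
        tpl <- sample(c(-1L, 0L, 1L), nt, replace = TRUE,
                      prob = c((1 - p0) / 2, p0, (1 - p0) / 2))
        if (all(tpl == 1L)) next
        if (!any(vapply(avoid, function(a) all(a == tpl), logical(1))))
            return(tpl)
    }
}

.nbDraw <- function(mu, dispersion) {
    if (dispersion == 0) return(round(mu))
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

.sampleSheet <- function(cfg, assay) {
    genos <- .simGenotypes(cfg)
    times <- c(0, cfg$stress_times)
    grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        time_h = times, genotype = genos,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[, c("genotype", "time_h", "replicate")]
    grid$assay <- assay
    grid$sample_id <- sprintf("%s_T%03d_R%d_%s", grid$genotype,
                              grid$time_h, grid$replicate, assay)
    grid[, c("sample_id", "genotype", "time_h", "replicate", "assay")]
}

## Turn a planted log2-CPM-scale mean array [gene, genotype, time] into a
## realized count matrix following a sample sheet.
.countsFromMeans <- function(log2_mean, sheet, depth, dispersion) {
    genes <- dimnames(log2_mean)[[1]]
    counts <- matrix(0, length(genes), nrow(sheet),
                     dimnames = list(genes, sheet$sample_id))
    depth_s <- round(stats::runif(nrow(sheet), 0.75 * depth, 1.25 * depth))
    for (s in seq_len(nrow(sheet))) {
        mu <- 2^log2_mean[, sheet$genotype[s], as.character(sheet$time_h[s])]
        expected <- mu / 1e6 * depth_s[s]
        counts[, s] <- .nbDraw(expected, dispersion)
    }
    counts
}

#' Generate a synthetic study with planted structure
#'
#' Plants, on the log2 fold-change scale: four parental-inheritance classes
#' (RIL codes copied from the designated parents, or deviating for the
#' non-parental class) at `fc_threshold + margin`; a steadily-upregulated
#' module in the focal genotype with the early (24 h) downregulation
#' contrast in the inferior genotypes; a constitutive module with an
#' elevated focal 0 h baseline and bounded stress response; a co-expression
#' module that is coherent (shared latent ramp, positive loadings) in the
#' focal genotype, sign-split into two blocks in the second inferior
#' genotype and absent (independent noise) elsewhere; miRNA families whose
#' members share a family profile; and repressive miRNA-target pairs whose
#' focal-genotype target profile is the negated family profile. Counts are
#' negative-binomial realizations of the exponentiated means. One seed, one
#' byte-stream.
#'
#' @param config a [simConfig()].
#' @return list with `mrna` and `mirna` ([CountMatrix-class]), `sample_sheet`
#'   (both assays), `family_map`, `pairs`, and `truth` (planted classes,
#'   module memberships, per-genotype coherence regimes, pair list, config).
#' @export
simulateStudy <- function(config) {
    cfg <- config
    set.seed(cfg$seed)
    genos <- .simGenotypes(cfg)
    rils <- .simRils(cfg)
    pA <- cfg$parents[1]; pB <- cfg$parents[2]
    nt <- length(cfg$stress_times)
    amp <- cfg$fc_threshold + cfg$margin
    classes <- c("complete", "parentA_like", "parentB_like", "non_parental")

    ids <- list(
        inherit = sprintf("GENE%04d", seq_len(4 * cfg$n_per_class)),
        steady = sprintf("STDY%03d", seq_len(cfg$steady_size)),
        consti = sprintf("CNST%03d", seq_len(cfg$constitutive_size)),
        coherent = sprintf("COEX%03d", seq_len(cfg$coherent_size)),
        target = sprintf("TRGT%03d", seq_len(cfg$n_pairs)),
        background = sprintf("BKGD%04d", seq_len(cfg$n_background)),
        low = sprintf("LOWA%03d", seq_len(cfg$n_low_abundance)))
    genes <- unlist(ids, use.names = FALSE)
    class_of <- rep(classes, each = cfg$n_per_class)

    ## planted log2 means: baseline + genotype baseline shift + fc
    mu <- stats::rnorm(length(genes), cfg$baseline_log2_mean,
                       cfg$baseline_log2_sd)
    names(mu) <- genes
    mu[ids$low] <- cfg$low_abundance_log2_mean
    shift <- matrix(0, length(genes), length(genos),
                    dimnames = list(genes, genos))
    fc <- array(0, dim = c(length(genes), length(genos), nt),
                dimnames = list(genes, genos,
                                as.character(cfg$stress_times)))

    ## (1) inheritance classes: code templates per genotype
    for (i in seq_along(ids$inherit)) {
        g <- ids$inherit[i]
        cl <- class_of[i]
        tA <- .drawTemplate(nt, cfg$zero_code_prob)
        tpl <- switch(cl,
            complete = {
                list(A = tA, B = tA, R = tA)
            },
            parentA_like = {
                tB <- .drawTemplate(nt, cfg$zero_code_prob, avoid = list(tA))
                list(A = tA, B = tB, R = tA)
            },
            parentB_like = {
                tB <- .drawTemplate(nt, cfg$zero_code_prob, avoid = list(tA))
                list(A = tA, B = tB, R = tB)
            },
            non_parental = {
                tB <- .drawTemplate(nt, cfg$zero_code_prob)
                tR <- .drawTemplate(nt, cfg$zero_code_prob,
                                    avoid = list(tA, tB))
                list(A = tA, B = tB, R = tR)
            })
        fc[g, pA, ] <- tpl$A * amp
        fc[g, pB, ] <- tpl$B * amp
        for (r in rils) fc[g, r, ] <- tpl$R * amp
        fc[g, , ] <- fc[g, , ] +
            stats::rnorm(length(genos) * nt, 0, cfg$noise_sd)
    }

    ## (2) steadily-upregulated module in the focal genotype
    for (g in ids$steady) {
        fc[g, cfg$focal, ] <- amp + abs(stats::rnorm(nt, 0, cfg$noise_sd))
        others <- setdiff(genos, cfg$focal)
        fc[g, others, ] <- stats::rnorm(length(others) * nt, 0, cfg$noise_sd)
        fc[g, cfg$inferior, 1] <- -amp +
            stats::rnorm(length(cfg$inferior), 0, cfg$noise_sd)
    }

    ## (3) constitutive-high module: raised focal baseline, bounded response
    band <- cfg$stability_threshold - cfg$margin
    for (g in ids$consti) {
        shift[g, cfg$focal] <- cfg$base_threshold + cfg$margin
        fc[g, , ] <- pmin(pmax(
            stats::rnorm(length(genos) * nt, 0, cfg$noise_sd), -band), band)
    }

    ## (4) co-expression module: coherent / fragmented / absent regimes
    lam <- cfg$lambda * cfg$module_amplitude
    regimes <- stats::setNames(rep("absent", length(genos)), genos)
    regimes[cfg$focal] <- "coherent"
    frag_geno <- cfg$inferior[2]
    regimes[frag_geno] <- "fragmented"
    loadings <- stats::runif(cfg$coherent_size, 0.8, 1.2)
    block <- rep(c(1L, 2L), times = cfg$fragmented_block_sizes)
    for (i in seq_along(ids$coherent)) {
        g <- ids$coherent[i]
        fc[g, cfg$focal, ] <- loadings[i] * lam +
            stats::rnorm(nt, 0, cfg$module_noise_sd)
        sgn <- if (block[i] == 1L) 1 else -1
        fc[g, frag_geno, ] <- sgn * loadings[i] * lam +
            stats::rnorm(nt, 0, cfg$module_noise_sd)
        absent <- setdiff(genos, c(cfg$focal, frag_geno))
        fc[g, absent, ] <- stats::rnorm(length(absent) * nt, 0, cfg$noise_sd)
    }

    ## (5) background and near-zero genes
    for (g in c(ids$background, ids$low))
        fc[g, , ] <- stats::rnorm(length(genos) * nt, 0, cfg$noise_sd)

    ## (6) miRNA families, members and repressive targets
    fam_names <- c("miR156", "miR160", "miR164", "miR166", "miR167",
                   "miR169", "miR172", "miR319", "miR396", "miR397",
                   "miR398", "miR827")
    if (cfg$n_families <= length(fam_names)) {
        fams <- fam_names[seq_len(cfg$n_families)]
    } else {
        fams <- c(fam_names, sprintf("miRf%02d",
                  seq_len(cfg$n_families - length(fam_names))))
    }
    fam_amp <- sample(c(-1, 1), cfg$n_families, replace = TRUE) *
        stats::runif(cfg$n_families, 0.7, 1.3)
    scales <- cfg$mirna_range_scales[genos]
    fam_fc_template <- array(0, dim = c(cfg$n_families, length(genos), nt),
                             dimnames = list(fams, genos,
                                             as.character(cfg$stress_times)))
    for (f in seq_len(cfg$n_families))
        for (g in seq_along(genos))
            fam_fc_template[f, g, ] <- fam_amp[f] * scales[g] *
                cfg$lambda * cfg$module_amplitude

    members <- unlist(lapply(fams, function(f)
        paste0(f, letters[seq_len(cfg$members_per_family)])))
    bg_mirna <- sprintf("bgmir%03d", seq_len(cfg$n_mirna_background))
    family_map <- data.frame(
        mirna_id = c(members, bg_mirna),
        family = c(rep(fams, each = cfg$members_per_family), bg_mirna),
        stringsAsFactors = FALSE)
    members <- family_map$mirna_id
    mu_mir <- stats::rnorm(length(members), cfg$baseline_log2_mean,
                           cfg$baseline_log2_sd)
    names(mu_mir) <- members
    fc_mir <- array(0, dim = c(length(members), length(genos), nt),
                    dimnames = list(members, genos,
                                    as.character(cfg$stress_times)))
    for (m in seq_along(members)) {
        f <- match(family_map$family[m], fams)
        fc_mir[m, , ] <- if (is.na(f)) {
            stats::rnorm(length(genos) * nt, 0, cfg$noise_sd)
        } else {
            fam_fc_template[f, , ] +
                stats::rnorm(length(genos) * nt, 0, cfg$module_noise_sd)
        }
    }

    pairs <- data.frame(family = fams[seq_len(cfg$n_pairs)],
                        gene_id = ids$target, stringsAsFactors = FALSE)
    for (i in seq_len(cfg$n_pairs)) {
        g <- ids$target[i]
        fc[g, cfg$focal, ] <- -fam_fc_template[i, cfg$focal, ] +
            stats::rnorm(nt, 0, cfg$module_noise_sd)
        others <- setdiff(genos, cfg$focal)
        fc[g, others, ] <- stats::rnorm(length(others) * nt, 0, cfg$noise_sd)
    }

    ## (7) realize counts
    log2_mean <- array(0, dim = c(length(genes), length(genos), nt + 1),
                       dimnames = list(genes, genos,
                                       as.character(c(0, cfg$stress_times))))
    for (g in genos) {
        log2_mean[, g, 1] <- mu + shift[, g]
        for (t in seq_len(nt))
            log2_mean[, g, t + 1] <- mu + shift[, g] + fc[, g, t]
    }
    sheet_mrna <- .sampleSheet(cfg, "mrna")
    counts_mrna <- .countsFromMeans(log2_mean, sheet_mrna, cfg$depth_mrna,
                                    cfg$nb_dispersion)
    log2_mean_mir <- array(0, dim = c(length(members), length(genos),
                                      nt + 1),
                           dimnames = list(members, genos,
                                           as.character(c(0,
                                               cfg$stress_times))))
    for (g in genos) {
        log2_mean_mir[, g, 1] <- mu_mir
        for (t in seq_len(nt))
            log2_mean_mir[, g, t + 1] <- mu_mir + fc_mir[, g, t]
    }
    sheet_mirna <- .sampleSheet(cfg, "mirna")
    counts_mirna <- .countsFromMeans(log2_mean_mir, sheet_mirna,
                                     cfg$depth_mirna, cfg$nb_dispersion)

    truth <- list(
        classes = data.frame(gene_id = ids$inherit, class = class_of,
                             stringsAsFactors = FALSE),
        modules = list(steady = ids$steady, constitutive = ids$consti,
                       coherent = ids$coherent,
                       coherent_blocks = split(ids$coherent, block)),
        regimes = regimes,
        pairs = pairs,
        low_abundance = ids$low,
        config = unclass(cfg))

    list(mrna = CountMatrix(counts_mrna, sheet_mrna),
         mirna = CountMatrix(counts_mirna, sheet_mirna),
         sample_sheet = rbind(sheet_mrna, sheet_mirna),
         family_map = family_map,
         pairs = pairs,
         truth = truth)
}

#' Write a generated study to disk
#'
#' Emits `mrna_counts.tsv`, `mirna_counts.tsv`, per-assay sample sheets,
#' `family_map.tsv`, `pairs.tsv` and `truth.json`; byte-identical for an
#' identical generator configuration.
#'
#' @param sim output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCountMatrix(sim$mrna, file.path(dir, "mrna_counts.tsv"),
                     file.path(dir, "samples_mrna.tsv"))
    writeCountMatrix(sim$mirna, file.path(dir, "mirna_counts.tsv"),
                     file.path(dir, "samples_mirna.tsv"))
    writeFamilyMap(sim$family_map, file.path(dir, "family_map.tsv"))
    utils::write.table(sim$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    truth <- sim$truth
    truth$config$mirna_range_scales <-
        as.list(truth$config$mirna_range_scales)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}

.jaccard <- function(a, b) {
    u <- union(a, b)
    if (length(u) == 0) return(1)
    length(intersect(a, b)) / length(u)
}

#' Recovery metrics of pipeline outputs against the planted truth
#'
#' @param truth the `truth` element of [simulateStudy()].
#' @param outputs named list with any of: `inheritance` (calls from
#'   [traceAll()]), `steady` and `constitutive` ([GeneModule-class]),
#'   `ranking` (data.frame from [compareNetworks()]), `pairs` (table from
#'   [pairCorrelation()]).
#' @return list of metrics in `[0, 1]` (plus the inheritance confusion
#'   matrix): `inheritance_accuracy`, `confusion`, `steady_jaccard`,
#'   `constitutive_jaccard`, `ranking_correct`, `pair_recall`.
#' @export
truthReport <- function(truth, outputs) {
    out <- list()
    if (!is.null(outputs$inheritance)) {
        calls <- outputs$inheritance
        keep <- calls$gene_id %in% truth$classes$gene_id
        if (!any(keep))
            stop("id mismatch: no truth gene appears in the inheritance calls")
        calls <- calls[keep, , drop = FALSE]
        planted <- truth$classes$class[match(calls$gene_id,
                                             truth$classes$gene_id)]
        out$inheritance_accuracy <- mean(calls$category == planted)
        out$confusion <- table(planted = planted, called = calls$category)
    }
    if (!is.null(outputs$steady))
        out$steady_jaccard <- .jaccard(moduleMembers(outputs$steady),
                                       truth$modules$steady)
    if (!is.null(outputs$constitutive))
        out$constitutive_jaccard <-
            .jaccard(moduleMembers(outputs$constitutive),
                     truth$modules$constitutive)
    if (!is.null(outputs$ranking)) {
        rk <- outputs$ranking$genotype
        coh <- names(truth$regimes)[truth$regimes == "coherent"]
        frg <- names(truth$regimes)[truth$regimes == "fragmented"]
        out$ranking_correct <- all(match(coh, rk) < min(match(frg, rk)))
    }
    if (!is.null(outputs$pairs)) {
        pt <- outputs$pairs
        focal <- truth$config$focal
        pt <- pt[pt$genotype == focal, , drop = FALSE]
        key <- paste(pt$family, pt$gene_id)
        want <- paste(truth$pairs$family, truth$pairs$gene_id)
        if (!any(want %in% key))
            stop("id mismatch: no truth pair appears in the pair table")
        out$pair_recall <- mean(pt$repression_consistent[key %in% want])
    }
    out
}
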