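test_that("one seed yields one byte-stream", {
    cfg <- smallConfig(seed = 61)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    writeStudy(simulateStudy(cfg), d1)
    writeStudy(simulateStudy(cfg), d2)
    files <- list.files(d1)
    expect_true(length(files) >= 7)
    for (f in files)
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = f)
    # a different seed changes the counts
    d3 <- withr::local_tempdir()
    writeStudy(simulateStudy(smallConfig(seed = 62)), d3)
    expect_false(identical(
        unname(tools::md5sum(file.path(d1, "mrna_counts.tsv"))),
        unname(tools::md5sum(file.path(d3, "mrna_counts.tsv")))))
})

test_that("truth tables mirror the configuration", {
    cfg <- smallConfig(seed = 63)
    sim <- simulateStudy(cfg)
    expect_equal(as.integer(table(sim$truth$classes$class)[
        c("complete", "parentA_like", "parentB_like", "non_parental")]),
        rep(cfg$n_per_class, 4))
    expect_length(sim$truth$modules$steady, cfg$steady_size)
    expect_length(sim$truth$modules$constitutive, cfg$constitutive_size)
    expect_length(sim$truth$modules$coherent, cfg$coherent_size)
    expect_equal(unname(sim$truth$regimes[c("FL510", "FL499")]),
                 c("coherent", "fragmented"))
    expect_equal(nrow(sim$truth$pairs), cfg$n_pairs)
    # truth references only generated ids
    expect_true(all(sim$truth$classes$gene_id %in% geneIDs(sim$mrna)))
    expect_true(all(sim$truth$pairs$gene_id %in% geneIDs(sim$mrna)))
    expect_true(all(sim$truth$pairs$family %in% sim$family_map$family))
    # generated files parse back into the same objects
    dir <- withr::local_tempdir()
    writeStudy(sim, dir)
    back <- readCountMatrix(file.path(dir, "mrna_counts.tsv"),
                            file.path(dir, "samples_mrna.tsv"))
    expect_identical(SummarizedExperiment::assay(back, "counts"),
                     SummarizedExperiment::assay(sim$mrna, "counts"))
})

test_that("the noiseless pipeline recovers all planted structure", {
    sim <- simulateStudy(smallConfig(seed = 64, noise_sd = 0,
                                     module_noise_sd = 0,
                                     nb_dispersion = 0))
    norm <- normalizeCounts(sim$mrna)
    tensor <- foldChangeTensor(norm)
    inh <- traceAll(tensor, norm, "IR29", "Pokkali",
                    c("FL478", "FL454", "FL510", "FL499"))
    steady <- refineByEarlyContrast(selectSteadyUp(tensor, "FL510"),
                                    tensor, c("FL454", "FL499"))
    consti <- selectConstitutive(tensor, "FL510", c("IR29", "Pokkali"))
    coex <- sim$truth$modules$coherent
    reps <- lapply(genotypeNames(tensor), function(g)
        fragmentationMetrics(suppressMessages(buildNetwork(
            temporalProfiles(tensor, coex, g), 0.95, -0.95, g))))
    fam_tensor <- foldChangeTensor(
        normalizeCounts(collapseFamilies(sim$mirna, sim$family_map)))
    pc <- pairCorrelation(fam_tensor, tensor, sim$pairs)
    tr <- truthReport(sim$truth,
                      list(inheritance = inh, steady = steady,
                           constitutive = consti,
                           ranking = compareNetworks(reps), pairs = pc))
    expect_equal(tr$inheritance_accuracy, 1)
    expect_equal(tr$steady_jaccard, 1)
    expect_equal(tr$constitutive_jaccard, 1)
    expect_true(tr$ranking_correct)
    expect_equal(tr$pair_recall, 1)
})

test_that("realized counts sit within negative-binomial scatter", {
    cfg <- smallConfig(seed = 65)
    expected <- simulateStudy(smallConfig(seed = 65, nb_dispersion = 0))
    realized <- simulateStudy(cfg)
    m <- SummarizedExperiment::assay(expected$mrna, "counts")
    x <- SummarizedExperiment::assay(realized$mrna, "counts")
    big <- m > 20
    z <- (x[big] - m[big]) / sqrt(m[big] + cfg$nb_dispersion * m[big]^2)
    expect_gt(mean(abs(z) < 3.5), 0.99)
    expect_lt(abs(mean(z)), 0.05)
})

test_that("truth report arithmetic counts mislabels exactly", {
    sim <- simulateStudy(smallConfig(seed = 66, noise_sd = 0,
                                     module_noise_sd = 0,
                                     nb_dispersion = 0))
    norm <- normalizeCounts(sim$mrna)
    tensor <- foldChangeTensor(norm)
    inh <- traceAll(tensor, norm, "IR29", "Pokkali", "FL478")
    tr <- truthReport(sim$truth, list(inheritance = inh))
    expect_equal(tr$inheritance_accuracy, 1)
    flip <- which(inh$gene_id == sim$truth$classes$gene_id[1])[1]
    inh$category[flip] <- "non_parental"   # was complete
    n <- sum(inh$gene_id %in% sim$truth$classes$gene_id)
    tr2 <- truthReport(sim$truth, list(inheritance = inh))
    expect_equal(tr2$inheritance_accuracy, (n - 1) / n)
    bogus <- inh
    bogus$gene_id <- paste0("XX", bogus$gene_id)
    expect_error(truthReport(sim$truth, list(inheritance = bogus)),
                 "id mismatch")
})

test_that("generator rejects inconsistent configurations", {
    expect_error(simConfig(fragmented_block_sizes = c(10, 10),
                           coherent_size = 50))
    expect_error(simConfig(focal = "IR29"), "disjoint")
    expect_error(simConfig(n_pairs = 20, n_families = 12))
})
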