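test_that("profiles discretize to strict threshold codes", {
    expect_identical(discretizeProfile(c(2.5, -2.5, 0, 1.9)),
                     c(1L, -1L, 0L, 0L))
    expect_identical(discretizeProfile(c(0, 0, 0, 0)), rep(0L, 4))
    expect_identical(discretizeProfile(c(2, -2, 2.0001, -2.0001)),
                     c(0L, 0L, 1L, -1L))
    expect_identical(discretizeProfile(c(NA, 3)), c(NA_integer_, 1L))
})

test_that("single-gene tracing follows the five-category rule", {
    z <- rep(0L, 4)
    expect_equal(traceGene(z, z, z)$category, "complete")
    up2 <- c(1L, 1L, 0L, 0L)
    expect_equal(traceGene(up2, up2, z)$category, "parentA_like")
    expect_equal(traceGene(up2, z, up2)$category, "parentB_like")
    expect_equal(traceGene(c(1L, 0L, 0L, 0L), z,
                           c(-1L, 0L, 0L, 0L))$category, "non_parental")
    expect_equal(traceGene(z, z, z, excluded = "outlier")$category,
                 "excluded")
    # missing times are dropped from comparison
    expect_equal(traceGene(c(1L, NA, 0L, 0L), c(1L, 1L, 0L, 0L),
                           c(1L, -1L, 0L, 0L))$category, "complete")
    allna <- traceGene(rep(NA_integer_, 4), z, z)
    expect_equal(allna$category, "excluded")
    expect_equal(allna$exclusion_reason, "low_abundance")
    expect_error(traceGene(z, z[1:3], z), "share length")
})

test_that("noiseless planted classes are recovered exactly", {
    sim <- simulateStudy(smallConfig(seed = 21, noise_sd = 0,
                                     module_noise_sd = 0,
                                     nb_dispersion = 0))
    norm <- normalizeCounts(sim$mrna)
    tensor <- foldChangeTensor(norm)
    inh <- traceAll(tensor, norm, "IR29", "Pokkali",
                    c("FL478", "FL454", "FL510", "FL499"))
    tr <- truthReport(sim$truth, list(inheritance = inh))
    expect_equal(tr$inheritance_accuracy, 1)
})

test_that("per-RIL category counts conserve the gene total", {
    d <- defaultDerived()
    inh <- traceAll(d$tensor, d$norm, "IR29", "Pokkali",
                    c("FL478", "FL454", "FL510", "FL499"))
    counts <- attr(inh, "counts")
    expect_true(all(rowSums(counts) == length(geneIDs(d$tensor))))
    shared <- attr(inh, "shared")
    expect_true(all(diag(shared) == length(geneIDs(d$tensor))))
    expect_identical(shared, t(shared))
    .fixtureCache$inh <- inh
})

test_that("swapping parents swaps the parent-like categories exactly", {
    d <- defaultDerived()
    rils <- c("FL478", "FL454", "FL510", "FL499")
    ab <- if (!is.null(.fixtureCache$inh)) .fixtureCache$inh else
        traceAll(d$tensor, d$norm, "IR29", "Pokkali", rils)
    ba <- traceAll(d$tensor, d$norm, "Pokkali", "IR29", rils)
    map <- c(complete = "complete", parentA_like = "parentB_like",
             parentB_like = "parentA_like", non_parental = "non_parental",
             excluded = "excluded")
    expect_identical(unname(map[ab$category]), ba$category)
})

test_that("a complete call implies matching parent codes", {
    d <- defaultDerived()
    inh <- if (!is.null(.fixtureCache$inh)) .fixtureCache$inh else
        traceAll(d$tensor, d$norm, "IR29", "Pokkali",
                 c("FL478", "FL454", "FL510", "FL499"))
    fc <- foldChanges(d$tensor)
    codesA <- (fc[, "IR29", ] > 2) - (fc[, "IR29", ] < -2)
    codesB <- (fc[, "Pokkali", ] > 2) - (fc[, "Pokkali", ] < -2)
    complete_genes <- unique(inh$gene_id[inh$category == "complete"])
    same <- codesA[complete_genes, ] == codesB[complete_genes, ]
    expect_true(all(same, na.rm = TRUE))
})

test_that("exclusion rules fire for low abundance and outliers", {
    d <- defaultDerived()
    inh <- if (!is.null(.fixtureCache$inh)) .fixtureCache$inh else
        traceAll(d$tensor, d$norm, "IR29", "Pokkali",
                 c("FL478", "FL454", "FL510", "FL499"))
    low <- d$sim$truth$low_abundance
    got <- inh[inh$gene_id %in% low, ]
    expect_true(all(got$category == "excluded"))
    expect_true(all(got$exclusion_reason == "low_abundance"))
    # an artificial outlier gene
    fc <- foldChanges(d$tensor)
    fc[1, "FL478", 1] <- 15
    t2 <- FoldChangeTensor(fc, baselines(d$tensor))
    inh2 <- traceAll(t2, d$norm, "IR29", "Pokkali", "FL478")
    expect_equal(inh2$exclusion_reason[1], "outlier")
    expect_error(traceAll(d$tensor, d$norm, "IR29", "Pokkali",
                          c("IR29", "FL478")), "cannot also be a RIL")
})

test_that("continuous and baseline-aware matching variants behave sensibly", {
    sim <- simulateStudy(smallConfig(seed = 22, noise_sd = 0,
                                     module_noise_sd = 0,
                                     nb_dispersion = 0))
    norm <- normalizeCounts(sim$mrna)
    tensor <- foldChangeTensor(norm)
    rils <- c("FL478", "FL454", "FL510", "FL499")
    # noiseless planted profiles sit on the template exactly, so the
    # continuous rule at a sub-margin tolerance agrees with the code rule
    inh_codes <- traceAll(tensor, norm, "IR29", "Pokkali", rils)
    inh_cheb <- traceAll(tensor, norm, "IR29", "Pokkali", rils,
                         match_rule = "chebyshev", delta = 1)
    keep <- inh_codes$gene_id %in% sim$truth$classes$gene_id
    expect_gt(mean(inh_codes$category[keep] == inh_cheb$category[keep]),
              0.99)
    # a strict baseline requirement demotes the constitutive module's
    # complete calls (its focal baseline is planted 2.75 log2 units high)
    inh_base <- traceAll(tensor, norm, "IR29", "Pokkali", "FL510",
                         baseline_delta = 0.5)
    consti <- sim$truth$modules$constitutive
    got <- inh_base[inh_base$gene_id %in% consti, ]
    expect_true(all(got$category %in% c("non_parental", "excluded")))
})
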