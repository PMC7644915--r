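# Programmatic fixtures. The reference synthetic study (seed 42, default
# design) is generated once per test run and shared.

.fixtureCache <- new.env(parent = emptyenv())

defaultSim <- function() {
    if (is.null(.fixtureCache$sim))
        .fixtureCache$sim <- simulateStudy(simConfig(seed = 42))
    .fixtureCache$sim
}

# Derived objects of the reference study, computed lazily.
defaultDerived <- function() {
    if (is.null(.fixtureCache$derived)) {
        sim <- defaultSim()
        norm <- normalizeCounts(sim$mrna)
        tensor <- foldChangeTensor(norm)
        .fixtureCache$derived <- list(sim = sim, norm = norm,
                                      tensor = tensor)
    }
    .fixtureCache$derived
}

# A small, fast generator configuration for structural tests. The
# background stays large relative to the planted modules so that the
# unchanged majority TMM normalization assumes is preserved.
smallConfig <- function(seed = 11, ...) {
    simConfig(seed = seed, n_per_class = 25, coherent_size = 20,
              fragmented_block_sizes = c(10, 10), steady_size = 12,
              constitutive_size = 10, n_background = 150,
              n_low_abundance = 5, n_families = 6,
              members_per_family = 2, n_mirna_background = 40,
              n_pairs = 4, ...)
}

# Random count matrix over an arbitrary design.
randomCountMatrix <- function(n_genes = 20,
                              genos = c("gA", "gB"),
                              times = c(0, 24, 48),
                              reps = 1:2, assay = "mrna",
                              lambda = 60) {
    grid <- expand.grid(replicate = reps, time_h = times, genotype = genos,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$assay <- assay
    grid$sample_id <- sprintf("%s_T%02d_R%d", grid$genotype, grid$time_h,
                              grid$replicate)
    counts <- matrix(rpois(n_genes * nrow(grid), lambda), n_genes,
                     dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                     grid$sample_id))
    CountMatrix(counts, grid[, c("sample_id", "genotype", "time_h",
                                 "replicate", "assay")])
}

# FoldChangeTensor built directly from an fc array (baselines default 100).
makeTensor <- function(fc, baseline = NULL) {
    if (is.null(baseline)) {
        baseline <- matrix(100, dim(fc)[1], dim(fc)[2],
                           dimnames = dimnames(fc)[1:2])
    }
    FoldChangeTensor(fc, baseline)
}

randomTensor <- function(n_genes = 30, genos = c("gA", "gB", "gC"),
                         times = c(24, 48, 72, 144), sd = 2) {
    fc <- array(rnorm(n_genes * length(genos) * length(times), 0, sd),
                dim = c(n_genes, length(genos), length(times)),
                dimnames = list(sprintf("g%03d", seq_len(n_genes)), genos,
                                as.character(times)))
    makeTensor(fc)
}
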