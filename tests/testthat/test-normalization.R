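test_that("TMM factors are 1 for identical and depth-scaled columns", {
    col <- c(500, 120, 3000, 60, 9, 800, 42, 11000)
    counts <- cbind(s1 = col, s2 = col, s3 = col, s4 = 10 * col)
    rownames(counts) <- sprintf("g%d", seq_along(col))
    sheet <- data.frame(sample_id = colnames(counts), genotype = "gA",
                        time_h = c(0, 0, 24, 24), replicate = c(1, 2, 1, 2),
                        assay = "mrna")
    f <- tmmFactors(CountMatrix(counts, sheet))
    expect_equal(unname(f), rep(1, 4), tolerance = 1e-9)
})

test_that("TMM factors match the independent trimmed weighted-mean oracle", {
    # composition-shift toy: sample B gains one dominant transcript
    counts <- cbind(sA = c(1000, 2000, 3000, 4000, 5000, 6000),
                    sB = c(1100, 1900, 3100, 3900, 5200, 60000))
    rownames(counts) <- sprintf("g%d", 1:6)
    sheet <- data.frame(sample_id = c("sA", "sB"), genotype = "gA",
                        time_h = c(0, 24), replicate = 1, assay = "mrna")
    x <- CountMatrix(counts, sheet)
    expect_equal(unname(tmmFactors(x)), tmmOracle(counts),
                 tolerance = 1e-9)

    # and on randomized fixtures
    set.seed(20)
    for (i in 1:10) {
        x <- randomCountMatrix(n_genes = 50, lambda = 200)
        counts <- SummarizedExperiment::assay(x, "counts")
        expect_equal(unname(tmmFactors(x)), tmmOracle(counts),
                     tolerance = 1e-9)
    }
})

test_that("TMM factors are invariant to global count rescaling", {
    set.seed(3)
    x <- randomCountMatrix(n_genes = 80, lambda = 300)
    x7 <- CountMatrix(7 * SummarizedExperiment::assay(x, "counts"),
                      sampleInfo(x))
    expect_equal(tmmFactors(x), tmmFactors(x7), tolerance = 1e-9)
    expect_equal(exp(mean(log(tmmFactors(x)))), 1, tolerance = 1e-9)
})

test_that("permuting samples permutes factors identically", {
    set.seed(4)
    x <- randomCountMatrix(n_genes = 60, lambda = 150)
    perm <- sample(ncol(x))
    xp <- CountMatrix(SummarizedExperiment::assay(x, "counts")[, perm],
                      sampleInfo(x)[perm, ])
    expect_equal(unname(tmmFactors(xp)), unname(tmmFactors(x)[perm]),
                 tolerance = 1e-12)
})

test_that("TMM rejects degenerate inputs", {
    one <- randomCountMatrix(n_genes = 5, genos = "gA", times = 0, reps = 1)
    expect_error(tmmFactors(one), "at least 2 samples")
    counts <- cbind(s1 = c(5L, 0L, 9L), s2 = c(0L, 7L, 0L),
                    s3 = c(6L, 1L, 4L))
    rownames(counts) <- c("g1", "g2", "g3")
    sheet <- data.frame(sample_id = colnames(counts), genotype = "gA",
                        time_h = c(0, 24, 48), replicate = 1, assay = "mrna")
    expect_error(tmmFactors(CountMatrix(counts, sheet)),
                 "no gene with nonzero counts in both samples")
})

test_that("normalizeCounts applies the CPM formula cell by cell", {
    # count 100, library 1e6, factor 1 -> value 100
    counts <- cbind(s1 = c(100, 1e6 - 100), s2 = c(200, 1e6 - 200))
    rownames(counts) <- c("g1", "g2")
    sheet <- data.frame(sample_id = c("s1", "s2"), genotype = "gA",
                        time_h = c(0, 24), replicate = 1, assay = "mrna")
    x <- CountMatrix(counts, sheet)
    n1 <- normalizeCounts(x, factors = c(1, 1))
    expect_equal(SummarizedExperiment::assay(n1)["g1", "s1"], 100)
    # doubling a factor halves that sample's values
    n2 <- normalizeCounts(x, factors = c(2, 0.5))
    expect_equal(SummarizedExperiment::assay(n2)[, "s1"],
                 SummarizedExperiment::assay(n1)[, "s1"] / 2)

    set.seed(5)
    x <- randomCountMatrix(n_genes = 20, genos = c("gA", "gB"),
                           times = c(0, 24, 48), reps = 1)
    norm <- normalizeCounts(x)
    counts <- SummarizedExperiment::assay(x, "counts")
    f <- normFactors(norm)
    lib <- librarySizes(norm)
    for (g in rownames(counts)) for (s in colnames(counts))
        expect_equal(SummarizedExperiment::assay(norm)[g, s],
                     counts[g, s] / (lib[[s]] * f[[s]]) * 1e6)
})

test_that("low-abundance mask is the stated predicate", {
    v <- rbind(zero = c(0, 0, 0, 0),
               boundary = c(1, 1, 0, 0),
               onehit = c(5, 0.2, 0.1, 0))
    colnames(v) <- sprintf("s%d", 1:4)
    sheet <- data.frame(sample_id = colnames(v), genotype = "gA",
                        time_h = c(0, 24, 48, 72), replicate = 1,
                        assay = "mrna")
    norm <- normalizeCounts(CountMatrix(matrix(1, 3, 4,
                                               dimnames = dimnames(v)),
                                        sheet), factors = rep(1, 4))
    # replace assay values directly to test the predicate in isolation
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(normcounts = v),
        colData = S4Vectors::DataFrame(sheet, norm_factor = rep(1, 4),
                                       lib_size = rep(1L, 4),
                                       row.names = sheet$sample_id))
    nm <- new("NormalizedMatrix", se)
    expect_identical(unname(lowAbundanceMask(nm)), c(FALSE, TRUE, FALSE))
    set.seed(6)
    w <- matrix(rexp(200, 1), 20, 10,
                dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
    sheet10 <- data.frame(sample_id = colnames(w), genotype = "gA",
                          time_h = seq(0, 90, by = 10), replicate = 1,
                          assay = "mrna")
    nm10 <- new("NormalizedMatrix", SummarizedExperiment::SummarizedExperiment(
        assays = list(normcounts = w),
        colData = S4Vectors::DataFrame(sheet10, norm_factor = rep(1, 10),
                                       lib_size = rep(1L, 10),
                                       row.names = sheet10$sample_id)))
    for (cutoff in c(0.5, 1, 2)) for (ms in c(1, 2, 4))
        expect_identical(lowAbundanceMask(nm10, cutoff, ms),
                         apply(w, 1, function(r) sum(r >= cutoff) >= ms))
})

test_that("fold-change tensor matches per-entry recomputation", {
    set.seed(8)
    x <- randomCountMatrix(n_genes = 25, genos = c("gA", "gB"),
                           times = c(0, 24, 48, 72), reps = 1:2,
                           lambda = 120)
    norm <- normalizeCounts(x)
    tensor <- foldChangeTensor(norm, pseudocount = 1)
    v <- SummarizedExperiment::assay(norm)
    si <- sampleInfo(norm)
    fc <- foldChanges(tensor)
    for (g in c("gA", "gB")) {
        m0 <- rowMeans(v[, si$genotype == g & si$time_h == 0])
        expect_equal(baselines(tensor)[, g], m0)
        for (t in c(24, 48, 72)) {
            mt <- rowMeans(v[, si$genotype == g & si$time_h == t])
            expect_equal(fc[, g, as.character(t)],
                         log2(mt + 1) - log2(m0 + 1))
        }
    }
    # control mean 3, stress mean 15, pseudocount 1 -> fc = log2(16/4) = 2
    v1 <- matrix(c(3, 15), 1, 2, dimnames = list("g1", c("c1", "t1")))
    se1 <- SummarizedExperiment::SummarizedExperiment(
        assays = list(normcounts = v1),
        colData = S4Vectors::DataFrame(
            sample_id = c("c1", "t1"), genotype = "gA",
            time_h = c(0L, 24L), replicate = 1L, assay = "mrna",
            norm_factor = c(1, 1), lib_size = c(1L, 1L),
            row.names = c("c1", "t1")))
    t1 <- foldChangeTensor(new("NormalizedMatrix", se1))
    expect_equal(unname(foldChanges(t1)["g1", "gA", "24"]), 2)
})

test_that("fold-change tensor commutes with gene subsetting", {
    set.seed(9)
    x <- randomCountMatrix(n_genes = 30)
    norm <- normalizeCounts(x)
    full <- foldChangeTensor(norm)
    sub_genes <- geneIDs(x)[c(3, 9, 21)]
    sub_first <- full[sub_genes, ]
    sub_after <- foldChangeTensor(norm[sub_genes, ])
    expect_equal(foldChanges(sub_first), foldChanges(sub_after))
    expect_equal(baselines(sub_first), baselines(sub_after))
})

test_that("a genotype without a control refuses fold-change computation", {
    x <- randomCountMatrix(n_genes = 5, genos = c("gA", "gB"),
                           times = c(0, 24), reps = 1)
    si <- sampleInfo(x)
    keep <- !(si$genotype == "gB" & si$time_h == 0)
    y <- CountMatrix(SummarizedExperiment::assay(x, "counts")[, keep],
                     si[keep, ])
    expect_error(foldChangeTensor(normalizeCounts(y)),
                 "without a 0 h control: gB")
})
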