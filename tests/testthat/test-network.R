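test_that("temporal profiles optionally carry the control zero", {
    fc <- array(rep(c(1, 2, 3, 4), each = 2), dim = c(2, 1, 4),
                dimnames = list(c("gX", "gY"), "gA", c(24, 48, 72, 144)))
    tensor <- makeTensor(fc)
    with0 <- temporalProfiles(tensor, c("gX", "gY"), "gA")
    expect_equal(unname(with0["gX", ]), c(0, 1, 2, 3, 4))
    without <- temporalProfiles(tensor, "gX", "gA",
                                include_control_zero = FALSE)
    expect_equal(unname(without[1, ]), c(1, 2, 3, 4))
    expect_equal(rownames(with0), c("gX", "gY"))
    expect_error(temporalProfiles(tensor, c("gX", "missing"), "gA"),
                 "absent from tensor: missing")
})

test_that("pcc matches the product-moment formula", {
    expect_equal(pcc(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4)), 1)
    expect_equal(pcc(c(0, 1, 2, 3, 4), -c(0, 1, 2, 3, 4)), -1)
    set.seed(41)
    for (i in 1:1000) {
        x <- rnorm(5); y <- rnorm(5)
        expect_equal(pcc(x, y), pccOracle(x, y), tolerance = 1e-12)
        expect_identical(pcc(x, y), pcc(y, x))
    }
    # affine invariance / sign flip
    x <- c(0, 1, 2, 3, 6); y <- rnorm(5)
    expect_equal(pcc(3.2 * x + 5, y), pcc(x, y), tolerance = 1e-12)
    expect_equal(pcc(-1.7 * x + 2, y), -pcc(x, y), tolerance = 1e-12)
    expect_true(is.na(pcc(rep(1, 5), y)))
    expect_error(pcc(1:2, 1:2), "length >= 3")
    expect_error(pcc(1:4, 1:5), "share length")
})

test_that("edges are thresholded inclusively and match a brute-force oracle", {
    x <- c(0, 1, 2, 3, 4); y <- c(0, 1, 2, 3, 6)
    r0 <- pccOracle(x, y)
    prof <- rbind(a = x, b = y)
    at <- buildNetwork(prof, pos_threshold = r0, neg_threshold = -0.99)
    expect_equal(nrow(networkEdges(at)), 1)   # inclusive at the boundary
    above <- buildNetwork(prof, pos_threshold = r0 + 1e-9,
                          neg_threshold = -0.99)
    expect_equal(nrow(networkEdges(above)), 0)

    ident <- matrix(rep(c(0, 1, 2, 3, 4), each = 3), 3,
                    dimnames = list(c("g1", "g2", "g3"), NULL))
    tri <- buildNetwork(ident, 0.95, -0.95)
    expect_equal(nrow(networkEdges(tri)), 3)
    expect_true(all(networkEdges(tri)$r == 1))

    set.seed(42)
    prof30 <- matrix(rnorm(30 * 5), 30, 5,
                     dimnames = list(sprintf("g%02d", 1:30), NULL))
    net <- buildNetwork(prof30, 0.5, -0.5)
    want <- 0L
    for (i in 1:29) for (j in (i + 1):30) {
        r <- pccOracle(prof30[i, ], prof30[j, ])
        if (r >= 0.5 || r <= -0.5) want <- want + 1L
    }
    expect_equal(nrow(networkEdges(net)), want)
})

test_that("the edge set is invariant to gene order", {
    set.seed(43)
    prof <- matrix(rnorm(20 * 5), 20, 5,
                   dimnames = list(sprintf("g%02d", 1:20), NULL))
    e1 <- networkEdges(buildNetwork(prof, 0.6, -0.6))
    perm <- sample(20)
    e2 <- networkEdges(buildNetwork(prof[perm, ], 0.6, -0.6))
    key <- function(e) sort(paste(e$gene_a, e$gene_b, e$sign))
    expect_identical(key(e1), key(e2))
})

test_that("zero-variance profiles form no edges", {
    prof <- rbind(flat = rep(2, 5), a = c(0, 1, 2, 3, 4),
                  b = c(0, 1.1, 2, 3.2, 4))
    expect_message(net <- buildNetwork(prof, 0.9, -0.9), "flat")
    e <- networkEdges(net)
    expect_false("flat" %in% c(e$gene_a, e$gene_b))
    expect_true("flat" %in% networkNodes(net))
})

test_that("fragmentation metrics quantify cohesion on toy graphs", {
    full <- matrix(rep(c(0, 1, 2, 3, 4), each = 5), 5,
                   dimnames = list(paste0("n", 1:5), NULL))
    m <- fragmentationMetrics(buildNetwork(full, 0.95, -0.95))
    expect_equal(m$n_components_positive, 1)
    expect_equal(m$largest_positive_component_fraction, 1)
    expect_equal(m$n_isolated_nodes, 0)

    # two positive 3-cliques joined only by negative edges:
    # clique profiles x and -x
    x <- c(0, 1, 2, 3, 4)
    prof <- rbind(a1 = x, a2 = x, a3 = x, b1 = -x, b2 = -x, b3 = -x)
    net <- buildNetwork(prof, 0.95, -0.95)
    m2 <- suppressWarnings(fragmentationMetrics(net,
                                                hub_genes = c("a1", "zz")))
    expect_equal(m2$n_pos_edges, 6)          # 3 within each clique
    expect_equal(m2$n_neg_edges, 9)          # all 3x3 across
    expect_equal(m2$negative_edge_fraction, 9 / 15)
    expect_equal(m2$n_components_positive, 2)
    expect_equal(m2$n_components_all, 1)
    expect_equal(m2$largest_positive_component_fraction, 3 / 6)
    expect_equal(unname(m2$hub_degrees["a1"]), 5)
    expect_warning(fragmentationMetrics(net, hub_genes = "zz"),
                   "not in network")

    lonely <- suppressMessages(
        buildNetwork(matrix(rep(1, 50), 10,
                            dimnames = list(paste0("i", 1:10), NULL)),
                     0.95, -0.95))
    m3 <- fragmentationMetrics(lonely)
    expect_equal(m3$n_isolated_nodes, 10)
    expect_equal(m3$largest_positive_component_fraction, 1 / 10)
    expect_equal(m3$negative_edge_fraction, 0)
})

test_that("network comparison ranks cohesion deterministically", {
    x <- c(0, 1, 2, 3, 4)
    cohesive <- fragmentationMetrics(
        buildNetwork(rbind(a = x, b = x, c = x), 0.95, -0.95))
    cohesive$genotype <- "coh"
    split2 <- fragmentationMetrics(
        buildNetwork(rbind(a = x, b = x, c = -x, d = -x), 0.95, -0.95))
    split2$genotype <- "frag"
    cmp <- compareNetworks(list(split2, cohesive))
    expect_equal(cmp$genotype, c("coh", "frag"))
    # stable order for identical metrics
    twin1 <- cohesive; twin1$genotype <- "first"
    twin2 <- cohesive; twin2$genotype <- "second"
    cmp2 <- compareNetworks(list(twin1, twin2))
    expect_equal(cmp2$genotype, c("first", "second"))
    expect_error(compareNetworks(list(cohesive)), "at least 2")
    expect_error(compareNetworks(list(cohesive, cohesive)), "duplicate")
})
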