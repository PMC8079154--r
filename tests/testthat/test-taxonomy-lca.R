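# LCA assignment: retention filters, deepest-supported-node semantics,
# order independence, run-level minimum support, gene-content counting.

test_that("retention applies min score, max E and top-percent filters", {
    cfg <- screenConfig()
    h <- mkHits(bits = c(200, 190, 90))
    expect_equal(sort(hitRecords(retainHits(h, cfg))$bit_score,
                      decreasing = TRUE), c(200, 190))  # cutoff 160

    all_low <- mkHits(bits = c(49, 30, 10))
    expect_length(retainHits(all_low, cfg), 0L)

    single <- mkHits(bits = 60, evalue = 1e-5)
    expect_length(retainHits(single, cfg), 1L)

    # top-percent is measured against the best survivor of the first two
    # filters, not the raw best
    mixed <- mkHits(bits = c(500, 90, 80), evalue = c(1, 1e-30, 1e-30))
    expect_equal(sort(hitRecords(retainHits(mixed, cfg))$bit_score),
                 c(80, 90))
})

test_that("LCA lands on the deepest node supported by the hit taxa", {
    tr <- fixedTaxonomy()
    cfg <- screenConfig()
    # taxa m1, m2: their LCA Mollusca has support 2/2
    a <- assignLca(mkHits(bits = c(200, 195), taxon = c("m1", "m2")),
                   tr, cfg)
    expect_identical(a$assigned_taxon_id, "Mollusca")
    expect_equal(a$support_fraction, 1)
    expect_equal(a$n_hits_retained, 2L)

    # no retained hit
    expect_identical(
        assignLca(mkHits(bits = 10), tr, cfg)$assigned_taxon_id,
        "UNASSIGNED")

    # 9 taxa under Lophotrochozoa + 1 algal at 90% support
    h <- mkHits(bits = 200,
                taxon = c(rep(c("m1", "m2", "Mollusca"), 3), "a1"),
                subject_id = sprintf("s%02d", 1:10))
    # 10 hits but only 4 unique taxa: support(Lophotrochozoa) = 3/4 < .9
    expect_identical(assignLca(h, tr, cfg)$assigned_taxon_id,
                     "Eukaryota")
    # per-taxon weighting: same taxon repeated never inflates support
    h2 <- mkHits(bits = 200, taxon = c(rep("m1", 9), "a1"),
                 subject_id = sprintf("s%02d", 1:10))
    expect_identical(assignLca(h2, tr, cfg)$assigned_taxon_id,
                     "Eukaryota")

    expect_error(assignLca(mkHits(bits = 200, taxon = "martian"), tr,
                           cfg), "martian")
})

test_that("LCA equals the exhaustive all-node scan on random instances", {
    cfg <- screenConfig()
    set.seed(42)
    for (i in 1:40) {
        tr <- simulateTaxonomy(sample(10:60, 1), seed = 1000 + i)
        pool <- taxonIds(tr)
        taxa <- sample(pool, sample(1:40, 1), replace = TRUE)
        bits <- runif(length(taxa), 60, 300)
        h <- mkHits(bits = bits, taxon = taxa,
                    subject_id = sprintf("s%03d", seq_along(taxa)))
        keep <- oracleRetain(bits, rep(1e-30, length(bits)), cfg)
        got <- assignLca(h, tr, cfg)$assigned_taxon_id
        expect_identical(got,
                         oracleLca(tr, taxa[keep], cfg@lca$lca_percent))
    }
})

test_that("raising lca_percent never deepens the assignment", {
    set.seed(43)
    for (i in 1:15) {
        tr <- simulateTaxonomy(30, seed = 2000 + i)
        taxa <- sample(taxonIds(tr), 8, replace = TRUE)
        h <- mkHits(bits = 200, taxon = taxa,
                    subject_id = sprintf("s%d", 1:8))
        prev <- NULL
        for (pct in c(50, 70, 90, 100)) {
            node <- assignLca(h, tr, screenConfig(
                lca = list(lca_percent = pct)))$assigned_taxon_id
            if (!is.null(prev))
                expect_true(node %in% ancestorPath(tr, prev))
            prev <- node
        }
    }
})

test_that("assignment is invariant to hit order", {
    tr <- fixedTaxonomy()
    cfg <- screenConfig()
    df <- hitRecords(mkHits(bits = c(300, 220, 210, 180),
                            taxon = c("m1", "a1", "m2", "b1"),
                            subject_id = sprintf("s%d", 1:4)))
    ref <- assignLca(HitTable(df), tr, cfg)
    for (i in 1:5) {
        perm <- df[sample(nrow(df)), , drop = FALSE]
        expect_identical(assignLca(HitTable(perm), tr, cfg), ref)
    }
})

test_that("run-level min support pushes weakly supported nodes up", {
    tr <- fixedTaxonomy()
    h <- rbind(hitRecords(mkHits("gA", bits = 200, taxon = "m1")),
               hitRecords(mkHits("gB", bits = 200, taxon = "m1")),
               hitRecords(mkHits("gC", bits = 200, taxon = "a1")))
    cfg <- screenConfig(lca = list(min_support = 2))
    res <- lcaScan(HitTable(h), tr, cfg)
    # m1 holds two genes and stays; a1 holds one and is pushed upward
    # until a node with enough support (here: beyond the root ->
    # the push passes through ancestors that still hold only one gene)
    expect_identical(res$assigned_taxon_id[res$gene_id == "gA"], "m1")
    expect_identical(res$assigned_taxon_id[res$gene_id == "gB"], "m1")
    expect_identical(res$assigned_taxon_id[res$gene_id == "gC"],
                     "UNASSIGNED")

    # low-complexity queries are dropped from assignment
    res2 <- lcaScan(HitTable(h), tr, screenConfig(),
                    low_complexity = c(gA = TRUE, gB = FALSE))
    expect_identical(res2$assigned_taxon_id[res2$gene_id == "gA"],
                     "UNASSIGNED")
    expect_identical(res2$assigned_taxon_id[res2$gene_id == "gC"], "a1")
})

test_that("scaffold gene content counts bacterial and host genes", {
    tr <- fixedTaxonomy()
    gr <- GenomicRanges::GRanges(
        rep(c("scf1", "scf2"), c(3, 2)),
        IRanges::IRanges(c(1, 500, 1000, 1, 500), width = 300))
    gr$gene_id <- sprintf("g%d", 1:5)
    cat <- GeneCatalog(gr)
    asg <- data.frame(
        gene_id = sprintf("g%d", 1:5),
        assigned_taxon_id = c("b1", "Bacteria", "Mollusca",
                              "UNASSIGNED", "a2"),
        n_hits_retained = 1L, support_fraction = 1)
    out <- classifyScaffoldGeneContent(asg, cat, tr)
    expect_equal(out[out$scaffold_id == "scf1",
                     c("n_bacterial", "n_lophotrochozoan", "n_other")],
                 data.frame(n_bacterial = 2L, n_lophotrochozoan = 1L,
                            n_other = 0L),
                 ignore_attr = TRUE)
    expect_equal(out[out$scaffold_id == "scf2", ]$n_other, 1L)

    # all unassigned -> zero everywhere
    asg$assigned_taxon_id <- "UNASSIGNED"
    out2 <- classifyScaffoldGeneContent(asg, cat, tr)
    expect_true(all(out2[, -1] == 0L))

    # mixed random content matches a direct membership recount
    set.seed(8)
    g <- taxonGroups(tr)
    nodes <- taxonIds(tr)
    asg3 <- data.frame(gene_id = sprintf("g%d", 1:5),
                       assigned_taxon_id = sample(nodes, 5, TRUE),
                       n_hits_retained = 1L, support_fraction = 1)
    out3 <- classifyScaffoldGeneContent(asg3, cat, tr)
    expect_equal(sum(out3$n_bacterial),
                 sum(asg3$assigned_taxon_id %in% g$prokaryote))
    expect_equal(sum(out3$n_lophotrochozoan),
                 sum(asg3$assigned_taxon_id %in% g$lophotrochozoa))
})
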