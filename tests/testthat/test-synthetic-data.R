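# Synthetic-data generators: determinism, validator conformance, planted
# structure.

test_that("generators are deterministic under a fixed seed", {
    expect_identical(simulateTaxonomy(25, seed = 4),
                     simulateTaxonomy(25, seed = 4))
    g1 <- simulateGenome(n_scaffolds = 4, genes_per_scaffold = 3,
                         n_hgt = 2, seed = 4)
    g2 <- simulateGenome(n_scaffolds = 4, genes_per_scaffold = 3,
                         n_hgt = 2, seed = 4)
    expect_identical(g1$truth, g2$truth)
    expect_identical(as.character(scaffoldSequences(g1$scaffolds)),
                     as.character(scaffoldSequences(g2$scaffolds)))
    tr <- simulateTaxonomy(20, seed = 4)
    expect_identical(hitRecords(simulateHitTable(g1, tr, seed = 4)),
                     hitRecords(simulateHitTable(g2, tr, seed = 4)))
    expect_identical(simulateReadHits(n_algal = 20, n_control = 30,
                                      seed = 4),
                     simulateReadHits(n_algal = 20, n_control = 30,
                                      seed = 4))
    expect_identical(simulateDepths(g1, seed = 4),
                     simulateDepths(g2, seed = 4))
    expect_identical(simulateCountsAndDegs(n_orthogroups = 15, seed = 4),
                     simulateCountsAndDegs(n_orthogroups = 15, seed = 4))
})

test_that("simulated taxonomies always satisfy the tree invariants", {
    for (seed in 1:25) {
        tr <- simulateTaxonomy(sample(8:60, 1), seed = seed)
        expect_true(methods::validObject(tr))
        g <- taxonGroups(tr)
        expect_length(intersect(g$algae, g$lophotrochozoa), 0L)
        expect_true(all(g$algae %in% g$eukaryote))
    }
})

test_that("genome truth labels match the requested plan", {
    gen <- simulateGenome(n_scaffolds = 6, genes_per_scaffold = 4,
                          n_hgt = 0, n_contaminant_scaffolds = 3,
                          sequences = FALSE, seed = 6)
    truth <- gen$truth
    expect_equal(sum(truth$genes$true_origin == "algal_hgt"), 0L)
    bact <- truth$scaffolds$scaffold_id[
        truth$scaffolds$true_label == "bacterial_contaminant"]
    expect_length(bact, 3L)
    for (s in bact) {
        on_s <- truth$genes[truth$genes$scaffold_id == s, ]
        expect_gte(nrow(on_s), 2L)
        expect_true(all(on_s$true_origin == "bacterial"))
    }
    # planted HGT genes always sit on nuclear scaffolds among host genes
    gen2 <- simulateGenome(n_scaffolds = 6, genes_per_scaffold = 4,
                           n_hgt = 5, sequences = FALSE, seed = 7)
    hgt <- gen2$truth$genes[gen2$truth$genes$true_origin == "algal_hgt", ]
    nuc <- gen2$truth$scaffolds$scaffold_id[
        gen2$truth$scaffolds$true_label == "nuclear"]
    expect_true(all(hgt$scaffold_id %in% nuc))

    expect_error(simulateGenome(n_scaffolds = 2, genes_per_scaffold = 5,
                                scaffold_length = 100, seed = 1),
                 "cannot hold")
    expect_error(simulateGenome(n_scaffolds = 1, genes_per_scaffold = 2,
                                n_hgt = 5, sequences = FALSE, seed = 1),
                 "more planted HGT")
})

test_that("generated artifacts survive their writers and readers", {
    gen <- simulateGenome(n_scaffolds = 3, genes_per_scaffold = 3,
                          n_hgt = 1, seed = 8)
    tr <- simulateTaxonomy(15, seed = 8)
    ht <- simulateHitTable(gen, tr, seed = 8)
    dir <- withr::local_tempdir()

    writeFastaScaffolds(gen$scaffolds, file.path(dir, "asm.fa"))
    ss <- readFastaScaffolds(file.path(dir, "asm.fa"))
    expect_identical(scaffoldInfo(ss), scaffoldInfo(gen$scaffolds))

    writeGffGenes(gen$genes, file.path(dir, "genes.gff3"))
    cat2 <- readGffGenes(file.path(dir, "genes.gff3"))
    expect_setequal(geneModels(cat2)$gene_id,
                    geneModels(gen$genes)$gene_id)
    expect_identical(geneScaffolds(cat2)[geneModels(gen$genes)$gene_id],
                     geneScaffolds(gen$genes))

    writeTaxonomy(tr, file.path(dir, "tax.tsv"))
    expect_true(methods::validObject(readTaxonomy(file.path(dir,
                                                            "tax.tsv"))))
    writeHitTable(ht, file.path(dir, "hits.tsv"))
    back <- readHitTable(file.path(dir, "hits.tsv"), "kleptoscreen")
    expect_equal(hitRecords(back)$bit_score, hitRecords(ht)$bit_score,
                 tolerance = 1e-12)

    dep <- simulateDepths(gen, seed = 8)
    writeDepthTable(dep, file.path(dir, "depths.tsv"))
    expect_equal(readDepthTable(file.path(dir, "depths.tsv"))[
        rownames(dep), colnames(dep)], dep, tolerance = 1e-12)
})

test_that("the Karlin-Altschul conversion matches direct evaluation", {
    m <- scoreModel()  # lambda 0.267, k 0.041
    expect_equal(bitsFromRaw(100, m),
                 (0.267 * 100 - log(0.041)) / log(2),
                 tolerance = 1e-12)
    expect_equal(bitsFromRaw(100, m), 43.13, tolerance = 1e-2)
    # monotone in the raw score
    s <- seq(10, 500, by = 10)
    expect_false(is.unsorted(bitsFromRaw(s, m)))
})

test_that("a noise-free hit table separates origins by the full margin", {
    tr <- simulateTaxonomy(30, seed = 10)
    gen <- simulateGenome(n_scaffolds = 5, genes_per_scaffold = 6,
                          n_hgt = 4, sequences = FALSE, seed = 10)
    ht <- simulateHitTable(gen, tr, model = scoreModel(noise_sd = 0),
                           margin = 150, seed = 10)
    idx <- hgtIndexScan(ht, tr, screenConfig())$table
    truth <- gen$truth$genes
    hgt <- truth$gene_id[truth$true_origin == "algal_hgt"]
    host <- truth$gene_id[truth$true_origin == "host"]
    expect_true(all(idx$hA_index[idx$gene_id %in% hgt] >= 150))
    expect_true(all(idx$hA_index[idx$gene_id %in% host] <= -150))
})

test_that("read and depth regimes hold their planted structure", {
    sim0 <- simulateReadHits(n_algal = 50, n_control = 50, mu_algal = 0,
                             seed = 11)
    expect_true(all(sim0$counts[sim0$set == "algal", ] == 0))

    gen <- simulateGenome(n_scaffolds = 8, genes_per_scaffold = 3,
                          n_organelle_scaffolds = 3, sequences = FALSE,
                          seed = 11)
    dep0 <- simulateDepths(gen, sd_nuclear = 0, seed = 11)
    truth <- gen$truth$scaffolds
    nuc <- truth$scaffold_id[truth$true_label == "nuclear"]
    expect_true(all(dep0[nuc, ] == 31))
    org <- truth$scaffold_id[truth$true_label == "organelle"]
    ratio <- dep0[org, "klepto_rich"] / dep0[org, "klepto_poor"]
    expect_true(all(ratio >= 2 & ratio <= 4))
})

test_that("planted orthogroup structure drives the expected statistics", {
    sim <- simulateCountsAndDegs(n_orthogroups = 50, seed = 12)
    ex <- expansionZscore(sim$counts, sim$focal_species)
    planted <- sim$truth$orthogroup_id[sim$truth$planted_expanded]
    expect_true(all(ex$expanded[ex$orthogroup_id %in% planted]))
    # the planted enrichment pattern reaches the published significance
    scan <- enrichmentScan(sim$membership, sim$deg, ex)
    expect_lt(scan$p_value[scan$orthogroup_id == planted[1]], 1e-4)
})
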