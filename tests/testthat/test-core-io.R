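# Readers/writers: dialect handling, validation, located errors, round trips.

test_that("hit-table dialects parse the documented column orders", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(paste("g1", "subj1", "95.5", "120", "5", "1", "1", "120",
                     "10", "129", "1e-180", "250", sep = "\t"), f)
    ht <- readHitTable(f, "blast6")
    h <- hitRecords(ht)
    expect_equal(h$bit_score, 250)
    expect_equal(h$e_value, 1e-180)  # no underflow to 0
    expect_identical(h$query_id, "g1")
    expect_true(is.na(h$query_length))

    # qlen + staxid extension
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(paste("g1", "subj1", "95.5", "120", "5", "1", "1", "120",
                     "10", "129", "1e-50", "250", "300", "tax9",
                     sep = "\t"), f2)
    h2 <- hitRecords(readHitTable(f2, "blast6_qlen_staxid"))
    expect_equal(h2$query_length, 300)
    expect_identical(h2$subject_taxon_id, "tax9")

    # lengths companion populates query_length for plain blast6
    h3 <- hitRecords(readHitTable(f, "blast6", lengths = c(g1 = 321)))
    expect_equal(h3$query_length, 321)
})

test_that("empty and malformed hit tables are handled explicitly", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(character(0), f)
    expect_length(readHitTable(f, "blast6"), 0L)

    writeLines(c(paste(rep("x", 12), collapse = "\t"),
                 paste(rep("y", 11), collapse = "\t")), f)
    expect_error(readHitTable(f, "blast6"), "line 2")
    writeLines(paste("g1", "s1", "95", "120", "5", "1", "1", "120",
                     "10", "129", "notanumber", "250", sep = "\t"), f)
    expect_error(readHitTable(f, "blast6"), "line 1.*e_value")
})

test_that("hit tables round-trip bit-exactly via the interchange format", {
    set.seed(11)
    n <- 25
    ht <- HitTable(data.frame(
        query_id = sample(sprintf("g%d", 1:5), n, TRUE),
        subject_id = sprintf("s%d", 1:n),
        subject_taxon_id = sprintf("t%d", 1:n),
        percent_identity = round(runif(n, 10, 100), 3),
        alignment_length = sample(30:500, n),
        bit_score = round(runif(n, 0, 900), 4),
        e_value = 10^-runif(n, 0, 180),
        query_start = 1L, query_end = sample(30:300, n),
        query_length = sample(100:400, n),
        raw_score = round(runif(n, 10, 2000), 3)))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeHitTable(ht, f)
    back <- hitRecords(readHitTable(f, "kleptoscreen"))
    orig <- hitRecords(ht)
    for (col in names(orig)) {
        if (is.numeric(orig[[col]]))
            expect_equal(back[[col]], orig[[col]], tolerance = 1e-12)
        else expect_identical(back[[col]], orig[[col]])
    }
})

test_that("taxonomy reader validates structure and round-trips", {
    tr <- fixedTaxonomy()
    f <- withr::local_tempfile(fileext = ".tsv")
    writeTaxonomy(tr, f)
    back <- readTaxonomy(f)
    expect_identical(back@nodes, tr@nodes)
    expect_identical(lapply(back@groups[names(tr@groups)], sort),
                     lapply(tr@groups, sort))

    # self-parent cycle
    bad <- tr@nodes
    bad$parent_id[bad$taxon_id == "b1"] <- "b1"
    expect_error(TaxonomyTree(bad, tr@groups), "cycle")
    # orphan
    bad2 <- tr@nodes
    bad2$parent_id[bad2$taxon_id == "b1"] <- "nowhere"
    expect_error(TaxonomyTree(bad2, tr@groups), "orphan")
    # overlapping donor/host groups
    g <- tr@groups
    g$algae <- c(g$algae, "m1")
    expect_error(TaxonomyTree(tr@nodes, g), "disjoint")
    # two roots
    bad3 <- rbind(tr@nodes,
                  data.frame(taxon_id = "root2", parent_id = NA,
                             name = "root2"))
    expect_error(TaxonomyTree(bad3, tr@groups), "one root")
})

test_that("every node of a random taxonomy walks up to the root", {
    tr <- simulateTaxonomy(50, seed = 7)
    r <- rootTaxon(tr)
    for (t in taxonIds(tr)) {
        p <- ancestorPath(tr, t)
        expect_identical(p[length(p)], r)
    }
})

test_that("GFF3 gene models and FASTA scaffolds read correctly", {
    f <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "scf1\tsrc\tgene\t100\t400\t.\t+\t.\tID=geneA",
                 "scf1\tsrc\texon\t100\t200\t.\t+\t.\tID=x1",
                 "scf2\tsrc\tgene\t5\t10\t.\t-\t.\tID=geneB"), f)
    cat <- readGffGenes(f)
    gm <- geneModels(cat)
    expect_length(cat, 2L)                     # exon row dropped
    expect_equal(GenomicRanges::width(gm)[gm$gene_id == "geneA"], 301)
    expect_identical(unname(geneScaffolds(cat)[["geneB"]]), "scf2")

    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">scf1 description", "ACGTACGT", ">scf2", "ACGTA"), fa)
    ss <- readFastaScaffolds(fa)
    expect_equal(scaffoldInfo(ss)$length, c(8L, 5L))
    expect_identical(scaffoldInfo(ss)$scaffold_id, c("scf1", "scf2"))
})

test_that("depth, count-matrix and DEG tables validate and round-trip", {
    dep <- matrix(c(31.5, 540.25, 30, 1100.1), 2, 2,
                  dimnames = list(c("s1", "s2"), c("libA", "libB")))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeDepthTable(dep, f)
    expect_equal(readDepthTable(f)[rownames(dep), colnames(dep)], dep)

    m <- matrix(c(203L, 5L, 0L, 4L, 2L, 2L), 2, 3,
                dimnames = list(c("OG1", "OG2"), c("PoB", "Ema", "Aca")))
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeCountMatrix(m, f2)
    expect_identical(readCountMatrix(f2), m)
    writeLines(c("orthogroup_id\tA\tB", "OG1\t2\t3.5"), f2)
    expect_error(readCountMatrix(f2), "non-negative integer")

    deg <- data.frame(gene_id = c("g1", "g2"),
                      log2_fold_change = c(2.5, -0.1),
                      fdr = c(0.001, 0.8), direction = c("up", "ns"))
    f3 <- withr::local_tempfile(fileext = ".tsv")
    writeDegTable(deg, f3)
    expect_equal(readDegTable(f3), deg, tolerance = 1e-12)
    deg$fdr[1] <- 0.5  # labelled up but above the cutoff
    writeDegTable(deg, f3)
    expect_error(readDegTable(f3), "cutoff")
})

test_that("screen config merges defaults, validates, and loads from file", {
    cfg <- screenConfig()
    expect_equal(cfg@lca$min_score, 50)
    expect_equal(cfg@lca$top_percent, 20)
    expect_equal(cfg@align_screen$min_query_coverage, 0.60)
    expect_equal(cfg@decontam$organelle_min_bitscore, 1000)
    cfg2 <- screenConfig(hgt_index = list(threshold = 150))
    expect_equal(cfg2@hgt_index$threshold, 150)
    expect_equal(cfg2@hgt_index$missing_group_bits, 0)
    expect_error(screenConfig(lca = list(bogus = 1)), "unknown")
    expect_error(screenConfig(lca = list(top_percent = 0)), "top_percent")

    f <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("lca:", "  min_score: 60", "expansion:",
                 "  z_threshold: 3"), f)
    cfg3 <- readScreenConfig(f)
    expect_equal(cfg3@lca$min_score, 60)
    expect_equal(cfg3@expansion$z_threshold, 3)
    expect_equal(cfg3@lca$max_expected, 1e-4)
})

test_that("hit table validity rejects inconsistent records", {
    expect_error(mkHits(bits = -5), "bit_score")
    expect_error(mkHits(qstart = 10, qend = 5), "query_start")
    expect_error(mkHits(evalue = -1), "e_value")
})
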