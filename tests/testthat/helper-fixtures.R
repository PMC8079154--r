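# Shared fixtures and independent oracles for the test suite.

# minimal hit-table builder with sensible filler for the unexercised fields
mkHits <- function(query_id = "g1", subject_id = NULL, taxon = NA,
                   bits = 100, evalue = 1e-30, qstart = 1, qend = 100,
                   qlen = NA, alen = 100, raw = NA, pident = 80) {
    n <- max(lengths(list(query_id, bits, evalue, taxon, qstart, qend,
                          qlen, alen, raw, pident)))
    if (is.null(subject_id)) subject_id <- sprintf("s%02d", seq_len(n))
    HitTable(data.frame(
        query_id = rep_len(query_id, n),
        subject_id = rep_len(subject_id, n),
        subject_taxon_id = rep_len(taxon, n),
        percent_identity = rep_len(pident, n),
        alignment_length = rep_len(alen, n),
        bit_score = rep_len(bits, n),
        e_value = rep_len(evalue, n),
        query_start = rep_len(qstart, n),
        query_end = rep_len(qend, n),
        query_length = rep_len(qlen, n),
        raw_score = rep_len(raw, n)))
}

# a small fixed taxonomy: root -> (Bacteria -> b1,b2; Eukaryota ->
# (Algae -> a1,a2; Lophotrochozoa -> Mollusca -> m1,m2; Other -> o1))
fixedTaxonomy <- function() {
    nodes <- data.frame(
        taxon_id = c("root", "Bacteria", "b1", "b2", "Eukaryota",
                     "Algae", "a1", "a2", "Lophotrochozoa", "Mollusca",
                     "m1", "m2", "Other", "o1"),
        parent_id = c(NA, "root", "Bacteria", "Bacteria", "root",
                      "Eukaryota", "Algae", "Algae", "Eukaryota",
                      "Lophotrochozoa", "Mollusca", "Mollusca",
                      "Eukaryota", "Other"),
        name = NA)
    nodes$name <- nodes$taxon_id
    TaxonomyTree(nodes, list(
        prokaryote = c("Bacteria", "b1", "b2"),
        eukaryote = c("Eukaryota", "Algae", "a1", "a2",
                      "Lophotrochozoa", "Mollusca", "m1", "m2",
                      "Other", "o1"),
        algae = c("Algae", "a1", "a2"),
        lophotrochozoa = c("Lophotrochozoa", "Mollusca", "m1", "m2")))
}

# brute-force retention oracle: Min Score / Max Expected filters, then
# the top-percent band around the best surviving bit score
oracleRetain <- function(bits, evalue, cfg) {
    keep <- bits >= cfg@lca$min_score & evalue <= cfg@lca$max_expected
    if (!any(keep)) return(logical(length(bits)))
    keep & bits >= (1 - cfg@lca$top_percent / 100) * max(bits[keep])
}

# exhaustive LCA oracle: scan EVERY tree node for the deepest one whose
# subtree holds >= pct of the unique hit taxa; ties resolved to their LCA
oracleLca <- function(tree, taxa, pct) {
    taxa <- unique(taxa)
    ids <- taxonIds(tree)
    support <- vapply(ids, function(node)
        mean(taxa %in% subtreeTaxa(tree, node)), numeric(1))
    qual <- ids[support >= pct / 100]
    depth <- taxonDepth(tree, qual)
    deepest <- qual[depth == max(depth)]
    if (length(deepest) == 1L) deepest else lcaTaxon(tree, deepest)
}

# Fisher oracle: enumerate every 2x2 table with the observed margins,
# computing point probabilities from first principles (choose(), no
# dhyper), and sum those no likelier than the observed table
oracleFisherTwoSided <- function(k, n_group, K, N) {
    kk <- max(0, n_group - (N - K)):min(n_group, K)
    prob <- vapply(kk, function(x)
        choose(K, x) * choose(N - K, n_group - x) / choose(N, n_group),
        numeric(1))
    obs <- prob[kk == k]
    min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# closed-form OLS slope oracle
oracleSlope <- function(x, y) sum((x - mean(x)) * (y - mean(y))) /
    sum((x - mean(x))^2)
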