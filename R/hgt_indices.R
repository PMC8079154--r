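# Bit-score HGT indices. The h-index is the difference in bit scores
# between a gene's best prokaryote and best eukaryote matches; the hA-index
# is the algal variant, the difference between the best algae and best
# lophotrochozoan matches. Both are computed donor-minus-host, so a large
# positive value points away from the host lineage; candidacy uses the
# conventional |100|-bit threshold. A group without any hit contributes
# `missing_group_bits` (default 0), the usual alien-index convention, so a
# gene with only algal hits gets a large positive hA. Indices are computed
# from the raw hit table: no LCA retention filter is applied first.

.bestGroupBits <- function(h, tree, groups_needed) {
    groups <- taxonGroups(tree)
    taxa <- h$subject_taxon_id
    if (nrow(h)) {
        if (anyNA(taxa))
            stop("hit(s) without a subject taxon; indices need resolvable taxa")
        unknown <- setdiff(taxa, taxonIds(tree))
        if (length(unknown))
            stop(sprintf("hit taxon '%s' absent from the taxonomy tree",
                         unknown[1L]))
    }
    vapply(groups_needed, function(g) {
        b <- h$bit_score[taxa %in% groups[[g]]]
        if (length(b)) max(b) else NA_real_
    }, numeric(1))
}

#' HGT indices of one gene
#'
#' @param hits a [HitTable-class] whose rows all share one `query_id`.
#' @param tree a [TaxonomyTree-class] supplying the four group sets.
#' @param cfg a [ScreenConfig-class]; `hgt_index$threshold` sets candidacy
#'   (index `>=` threshold after applying `hgt_index$sign`), and
#'   `hgt_index$missing_group_bits` is the bit score substituted for a group
#'   with no hit.
#' @return a one-row `data.frame`: `gene_id`, the four per-group best bit
#'   scores (`bits_prokaryote`, `bits_eukaryote`, `bits_algae`,
#'   `bits_lophotrochozoa`), `h_index`, `hA_index`, `h_candidate`,
#'   `hA_candidate`, `no_hits`.
#' @export
#' @examples
#' cfg <- screenConfig()
#' tr <- simulateTaxonomy(12, seed = 1)
#' alg <- taxonGroups(tr)$algae[1]
#' lop <- taxonGroups(tr)$lophotrochozoa[1]
#' h <- HitTable(data.frame(query_id = "g", subject_id = c("s1", "s2"),
#'                          subject_taxon_id = c(alg, lop),
#'                          percent_identity = 60, alignment_length = 150,
#'                          bit_score = c(300, 150), e_value = 1e-30,
#'                          query_start = 1, query_end = 150))
#' computeHgtIndices(h, tr, cfg)$hA_index  # 150: algal candidate
computeHgtIndices <- function(hits, tree, cfg = screenConfig()) {
    h <- hitRecords(hits)
    qid <- unique(h$query_id)
    if (length(qid) > 1L)
        stop("computeHgtIndices expects hits of a single query")
    if (length(qid) == 0L) qid <- NA_character_
    p <- cfg@hgt_index
    best <- .bestGroupBits(h, tree, c("prokaryote", "eukaryote", "algae",
                                      "lophotrochozoa"))
    filled <- ifelse(is.na(best), p$missing_group_bits, best)
    h_index <- p$sign * (filled[["prokaryote"]] - filled[["eukaryote"]])
    hA_index <- p$sign * (filled[["algae"]] - filled[["lophotrochozoa"]])
    data.frame(gene_id = qid,
               bits_prokaryote = filled[["prokaryote"]],
               bits_eukaryote = filled[["eukaryote"]],
               bits_algae = filled[["algae"]],
               bits_lophotrochozoa = filled[["lophotrochozoa"]],
               h_index = h_index, hA_index = hA_index,
               h_candidate = h_index >= p$threshold,
               hA_candidate = hA_index >= p$threshold,
               no_hits = nrow(h) == 0L)
}

#' HGT-index scan over a whole hit table
#'
#' Computes [computeHgtIndices()] for every query of the table. Genes listed
#' in `all_genes` but absent from the table are reported with both indices 0
#' and flagged `no_hits` (they can never be candidates at a positive
#' threshold).
#'
#' @param hits a [HitTable-class] covering one or more queries.
#' @param tree a [TaxonomyTree-class].
#' @param cfg a [ScreenConfig-class].
#' @param all_genes optional character vector of gene ids the scan must
#'   report even without hits.
#' @return a list with `table` (one row per gene, ordered by gene id) and
#'   `candidates` (the rows with `hA_candidate`, sorted by `hA_index`
#'   decreasing).
#' @export
hgtIndexScan <- function(hits, tree, cfg = screenConfig(),
                         all_genes = NULL) {
    h <- hitRecords(hits)
    rows <- lapply(split(h, h$query_id), function(hh)
        computeHgtIndices(HitTable(hh), tree, cfg))
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    zero_hit <- setdiff(all_genes, h$query_id)
    if (length(zero_hit)) {
        mgb <- cfg@hgt_index$missing_group_bits
        empty <- data.frame(gene_id = zero_hit, bits_prokaryote = mgb,
                            bits_eukaryote = mgb, bits_algae = mgb,
                            bits_lophotrochozoa = mgb, h_index = 0,
                            hA_index = 0,
                            h_candidate = 0 >= cfg@hgt_index$threshold,
                            hA_candidate = 0 >= cfg@hgt_index$threshold,
                            no_hits = TRUE)
        tab <- if (is.null(tab)) empty else rbind(tab, empty)
    }
    if (is.null(tab)) stop("hit table covers no gene")
    tab <- tab[order(tab$gene_id), , drop = FALSE]
    rownames(tab) <- NULL
    cand <- tab[tab$hA_candidate, , drop = FALSE]
    cand <- cand[order(-cand$hA_index), , drop = FALSE]
    rownames(cand) <- NULL
    list(table = tab, candidates = cand)
}
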