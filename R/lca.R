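# MEGAN-style lowest-common-ancestor assignment of gene origins from
# homology hit tables, with the retention parameters of the published
# screen: Min Score 50, Max Expected 1e-4, Top Percent 20, Min Support
# Percent 0.1, Min Support 1, LCA percent 90.

#' Retain hits for LCA assignment
#'
#' Applies the three retention filters, per query: bit score >= `min_score`,
#' E-value <= `max_expected`, and bit score within `top_percent` percent of
#' the best bit score among the hits surviving the first two filters
#' (i.e. `bit_score >= (1 - top_percent/100) * best`).
#'
#' @param hits a [HitTable-class]; may span several queries (filters are
#'   applied within each query independently).
#' @param cfg a [ScreenConfig-class].
#' @return a [HitTable-class] of the retained hits.
#' @export
#' @examples
#' h <- HitTable(data.frame(query_id = "g", subject_id = c("a", "b", "c"),
#'                          percent_identity = 80, alignment_length = 100,
#'                          bit_score = c(200, 190, 90), e_value = 1e-30,
#'                          query_start = 1, query_end = 100))
#' length(retainHits(h, screenConfig()))  # 2: cutoff is 0.8 * 200 = 160
retainHits <- function(hits, cfg = screenConfig()) {
    h <- hitRecords(hits)
    if (!nrow(h)) return(hits)
    p <- cfg@lca
    keep <- h$bit_score >= p$min_score & h$e_value <= p$max_expected
    h <- h[keep, , drop = FALSE]
    if (!nrow(h)) return(HitTable(h))
    best <- tapply(h$bit_score, h$query_id, max)
    cut <- (1 - p$top_percent / 100) * best[h$query_id]
    HitTable(h[h$bit_score >= cut, , drop = FALSE])
}

# support of every candidate node: fraction of the unique hit taxa whose
# ancestor path passes through the node. Candidate nodes are exactly the
# union of the taxa's ancestor paths (any other node has support 0).
.nodeSupport <- function(tree, taxa) {
    paths <- lapply(taxa, function(t) ancestorPath(tree, t))
    tab <- table(unlist(lapply(paths, unique)))
    data.frame(node = names(tab),
               support = as.vector(tab) / length(taxa),
               stringsAsFactors = FALSE)
}

#' Assign the LCA origin of one query
#'
#' Retains hits with [retainHits()], reduces them to their unique subject
#' taxa (several hits to one taxon count once, so a single subject genome
#' cannot dominate), and assigns the deepest tree node whose subtree
#' contains at least `lca_percent` percent of those taxa. Ties among equally
#' deep qualifying nodes are resolved to their LCA so the result never
#' depends on hit order.
#'
#' @param hits a [HitTable-class] whose rows all share one `query_id`.
#' @param tree a [TaxonomyTree-class]; every retained hit taxon must be a
#'   node of the tree (an unknown taxon is an error naming it).
#' @param cfg a [ScreenConfig-class].
#' @return a one-row `data.frame` with `gene_id`, `assigned_taxon_id`
#'   (`"UNASSIGNED"` when no hit is retained), `n_hits_retained` and
#'   `support_fraction`.
#' @export
assignLca <- function(hits, tree, cfg = screenConfig()) {
    h <- hitRecords(hits)
    qid <- unique(h$query_id)
    if (length(qid) > 1L)
        stop("assignLca expects hits of a single query; got ",
             length(qid))
    if (length(qid) == 0L) qid <- NA_character_
    kept <- hitRecords(retainHits(hits, cfg))
    if (!nrow(kept))
        return(data.frame(gene_id = qid,
                          assigned_taxon_id = "UNASSIGNED",
                          n_hits_retained = 0L, support_fraction = 0))
    taxa <- kept$subject_taxon_id
    if (anyNA(taxa))
        stop(sprintf("query '%s': retained hit(s) without a subject taxon",
                     qid))
    unknown <- setdiff(taxa, taxonIds(tree))
    if (length(unknown))
        stop(sprintf("hit taxon '%s' absent from the taxonomy tree",
                     unknown[1L]))
    taxa <- unique(taxa)
    sup <- .nodeSupport(tree, taxa)
    qual <- sup[sup$support >= cfg@lca$lca_percent / 100, , drop = FALSE]
    # the root always has support 1 >= any valid lca_percent
    depth <- taxonDepth(tree, qual$node)
    deepest <- qual$node[depth == max(depth)]
    node <- if (length(deepest) == 1L) deepest else
        lcaTaxon(tree, deepest)
    support <- sup$support[match(node, sup$node)]
    data.frame(gene_id = qid, assigned_taxon_id = node,
               n_hits_retained = nrow(kept),
               support_fraction = unname(support))
}

#' Assign LCA origins for a whole hit table
#'
#' Splits the table by query, assigns each query with [assignLca()], then
#' applies the run-level minimum-support rule with MEGAN semantics: a node
#' whose assignment tally is below
#' `max(min_support, min_support_percent/100 * n_assigned)` has its queries
#' pushed to its parent, repeatedly, until every occupied node meets the
#' threshold (queries that would pass beyond the root become
#' `UNASSIGNED`).
#'
#' @param hits a [HitTable-class] covering one or more queries.
#' @param tree a [TaxonomyTree-class].
#' @param cfg a [ScreenConfig-class].
#' @param low_complexity optional named logical vector (per query id):
#'   queries marked `TRUE` are treated as too low-complexity to assign and
#'   become `UNASSIGNED`, mirroring a sequence-complexity pre-filter that
#'   this pipeline accepts as an input flag rather than computing. When
#'   absent the filter is logged as skipped.
#' @return a `data.frame` with one row per query: `gene_id`,
#'   `assigned_taxon_id`, `n_hits_retained`, `support_fraction`.
#' @export
lcaScan <- function(hits, tree, cfg = screenConfig(),
                    low_complexity = NULL) {
    h <- hitRecords(hits)
    if (is.null(low_complexity))
        ksLog("no low-complexity flags supplied; complexity filter skipped",
              level = "debug")
    res <- lapply(split(h, h$query_id), function(hh)
        assignLca(HitTable(hh), tree, cfg))
    res <- do.call(rbind, c(res, list(make.row.names = FALSE)))
    if (is.null(res))
        res <- data.frame(gene_id = character(0),
                          assigned_taxon_id = character(0),
                          n_hits_retained = integer(0),
                          support_fraction = numeric(0))
    if (!is.null(low_complexity)) {
        lc <- res$gene_id %in% names(low_complexity)[low_complexity]
        res$assigned_taxon_id[lc] <- "UNASSIGNED"
        res$support_fraction[lc] <- 0
    }
    res <- res[order(res$gene_id), , drop = FALSE]
    rownames(res) <- NULL
    n_assigned <- sum(res$assigned_taxon_id != "UNASSIGNED")
    if (!n_assigned) return(res)
    threshold <- max(cfg@lca$min_support,
                     cfg@lca$min_support_percent / 100 * n_assigned)
    parent <- .parentMap(tree)
    repeat {
        occupied <- res$assigned_taxon_id[
            res$assigned_taxon_id != "UNASSIGNED"]
        tab <- table(occupied)
        weak <- names(tab)[tab < threshold]
        if (!length(weak)) break
        # push the deepest under-supported node up one level
        weak <- weak[order(-taxonDepth(tree, weak))][1L]
        up <- parent[[weak]]
        sel <- res$assigned_taxon_id == weak
        if (is.na(up)) {
            res$assigned_taxon_id[sel] <- "UNASSIGNED"
            res$support_fraction[sel] <- 0
        } else {
            res$assigned_taxon_id[sel] <- up
        }
    }
    res
}

# TRUE iff the taxon is a member of the (explicitly enumerated) group set
.inGroup <- function(taxon, group_set) taxon %in% group_set

#' Per-scaffold gene-content counts
#'
#' Counts, for every scaffold, how many of its genes were assigned to the
#' bacterial (prokaryote) group, to the lophotrochozoan (host) group, and to
#' any other taxon. Unassigned genes count towards none of the three. These
#' counts feed the bacterial-contaminant scaffold rule.
#'
#' @param assignments a `data.frame` from [lcaScan()].
#' @param catalog a [GeneCatalog-class] placing each gene on its scaffold.
#' @param tree a [TaxonomyTree-class] supplying the group sets.
#' @return a `data.frame` with `scaffold_id`, `n_bacterial`,
#'   `n_lophotrochozoan`, `n_other` (one row per scaffold of the catalog).
#' @export
classifyScaffoldGeneContent <- function(assignments, catalog, tree) {
    scf <- geneScaffolds(catalog)
    groups <- taxonGroups(tree)
    a <- assignments
    a$scaffold_id <- unname(scf[a$gene_id])
    if (anyNA(a$scaffold_id))
        stop("assignment(s) for gene(s) absent from the catalog: ",
             paste(utils::head(a$gene_id[is.na(a$scaffold_id)], 3L),
                   collapse = ", "))
    assigned <- a$assigned_taxon_id != "UNASSIGNED"
    a$is_bact <- assigned & a$assigned_taxon_id %in% groups$prokaryote
    a$is_loph <- assigned & a$assigned_taxon_id %in% groups$lophotrochozoa
    a$is_other <- assigned & !a$is_bact & !a$is_loph
    all_scf <- unique(as.character(
        GenomicRanges::seqnames(geneModels(catalog))))
    agg <- function(flag) {
        s <- tapply(flag, a$scaffold_id, sum)
        v <- setNames(integer(length(all_scf)), all_scf)
        v[names(s)] <- as.integer(s)
        v
    }
    data.frame(scaffold_id = all_scf,
               n_bacterial = unname(agg(a$is_bact)),
               n_lophotrochozoan = unname(agg(a$is_loph)),
               n_other = unname(agg(a$is_other)))
}
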