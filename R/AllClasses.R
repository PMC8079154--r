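#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomicRanges GRanges seqnames start end strand mcols
#' @importFrom IRanges IRanges
NULL

# ---------------------------------------------------------------------------
# HitTable
# ---------------------------------------------------------------------------

.HIT_COLUMNS <- c("query_id", "subject_id", "subject_taxon_id",
                  "percent_identity", "alignment_length", "bit_score",
                  "e_value", "query_start", "query_end", "query_length",
                  "raw_score")

#' Homology hit table
#'
#' An S4 container for BLAST-outfmt-6-style homology matches: one row per
#' local alignment between a query (typically a predicted protein of the host
#' genome) and a subject sequence of known taxonomic origin. This is the
#' substrate of the LCA assignment, the HGT indices and the credibility
#' screens.
#'
#' The underlying table always carries the columns `query_id`, `subject_id`,
#' `subject_taxon_id` (may be `NA`), `percent_identity`, `alignment_length`,
#' `bit_score`, `e_value`, `query_start`, `query_end`, `query_length` (may be
#' `NA`), and `raw_score` (may be `NA`; the raw alignment score, i.e. the sum
#' of substitution-matrix scores and gap penalties, used by the normalized
#' alignment-score screen).
#'
#' @slot hits a `data.frame` with the columns listed above.
#' @seealso [readHitTable()], [retainHits()], [computeHgtIndices()]
#' @exportClass HitTable
setClass("HitTable", representation(hits = "data.frame"))

.validHitTable <- function(object) {
    h <- object@hits
    msg <- character()
    missing <- setdiff(.HIT_COLUMNS, names(h))
    if (length(missing))
        return(paste("missing hit columns:", paste(missing, collapse = ", ")))
    if (nrow(h)) {
        if (any(h$bit_score < 0, na.rm = TRUE))
            msg <- c(msg, "bit_score must be >= 0")
        if (any(h$e_value < 0, na.rm = TRUE))
            msg <- c(msg, "e_value must be >= 0")
        if (any(h$alignment_length < 1, na.rm = TRUE))
            msg <- c(msg, "alignment_length must be >= 1")
        bad <- !is.na(h$query_start) & !is.na(h$query_end) &
            h$query_start > h$query_end
        if (any(bad))
            msg <- c(msg, "query_start must be <= query_end")
        pid <- h$percent_identity
        if (any(pid < 0 | pid > 100, na.rm = TRUE))
            msg <- c(msg, "percent_identity must lie in [0, 100]")
    }
    if (length(msg)) msg else TRUE
}
setValidity("HitTable", .validHitTable)

#' Construct a HitTable
#'
#' @param hits a `data.frame` holding (at least) the canonical hit columns;
#'   absent optional columns (`subject_taxon_id`, `query_length`, `raw_score`)
#'   are filled with `NA`.
#' @return a validated [HitTable-class] object.
#' @export
#' @examples
#' HitTable(data.frame(query_id = "g1", subject_id = "s1",
#'                     percent_identity = 90, alignment_length = 100,
#'                     bit_score = 250, e_value = 1e-50,
#'                     query_start = 1, query_end = 100))
HitTable <- function(hits = data.frame()) {
    if (!is.data.frame(hits))
        stop("'hits' must be a data.frame")
    if (nrow(hits) == 0L && ncol(hits) == 0L) {
        hits <- as.data.frame(setNames(
            rep(list(logical(0)), length(.HIT_COLUMNS)), .HIT_COLUMNS))
        hits$query_id <- character(0); hits$subject_id <- character(0)
        hits$subject_taxon_id <- character(0)
        for (num in c("percent_identity", "alignment_length", "bit_score",
                      "e_value", "query_start", "query_end", "query_length",
                      "raw_score"))
            hits[[num]] <- numeric(0)
    }
    for (opt in c("subject_taxon_id", "query_length", "raw_score"))
        if (is.null(hits[[opt]]))
            hits[[opt]] <- if (opt == "subject_taxon_id")
                NA_character_ else NA_real_
    hits <- hits[, .HIT_COLUMNS, drop = FALSE]
    hits$query_id <- as.character(hits$query_id)
    hits$subject_id <- as.character(hits$subject_id)
    hits$subject_taxon_id <- as.character(hits$subject_taxon_id)
    rownames(hits) <- NULL
    new("HitTable", hits = hits)
}

#' @describeIn HitTable-class number of hit records.
#' @param x a `HitTable`.
#' @export
setMethod("length", "HitTable", function(x) nrow(x@hits))

setMethod("show", "HitTable", function(object) {
    h <- object@hits
    cat("HitTable with", nrow(h), "hits over",
        length(unique(h$query_id)), "queries\n")
    if (nrow(h)) {
        utils::head(h, 5L) |> print()
        if (nrow(h) > 5L) cat("...\n")
    }
})

#' Extract the hit records of a HitTable
#'
#' @param x a [HitTable-class].
#' @return the underlying `data.frame` of hit records.
#' @export
hitRecords <- function(x) {
    stopifnot(is(x, "HitTable"))
    x@hits
}

# ---------------------------------------------------------------------------
# TaxonomyTree
# ---------------------------------------------------------------------------

.REQUIRED_GROUPS <- c("prokaryote", "eukaryote", "algae", "lophotrochozoa")

#' Rooted taxonomy with named groups
#'
#' A rooted taxonomic tree stored as a parent-pointer table, plus named taxon
#' groups. Four groups are mandatory for the screens: `prokaryote`,
#' `eukaryote`, `algae` (the candidate HGT donors) and `lophotrochozoa` (the
#' host lineage). Group membership is an explicit set of taxon ids; the
#' simulator populates whole subtrees.
#'
#' @slot nodes a `data.frame` with columns `taxon_id`, `parent_id` (`NA` for
#'   the single root) and `name`.
#' @slot groups named `list` of character vectors of taxon ids.
#' @seealso [readTaxonomy()], [simulateTaxonomy()], [assignLca()]
#' @exportClass TaxonomyTree
setClass("TaxonomyTree",
         representation(nodes = "data.frame", groups = "list"))

.validTaxonomyTree <- function(object) {
    nd <- object@nodes
    if (!all(c("taxon_id", "parent_id", "name") %in% names(nd)))
        return("nodes needs columns taxon_id, parent_id, name")
    if (anyDuplicated(nd$taxon_id))
        return("duplicated taxon_id")
    roots <- nd$taxon_id[is.na(nd$parent_id)]
    if (length(roots) != 1L)
        return(sprintf("tree must have exactly one root (found %d)",
                       length(roots)))
    known <- nd$taxon_id
    nonroot <- nd[!is.na(nd$parent_id), , drop = FALSE]
    orphan <- setdiff(nonroot$parent_id, known)
    if (length(orphan))
        return(paste("orphan parent id(s):", paste(orphan, collapse = ", ")))
    if (any(nonroot$parent_id == nonroot$taxon_id))
        return("node whose parent is itself (cycle)")
    # every path must terminate at the root
    parent <- setNames(nd$parent_id, nd$taxon_id)
    for (tid in known) {
        seen <- character(); cur <- tid
        while (!is.na(parent[[cur]])) {
            if (cur %in% seen)
                return(sprintf("cycle detected at taxon '%s'", tid))
            seen <- c(seen, cur)
            cur <- parent[[cur]]
        }
    }
    g <- object@groups
    missing <- setdiff(.REQUIRED_GROUPS, names(g))
    if (length(missing))
        return(paste("missing group(s):",
                     paste(missing, collapse = ", ")))
    unknown <- setdiff(unique(unlist(g)), known)
    if (length(unknown))
        return(paste("group member(s) not in tree:",
                     paste(unknown, collapse = ", ")))
    if (!all(g$algae %in% g$eukaryote))
        return("algae group must be a subset of eukaryote")
    if (!all(g$lophotrochozoa %in% g$eukaryote))
        return("lophotrochozoa group must be a subset of eukaryote")
    if (length(intersect(g$algae, g$lophotrochozoa)))
        return("algae and lophotrochozoa groups must be disjoint")
    TRUE
}
setValidity("TaxonomyTree", .validTaxonomyTree)

#' Construct a TaxonomyTree
#'
#' @param nodes `data.frame` with columns `taxon_id`, `parent_id`, `name`.
#' @param groups named list of character vectors; must contain the groups
#'   `prokaryote`, `eukaryote`, `algae` and `lophotrochozoa`.
#' @return a validated [TaxonomyTree-class].
#' @export
TaxonomyTree <- function(nodes, groups) {
    nodes$taxon_id <- as.character(nodes$taxon_id)
    nodes$parent_id <- as.character(nodes$parent_id)
    nodes$name <- as.character(nodes$name)
    rownames(nodes) <- NULL
    new("TaxonomyTree", nodes = nodes,
        groups = lapply(groups, as.character))
}

setMethod("show", "TaxonomyTree", function(object) {
    cat("TaxonomyTree with", nrow(object@nodes), "taxa; groups:",
        paste(sprintf("%s(%d)", names(object@groups),
                      lengths(object@groups)), collapse = ", "), "\n")
})

#' @describeIn TaxonomyTree-class number of taxa in the tree.
#' @param x a `TaxonomyTree`.
#' @export
setMethod("length", "TaxonomyTree", function(x) nrow(x@nodes))

#' Taxon ids of a taxonomy tree
#' @param tree a [TaxonomyTree-class].
#' @return character vector of all taxon ids.
#' @export
taxonIds <- function(tree) tree@nodes$taxon_id

#' Named taxon groups of a taxonomy tree
#' @param tree a [TaxonomyTree-class].
#' @return named list of character vectors.
#' @export
taxonGroups <- function(tree) tree@groups

#' Root taxon of a taxonomy tree
#' @param tree a [TaxonomyTree-class].
#' @return the taxon id of the single root.
#' @export
rootTaxon <- function(tree)
    tree@nodes$taxon_id[is.na(tree@nodes$parent_id)]

.parentMap <- function(tree)
    setNames(tree@nodes$parent_id, tree@nodes$taxon_id)

#' Ancestor path of a taxon
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxon a taxon id present in the tree.
#' @return character vector from `taxon` up to (and including) the root.
#' @export
ancestorPath <- function(tree, taxon) {
    parent <- .parentMap(tree)
    if (!taxon %in% names(parent))
        stop(sprintf("taxon '%s' not in tree", taxon))
    path <- taxon
    while (!is.na(parent[[taxon]])) {
        taxon <- parent[[taxon]]
        path <- c(path, taxon)
    }
    path
}

#' Depth of taxa in the tree (root = 0)
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxa taxon ids.
#' @return integer vector of depths.
#' @export
taxonDepth <- function(tree, taxa) {
    vapply(taxa, function(t) length(ancestorPath(tree, t)) - 1L,
           integer(1))
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxa character vector of taxon ids (length >= 1).
#' @return the taxon id of the LCA node.
#' @export
lcaTaxon <- function(tree, taxa) {
    taxa <- unique(taxa)
    stopifnot(length(taxa) >= 1L)
    path <- ancestorPath(tree, taxa[1L])
    for (t in taxa[-1L])
        path <- path[path %in% ancestorPath(tree, t)]
    path[1L]
}

#' Taxa forming the subtree rooted at a node
#'
#' @param tree a [TaxonomyTree-class].
#' @param node a taxon id.
#' @return character vector of all taxa whose ancestor path contains `node`
#'   (including `node` itself).
#' @export
subtreeTaxa <- function(tree, node) {
    ids <- taxonIds(tree)
    ids[vapply(ids, function(t) node %in% ancestorPath(tree, t),
               logical(1))]
}

# ---------------------------------------------------------------------------
# GeneCatalog
# ---------------------------------------------------------------------------

#' Gene models placed on assembly scaffolds
#'
#' Wraps a `GRanges` whose seqnames are scaffold ids and whose metadata
#' columns carry `gene_id` and (optionally, after LCA assignment)
#' `assigned_taxon`. Coordinates follow the Bioconductor 1-based inclusive
#' convention throughout; GFF3 input needs no shifting.
#'
#' @slot genes a `GRanges` with mcols `gene_id` (character) and
#'   `assigned_taxon` (character, `NA` when unassigned).
#' @seealso [readGffGenes()], [simulateGenome()]
#' @exportClass GeneCatalog
setClass("GeneCatalog", representation(genes = "GRanges"))

.validGeneCatalog <- function(object) {
    g <- object@genes
    mc <- names(S4Vectors::mcols(g))
    if (!"gene_id" %in% mc)
        return("genes must carry an mcol 'gene_id'")
    if (anyDuplicated(g$gene_id))
        return("duplicated gene_id")
    TRUE
}
setValidity("GeneCatalog", .validGeneCatalog)

#' Construct a GeneCatalog
#'
#' @param genes a `GRanges` with an mcol `gene_id`; an `assigned_taxon`
#'   mcol is added (all `NA`) when absent.
#' @return a validated [GeneCatalog-class].
#' @export
GeneCatalog <- function(genes) {
    if (is.null(genes$assigned_taxon))
        genes$assigned_taxon <- NA_character_
    new("GeneCatalog", genes = genes)
}

#' @describeIn GeneCatalog-class number of gene models.
#' @param x a `GeneCatalog`.
#' @export
setMethod("length", "GeneCatalog", function(x) length(x@genes))

setMethod("show", "GeneCatalog", function(object) {
    cat("GeneCatalog with", length(object@genes), "genes on",
        length(unique(as.character(
            GenomicRanges::seqnames(object@genes)))), "scaffolds\n")
})

#' Gene models of a GeneCatalog
#' @param x a [GeneCatalog-class].
#' @return the underlying `GRanges`.
#' @export
geneModels <- function(x) {
    stopifnot(is(x, "GeneCatalog"))
    x@genes
}

#' Scaffold id of each gene
#' @param x a [GeneCatalog-class].
#' @return named character vector, gene_id -> scaffold_id.
#' @export
geneScaffolds <- function(x) {
    g <- geneModels(x)
    setNames(as.character(GenomicRanges::seqnames(g)), g$gene_id)
}

# ---------------------------------------------------------------------------
# ScaffoldSet
# ---------------------------------------------------------------------------

#' Assembly scaffolds with per-library read depths
#'
#' Holds the scaffolds of an assembly: id, length, optional sequence
#' (`DNAStringSet`), and a matrix of mean read depths (scaffold x library).
#' This is the substrate of the decontamination rules.
#'
#' @slot info `data.frame` with columns `scaffold_id`, `length`.
#' @slot depths numeric matrix, rownames = scaffold ids, one column per
#'   sequencing library; may have zero columns when no depth data exist.
#' @slot sequences a `DNAStringSet` or `NULL`.
#' @seealso [readFastaScaffolds()], [readDepthTable()], [decontaminate()]
#' @exportClass ScaffoldSet
setClass("ScaffoldSet",
         representation(info = "data.frame", depths = "matrix",
                        sequences = "ANY"))

.validScaffoldSet <- function(object) {
    info <- object@info
    if (!all(c("scaffold_id", "length") %in% names(info)))
        return("info needs columns scaffold_id, length")
    if (anyDuplicated(info$scaffold_id))
        return("duplicated scaffold_id")
    if (nrow(info) && any(info$length < 1))
        return("scaffold length must be >= 1")
    d <- object@depths
    if (nrow(d) && !identical(rownames(d), info$scaffold_id))
        return("depths rownames must equal scaffold ids")
    if (length(d) && any(d < 0, na.rm = TRUE))
        return("depths must be >= 0")
    TRUE
}
setValidity("ScaffoldSet", .validScaffoldSet)

#' Construct a ScaffoldSet
#'
#' @param info `data.frame` with `scaffold_id` and `length`.
#' @param depths optional depth matrix (scaffold x library); defaults to a
#'   zero-column matrix.
#' @param sequences optional `DNAStringSet` named by scaffold id.
#' @return a validated [ScaffoldSet-class].
#' @export
ScaffoldSet <- function(info, depths = NULL, sequences = NULL) {
    info$scaffold_id <- as.character(info$scaffold_id)
    info$length <- as.integer(info$length)
    rownames(info) <- NULL
    if (is.null(depths)) {
        depths <- matrix(numeric(0), nrow = nrow(info), ncol = 0,
                         dimnames = list(info$scaffold_id, NULL))
    } else {
        depths <- as.matrix(depths)
        depths <- depths[info$scaffold_id, , drop = FALSE]
    }
    new("ScaffoldSet", info = info, depths = depths, sequences = sequences)
}

#' @describeIn ScaffoldSet-class number of scaffolds.
#' @param x a `ScaffoldSet`.
#' @export
setMethod("length", "ScaffoldSet", function(x) nrow(x@info))

setMethod("show", "ScaffoldSet", function(object) {
    cat("ScaffoldSet with", nrow(object@info), "scaffolds,",
        ncol(object@depths), "depth librar(ies),",
        if (is.null(object@sequences)) "no" else "with", "sequences\n")
})

#' Scaffold table of a ScaffoldSet
#' @param x a [ScaffoldSet-class].
#' @return `data.frame` of scaffold id and length.
#' @export
scaffoldInfo <- function(x) {
    stopifnot(is(x, "ScaffoldSet"))
    x@info
}

#' Depth matrix of a ScaffoldSet
#' @param x a [ScaffoldSet-class].
#' @return numeric matrix scaffold x library.
#' @export
scaffoldDepths <- function(x) {
    stopifnot(is(x, "ScaffoldSet"))
    x@depths
}

#' Scaffold sequences (possibly NULL)
#' @param x a [ScaffoldSet-class].
#' @return a `DNAStringSet` or `NULL`.
#' @export
scaffoldSequences <- function(x) {
    stopifnot(is(x, "ScaffoldSet"))
    x@sequences
}
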