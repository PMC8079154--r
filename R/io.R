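# Readers and writers for the external tabular formats the screen consumes:
# BLAST-outfmt-6-style hit tables (explicit dialects, never sniffed),
# taxonomy tables, GFF3 gene models, FASTA scaffolds, depth tables,
# orthogroup count matrices and DEG tables. All parsers validate against the
# type invariants and fail with a located error, never a silent skip.

# Column orders per hit-table dialect. outfmt-6 variants differ silently in
# column order, so the dialect is always stated by the caller.
.HIT_DIALECTS <- list(
    blast6 = c("query_id", "subject_id", "percent_identity",
               "alignment_length", "mismatch", "gapopen", "query_start",
               "query_end", "subject_start", "subject_end", "e_value",
               "bit_score"),
    blast6_qlen = c("query_id", "subject_id", "percent_identity",
                    "alignment_length", "mismatch", "gapopen",
                    "query_start", "query_end", "subject_start",
                    "subject_end", "e_value", "bit_score", "query_length"),
    blast6_qlen_staxid = c("query_id", "subject_id", "percent_identity",
                           "alignment_length", "mismatch", "gapopen",
                           "query_start", "query_end", "subject_start",
                           "subject_end", "e_value", "bit_score",
                           "query_length", "subject_taxon_id"),
    mmseq2 = c("query_id", "subject_id", "percent_identity",
               "alignment_length", "mismatch", "gapopen", "query_start",
               "query_end", "subject_start", "subject_end", "e_value",
               "bit_score"),
    # tabular export of a protein-to-genome aligner run (raw alignment score
    # = substitution-matrix scores plus gap penalties)
    exonerate = c("query_id", "subject_id", "query_start", "query_end",
                  "query_length", "alignment_length", "raw_score",
                  "e_value", "bit_score"),
    # the package's own full-width interchange format (round-trippable)
    kleptoscreen = .HIT_COLUMNS
)

.HIT_NUMERIC <- c("percent_identity", "alignment_length", "mismatch",
                  "gapopen", "query_start", "query_end", "subject_start",
                  "subject_end", "e_value", "bit_score", "query_length",
                  "raw_score")

# read a header-less TSV into character columns, checking the column count
# row by row so errors can name the offending line
.readRaggedTsv <- function(path, n_col, what) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines))
        return(matrix(character(0), nrow = 0, ncol = n_col))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != n_col)
    if (length(bad))
        stop(sprintf("%s: line %d has %d field(s), expected %d",
                     what, bad[1L], lengths(parts)[bad[1L]], n_col))
    matrix(unlist(parts), nrow = length(parts), ncol = n_col, byrow = TRUE)
}

.numericOrDie <- function(x, col, what) {
    suppress <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(suppress) & !is.na(x) & x != "NA")
    if (length(bad))
        stop(sprintf("%s: line %d, column '%s': cannot parse '%s' as a number",
                     what, bad[1L], col, x[bad[1L]]))
    suppress
}

#' Read a homology hit table
#'
#' Parses a tab-separated hit table in an explicitly named dialect (column
#' orders of outfmt-6 variants differ silently, so the dialect is never
#' sniffed) and returns a validated [HitTable-class].
#'
#' @param path path to a header-less TSV file.
#' @param dialect one of `"blast6"` (12 canonical columns),
#'   `"blast6_qlen"` (+`qlen`), `"blast6_qlen_staxid"` (+`qlen`, `staxid`),
#'   `"mmseq2"` (12 columns, BLAST-compatible order), `"exonerate"`
#'   (query, target, qstart, qend, qlen, alnlen, rawscore, evalue, bits),
#'   or `"kleptoscreen"` (the package's own full-width interchange format).
#' @param lengths optional named numeric vector (or `Biostrings::DNAStringSet`
#'   / `AAStringSet`, whose widths are used) giving query lengths for
#'   dialects that lack a `qlen` column.
#' @param taxa optional named character vector mapping `subject_id` to a
#'   taxon id, for dialects without a `staxid` column.
#' @return a [HitTable-class]; `query_length` is populated from the column,
#'   `lengths`, or left `NA`.
#' @export
readHitTable <- function(path, dialect = c("blast6", "blast6_qlen",
                                           "blast6_qlen_staxid", "mmseq2",
                                           "exonerate", "kleptoscreen"),
                         lengths = NULL, taxa = NULL) {
    dialect <- match.arg(dialect)
    cols <- .HIT_DIALECTS[[dialect]]
    m <- .readRaggedTsv(path, length(cols), basename(path))
    if (nrow(m) == 0L) return(HitTable())
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- cols
    for (col in intersect(cols, .HIT_NUMERIC))
        df[[col]] <- .numericOrDie(df[[col]], col, basename(path))
    if (is.null(df$percent_identity)) df$percent_identity <- NA_real_
    if (!is.null(lengths)) {
        if (methods::is(lengths, "XStringSet"))
            lengths <- setNames(Biostrings::width(lengths), names(lengths))
        df$query_length <- unname(lengths[df$query_id])
    }
    if (!is.null(taxa))
        df$subject_taxon_id <- unname(taxa[df$subject_id])
    HitTable(df)
}

#' Write a hit table in the package interchange format
#'
#' Emits all canonical columns as a header-less TSV readable back with
#' `readHitTable(path, dialect = "kleptoscreen")`; numbers are written at
#' full precision so a round trip is value-exact.
#'
#' @param x a [HitTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(x, path) {
    h <- hitRecords(x)
    num <- vapply(h, is.numeric, logical(1))
    h[num] <- lapply(h[num], function(v) format(v, digits = 17L,
                                                trim = TRUE,
                                                scientific = TRUE))
    utils::write.table(h, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a taxonomy table
#'
#' Expects a TSV with a header line `taxon_id  parent_id  name  groups`;
#' `parent_id` is empty (or `NA`) for the single root, and `groups` is a
#' `;`-separated list of group names the taxon belongs to (may be empty).
#'
#' @param path path to the TSV file.
#' @return a validated [TaxonomyTree-class].
#' @export
readTaxonomy <- function(path) {
    df <- utils::read.delim(path, colClasses = "character")
    need <- c("taxon_id", "parent_id", "name", "groups")
    if (!all(need %in% names(df)))
        stop("taxonomy table needs columns: ", paste(need, collapse = ", "))
    df$parent_id[df$parent_id %in% c("", "NA", "-")] <- NA_character_
    groups <- list()
    for (i in seq_len(nrow(df))) {
        gs <- strsplit(df$groups[i], ";", fixed = TRUE)[[1L]]
        gs <- gs[nzchar(gs)]
        for (g in gs) groups[[g]] <- c(groups[[g]], df$taxon_id[i])
    }
    for (g in .REQUIRED_GROUPS)
        if (is.null(groups[[g]])) groups[[g]] <- character(0)
    TaxonomyTree(df[, c("taxon_id", "parent_id", "name")], groups)
}

#' Write a taxonomy table
#'
#' Inverse of [readTaxonomy()].
#'
#' @param tree a [TaxonomyTree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTaxonomy <- function(tree, path) {
    nd <- tree@nodes
    gps <- tree@groups
    nd$groups <- vapply(nd$taxon_id, function(t) {
        paste(names(gps)[vapply(gps, function(m) t %in% m, logical(1))],
              collapse = ";")
    }, character(1))
    nd$parent_id[is.na(nd$parent_id)] <- ""
    utils::write.table(nd, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file via `rtracklayer` and keeps rows of type `gene`.
#' Coordinates remain 1-based inclusive (the GFF3 and Bioconductor
#' convention).
#'
#' @param path path to a GFF3 file.
#' @return a [GeneCatalog-class]; `gene_id` is taken from the `ID`
#'   attribute.
#' @export
readGffGenes <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    if (!length(gr)) stop("no gene rows in ", path)
    if (is.null(gr$ID) || anyNA(gr$ID))
        stop("every gene row needs an ID attribute: ", path)
    out <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr),
        IRanges::IRanges(GenomicRanges::start(gr),
                         GenomicRanges::end(gr)),
        strand = GenomicRanges::strand(gr))
    out$gene_id <- as.character(gr$ID)
    GeneCatalog(out)
}

#' Write gene models as GFF3
#'
#' @param x a [GeneCatalog-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGffGenes <- function(x, path) {
    gr <- geneModels(x)
    gr$type <- "gene"
    gr$ID <- gr$gene_id
    gr$source <- "kleptoscreen"
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Read assembly scaffolds from FASTA
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @param depths optional depth matrix or [readDepthTable()] result to
#'   attach.
#' @return a [ScaffoldSet-class] with sequences and lengths.
#' @export
readFastaScaffolds <- function(path, depths = NULL) {
    seqs <- Biostrings::readDNAStringSet(path)
    if (!length(seqs)) stop("no FASTA records in ", path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    info <- data.frame(scaffold_id = names(seqs),
                       length = Biostrings::width(seqs))
    ScaffoldSet(info, depths = depths, sequences = seqs)
}

#' Write scaffold sequences as FASTA
#'
#' @param x a [ScaffoldSet-class] carrying sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastaScaffolds <- function(x, path) {
    seqs <- scaffoldSequences(x)
    if (is.null(seqs)) stop("ScaffoldSet carries no sequences")
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Read a per-scaffold per-library depth table
#'
#' Expects a TSV with header `scaffold_id  library_id  depth` (long format).
#'
#' @param path path to the TSV file.
#' @return numeric matrix scaffold x library.
#' @export
readDepthTable <- function(path) {
    df <- utils::read.delim(path, colClasses = c("character", "character",
                                                 "numeric"))
    need <- c("scaffold_id", "library_id", "depth")
    if (!all(need %in% names(df)))
        stop("depth table needs columns: ", paste(need, collapse = ", "))
    if (any(df$depth < 0)) stop("depths must be >= 0: ", path)
    scf <- unique(df$scaffold_id); lib <- unique(df$library_id)
    m <- matrix(NA_real_, length(scf), length(lib),
                dimnames = list(scf, lib))
    m[cbind(df$scaffold_id, df$library_id)] <- df$depth
    m
}

#' Write a depth matrix as a long-format TSV
#'
#' Inverse of [readDepthTable()].
#'
#' @param depths numeric matrix scaffold x library.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDepthTable <- function(depths, path) {
    df <- data.frame(
        scaffold_id = rep(rownames(depths), times = ncol(depths)),
        library_id = rep(colnames(depths), each = nrow(depths)),
        depth = as.vector(depths))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read an orthogroup x species gene-count matrix
#'
#' Expects a TSV whose first column is `orthogroup_id` and whose remaining
#' columns are species; every cell must be a non-negative integer.
#'
#' @param path path to the TSV file.
#' @return integer matrix, rownames = orthogroup ids.
#' @export
readCountMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    if (names(df)[1L] != "orthogroup_id")
        stop("first column must be 'orthogroup_id': ", path)
    og <- df[[1L]]
    m <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(as.numeric(m))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad)) {
        r <- (bad[1L] - 1L) %% nrow(m) + 1L
        c <- (bad[1L] - 1L) %/% nrow(m) + 1L
        stop(sprintf(
            "%s: row %d ('%s'), species '%s': '%s' is not a non-negative integer count",
            basename(path), r, og[r], colnames(m)[c], m[bad[1L]]))
    }
    out <- matrix(as.integer(num), nrow(m), ncol(m),
                  dimnames = list(og, colnames(m)))
    out
}

#' Write an orthogroup count matrix
#'
#' Inverse of [readCountMatrix()].
#'
#' @param m integer matrix with orthogroup rownames and species colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(m, path) {
    df <- data.frame(orthogroup_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a differential-expression table
#'
#' Expects a TSV with header `gene_id  log2_fold_change  fdr  direction`;
#' `direction` must be one of `up`, `down`, `ns`.
#'
#' @param path path to the TSV file.
#' @param fdr_cutoff the FDR threshold under which `up`/`down` labels were
#'   called (default 0.01); rows labelled `up`/`down` with `fdr` at or above
#'   it raise an error.
#' @return `data.frame` with the four columns.
#' @export
readDegTable <- function(path, fdr_cutoff = 0.01) {
    df <- utils::read.delim(path, colClasses = c("character", "numeric",
                                                 "numeric", "character"))
    need <- c("gene_id", "log2_fold_change", "fdr", "direction")
    if (!all(need %in% names(df)))
        stop("DEG table needs columns: ", paste(need, collapse = ", "))
    if (any(!df$direction %in% c("up", "down", "ns")))
        stop("direction must be up/down/ns: ", path)
    if (any(df$fdr < 0 | df$fdr > 1))
        stop("fdr must lie in [0, 1]: ", path)
    bad <- df$direction %in% c("up", "down") & df$fdr >= fdr_cutoff
    if (any(bad))
        stop(sprintf("%s: gene '%s' labelled '%s' but fdr %.3g >= cutoff %.3g",
                     basename(path), df$gene_id[which(bad)[1L]],
                     df$direction[which(bad)[1L]],
                     df$fdr[which(bad)[1L]], fdr_cutoff))
    df[, need]
}

#' Write a differential-expression table
#'
#' Inverse of [readDegTable()].
#'
#' @param deg a DEG `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDegTable <- function(deg, path) {
    num <- vapply(deg, is.numeric, logical(1))
    deg[num] <- lapply(deg[num], function(v) format(v, digits = 17L,
                                                    trim = TRUE))
    utils::write.table(deg, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
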