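# Scaffold decontamination. Bacterial contaminant scaffolds encode two or
# more bacterial genes and no lophotrochozoan gene. Organelle-derived
# scaffolds match an organelle reference with bit score > 1000 and show a
# coverage depth far above the nuclear mean (the published screen saw
# organelle depths of 537-5143x against a nuclear mean of 31x, and a
# 2-4 fold depth increase in the kleptoplast-rich tissue library).
# Removal is deliberately conservative: ambiguous scaffolds are retained
# and reported so no horizontally transferred gene is discarded.

#' Bacterial-contaminant rule
#'
#' A scaffold is a bacterial contaminant iff it carries at least
#' `decontam$min_bacterial_genes` (default 2) bacterial genes and at most
#' `decontam$max_loph_genes` (default 0) lophotrochozoan genes. A single
#' host-assigned gene always rescues the scaffold.
#'
#' @param n_bacterial,n_lophotrochozoan integer vectors of per-scaffold
#'   gene-content counts (see [classifyScaffoldGeneContent()]).
#' @param cfg a [ScreenConfig-class].
#' @return logical vector.
#' @export
#' @examples
#' classifyBacterial(c(2, 2, 1), c(0, 1, 0))  # TRUE FALSE FALSE
classifyBacterial <- function(n_bacterial, n_lophotrochozoan,
                              cfg = screenConfig()) {
    p <- cfg@decontam
    n_bacterial >= p$min_bacterial_genes &
        n_lophotrochozoan <= p$max_loph_genes
}

#' Organelle-scaffold rule
#'
#' Two-pass classification: scaffolds whose best bit score against any
#' organelle reference strictly exceeds `organelle_min_bitscore` (default
#' 1000) are bit-flagged; the nuclear mean depth is then computed over the
#' remaining scaffolds only (so organelle depths cannot inflate the
#' baseline), and a bit-flagged scaffold is `organelle` when its mean depth
#' is at least `organelle_min_depth_fold` times that nuclear mean,
#' `ambiguous` when it is not. Without depth data the rule degrades to
#' bit-score-only with a logged warning.
#'
#' @param scaffolds a [ScaffoldSet-class] (its depth matrix is used).
#' @param organelle_hits a [HitTable-class] of scaffold-vs-organelle-
#'   reference matches (`query_id` = scaffold id).
#' @param cfg a [ScreenConfig-class].
#' @return a `data.frame` with one row per scaffold: `scaffold_id`,
#'   `best_organelle_bitscore`, `mean_depth`, `depth_fold_vs_nuclear_mean`,
#'   `organelle_call` in `{organelle, ambiguous, no}`.
#' @export
classifyOrganelle <- function(scaffolds, organelle_hits,
                              cfg = screenConfig()) {
    p <- cfg@decontam
    info <- scaffoldInfo(scaffolds)
    h <- hitRecords(organelle_hits)
    best <- tapply(h$bit_score, h$query_id, max)
    bits <- setNames(numeric(nrow(info)), info$scaffold_id)
    bits[names(best)] <- best
    bit_flag <- bits > p$organelle_min_bitscore
    depths <- scaffoldDepths(scaffolds)
    if (ncol(depths) == 0L) {
        ksLog("no depth data: organelle rule is bit-score-only",
              level = "warn")
        call <- ifelse(bit_flag, "organelle", "no")
        return(data.frame(scaffold_id = info$scaffold_id,
                          best_organelle_bitscore = unname(bits),
                          mean_depth = NA_real_,
                          depth_fold_vs_nuclear_mean = NA_real_,
                          organelle_call = call))
    }
    mean_depth <- rowMeans(depths, na.rm = TRUE)
    nuclear_mean <- mean(mean_depth[!bit_flag])
    fold <- mean_depth / nuclear_mean
    call <- ifelse(!bit_flag, "no",
                   ifelse(fold >= p$organelle_min_depth_fold,
                          "organelle", "ambiguous"))
    data.frame(scaffold_id = info$scaffold_id,
               best_organelle_bitscore = unname(bits),
               mean_depth = unname(mean_depth),
               depth_fold_vs_nuclear_mean = unname(fold),
               organelle_call = unname(call))
}

#' Tissue depth-ratio corroboration
#'
#' Checks whether a scaffold's coverage depth rises by two- to four-fold in
#' the kleptoplast-rich library relative to the kleptoplast-poor library —
#' the signature of kleptoplast DNA. Library depths are median-normalized
#' before the ratio because raw library sizes differ; the interval
#' `[tissue_ratio_min, tissue_ratio_max]` is closed.
#'
#' @param depths numeric depth matrix (scaffold x library).
#' @param rich_lib,poor_lib column names of the kleptoplast-rich and
#'   kleptoplast-poor libraries.
#' @param cfg a [ScreenConfig-class].
#' @return a `data.frame` with `scaffold_id`, `normalized_ratio`,
#'   `consistent_with_kleptoplast` (`NA` where the denominator is zero).
#' @export
tissueRatioCheck <- function(depths, rich_lib, poor_lib,
                             cfg = screenConfig()) {
    p <- cfg@decontam
    if (!all(c(rich_lib, poor_lib) %in% colnames(depths)))
        stop("depth matrix lacks the requested libraries")
    rich <- depths[, rich_lib] / stats::median(depths[, rich_lib])
    poor <- depths[, poor_lib] / stats::median(depths[, poor_lib])
    ratio <- ifelse(poor > 0, rich / poor, NA_real_)
    data.frame(scaffold_id = rownames(depths),
               normalized_ratio = unname(ratio),
               consistent_with_kleptoplast =
                   ratio >= p$tissue_ratio_min & ratio <= p$tissue_ratio_max)
}

#' Full per-scaffold verdicts
#'
#' Combines the gene-content and organelle rules into one label per
#' scaffold: `bacterial_contaminant`, `organelle`, `ambiguous`
#' (organelle-like bit score without the depth corroboration), or
#' `nuclear`. When the two tissue libraries are named, the tissue ratio is
#' attached as a corroboration flag (it never gates the label).
#'
#' @param scaffolds a [ScaffoldSet-class].
#' @param gene_content a `data.frame` from [classifyScaffoldGeneContent()];
#'   scaffolds without gene models count zero everywhere.
#' @param organelle_hits a [HitTable-class] of scaffold-vs-organelle
#'   matches.
#' @param cfg a [ScreenConfig-class].
#' @param rich_lib,poor_lib optional library column names for
#'   [tissueRatioCheck()].
#' @return a `data.frame` with one row per scaffold: `scaffold_id`,
#'   `label`, the evidence columns of both rules, and (when requested)
#'   `tissue_depth_ratio` + `consistent_with_kleptoplast`.
#' @export
classifyScaffolds <- function(scaffolds, gene_content, organelle_hits,
                              cfg = screenConfig(), rich_lib = NULL,
                              poor_lib = NULL) {
    info <- scaffoldInfo(scaffolds)
    gc <- gene_content[match(info$scaffold_id, gene_content$scaffold_id), ,
                       drop = FALSE]
    gc$n_bacterial[is.na(gc$n_bacterial)] <- 0L
    gc$n_lophotrochozoan[is.na(gc$n_lophotrochozoan)] <- 0L
    bact <- classifyBacterial(gc$n_bacterial, gc$n_lophotrochozoan, cfg)
    org <- classifyOrganelle(scaffolds, organelle_hits, cfg)
    label <- ifelse(bact, "bacterial_contaminant",
                    ifelse(org$organelle_call == "organelle", "organelle",
                           ifelse(org$organelle_call == "ambiguous",
                                  "ambiguous", "nuclear")))
    out <- data.frame(scaffold_id = info$scaffold_id, label = label,
                      n_bacterial_genes = gc$n_bacterial,
                      n_loph_genes = gc$n_lophotrochozoan,
                      best_organelle_bitscore = org$best_organelle_bitscore,
                      depth_fold_vs_nuclear_mean =
                          org$depth_fold_vs_nuclear_mean)
    if (!is.null(rich_lib) && !is.null(poor_lib)) {
        tr <- tissueRatioCheck(scaffoldDepths(scaffolds), rich_lib,
                               poor_lib, cfg)
        out$tissue_depth_ratio <-
            tr$normalized_ratio[match(out$scaffold_id, tr$scaffold_id)]
        out$consistent_with_kleptoplast <-
            tr$consistent_with_kleptoplast[match(out$scaffold_id,
                                                 tr$scaffold_id)]
    }
    out
}

.subsetScaffoldSet <- function(x, ids) {
    info <- scaffoldInfo(x)
    keep <- info$scaffold_id %in% ids
    seqs <- scaffoldSequences(x)
    ScaffoldSet(info[keep, , drop = FALSE],
                depths = scaffoldDepths(x)[keep, , drop = FALSE],
                sequences = if (is.null(seqs)) NULL else
                    seqs[info$scaffold_id[keep]])
}

#' Remove contaminant and organelle scaffolds
#'
#' Removes only the scaffolds labelled `bacterial_contaminant` or
#' `organelle`; `ambiguous` scaffolds are retained and listed in the
#' report, keeping the screen conservative.
#'
#' @param scaffolds a [ScaffoldSet-class].
#' @param verdicts a `data.frame` from [classifyScaffolds()].
#' @return a list: `retained` and `removed` ([ScaffoldSet-class]s that
#'   partition the input) and `report` (every removal or ambiguity with its
#'   evidence).
#' @export
decontaminate <- function(scaffolds, verdicts) {
    info <- scaffoldInfo(scaffolds)
    v <- verdicts[match(info$scaffold_id, verdicts$scaffold_id), ,
                  drop = FALSE]
    if (anyNA(v$label))
        stop("verdict missing for scaffold(s): ",
             paste(utils::head(info$scaffold_id[is.na(v$label)], 3L),
                   collapse = ", "))
    drop <- v$label %in% c("bacterial_contaminant", "organelle")
    list(retained = .subsetScaffoldSet(scaffolds,
                                       info$scaffold_id[!drop]),
         removed = .subsetScaffoldSet(scaffolds, info$scaffold_id[drop]),
         report = v[drop | v$label == "ambiguous", , drop = FALSE])
}
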