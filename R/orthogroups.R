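# Orthogroup statistics: lineage-specific gene-family expansion by Z-score
# of the per-species gene counts (expanded at Z > 2), and Fisher exact
# enrichment of up-regulated genes within an orthogroup against the
# genome-wide background.

#' Orthogroup expansion Z-scores
#'
#' For each orthogroup, `z = (count_focal - mean) / sd` where mean and
#' sample SD (n-1 denominator) are taken over the species columns —
#' including the focal species by default (`expansion$include_focal`), the
#' way a per-row heatmap Z-score is ordinarily computed. An orthogroup with
#' zero count variance gets `z = 0` and is never expanded. Expansion is
#' strict: `z > z_threshold`.
#'
#' @param counts integer matrix orthogroup x species (see
#'   [readCountMatrix()]); at least 3 species columns.
#' @param focal_species the species column of interest (error if absent).
#' @param cfg a [ScreenConfig-class].
#' @return a `data.frame` with `orthogroup_id`, `focal_species`, `count`,
#'   `z`, `expanded`.
#' @export
#' @examples
#' m <- rbind(og1 = c(10, 2, 2, 2), og2 = c(3, 3, 3, 3))
#' colnames(m) <- c("focal", "s1", "s2", "s3")
#' expansionZscore(m, "focal")$z  # 1.5, 0
expansionZscore <- function(counts, focal_species, cfg = screenConfig()) {
    if (ncol(counts) < 3L)
        stop("need >= 3 species columns")
    if (!focal_species %in% colnames(counts))
        stop(sprintf("focal species '%s' absent from the count matrix",
                     focal_species))
    p <- cfg@expansion
    bg <- if (p$include_focal) counts else
        counts[, colnames(counts) != focal_species, drop = FALSE]
    mu <- rowMeans(bg)
    sd <- apply(bg, 1L, stats::sd)
    z <- ifelse(sd > 0, (counts[, focal_species] - mu) / sd, 0)
    data.frame(orthogroup_id = rownames(counts),
               focal_species = focal_species,
               count = counts[, focal_species],
               z = unname(z),
               expanded = unname(z > p$z_threshold))
}

#' Fisher exact enrichment of up-regulated genes in an orthogroup
#'
#' Exact hypergeometric test on the 2x2 table
#' (in-group up, in-group not-up; out-group up, out-group not-up). The
#' two-sided p sums the probabilities of all tables with the observed
#' margins whose point probability does not exceed that of the observed
#' table (the common statistical-package convention); `sided = "greater"`
#' gives the one-sided enrichment tail. The odds ratio is the sample
#' cross-product `ad/bc` (`Inf` allowed).
#'
#' @param k up-regulated genes inside the orthogroup.
#' @param n_group genes in the orthogroup.
#' @param K_up_total up-regulated genes overall.
#' @param N_total genes overall (the background universe).
#' @param sided `"two"` (default) or `"greater"`.
#' @return a one-row `data.frame`: `k`, `n_group`, `K_up_total`,
#'   `N_total`, `odds_ratio`, `p_value`.
#' @export
#' @examples
#' fisherEnrichment(2, 2, 2, 4)$p_value  # 1/3
#' fisherEnrichment(45, 203, 162, 77230)$p_value < 1e-4
fisherEnrichment <- function(k, n_group, K_up_total, N_total,
                             sided = c("two", "greater")) {
    sided <- match.arg(sided)
    a <- k; b <- n_group - k; c <- K_up_total - k
    d <- N_total - n_group - c
    if (any(c(a, b, c, d) < 0) ||
        any(c(a, b, c, d) != round(c(a, b, c, d))))
        stop(sprintf(
            "impossible 2x2 table: a=%s b=%s c=%s d=%s", a, b, c, d))
    m <- K_up_total; n <- N_total - K_up_total
    kk <- max(0L, n_group - n):min(n_group, m)
    probs <- stats::dhyper(kk, m, n, n_group)
    p_obs <- stats::dhyper(k, m, n, n_group)
    p <- if (sided == "two")
        sum(probs[probs <= p_obs * (1 + 1e-7)])
    else
        sum(probs[kk >= k])
    p <- min(1, p)
    or <- (a * d) / (b * c)
    data.frame(k = k, n_group = n_group, K_up_total = K_up_total,
               N_total = N_total, odds_ratio = or, p_value = p)
}

#' Enrichment scan over expanded orthogroups
#'
#' For every expanded orthogroup, tests whether the up-regulated genes are
#' over-represented among its members with [fisherEnrichment()]. Genes of
#' the DEG table absent from the membership table are excluded with a
#' warning. The background universe defaults to all genes of the
#' membership table; pass `N_total` to use a wider universe (e.g. all gene
#' models of the assembly).
#'
#' @param membership `data.frame` with columns `gene_id`, `orthogroup_id`
#'   (focal-species genes).
#' @param deg a DEG `data.frame` (see [readDegTable()]).
#' @param expansion a `data.frame` from [expansionZscore()].
#' @param N_total background universe size (default `nrow(membership)`).
#' @param alpha significance level for the `enriched` flag (default 0.05).
#' @param sided passed to [fisherEnrichment()].
#' @return a `data.frame`, one row per expanded orthogroup: the Fisher
#'   columns plus `z`, `contains_up` and `enriched`.
#' @export
enrichmentScan <- function(membership, deg, expansion,
                           N_total = nrow(membership), alpha = 0.05,
                           sided = "two") {
    up <- deg$gene_id[deg$direction == "up"]
    missing <- setdiff(up, membership$gene_id)
    if (length(missing)) {
        warning(length(missing),
                " DEG gene(s) absent from the membership table; excluded")
        up <- setdiff(up, missing)
    }
    K <- length(up)
    exp_og <- expansion[expansion$expanded, , drop = FALSE]
    rows <- lapply(seq_len(nrow(exp_og)), function(i) {
        og <- exp_og$orthogroup_id[i]
        members <- membership$gene_id[membership$orthogroup_id == og]
        k <- sum(members %in% up)
        fe <- fisherEnrichment(k, length(members), K, N_total,
                               sided = sided)
        cbind(data.frame(orthogroup_id = og, z = exp_og$z[i]), fe)
    })
    res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(res))
        return(data.frame(orthogroup_id = character(0), z = numeric(0),
                          k = integer(0), n_group = integer(0),
                          K_up_total = integer(0), N_total = integer(0),
                          odds_ratio = numeric(0), p_value = numeric(0),
                          contains_up = logical(0), enriched = logical(0)))
    res$contains_up <- res$k >= 1L
    res$enriched <- res$p_value < alpha
    res
}
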