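# Genome-level alignment credibility screen and read-level screen.
# A protein-to-genome hit is credible when it covers more than 60% of the
# query and its normalized alignment score (raw alignment score, i.e.
# substitution-matrix scores plus gap penalties, divided by the aligned
# length in bp) exceeds 2; a translated-search hit is credible below
# E = 1e-4. Read hits are length-normalized to TPM and the algal query set
# is compared with the host single-copy control set by Welch's t-test;
# algal queries whose normalized count exceeds 100 are flagged for
# host-homolog inspection rather than auto-classified as HGT.

.verdictFrame <- function(query_id) {
    data.frame(query_id = query_id, n_hits_total = 0L,
               n_hits_credible = 0L, credible = FALSE,
               best_subject = NA_character_, best_bit_score = NA_real_)
}

#' Alignment-level credibility screen
#'
#' A hit is credible iff `(query_end - query_start + 1) / query_length`
#' exceeds `min_query_coverage` (strict `>`) and
#' `raw_score / alignment_length` exceeds `min_norm_score` (strict `>`).
#'
#' @param hits a [HitTable-class]; every hit must carry `raw_score` and
#'   `query_length` (an error otherwise — use a dialect that provides them).
#' @param cfg a [ScreenConfig-class].
#' @param queries optional character vector of query ids to report even
#'   when they have no hits (verdict `credible = FALSE`, `n = 0`).
#' @return a `data.frame` with one row per query: `query_id`,
#'   `n_hits_total`, `n_hits_credible`, `credible`, `best_subject`,
#'   `best_bit_score` (best credible hit, or best overall when none is
#'   credible).
#' @export
screenAlignmentHits <- function(hits, cfg = screenConfig(),
                                queries = NULL) {
    h <- hitRecords(hits)
    if (nrow(h) && (anyNA(h$raw_score) || anyNA(h$query_length)))
        stop("alignment screen needs raw_score and query_length on every hit")
    p <- cfg@align_screen
    if (nrow(h)) {
        cov <- (h$query_end - h$query_start + 1) / h$query_length
        norm <- h$raw_score / h$alignment_length
        h$credible <- cov > p$min_query_coverage & norm > p$min_norm_score
    }
    .perQueryVerdict(h, queries)
}

#' Translated-search (tblastn-style) reliability screen
#'
#' A hit is reliable iff its E-value is strictly below `max_evalue`
#' (default 1e-4); a hit at exactly the threshold is not.
#'
#' @inheritParams screenAlignmentHits
#' @return same shape as [screenAlignmentHits()].
#' @export
screenTblastnHits <- function(hits, cfg = screenConfig(), queries = NULL) {
    h <- hitRecords(hits)
    if (nrow(h))
        h$credible <- h$e_value < cfg@align_screen$max_evalue
    .perQueryVerdict(h, queries)
}

.perQueryVerdict <- function(h, queries) {
    out <- list()
    for (q in unique(h$query_id)) {
        hh <- h[h$query_id == q, , drop = FALSE]
        n_cred <- sum(hh$credible)
        pick <- if (n_cred) hh[hh$credible, , drop = FALSE] else hh
        best <- pick[which.max(pick$bit_score), , drop = FALSE]
        out[[q]] <- data.frame(query_id = q, n_hits_total = nrow(hh),
                               n_hits_credible = n_cred,
                               credible = n_cred >= 1L,
                               best_subject = best$subject_id,
                               best_bit_score = best$bit_score)
    }
    for (q in setdiff(queries, names(out)))
        out[[q]] <- .verdictFrame(q)
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    if (is.null(res)) res <- .verdictFrame(character(0))
    res[order(res$query_id), , drop = FALSE]
}

#' Length-normalized read counts (TPM)
#'
#' Transcripts-per-kilobase-million over the supplied query universe:
#' `rate = count / (length/1000)`, `tpm = rate / sum(rate) * 1e6`. The
#' universe (the denominator) is exactly the set of queries passed in —
#' conventionally the union of the target set and the control set within
#' one library. When every count is zero all TPM values are zero.
#'
#' @param counts named numeric vector of raw read counts (>= 0).
#' @param lengths named numeric vector of query lengths in bp (> 0; an
#'   error otherwise), covering every name of `counts`.
#' @return a `data.frame` with `query_id`, `query_length`, `raw_reads`,
#'   `tpm`.
#' @export
#' @examples
#' computeTpm(c(a = 10, b = 5), c(a = 1000, b = 500))$tpm  # 5e5, 5e5
computeTpm <- function(counts, lengths) {
    if (is.null(names(counts)) || anyNA(names(counts)))
        stop("'counts' must be a named vector")
    lengths <- lengths[names(counts)]
    if (anyNA(lengths))
        stop("missing query length(s) for: ",
             paste(utils::head(names(counts)[is.na(lengths)], 3L),
                   collapse = ", "))
    if (any(lengths <= 0))
        stop("query lengths must be > 0")
    if (any(counts < 0))
        stop("read counts must be >= 0")
    rate <- counts / (lengths / 1000)
    total <- sum(rate)
    tpm <- if (total > 0) rate / total * 1e6 else rate * 0
    data.frame(query_id = names(counts),
               query_length = unname(lengths),
               raw_reads = unname(counts), tpm = unname(tpm))
}

#' Compare a query set's normalized read counts against a control set
#'
#' Runs a two-sided Welch t-test (via [welchTTest()]) on the TPM values of
#' the two sets and flags the members of the target set whose TPM exceeds
#' `read_screen$flag_tpm` (strict `>`). Flagged queries are candidates for
#' host-homolog inspection ([resolveFlaggedByHostHomolog()]), not automatic
#' HGT calls.
#'
#' @param setA a `data.frame` from [computeTpm()] for the target (e.g.
#'   algal) queries.
#' @param setControl same, for the control (e.g. host single-copy) queries.
#' @param cfg a [ScreenConfig-class].
#' @return a list: `mean_a`, `sd_a`, `n_a`, `mean_control`, `sd_control`,
#'   `n_control`, `welch` (a [welchTTest()] result), `flagged_queries`.
#' @export
compareReadSets <- function(setA, setControl, cfg = screenConfig()) {
    if (nrow(setA) < 2L || nrow(setControl) < 2L)
        stop("both sets need >= 2 queries (variance undefined otherwise)")
    w <- welchTTest(setA$tpm, setControl$tpm)
    flagged <- setA$query_id[setA$tpm > cfg@read_screen$flag_tpm]
    list(mean_a = mean(setA$tpm), sd_a = stats::sd(setA$tpm),
         n_a = nrow(setA),
         mean_control = mean(setControl$tpm),
         sd_control = stats::sd(setControl$tpm),
         n_control = nrow(setControl),
         welch = w, flagged_queries = flagged)
}

#' Resolve a flagged query by host-homolog read sharing
#'
#' A flagged query is explained by a host homolog when more than
#' `read_screen$host_share_fraction` (default 0.5, strict `>`) of the reads
#' hitting it also hit at least one host gene under the same search
#' parameters — the signature of a conserved host gene rather than an
#' algae-derived locus.
#'
#' @param query_reads character vector of read ids that hit the flagged
#'   query.
#' @param host_hits a [HitTable-class] of read-vs-host-gene hits
#'   (`query_id` = read id).
#' @param cfg a [ScreenConfig-class].
#' @return a list: `n_reads`, `n_shared`, `fraction`, and `status`
#'   (`"host_homolog_explained"` or `"unexplained"`).
#' @export
#' @examples
#' # 733 of 970 reads shared -> fraction 0.756 -> explained
resolveFlaggedByHostHomolog <- function(query_reads, host_hits,
                                        cfg = screenConfig()) {
    reads_hitting_host <- unique(hitRecords(host_hits)$query_id)
    n <- length(query_reads)
    shared <- sum(query_reads %in% reads_hitting_host)
    frac <- if (n) shared / n else 0
    list(n_reads = n, n_shared = shared, fraction = frac,
         status = if (frac > cfg@read_screen$host_share_fraction)
             "host_homolog_explained" else "unexplained")
}
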