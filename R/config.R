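# Screen configuration: every threshold of the pipeline with its default.
# Defaults follow the published screen: LCA retention (Min Score 50,
# Max Expected 1e-4, Top Percent 20, Min Support Percent 0.1, Min Support 1,
# LCA percent 90), alignment credibility (>60% query coverage, normalized
# alignment score > 2, E < 1e-4), read screen (E < 1e-3, flag at TPM > 100),
# HGT-index candidacy at |100| bits, bacterial rule (>= 2 bacterial genes and
# 0 lophotrochozoan genes), organelle rule (bit score > 1000 plus depth
# corroboration), tissue depth ratio in [2, 4], expansion at Z > 2.

.SCREEN_DEFAULTS <- list(
    lca = list(min_score = 50, max_expected = 1e-4, top_percent = 20,
               min_support_percent = 0.1, min_support = 1,
               lca_percent = 90),
    align_screen = list(min_query_coverage = 0.60, min_norm_score = 2.0,
                        max_evalue = 1e-4),
    read_screen = list(max_evalue = 1e-3, flag_tpm = 100,
                       host_share_fraction = 0.5),
    hgt_index = list(threshold = 100, missing_group_bits = 0, sign = 1),
    decontam = list(min_bacterial_genes = 2, max_loph_genes = 0,
                    organelle_min_bitscore = 1000,
                    organelle_min_depth_fold = 10,
                    tissue_ratio_min = 2, tissue_ratio_max = 4),
    expansion = list(z_threshold = 2.0, include_focal = TRUE),
    rng_seed = 1L
)

#' Screen configuration
#'
#' Bundles every tunable threshold of the HGT screen, grouped by stage.
#' Construct with [screenConfig()]; any value not supplied keeps its default
#' (the published screening parameters, see the package vignette).
#'
#' @slot lca,align_screen,read_screen,hgt_index,decontam,expansion named
#'   lists of thresholds for the corresponding stage.
#' @slot rng_seed integer seed recorded for provenance.
#' @exportClass ScreenConfig
setClass("ScreenConfig",
         representation(lca = "list", align_screen = "list",
                        read_screen = "list", hgt_index = "list",
                        decontam = "list", expansion = "list",
                        rng_seed = "numeric"))

.validScreenConfig <- function(object) {
    num <- unlist(object@lca)
    if (!all(is.finite(unlist(c(object@lca, object@align_screen,
                                object@read_screen, object@hgt_index,
                                object@decontam, object@expansion)))))
        return("all thresholds must be finite")
    if (object@lca$top_percent <= 0 || object@lca$top_percent > 100)
        return("top_percent must lie in (0, 100]")
    if (object@lca$lca_percent <= 0 || object@lca$lca_percent > 100)
        return("lca_percent must lie in (0, 100]")
    if (!object@hgt_index$sign %in% c(-1, 1))
        return("hgt_index$sign must be +1 (donor-minus-host) or -1")
    TRUE
}
setValidity("ScreenConfig", .validScreenConfig)

.mergeDefaults <- function(defaults, given, where) {
    if (is.null(given)) return(defaults)
    extra <- setdiff(names(given), names(defaults))
    if (length(extra))
        stop(sprintf("unknown %s option(s): %s", where,
                     paste(extra, collapse = ", ")))
    utils::modifyList(defaults, given)
}

#' Build a screen configuration
#'
#' @param lca,align_screen,read_screen,hgt_index,decontam,expansion named
#'   lists overriding individual defaults of the corresponding stage;
#'   unknown names raise an error.
#' @param rng_seed integer seed recorded alongside the thresholds.
#' @return a validated [ScreenConfig-class].
#' @export
#' @examples
#' cfg <- screenConfig(hgt_index = list(threshold = 150))
#' cfg@hgt_index$threshold
screenConfig <- function(lca = list(), align_screen = list(),
                         read_screen = list(), hgt_index = list(),
                         decontam = list(), expansion = list(),
                         rng_seed = 1L) {
    d <- .SCREEN_DEFAULTS
    new("ScreenConfig",
        lca = .mergeDefaults(d$lca, lca, "lca"),
        align_screen = .mergeDefaults(d$align_screen, align_screen,
                                      "align_screen"),
        read_screen = .mergeDefaults(d$read_screen, read_screen,
                                     "read_screen"),
        hgt_index = .mergeDefaults(d$hgt_index, hgt_index, "hgt_index"),
        decontam = .mergeDefaults(d$decontam, decontam, "decontam"),
        expansion = .mergeDefaults(d$expansion, expansion, "expansion"),
        rng_seed = as.numeric(rng_seed))
}

setMethod("show", "ScreenConfig", function(object) {
    cat("ScreenConfig\n")
    for (s in c("lca", "align_screen", "read_screen", "hgt_index",
                "decontam", "expansion")) {
        v <- slot(object, s)
        cat(sprintf("  %-12s %s\n", s,
                    paste(names(v), unlist(v), sep = "=",
                          collapse = ", ")))
    }
})

#' Read a screen configuration from YAML or JSON
#'
#' The file holds any subset of the configuration sections
#' (`lca`, `align_screen`, `read_screen`, `hgt_index`, `decontam`,
#' `expansion`, `rng_seed`); missing values keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [ScreenConfig-class].
#' @export
readScreenConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else
        yaml::read_yaml(path)
    screenConfig(
        lca = raw$lca, align_screen = raw$align_screen,
        read_screen = raw$read_screen, hgt_index = raw$hgt_index,
        decontam = raw$decontam, expansion = raw$expansion,
        rng_seed = if (is.null(raw$rng_seed)) 1L else raw$rng_seed)
}

# stderr logger; level filtering via option kleptoscreen.log_level
.LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L)

ksLog <- function(msg, ..., level = "info") {
    threshold <- getOption("kleptoscreen.log_level", "info")
    if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[threshold]])
        message(sprintf("[kleptoscreen:%s] %s", level, sprintf(msg, ...)))
    invisible(NULL)
}
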