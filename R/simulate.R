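# Seeded generators for fully-labelled synthetic inputs: taxonomies,
# genomes with planted algal-HGT genes and contaminant/organelle scaffolds,
# bit-score hit tables with donor-affine structure, read-hit counts with
# the "rare algal reads vs abundant host single-copy reads" regime,
# two-library depth tables, and orthogroup count matrices with planted
# expansion and enrichment. Every generator is deterministic under its
# seed, and every artifact passes the corresponding reader/validator.

#' Karlin-Altschul score model for synthetic hit tables
#'
#' Bit scores are synthesized from a raw-score model and converted with the
#' standard Karlin-Altschul form `bits = (lambda * S_raw - ln K) / ln 2`
#' (monotone in the raw score). The defaults are classic protein-search
#' constants; they parameterize synthesis only.
#'
#' @param lambda,k Karlin-Altschul parameters (> 0).
#' @param bits_per_identical_residue expected bits contributed per aligned
#'   residue of an identical match (> 0).
#' @param divergence_decay multiplicative decay of the per-residue signal
#'   with evolutionary distance, in (0, 1].
#' @param noise_sd SD (bits) of the score jitter; the jitter is a normal
#'   truncated at +/- 2 SD, so a planted bit-score margin `m` guarantees
#'   full separation whenever `noise_sd <= m/4` (see the vignette).
#' @return a validated list of class `score_model`.
#' @export
scoreModel <- function(lambda = 0.267, k = 0.041,
                       bits_per_identical_residue = 2,
                       divergence_decay = 0.7, noise_sd = 20) {
    stopifnot(lambda > 0, k > 0, bits_per_identical_residue > 0,
              divergence_decay > 0, divergence_decay <= 1, noise_sd >= 0)
    structure(list(lambda = lambda, k = k,
                   bits_per_identical_residue = bits_per_identical_residue,
                   divergence_decay = divergence_decay,
                   noise_sd = noise_sd),
              class = "score_model")
}

#' Convert a raw alignment score to bits
#'
#' @param s_raw raw alignment score(s).
#' @param model a [scoreModel()].
#' @return bit score(s), `(lambda * s_raw - ln k) / ln 2`.
#' @export
#' @examples
#' bitsFromRaw(100, scoreModel())  # about 43.13
bitsFromRaw <- function(s_raw, model = scoreModel()) {
    (model$lambda * s_raw - log(model$k)) / log(2)
}

.rawFromBits <- function(bits, model) {
    (bits * log(2) + log(model$k)) / model$lambda
}

# normal jitter truncated at +/- 2 SD (bounded tails give the planted
# margin a deterministic separation guarantee at noise_sd <= margin/4)
.truncNoise <- function(n, sd) {
    if (sd == 0) return(numeric(n))
    pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)
}

#' Simulate a taxonomy tree
#'
#' Builds a rooted tree with a fixed backbone (Bacteria; Eukaryota
#' splitting into an algal clade, Lophotrochozoa, and other opisthokonts)
#' and attaches the remaining taxa at random. The four required groups are
#' populated with their whole subtrees, so they satisfy every
#' [TaxonomyTree-class] invariant by construction.
#'
#' @param n_taxa total number of taxa (>= 8).
#' @param seed RNG seed; identical seeds give identical trees.
#' @return a [TaxonomyTree-class].
#' @export
simulateTaxonomy <- function(n_taxa = 40, seed = 1) {
    if (n_taxa < 8) stop("need n_taxa >= 8")
    set.seed(seed)
    nodes <- data.frame(
        taxon_id = c("root", "Bacteria", "Eukaryota", "Algae",
                     "Lophotrochozoa", "Opisthokonta_other"),
        parent_id = c(NA, "root", "root", "Eukaryota", "Eukaryota",
                      "Eukaryota"),
        name = c("cellular organisms", "Bacteria", "Eukaryota",
                 "green algae", "Lophotrochozoa", "other opisthokonts"))
    clades <- c("Bacteria", "Algae", "Lophotrochozoa",
                "Opisthokonta_other")
    members <- as.list(setNames(clades, clades))
    n_extra <- n_taxa - nrow(nodes)
    clade_of <- c(clades[seq_len(min(4L, n_extra))],
                  sample(clades, max(0L, n_extra - 4L), replace = TRUE))
    for (i in seq_len(n_extra)) {
        cl <- clade_of[i]
        tid <- sprintf("t%04d", i)
        parent <- if (length(members[[cl]]) == 1L) members[[cl]] else
            sample(members[[cl]], 1L)
        nodes <- rbind(nodes, data.frame(taxon_id = tid,
                                         parent_id = parent,
                                         name = tid))
        members[[cl]] <- c(members[[cl]], tid)
    }
    TaxonomyTree(nodes, list(
        prokaryote = members$Bacteria,
        eukaryote = c("Eukaryota", members$Algae, members$Lophotrochozoa,
                      members$Opisthokonta_other),
        algae = members$Algae,
        lophotrochozoa = members$Lophotrochozoa))
}

.randomDna <- function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Simulate a genome with planted ground truth
#'
#' Generates nuclear scaffolds of host genes with `n_hgt` planted
#' algal-HGT genes scattered among them (so decontamination must not
#' remove them), `n_contaminant_scaffolds` bacterial contaminant scaffolds
#' carrying only bacterial genes, and `n_organelle_scaffolds`
#' organelle-derived scaffolds. Every entity receives exactly one
#' immutable truth label.
#'
#' @param n_scaffolds nuclear scaffolds.
#' @param genes_per_scaffold host genes per nuclear scaffold.
#' @param n_hgt planted algal-HGT genes (placed on nuclear scaffolds).
#' @param n_contaminant_scaffolds,n_organelle_scaffolds planted
#'   contaminant and organelle scaffold counts.
#' @param contaminant_genes bacterial genes per contaminant scaffold
#'   (>= 2 so the bacterial rule can fire).
#' @param organelle_genes genes per organelle scaffold.
#' @param gene_length,intergenic gene and spacer lengths in bp.
#' @param scaffold_length optional nuclear scaffold length; an error when
#'   the requested genes do not fit.
#' @param sequences generate random nucleotide sequences (`TRUE`) or only
#'   lengths (`FALSE`, faster; no screen reads sequence content).
#' @param seed RNG seed.
#' @return a list: `scaffolds` ([ScaffoldSet-class]), `genes`
#'   ([GeneCatalog-class]), `truth` (list of `genes` and `scaffolds`
#'   label `data.frame`s).
#' @export
simulateGenome <- function(n_scaffolds = 100, genes_per_scaffold = 20,
                           n_hgt = 20, n_contaminant_scaffolds = 3,
                           n_organelle_scaffolds = 2,
                           contaminant_genes = 3, organelle_genes = 2,
                           gene_length = 900, intergenic = 150,
                           scaffold_length = NULL, sequences = TRUE,
                           seed = 1) {
    set.seed(seed)
    need <- genes_per_scaffold * (gene_length + intergenic) + intergenic
    if (is.null(scaffold_length)) scaffold_length <- need
    if (scaffold_length < need)
        stop(sprintf(
            "scaffold_length %d cannot hold %d genes (need %d bp)",
            scaffold_length, genes_per_scaffold, need))
    n_host <- n_scaffolds * genes_per_scaffold
    if (n_hgt > n_host)
        stop("more planted HGT genes than host gene slots")
    place <- function(scaffold_ids, genes_per, prefix, start_idx) {
        rows <- list()
        idx <- start_idx
        for (s in scaffold_ids) {
            for (j in seq_len(genes_per)) {
                st <- intergenic + (j - 1L) * (gene_length + intergenic) + 1L
                rows[[length(rows) + 1L]] <- data.frame(
                    scaffold_id = s, gene_id = sprintf("%s%05d", prefix, idx),
                    start = st, end = st + gene_length - 1L,
                    strand = sample(c("+", "-"), 1L))
                idx <- idx + 1L
            }
        }
        do.call(rbind, rows)
    }
    nuc_ids <- sprintf("scaffold%04d", seq_len(n_scaffolds))
    bac_ids <- if (n_contaminant_scaffolds)
        sprintf("contig_bact%02d", seq_len(n_contaminant_scaffolds))
        else character(0)
    org_ids <- if (n_organelle_scaffolds)
        sprintf("contig_org%02d", seq_len(n_organelle_scaffolds))
        else character(0)
    g_nuc <- place(nuc_ids, genes_per_scaffold, "g", 1L)
    g_bac <- if (length(bac_ids))
        place(bac_ids, contaminant_genes, "bg", 1L) else NULL
    g_org <- if (length(org_ids))
        place(org_ids, organelle_genes, "og", 1L) else NULL
    g_nuc$true_origin <- "host"
    hgt_idx <- sample(nrow(g_nuc), n_hgt)
    g_nuc$true_origin[hgt_idx] <- "algal_hgt"
    if (!is.null(g_bac)) g_bac$true_origin <- "bacterial"
    if (!is.null(g_org)) g_org$true_origin <- "organelle"
    genes <- rbind(g_nuc, g_bac, g_org)
    scf_info <- data.frame(
        scaffold_id = c(nuc_ids, bac_ids, org_ids),
        length = c(rep(scaffold_length, length(nuc_ids)),
                   rep(contaminant_genes * (gene_length + intergenic) +
                           intergenic, length(bac_ids)),
                   rep(organelle_genes * (gene_length + intergenic) +
                           intergenic, length(org_ids))))
    seqs <- NULL
    if (sequences) {
        seqs <- Biostrings::DNAStringSet(vapply(scf_info$length,
                                                .randomDna, character(1)))
        names(seqs) <- scf_info$scaffold_id
    }
    gr <- GenomicRanges::GRanges(
        genes$scaffold_id,
        IRanges::IRanges(genes$start, genes$end),
        strand = genes$strand)
    gr$gene_id <- genes$gene_id
    truth_scf <- data.frame(
        scaffold_id = scf_info$scaffold_id,
        true_label = c(rep("nuclear", length(nuc_ids)),
                       rep("bacterial_contaminant", length(bac_ids)),
                       rep("organelle", length(org_ids))))
    list(scaffolds = ScaffoldSet(scf_info, sequences = seqs),
         genes = GeneCatalog(gr),
         truth = list(
             genes = genes[, c("gene_id", "scaffold_id", "true_origin")],
             scaffolds = truth_scf))
}

.sampleTaxa <- function(pool, n)
    if (length(pool) <= n) pool else sample(pool, n)

#' Simulate a hit table reflecting each gene's true origin
#'
#' Every gene receives hits to taxa of its true-origin group whose best bit
#' score follows `length_aa * bits_per_identical_residue *
#' divergence_decay` plus truncated-normal jitter, and hits to the opposing
#' group lower by `margin` bits (plus jitter). Host genes additionally get
#' a prokaryote hit `margin` bits below their best eukaryote hit, so the
#' h-index is strongly negative for them. Raw scores are derived from the
#' bit scores by inverting the Karlin-Altschul conversion, keeping the two
#' scales consistent.
#'
#' @param genome a [simulateGenome()] result.
#' @param tree a [simulateTaxonomy()] result (or any compatible
#'   [TaxonomyTree-class]).
#' @param model a [scoreModel()].
#' @param margin planted bit-score separation between the true-origin
#'   group and the opposing group (default 250 bits). With the truncated
#'   jitter, separation at the conventional 100-bit index threshold is
#'   guaranteed whenever `noise_sd <= margin/4`.
#' @param seed RNG seed.
#' @return a [HitTable-class] covering every gene of the genome.
#' @export
simulateHitTable <- function(genome, tree, model = scoreModel(),
                             margin = 250, seed = 1) {
    set.seed(seed)
    groups <- taxonGroups(tree)
    other_euk <- setdiff(groups$eukaryote,
                         c(groups$algae, groups$lophotrochozoa))
    g <- genome$truth$genes
    widths <- GenomicRanges::width(geneModels(genome$genes))
    names(widths) <- geneModels(genome$genes)$gene_id
    rows <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
        gid <- g$gene_id[i]
        L <- max(50L, round(widths[[gid]] / 3))
        clean <- L * model$bits_per_identical_residue *
            model$divergence_decay
        own <- switch(g$true_origin[i],
                      host = groups$lophotrochozoa,
                      algal_hgt = groups$algae,
                      organelle = groups$algae,
                      bacterial = groups$prokaryote)
        cross <- switch(g$true_origin[i],
                        host = groups$algae,
                        algal_hgt = groups$lophotrochozoa,
                        organelle = groups$lophotrochozoa,
                        bacterial = other_euk)
        own_taxa <- .sampleTaxa(own, 3L)
        best <- clean + .truncNoise(1L, model$noise_sd)
        own_bits <- best - c(0, cumsum(stats::runif(
            length(own_taxa) - 1L, 0, 0.05 * best)))
        cross_taxa <- .sampleTaxa(cross, 1L)
        cross_bits <- best - (margin + .truncNoise(length(cross_taxa),
                                                   model$noise_sd))
        taxa <- c(own_taxa, cross_taxa)
        bits <- c(own_bits, cross_bits)
        if (g$true_origin[i] == "host") {
            # a weak prokaryote match keeps the h-index strongly negative
            ptax <- .sampleTaxa(groups$prokaryote, 1L)
            taxa <- c(taxa, ptax)
            bits <- c(bits, best - (margin + .truncNoise(1L,
                                                         model$noise_sd)))
        }
        bits <- pmax(bits, 25)
        n <- length(taxa)
        rows[[i]] <- data.frame(
            query_id = gid,
            subject_id = paste0(taxa, "_prot", seq_len(n)),
            subject_taxon_id = taxa,
            percent_identity = round(stats::runif(n, 35, 95), 1),
            alignment_length = pmax(30L, round(L * stats::runif(n, 0.6,
                                                                0.95))),
            bit_score = round(bits, 1),
            e_value = pmin(10, 2^(-bits) * 1e10),
            query_start = 1L,
            query_end = pmax(30L, round(L * stats::runif(n, 0.7, 1))),
            query_length = L,
            raw_score = round(.rawFromBits(bits, model), 1))
    }
    HitTable(do.call(rbind, rows))
}

#' Simulate scaffold-vs-organelle-reference hits
#'
#' Organelle-derived scaffolds receive a strong match (bit score well
#' above 1000) against a kleptoplast or mitochondrial reference; other
#' scaffolds occasionally receive a weak spurious match far below the
#' threshold.
#'
#' @param genome a [simulateGenome()] result.
#' @param spurious_rate fraction of non-organelle scaffolds receiving a
#'   weak match.
#' @param seed RNG seed.
#' @return a [HitTable-class] with `query_id` = scaffold id.
#' @export
simulateOrganelleHits <- function(genome, spurious_rate = 0.1, seed = 1) {
    set.seed(seed)
    truth <- genome$truth$scaffolds
    rows <- list()
    for (i in seq_len(nrow(truth))) {
        sid <- truth$scaffold_id[i]
        if (truth$true_label[i] == "organelle") {
            bit <- stats::runif(1, 1100, 1600)
            ref <- sample(c("kleptoplast_ref", "mito_ref"), 1L)
        } else if (stats::runif(1) < spurious_rate) {
            bit <- stats::runif(1, 50, 600)
            ref <- "kleptoplast_ref"
        } else next
        rows[[length(rows) + 1L]] <- data.frame(
            query_id = sid, subject_id = ref,
            percent_identity = round(stats::runif(1, 70, 99), 1),
            alignment_length = round(bit * 2),
            bit_score = round(bit, 1), e_value = 1e-180,
            query_start = 1L, query_end = round(bit * 2))
    }
    if (!length(rows)) return(HitTable())
    HitTable(do.call(rbind, rows))
}

#' Simulate per-scaffold depths for two tissue libraries
#'
#' Nuclear scaffolds draw from `Normal(mu_nuclear, sd_nuclear)` in both
#' libraries; bacterial contaminant scaffolds from a distinct shallow
#' range; organelle scaffolds get a kleptoplast-poor depth of
#' `mu_nuclear` times a fold drawn from `organelle_fold` and a
#' kleptoplast-rich depth larger by a ratio drawn from `tissue_ratio`
#' (default `[2, 4]`).
#'
#' @param genome a [simulateGenome()] result.
#' @param mu_nuclear,sd_nuclear nuclear depth mean and SD (x coverage).
#' @param organelle_fold range of the organelle/nuclear depth fold.
#' @param tissue_ratio range of the rich/poor organelle depth ratio.
#' @param bacterial_depth depth range of contaminant scaffolds.
#' @param libraries names of the (rich, poor) libraries, in that order.
#' @param seed RNG seed.
#' @return numeric depth matrix scaffold x library.
#' @export
simulateDepths <- function(genome, mu_nuclear = 31, sd_nuclear = 4,
                           organelle_fold = c(20, 100),
                           tissue_ratio = c(2, 4),
                           bacterial_depth = c(5, 15),
                           libraries = c("klepto_rich", "klepto_poor"),
                           seed = 1) {
    stopifnot(length(libraries) == 2L)
    set.seed(seed)
    truth <- genome$truth$scaffolds
    n <- nrow(truth)
    m <- matrix(NA_real_, n, 2L,
                dimnames = list(truth$scaffold_id, libraries))
    for (i in seq_len(n)) {
        m[i, ] <- switch(
            truth$true_label[i],
            nuclear = pmax(1, stats::rnorm(2L, mu_nuclear, sd_nuclear)),
            bacterial_contaminant = stats::runif(2L, bacterial_depth[1L],
                                                 bacterial_depth[2L]),
            organelle = {
                poor <- mu_nuclear * stats::runif(1, organelle_fold[1L],
                                                  organelle_fold[2L])
                c(poor * stats::runif(1, tissue_ratio[1L],
                                      tissue_ratio[2L]), poor)
            })
    }
    m
}

#' Simulate read-hit counts for the read-level screen
#'
#' Negative-binomial counts (overdispersed, as the published control set's
#' SD of the same order as its mean requires) for an algal query set and a
#' host single-copy control set, with the control rate about 100 times the
#' algal rate. Optionally plants a "shared-homolog" algal query with
#' control-like counts, which the TPM flag rule must pick up.
#'
#' @param n_algal,n_control query-set sizes (defaults: the 614 algal
#'   queries and the 905 single-copy host controls of the published
#'   screen).
#' @param mu_algal,mu_control mean reads per query; `mu_algal = 0` gives
#'   all-zero algal counts.
#' @param size_algal,size_control negative-binomial size (dispersion)
#'   parameters.
#' @param planted_shared plant one high-count algal query (`TRUE`/`FALSE`).
#' @param n_libraries independent libraries to draw.
#' @param seed RNG seed.
#' @return a list: `counts` (query x library matrix), `lengths` (named bp
#'   vector), `set` (named `"algal"`/`"control"` vector), `shared_query`
#'   (id or `NA`).
#' @export
simulateReadHits <- function(n_algal = 614, n_control = 905,
                             mu_algal = 2.5, mu_control = 250,
                             size_algal = 0.06, size_control = 1.4,
                             planted_shared = FALSE, n_libraries = 1,
                             seed = 1) {
    set.seed(seed)
    ids <- c(sprintf("algal_q%04d", seq_len(n_algal)),
             sprintf("host_sc%04d", seq_len(n_control)))
    set <- setNames(rep(c("algal", "control"), c(n_algal, n_control)),
                    ids)
    lengths <- setNames(round(stats::runif(length(ids), 500, 2500)), ids)
    draw <- function()
        c(if (mu_algal > 0)
              stats::rnbinom(n_algal, size = size_algal, mu = mu_algal)
          else rep(0L, n_algal),
          stats::rnbinom(n_control, size = size_control, mu = mu_control))
    counts <- vapply(seq_len(n_libraries), function(i) draw(),
                     numeric(length(ids)))
    rownames(counts) <- ids
    colnames(counts) <- sprintf("lib%02d", seq_len(n_libraries))
    shared <- NA_character_
    if (planted_shared) {
        shared <- ids[1L]
        counts[1L, ] <- stats::rnbinom(n_libraries, size = size_control,
                                       mu = 2 * mu_control)
    }
    list(counts = counts, lengths = lengths, set = set,
         shared_query = shared)
}

#' Simulate an orthogroup count matrix with planted expansion/enrichment
#'
#' Baseline counts are Poisson across species; each planted orthogroup has
#' its focal-species count inflated (guaranteeing a Z-score above 2 at the
#' defaults) and, when enriched, an up-regulated gene fraction far above
#' the background rate. A gene-to-orthogroup membership table and DEG
#' table for the focal species are generated alongside.
#'
#' @param n_orthogroups,n_species matrix dimensions (the focal species is
#'   the first column, named `"focal"`).
#' @param lambda_base Poisson mean of the baseline counts.
#' @param planted list of planted groups, each a list with `focal_count`
#'   and `n_up` (defaults to one group mirroring the 203-gene, 45-up
#'   cathepsin-D-like pattern).
#' @param background_up_rate probability that a background gene is
#'   up-regulated.
#' @param seed RNG seed.
#' @return a list: `counts`, `membership` (`gene_id`, `orthogroup_id`),
#'   `deg`, `truth` (per-orthogroup planted flags), `focal_species`.
#' @export
simulateCountsAndDegs <- function(n_orthogroups = 300, n_species = 18,
                                  lambda_base = 3,
                                  planted = list(list(focal_count = 203,
                                                      n_up = 45)),
                                  background_up_rate = 0.002, seed = 1) {
    set.seed(seed)
    species <- c("focal", sprintf("sp%02d", seq_len(n_species - 1L)))
    og_ids <- sprintf("OG%07d", seq_len(n_orthogroups))
    counts <- matrix(stats::rpois(n_orthogroups * n_species, lambda_base),
                     n_orthogroups, n_species,
                     dimnames = list(og_ids, species))
    n_planted <- length(planted)
    if (n_planted > n_orthogroups) stop("more planted groups than rows")
    planted_rows <- seq_len(n_planted)  # first rows are planted
    for (i in planted_rows) {
        counts[i, ] <- sample(0:5, n_species, replace = TRUE)
        counts[i, "focal"] <- planted[[i]]$focal_count
    }
    membership <- do.call(rbind, lapply(seq_len(n_orthogroups),
                                        function(i) {
        n <- counts[i, "focal"]
        if (!n) return(NULL)
        data.frame(gene_id = sprintf("%s_g%03d", og_ids[i], seq_len(n)),
                   orthogroup_id = og_ids[i])
    }))
    up <- character(0)
    for (i in planted_rows) {
        members <- membership$gene_id[
            membership$orthogroup_id == og_ids[i]]
        n_up <- planted[[i]]$n_up
        if (n_up > length(members))
            stop("planted n_up exceeds the group's focal gene count")
        up <- c(up, sample(members, n_up))
    }
    bg <- setdiff(membership$gene_id, up)
    up <- c(up, bg[stats::runif(length(bg)) < background_up_rate])
    deg <- data.frame(
        gene_id = membership$gene_id,
        log2_fold_change = stats::rnorm(nrow(membership), 0, 0.5),
        fdr = stats::runif(nrow(membership), 0.02, 1),
        direction = "ns")
    is_up <- deg$gene_id %in% up
    deg$direction[is_up] <- "up"
    deg$fdr[is_up] <- stats::runif(sum(is_up), 0, 0.009)
    deg$log2_fold_change[is_up] <- stats::runif(sum(is_up), 1, 6)
    truth <- data.frame(orthogroup_id = og_ids,
                        planted_expanded = seq_len(n_orthogroups) %in%
                            planted_rows,
                        planted_enriched = seq_len(n_orthogroups) %in%
                            planted_rows[vapply(planted,
                                                function(p) p$n_up > 0,
                                                logical(1))])
    list(counts = counts, membership = membership, deg = deg,
         truth = truth, focal_species = "focal")
}
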