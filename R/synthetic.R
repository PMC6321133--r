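#' @title Synthetic data with planted structure
#' @description Generates complete inputs with the statistical
#'   structure the analysis assumes — a two-diet repeated-measures
#'   design (6 control + 5 AD mice sampled at 5 ages), a log-normal
#'   metabolome with subject intercepts and low-abundance dropout, a
#'   Dirichlet-multinomial genus table with a random phylogeny,
#'   metabolite-genus couplings through shared latent factors, and
#'   matching gene-content and pathway references — together with the
#'   ground truth needed for recovery tests.
#' @name synthetic_data
NULL

#' Generate the sampling design
#'
#' Mice keep their subject id across ages, so repeated measures can be
#' modelled; defaults give 11 mice x 5 timepoints = 55 samples.
#'
#' @param n_control,n_ad mice per diet group (defaults 6 and 5).
#' @param weeks sampling ages in weeks.
#' @param seed unused (the design is deterministic) but accepted for
#'   interface symmetry.
#' @return sample metadata data.frame (`sample_id`, `group`,
#'   `subject_id`, `age_weeks`).
#' @export
generate_design <- function(n_control = 6, n_ad = 5,
                            weeks = c(8, 12, 24, 36, 52), seed = NULL) {
  if (n_control < 1 || n_ad < 1) stop("group sizes must be positive")
  subjects <- c(sprintf("C%02d", seq_len(n_control)),
                sprintf("A%02d", seq_len(n_ad)))
  groups <- rep(c("control", "AD"), c(n_control, n_ad))
  df <- expand.grid(subject_id = subjects, age_weeks = as.integer(weeks),
                    stringsAsFactors = FALSE)
  df$group <- factor(groups[match(df$subject_id, subjects)],
                     levels = c("control", "AD"))
  df$sample_id <- sprintf("%s_w%02d", df$subject_id, df$age_weeks)
  df[, c("sample_id", "group", "subject_id", "age_weeks")]
}

#' Generate a metabolome table with planted diet effects
#'
#' Concentrations are log-normal around per-metabolite baselines, with
#' a per-mouse random intercept (repeated measures) and iid noise.  A
#' chosen subset of metabolites receives an additive diet effect on the
#' log2 scale; most planted effects are decreases in the AD group,
#' mirroring the direction balance this kind of diet switch produces.
#' About `nd_frac` of cells are masked "not detected", preferentially
#' at low concentrations.
#'
#' @param meta design from [generate_design()].
#' @param n_features number of metabolites (default 184).
#' @param n_diet_affected how many receive a diet effect (default 40).
#' @param effect_log2fc absolute log2 fold change of planted effects
#'   (default 2).
#' @param noise_sd residual sd on the natural-log scale (default 0.6).
#' @param subject_sd sd of the per-mouse intercept (default 0.3).
#' @param nd_frac target fraction of "not detected" cells (default 0.05).
#' @param frac_down fraction of planted effects that are decreases in
#'   AD (default 0.85).
#' @param seed RNG seed.
#' @return list: `table` (a `feature_table`, unit concentration) and
#'   `truth` (`diet_affected`, signed `effect_log2fc` per affected
#'   feature, `seed`).
#' @export
generate_metabolome <- function(meta, n_features = 184, n_diet_affected = 40,
                                effect_log2fc = 2, noise_sd = 0.6,
                                subject_sd = 0.3, nd_frac = 0.05,
                                frac_down = 0.85, seed = NULL) {
  if (n_diet_affected > n_features)
    stop("n_diet_affected exceeds n_features")
  n <- nrow(meta)
  with_seed(seed, {
    feat <- sprintf("met_%03d", seq_len(n_features))
    base <- stats::rnorm(n_features, mean = 2, sd = 1.2)   # log nmol/g
    affected <- sort(sample(n_features, n_diet_affected))
    sign_vec <- ifelse(stats::runif(n_diet_affected) < frac_down, -1, 1)
    effect <- numeric(n_features)
    effect[affected] <- sign_vec * effect_log2fc * log(2)  # natural log
    subjects <- unique(meta$subject_id)
    intercept <- stats::setNames(stats::rnorm(length(subjects), 0,
                                              subject_sd), subjects)
    is_ad <- meta$group == "AD"
    logv <- matrix(base, n, n_features, byrow = TRUE) +
      outer(as.numeric(is_ad), effect) +
      intercept[meta$subject_id] +
      matrix(stats::rnorm(n * n_features, 0, noise_sd), n)
    v <- exp(logv)
    dimnames(v) <- list(meta$sample_id, feat)
    # dropout: mask with probability decreasing in the cell's rank
    pr <- 2 * nd_frac * (1 - (rank(v) - 0.5) / length(v))
    mask <- stats::runif(length(v)) < pr
    v[mask] <- NA
    list(table = feature_table(v, block = "metabolite",
                               unit = "concentration"),
         truth = list(diet_affected = feat[affected],
                      effect_log2fc = stats::setNames(
                        sign_vec * effect_log2fc, feat[affected]),
                      seed = seed))
  })
}

#' Generate a genus count table and phylogeny with planted diet effects
#'
#' Counts are Dirichlet-multinomial: per-genus base weights follow a
#' log-normal rank-abundance curve, each sample draws Dirichlet
#' proportions at concentration `theta` (overdispersion) and then
#' multinomial counts at a depth drawn uniformly from `depth_range`.
#' Diet effects multiply the Dirichlet weights of planted genera in the
#' AD group by `2^effect_log2fc` (half up, half down).  The phylogeny is
#' a random bifurcating tree with exponential branch lengths.
#'
#' @param meta design from [generate_design()].
#' @param n_genera number of genera (default 106).
#' @param depth_range per-sample read-depth range; the minimum must
#'   exceed the rarefaction depth so rarefaction is exercised.
#' @param n_diet_affected planted diet-responsive genera (default 15).
#' @param effect_log2fc absolute log2 fold change on Dirichlet weights
#'   (default 2).
#' @param theta Dirichlet concentration (default 200; larger = less
#'   overdispersed).
#' @param seed RNG seed.
#' @return list: `table` (counts), `tree` (`phylo`), `truth`
#'   (`diet_affected`, signed effects, `seed`).
#' @export
generate_microbiome <- function(meta, n_genera = 106,
                                depth_range = c(20000, 40000),
                                n_diet_affected = 15, effect_log2fc = 2,
                                theta = 200, seed = NULL) {
  n <- nrow(meta)
  with_seed(seed, {
    gen <- sprintf("genus_%03d", seq_len(n_genera))
    w <- sort(exp(stats::rnorm(n_genera, 0, 1.5)), decreasing = TRUE)
    names(w) <- gen
    # plant effects on moderately abundant genera so rank tests see them
    mid <- which(rank(-w) <= max(30, n_diet_affected * 2))
    affected <- sort(sample(mid, n_diet_affected))
    sign_vec <- rep(c(1, -1), length.out = n_diet_affected)
    mult <- rep(1, n_genera)
    mult[affected] <- 2^(sign_vec * effect_log2fc)
    is_ad <- meta$group == "AD"
    depth <- sample(seq(depth_range[1], depth_range[2]), n, replace = TRUE)
    v <- matrix(0L, n, n_genera, dimnames = list(meta$sample_id, gen))
    for (i in seq_len(n)) {
      wi <- w * (if (is_ad[i]) mult else 1)
      alpha <- theta * wi / sum(wi)
      prop <- stats::rgamma(n_genera, shape = alpha)
      prop <- prop / sum(prop)
      v[i, ] <- stats::rmultinom(1, size = depth[i], prob = prop)
    }
    tree <- ape::rtree(n_genera, rooted = TRUE,
                       br = function(k) stats::rexp(k, rate = 5))
    tree$tip.label <- sample(gen)   # detach topology from abundance rank
    list(table = feature_table(v, block = "taxon", unit = "count"),
         tree = tree,
         truth = list(diet_affected = gen[affected],
                      effect_log2fc = stats::setNames(
                        sign_vec * effect_log2fc, gen[affected]),
                      seed = seed))
  })
}

#' Couple metabolites to genera and build the reference tables
#'
#' Each requested (metabolite, genus) pair is coupled through a shared
#' latent factor: the genus' relative abundance is converted to normal
#' scores, and the metabolite column is regenerated on the log scale as
#' a mixture of that score and fresh noise, with the mixing weight
#' `r = 2 sin(pi * rho / 6)` chosen so the realised Spearman
#' correlation matches the target `rho` (the Pearson-to-Spearman map
#' for bivariate normals).  The gene-content reference gives coupled
#' genera elevated counts on the KOs of a designated SCFA
#' ("butyrate metabolism") pathway, so the predicted pathway abundance
#' co-varies with the coupled metabolite, and the pathway library
#' places planted diet-affected metabolites into one enriched pathway.
#'
#' @param metabolome result of [generate_metabolome()].
#' @param microbiome result of [generate_microbiome()].
#' @param couplings data.frame with columns `metabolite`, `genus`,
#'   `rho` (each in (-1, 1)).  Default: the first 6 planted
#'   diet-affected metabolites paired with the first 6 planted genera
#'   at rho 0.7.
#' @param n_ko number of KOs in the reference (default 60).
#' @param n_pathways number of KO pathways (default 6; the first is the
#'   designated SCFA pathway).
#' @param seed RNG seed.
#' @return list: `metabolome` (adjusted table), `microbiome` (unchanged
#'   table), `gene_reference` ([gene_content_reference()]),
#'   `pathway_library` ([pathway_library()]), `truth` (couplings,
#'   enriched pathway id, SCFA pathway id, seed).
#' @export
generate_couplings_and_reference <- function(metabolome, microbiome,
                                             couplings = NULL, n_ko = 60,
                                             n_pathways = 6, seed = NULL) {
  mtab <- metabolome$table
  gtab <- microbiome$table
  if (is.null(couplings)) {
    # pair with genera elevated in AD, mirroring the SCFA-producer story:
    # same-direction genera keep the designated pathway's abundance
    # positively associated with each coupled genus
    g_eff <- microbiome$truth$effect_log2fc
    g_up <- names(g_eff)[g_eff > 0]
    if (!length(g_up)) g_up <- microbiome$truth$diet_affected
    nm <- min(6, length(metabolome$truth$diet_affected), length(g_up))
    couplings <- data.frame(
      metabolite = metabolome$truth$diet_affected[seq_len(nm)],
      genus = g_up[seq_len(nm)],
      rho = 0.7, stringsAsFactors = FALSE)
  }
  if (any(abs(couplings$rho) >= 1)) stop("target rho must lie in (-1, 1)")
  if (!all(couplings$metabolite %in% feature_ids(mtab)))
    stop("unknown coupling metabolite(s)")
  if (!all(couplings$genus %in% feature_ids(gtab)))
    stop("unknown coupling genus(es)")
  n <- nrow(mtab$values)
  relab <- sweep(gtab$values, 1, rowSums(gtab$values), "/")
  with_seed(seed, {
    for (i in seq_len(nrow(couplings))) {
      gcol <- relab[, couplings$genus[i]]
      z <- stats::qnorm((rank(gcol, ties.method = "average") - 0.5) / n)
      old <- log(mtab$values[, couplings$metabolite[i]])
      mu <- mean(old, na.rm = TRUE)
      sdv <- max(stats::sd(old, na.rm = TRUE), 0.3, na.rm = TRUE)
      r <- 2 * sin(pi * couplings$rho[i] / 6)
      mtab$values[, couplings$metabolite[i]] <-
        exp(mu + sdv * (r * z + sqrt(1 - r^2) * stats::rnorm(n)))
    }
    genera <- feature_ids(gtab)
    kos <- sprintf("K%05d", seq_len(n_ko))
    pw_ids <- c("pw_butyrate_metabolism",
                sprintf("pw_%02d", seq_len(n_pathways - 1)))
    pathway_map <- stats::setNames(
      as.list(sample(pw_ids, n_ko, replace = TRUE)), kos)
    scfa_kos <- names(pathway_map)[
      vapply(pathway_map, function(p) pw_ids[1] %in% p, TRUE)]
    if (length(scfa_kos) < 3) {          # guarantee the pathway has KOs
      extra <- utils::head(setdiff(kos, scfa_kos), 3 - length(scfa_kos))
      for (k in extra) pathway_map[[k]] <- pw_ids[1]
      scfa_kos <- c(scfa_kos, extra)
    }
    ko_content <- matrix(stats::rpois(length(genera) * n_ko, 1),
                         length(genera), n_ko,
                         dimnames = list(genera, kos))
    ko_content[couplings$genus, scfa_kos] <-
      ko_content[couplings$genus, scfa_kos, drop = FALSE] +
      3 + stats::rpois(length(couplings$genus) * length(scfa_kos), 5)
    copy_number <- stats::setNames(sample(1:7, length(genera),
                                          replace = TRUE), genera)
    ref <- gene_content_reference(copy_number, ko_content, pathway_map)
    # pathway library over the metabolite universe: one planted
    # enriched pathway plus background pathways
    mets <- feature_ids(mtab)
    planted <- metabolome$truth$diet_affected
    enr_members <- unique(c(
      utils::head(planted, 15),
      sample(setdiff(mets, planted), 5)))
    pws <- list(pw_planted = enr_members)
    for (b in seq_len(7))
      pws[[sprintf("pw_bg_%02d", b)]] <-
        sample(mets, sample(15:40, 1))
    lib <- pathway_library(pws, mets)
    list(metabolome = mtab, microbiome = gtab, gene_reference = ref,
         pathway_library = lib,
         truth = list(couplings = couplings,
                      enriched_pathway = "pw_planted",
                      scfa_pathway = pw_ids[1],
                      seed = seed))
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running the full generator chain under
#' sub-seeds derived from one master seed.  All defaults mirror the
#' emulated study design.
#'
#' @param seed master seed.
#' @param ... overrides forwarded to the component generators as
#'   `metabolome = list(...)`, `microbiome = list(...)`,
#'   `couplings = list(...)`, `design = list(...)`.
#' @return list: `meta`, `metabolome`, `microbiome` (count table),
#'   `tree`, `gene_reference`, `pathway_library`, `truth` (merged).
#' @export
generate_dataset <- function(seed = 1, ...) {
  over <- list(...)
  arg <- function(nm) if (!is.null(over[[nm]])) over[[nm]] else list()
  meta <- do.call(generate_design, arg("design"))
  met <- do.call(generate_metabolome,
                 c(list(meta = meta, seed = seed + 101L), arg("metabolome")))
  mic <- do.call(generate_microbiome,
                 c(list(meta = meta, seed = seed + 211L), arg("microbiome")))
  cpl <- do.call(generate_couplings_and_reference,
                 c(list(metabolome = met, microbiome = mic,
                        seed = seed + 307L), arg("couplings")))
  list(meta = meta,
       metabolome = cpl$metabolome,
       microbiome = cpl$microbiome,
       tree = mic$tree,
       gene_reference = cpl$gene_reference,
       pathway_library = cpl$pathway_library,
       truth = list(metabolome = met$truth, microbiome = mic$truth,
                    integration = cpl$truth, master_seed = seed))
}

#' Write a full synthetic dataset to disk in the pipeline's input formats
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param ... forwarded to [generate_dataset()].
#' @return invisibly, the named vector of paths written.
#' @export
write_synthetic_inputs <- function(dir, seed = 1, ...) {
  ds <- generate_dataset(seed = seed, ...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    metabolome = file.path(dir, "metabolome.tsv"),
    counts = file.path(dir, "genus_counts.tsv"),
    meta = file.path(dir, "sample_metadata.tsv"),
    tree = file.path(dir, "genus_tree.nwk"),
    pathways = file.path(dir, "metabolite_pathways.tsv"),
    gene_reference = file.path(dir, "gene_reference"))
  write_feature_table(ds$metabolome, paths[["metabolome"]])
  write_feature_table(ds$microbiome, paths[["counts"]])
  write_sample_metadata(ds$meta, paths[["meta"]])
  write_newick(ds$tree, paths[["tree"]])
  write_pathway_library(ds$pathway_library, paths[["pathways"]])
  write_gene_content_reference(ds$gene_reference, paths[["gene_reference"]])
  invisible(paths)
}
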