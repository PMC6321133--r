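#' @title One-command pipeline
#' @description Runs the full metabologenomic workflow — metabolome
#'   stage, microbiome stage, integration — from a run configuration,
#'   writing all result tables, the network export, a plain-text log
#'   with stage timings, and a JSON manifest with seeds, per-stage
#'   counts and output checksums.
#' @name pipeline_cli
NULL

#' Default run configuration
#'
#' All thresholds of the reference workflow: detection in >= 4 samples
#' per group, PCA loading report at |coefficient| > 0.11, OPLS-DA
#' covariance report at 0.16 (metabolites) / 0.11 (genera), LDA score
#' 2.0, FDR 0.05, rarefaction depth 16,014 reads, and 7/5/3 clusters
#' for the metabolite/genus/gene-set autocorrelation maps.
#'
#' @param inputs named list/vector of input paths (`metabolome`,
#'   `counts`, `meta`, `tree`, `pathways`, `gene_reference`).
#' @param out output directory.
#' @param seed master seed for every stochastic step (rarefaction,
#'   ANOSIM permutations, LDA bootstrap, CV shuffles).
#' @return a config list suitable for [run_pipeline()].
#' @export
default_run_config <- function(inputs, out, seed = 1) {
  list(inputs = as.list(inputs), out = out, seed = seed,
       min_detect = 4, pc_loading_thresh = 0.11,
       oplsda_cov_thresh_metabolome = 0.16,
       oplsda_cov_thresh_genera = 0.11,
       lda_thresh = 2.0, fdr = 0.05, depth = 16014,
       clusters = c(metabolite = 7, taxon = 5, gene_set = 3),
       n_perm = 999, n_orth = 1, n_folds = 7, weighted_normalized = FALSE)
}

.stage_log <- function(con, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  writeLines(line, con)
  message(line)
}

#' Run the full metabologenomic pipeline
#'
#' Executes metabolome statistics (detection filter, Pareto scaling,
#' PCA, OPLS-DA, differential testing, MSEA), microbiome statistics
#' (rarefaction, relative abundance, alpha diversity, unweighted and
#' weighted UniFrac with PCoA and ANOSIM, LDA effect sizes, metagenome
#' prediction) and the integration layer (Procrustes, autocorrelation
#' clusters, cross-block network), writing every result under
#' `config$out`.  Any stage failure aborts with the stage name in the
#' error.
#'
#' @param config a config list from [default_run_config()], or the path
#'   to a YAML file holding one.
#' @return the manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_run_config(config$inputs, config$out,
                                 seed = if (is.null(config$seed)) 1
                                        else config$seed)
  config <- utils::modifyList(defaults, config)
  cl <- unlist(config$clusters)
  if (is.null(names(cl)) || any(!nzchar(names(cl))))
    names(cl) <- c("metabolite", "taxon", "gene_set")
  need <- c("metabolome", "counts", "meta", "tree", "pathways",
            "gene_reference")
  miss <- setdiff(need, names(config$inputs))
  if (length(miss))
    stop("config$inputs lacks: ", paste(miss, collapse = ", "))
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out, "run.log"), "w")
  on.exit(close(logf))
  seed <- as.integer(config$seed)
  manifest <- list(package = "metabologenomics",
                   version = as.character(utils::packageVersion(
                     "metabologenomics")),
                   seed = seed, config = config[setdiff(names(config),
                                                        "inputs")])
  t0 <- Sys.time()
  stage <- function(name, expr) {
    .stage_log(logf, paste("stage:", name))
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    .stage_log(logf, sprintf("stage %s done in %.1fs", name,
                             as.numeric(difftime(Sys.time(), st, "secs"))))
    res
  }

  inp <- stage("read_inputs", {
    list(met = read_feature_table(config$inputs$metabolome, "metabolite",
                                  "concentration"),
         cnt = read_feature_table(config$inputs$counts, "taxon", "count"),
         meta = read_sample_metadata(config$inputs$meta,
                                     group_levels = c("control", "AD")),
         tree = read_newick(config$inputs$tree),
         lib = read_pathway_library(config$inputs$pathways),
         ref = read_gene_content_reference(config$inputs$gene_reference))
  })
  meta <- inp$meta

  ## ---- metabolome stage ----
  met_res <- stage("metabolome", {
    filt <- detection_filter(inp$met, meta, config$min_detect)
    scaled <- pareto_scale(filt)
    ord <- pca(scaled)
    grp <- meta$group[match(sample_ids(scaled), meta$sample_id)]
    opls <- oplsda(scaled, grp, n_orth = config$n_orth,
                   n_folds = config$n_folds, seed = seed + 11L)
    diff <- select_differential(filt, meta, q_thresh = config$fdr)
    enr <- msea_ora(diff$selected, inp$lib)
    list(filtered = filt, scaled = scaled, pca = ord, opls = opls,
         diff = diff, enrichment = enr)
  })
  utils::write.table(met_res$diff$table,
                     file.path(out, "metabolome_differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(met_res$enrichment,
                     file.path(out, "metabolome_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(met_res$pca$scores), met_res$pca$scores),
    file.path(out, "metabolome_pca_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(loading_report(met_res$pca, 2,
                                    config$pc_loading_thresh),
                     file.path(out, "metabolome_pc2_loadings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(covariance_report(met_res$opls,
                                       config$oplsda_cov_thresh_metabolome),
                     file.path(out, "metabolome_oplsda_covariance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- microbiome stage ----
  mic_res <- stage("microbiome", {
    rar <- rarefy(inp$cnt, depth = config$depth, seed = seed + 23L)
    meta_r <- meta[match(sample_ids(rar), meta$sample_id), ]
    relab <- relative_abundance(rar)
    alpha <- alpha_diversity(rar)
    d_u <- unifrac(rar, inp$tree, weighted = FALSE)
    d_w <- unifrac(rar, inp$tree, weighted = TRUE,
                   normalized = isTRUE(config$weighted_normalized))
    an_u <- anosim_test(d_u, meta_r$group, config$n_perm, seed + 31L)
    an_w <- anosim_test(d_w, meta_r$group, config$n_perm, seed + 37L)
    ord_w <- pcoa(d_w, k = 3)
    lda <- lda_effect_size(relab, meta_r$group,
                           threshold = config$lda_thresh, seed = seed + 41L)
    pred <- predict_metagenome(rar, inp$ref)
    diff <- select_differential(relab, meta_r, q_thresh = config$fdr)
    list(rarefied = rar, relab = relab, alpha = alpha,
         unifrac_unweighted = d_u, unifrac_weighted = d_w,
         anosim_unweighted = an_u, anosim_weighted = an_w,
         pcoa_weighted = ord_w, lda = lda, predicted = pred, diff = diff,
         meta = meta_r)
  })
  utils::write.table(mic_res$alpha, file.path(out, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mic_res$diff$table,
                     file.path(out, "genus_differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mic_res$lda, file.path(out, "genus_lda_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(mic_res$pcoa_weighted$scores),
               mic_res$pcoa_weighted$scores),
    file.path(out, "weighted_unifrac_pcoa_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- integration stage ----
  int_res <- stage("integration", {
    common <- intersect(rownames(met_res$pca$scores),
                        rownames(mic_res$pcoa_weighted$scores))
    pro <- procrustes_fit(met_res$pca$scores[common, , drop = FALSE],
                          mic_res$pcoa_weighted$scores[common, , drop = FALSE],
                          k = 3)
    pw_relab <- relative_abundance(mic_res$predicted$pathway_table)
    gs_diff <- select_differential(pw_relab, mic_res$meta,
                                   q_thresh = config$fdr)
    blocks <- list(metabolite = met_res$diff$subset,
                   taxon = mic_res$diff$subset,
                   gene_set = gs_diff$subset)
    nonempty <- vapply(blocks, function(b) ncol(b$values) > 0, TRUE)
    clusters <- list()
    for (nm in names(blocks)[nonempty]) {
      cm <- autocorrelation_map(blocks[[nm]])
      kk <- min(cl[[nm]], ncol(blocks[[nm]]$values))
      clusters[[nm]] <- hca_clusters(cm, kk)
    }
    directions <- c(
      stats::setNames(met_res$diff$table$direction,
                      met_res$diff$table$feature),
      stats::setNames(mic_res$diff$table$direction,
                      mic_res$diff$table$feature),
      stats::setNames(gs_diff$table$direction, gs_diff$table$feature))
    net <- build_network(blocks[nonempty], q_thresh = config$fdr,
                         clusters = clusters, directions = directions)
    list(procrustes = pro, network = net, clusters = clusters,
         gs_diff = gs_diff)
  })
  write_network(int_res$network, file.path(out, "network"))
  utils::write.table(
    data.frame(sample_id = rownames(int_res$procrustes$reference),
               ref = int_res$procrustes$reference,
               rot = int_res$procrustes$rotated),
    file.path(out, "procrustes_coordinates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cl_df <- do.call(rbind, lapply(names(int_res$clusters), function(nm)
    data.frame(block = nm, feature = names(int_res$clusters[[nm]]),
               cluster = as.integer(int_res$clusters[[nm]]))))
  utils::write.table(cl_df, file.path(out, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- manifest ----
  manifest$counts <- list(
    metabolites_after_filter = ncol(met_res$filtered$values),
    metabolites_significant = length(met_res$diff$selected),
    genera = ncol(mic_res$rarefied$values),
    genera_significant = length(mic_res$diff$selected),
    gene_sets_significant = length(int_res$gs_diff$selected),
    network_nodes = nrow(int_res$network$nodes),
    network_edges = nrow(int_res$network$edges))
  manifest$results <- list(
    oplsda_Q2_cum = met_res$opls$Q2_cum,
    oplsda_R2X_cum = met_res$opls$R2X_cum,
    anosim_unweighted = mic_res$anosim_unweighted,
    anosim_weighted = mic_res$anosim_weighted,
    procrustes_M2 = int_res$procrustes$M2,
    top_enriched_pathway = met_res$enrichment$pathway[1])
  files <- list.files(out, full.names = TRUE)
  files <- setdiff(files, file.path(out, c("manifest.json", "run.log")))
  manifest$artifacts <- lapply(stats::setNames(files, basename(files)),
                               function(f) unname(tools::md5sum(f)))
  manifest$elapsed_seconds <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .stage_log(logf, sprintf("pipeline done in %.1fs",
                           manifest$elapsed_seconds))
  invisible(manifest)
}
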