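#' @title Microbiome stage
#' @description Statistics downstream of a genus/OTU count table:
#'   rarefaction to a common depth, relative abundance, alpha diversity
#'   (observed, Chao1, Shannon), unweighted and weighted UniFrac, PCoA,
#'   ANOSIM, LEfSe-style LDA effect sizes, and PICRUSt-style metagenome
#'   prediction with pathway aggregation.
#' @name microbiome_stage
NULL

#' Rarefy a count table to a fixed depth
#'
#' Reads are subsampled without replacement so that every retained
#' sample sums exactly to `depth` (default 16,014, the filter-passed
#' read count the reference workflow rarefied to).  Samples with fewer
#' total reads are dropped with a warning.
#'
#' @param counts `feature_table` of integer counts.
#' @param depth target reads per sample.
#' @param seed RNG seed for the subsampling.
#' @return rarefied `feature_table`.
#' @export
rarefy <- function(counts, depth = 16014, seed = NULL) {
  if (depth <= 0) stop("depth must be positive")
  v <- counts$values
  if (any(v != round(v), na.rm = TRUE)) stop("counts must be integers")
  tot <- rowSums(v)
  low <- tot < depth
  if (any(low)) {
    warning("dropping ", sum(low), " sample(s) below depth ", depth, ": ",
            paste(rownames(v)[low], collapse = ", "))
    v <- v[!low, , drop = FALSE]
  }
  if (!nrow(v)) stop("no samples at or above the rarefaction depth")
  # rrarefy warns whenever small counts are present; input is validated
  # as observed integer counts above, so the warning carries no signal
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(v, depth)))
  feature_table(out, block = counts$block, unit = "count")
}

#' Convert counts to relative abundances
#'
#' @param counts `feature_table` of non-negative counts with positive
#'   row sums.
#' @return `feature_table` of fractions (rows sum to 1).
#' @export
relative_abundance <- function(counts) {
  v <- counts$values
  rs <- rowSums(v)
  if (any(rs <= 0)) stop("zero-sum sample(s): ",
                         paste(rownames(v)[rs <= 0], collapse = ", "))
  feature_table(sweep(v, 1, rs, "/"), block = counts$block, unit = "fraction")
}

#' Taxa above a mean relative abundance threshold
#'
#' Reproduces "top most-abundant genera" selections: taxa whose average
#' relative abundance across all samples exceeds `min_mean` (default 1%),
#' sorted by decreasing mean.
#'
#' @param relab `feature_table` of fractions.
#' @param min_mean mean-fraction threshold (default 0.01).
#' @return data.frame `taxon`, `mean_abundance`.
#' @export
top_taxa <- function(relab, min_mean = 0.01) {
  m <- colMeans(relab$values)
  sel <- m > min_mean
  out <- data.frame(taxon = names(m)[sel], mean_abundance = unname(m[sel]))
  out[order(-out$mean_abundance), , drop = FALSE]
}

#' Per-sample alpha diversity
#'
#' Observed taxa, bias-corrected Chao1
#' (`S + F1 (F1 - 1) / (2 (F2 + 1))`, via [vegan::estimateR()]) and
#' Shannon entropy (natural log, via [vegan::diversity()]).  Chao1
#' requires integer counts, i.e. a rarefied table.
#'
#' @param counts `feature_table` of integer counts.
#' @return data.frame `sample_id`, `observed`, `chao1`, `shannon`.
#' @export
alpha_diversity <- function(counts) {
  v <- counts$values
  if (any(v != round(v))) stop("chao1 requires integer counts")
  est <- vegan::estimateR(v)
  data.frame(sample_id = rownames(v),
             observed = rowSums(v > 0),
             chao1 = unname(est["S.chao1", ]),
             shannon = unname(vegan::diversity(v, index = "shannon")),
             row.names = NULL)
}

# edge-wise descendant-abundance matrix: rows = tree edges, cols = samples
.edge_abundance <- function(values, tree) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  missing <- setdiff(colnames(values), tips)
  if (length(missing))
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  # node x tip incidence built in postorder, then edge rows taken from
  # each edge's child node
  tr <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tr$Nnode
  desc <- matrix(FALSE, n_node, n_tip)
  desc[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[par, ] <- desc[par, ] | desc[ch, ]
  }
  tip_ab <- matrix(0, n_tip, nrow(values),
                   dimnames = list(tips, rownames(values)))
  tip_ab[colnames(values), ] <- t(values)
  list(edge_ab = desc[tr$edge[, 2], , drop = FALSE] %*% tip_ab,
       lengths = tr$edge.length)
}

#' UniFrac distances
#'
#' Phylogenetic beta diversity between every pair of samples.
#' Unweighted UniFrac is the branch length unique to either sample's
#' taxa divided by the branch length covered by both together (in
#' \[0, 1\]).  Weighted UniFrac is
#' `sum_b l_b |A_b/A_T - B_b/B_T|` over branches b, with `A_b` the
#' abundance below branch b and `A_T` the sample total; `normalized`
#' divides by `sum_b l_b (A_b/A_T + B_b/B_T)`.  The raw
#' (non-normalised) weighted form is the default, matching the
#' historical default of the reference pipeline.
#'
#' @param counts `feature_table`; every taxon must be a tree leaf.
#' @param tree rooted `phylo` with branch lengths.
#' @param weighted abundance-weighted (TRUE) or presence/absence (FALSE).
#' @param normalized for weighted UniFrac, divide by the maximum
#'   attainable value (default FALSE).
#' @return `distance_matrix`: symmetric matrix with zero diagonal.
#' @export
unifrac <- function(counts, tree, weighted = FALSE, normalized = FALSE) {
  v <- counts$values
  ea <- .edge_abundance(v, tree)
  A <- ea$edge_ab; l <- ea$lengths
  n <- ncol(A)
  if (weighted) {
    tot <- rowSums(v)[colnames(A)]
    P <- sweep(A, 2, tot, "/")
  } else {
    P <- A > 0
  }
  d <- matrix(0, n, n, dimnames = list(colnames(A), colnames(A)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (weighted) {
        num <- sum(l * abs(P[, i] - P[, j]))
        d[i, j] <- if (normalized) {
          den <- sum(l * (P[, i] + P[, j]))
          if (den > 0) num / den else 0
        } else num
      } else {
        uniq <- xor(P[, i], P[, j])
        either <- P[, i] | P[, j]
        den <- sum(l[either])
        d[i, j] <- if (den > 0) sum(l[uniq]) / den else 0
      }
      d[j, i] <- d[i, j]
    }
  }
  structure(d, class = c("distance_matrix", "matrix"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d samples\n", nrow(x)))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x)))])
  invisible(x)
}

#' Principal coordinate analysis
#'
#' Gower double-centring + eigendecomposition via [stats::cmdscale()].
#' Negative eigenvalues are kept in `eigenvalues` rather than silently
#' dropped; explained-variance ratios are taken over the positive
#' eigenvalues.  Axis signs follow the same largest-element-positive
#' convention as [pca()].
#'
#' @param d `distance_matrix` (or anything [stats::as.dist()] accepts).
#' @param k number of coordinates (truncated at n - 1).
#' @return `ordination_result` with `scores` and `eigenvalues`.
#' @export
pcoa <- function(d, k = 2) {
  dd <- stats::as.dist(d)
  n <- attr(dd, "Size")
  k <- min(k, n - 1)
  cm <- stats::cmdscale(dd, k = k, eig = TRUE)
  scores <- cm$points
  colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  pos <- cm$eig[cm$eig > 0]
  structure(list(scores = scores, loadings = NULL,
                 explained_variance_ratio = cm$eig[seq_len(k)] / sum(pos),
                 eigenvalues = cm$eig),
            class = "ordination_result")
}

#' ANOSIM: analysis of similarities
#'
#' Rank-based permutation test of whether between-group distances
#' exceed within-group distances; `R = (mean rank between - mean rank
#' within) / (M/2)` with `M = n(n-1)/2`, and
#' `p = (1 + #{perm R >= obs}) / (1 + n_perm)`.  Delegates to
#' [vegan::anosim()] under a local seed.
#'
#' @param d `distance_matrix`.
#' @param groups factor with >= 2 members per level.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list `R`, `p`, `n_perm`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = NULL) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2) stop("ANOSIM needs at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  fit <- with_seed(seed,
                   vegan::anosim(stats::as.dist(d), groups,
                                 permutations = n_perm))
  list(R = unname(fit$statistic), p = fit$signif, n_perm = n_perm)
}

#' LEfSe-style LDA effect sizes for two classes
#'
#' The published two-class recipe: per-sample values are scaled to sum
#' to one million; features are screened by Kruskal-Wallis at
#' `alpha` (equivalent to Mann-Whitney for two groups); surviving
#' features enter `n_boot` bootstrap rounds in which two thirds of each
#' class is drawn, a linear discriminant is fitted, and a per-feature
#' effect size is taken as the mean of the absolute class-mean
#' difference and the feature's discriminant contribution.  The LDA
#' score is `log10` of the bootstrap-averaged effect, signed by the
#' enriched class; features with `|score| > threshold` are reported.
#' The multi-subclass Wilcoxon step of the original tool is omitted:
#' this design has no subclasses.
#'
#' @param relab `feature_table` of relative abundances (fractions).
#' @param groups two-level factor aligned with the samples.
#' @param n_boot bootstrap rounds (default 30).
#' @param threshold `|log10 LDA score|` cut-off (default 2.0).
#' @param alpha Kruskal-Wallis screening level (default 0.05).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame `feature`, `lda_score`, `direction`.
#' @export
lda_effect_size <- function(relab, groups, n_boot = 30, threshold = 2.0,
                            alpha = 0.05, seed = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly 2 groups required")
  v <- relab$values * 1e6
  keep <- apply(v, 2, stats::sd) > 0
  v <- v[, keep, drop = FALSE]
  pk <- apply(v, 2, function(col)
    stats::kruskal.test(col, groups)$p.value)
  v <- v[, pk < alpha, drop = FALSE]
  if (!ncol(v))
    return(data.frame(feature = character(), lda_score = numeric(),
                      direction = character()))
  g1 <- groups == levels(groups)[1]
  eff <- matrix(NA_real_, n_boot, ncol(v))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      i1 <- sample(which(g1), max(2, floor(sum(g1) * 2 / 3)))
      i2 <- sample(which(!g1), max(2, floor(sum(!g1) * 2 / 3)))
      idx <- c(i1, i2)
      xb <- v[idx, , drop = FALSE]
      # tiny jitter keeps within-class covariance non-singular
      xb <- xb + matrix(stats::rnorm(length(xb), 0, 1e-6 * max(xb)),
                        nrow(xb))
      fit <- tryCatch(
        suppressWarnings(MASS::lda(xb, grouping = droplevels(groups[idx]),
                                   tol = 1e-10)),
        error = function(e) NULL)
      if (is.null(fit)) next
      w <- fit$scaling[, 1]
      w_unit <- w / sqrt(sum(w^2))
      m1 <- colMeans(xb[seq_along(i1), , drop = FALSE])
      m2 <- colMeans(xb[-seq_along(i1), , drop = FALSE])
      ld_gap <- abs(sum(w_unit * (m1 - m2)))
      eff[b, ] <- (abs(m1 - m2) + abs(w_unit) * ld_gap) / 2
    }
  })
  mean_eff <- colMeans(eff, na.rm = TRUE)
  mean_eff[!is.finite(mean_eff)] <- 0
  dir_up1 <- colMeans(v[g1, , drop = FALSE]) >
    colMeans(v[!g1, , drop = FALSE])
  score <- ifelse(dir_up1, 1, -1) * log10(pmax(mean_eff, 1e-10))
  sel <- abs(score) > threshold
  out <- data.frame(
    feature = colnames(v)[sel],
    lda_score = unname(score[sel]),
    direction = ifelse(dir_up1[sel], levels(groups)[1], levels(groups)[2]),
    stringsAsFactors = FALSE)
  out[order(-abs(out$lda_score)), , drop = FALSE]
}

#' Predict metagenome content from taxon counts
#'
#' PICRUSt-style arithmetic: taxon counts are divided by their 16S
#' copy numbers, the normalised abundances are multiplied by the
#' reference taxon x KO gene-content matrix, and KO abundances are
#' aggregated into pathways via the KO -> pathway map (a KO mapped to
#' several pathways contributes to each).
#'
#' @param counts `feature_table` of taxon counts.
#' @param ref a [gene_content_reference()].
#' @param strict error on taxa missing from the reference (TRUE,
#'   default) or drop them with a warning (FALSE).
#' @return list with `ko_table` and `pathway_table`, both
#'   `feature_table`s of block `"gene_set"`.
#' @export
predict_metagenome <- function(counts, ref, strict = TRUE) {
  v <- counts$values
  missing <- setdiff(colnames(v), rownames(ref$ko_content))
  if (length(missing)) {
    if (strict) stop("taxa missing from the reference: ",
                     paste(missing, collapse = ", "))
    warning("dropping ", length(missing), " taxa missing from the reference")
    v <- v[, setdiff(colnames(v), missing), drop = FALSE]
  }
  cn <- ref$copy_number[colnames(v)]
  norm <- sweep(v, 2, cn, "/")
  ko <- norm %*% ref$ko_content[colnames(v), , drop = FALSE]
  pw_ids <- sort(unique(unlist(ref$pathway_map)))
  pw <- matrix(0, nrow(ko), length(pw_ids),
               dimnames = list(rownames(ko), pw_ids))
  for (k in colnames(ko)) {
    for (p in ref$pathway_map[[k]]) pw[, p] <- pw[, p] + ko[, k]
  }
  list(ko_table = feature_table(ko, block = "gene_set", unit = "count"),
       pathway_table = feature_table(pw, block = "gene_set", unit = "count"))
}
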