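#' @title Integration stage
#' @description The metabologenomic layer: Procrustes superimposition of
#'   the metabolome PCA on the microbiome PCoA, block-wise Spearman
#'   autocorrelation maps cut into a fixed number of clusters, selection
#'   of diet-differential features by Mann-Whitney + Benjamini-Hochberg,
#'   and the cross-block Spearman correlation network at FDR < 0.05.
#' @name integration_stage
NULL

#' Procrustes superimposition of two ordinations
#'
#' Least-squares Procrustes with translation, uniform scaling and
#' rotation/reflection (the symmetric form of [vegan::procrustes()], in
#' which both configurations are standardised, so the fit statistic does
#' not depend on which ordination is called the reference).  `M2` is the
#' residual sum of squared deviations over the first `min(k, 3)`
#' dimensions; 0 means the configurations are identical up to a
#' similarity transform.
#'
#' @param coords_a reference coordinates (by convention the metabolome
#'   PCA scores), samples x dimensions, rownames = sample ids.
#' @param coords_b coordinates rotated onto the reference (the
#'   microbiome PCoA scores).
#' @param k number of leading dimensions compared (default 3).
#' @return `procrustes_result`: `M2`, `reference` and `rotated`
#'   coordinates, `k`.
#' @export
procrustes_fit <- function(coords_a, coords_b, k = 3) {
  if (is.null(rownames(coords_a)) || is.null(rownames(coords_b)) ||
      !identical(rownames(coords_a), rownames(coords_b)))
    stop("coordinate sets must share the same samples in the same order")
  k <- min(k, ncol(coords_a), ncol(coords_b))
  if (k < 2) stop("need at least 2 shared dimensions")
  a <- coords_a[, seq_len(k), drop = FALSE]
  b <- coords_b[, seq_len(k), drop = FALSE]
  pr <- vegan::procrustes(a, b, symmetric = TRUE)
  structure(list(M2 = pr$ss, reference = pr$X, rotated = pr$Yrot, k = k),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes_result> M2 = %.4g over first %d dimensions\n",
              x$M2, x$k))
  invisible(x)
}

#' Spearman autocorrelation map of a feature table
#'
#' Feature x feature matrix of Spearman rank correlations (Pearson on
#' midranks, identical to element-wise [spearman_rho()]).  Constant
#' features yield undefined entries; they are left `NA` and listed in
#' the `"constant_features"` attribute.  The diagonal is 1 for every
#' non-constant feature.
#'
#' @param tbl `feature_table` with >= 3 samples.
#' @return symmetric correlation matrix.
#' @export
autocorrelation_map <- function(tbl) {
  v <- tbl$values
  if (nrow(v) < 3) stop("need at least 3 samples")
  r <- suppressWarnings(stats::cor(v, method = "spearman",
                                   use = "pairwise.complete.obs"))
  const <- apply(v, 2, function(col) stats::sd(rank(col[!is.na(col)])) == 0)
  diag(r)[!const] <- 1
  attr(r, "constant_features") <- colnames(v)[const]
  r
}

#' Cut a correlation map into exactly k clusters
#'
#' Rows of the correlation matrix are treated as feature profiles,
#' their Euclidean distances are clustered agglomeratively (complete
#' linkage by default) and the tree is cut to exactly `k` clusters.
#' Cluster labels are renumbered by first appearance in feature order,
#' which makes the labelling deterministic.
#'
#' @param corr correlation matrix from [autocorrelation_map()] (or a raw
#'   profile matrix when clustering abundances directly).
#' @param k number of clusters (7 metabolite, 5 genus and 3 gene-set
#'   clusters in the reference workflow).
#' @param method agglomeration method for [stats::hclust()].
#' @return named integer vector (feature -> cluster in 1..k) of class
#'   `cluster_assignment`.
#' @export
hca_clusters <- function(corr, k, method = "complete") {
  if (k < 1) stop("k must be >= 1")
  m <- as.matrix(corr)
  if (anyNA(m)) {
    drop <- unique(which(is.na(m), arr.ind = TRUE)[, 1])
    stop("undefined correlations for features: ",
         paste(rownames(m)[drop], collapse = ", "))
  }
  if (k > nrow(m)) stop("k exceeds the number of features")
  hc <- stats::hclust(stats::dist(m), method = method)
  raw <- stats::cutree(hc, k = k)
  relabel <- match(raw, unique(raw[rownames(m)]))
  names(relabel) <- rownames(m)
  structure(relabel, class = "cluster_assignment", k = k)
}

#' Select features that differ between the diet groups
#'
#' Per feature: two-sided Mann-Whitney U on the two groups, BH
#' adjustment within the block, selection at `q < q_thresh`.  The fold
#' change is `mean(AD) / mean(control)` (second group level over first);
#' when the control mean is zero the reported label is `"-"`, matching
#' how such taxa are tabulated.  Observations from all timepoints are
#' pooled by default; `per_subject = TRUE` first averages repeated
#' measures within each mouse.
#'
#' @param tbl `feature_table`.
#' @param meta sample metadata.
#' @param q_thresh BH FDR threshold (default 0.05).
#' @param per_subject aggregate to per-subject means before testing.
#' @return list: `table` (data.frame `feature`, `U`, `p`, `q`,
#'   `fold_change`, `fold_label`, `direction`), `selected` feature ids,
#'   `subset` the selected columns of `tbl`.
#' @export
select_differential <- function(tbl, meta, q_thresh = 0.05,
                                per_subject = FALSE) {
  v <- tbl$values
  meta <- meta[match(rownames(v), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("samples missing from metadata")
  grp <- meta$group
  if (per_subject) {
    agg <- stats::aggregate(v, by = list(subject = meta$subject_id), FUN = mean,
                            na.rm = TRUE)
    grp <- meta$group[match(agg$subject, meta$subject_id)]
    v <- as.matrix(agg[, -1, drop = FALSE])
    rownames(v) <- agg$subject
  }
  ctrl <- grp == levels(grp)[1]
  rows <- lapply(seq_len(ncol(v)), function(j) {
    xc <- v[ctrl, j]; xa <- v[!ctrl, j]
    mw <- mann_whitney_u(xa, xc)   # U reported for the AD group
    mc <- mean(xc, na.rm = TRUE); ma <- mean(xa, na.rm = TRUE)
    fold <- if (mc == 0) NA_real_ else ma / mc
    data.frame(feature = colnames(v)[j], U = mw$U, p = mw$p,
               fold_change = fold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$fold_label <- ifelse(is.na(out$fold_change), "-",
                           sprintf("%.2f", out$fold_change))
  out$direction <- ifelse(is.na(out$fold_change) | out$fold_change > 1,
                          levels(grp)[2], levels(grp)[1])
  out <- out[, c("feature", "U", "p", "q", "fold_change", "fold_label",
                 "direction")]
  selected <- out$feature[!is.na(out$q) & out$q < q_thresh]
  list(table = out, selected = selected,
       subset = subset_table(tbl, features = selected))
}

# vectorised Spearman rho + t-approximation p for all column pairs of
# two matrices (consistent with spearman_rho element-wise)
.spearman_block <- function(a, b) {
  ra <- apply(a, 2, rank)
  rb <- apply(b, 2, rank)
  n <- nrow(a)
  rho <- suppressWarnings(stats::cor(ra, rb))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p)
}

#' Cross-block Spearman correlation network at a joint FDR
#'
#' Spearman rho and p are computed for every pair of features from
#' different blocks (within-block pairs optionally included), all
#' computed p-values are BH-adjusted in a single family, and pairs at
#' `q < q_thresh` become signed edges.  Nodes carry their block, their
#' autocorrelation-map cluster and their direction of change between
#' the diet groups.  Intended input is the diet-differential subset of
#' each block (see [select_differential()]).
#'
#' @param blocks named list of `feature_table`s (>= 2) sharing samples;
#'   names are used in the node annotation when a table's `block` label
#'   is ambiguous.
#' @param q_thresh BH FDR threshold for edges (default 0.05).
#' @param within_block also test pairs inside the same block
#'   (default FALSE; the portrayed network is cross-block).
#' @param clusters optional named list (same names as `blocks`) of
#'   [hca_clusters()] assignments.
#' @param directions optional named character vector feature ->
#'   enriched group.
#' @return a [correlation_network()].  The full tested pair list with
#'   rho, p, q is attached as attribute `"pairs"`.
#' @export
build_network <- function(blocks, q_thresh = 0.05, within_block = FALSE,
                          clusters = NULL, directions = NULL) {
  if (length(blocks) < 2) stop("need at least 2 blocks")
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    stop("`blocks` must be a named list")
  shared <- Reduce(intersect, lapply(blocks, sample_ids))
  if (!length(shared)) stop("blocks share no samples")
  vals <- lapply(blocks, function(b) b$values[shared, , drop = FALSE])
  all_feat <- unlist(lapply(vals, colnames), use.names = FALSE)
  if (anyDuplicated(all_feat))
    stop("feature ids must be unique across blocks")
  bl <- names(blocks)
  pairs <- NULL
  idx <- if (within_block) {
    cbind(rep(seq_along(bl), each = length(bl)),
          rep(seq_along(bl), length(bl)))
  } else {
    t(utils::combn(seq_along(bl), 2))
  }
  idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (i == j && !within_block) next
    sb <- .spearman_block(vals[[i]], vals[[j]])
    df <- data.frame(
      source = rep(colnames(vals[[i]]), times = ncol(vals[[j]])),
      target = rep(colnames(vals[[j]]), each = ncol(vals[[i]])),
      rho = as.vector(sb$rho), p = as.vector(sb$p),
      stringsAsFactors = FALSE)
    if (i == j)
      df <- df[match(df$source, colnames(vals[[i]])) <
                 match(df$target, colnames(vals[[j]])), , drop = FALSE]
    pairs <- rbind(pairs, df)
  }
  undef <- is.na(pairs$rho)
  if (any(undef)) {
    warning(sum(undef), " pairs with undefined correlation excluded")
    pairs <- pairs[!undef, , drop = FALSE]
  }
  pairs$q <- bh_fdr(pairs$p)
  edges <- pairs[pairs$q < q_thresh, , drop = FALSE]
  edges$sign <- ifelse(edges$rho >= 0, 1, -1)
  block_of <- rep(bl, vapply(vals, ncol, 1L))
  names(block_of) <- all_feat
  cl <- rep(NA_character_, length(all_feat)); names(cl) <- all_feat
  if (!is.null(clusters)) {
    for (nm in names(clusters)) {
      a <- clusters[[nm]]
      cl[names(a)] <- paste0(nm, "_", unclass(a))
    }
  }
  dir <- rep(NA_character_, length(all_feat)); names(dir) <- all_feat
  if (!is.null(directions)) {
    common <- intersect(names(directions), all_feat)
    dir[common] <- directions[common]
  }
  nodes <- data.frame(feature = all_feat, block = unname(block_of),
                      cluster = unname(cl), direction = unname(dir),
                      stringsAsFactors = FALSE)
  net <- correlation_network(nodes,
                             edges[, c("source", "target", "rho", "q",
                                       "sign")])
  attr(net, "pairs") <- pairs
  net
}
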