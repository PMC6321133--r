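#' @title Metabolome stage
#' @description From raw CE-TOFMS-style peak areas to statistics:
#'   internal-standard quantification, the "detected in at least 4
#'   samples per group" filter, half-minimum imputation, Pareto scaling,
#'   PCA with a loading report, OPLS-DA with covariance ranking and a
#'   cross-validated Q2, and hypergeometric metabolite-set enrichment
#'   (MSEA in over-representation mode).
#' @name metabolome_stage
NULL

#' Quantify metabolites against internal standards
#'
#' Each metabolite is referenced to the internal standard of its ion
#' mode (cationic: methionine sulfone; anionic: CSA).  The concentration
#' is `(area / IS_area) / standard_relative_area * standard_concentration`,
#' in the unit of the supplied standard concentrations (nmol per g feces
#' once sample masses are folded into the standards table).  Samples
#' missing an internal-standard area are rejected with a warning.
#'
#' @param peak_areas `feature_table` of raw peak areas (unit `"area"`).
#' @param is_areas matrix or data.frame of internal-standard areas, one
#'   row per sample (rownames = sample ids), columns `cationic` and
#'   `anionic`.
#' @param standards data.frame with columns `metabolite`, `ion_mode`
#'   (`"cationic"`/`"anionic"`), `std_relative_area`, `std_concentration`.
#' @return `feature_table` of concentrations.
#' @export
quantify <- function(peak_areas, is_areas, standards) {
  stopifnot(inherits(peak_areas, "feature_table"))
  v <- peak_areas$values
  is_areas <- as.matrix(is_areas)
  if (!all(c("cationic", "anionic") %in% colnames(is_areas)))
    stop("is_areas needs columns 'cationic' and 'anionic'")
  is_areas <- is_areas[rownames(v), c("cationic", "anionic"), drop = FALSE]
  bad <- rowSums(!is.finite(is_areas) | is_areas <= 0) > 0
  if (any(bad)) {
    warning("rejecting ", sum(bad),
            " sample(s) with missing internal-standard areas: ",
            paste(rownames(v)[bad], collapse = ", "))
    v <- v[!bad, , drop = FALSE]
    is_areas <- is_areas[!bad, , drop = FALSE]
  }
  std <- standards[match(colnames(v), standards$metabolite), ]
  if (anyNA(std$metabolite))
    stop("standards table lacks entries for: ",
         paste(setdiff(colnames(v), standards$metabolite), collapse = ", "))
  mode_col <- ifelse(std$ion_mode == "cationic", 1L, 2L)
  conc <- v
  for (j in seq_len(ncol(v))) {
    conc[, j] <- (v[, j] / is_areas[, mode_col[j]]) /
      std$std_relative_area[j] * std$std_concentration[j]
  }
  feature_table(conc, block = "metabolite", unit = "concentration")
}

#' Detection filter: keep metabolites seen in enough samples per group
#'
#' A metabolite is retained only if it is detected (non-`NA`) in at
#' least `min_per_group` samples in *every* group.  Column order is
#' preserved, and the filter is idempotent.
#'
#' @param tbl `feature_table` with `NA` marking "not detected".
#' @param meta sample metadata (see [read_sample_metadata()]).
#' @param min_per_group minimum detections per group; default 4.
#' @return filtered `feature_table`.
#' @export
detection_filter <- function(tbl, meta, min_per_group = 4) {
  v <- tbl$values
  grp <- meta$group[match(rownames(v), meta$sample_id)]
  if (anyNA(grp)) stop("samples missing from metadata")
  if (any(table(grp) < min_per_group))
    stop("a group has fewer than ", min_per_group, " samples in total")
  detected <- !is.na(v)
  keep <- rep(TRUE, ncol(v))
  for (g in levels(grp)) {
    keep <- keep & colSums(detected[grp == g, , drop = FALSE]) >= min_per_group
  }
  subset_table(tbl, features = which(keep))
}

#' Impute "not detected" cells as half the per-feature minimum
#'
#' Standard metabolomics practice ahead of scaling and ordination:
#' every `NA` in a column becomes half that column's minimum observed
#' value.
#'
#' @param tbl `feature_table`.
#' @return `feature_table` with no `NA` cells.
#' @export
impute_half_min <- function(tbl) {
  v <- tbl$values
  for (j in seq_len(ncol(v))) {
    nas <- is.na(v[, j])
    if (any(nas)) {
      if (all(nas)) stop("feature ", colnames(v)[j], " has no detected value")
      v[nas, j] <- min(v[, j], na.rm = TRUE) / 2
    }
  }
  out <- tbl
  out$values <- v
  out
}

#' Pareto scaling
#'
#' Per feature: subtract the mean and divide by the square root of the
#' sample standard deviation (n-1).  Pareto scaling shrinks the
#' dominance of high-variance metabolites without amplifying noise the
#' way unit-variance scaling does.  Zero-variance features are centred
#' only and listed in the `"constant_features"` attribute.
#'
#' @param tbl `feature_table` without missing values (see
#'   [impute_half_min()]).
#' @param impute impute `NA` cells first via [impute_half_min()]
#'   (default TRUE).
#' @return `feature_table`, unit `"scaled"`, column means 0.
#' @export
pareto_scale <- function(tbl, impute = TRUE) {
  if (impute && anyNA(tbl$values)) tbl <- impute_half_min(tbl)
  v <- tbl$values
  if (anyNA(v)) stop("missing values; impute before scaling")
  mu <- colMeans(v)
  sdev <- apply(v, 2, stats::sd)
  const <- sdev == 0
  sc <- sweep(v, 2, mu, "-")
  sc[, !const] <- sweep(sc[, !const, drop = FALSE], 2,
                        sqrt(sdev[!const]), "/")
  out <- feature_table(sc, block = tbl$block, unit = "scaled")
  attr(out, "constant_features") <- colnames(v)[const]
  out
}

#' Principal component analysis of a scaled table
#'
#' SVD-based (no further centring or scaling: apply [pareto_scale()]
#' first).  Axis signs are made deterministic by flipping each component
#' so that its largest-magnitude loading is positive.
#'
#' @param tbl scaled `feature_table`.
#' @param k number of components to keep (truncated at the matrix rank).
#' @return an `ordination_result`: `scores` (samples x components),
#'   `loadings` (features x components), `explained_variance_ratio`.
#' @export
pca <- function(tbl, k = NULL) {
  v <- tbl$values
  pr <- stats::prcomp(v, center = FALSE, scale. = FALSE)
  var_all <- pr$sdev^2
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-12)
  k <- if (is.null(k)) rank else min(k, rank)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = var_all[seq_len(k)] / sum(var_all),
                 eigenvalues = var_all),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d samples, %d components (%.1f%% var)\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Report features whose loading magnitude exceeds a threshold
#'
#' Reproduces the bar-graph selection style of the loading plots:
#' features with `|coefficient| > threshold` on a chosen component,
#' sorted by the signed coefficient.
#'
#' @param ord an `ordination_result` from [pca()].
#' @param component which component (default 2, the diet axis in this
#'   design).
#' @param threshold loading magnitude cut-off (default 0.11).
#' @return data.frame with `feature`, `coefficient`.
#' @export
loading_report <- function(ord, component = 2, threshold = 0.11) {
  co <- ord$loadings[, component]
  sel <- abs(co) > threshold
  out <- data.frame(feature = names(co)[sel], coefficient = unname(co[sel]))
  out[order(out$coefficient, decreasing = TRUE), , drop = FALSE]
}

# one O-PLS fit on centred X, y: returns predictive weights/scores and
# the orthogonal filter needed to project new samples
.opls_fit <- function(X, y, n_orth) {
  w <- drop(crossprod(X, y)) / drop(crossprod(y))
  w <- w / sqrt(sum(w^2))
  W_orth <- matrix(0, ncol(X), n_orth)
  P_orth <- matrix(0, ncol(X), n_orth)
  T_orth <- matrix(0, nrow(X), n_orth)
  Xf <- X
  for (a in seq_len(n_orth)) {
    t <- drop(Xf %*% w)
    p <- drop(crossprod(Xf, t)) / sum(t^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) {            # no orthogonal variation left
      W_orth <- W_orth[, seq_len(a - 1), drop = FALSE]
      P_orth <- P_orth[, seq_len(a - 1), drop = FALSE]
      T_orth <- T_orth[, seq_len(a - 1), drop = FALSE]
      break
    }
    w_o <- w_o / nw
    t_o <- drop(Xf %*% w_o)
    p_o <- drop(crossprod(Xf, t_o)) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    W_orth[, a] <- w_o; P_orth[, a] <- p_o; T_orth[, a] <- t_o
  }
  t_pred <- drop(Xf %*% w)
  p_pred <- drop(crossprod(Xf, t_pred)) / sum(t_pred^2)
  c_pred <- drop(crossprod(y, t_pred)) / sum(t_pred^2)
  list(w = w, W_orth = W_orth, P_orth = P_orth, T_orth = T_orth,
       t_pred = t_pred, p_pred = p_pred, c_pred = c_pred, X_filtered = Xf)
}

# apply a fitted orthogonal filter to new (centred) samples and return
# predictive scores
.opls_project <- function(fit, Xnew) {
  Xf <- Xnew
  if (ncol(fit$W_orth) > 0) {
    for (a in seq_len(ncol(fit$W_orth))) {
      t_o <- drop(Xf %*% fit$W_orth[, a])
      Xf <- Xf - tcrossprod(t_o, fit$P_orth[, a])
    }
  }
  drop(Xf %*% fit$w)
}

#' OPLS-DA: orthogonal projections to latent structures, two classes
#'
#' NIPALS O-PLS in the Trygg-Wold formulation: class-orthogonal
#' variation is stripped from X component by component, then a single
#' predictive component is extracted.  Features are ranked by their
#' covariance with the predictive score (the x-axis of an S-plot), and
#' the predictive ability Q2 is estimated by k-fold cross-validation
#' with venetian-blind fold assignment after a seeded shuffle.
#'
#' @param tbl scaled `feature_table`.
#' @param groups two-level factor aligned with the table's samples.
#' @param n_orth number of orthogonal components (default 1).
#' @param n_folds cross-validation folds for Q2 (default 7); reduced
#'   with a message when there are fewer samples than folds.
#' @param seed seed for the CV shuffle.
#' @return `oplsda_result`: `t_pred`, `t_orth`, `covariance` (named, per
#'   feature), `correlation`, `Q2_cum`, `R2X_cum`.
#' @export
oplsda <- function(tbl, groups, n_orth = 1, n_folds = 7, seed = NULL) {
  v <- tbl$values
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("OPLS-DA needs exactly 2 groups")
  if (length(groups) != nrow(v)) stop("groups must match samples")
  y_raw <- ifelse(groups == levels(groups)[2], 1, -1)
  y <- y_raw - mean(y_raw)
  X <- sweep(v, 2, colMeans(v), "-")
  fit <- .opls_fit(X, y, n_orth)
  n <- nrow(X)
  covariance <- drop(crossprod(X, fit$t_pred)) / (n - 1)
  names(covariance) <- colnames(v)
  sd_t <- stats::sd(fit$t_pred)
  sd_x <- apply(X, 2, stats::sd)
  correlation <- ifelse(sd_x > 0, covariance / (sd_t * sd_x), NA_real_)
  # explained X variance of the model components (predictive + orthogonal)
  ssx <- sum(X^2)
  E <- fit$X_filtered - tcrossprod(fit$t_pred, fit$p_pred)
  R2X_cum <- 1 - sum(E^2) / ssx
  # Q2 by k-fold CV
  if (n_folds > n) {
    message("reducing CV folds from ", n_folds, " to ", n)
    n_folds <- n
  }
  press <- 0
  with_seed(seed, {
    ord <- sample(n)
    fold <- integer(n)
    fold[ord] <- rep_len(seq_len(n_folds), n)
    for (f in seq_len(n_folds)) {
      te <- fold == f
      Xtr <- v[!te, , drop = FALSE]
      mu <- colMeans(Xtr)
      Xtr <- sweep(Xtr, 2, mu, "-")
      ytr <- y_raw[!te]; ymu <- mean(ytr)
      ftr <- .opls_fit(Xtr, ytr - ymu, n_orth)
      Xte <- sweep(v[te, , drop = FALSE], 2, mu, "-")
      t_te <- .opls_project(ftr, Xte)
      yhat <- t_te * ftr$c_pred + ymu
      press <- press + sum((y_raw[te] - yhat)^2)
    }
  })
  Q2_cum <- 1 - press / sum((y_raw - mean(y_raw))^2)
  structure(list(t_pred = fit$t_pred, t_orth = fit$T_orth,
                 covariance = covariance, correlation = correlation,
                 Q2_cum = Q2_cum, R2X_cum = R2X_cum,
                 groups = groups),
            class = "oplsda_result")
}

#' @export
print.oplsda_result <- function(x, ...) {
  cat(sprintf(
    "<oplsda_result> 1 predictive + %d orthogonal | Q2(cum)=%.3f R2X(cum)=%.3f\n",
    ncol(x$t_orth), x$Q2_cum, x$R2X_cum))
  invisible(x)
}

#' Features over an OPLS-DA covariance threshold
#' @param fit an `oplsda_result`.
#' @param threshold covariance magnitude cut-off (0.16 for metabolites,
#'   0.11 for genera in the reference workflow).
#' @return data.frame `feature`, `covariance`, sorted by signed value.
#' @export
covariance_report <- function(fit, threshold = 0.16) {
  co <- fit$covariance
  sel <- !is.na(co) & abs(co) > threshold
  out <- data.frame(feature = names(co)[sel], covariance = unname(co[sel]))
  out[order(out$covariance, decreasing = TRUE), , drop = FALSE]
}

#' Metabolite set enrichment (over-representation analysis)
#'
#' For each pathway in the library: `K` = pathway size, `k` = hits in
#' the query, `expect = K * n / N` (chance-level hit count given query
#' size `n` and universe `N`), `fold = k / expect`, and a hypergeometric
#' upper-tail p-value.  Query metabolites outside the library universe
#' are dropped with a warning.  Rows come back sorted by p.
#'
#' @param query character vector of significant metabolites.
#' @param lib a [pathway_library()].
#' @return data.frame with columns `pathway`, `total`, `hits`, `expect`,
#'   `fold`, `p`, `hit_metabolites`.
#' @export
msea_ora <- function(query, lib) {
  if (!length(query)) stop("empty query set")
  query <- unique(query)
  outside <- setdiff(query, lib$universe)
  if (length(outside)) {
    warning(length(outside), " query metabolites outside the library universe")
    query <- intersect(query, lib$universe)
  }
  if (!length(query)) stop("no query metabolites in the library universe")
  N <- length(lib$universe); n <- length(query)
  rows <- lapply(names(lib$pathways), function(pw) {
    members <- lib$pathways[[pw]]
    K <- length(members)
    hit <- intersect(query, members)
    k <- length(hit)
    expect <- K * n / N
    data.frame(pathway = pw, total = K, hits = k, expect = expect,
               fold = if (expect > 0) k / expect else NA_real_,
               p = hypergeom_upper_tail(N, K, n, k),
               hit_metabolites = paste(hit, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, -out$fold), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
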