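test_that("procrustes M2 is zero under similarity transforms", {
  set.seed(2)
  a <- matrix(rnorm(30), 10, 3, dimnames = list(sprintf("s%02d", 1:10),
                                                NULL))
  expect_equal(procrustes_fit(a, a)$M2, 0, tolerance = 1e-12)
  # rotate + scale + translate
  th <- 0.7
  R <- diag(3); R[1:2, 1:2] <- matrix(c(cos(th), sin(th),
                                        -sin(th), cos(th)), 2)
  b <- 2.5 * a %*% R + matrix(c(3, -1, 7), 10, 3, byrow = TRUE)
  expect_lt(procrustes_fit(a, b)$M2, 1e-10)
  # invariance of M2 when a common transform hits both inputs
  set.seed(4)
  b2 <- a + matrix(rnorm(30, 0, 0.5), 10)
  m_ref <- procrustes_fit(a, b2)$M2
  a_t <- 0.3 * a %*% R + 1; b_t <- 0.3 * b2 %*% R + 1
  expect_equal(procrustes_fit(a_t, b_t)$M2, m_ref, tolerance = 1e-10)
  expect_error(procrustes_fit(a, b[c(2, 1, 3:10), ]), "same samples")
})

test_that("procrustes matches a grid-search oracle on a planar example", {
  a <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE,
              dimnames = list(letters[1:4], NULL))
  set.seed(6)
  b <- a + matrix(rnorm(8, 0, 0.3), 4)
  dimnames(b) <- dimnames(a)
  m_impl <- procrustes_fit(a, b, k = 2)$M2
  m_grid <- procrustes_grid_M2(a, b)
  expect_equal(m_impl, m_grid, tolerance = 1e-4)
})

test_that("autocorrelation map equals element-wise Spearman calls", {
  set.seed(10)
  v <- matrix(rnorm(24), 8, 3,
              dimnames = list(sprintf("s%d", 1:8), c("f1", "f2", "f3")))
  v[, 3] <- -v[, 1] + rnorm(8, 0, 0.01)
  r <- autocorrelation_map(toy_table(v, unit = "scaled"))
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(r[i, j], spearman_rho(v[, i], v[, j])$rho)
  # identical features correlate at 1, negated features at -1
  v2 <- cbind(v, f4 = v[, 1], f5 = -v[, 1])
  r2 <- autocorrelation_map(toy_table(v2, unit = "scaled"))
  expect_equal(r2["f1", "f4"], 1)
  expect_equal(r2["f1", "f5"], -1)
  # constant feature flagged
  v3 <- cbind(v, cst = 1)
  r3 <- autocorrelation_map(toy_table(v3, unit = "scaled"))
  expect_identical(attr(r3, "constant_features"), "cst")
})

test_that("hierarchical clustering cuts into exactly k faithful clusters", {
  set.seed(12)
  n <- 20
  z1 <- rnorm(n); z2 <- rnorm(n)
  v <- cbind(
    sapply(1:5, function(i) z1 + rnorm(n, 0, 0.1)),
    sapply(1:5, function(i) z2 + rnorm(n, 0, 0.1)))
  dimnames(v) <- list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:10))
  r <- autocorrelation_map(toy_table(v, unit = "scaled"))
  cl <- hca_clusters(r, k = 2)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:5])), 1)
  expect_equal(length(unique(cl[6:10])), 1)
  expect_true(cl[1] != cl[6])
  # first-seen feature gets label 1 (deterministic labelling)
  expect_equal(unname(cl[1]), 1)
  # degenerate cuts
  expect_equal(length(unique(hca_clusters(r, k = 1))), 1)
  expect_equal(length(unique(hca_clusters(r, k = 10))), 10)
  expect_error(hca_clusters(r, k = 0), ">= 1")
  expect_error(hca_clusters(r, k = 11), "exceeds")
})

test_that("differential selection reproduces tabulated fold-change style", {
  meta <- toy_meta(6, 5)
  set.seed(20)
  v <- matrix(rlnorm(11 * 4), 11, 4,
              dimnames = list(meta$sample_id, sprintf("f%d", 1:4)))
  # planted separation, means scaled to the tabulated example
  ctrl <- meta$group == "control"
  v[ctrl, 1] <- c(0.5, 0.6, 0.7, 0.75, 0.8, 0.736) # mean 0.681
  v[!ctrl, 1] <- c(0.1, 0.15, 0.2, 0.25, 0.165)    # mean 0.173
  v[ctrl, 2] <- 0                                  # absent in control
  v[!ctrl, 2] <- c(0.005, 0.006, 0.007, 0.008, 0.009)
  res <- select_differential(toy_table(v), meta, q_thresh = 0.05)
  tab <- res$table
  expect_equal(tab$fold_change[1], 0.173 / 0.681, tolerance = 1e-12)
  expect_equal(tab$fold_label[1], "0.25")
  expect_identical(tab$fold_label[2], "-")          # control mean zero
  expect_true(is.na(tab$fold_change[2]))
  expect_equal(tab$direction[1], "control")
  expect_equal(tab$direction[2], "AD")
  expect_true(all(c("f1", "f2") %in% res$selected))
  expect_true(all(tab$q >= tab$p))
  # identical group distributions select nothing
  v0 <- matrix(rep(c(1:6, 1:5), 3), 11, 3,
               dimnames = list(meta$sample_id, c("a", "b", "c")))
  expect_length(select_differential(toy_table(v0), meta)$selected, 0)
})

test_that("per-subject aggregation collapses repeated measures", {
  meta <- generate_design(n_control = 3, n_ad = 3, weeks = c(8, 12))
  set.seed(33)
  v <- matrix(rlnorm(12 * 3), 12, 3,
              dimnames = list(meta$sample_id, c("a", "b", "c")))
  res <- select_differential(toy_table(v), meta, per_subject = TRUE)
  # 6 subjects, 3 per group -> exact MWU on small n still runs
  expect_true(all(res$table$p >= 0 & res$table$p <= 1))
})

test_that("the network keeps planted edges and honours the FDR gate", {
  set.seed(40)
  n <- 30
  sid <- sprintf("s%02d", 1:n)
  z <- rnorm(n)
  met <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(sid, paste0("m", 1:4)))
  gen <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(sid, paste0("g", 1:4)))
  met[, 1] <- z; gen[, 1] <- z          # a perfect planted pair
  blocks <- list(metabolite = toy_table(met, unit = "scaled"),
                 taxon = toy_table(gen, "taxon", "scaled"))
  net <- build_network(blocks, q_thresh = 0.05)
  hit <- net$edges[net$edges$source == "m1" & net$edges$target == "g1", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$sign, 1)
  expect_equal(hit$rho, 1)
  # cross-block only by default: all 16 pairs tested, none within-block
  pairs <- attr(net, "pairs")
  expect_equal(nrow(pairs), 16)
  expect_true(all(pairs$q >= pairs$p))
  # q_thresh = 0 empties the edge set but keeps the nodes
  net0 <- build_network(blocks, q_thresh = 0)
  expect_equal(nrow(net0$edges), 0)
  expect_equal(nrow(net0$nodes), 8)
  # within-block flag adds intra-block pairs
  netw <- build_network(blocks, within_block = TRUE)
  expect_equal(nrow(attr(netw, "pairs")), 16 + choose(4, 2) * 2)
  # sample reordering leaves the edge set unchanged
  perm <- sample(n)
  blocks_p <- lapply(blocks, function(b) subset_table(b, samples = perm))
  net_p <- build_network(blocks_p, q_thresh = 0.05)
  key <- function(x) sort(paste(x$edges$source, x$edges$target))
  expect_identical(key(net_p), key(net))
  expect_error(build_network(blocks[1]), "at least 2")
})

test_that("node annotations carry block, cluster and direction", {
  set.seed(44)
  n <- 20
  sid <- sprintf("s%02d", 1:n)
  met <- matrix(rnorm(n * 2), n, 2, dimnames = list(sid, c("m1", "m2")))
  gen <- matrix(rnorm(n * 2), n, 2, dimnames = list(sid, c("g1", "g2")))
  blocks <- list(metabolite = toy_table(met, unit = "scaled"),
                 taxon = toy_table(gen, "taxon", "scaled"))
  clusters <- list(
    metabolite = hca_clusters(autocorrelation_map(blocks$metabolite), 2),
    taxon = hca_clusters(autocorrelation_map(blocks$taxon), 1))
  net <- build_network(blocks, clusters = clusters,
                       directions = c(m1 = "AD", g1 = "control"))
  nd <- net$nodes
  expect_equal(nd$block[nd$feature == "m1"], "metabolite")
  expect_equal(nd$cluster[nd$feature == "g1"], "taxon_1")
  expect_equal(nd$direction[nd$feature == "m1"], "AD")
  expect_true(is.na(nd$direction[nd$feature == "m2"]))
})
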