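test_that("rarefaction subsamples every retained sample to the depth", {
  set.seed(2)
  v <- matrix(rpois(5 * 20, 40), 5, 20,
              dimnames = list(sprintf("s%d", 1:5), sprintf("t%02d", 1:20)))
  tbl <- toy_table(v, "taxon", "count")
  r <- rarefy(tbl, depth = 300, seed = 9)
  expect_true(all(rowSums(r$values) == 300))
  expect_true(all(r$values <= v))
  # depth equal to a sample total leaves it unchanged
  one <- toy_table(v[1, , drop = FALSE], "taxon", "count")
  expect_identical(rarefy(one, depth = sum(v[1, ]), seed = 1)$values[1, ],
                   v[1, ])
  # shallow samples dropped with a warning
  v2 <- v; v2[2, ] <- 0L
  expect_warning(r2 <- rarefy(toy_table(v2, "taxon", "count"), 300, 1),
                 "dropping")
  expect_false("s2" %in% rownames(r2$values))
  expect_error(rarefy(tbl, depth = 0), "positive")
})

test_that("rarefaction is unbiased for taxon proportions", {
  v <- matrix(c(600, 300, 100), 1, 3,
              dimnames = list("s1", c("a", "b", "c")))
  tbl <- toy_table(v, "taxon", "count")
  tots <- rowMeans(vapply(1:1000, function(s)
    rarefy(tbl, depth = 500, seed = s)$values[1, ], numeric(3)))
  expect_equal(unname(tots), 500 * c(0.6, 0.3, 0.1), tolerance = 0.02)
})

test_that("relative abundance normalises rows and is scale invariant", {
  v <- matrix(c(2, 10, 2, 30, 6, 60), 2, 3,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  ra <- relative_abundance(toy_table(v, "taxon", "count"))
  expect_equal(rowSums(ra$values), c(s1 = 1, s2 = 1))
  expect_equal(unname(ra$values["s1", ]), c(0.2, 0.2, 0.6))
  # scaling a row by 10 leaves its fractions unchanged
  expect_equal(ra$values["s2", ], ra$values["s1", ] * c(1, 3, 2) /
                 sum(c(0.2, 0.2, 0.6) * c(1, 3, 2)), tolerance = 1e-12)
  v10 <- v; v10[1, ] <- v10[1, ] * 10
  expect_equal(relative_abundance(toy_table(v10, "taxon",
                                            "count"))$values["s1", ],
               ra$values["s1", ])
  vz <- v; vz[1, ] <- 0
  expect_error(relative_abundance(toy_table(vz, "taxon", "count")),
               "zero-sum")
  # top-taxa selection at the 1% mean-abundance threshold
  vt <- matrix(c(96.5, 98.5, 3, 1, 0.5, 0.5), 2, 3,
               dimnames = list(c("s1", "s2"), c("dom", "mid", "rare")))
  tt <- top_taxa(relative_abundance(toy_table(vt, "taxon", "count")))
  expect_identical(tt$taxon, c("dom", "mid"))
})

test_that("alpha diversity metrics match their closed forms", {
  v <- matrix(c(25, 25, 25, 25, 0,
                10, 1, 1, 2, 6), 2, 5, byrow = TRUE,
              dimnames = list(c("u", "m"), sprintf("t%d", 1:5)))
  a <- alpha_diversity(toy_table(v, "taxon", "count"))
  # uniform 4-taxon sample: shannon = ln 4, no F1/F2 -> chao1 = observed
  expect_equal(a$shannon[1], log(4))
  expect_equal(a$observed[1], 4)
  expect_equal(a$chao1[1], 4)
  # F1 = 2 singletons, F2 = 1 doubleton, S = 5 -> 5 + 2*1/(2*2) = 5.5
  expect_equal(a$chao1[2], 5.5)
  expect_error(alpha_diversity(toy_table(v / 3, "taxon", "count")),
               "integer")
})

test_that("unifrac reproduces the hand-enumerated 3-leaf case", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  v <- matrix(c(1, 0, 0, 0, 0, 1), 2, 3,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  tbl <- toy_table(v, "taxon", "count")
  expect_equal(unifrac(tbl, tree)["s1", "s2"], 1)          # (1+1+2)/(1+1+2)
  expect_equal(unifrac(tbl, tree, weighted = TRUE)["s1", "s2"], 4)
  expect_equal(unifrac(tbl, tree, weighted = TRUE,
                       normalized = TRUE)["s1", "s2"], 1)
  # identical communities at distance zero, both variants
  v2 <- rbind(s1 = c(A = 3, B = 1, C = 2), s2 = c(A = 3, B = 1, C = 2))
  t2 <- toy_table(v2, "taxon", "count")
  expect_equal(unifrac(t2, tree)["s1", "s2"], 0)
  expect_equal(unifrac(t2, tree, weighted = TRUE)["s1", "s2"], 0)
  # disjoint single-taxon communities on a star tree: unweighted = 1
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(unifrac(tbl, star)["s1", "s2"], 1)
  expect_error(unifrac(toy_table(cbind(v, Z = c(1, 1)), "taxon", "count"),
                       tree), "absent from the tree")
})

test_that("unifrac agrees with phyloseq on random trees and tables", {
  skip_if_not_installed("phyloseq")
  set.seed(31)
  for (i in 1:3) {
    nt <- sample(6:10, 1)
    tree <- ape::rtree(nt)
    v <- matrix(rpois(4 * nt, 8), 4, nt,
                dimnames = list(sprintf("s%d", 1:4), tree$tip.label))
    tbl <- toy_table(v, "taxon", "count")
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(t(v), taxa_are_rows = TRUE),
      phyloseq::phy_tree(tree))
    for (w in c(FALSE, TRUE)) {
      mine <- unifrac(tbl, tree, weighted = w,
                      normalized = FALSE)
      ref <- as.matrix(phyloseq::UniFrac(ps, weighted = w,
                                         normalized = FALSE))
      expect_equal(unclass(mine)[rownames(ref), colnames(ref)],
                   ref, tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("unweighted unifrac satisfies the triangle inequality", {
  set.seed(17)
  for (i in 1:10) {
    tree <- ape::rtree(6)
    v <- matrix(rbinom(5 * 6, 1, 0.6), 5, 6,
                dimnames = list(sprintf("s%d", 1:5), tree$tip.label))
    v[rowSums(v) == 0, 1] <- 1L
    d <- unifrac(toy_table(v, "taxon", "count"), tree)
    for (a in 1:3) for (b in (a + 1):4) for (cc in (b + 1):5)
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-12)
    expect_true(all(d >= 0 & d <= 1 + 1e-12))
  }
})

test_that("pcoa embeds Euclidean data up to a similarity transform", {
  set.seed(23)
  pts <- matrix(rnorm(20), 10, 2,
                dimnames = list(sprintf("s%02d", 1:10), NULL))
  d <- as.matrix(dist(pts))
  ord <- pcoa(d, k = 2)
  pr <- procrustes_fit(pts, ord$scores, k = 2)
  expect_lt(pr$M2, 1e-10)
  # eigenvalues sorted descending, negatives reported not dropped
  expect_equal(ord$eigenvalues, sort(ord$eigenvalues, decreasing = TRUE))
  # duplicate samples land on coincident coordinates
  d2 <- as.matrix(dist(pts[c(1, 1, 2:10), ]))
  dimnames(d2) <- list(sprintf("s%02d", 1:11), sprintf("s%02d", 1:11))
  ord2 <- pcoa(d2, k = 2)
  expect_equal(ord2$scores[1, ], ord2$scores[2, ], tolerance = 1e-10)
  # k capped at n - 1 (planar input: only 2 positive eigenvalues survive)
  expect_lte(ncol(suppressWarnings(pcoa(d, k = 50))$scores), 9)
})

test_that("anosim matches hand-computed ranks and finds no fake structure", {
  # 2 + 2 samples with all between-distances exceeding within-distances
  d <- matrix(c(0, 1, 10, 11,
                1, 0, 12, 13,
                10, 12, 0, 2,
                11, 13, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  res <- anosim_test(d, c("g1", "g1", "g2", "g2"), n_perm = 99, seed = 1)
  # hand ranks: within {1,2}, between {3,4,5,6}; R = (4.5 - 1.5)/(6/2) = 1
  expect_equal(res$R, 1)
  within <- c(1, 2); between <- c(3, 4, 5, 6)
  expect_equal(res$R, (mean(between) - mean(within)) / (4 * 3 / 2 / 2))
  expect_error(anosim_test(d, rep("g", 4), 99), "at least 2 groups")
  # unstructured labels: R near zero on average
  set.seed(5)
  pts <- matrix(rnorm(40), 20)
  dd <- as.matrix(dist(pts))
  dimnames(dd) <- list(sprintf("s%d", 1:20), sprintf("s%d", 1:20))
  rs <- vapply(1:20, function(i) {
    g <- sample(rep(c("a", "b"), 10))
    anosim_test(dd, g, n_perm = 49, seed = i)$R
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("LDA effect size reports strong separations with direction", {
  set.seed(9)
  meta <- toy_meta(10, 10)
  n <- 20
  v <- matrix(runif(n * 8, 0.01, 0.05), n, 8,
              dimnames = list(meta$sample_id, sprintf("g%d", 1:8)))
  v[meta$group == "AD", 1] <- v[meta$group == "AD", 1] * 100  # no overlap
  v <- sweep(v, 1, rowSums(v), "/")
  relab <- toy_table(v, "taxon", "fraction")
  res <- lda_effect_size(relab, meta$group, seed = 3)
  expect_true("g1" %in% res$feature)
  expect_equal(res$direction[res$feature == "g1"], "AD")
  expect_gt(abs(res$lda_score[res$feature == "g1"]), 2)
  # identical distributions are not reported
  expect_false(any(sprintf("g%d", 2:8) %in% res$feature[
    abs(res$lda_score) > 5]))
  # infinite threshold empties the report
  expect_equal(nrow(lda_effect_size(relab, meta$group, threshold = Inf,
                                    seed = 3)), 0)
})

test_that("metagenome prediction is exact copy-number arithmetic", {
  ref <- gene_content_reference(
    c(t1 = 2, t2 = 1, t3 = 4),
    matrix(c(3, 1, 0,
             0, 2, 0,
             0, 0, 0), 3, 3, byrow = TRUE,
           dimnames = list(c("t1", "t2", "t3"), c("K1", "K2", "K3"))),
    list(K1 = "pwA", K2 = c("pwA", "pwB"), K3 = "pwB"))
  v <- matrix(c(10, 4, 8), 1, 3, dimnames = list("s1", c("t1", "t2", "t3")))
  pred <- predict_metagenome(toy_table(v, "taxon", "count"), ref)
  # K1: 10/2 * 3 = 15; K2: 10/2 * 1 + 4/1 * 2 = 13
  expect_equal(pred$ko_table$values["s1", "K1"], 15)
  expect_equal(pred$ko_table$values["s1", "K2"], 13)
  expect_equal(pred$ko_table$values["s1", "K3"], 0)   # empty KO row
  # pathway aggregation with KO multiplicity
  expect_equal(pred$pathway_table$values["s1", "pwA"], 15 + 13)
  expect_equal(pred$pathway_table$values["s1", "pwB"], 13 + 0)
  mult <- table(unlist(ref$pathway_map))
  expect_equal(sum(pred$pathway_table$values),
               sum(pred$ko_table$values["s1", names(ref$pathway_map)] *
                     lengths(ref$pathway_map)))
  # copy numbers of 1 reduce to a plain matrix product
  ref1 <- gene_content_reference(c(t1 = 1, t2 = 1, t3 = 1),
                                 ref$ko_content, ref$pathway_map)
  expect_equal(predict_metagenome(toy_table(v, "taxon", "count"),
                                  ref1)$ko_table$values,
               v %*% ref$ko_content)
  # linearity: doubling counts doubles the KO row
  pred2 <- predict_metagenome(toy_table(v * 2, "taxon", "count"), ref)
  expect_equal(pred2$ko_table$values, pred$ko_table$values * 2)
  expect_error(predict_metagenome(
    toy_table(cbind(v, tX = 1), "taxon", "count"), ref), "missing")
})
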