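# Independent oracles used across the suite.  Each recomputes a quantity
# from its definition by brute force, never through the package's own
# code path.

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values into two groups of the observed sizes
enum_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- u_of(seq_len(n1))
  splits <- utils::combn(length(pooled), n1)
  ud <- apply(splits, 2, u_of)
  p_le <- mean(ud <= obs)
  p_ge <- mean(ud >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg step-up, written out from the definition
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

# branch-walk UniFrac for one sample pair: explicit loop over tree
# edges with descendant tip sets from phangorn (independent of the
# package's incidence-matrix path)
unifrac_oracle <- function(tree, a, b, weighted = FALSE,
                           normalized = FALSE, desc = NULL) {
  tips <- tree$tip.label
  if (is.null(desc))
    desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  num <- 0; den <- 0
  at <- sum(a); bt <- sum(b)
  for (e in seq_len(nrow(tree$edge))) {
    l <- tree$edge.length[e]
    ta <- sum(a[tips[desc[[e]]]])
    tb <- sum(b[tips[desc[[e]]]])
    if (weighted) {
      num <- num + l * abs(ta / at - tb / bt)
      den <- den + l * (ta / at + tb / bt)
    } else {
      if (xor(ta > 0, tb > 0)) num <- num + l
      if (ta > 0 || tb > 0) den <- den + l
    }
  }
  if (weighted) {
    if (!normalized) num else if (den > 0) num / den else 0
  } else {
    if (den > 0) num / den else 0
  }
}

# grid-search symmetric Procrustes M2 for planar configurations:
# both configurations are centred and scaled to unit sum of squares,
# then the residual is minimised over rotation angle, reflection and
# uniform scale (scale solved in closed form per angle)
procrustes_grid_M2 <- function(a, b, n_angle = 4000) {
  std <- function(m) {
    m <- scale(m, scale = FALSE)
    m / sqrt(sum(m^2))
  }
  a <- std(a); b <- std(b)
  best <- Inf
  for (refl in c(1, -1)) {
    for (th in seq(0, 2 * pi, length.out = n_angle)) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) %*%
        diag(c(1, refl))
      br <- b %*% R
      cc <- sum(a * br)            # optimal scale, ||br|| = 1
      best <- min(best, sum((a - cc * br)^2))
    }
  }
  best
}

# small two-group metadata used by several fixtures
toy_meta <- function(n1 = 6, n2 = 5) {
  data.frame(
    sample_id = c(sprintf("c%d", seq_len(n1)), sprintf("a%d", seq_len(n2))),
    group = factor(rep(c("control", "AD"), c(n1, n2)),
                   levels = c("control", "AD")),
    subject_id = c(sprintf("c%d", seq_len(n1)), sprintf("a%d", seq_len(n2))),
    age_weeks = 8L)
}

toy_table <- function(values, block = "metabolite",
                      unit = "concentration") {
  feature_table(values, block = block, unit = unit)
}
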