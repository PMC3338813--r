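test_that("mean scaling equalises column means before the log transform", {
  v <- matrix(c(100, 100, 200, 200), 2, 2)  # column means 100 and 200
  em <- make_em(v, conditions = c("control", "treated"))
  nem <- normalize_intensities(em)
  # grand mean 150: factors 1.5 and 0.75
  expect_equal(colMeans(2^nem$values), c(150, 150), ignore_attr = TRUE)
  expect_equal(2^nem$values[1, 1], 150)
  # already-equal means: factors 1, values only log-transformed
  v2 <- matrix(c(10, 30, 30, 10), 2, 2)
  em2 <- make_em(v2, conditions = c("control", "treated"))
  expect_equal(normalize_intensities(em2)$values, log2(v2), ignore_attr = TRUE)
  # defining property on arbitrary input
  set.seed(1)
  v3 <- matrix(rexp(60, 0.01), 10, 6)
  em3 <- make_em(v3, conditions = rep(c("control", "treated"), 3))
  cm <- colMeans(2^normalize_intensities(em3)$values)
  expect_lt(diff(range(cm)), 1e-9)
})

test_that("non-positive intensities are floored with a warning", {
  v <- matrix(c(0, 4, 8, 16), 2, 2)
  em <- make_em(v, conditions = c("control", "treated"))
  expect_warning(nem <- normalize_intensities(em), "non-positive")
  expect_true(all(is.finite(nem$values)))
})

test_that("pairwise t statistics match the closed-form pooled computation", {
  v <- 2^matrix(c(1, 2, 3, 4, 5, 6,
                  1, 2, 3, 4, 5, 6), 2, 6, byrow = TRUE)
  rownames(v) <- c("pA", "pB")
  em <- make_em(log2(v), conditions = rep(c("control", "treated"), each = 3),
                normalized = TRUE)
  de <- pairwise_de(em, 6)
  # log2 groups (1,2,3) vs (4,5,6): pooled t with df = 4
  expect_equal(abs(de$t[1]), 3.674, tolerance = 1e-3)
  expect_equal(de$p[1], 2 * pt(-sqrt(27 / 2), 4), tolerance = 1e-10)
  expect_equal(de$p[1], 0.0214, tolerance = 1e-2)
  expect_equal(de$fold[1], 2^3)
})

test_that("probes with identical values in both groups give p = 1, fold 1", {
  v <- matrix(5, 3, 4, dimnames = list(paste0("p", 1:3), NULL))
  em <- make_em(v, conditions = rep(c("control", "treated"), each = 2),
                normalized = TRUE)
  de <- pairwise_de(em, 6)
  expect_equal(de$p, rep(1, 3))
  expect_equal(de$fold, rep(1, 3))
  # zero variance but unequal means: flagged, minimal p
  v2 <- rbind(p1 = c(1, 1, 3, 3), p2 = c(2, 2, 2, 2))
  em2 <- make_em(v2, conditions = rep(c("control", "treated"), each = 2),
                 normalized = TRUE)
  de2 <- pairwise_de(em2, 6)
  expect_true(de2$zero_var_shift[de2$probe_id == "p1"])
  expect_equal(de2$p[de2$probe_id == "p1"], .Machine$double.xmin)
})

test_that("the spiked probe attains the smallest q at its time point", {
  cfg <- simulation_config(5, array = list(replicates = 4L, n_de = 1L,
                                           effect = 2, sigma = 0.2))
  sim <- simulate_microarray(cfg)
  nem <- normalize_intensities(sim$em)
  tm <- sim$truth$time_h[1]
  de <- pairwise_de(nem, tm)
  expect_equal(de$probe_id[which.min(de$q)], sim$truth$probe_id[1])
})

test_that("two-level ANOVA reproduces the pairwise t-test exactly", {
  set.seed(21)
  for (i in 1:10) {
    v <- matrix(rnorm(200, 10), 25, 8,
                dimnames = list(sprintf("p%02d", 1:25), NULL))
    em <- make_em(v, conditions = rep(c("control", "treated"), each = 4),
                  normalized = TRUE)
    av <- anova_de(em, groups = em$samples$condition)
    pw <- pairwise_de(em, 6)
    expect_equal(av$p, pw$p, tolerance = 1e-10)
    expect_equal(av$F, pw$t^2, tolerance = 1e-8)
  }
})

test_that("ANOVA handles degenerate probes and recovers a per-time spike", {
  v <- matrix(7, 3, 8, dimnames = list(paste0("p", 1:3), NULL))
  em <- make_em(v, conditions = rep(c("control", "treated"), each = 4),
                normalized = TRUE)
  av <- anova_de(em, groups = em$samples$condition)
  expect_equal(av$F, rep(0, 3))
  expect_equal(av$p, rep(1, 3))

  cfg <- simulation_config(9, array = list(replicates = 4L, n_de = 1L,
                                           effect = 2, sigma = 0.2))
  sim <- simulate_microarray(cfg)
  nem <- normalize_intensities(sim$em)
  av2 <- anova_de(nem)
  expect_equal(av2$probe_id[which.min(av2$q)], sim$truth$probe_id[1])

  expect_error(anova_de(nem, groups = seq_len(ncol(nem$values))), "replicates")
})

test_that("venn region counts enumerate the 7 regions and conserve the union", {
  vc <- venn_counts(list(A = c("a", "b", "c"), B = c("b", "c"), C = "c"))
  expect_equal(vc[["A"]], 1)
  expect_equal(vc[["B"]], 0)
  expect_equal(vc[["C"]], 0)
  expect_equal(vc[["A&B"]], 1)
  expect_equal(vc[["A&C"]], 0)
  expect_equal(vc[["B&C"]], 0)
  expect_equal(vc[["A&B&C"]], 1)

  d <- venn_counts(list(A = "x", B = "y", C = "z"))
  expect_equal(sum(d[4:7]), 0)
  i <- venn_counts(list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y")))
  expect_equal(unname(i[1:6]), rep(0, 6))
  expect_equal(i[["A&B&C"]], 2)

  set.seed(3)
  for (r in 1:20) {
    sets <- lapply(1:3, function(i) sample(letters, sample(0:15, 1)))
    names(sets) <- c("A", "B", "C")
    expect_equal(sum(venn_counts(sets)), length(unique(unlist(sets))))
  }
})

test_that("PCA is complete, ordered and stable under sample duplication", {
  set.seed(12)
  v <- matrix(rnorm(80, 8), 16, 5, dimnames = list(sprintf("p%02d", 1:16), NULL))
  em <- make_em(v, conditions = c("control", "treated", "control", "treated", "control"),
                normalized = TRUE)
  pc <- pca_samples(em)
  # completeness: scores x loadings reconstruct the centred matrix
  centred <- t(scale(t(em$values), center = TRUE, scale = FALSE))
  recon <- pc$prcomp$x %*% t(pc$prcomp$rotation)
  expect_lt(max(abs(t(recon) - centred)), 1e-8)
  # total variance conserved
  expect_equal(sum(pc$explained_variance), sum(apply(t(em$values), 2, var)),
               tolerance = 1e-8)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))

  # rank-1 input: one component carries all variance
  v1 <- outer(rnorm(10), c(1, 2, 3, 4))
  em1 <- make_em(v1 + 10, conditions = rep(c("control", "treated"), 2),
                 normalized = TRUE)
  pc1 <- pca_samples(em1)
  expect_equal(pc1$proportion[1], 1, tolerance = 1e-10)

  # oracle recomputation: eigendecomposition of the probe covariance
  ee <- eigen(stats::cov(t(em$values)), symmetric = TRUE)
  k <- 4  # 5 samples -> rank 4 after centring
  expect_equal(pc$explained_variance[1:k], ee$values[1:k], tolerance = 1e-8)
  dots <- abs(colSums(pc$prcomp$rotation[, 1:k] * ee$vectors[, 1:k]))
  expect_equal(unname(dots), rep(1, k), tolerance = 1e-6)
})

test_that("Manhattan/average-linkage clustering matches hand computation", {
  v <- matrix(c(0, 1, 10), 1, 3,
              dimnames = list("p1", c("s1", "s2", "s3")))
  em <- make_em(v, conditions = c("control", "control", "treated"),
                normalized = TRUE)
  hc <- hcluster_manhattan_average(em)
  expect_equal(hc$height, c(1, 9.5))

  vi <- matrix(3, 4, 3, dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
  emi <- make_em(vi, conditions = c("control", "control", "treated"),
                 normalized = TRUE)
  expect_equal(hcluster_manhattan_average(emi)$height, c(0, 0))

  # permutation invariance of the tree (as cophenetic distances)
  set.seed(8)
  v2 <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("s", 1:5)))
  rownames(v2) <- paste0("p", 1:8)
  em2 <- make_em(v2, conditions = rep("control", 5), normalized = TRUE)
  perm <- c(3, 1, 5, 2, 4)
  em3 <- make_em(v2[, perm], conditions = rep("control", 5), normalized = TRUE)
  d1 <- as.matrix(cophenetic(hcluster_manhattan_average(em2)))
  d2 <- as.matrix(cophenetic(hcluster_manhattan_average(em3)))
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-12)

  nwk <- dendrogram_newick(hcluster_manhattan_average(em2))
  expect_match(nwk, "^\\(")
  expect_equal(length(ape::read.tree(text = nwk)$tip.label), 5)
})

test_that("the signed fold convention is an involution under label swap", {
  set.seed(4)
  v <- matrix(rnorm(120, 9, 1), 20, 6,
              dimnames = list(sprintf("p%02d", 1:20), NULL))
  em <- make_em(v, conditions = rep(c("control", "treated"), each = 3),
                normalized = TRUE)
  de <- pairwise_de(em, 6)
  em2 <- em
  em2$samples$condition <- ifelse(em$samples$condition == "control",
                                  "treated", "control")
  de2 <- pairwise_de(em2, 6)
  expect_equal(de2$p, de$p, tolerance = 1e-12)
  big <- abs(de$fold) > 1 + 1e-12
  expect_equal(de2$fold[big], -de$fold[big], tolerance = 1e-9)
})
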