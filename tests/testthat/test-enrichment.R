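test_that("term_stats sums reads and lengths and normalises per kilobase", {
  fx <- make_contig_fixture()
  # term A in treated: (10, 500) + (30, 1500)
  st <- term_stats(fx$contigs, fx$annotations, "A", "treated")
  expect_equal(st$reads_sum, 40)
  expect_equal(st$length_sum, 2000)
  expect_equal(st$weight, 20)
  expect_equal(st$n_contigs, 2)
  # unannotated term: zeros, not an error
  st0 <- term_stats(fx$contigs, fx$annotations, "Z", "treated")
  expect_equal(st0$weight, 0)
  expect_equal(st0$n_contigs, 0)
  # single contig, scale division
  one <- data.frame(contig_id = "x", group = "treated", length_bp = 7000L,
                    reads = 7L, stringsAsFactors = FALSE)
  expect_equal(term_stats(one, list(x = "A"), "A", "treated")$weight, 1)
})

test_that("build_contingency forms rounded annotated/complement cells", {
  st <- function(w) list(term = "t", weight = w)
  tab <- build_contingency(st(20), st(5), 100, 100)
  expect_equal(unname(tab), matrix(c(20L, 80L, 5L, 95L), 2, byrow = TRUE))
  tab0 <- build_contingency(st(0), st(0), 50, 50)
  expect_equal(unname(tab0), matrix(c(0L, 50L, 0L, 50L), 2, byrow = TRUE))
  # round-half-even: 20.4 -> 20, 20.5 -> 20, 21.5 -> 22
  expect_equal(build_contingency(st(20.4), st(0), 100, 100)[1, 1], 20L,
               ignore_attr = TRUE)
  expect_equal(build_contingency(st(20.5), st(0), 100, 100)[1, 1], 20L,
               ignore_attr = TRUE)
  expect_equal(build_contingency(st(21.5), st(0), 100, 100)[1, 1], 22L,
               ignore_attr = TRUE)
  expect_warning(tabc <- build_contingency(st(120), st(10), 100, 100), "clamped")
  expect_equal(tabc[1, 2], 0L, ignore_attr = TRUE)
})

test_that("two-sided Fisher p matches enumeration on the worked tables", {
  expect_equal(fisher_exact_two_sided(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
               34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(matrix(c(2, 2, 2, 2), 2, byrow = TRUE)), 1)
  expect_equal(fisher_exact_two_sided(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               2 / 252, tolerance = 1e-12)
  z <- fisher_exact_two_sided(matrix(0, 2, 2))
  expect_equal(as.numeric(z), 1)
  expect_true(attr(z, "degenerate"))
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(2, 10, 40), 1)), 2)
    p_ref <- stats::fisher.test(tab)$p.value
    expect_equal(fisher_exact_two_sided(tab), p_ref, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(bh_adjust(0.005), 0.005)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)), c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_identical(bh_adjust(numeric()), numeric())
  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    expect_true(!is.unsorted(q[order(p)]))
  }
})

test_that("fold is the ratio of within-group proportions with sentinel rules", {
  st <- function(w) list(term = "t", weight = w)
  r <- fold_and_direction(st(20), st(5), 100, 100)
  expect_equal(r$fold, 4)
  expect_equal(r$direction, "enriched")
  r1 <- fold_and_direction(st(10), st(10), 100, 100)
  expect_equal(r1$fold, 1)
  r2 <- fold_and_direction(st(10), st(0), 100, 100)
  expect_equal(r2$fold, Inf)
  expect_equal(r2$direction, "enriched")
  r3 <- fold_and_direction(st(0), st(0), 100, 100)
  expect_true(is.na(r3$fold))
})

test_that("child pruning reports only the most specific significant terms", {
  chain <- ontology(
    terms = data.frame(id = c("A", "B"), name = c("a", "b"),
                       namespace = "biological_process"),
    edges = data.frame(child = "B", parent = "A"))
  res <- data.frame(term = c("A", "B"), q = c(0.01, 0.01), flags = "",
                    stringsAsFactors = FALSE)
  out <- prune_by_children(res, chain, 0.05)
  expect_match(out$flags[out$term == "A"], "child_pruned")
  expect_equal(out$flags[out$term == "B"], "")

  res2 <- data.frame(term = c("A", "B"), q = c(0.01, 0.5), flags = "",
                     stringsAsFactors = FALSE)
  out2 <- prune_by_children(res2, chain, 0.05)
  expect_equal(out2$flags, c("", ""))

  ont <- make_diamond()
  res3 <- data.frame(term = c("A", "B", "C", "D"), q = c(0.9, 0.9, 0.9, 0.01),
                     flags = "", stringsAsFactors = FALSE)
  out3 <- prune_by_children(res3, ont, 0.05)
  expect_equal(out3$flags, rep("", 4))

  res4 <- data.frame(term = c("A", "B", "ghost"), q = c(0.01, 0.01, 0.01),
                     flags = "", stringsAsFactors = FALSE)
  expect_warning(out4 <- prune_by_children(res4, chain, 0.05), "ghost")
  expect_equal(out4$flags[out4$term == "ghost"], "")
})

test_that("quantitative enrichment recovers a spiked term and is label-symmetric", {
  cfg <- simulation_config(11, contigs = list(n_contigs = c(control = 300L, treated = 300L),
                                              total_reads = c(control = 15000L, treated = 15000L),
                                              n_terms = 40L))
  ont <- simulate_ontology(cfg)
  lv <- spike_candidates(ont)
  cfg$contigs$spiked <- data.frame(term = lv[1], fold = 5)
  exp <- simulate_contig_experiment(cfg, ont)
  ann <- propagate_annotations(exp$annotations, ont)
  res <- run_quantitative_enrichment(exp$contigs, ann, ont)
  row <- res[res$term == lv[1], ]
  expect_true(row$reported)
  expect_equal(row$direction, "enriched")

  # swapping the group labels leaves p unchanged and mirrors direction
  swapped <- exp$contigs
  swapped$group <- ifelse(swapped$group == "treated", "control", "treated")
  res2 <- run_quantitative_enrichment(swapped, ann, ont)
  m <- match(res$term, res2$term)
  expect_equal(res2$p[m], res$p, tolerance = 1e-12)
  expect_equal(res2$q[m], res$q, tolerance = 1e-12)
  informative <- !is.na(res$fold) & res$fold != 1
  expect_true(all(res2$direction[m][informative] != res$direction[informative]))
})

test_that("qualitative enrichment uses contig-presence cells", {
  contigs <- data.frame(
    contig_id = c(sprintf("t%03d", 1:100), sprintf("c%03d", 1:100)),
    group = rep(c("treated", "control"), each = 100),
    length_bp = 500L, reads = 10L, stringsAsFactors = FALSE)
  # term X: 10/100 in each group -> p = 1
  ann <- c(
    setNames(as.list(rep("X", 10)), sprintf("t%03d", 1:10)),
    setNames(as.list(rep("X", 10)), sprintf("c%03d", 1:10)))
  res <- run_qualitative_enrichment(contigs, ann, propagate = FALSE)
  expect_equal(res$p[res$term == "X"], 1)
  expect_false(res$reported[res$term == "X"])

  # term Y: 30/100 treated vs 2/100 control -> enriched, p from enumeration
  ann2 <- c(
    setNames(as.list(rep("Y", 30)), sprintf("t%03d", 1:30)),
    setNames(as.list(rep("Y", 2)), sprintf("c%03d", 1:2)))
  res2 <- run_qualitative_enrichment(contigs, ann2, propagate = FALSE)
  row <- res2[res2$term == "Y", ]
  expect_equal(row$p, fisher_oracle(30, 70, 2, 98), tolerance = 1e-9)
  expect_true(row$reported)
  expect_equal(row$direction, "enriched")

  # a term with a single supporting contig is flagged
  ann3 <- list(t001 = c("Y", "solo"), c001 = "Y")
  res3 <- run_qualitative_enrichment(contigs, ann3, propagate = FALSE)
  expect_match(res3$flags[res3$term == "solo"], "min_contig_filtered")
})

test_that("degenerate all-zero tables are excluded from the BH family", {
  contigs <- data.frame(contig_id = c("t1", "c1"),
                        group = c("treated", "control"),
                        length_bp = c(1000L, 1000L), reads = c(0L, 0L),
                        stringsAsFactors = FALSE)
  ann <- list(t1 = "A", c1 = "A")
  res <- run_quantitative_enrichment(contigs, ann, propagate = FALSE)
  expect_equal(res$p[res$term == "A"], 1)
  expect_true(is.na(res$q[res$term == "A"]))
  expect_false(res$reported[res$term == "A"])
})

test_that("the score restriction flags weights at or below the threshold", {
  fx <- make_contig_fixture()
  res <- run_quantitative_enrichment(fx$contigs, fx$annotations, propagate = FALSE,
                                     score_threshold = 1000)
  expect_true(all(grepl("score_filtered", res$flags)))
  res2 <- run_quantitative_enrichment(fx$contigs, fx$annotations, propagate = FALSE,
                                      score_threshold = 1)
  expect_false(any(grepl("score_filtered", res2$flags)))
})

test_that("under the global null the exact test is valid (never anti-conservative)", {
  # two-binomial null at moderate margins; the Fisher test is discrete and
  # conservative, so the attained rate must not exceed the nominal level
  # beyond Monte Carlo error
  set.seed(99)
  n <- 4000
  a <- rbinom(n, 128, 0.5); c_ <- rbinom(n, 128, 0.5)
  p <- vapply(seq_len(n), function(i) {
    fisher_exact_two_sided(c(a[i], 128 - a[i], c_[i], 128 - c_[i]))
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n))
  expect_gt(rate, 0)
})

test_that("term_read_summary tallies reads per group without testing", {
  contigs <- data.frame(
    contig_id = c("t1", "t2", "c1"), group = c("treated", "treated", "control"),
    length_bp = c(500L, 800L, 400L), reads = c(12L, 8L, 9L),
    stringsAsFactors = FALSE)
  ann <- list(t1 = "alp", t2 = "apn", c1 = "apn")
  out <- term_read_summary(contigs, ann, terms = c("alp", "apn"))
  # found only in intoxicated larvae: zero control reads
  expect_equal(out$reads_control[out$term == "alp"], 0)
  expect_equal(out$reads_treated[out$term == "alp"], 12)
  expect_equal(out$reads_treated[out$term == "apn"], 8)
  expect_equal(out$reads_control[out$term == "apn"], 9)
  # empty match gives an empty table
  empty <- term_read_summary(contigs, ann, keyword = "zzz",
                             ont = make_diamond())
  expect_equal(nrow(empty), 0)
  # with one direct term per contig, summed reads are conserved
  expect_equal(sum(out$reads_treated), sum(contigs$reads[contigs$group == "treated"]))
  expect_equal(sum(out$reads_control), sum(contigs$reads[contigs$group == "control"]))
})
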