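# Independent oracles and shared fixtures.

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins, probability from the closed-form factorial expression (lgamma),
# sum the probabilities not exceeding the observed one.
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(1)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  logp <- vapply(lo:hi, function(x) {
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1) -
      lgamma(n + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) -
      lgamma(c1 - x + 1) - lgamma(n - r1 - c1 + x + 1)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[(lo:hi) == a]
  min(sum(p[p <= obs * (1 + 1e-7)]), 1)
}

# Step-up BH applied literally: sort, q_(i) = min_{j>=i} p_(j) * m / j,
# clip at 1, return in input order.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric())
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Diamond DAG: D is_a B, D is_a C, B is_a A, C is_a A.
make_diamond <- function() {
  ontology(
    terms = data.frame(id = c("A", "B", "C", "D"),
                       name = paste("term", c("A", "B", "C", "D")),
                       namespace = "biological_process",
                       stringsAsFactors = FALSE),
    edges = data.frame(child = c("B", "C", "D", "D"),
                       parent = c("A", "A", "B", "C"),
                       stringsAsFactors = FALSE))
}

# A five-stanza OBO file: chain A <- B <- C plus isolated D and E,
# plus one obsolete stanza that must be dropped.
write_test_obo <- function(path, obsolete = FALSE) {
  lines <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:000A", "name: alpha", "namespace: biological_process", "",
    "[Term]", "id: GO:000B", "name: beta", "namespace: biological_process",
    "is_a: GO:000A ! alpha", "",
    "[Term]", "id: GO:000C", "name: gamma", "namespace: biological_process",
    "is_a: GO:000B", "",
    "[Term]", "id: GO:000D", "name: delta", "namespace: cellular_component", "",
    "[Term]", "id: GO:000E", "name: epsilon", "namespace: molecular_function", "")
  if (obsolete) {
    lines <- c(lines,
               "[Term]", "id: GO:000F", "name: zeta",
               "namespace: molecular_function", "is_obsolete: true", "")
  }
  writeLines(lines, path)
  path
}

# Minimal contig table with one term per contig, convenient for
# hand-computable enrichment fixtures.
make_contig_fixture <- function() {
  contigs <- data.frame(
    contig_id = c("Bt-1", "Bt-2", "Bt-3", "Cont-1", "Cont-2", "Cont-3"),
    group = rep(c("treated", "control"), each = 3),
    length_bp = c(500L, 1500L, 1000L, 500L, 1500L, 1000L),
    reads = c(10L, 30L, 20L, 5L, 15L, 40L),
    stringsAsFactors = FALSE)
  ann <- list(
    `Bt-1` = "A", `Bt-2` = "A", `Bt-3` = "B",
    `Cont-1` = "A", `Cont-2` = "A", `Cont-3` = "B")
  list(contigs = contigs, annotations = ann)
}

# Expression matrix from a plain values matrix with a minimal balanced
# design at a single time point.
make_em <- function(values, conditions, time_h = 6, normalized = FALSE) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
  samples <- data.frame(
    sample_id = colnames(values),
    condition = conditions,
    time_h = time_h,
    dye = rep(c("Cy3", "Cy5"), length.out = n),
    replicate = seq_len(n),
    stringsAsFactors = FALSE)
  expression_matrix(values, samples, normalized = normalized)
}
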