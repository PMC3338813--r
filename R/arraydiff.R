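#' Probe-intensity matrix with sample metadata
#'
#' @param values numeric matrix, probes x samples, non-negative
#'   intensities; rownames are probe ids, colnames sample ids.
#' @param samples data.frame with one row per column of `values`:
#'   `sample_id`, `condition` (`control`/`treated`), `time_h`, `dye`,
#'   `replicate`.
#' @param normalized set `TRUE` when `values` are already on the
#'   normalized log2 scale (e.g. imported from another tool); such a
#'   matrix is accepted by the test stages directly.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples, normalized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("values needs probe ids as rownames")
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "condition", "time_h", "dye", "replicate") %in%
                  names(samples)),
            nrow(samples) == ncol(values))
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  stopifnot(identical(colnames(values), as.character(samples$sample_id)))
  bad <- setdiff(unique(samples$condition), c("control", "treated"))
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  structure(list(values = values, samples = samples,
                 normalized = isTRUE(normalized)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples", if (x$normalized) "(normalized, log2)" else "(raw)", "\n")
  invisible(x)
}

#' Normalize intensities by relative intensity of the means, then log2
#'
#' Each sample column is scaled so that its mean equals the grand mean of
#' the column means (so all columns have the same mean intensity), and the
#' scaled matrix is log2-transformed. Non-positive intensities are replaced
#' by half the smallest positive value in the matrix, with a warning.
#'
#' @param em an [expression_matrix()] of raw intensities.
#' @return an `expression_matrix` of log2 normalized values
#'   (`normalized = TRUE`).
#' @export
normalize_intensities <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$normalized) stop("matrix is already normalized")
  v <- em$values
  if (any(v <= 0)) {
    floor_val <- min(v[v > 0]) / 2
    if (!is.finite(floor_val)) stop("a column of all zeros cannot be normalized")
    warning(sum(v <= 0), " non-positive intensities replaced by ", floor_val)
    v[v <= 0] <- floor_val
  }
  cm <- colMeans(v)
  if (any(cm == 0)) stop("a column of all zeros cannot be normalized")
  grand <- mean(cm)
  v <- sweep(v, 2, grand / cm, `*`)
  em$values <- log2(v)
  em$normalized <- TRUE
  em
}

# vectorised two-sample pooled-variance t over rows of two matrices
.rowwise_pooled_t <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tval), df)
  zero_var <- sp2 == 0
  equal <- zero_var & m1 == m2
  shifted <- zero_var & m1 != m2
  tval[equal] <- 0; p[equal] <- 1
  tval[shifted] <- sign(m1 - m2)[shifted] * Inf
  p[shifted] <- .Machine$double.xmin
  list(mean1 = m1, mean2 = m2, t = tval, p = p, df = df,
       zero_var_shift = shifted)
}

.signed_fold <- function(log2_diff) {
  raw <- 2^log2_diff
  ifelse(raw >= 1, raw, -1 / raw)
}

#' Per-probe control-vs-treated t tests at one exposure time
#'
#' Two-sample pooled-variance (Student) t test per probe on the log2
#' normalized values of the columns at `time_h`, treated minus control,
#' with BH adjustment across probes. Fold changes below 1 are reported with
#' the negative-reciprocal convention (0.5 -> -2).
#'
#' @param em a normalized [expression_matrix()].
#' @param time_h exposure time (h) selecting the columns to compare.
#' @param welch use Welch's unequal-variance test instead of the pooled
#'   test (default `FALSE`).
#' @return data.frame: `probe_id`, `mean_log_control`, `mean_log_treated`,
#'   `fold` (signed), `t`, `p`, `q`, `zero_var_shift` flag.
#' @export
pairwise_de <- function(em, time_h, welch = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!em$normalized) stop("normalize the matrix first (normalize_intensities)")
  sel_t <- em$samples$time_h == time_h & em$samples$condition == "treated"
  sel_c <- em$samples$time_h == time_h & em$samples$condition == "control"
  if (sum(sel_t) < 2 || sum(sel_c) < 2) {
    stop("need >= 2 replicates of each condition at time ", time_h, " h")
  }
  xt <- em$values[, sel_t, drop = FALSE]
  xc <- em$values[, sel_c, drop = FALSE]
  if (welch) {
    n1 <- ncol(xt); n2 <- ncol(xc)
    m1 <- rowMeans(xt); m2 <- rowMeans(xc)
    v1 <- apply(xt, 1, stats::var); v2 <- apply(xc, 1, stats::var)
    se2 <- v1 / n1 + v2 / n2
    tval <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tval), df)
    zero <- se2 == 0
    tval[zero & m1 == m2] <- 0; p[zero & m1 == m2] <- 1
    shifted <- zero & m1 != m2
    tval[shifted] <- sign(m1 - m2)[shifted] * Inf
    p[shifted] <- .Machine$double.xmin
    tt <- list(mean1 = m1, mean2 = m2, t = tval, p = p,
               zero_var_shift = shifted)
  } else {
    tt <- .rowwise_pooled_t(xt, xc)
  }
  data.frame(probe_id = rownames(em$values),
             mean_log_control = tt$mean2, mean_log_treated = tt$mean1,
             fold = .signed_fold(tt$mean1 - tt$mean2),
             t = tt$t, p = tt$p, q = bh_adjust(tt$p),
             zero_var_shift = tt$zero_var_shift,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-probe one-way ANOVA of control against all exposure times
#'
#' Fixed-effects one-way F test per probe. By default the levels are the
#' pooled control samples plus one level per treated exposure time
#' (control, 6h, 12h, 24h); an explicit grouping factor over the columns
#' may be supplied instead.
#'
#' @param em a normalized [expression_matrix()].
#' @param groups optional factor/character vector, one entry per sample
#'   column, defining the levels.
#' @return data.frame: `probe_id`, `F`, `p`, `q`.
#' @export
anova_de <- function(em, groups = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!em$normalized) stop("normalize the matrix first (normalize_intensities)")
  if (is.null(groups)) {
    groups <- ifelse(em$samples$condition == "control", "control",
                     paste0(em$samples$time_h, "h"))
  }
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("every level needs >= 2 replicates")
  k <- nlevels(groups)
  if (k < 2) stop("need >= 2 levels")
  v <- em$values
  N <- ncol(v)
  level_n <- as.integer(table(groups)[levels(groups)])
  # per-level row means via matrix multiply
  ind <- stats::model.matrix(~ groups - 1)
  level_sums <- v %*% ind
  level_means <- sweep(level_sums, 2, level_n, `/`)
  grand <- rowMeans(v)
  ssb <- rowSums(sweep((level_means - grand)^2, 2, level_n, `*`))
  ssw <- rowSums((v - level_means[, as.integer(groups), drop = FALSE])^2)
  df1 <- k - 1; df2 <- N - k
  msb <- ssb / df1; msw <- ssw / df2
  f <- msb / msw
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  zero <- msw == 0
  f[zero & ssb == 0] <- 0; p[zero & ssb == 0] <- 1
  shifted <- zero & ssb > 0
  f[shifted] <- Inf; p[shifted] <- .Machine$double.xmin
  data.frame(probe_id = rownames(v), F = f, p = p, q = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Region counts of a three-set Venn diagram
#'
#' @param sets named list of exactly three character vectors (e.g. the
#'   significant probe ids at 6, 12 and 24 h).
#' @return named integer vector over the 7 regions, named by membership
#'   pattern (e.g. `"6h"`, `"6h&12h"`, `"6h&12h&24h"`), summing to the size
#'   of the union.
#' @export
venn_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 3)
  if (is.null(names(sets))) names(sets) <- c("A", "B", "C")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0) member <- matrix(logical(0), 0, 3,
                                              dimnames = list(NULL, names(sets)))
  if (length(universe) == 1) member <- matrix(member, 1, 3,
                                              dimnames = list(NULL, names(sets)))
  patterns <- list(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                   c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                   c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
                   c(TRUE, TRUE, TRUE))
  counts <- vapply(patterns, function(p) {
    sum(apply(member, 1, function(r) all(r == p)))
  }, integer(1))
  names(counts) <- vapply(patterns, function(p) {
    paste(names(sets)[p], collapse = "&")
  }, character(1))
  counts
}

#' Principal component analysis of the sample profiles
#'
#' Samples (columns) are the observations; probes the variables. Columns
#' of the log2 normalized matrix are centred per probe and decomposed with
#' [stats::prcomp()].
#'
#' @param em a normalized [expression_matrix()] (>= 2 samples).
#' @return list with `scores` (samples x components), `explained_variance`
#'   (component variances), `proportion` (fraction of total variance) and
#'   the underlying `prcomp` object.
#' @export
pca_samples <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (ncol(em$values) < 2) stop("need >= 2 samples")
  pr <- stats::prcomp(t(em$values), center = TRUE, scale. = FALSE)
  vars <- pr$sdev^2
  list(scores = pr$x, explained_variance = vars,
       proportion = vars / sum(vars), prcomp = pr)
}

#' Average-linkage clustering of samples on Manhattan distance
#'
#' @param em an [expression_matrix()] (>= 2 samples); the sample profiles
#'   (columns) are clustered.
#' @return an object of class `hclust` (merge order and heights).
#' @export
hcluster_manhattan_average <- function(em) {
  vals <- if (inherits(em, "expression_matrix")) em$values else as.matrix(em)
  if (ncol(vals) < 2) stop("need >= 2 samples")
  d <- stats::dist(t(vals), method = "manhattan")
  stats::hclust(d, method = "average")
}

#' Serialize a dendrogram to Newick
#'
#' @param hc an `hclust` object.
#' @return single-element character vector with the Newick string.
#' @export
dendrogram_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}
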