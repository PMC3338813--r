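#' Configuration of the enrichment cascade
#'
#' Defaults reproduce the reporting cascade used for the gut-transcriptome
#' contrast: two-sided Fisher test, Benjamini-Hochberg FDR at `alpha`, fold
#' change strictly different from 1, at least `min_contigs` contigs
#' supporting the term overall, pruning of terms with a significant
#' descendant, and (quantitative mode only) a score restriction at
#' `score_threshold` where the score is the larger group weight.
#'
#' @param alpha FDR cut-off (default 0.05).
#' @param scale weight scale: weights are reads per `scale` bases
#'   (default 1000, i.e. reads per kilobase).
#' @param min_contigs minimum number of annotated contigs, summed over both
#'   groups (default 2).
#' @param score_threshold score restriction; terms with score `<=` this are
#'   flagged. `NULL` disables. Default 100 in quantitative mode, disabled in
#'   qualitative mode.
#' @param mode `"quantitative"` (read/length-weighted cells) or
#'   `"qualitative"` (contig-presence cells).
#' @param propagate propagate annotations to `is_a` ancestors before
#'   counting (true-path rule)? Default `TRUE`.
#' @param two_sided two-sided test (default) or one-sided in the direction
#'   of enrichment in the treated group.
#' @param complement construction of the "function not annotated" cell in
#'   quantitative mode: `"rest"` (default) uses the weight of the contigs
#'   not annotated to the term; `"dataset"` uses the whole-group weight
#'   minus the term weight.
#' @param fold_filter apply the fold-change-different-from-1 filter?
#'   Default on in quantitative mode, off in qualitative mode.
#' @return list of class `enrichment_config`.
#' @export
enrichment_config <- function(alpha = 0.05, scale = 1000, min_contigs = 2,
                              score_threshold = NULL,
                              mode = c("quantitative", "qualitative"),
                              propagate = TRUE, two_sided = TRUE,
                              complement = c("rest", "dataset"),
                              fold_filter = NULL) {
  mode <- match.arg(mode)
  complement <- match.arg(complement)
  stopifnot(alpha > 0, alpha < 1, scale > 0, min_contigs >= 0)
  if (is.null(score_threshold)) {
    score_threshold <- if (mode == "quantitative") 100 else Inf
  }
  if (is.null(fold_filter)) fold_filter <- mode == "quantitative"
  structure(list(alpha = alpha, scale = scale, min_contigs = min_contigs,
                 score_threshold = score_threshold, mode = mode,
                 propagate = propagate, two_sided = two_sided,
                 complement = complement, fold_filter = fold_filter),
            class = "enrichment_config")
}

#' Per-term, per-group read and length totals
#'
#' Sums reads and lengths over the contigs of one group whose annotation
#' set contains the term, and forms the normalised weight
#' `scale * reads_sum / length_sum` (reads per `scale` bases; 0 when no
#' contig is annotated).
#'
#' @param contigs contig table: data.frame with columns `contig_id`,
#'   `group`, `length_bp`, `reads`.
#' @param annotations named list contig id -> term ids (use the
#'   `propagated` component of an annotation set for true-path counting).
#' @param term term id.
#' @param group group label.
#' @param scale weight scale (reads per `scale` bases).
#' @return list with `term`, `group`, `n_contigs`, `reads_sum`,
#'   `length_sum`, `weight`.
#' @export
term_stats <- function(contigs, annotations, term, group, scale = 1000) {
  in_grp <- contigs$group == group
  has <- vapply(contigs$contig_id, function(id) {
    tt <- annotations[[id]]
    !is.null(tt) && term %in% tt
  }, logical(1))
  sel <- in_grp & has
  R <- sum(contigs$reads[sel])
  L <- sum(contigs$length_bp[sel])
  list(term = term, group = group, n_contigs = sum(sel),
       reads_sum = R, length_sum = L,
       weight = if (L > 0) scale * R / L else 0)
}

#' Build the 2x2 "annotated / not annotated" table for one term
#'
#' Rows are groups (treated, control); columns are "function annotated"
#' and "function not annotated". The annotated cell is the rounded term
#' weight; the complement cell is the rounded group total minus it.
#' Rounding is round-half-even; negative complements are clamped to zero
#' with a warning.
#'
#' @param stats_treated,stats_control outputs of [term_stats()].
#' @param total_treated,total_control the group totals against which the
#'   term weight is contrasted (see `complement` in [enrichment_config()]).
#' @return 2x2 integer matrix, rows `treated`/`control`, columns
#'   `annotated`/`not_annotated`.
#' @export
build_contingency <- function(stats_treated, stats_control,
                              total_treated, total_control) {
  if (total_treated < 0 || total_control < 0) stop("negative group total")
  a <- round(stats_treated$weight)
  c_ <- round(stats_control$weight)
  b <- round(total_treated) - a
  d <- round(total_control) - c_
  if (b < 0 || d < 0) {
    warning("term weight exceeds group total; complement clamped to 0 for term ",
            stats_treated$term)
    b <- max(b, 0)
    d <- max(d, 0)
  }
  matrix(as.integer(c(a, b, c_, d)), nrow = 2, byrow = TRUE,
         dimnames = list(c("treated", "control"),
                         c("annotated", "not_annotated")))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p value is the sum of the hypergeometric probabilities,
#' over all tables with the observed margins, that do not exceed the
#' probability of the observed table (within relative tolerance 1e-7, the
#' conventional guard against floating-point ties). Degenerate tables whose
#' margins admit a single configuration give p = 1.
#'
#' @param table 2x2 matrix of non-negative integers (or a length-4 vector
#'   `a, b, c, d` read row-wise).
#' @param alternative `"two.sided"` (default), `"greater"` (top-left cell
#'   larger than expected) or `"less"`.
#' @return p value in (0, 1]. If all cells are zero, p = 1 with attribute
#'   `degenerate = TRUE`.
#' @export
fisher_exact_two_sided <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.integer(table)
  if (length(x) != 4L || any(x < 0)) stop("need a 2x2 table of non-negative integers")
  if (is.matrix(table)) {
    a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  }
  n <- a + b + c_ + d
  if (n == 0L) return(structure(1, degenerate = TRUE))
  r1 <- a + b
  c1 <- a + c_
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  obs <- probs[support == a]
  p <- switch(alternative,
    two.sided = sum(probs[probs <= obs * (1 + 1e-7)]),
    greater   = sum(probs[support >= a]),
    less      = sum(probs[support <= a]))
  min(p, 1)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment, returned in input order and clipped at 1.
#'
#' @param pvals numeric vector of p values in \[0, 1\].
#' @return numeric vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Fold change and direction for one term
#'
#' The fold is the ratio of within-group relative abundances
#' (`weight / total`), treated over control. A zero control proportion
#' with a positive treated proportion gives `Inf`; both zero gives `NA`
#' (the term carries no signal and is flagged downstream).
#'
#' @param stats_treated,stats_control outputs of [term_stats()].
#' @param total_treated,total_control whole-group weights used to form the
#'   proportions.
#' @return list with `fold` (> 0, `Inf`, or `NA`) and `direction`
#'   (`"enriched"` or `"repressed"`).
#' @export
fold_and_direction <- function(stats_treated, stats_control,
                               total_treated, total_control) {
  if (total_treated <= 0 || total_control <= 0) stop("group totals must be positive")
  pt <- stats_treated$weight / total_treated
  pc <- stats_control$weight / total_control
  if (pt == 0 && pc == 0) {
    return(list(fold = NA_real_, direction = "repressed"))
  }
  fold <- if (pc == 0) Inf else pt / pc
  list(fold = fold, direction = if (pt > pc) "enriched" else "repressed")
}

#' Prune significant terms that have a significant descendant
#'
#' Implements the "lacking significant child terms" reporting rule: a
#' significant term with at least one significant `is_a` descendant gains
#' the `child_pruned` flag, so the reported set contains no significant
#' ancestor-descendant pair (it is an antichain). "Child" is read as any
#' descendant, which is stricter than direct children and order-independent.
#'
#' @param results enrichment result data.frame (needs `term`, `q`, `flags`).
#' @param ont an [ontology].
#' @param alpha significance cut-off on `q`.
#' @return `results` with `child_pruned` added to `flags` where applicable.
#' @export
prune_by_children <- function(results, ont, alpha = 0.05) {
  sig <- !is.na(results$q) & results$q <= alpha
  if (!any(sig)) return(results)
  missing <- setdiff(results$term, ont$terms$id)
  if (length(missing)) {
    warning("term(s) absent from ontology left unpruned: ",
            paste(missing, collapse = ", "))
  }
  sig_terms <- results$term[sig]
  for (i in which(sig & results$term %in% ont$terms$id)) {
    desc <- term_closure(ont, results$term[i], "descendants")
    if (any(sig_terms %in% desc)) {
      results$flags[i] <- .add_flag(results$flags[i], "child_pruned")
    }
  }
  results
}

.add_flag <- function(flags, flag) {
  if (flags == "") flag else paste(flags, flag, sep = ";")
}

# per-term x per-group totals for every annotated term at once
.term_group_table <- function(contigs, ann, scale) {
  long <- data.frame(
    contig_id = rep(names(ann), lengths(ann)),
    term = unlist(ann, use.names = FALSE), stringsAsFactors = FALSE)
  long <- long[long$contig_id %in% contigs$contig_id, , drop = FALSE]
  idx <- match(long$contig_id, contigs$contig_id)
  long$group <- contigs$group[idx]
  long$reads <- contigs$reads[idx]
  long$length_bp <- contigs$length_bp[idx]
  key <- paste(long$term, long$group, sep = "\r")
  agg <- rowsum(cbind(reads = long$reads, length_bp = long$length_bp,
                      n = rep(1L, nrow(long))), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(term = vapply(parts, `[`, "", 1L),
             group = vapply(parts, `[`, "", 2L),
             n_contigs = as.integer(agg[, "n"]),
             reads_sum = agg[, "reads"],
             length_sum = agg[, "length_bp"],
             weight = ifelse(agg[, "length_bp"] > 0,
                             scale * agg[, "reads"] / agg[, "length_bp"], 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the functional enrichment cascade
#'
#' Tests every term annotated to at least one contig for differential
#' representation between the treated and control contig sets, then applies
#' the reporting cascade: BH FDR at `config$alpha`, fold change different
#' from 1 (quantitative mode), minimum supporting contigs, child-term
#' pruning, and the score restriction. A term is *reported* when `q <=
#' alpha` and no filter flag is set.
#'
#' In quantitative mode the table cells are read-abundance weights: for each
#' term and group, the reads in contigs annotated to the term are normalised
#' by the summed contig length (reads per `scale` bases) and contrasted
#' against the weight of the remaining contigs. In qualitative mode the
#' cells are contig counts, ignoring read abundance.
#'
#' @param contigs contig table (`contig_id`, `group`, `length_bp`, `reads`)
#'   containing exactly two groups.
#' @param annotations an annotation set from [propagate_annotations()] or a
#'   plain named list contig id -> term ids (treated as direct annotations;
#'   propagated on the fly when `config$propagate` and `ont` are given).
#' @param ont an [ontology], used for propagation and child pruning; may be
#'   `NULL` to skip both.
#' @param config an [enrichment_config()].
#' @param treated,control the group labels (defaults `"treated"`,
#'   `"control"`).
#' @return data.frame of class `enrichment_result`, one row per tested
#'   term: group stats, `fold`, `direction`, `p`, `q`, `score`, `flags`
#'   (`;`-separated), and logical `reported`.
#' @export
run_enrichment <- function(contigs, annotations, ont = NULL,
                           config = enrichment_config(),
                           treated = "treated", control = "control") {
  stopifnot(inherits(config, "enrichment_config"))
  contigs <- validate_contigs(contigs)
  groups <- unique(contigs$group)
  if (!setequal(groups, c(treated, control))) {
    stop("contig table must contain exactly the groups '", treated,
         "' and '", control, "'")
  }
  if (inherits(annotations, "annotation_set")) {
    ann <- if (config$propagate) annotations$propagated else annotations$direct
  } else {
    ann <- annotations
    if (config$propagate) {
      if (is.null(ont)) stop("propagation requested but no ontology given")
      ann <- propagate_annotations(ann, ont)$propagated
    }
  }
  if (!length(ann) || !length(unlist(ann))) stop("no annotations to test")

  tg <- .term_group_table(contigs, ann, config$scale)
  terms <- sort(unique(tg$term))
  get <- function(col, grp) {
    v <- stats::setNames(rep(0, length(terms)), terms)
    sel <- tg$group == grp
    v[tg$term[sel]] <- tg[[col]][sel]
    v
  }
  n_t <- get("n_contigs", treated);  n_c <- get("n_contigs", control)
  R_t <- get("reads_sum", treated);  R_c <- get("reads_sum", control)
  L_t <- get("length_sum", treated); L_c <- get("length_sum", control)
  W_t <- get("weight", treated);     W_c <- get("weight", control)

  grp_reads <- tapply(contigs$reads, contigs$group, sum)
  grp_len <- tapply(as.numeric(contigs$length_bp), contigs$group, sum)
  grp_n <- table(contigs$group)
  T_ds_t <- config$scale * grp_reads[[treated]] / grp_len[[treated]]
  T_ds_c <- config$scale * grp_reads[[control]] / grp_len[[control]]

  rest_weight <- function(R, L, grp_R, grp_L) {
    dl <- grp_L - L
    ifelse(dl > 0, config$scale * (grp_R - R) / dl, 0)
  }

  if (config$mode == "quantitative") {
    if (config$complement == "rest") {
      tot_t <- W_t + rest_weight(R_t, L_t, grp_reads[[treated]], grp_len[[treated]])
      tot_c <- W_c + rest_weight(R_c, L_c, grp_reads[[control]], grp_len[[control]])
    } else {
      tot_t <- rep(T_ds_t, length(terms))
      tot_c <- rep(T_ds_c, length(terms))
    }
    cell_a <- round(W_t); cell_c <- round(W_c)
  } else {
    tot_t <- rep(as.numeric(grp_n[[treated]]), length(terms))
    tot_c <- rep(as.numeric(grp_n[[control]]), length(terms))
    cell_a <- n_t; cell_c <- n_c
  }
  cell_b <- pmax(round(tot_t) - cell_a, 0)
  cell_d <- pmax(round(tot_c) - cell_c, 0)

  alt <- if (config$two_sided) "two.sided" else "greater"
  p <- vapply(seq_along(terms), function(i) {
    fisher_exact_two_sided(c(cell_a[i], cell_b[i], cell_c[i], cell_d[i]),
                           alternative = alt)
  }, numeric(1))
  degenerate <- (cell_a + cell_b + cell_c + cell_d) == 0
  q <- rep(NA_real_, length(terms))
  q[!degenerate] <- bh_adjust(p[!degenerate])

  # fold from relative abundance within each whole group
  if (config$mode == "quantitative") {
    prop_t <- W_t / T_ds_t; prop_c <- W_c / T_ds_c
  } else {
    prop_t <- n_t / as.numeric(grp_n[[treated]])
    prop_c <- n_c / as.numeric(grp_n[[control]])
  }
  fold <- ifelse(prop_t == 0 & prop_c == 0, NA_real_,
                 ifelse(prop_c == 0, Inf, prop_t / prop_c))
  direction <- ifelse(prop_t > prop_c, "enriched", "repressed")
  score <- pmax(W_t, W_c)

  flags <- rep("", length(terms))
  if (config$fold_filter) {
    no_change <- is.na(fold) | fold == 1
    flags[no_change] <- vapply(flags[no_change], .add_flag, "", flag = "fold_filtered")
  } else {
    flags[is.na(fold)] <- vapply(flags[is.na(fold)], .add_flag, "",
                                 flag = "fold_filtered")
  }
  few <- (n_t + n_c) < config$min_contigs
  flags[few] <- vapply(flags[few], .add_flag, "", flag = "min_contig_filtered")
  if (is.finite(config$score_threshold)) {
    low <- score <= config$score_threshold
    flags[low] <- vapply(flags[low], .add_flag, "", flag = "score_filtered")
  }

  res <- data.frame(
    term = terms,
    name = NA_character_, namespace = NA_character_,
    n_contigs_control = as.integer(n_c), n_contigs_treated = as.integer(n_t),
    reads_control = R_c, reads_treated = R_t,
    length_control = L_c, length_treated = L_t,
    weight_control = W_c, weight_treated = W_t,
    fold = fold, direction = direction,
    p = p, q = q, score = score, flags = flags,
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(ont)) {
    idx <- match(res$term, ont$terms$id)
    res$name <- ont$terms$name[idx]
    res$namespace <- ont$terms$namespace[idx]
    res <- prune_by_children(res, ont, config$alpha)
  }
  res$reported <- !is.na(res$q) & res$q <= config$alpha & res$flags == ""
  res <- res[order(res$q, res$p, res$term), ]
  rownames(res) <- NULL
  attr(res, "config") <- config
  class(res) <- c("enrichment_result", class(res))
  res
}

#' @rdname run_enrichment
#' @param ... further arguments passed to [enrichment_config()].
#' @export
run_quantitative_enrichment <- function(contigs, annotations, ont = NULL, ...) {
  run_enrichment(contigs, annotations, ont,
                 config = enrichment_config(mode = "quantitative", ...))
}

#' @rdname run_enrichment
#' @export
run_qualitative_enrichment <- function(contigs, annotations, ont = NULL, ...) {
  run_enrichment(contigs, annotations, ont,
                 config = enrichment_config(mode = "qualitative", ...))
}

#' Per-group read totals for selected terms
#'
#' Descriptive comparison of read abundance for terms of interest (e.g.
#' putative toxin receptors: cadherin, aminopeptidase N, alkaline
#' phosphatase) -- no test is applied.
#'
#' @param contigs contig table.
#' @param annotations annotation set or named list (as in
#'   [run_enrichment()]; the direct sets are used unless an
#'   `annotation_set`'s propagated sets are passed explicitly).
#' @param terms character vector of term ids, or `NULL` with `keyword`.
#' @param keyword case-insensitive regular expression matched against term
#'   names in `ont` to select terms.
#' @param ont an [ontology], required for `keyword` matching and names.
#' @param treated,control group labels.
#' @return data.frame: term, name, reads_control, reads_treated,
#'   n_contigs_control, n_contigs_treated.
#' @export
term_read_summary <- function(contigs, annotations, terms = NULL,
                              keyword = NULL, ont = NULL,
                              treated = "treated", control = "control") {
  contigs <- validate_contigs(contigs)
  ann <- if (inherits(annotations, "annotation_set")) annotations$direct else annotations
  if (is.null(terms)) {
    if (is.null(keyword)) stop("give either terms or a keyword")
    if (is.null(ont)) stop("keyword matching needs an ontology")
    terms <- ont$terms$id[grepl(keyword, ont$terms$name, ignore.case = TRUE)]
  }
  if (!length(terms)) {
    return(data.frame(term = character(), name = character(),
                      reads_control = numeric(), reads_treated = numeric(),
                      n_contigs_control = integer(), n_contigs_treated = integer()))
  }
  rows <- lapply(terms, function(tm) {
    st <- term_stats(contigs, ann, tm, treated)
    sc <- term_stats(contigs, ann, tm, control)
    data.frame(term = tm,
               name = if (!is.null(ont)) ont$terms$name[match(tm, ont$terms$id)] else NA_character_,
               reads_control = sc$reads_sum, reads_treated = st$reads_sum,
               n_contigs_control = sc$n_contigs, n_contigs_treated = st$n_contigs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
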