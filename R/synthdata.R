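#' Simulation configuration
#'
#' Bundles the parameters of the three generators. The `"study"` profile
#' mirrors the scale of the T. molitor gut 454 dataset the pipeline was
#' built around: 1,318 control and 1,140 Cry3Aa-treated contigs carrying
#' 134,090 and 124,287 reads, with a mean contig length near 780 bp
#' (log-normal lengths). The `"tiny"` profile (100 contigs and 5,000 reads
#' per group) is the default for fast exercises and tests.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param profile `"tiny"` or `"study"`.
#' @param ... named overrides of individual fields within the `contigs`,
#'   `array` and `qpcr` sub-lists, e.g. `contigs = list(n_terms = 200)`.
#' @return nested list of class `simulation_config` with components
#'   `seed`, `contigs`, `array`, `qpcr`.
#' @export
simulation_config <- function(seed, profile = c("tiny", "study"), ...) {
  profile <- match.arg(profile)
  stopifnot(is.numeric(seed), length(seed) == 1)
  base <- list(
    seed = as.integer(seed),
    profile = profile,
    contigs = list(
      n_contigs = c(control = 100L, treated = 100L),
      total_reads = c(control = 5000L, treated = 5000L),
      length_meanlog = log(780) - 0.5^2 / 2,
      length_sdlog = 0.5,
      min_length = 100L,
      n_terms = 50L,
      density = 1L,
      spiked = NULL  # data.frame(term, fold) or NULL
    ),
    array = list(
      n_probes = 300L,
      n_de = 10L,
      effect = 2,
      sigma = 0.2,
      replicates = 2L,
      dye_swap = TRUE,
      times = c(6L, 12L, 24L),
      baseline_mean = 10,
      baseline_sd = 1,
      de_all_times = FALSE
    ),
    qpcr = list(
      true_folds = c(cbd3_a = 37.9, cbd3_b = 1 / 7.2),
      reference = "rpl24",
      sigma = 0.2,
      n_bio = 2L,
      n_tech = 3L,
      base_ct_mean = 22,
      base_ct_sd = 1.5
    )
  )
  if (profile == "study") {
    base$contigs$n_contigs <- c(control = 1318L, treated = 1140L)
    base$contigs$total_reads <- c(control = 134090L, treated = 124287L)
    base$contigs$n_terms <- 200L
    base$array$n_probes <- 2000L
  }
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% c("contigs", "array", "qpcr")) {
      base[[nm]] <- utils::modifyList(base[[nm]], ov[[nm]])
    } else {
      base[[nm]] <- ov[[nm]]
    }
  }
  structure(base, class = "simulation_config")
}

#' Simulate a GO-like ontology
#'
#' Random rooted DAG: term 1 is the root; every later term attaches to one
#' or two earlier terms by `is_a` edges, so the graph is acyclic by
#' construction. Namespaces are drawn for children of the root and
#' inherited from the first parent otherwise.
#'
#' @param config a [simulation_config()] (uses `config$contigs$n_terms` and
#'   `config$seed`).
#' @return an [ontology].
#' @export
simulate_ontology <- function(config) {
  n <- config$contigs$n_terms
  stopifnot(n >= 3)
  with_seed(config$seed, {
    ids <- sprintf("GO:%07d", seq_len(n))
    ns <- character(n)
    ns[1] <- "biological_process"
    child <- character(0); parent <- character(0)
    all_ns <- c("biological_process", "cellular_component", "molecular_function")
    for (i in 2:n) {
      # the first two children hang off the root, giving the three-term
      # minimal case a fixed root + 2 children shape
      k <- if (i <= 3) 1L else sample(1:2, 1)
      par <- if (i <= 3) 1L else sample(seq_len(i - 1), min(k, i - 1))
      child <- c(child, rep(ids[i], length(par)))
      parent <- c(parent, ids[par])
      ns[i] <- if (par[1] == 1L) sample(all_ns, 1) else ns[par[1]]
    }
    ontology(
      terms = data.frame(id = ids, name = sprintf("simulated term %d", seq_len(n)),
                         namespace = ns, stringsAsFactors = FALSE),
      edges = data.frame(child = child, parent = parent, stringsAsFactors = FALSE))
  })
}

#' Terms suitable for spiking
#'
#' Spiked terms should have small propagated coverage, otherwise the
#' spiked read mass dominates the dataset and the compositional
#' renormalisation depresses every other term. Returns the term ids with
#' at most `max_descendants` `is_a` descendants (default: leaves), in id
#' order.
#'
#' @param ont an [ontology].
#' @param max_descendants maximum number of descendants allowed.
#' @return character vector of term ids.
#' @export
spike_candidates <- function(ont, max_descendants = 0) {
  n_children <- table(factor(ont$edges$parent, levels = ont$terms$id))
  if (max_descendants == 0) return(ont$terms$id[n_children == 0])
  ok <- vapply(ont$terms$id, function(tm) {
    length(term_closure(ont, tm, "descendants")) <= max_descendants
  }, logical(1))
  ont$terms$id[ok]
}

#' Simulate a two-group contig experiment with spiked terms
#'
#' Per group, contig lengths are log-normal and reads are allocated
#' multinomially with probabilities proportional to length, so the
#' reads-per-kilobase weight is flat across terms under the null. In the
#' treated group, contigs whose (propagated) annotation set contains a
#' spiked term receive a read-probability multiplier calibrated so that the
#' expected treated/control weight ratio of the spiked term equals its
#' configured fold exactly (the renormalisation that keeps the group read
#' total fixed is compensated). Group read totals match the configuration
#' exactly.
#'
#' @param config a [simulation_config()]; `config$contigs$spiked` is a
#'   data.frame with columns `term`, `fold` (fold > 1 enriched, < 1
#'   repressed) or `NULL` for a null dataset.
#' @param ont an [ontology], e.g. from [simulate_ontology()].
#' @return list with `contigs` (contig table), `annotations` (named list
#'   contig id -> direct term ids), `truth` (data.frame `term`,
#'   `true_fold`, `direction`).
#' @export
simulate_contig_experiment <- function(config, ont) {
  cc <- config$contigs
  spiked <- cc$spiked
  if (!is.null(spiked)) {
    stopifnot(all(c("term", "fold") %in% names(spiked)), all(spiked$fold > 0))
    missing <- setdiff(spiked$term, ont$terms$id)
    if (length(missing)) stop("spiked term(s) not in ontology: ",
                              paste(missing, collapse = ", "))
  }
  with_seed(config$seed + 1L, {
    groups <- c("control", "treated")
    prefix <- c(control = "Cont", treated = "Bt")
    contigs <- list(); direct <- list()
    for (g in groups) {
      n <- cc$n_contigs[[g]]
      len <- pmax(round(stats::rlnorm(n, cc$length_meanlog, cc$length_sdlog)),
                  cc$min_length)
      ids <- sprintf("%s-%05d", prefix[[g]], seq_len(n))
      # stratified term assignment: each term is dealt to (near-)equally
      # many contigs, so per-term membership counts are balanced between
      # the groups and the unspiked dataset is null at the term level
      # (i.i.d. uniform draws would leave rare terms present in one group
      # and absent in the other -- a real abundance difference)
      d <- min(cc$density, nrow(ont$terms))
      pool <- sample(rep(ont$terms$id, length.out = n * d))
      ann <- lapply(seq_len(n), function(i) {
        unique(pool[((i - 1L) * d + 1L):(i * d)])
      })
      names(ann) <- ids
      # every spiked term needs annotated contigs in every group to be
      # measurable; re-draw by force-annotating random contigs if absent
      if (!is.null(spiked)) {
        for (tm in spiked$term) {
          has <- vapply(ann, function(x) tm %in% x, logical(1))
          if (sum(has) < 2) {
            message("spiked term ", tm, " under-annotated in group ", g,
                    "; re-annotating")
            add <- sample(which(!has), 2 - sum(has))
            for (i in add) ann[[i]] <- c(ann[[i]], tm)
          }
        }
      }
      prob <- len / sum(len)
      if (g == "treated" && !is.null(spiked) && nrow(spiked)) {
        prop <- propagate_annotations(ann, ont)$propagated
        mult <- rep(1, n)
        for (j in seq_len(nrow(spiked))) {
          hit <- vapply(prop, function(x) spiked$term[j] %in% x, logical(1))
          mult[hit] <- pmax(mult[hit], spiked$fold[j])
        }
        # target read share of spiked contigs = fold x length share;
        # remaining mass spread over unspiked contigs by length
        share <- mult * len / sum(len)
        spk <- mult != 1
        if (sum(share[spk]) >= 0.9) stop("spiked terms cover too much of the dataset")
        prob <- numeric(n)
        prob[spk] <- share[spk]
        prob[!spk] <- (1 - sum(share[spk])) * len[!spk] / sum(len[!spk])
      }
      reads <- as.integer(stats::rmultinom(1, cc$total_reads[[g]], prob))
      contigs[[g]] <- data.frame(contig_id = ids, group = g,
                                 length_bp = as.integer(len), reads = reads,
                                 stringsAsFactors = FALSE)
      direct <- c(direct, ann)
    }
    truth <- if (is.null(spiked) || !nrow(spiked)) {
      data.frame(term = character(), true_fold = numeric(),
                 direction = character(), stringsAsFactors = FALSE)
    } else {
      data.frame(term = spiked$term, true_fold = spiked$fold,
                 direction = ifelse(spiked$fold > 1, "enriched", "repressed"),
                 stringsAsFactors = FALSE)
    }
    list(contigs = do.call(rbind, c(contigs, list(make.row.names = FALSE))),
         annotations = direct, truth = truth)
  })
}

#' Score enrichment results against a spike truth table
#'
#' A spiked term counts as recovered when it reaches `q <= alpha` in its
#' true direction (before child pruning, which deliberately suppresses a
#' term whenever a more specific significant descendant exists). Ancestors
#' and descendants of spiked terms are genuinely differentially abundant
#' by construction -- their reads include the spiked reads -- so they
#' count neither as true nor as false positives; the empirical false
#' discovery proportion is taken over the remaining significant terms.
#'
#' @param res an `enrichment_result` from [run_enrichment()].
#' @param truth truth table from [simulate_contig_experiment()].
#' @param ont the [ontology] used for the run.
#' @param alpha significance cut-off on `q`.
#' @return list with `tpr`, `fdr`, `n_sig`, `n_tp`, `n_fp`.
#' @export
evaluate_recovery <- function(res, truth, ont, alpha = 0.05) {
  sig <- !is.na(res$q) & res$q <= alpha
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    j <- match(truth$term[i], res$term)
    !is.na(j) && sig[j] && res$direction[j] == truth$direction[i]
  }, logical(1))
  related <- unique(unlist(lapply(truth$term, function(tm) {
    c(term_closure(ont, tm, "ancestors"), term_closure(ont, tm, "descendants"))
  })))
  fp <- sig & !(res$term %in% truth$term) & !(res$term %in% related)
  n_eval <- sum(hit) + sum(fp)
  list(tpr = if (nrow(truth)) mean(hit) else NA_real_,
       fdr = if (n_eval > 0) sum(fp) / n_eval else 0,
       n_sig = sum(sig), n_tp = sum(hit), n_fp = sum(fp))
}

#' Simulate a dye-swapped two-colour time-course microarray
#'
#' Design: 2 conditions x exposure times x `replicates` biological
#' replicates, dye assignment swapped between successive replicates.
#' Per-probe baseline log2 intensities are normal; differentially expressed
#' probes are shifted by `effect` log2 units (random sign) in the treated
#' condition at one random time (or all times when `de_all_times`); i.i.d.
#' normal noise with sd `sigma` is added and values are exponentiated to
#' the intensity scale.
#'
#' @param config a [simulation_config()].
#' @return list with `em` (raw-intensity [expression_matrix()]) and
#'   `truth` (data.frame `probe_id`, `time_h`, `log2_effect`).
#' @export
simulate_microarray <- function(config) {
  ac <- config$array
  with_seed(config$seed + 2L, {
    probes <- sprintf("probe_%05d", seq_len(ac$n_probes))
    design <- expand.grid(replicate = seq_len(ac$replicates),
                          condition = c("control", "treated"),
                          time_h = ac$times, stringsAsFactors = FALSE)
    design$sample_id <- sprintf("%s_%02dh_r%d",
                                ifelse(design$condition == "control", "c", "t"),
                                design$time_h, design$replicate)
    if (ac$dye_swap) {
      swap <- design$replicate %% 2 == 0
      design$dye <- ifelse(xor(design$condition == "treated", swap),
                           "Cy5", "Cy3")
    } else {
      design$dye <- ifelse(design$condition == "treated", "Cy5", "Cy3")
    }
    baseline <- stats::rnorm(ac$n_probes, ac$baseline_mean, ac$baseline_sd)
    de_idx <- if (ac$n_de > 0) sample(ac$n_probes, ac$n_de) else integer()
    de_sign <- sample(c(-1, 1), length(de_idx), replace = TRUE)
    de_time <- if (ac$de_all_times) rep(NA_integer_, length(de_idx)) else
      sample(ac$times, length(de_idx), replace = TRUE)
    logv <- matrix(baseline, nrow = ac$n_probes, ncol = nrow(design))
    for (j in seq_along(de_idx)) {
      cols <- design$condition == "treated" &
        (is.na(de_time[j]) | design$time_h == de_time[j])
      logv[de_idx[j], cols] <- logv[de_idx[j], cols] + de_sign[j] * ac$effect
    }
    if (ac$sigma > 0) {
      logv <- logv + matrix(stats::rnorm(length(logv), 0, ac$sigma),
                            nrow = nrow(logv))
    }
    vals <- 2^logv
    dimnames(vals) <- list(probes, design$sample_id)
    truth <- data.frame(probe_id = probes[de_idx],
                        time_h = de_time,
                        log2_effect = de_sign * ac$effect,
                        stringsAsFactors = FALSE)
    cols <- c("sample_id", "condition", "time_h", "dye", "replicate")
    list(em = expression_matrix(vals, design[, cols]), truth = truth)
  })
}

#' Simulate a qPCR Ct table
#'
#' The reference gene has the same expected Ct in both conditions; each
#' target gene's treated Ct is shifted by `-log2(true fold)` relative to
#' control. Measurement noise (sd `sigma`) is added per technical
#' replicate.
#'
#' @param config a [simulation_config()].
#' @return list with `records` (Ct table) and `truth` (data.frame `gene`,
#'   `true_fold`, `signed_fold`).
#' @export
simulate_qpcr <- function(config) {
  qc <- config$qpcr
  with_seed(config$seed + 3L, {
    genes <- c(stats::setNames(1, qc$reference), qc$true_folds)
    base_ct <- stats::rnorm(length(genes), qc$base_ct_mean, qc$base_ct_sd)
    names(base_ct) <- names(genes)
    grid <- expand.grid(replicate = seq_len(qc$n_tech),
                        sample_id = paste0("bio", seq_len(qc$n_bio)),
                        condition = c("control", "treated"),
                        gene = names(genes), stringsAsFactors = FALSE)
    mu <- base_ct[grid$gene] -
      ifelse(grid$condition == "treated", log2(genes[grid$gene]), 0)
    grid$ct <- mu + stats::rnorm(nrow(grid), 0, qc$sigma)
    grid <- grid[, c("sample_id", "condition", "gene", "replicate", "ct")]
    tf <- qc$true_folds
    truth <- data.frame(gene = names(tf), true_fold = unname(tf),
                        signed_fold = ifelse(tf >= 1, tf, -1 / tf),
                        stringsAsFactors = FALSE)
    list(records = grid, truth = truth)
  })
}
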