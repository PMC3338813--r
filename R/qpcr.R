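#' Ct table validation
#'
#' @param records data.frame with columns `sample_id` (biological
#'   replicate), `condition` (`control`/`treated`), `gene`, `replicate`
#'   (technical), `ct` (cycles, > 0).
#' @return the validated data.frame.
#' @export
validate_ct_table <- function(records) {
  need <- c("sample_id", "condition", "gene", "replicate", "ct")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$ct)) || any(records$ct <= 0)) {
    stop("Ct values must be finite and > 0")
  }
  bad <- setdiff(unique(records$condition), c("control", "treated"))
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  records
}

#' Mean Ct for one gene in one condition
#'
#' Technical replicates are averaged within each biological replicate
#' (sample), then the biological-replicate means are averaged.
#'
#' @param records a Ct table (see [validate_ct_table()]).
#' @param condition `"control"` or `"treated"`.
#' @param gene gene name.
#' @return mean Ct (cycles).
#' @export
mean_ct <- function(records, condition, gene) {
  sel <- records$condition == condition & records$gene == gene
  if (!any(sel)) stop("no Ct records for gene '", gene, "' in condition '",
                      condition, "'")
  per_bio <- tapply(records$ct[sel], records$sample_id[sel], mean)
  mean(per_bio)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt_g = Ct_target,g - Ct_reference,g` per condition; `ddCt =
#' dCt_treated - dCt_control`; raw fold `= 2^(-ddCt)` (amplification
#' efficiency fixed at 100%). Folds below 1 are reported with the
#' negative-reciprocal sign convention (0.125 -> -8).
#'
#' @param records a Ct table.
#' @param target target gene name.
#' @param reference reference gene name (e.g. ribosomal protein L24).
#' @return list with `fold` (signed), `raw_fold`, `ddct`, and the four
#'   mean Cts.
#' @export
ddct_fold <- function(records, target, reference) {
  records <- validate_ct_table(records)
  ct_tt <- mean_ct(records, "treated", target)
  ct_tr <- mean_ct(records, "treated", reference)
  ct_ct <- mean_ct(records, "control", target)
  ct_cr <- mean_ct(records, "control", reference)
  ddct <- (ct_tt - ct_tr) - (ct_ct - ct_cr)
  raw <- 2^(-ddct)
  list(fold = if (raw >= 1) raw else -1 / raw,
       raw_fold = raw, ddct = ddct,
       ct_target_treated = ct_tt, ct_reference_treated = ct_tr,
       ct_target_control = ct_ct, ct_reference_control = ct_cr)
}

#' Signed fold table for several target genes
#'
#' @param records a Ct table.
#' @param targets character vector of target genes (default: every gene
#'   except the reference).
#' @param reference reference gene name.
#' @return data.frame: `gene`, `fold` (signed), `raw_fold`, `ddct`.
#' @export
qpcr_fold_table <- function(records, targets = NULL, reference) {
  records <- validate_ct_table(records)
  if (is.null(targets)) targets <- setdiff(unique(records$gene), reference)
  rows <- lapply(targets, function(g) {
    r <- ddct_fold(records, g, reference)
    data.frame(gene = g, fold = r$fold, raw_fold = r$raw_fold,
               ddct = r$ddct, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
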