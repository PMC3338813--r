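# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards, so generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Validate a contig table
#'
#' @param contigs data.frame with columns `contig_id`, `group`,
#'   `length_bp`, `reads`.
#' @return the validated data.frame (ids as character).
#' @export
validate_contigs <- function(contigs) {
  need <- c("contig_id", "group", "length_bp", "reads")
  miss <- setdiff(need, names(contigs))
  if (length(miss)) stop("contig table lacks column(s): ", paste(miss, collapse = ", "))
  contigs$contig_id <- as.character(contigs$contig_id)
  if (any(contigs$length_bp < 1)) stop("contig lengths must be >= 1 bp")
  if (any(contigs$reads < 0)) stop("read counts must be >= 0")
  key <- paste(contigs$group, contigs$contig_id)
  if (anyDuplicated(key)) {
    stop("duplicate contig id within a group: ",
         paste(unique(contigs$contig_id[duplicated(key)]), collapse = ", "))
  }
  contigs
}
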