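#' Read a contig table
#'
#' Tab-separated with header `contig_id group length_bp reads`; `#`
#' comment lines are allowed. Rows are validated (length >= 1 bp, reads >=
#' 0, no duplicate id within a group) and errors name the offending file
#' line.
#'
#' @param path path to the TSV file.
#' @return validated contig data.frame.
#' @export
read_contig_table <- function(path) {
  if (!file.exists(path)) stop("contig table not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(keep)) stop("empty contig table: ", path)
  header <- strsplit(lines[keep[1]], "\t", fixed = TRUE)[[1]]
  need <- c("contig_id", "group", "length_bp", "reads")
  if (!identical(header, need)) {
    stop("line ", keep[1], ": expected header '", paste(need, collapse = "\t"), "'")
  }
  rows <- keep[-1]
  if (!length(rows)) stop("contig table has no data rows: ", path)
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- parts[[i]]
    if (length(f) != 4) stop("line ", rows[i], ": expected 4 tab-separated fields")
    len <- suppressWarnings(as.numeric(f[3]))
    rd <- suppressWarnings(as.numeric(f[4]))
    if (is.na(len) || len < 1) stop("line ", rows[i], ": invalid length_bp '", f[3], "'")
    if (is.na(rd) || rd < 0) stop("line ", rows[i], ": invalid reads '", f[4], "'")
    out[[i]] <- data.frame(contig_id = f[1], group = f[2],
                           length_bp = as.integer(len), reads = as.integer(rd),
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  key <- paste(df$group, df$contig_id)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop("line ", rows[dup], ": duplicate contig id '", df$contig_id[dup],
         "' within group '", df$group[dup], "'")
  }
  df
}

#' Write a contig table
#' @param contigs contig data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contig_table <- function(contigs, path) {
  contigs <- validate_contigs(contigs)
  utils::write.table(contigs[, c("contig_id", "group", "length_bp", "reads")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequence ids from a FASTA file
#'
#' Ids are the first whitespace-delimited token of each header, in file
#' order; used to cross-check contig tables against the assembly. CRLF
#' endings are tolerated; duplicated ids raise a warning.
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return character vector of ids.
#' @export
read_fasta_ids <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lens <- Biostrings::fasta.seqlengths(path)
  if (!length(lens)) stop("no sequences in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(lens))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA id(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ids
}

#' Write an enrichment result table
#'
#' One row per tested term; `flags` are `;`-separated; the free-text
#' `name` column is quoted.
#'
#' @param res an `enrichment_result` from [run_enrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(res, path) {
  cols <- c("term", "name", "namespace", "n_contigs_control",
            "n_contigs_treated", "reads_control", "reads_treated",
            "length_control", "length_treated", "weight_control",
            "weight_treated", "fold", "direction", "p", "q", "score",
            "flags", "reported")
  df <- as.data.frame(res)[, intersect(cols, names(res))]
  utils::write.table(df, path, sep = "\t", quote = which(names(df) == "name"),
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read/write a probe-intensity matrix with its sample metadata
#'
#' The values file is a TSV with a `probe_id` column followed by one
#' column per sample; the metadata file has columns `sample_id`,
#' `condition`, `time_h`, `dye`, `replicate`.
#'
#' @param values_path,samples_path paths to the two TSV files.
#' @return an [expression_matrix()] (raw scale).
#' @export
read_expression_matrix <- function(values_path, samples_path) {
  vals <- utils::read.delim(values_path, check.names = FALSE)
  if (names(vals)[1] != "probe_id") stop("first column must be probe_id")
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$probe_id
  samples <- utils::read.delim(samples_path, colClasses = c(sample_id = "character"))
  samples <- samples[match(colnames(m), samples$sample_id), ]
  if (anyNA(samples$sample_id)) stop("sample metadata does not cover all value columns")
  expression_matrix(m, samples)
}

#' @rdname read_expression_matrix
#' @param em an [expression_matrix()].
#' @return paths, invisibly.
#' @export
write_expression_matrix <- function(em, values_path, samples_path) {
  df <- data.frame(probe_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(em$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(values_path, samples_path))
}

#' Read/write a qPCR Ct table
#'
#' TSV with columns `sample_id`, `condition`, `gene`, `replicate`, `ct`.
#'
#' @param path path to the TSV file.
#' @return validated Ct data.frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  validate_ct_table(utils::read.delim(path, colClasses = c(sample_id = "character")))
}

#' @rdname read_ct_table
#' @param records Ct data.frame.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(records, path) {
  records <- validate_ct_table(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
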