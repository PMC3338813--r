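#' Gene Ontology subset: construction and validation
#'
#' An `ontology` object is a rooted DAG of terms connected by `is_a` edges
#' (child -> parent). Only the fields the enrichment stage needs are kept:
#' term id, name and namespace. Obsolete terms are dropped at load time.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent` (term ids).
#' @return An object of class `ontology`: list with elements `terms`
#'   (data.frame) and `edges` (data.frame).
#' @export
ontology <- function(terms, edges) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "namespace") %in% names(terms)))
  if (nrow(edges) == 0L) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("child", "parent") %in% names(edges)))
  terms$id <- as.character(terms$id)
  if (anyDuplicated(terms$id)) {
    stop("duplicate term id(s): ",
         paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  }
  ok_ns <- c("biological_process", "cellular_component", "molecular_function")
  bad_ns <- setdiff(unique(terms$namespace), ok_ns)
  if (length(bad_ns)) stop("unknown namespace(s): ", paste(bad_ns, collapse = ", "))
  dangling <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(dangling)) {
    stop("is_a edge references undeclared term(s): ",
         paste(dangling, collapse = ", "))
  }
  obj <- structure(list(terms = terms[, c("id", "name", "namespace")],
                        edges = edges[, c("child", "parent")]),
                   class = "ontology")
  cyc <- .find_cycle(obj)
  if (!is.null(cyc)) {
    stop("is_a graph contains a cycle through: ", paste(cyc, collapse = " -> "))
  }
  obj
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology:", nrow(x$terms), "terms,", nrow(x$edges), "is_a edges\n")
  ns <- table(x$terms$namespace)
  cat(paste0("  ", names(ns), ": ", as.integer(ns), collapse = "\n"), "\n")
  invisible(x)
}

# igraph representation, edges oriented child -> parent
.ontology_graph <- function(ont) {
  igraph::graph_from_data_frame(ont$edges, directed = TRUE,
                                vertices = ont$terms$id)
}

# NULL if acyclic, otherwise the members of one strongly connected component
.find_cycle <- function(ont) {
  if (nrow(ont$edges) == 0L) return(NULL)
  if (any(ont$edges$child == ont$edges$parent)) {
    self <- ont$edges$child[ont$edges$child == ont$edges$parent][1L]
    return(c(self, self))
  }
  g <- .ontology_graph(ont)
  if (igraph::is_dag(g)) return(NULL)
  comp <- igraph::components(g, mode = "strong")
  bad <- which(comp$csize > 1L)[1L]
  names(comp$membership)[comp$membership == bad]
}

#' Read an OBO 1.2 ontology subset
#'
#' Parses `[Term]` stanzas, keeping `id`, `name`, `namespace` and `is_a`
#' lines; stanzas flagged `is_obsolete: true` are excluded together with
#' their edges. The result is validated (declared endpoints, acyclic).
#'
#' @param path path to an OBO flat file.
#' @return An [ontology] object.
#' @export
load_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  # split into stanzas at [Term] headers; header material before the first
  # stanza and non-Term stanzas ([Typedef] etc.) are ignored
  starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  if (!length(term_starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(); nms <- character(); nss <- character()
  obs <- logical()
  e_child <- character(); e_parent <- character()
  for (s in term_starts) {
    end <- min(bounds[bounds > s]) - 1L
    block <- lines[(s + 1L):end]
    getval <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      if (!length(v)) return(NA_character_)
      trimws(sub(paste0("^", key, ":"), "", v[1L]))
    }
    id <- getval("id")
    if (is.na(id)) stop("[Term] stanza without id line in ", path)
    ids <- c(ids, id)
    nms <- c(nms, getval("name"))
    nss <- c(nss, getval("namespace"))
    obs <- c(obs, identical(getval("is_obsolete"), "true"))
    isa <- block[startsWith(block, "is_a:")]
    if (length(isa)) {
      # strip trailing "! name" comments
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", isa)))
      e_child <- c(e_child, rep(id, length(tgt)))
      e_parent <- c(e_parent, tgt)
    }
  }
  dangling <- setdiff(e_parent, ids)
  if (length(dangling)) {
    stop("is_a target not declared in file: ", paste(dangling, collapse = ", "))
  }
  keep <- !obs
  terms <- data.frame(id = ids[keep], name = nms[keep], namespace = nss[keep],
                      stringsAsFactors = FALSE)
  ed <- data.frame(child = e_child, parent = e_parent, stringsAsFactors = FALSE)
  # edges touching obsolete terms are dropped with the term
  ed <- ed[ed$child %in% terms$id & ed$parent %in% terms$id, , drop = FALSE]
  ontology(terms, ed)
}

#' Transitive ancestors or descendants of a term
#'
#' Closure under the `is_a` relation, excluding the query term itself.
#' Ancestors of a root (and descendants of a leaf) are the empty set.
#'
#' @param ont an [ontology].
#' @param term a term id present in `ont`.
#' @param direction `"ancestors"` (towards the root) or `"descendants"`.
#' @return character vector of term ids.
#' @export
term_closure <- function(ont, term, direction = c("ancestors", "descendants")) {
  direction <- match.arg(direction)
  if (!term %in% ont$terms$id) stop("unknown term id: ", term)
  g <- .ontology_graph(ont)
  mode <- if (direction == "ancestors") "out" else "in"
  reach <- igraph::subcomponent(g, term, mode = mode)
  setdiff(names(reach), term)
}

# ancestor sets for every term at once (list keyed by term id);
# edges child -> parent so "out" reachability is ancestry
.all_ancestors <- function(ont) {
  g <- .ontology_graph(ont)
  ids <- ont$terms$id
  out <- igraph::ego(g, order = nrow(ont$terms), nodes = ids, mode = "out")
  res <- lapply(seq_along(ids), function(i) setdiff(names(out[[i]]), ids[i]))
  names(res) <- ids
  res
}

#' Annotation sets: direct and ancestor-closed term assignments
#'
#' @param direct named list: contig id -> character vector of term ids.
#' @param ont an [ontology].
#' @param on_unknown what to do with annotations to terms absent from the
#'   ontology: `"warn"` drops them with a warning, `"error"` aborts.
#' @return An `annotation_set`: list with `direct` and `propagated`
#'   components, both named lists of term-id vectors. `propagated` is closed
#'   under the `is_a` ancestor relation (true-path rule) and is a superset
#'   of `direct` for every contig.
#' @export
propagate_annotations <- function(direct, ont, on_unknown = c("warn", "error")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(is.list(direct))
  known <- ont$terms$id
  unknown <- setdiff(unique(unlist(direct, use.names = FALSE)), known)
  if (length(unknown)) {
    msg <- paste0("annotation(s) to unknown term(s) skipped: ",
                  paste(unknown, collapse = ", "))
    if (on_unknown == "error") stop(msg) else warning(msg)
    direct <- lapply(direct, function(x) x[x %in% known])
  }
  anc <- .all_ancestors(ont)
  propagated <- lapply(direct, function(tt) {
    if (!length(tt)) return(character())
    sort(unique(c(tt, unlist(anc[tt], use.names = FALSE))))
  })
  structure(list(direct = lapply(direct, function(x) sort(unique(x))),
                 propagated = propagated),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$direct), "contigs,",
      length(unique(unlist(x$direct))), "direct terms,",
      length(unique(unlist(x$propagated))), "after propagation\n")
  invisible(x)
}

#' Read a two-column contig-to-term annotation table
#'
#' Tab-separated `contig_id<TAB>term_id`, one pair per row; `#` comment
#' lines allowed; a header row `contig_id	term_id` is recognised and
#' skipped.
#'
#' @param path path to the TSV file.
#' @return named list contig id -> character vector of term ids (the
#'   `direct` input of [propagate_annotations()]).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character", col.names = c("contig_id", "term_id"))
  if (nrow(df) && df$contig_id[1] == "contig_id") df <- df[-1, , drop = FALSE]
  split(df$term_id, df$contig_id)
}

#' Write an annotation table
#' @param direct named list contig id -> term ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(direct, path) {
  df <- data.frame(
    contig_id = rep(names(direct), lengths(direct)),
    term_id = unlist(direct, use.names = FALSE), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an ontology as a minimal OBO 1.2 file
#'
#' Emits only the subset of OBO that [load_obo()] reads, so simulated
#' ontologies round-trip losslessly.
#'
#' @param ont an [ontology].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  parents <- split(ont$edges$parent, ont$edges$child)
  for (i in seq_len(nrow(ont$terms))) {
    id <- ont$terms$id[i]
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", ont$terms$name[i]),
                 paste0("namespace: ", ont$terms$namespace[i])), con)
    for (p in parents[[id]]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}
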