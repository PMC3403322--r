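#' GO graph objects
#'
#' A `go_graph` holds the is_a hierarchy of a Gene Ontology release: the set
#' of non-obsolete term identifiers, directed child-to-parent `is_a` edges,
#' and the namespace of every term. Obsolete terms encountered at parse time
#' are recorded separately and carry no edges. Only `is_a` edges are
#' represented; other relationship types (`part_of`, `regulates`, ...) are
#' outside the hierarchy this package uses for leaf detection and edge
#' distance.
#'
#' @param terms character vector of term ids (`"GO:NNNNNNN"`).
#' @param edges data frame with columns `child`, `parent`; one row per
#'   `is_a` edge. Both endpoints must appear in `terms`.
#' @param namespace character vector parallel to `terms`, each one of
#'   `"molecular_function"`, `"biological_process"`, `"cellular_component"`.
#' @param obsolete character vector of obsolete term ids (excluded from the
#'   graph).
#'
#' @return An object of class `go_graph`.
#' @export
go_graph <- function(terms, edges, namespace, obsolete = character()) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) .stop("duplicate GO term ids")
  if (length(namespace) != length(terms)) {
    .stop("'namespace' must have one entry per term")
  }
  ns_ok <- namespace %in% c("molecular_function", "biological_process",
                            "cellular_component")
  if (!all(ns_ok)) {
    .stop("unknown namespace: ", paste(unique(namespace[!ns_ok]), collapse = ", "))
  }
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    if (!all(c("child", "parent") %in% names(edges))) {
      .stop("'edges' needs columns 'child' and 'parent'")
    }
    missing <- setdiff(unique(c(edges$child, edges$parent)), terms)
    if (length(missing)) {
      .stop("is_a edge endpoint(s) not defined as terms: ",
            paste(head(missing, 5), collapse = ", "))
    }
  } else {
    edges <- data.frame(child = character(), parent = character())
  }
  g <- structure(
    list(terms = terms,
         namespace = stats::setNames(as.character(namespace), terms),
         edges = edges[, c("child", "parent")],
         obsolete = as.character(obsolete)),
    class = "go_graph")
  if (nrow(edges) > 0) {
    ig <- .go_igraph(g, directed = TRUE)
    if (!igraph::is_dag(ig)) .stop("is_a edges contain a cycle")
  }
  g
}

# internal: igraph view of the hierarchy, optionally restricted to a namespace
.go_igraph <- function(g, directed = TRUE, namespace = NULL) {
  terms <- g$terms
  edges <- g$edges
  if (!is.null(namespace)) {
    terms <- terms[g$namespace[terms] == namespace]
    keep <- edges$child %in% terms & edges$parent %in% terms
    edges <- edges[keep, , drop = FALSE]
  }
  ig <- igraph::make_empty_graph(n = 0, directed = directed)
  ig <- igraph::add_vertices(ig, length(terms), name = terms)
  if (nrow(edges) > 0) {
    ig <- igraph::add_edges(ig, rbind(edges$child, edges$parent))
  }
  ig
}

#' @export
print.go_graph <- function(x, ...) {
  cat(sprintf("go_graph: %d terms, %d is_a edges, %d obsolete\n",
              length(x$terms), nrow(x$edges), length(x$obsolete)))
  for (ns in unique(x$namespace)) {
    cat(sprintf("  %s: %d terms\n", ns, sum(x$namespace == ns)))
  }
  invisible(x)
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas from a Gene Ontology OBO v1.2 flat file, keeping
#' the id, namespace and `is_a` parents of every non-obsolete term. Obsolete
#' terms are recorded on the returned object but excluded from the graph
#' (they carry no edges). Trailing `! comment` text on `is_a` lines is
#' ignored, as are header lines and non-Term stanzas (e.g. `[Typedef]`).
#'
#' @param path path to an OBO 1.2 text file.
#' @return A [go_graph].
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) .stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    .stop("empty OBO file: ", path)
  }
  stanza <- NA_character_    # NA = header section
  cur <- NULL
  terms <- list()
  flush <- function(cur) { if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1L]] <<- cur }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "!")) next
    if (grepl("^\\[.+\\]$", ln)) {
      flush(cur)
      stanza <- substr(ln, 2, nchar(ln) - 1)
      cur <- if (identical(stanza, "Term")) list(is_a = character(), obsolete = FALSE) else NULL
      next
    }
    m <- regexec("^([A-Za-z_-]+):\\s*(.*)$", ln)[[1]]
    if (m[1] == -1) .stop(sprintf("malformed OBO line %d: '%s'", i, lines[[i]]))
    if (!identical(stanza, "Term")) next
    key <- regmatches(ln, regexec("^([A-Za-z_-]+):\\s*(.*)$", ln))[[1]]
    val <- key[3]; key <- key[2]
    if (key == "id") {
      cur$id <- val
    } else if (key == "namespace") {
      cur$namespace <- val
    } else if (key == "is_a") {
      cur$is_a <- c(cur$is_a, trimws(sub("!.*$", "", val)))
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(trimws(val), "true")
    }
  }
  flush(cur)
  if (length(terms) == 0) .stop("no [Term] stanzas in ", path)
  obs <- vapply(terms, function(t) isTRUE(t$obsolete), logical(1))
  ids <- vapply(terms, `[[`, character(1), "id")
  ns <- vapply(terms, function(t) t$namespace %||% "molecular_function", character(1))
  live <- terms[!obs]
  edges <- do.call(rbind, lapply(live, function(t) {
    if (length(t$is_a) == 0) return(NULL)
    data.frame(child = t$id, parent = t$is_a)
  }))
  if (is.null(edges)) edges <- data.frame(child = character(), parent = character())
  # drop edges whose parent is obsolete (an obsolete term carries no edges)
  edges <- edges[!(edges$parent %in% ids[obs]), , drop = FALSE]
  go_graph(terms = ids[!obs], edges = edges, namespace = ns[!obs],
           obsolete = ids[obs])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leaf terms of a GO namespace
#'
#' A leaf is a term with no child: no other term of the same namespace names
#' it as an `is_a` parent. Leaves are the functionally most specific
#' annotation level and are the terms this method trains and predicts on.
#'
#' @param g a [go_graph].
#' @param namespace one of the three GO namespaces.
#' @return Character vector of leaf term ids (sorted).
#' @export
go_leaves <- function(g, namespace = "molecular_function") {
  stopifnot(inherits(g, "go_graph"))
  if (!namespace %in% c("molecular_function", "biological_process",
                        "cellular_component")) {
    .stop("unknown namespace: ", namespace)
  }
  in_ns <- g$terms[g$namespace[g$terms] == namespace]
  parents_with_children <- unique(g$edges$parent[g$edges$child %in% in_ns &
                                                   g$edges$parent %in% in_ns])
  sort(setdiff(in_ns, parents_with_children))
}

#' Edge distance between two GO terms
#'
#' Length of the shortest path between two terms treating `is_a` edges as
#' undirected, restricted to the namespace of the first term. Used as a
#' proxy for functional divergence: siblings under one parent are at
#' distance 2, a child and its parent at distance 1.
#'
#' @param g a [go_graph].
#' @param t1,t2 term ids present in the graph.
#' @return A non-negative integer; `0` iff `t1 == t2`; `Inf` when the terms
#'   are unreachable from one another (including terms of different
#'   namespaces).
#' @export
go_edge_distance <- function(g, t1, t2) {
  stopifnot(inherits(g, "go_graph"))
  for (t in c(t1, t2)) if (!t %in% g$terms) .stop("term not in graph: ", t)
  if (identical(t1, t2)) return(0)
  ns <- g$namespace[[t1]]
  if (!identical(ns, g$namespace[[t2]])) return(Inf)
  ig <- .go_igraph(g, directed = FALSE, namespace = ns)
  d <- igraph::distances(ig, v = t1, to = t2)[1, 1]
  as.numeric(d)
}

# internal: all-pairs edge distances within one namespace (term x term matrix)
.go_distance_matrix <- function(g, namespace = "molecular_function") {
  ig <- .go_igraph(g, directed = FALSE, namespace = namespace)
  igraph::distances(ig)
}

#' Write a go_graph back to OBO 1.2 text
#'
#' Minimal emitter covering what [parse_obo()] reads: one `[Term]` stanza
#' per term with id, namespace and `is_a` lines, obsolete stanzas flagged.
#'
#' @param g a [go_graph].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(g, path) {
  stopifnot(inherits(g, "go_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in g$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("namespace: ", g$namespace[[t]])), con)
    parents <- g$edges$parent[g$edges$child == t]
    for (p in parents) writeLines(paste0("is_a: ", p), con)
  }
  for (t in g$obsolete) {
    writeLines(c("", "[Term]", paste0("id: ", t), "is_obsolete: true"), con)
  }
  invisible(path)
}
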