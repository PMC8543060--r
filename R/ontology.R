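#' Default contribution weights for ontology relations
#'
#' The Wang graph-based similarity discounts an ancestor's contribution by a
#' per-edge-type factor; 0.8 for `is_a` and 0.6 for `part_of` are the
#' metric's standard constants.
#'
#' @export
DEFAULT_SEMANTIC_WEIGHTS <- c(is_a = 0.8, part_of = 0.6)

#' Construct an ontology DAG
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param relations data.frame with columns `child`, `parent`, `type`
#'   (type in `is_a`, `part_of`), edges pointing child -> parent.
#' @return Object of class `ontology_dag` with components `terms`,
#'   `relations` and `graph` (directed igraph, child -> parent, edge
#'   attribute `type`).
#' @export
ontology_dag <- function(terms, relations) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  if (nrow(relations) == 0L)
    relations <- data.frame(child = character(), parent = character(),
                            type = character(), stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent", "type") %in% names(relations)))
  if (anyDuplicated(terms$id))
    stop("duplicate term ids")
  if (nrow(relations) > 0L) {
    if (!all(relations$type %in% c("is_a", "part_of")))
      stop("relation types must be is_a or part_of")
    missing <- setdiff(c(relations$child, relations$parent), terms$id)
    if (length(missing))
      stop("relation endpoint(s) not among terms: ",
           paste(head(missing, 5L), collapse = ", "))
  }
  terms <- terms[order(terms$id), , drop = FALSE]
  relations <- unique(relations[order(relations$child, relations$parent,
                                      relations$type), , drop = FALSE])
  rownames(terms) <- NULL
  rownames(relations) <- NULL

  g <- igraph::graph_from_data_frame(
    d = relations, directed = TRUE,
    vertices = data.frame(id = terms$id, stringsAsFactors = FALSE))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1L)]
    stop("ontology relations contain a cycle involving: ",
         paste(head(sort(cyc), 10L), collapse = " -> "))
  }
  structure(list(terms = terms, relations = relations, graph = g),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("Ontology DAG:", nrow(x$terms), "terms,",
      nrow(x$relations), "relations (",
      sum(x$relations$type == "is_a"), "is_a,",
      sum(x$relations$type == "part_of"), "part_of )\n")
  invisible(x)
}

#' Parse an OBO flat file into an ontology DAG
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 file: `id`, `name`,
#' `namespace`, `is_a` and `relationship: part_of` lines. Obsolete terms are
#' dropped; relation types other than `is_a`/`part_of` are ignored (their
#' count is reported). A cyclic relation set is a hard error naming terms on
#' a cycle.
#'
#' @param path path to the OBO file.
#' @return An [ontology_dag].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  is_term <- lines[starts] == "[Term]"
  ends <- c(starts[-1L] - 1L, length(lines))

  ids <- character(); nms <- character(); nss <- character()
  child <- character(); parent <- character(); type <- character()
  n_other_rel <- 0L
  strip <- function(x) sub("\\s*(!.*)?$", "", x)

  for (k in which(is_term)) {
    block <- lines[starts[k]:ends[k]]
    get1 <- function(key) {
      v <- grep(paste0("^", key, ": "), block, value = TRUE)
      if (length(v)) strip(sub(paste0("^", key, ": "), "", v[1L])) else NA_character_
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id) || !nzchar(id)) next
    ids <- c(ids, id)
    nms <- c(nms, if (is.na(get1("name"))) id else get1("name"))
    nss <- c(nss, if (is.na(get1("namespace"))) "biological_process" else get1("namespace"))

    isa <- strip(sub("^is_a: ", "", grep("^is_a: ", block, value = TRUE)))
    if (length(isa)) {
      child <- c(child, rep(id, length(isa)))
      parent <- c(parent, isa)
      type <- c(type, rep("is_a", length(isa)))
    }
    rel <- grep("^relationship: ", block, value = TRUE)
    if (length(rel)) {
      parts <- strsplit(strip(sub("^relationship: ", "", rel)), "\\s+")
      for (p in parts) {
        if (identical(p[1L], "part_of")) {
          child <- c(child, id); parent <- c(parent, p[2L])
          type <- c(type, "part_of")
        } else n_other_rel <- n_other_rel + 1L
      }
    }
  }
  if (n_other_rel > 0L)
    message("ignored ", n_other_rel,
            " relationship(s) of types other than is_a/part_of")

  keep <- parent %in% ids
  if (any(!keep)) {
    warning(sum(!keep), " relation(s) to undeclared/obsolete parent terms dropped")
    child <- child[keep]; parent <- parent[keep]; type <- type[keep]
  }
  ontology_dag(
    data.frame(id = ids, name = nms, namespace = nss, stringsAsFactors = FALSE),
    data.frame(child = child, parent = parent, type = type,
               stringsAsFactors = FALSE))
}

#' Write an ontology DAG as an OBO flat file
#'
#' Emits the dialect [read_obo()] consumes; terms are written in id order so
#' output is byte-reproducible.
#'
#' @param dag an [ontology_dag].
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    rel <- dag$relations[dag$relations$child == id, , drop = FALSE]
    writeLines(c(
      "[Term]",
      paste0("id: ", id),
      paste0("name: ", dag$terms$name[i]),
      paste0("namespace: ", dag$terms$namespace[i]),
      if (nrow(rel)) ifelse(rel$type == "is_a",
                            paste0("is_a: ", rel$parent),
                            paste0("relationship: part_of ", rel$parent)),
      ""), con)
  }
  invisible(path)
}

#' Semantic contribution values (S-values) of a term's ancestor closure
#'
#' For an anchor term `t`, every term in `{t} + ancestors(t)` receives a
#' contribution: 1 for the anchor, and for an ancestor the maximum over
#' child->parent paths of the product of per-edge weights. Computed by
#' dynamic programming over a topological order of the ancestor subgraph.
#'
#' @param dag an [ontology_dag].
#' @param term anchor term id.
#' @param weights named numeric, contribution weight per relation type.
#' @return List with `anchor`, `svalues` (named numeric over the ancestor
#'   closure, anchor included at 1) and `SV` (their sum).
#' @export
svalues <- function(dag, term, weights = DEFAULT_SEMANTIC_WEIGHTS) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$terms$id) stop("unknown term: ", term)
  stopifnot(all(weights > 0), all(weights < 1))
  g <- dag$graph
  closure <- igraph::subcomponent(g, term, mode = "out")$name
  sub <- igraph::induced_subgraph(g, closure)
  ord <- igraph::topo_sort(sub, mode = "out")$name  # children before parents
  s <- setNames(rep(0, length(ord)), ord)
  s[term] <- 1
  for (u in ord) {
    if (s[u] == 0) next
    out <- igraph::incident(sub, u, mode = "out")
    if (length(out) == 0L) next
    pts <- igraph::head_of(sub, out)$name
    w <- weights[igraph::edge_attr(sub, "type", out)]
    cand <- w * s[u]
    upd <- cand > s[pts]
    s[pts[upd]] <- cand[upd]
  }
  s <- s[s > 0]
  list(anchor = term, svalues = s, SV = sum(s))
}

#' Wang graph-based semantic similarity of two ontology terms
#'
#' `sim(a, b) = sum over common ancestors t of (S_a(t) + S_b(t)) /
#' (SV(a) + SV(b))`, where S-values and their sums SV come from [svalues()].
#' Symmetric, bounded in \[0, 1\], and `sim(a, a) = 1`.
#'
#' @inheritParams svalues
#' @param a,b term ids.
#' @return Similarity in \[0, 1\].
#' @export
wang_similarity <- function(dag, a, b, weights = DEFAULT_SEMANTIC_WEIGHTS) {
  sa <- svalues(dag, a, weights)
  sb <- svalues(dag, b, weights)
  wang_from_svalues(sa, sb)
}

wang_from_svalues <- function(sa, sb) {
  common <- intersect(names(sa$svalues), names(sb$svalues))
  if (length(common) == 0L) return(0)
  sum(sa$svalues[common] + sb$svalues[common]) / (sa$SV + sb$SV)
}
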