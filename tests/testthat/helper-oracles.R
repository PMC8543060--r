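# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph) so they can serve as cross-checks.

# distinct-neighbour degree by a linear scan over the edge table
oracle_degree <- function(kg, v) {
  e <- kg$edges
  length(unique(c(e$target[e$source == v], e$source[e$target == v])))
}

# |neighbours(candidate) 'intersect' members| by scanning the edge table
oracle_links <- function(kg, members, candidate) {
  e <- kg$edges
  nb <- unique(c(e$target[e$source == candidate],
                 e$source[e$target == candidate]))
  sum(nb %in% members)
}

# upper-tail hypergeometric by exhaustive enumeration of all C(N_U, M) draws;
# elements 1..K are the successes
oracle_hyper <- function(Ni, M, K, N_U) {
  draws <- utils::combn(N_U, M)
  mean(colSums(draws <= K) >= Ni)
}

# Benjamini-Yekutieli straight from the step-up definition
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i)
    min(ps[i:m] * m * cm / (i:m)), numeric(1))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# S-values by exhaustive enumeration of every child->parent path
oracle_svalues <- function(dag, term, weights = DEFAULT_SEMANTIC_WEIGHTS) {
  rel <- dag$relations
  s <- c(1)
  names(s) <- term
  recurse <- function(node, value) {
    up <- rel[rel$child == node, , drop = FALSE]
    for (i in seq_len(nrow(up))) {
      v <- value * weights[[up$type[i]]]
      p <- up$parent[i]
      if (is.na(s[p]) || v > s[p]) s[p] <<- v
      recurse(p, v)
    }
  }
  recurse(term, 1)
  s
}

oracle_wang <- function(dag, a, b, weights = DEFAULT_SEMANTIC_WEIGHTS) {
  sa <- oracle_svalues(dag, a, weights)
  sb <- oracle_svalues(dag, b, weights)
  common <- intersect(names(sa), names(sb))
  if (!length(common)) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# random DAG on n terms: edges only from higher to lower index, so acyclic
random_dag <- function(n, p_edge = 0.25, p_part_of = 0.3) {
  ids <- sprintf("T%02d", seq_len(n))
  child <- character(); parent <- character(); type <- character()
  for (i in seq_len(n)[-1]) {
    to <- which(stats::runif(i - 1) < p_edge)
    if (!length(to) && i > 1) to <- sample.int(i - 1, 1)  # keep it connected
    child <- c(child, rep(ids[i], length(to)))
    parent <- c(parent, ids[to])
    type <- c(type, ifelse(stats::runif(length(to)) < p_part_of,
                           "part_of", "is_a"))
  }
  ontology_dag(
    data.frame(id = ids, name = ids, namespace = "biological_process",
               stringsAsFactors = FALSE),
    data.frame(child = child, parent = parent, type = type,
               stringsAsFactors = FALSE))
}

# random block similarity matrix with given block sizes and similarities
block_similarity <- function(sizes, within, between, noise = 0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  m <- matrix(between, n, n)
  for (b in seq_along(sizes)) m[lab == b, lab == b] <- within
  if (noise > 0) {
    jit <- matrix(stats::runif(n * n, -noise, noise), n, n)
    jit <- (jit + t(jit)) / 2
    m <- pmin(pmax(m + jit, 0), 1)
  }
  diag(m) <- 1
  dimnames(m) <- list(sprintf("P%03d", seq_len(n)), sprintf("P%03d", seq_len(n)))
  attr(m, "labels") <- lab
  m
}

tiny_graph_file <- function(lines, dir = tempdir()) {
  path <- tempfile("kg", tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}
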