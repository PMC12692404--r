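#' Enumerate connected edge subgraphs
#'
#' All connected subgraphs with exactly `m` edges, each appearing once, in
#' lexicographic order of their sorted edge-index sets. Enumeration runs in
#' compiled code over the bond line graph with a canonical anchor-and-grow
#' rule, so no duplicates are generated.
#'
#' @param graph A `mol_graph`.
#' @param m Number of edges (1 to 7). `m > L` yields an empty list.
#' @return List of integer vectors of bond indices (rows of `graph$bonds`).
#' @export
enumerate_edge_subgraphs <- function(graph, m) {
  stopifnot(inherits(graph, "mol_graph"))
  if (!is.numeric(m) || length(m) != 1L || m < 1L) {
    rlang::abort("m must be a single integer >= 1")
  }
  m <- as.integer(m)
  if (m > graph$L) return(list())
  sets <- enumerate_subgraphs_cpp(graph$bonds$i - 1L, graph$bonds$j - 1L,
                                  nrow(graph$atoms), min(m, 7L))
  sets <- Filter(function(s) length(s) == m, sets)
  key <- vapply(sets, function(s) paste(sprintf("%04d", s), collapse = ""), "")
  sets[order(key)]
}

#' Classify a connected edge subgraph
#'
#' Kier-Hall structural typing of a connected edge set: `Ch` (chain/ring)
#' if it contains a cycle; otherwise `P` (path) when every atom has
#' subgraph degree at most 2, `C` (cluster/star) when exactly one atom has
#' degree 3 or more and all others are leaves, `PC` (path-cluster)
#' otherwise.
#'
#' @param graph A `mol_graph`.
#' @param edges Integer vector of bond indices forming a connected subgraph.
#' @return One of `"P"`, `"C"`, `"PC"`, `"Ch"`.
#' @export
classify_subgraph <- function(graph, edges) {
  stopifnot(inherits(graph, "mol_graph"), length(edges) >= 1L)
  bi <- graph$bonds$i[edges]
  bj <- graph$bonds$j[edges]
  atoms <- unique(c(bi, bj))
  # connectivity check over the edge set
  comp <- stats::setNames(seq_along(atoms), atoms)
  for (k in seq_along(edges)) {
    a <- comp[as.character(bi[k])]
    b <- comp[as.character(bj[k])]
    if (a != b) comp[comp == b] <- a
  }
  if (length(unique(comp)) > 1L) {
    rlang::abort("edge set is not connected")
  }
  if (length(edges) >= length(atoms)) return("Ch")
  deg <- table(factor(c(bi, bj), levels = atoms))
  nbig <- sum(deg >= 3)
  if (nbig == 0L) return("P")
  if (nbig == 1L && all(deg[deg < 3] == 1L)) return("C")
  "PC"
}

#' Subgraph census
#'
#' Counts of connected edge subgraphs per structural type and order, the
#' building block of the connectivity indices and the fragment-wise reading
#' of fitted models.
#'
#' @param graph A `mol_graph`.
#' @param m_max Largest order to enumerate (default 6).
#' @return Tibble with columns `type`, `m`, `count`.
#' @export
subgraph_census <- function(graph, m_max = 6L) {
  stopifnot(inherits(graph, "mol_graph"))
  ones_a <- rep(1, nrow(graph$atoms))
  ones_e <- rep(1, graph$L)
  df <- subgraph_census_cpp(graph$bonds$i - 1L, graph$bonds$j - 1L,
                            nrow(graph$atoms), as.integer(m_max),
                            ones_a, ones_e)
  as_tibble(df) |>
    select("type", "m", "count") |>
    mutate(count = as.integer(.data$count))
}
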