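# Undirected igraph view of a gecn/subnetwork (directed inputs collapsed).
gecn_igraph <- function(g) {
  stopifnot(inherits(g, "gecn"))
  if (g$directed) g <- collapse_to_undirected(g)
  igraph::graph_from_data_frame(
    g$edges[, c("from", "to")], directed = FALSE,
    vertices = tibble(name = g$nodes$enzyme_id))
}

#' Connected components of an enzyme network
#'
#' Directed networks are collapsed to undirected first. Components are
#' sorted by size descending, ties broken by the lexicographically smallest
#' member; per-component edge counts are reported alongside.
#'
#' @param g A `gecn` or `subnetwork`.
#' @return A `component_decomposition`: list with `components` (tibble
#'   `component`, `nodes` list-column, `n_nodes`, `n_edges`) and
#'   `membership` (tibble `node`, `component`).
#' @export
connected_components <- function(g) {
  if (g$directed) g <- collapse_to_undirected(g)
  nodes <- g$nodes$enzyme_id
  if (length(nodes) == 0) {
    return(structure(list(
      components = tibble(component = integer(), nodes = list(),
                          n_nodes = integer(), n_edges = integer()),
      membership = tibble(node = character(), component = integer())),
      class = "component_decomposition"))
  }
  ig <- gecn_igraph(g)
  memb <- igraph::components(ig)$membership[nodes]
  groups <- split(nodes, memb)
  groups <- lapply(groups, lex_sort)
  sizes <- vapply(groups, length, integer(1))
  smallest <- vapply(groups, `[`, character(1), 1)
  ord <- order(-sizes, smallest, method = "radix")
  groups <- groups[ord]
  edge_counts <- vapply(groups, function(ns) {
    sum(g$edges$from %in% ns & g$edges$to %in% ns)
  }, numeric(1))
  components <- tibble(component = seq_along(groups), nodes = unname(groups),
                       n_nodes = unname(sizes[ord]),
                       n_edges = as.integer(unname(edge_counts)))
  membership <- tidyr::unnest(components[, c("component", "nodes")],
                              cols = "nodes") |>
    select(node = "nodes", "component")
  structure(list(components = components, membership = membership),
            class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat("<component_decomposition> ", nrow(x$components), " component(s)\n", sep = "")
  print(x$components, n = 10)
  invisible(x)
}

#' Number of connected node pairs
#'
#' The NetworkAnalyzer-style statistic: the count of unordered node pairs
#' lying in the same connected component, i.e. the sum of k(k-1)/2 over
#' component sizes k.
#'
#' @param g A `gecn`/`subnetwork`, or a `component_decomposition`.
#' @return Integer count.
#' @export
connected_pairs_count <- function(g) {
  comp <- if (inherits(g, "component_decomposition")) g else connected_components(g)
  k <- comp$components$n_nodes
  as.integer(sum(k * (k - 1) / 2))
}

# Collapse a network to one node per EC key: nodes with an empty EC are
# excluded; partial ECs (e.g. "2.4.1.-") are kept as exact strings when
# include_partial is TRUE. Two EC keys are adjacent iff any pair of their
# representative enzymes is adjacent.
ec_collapse <- function(g, include_partial = TRUE) {
  if (g$directed) g <- collapse_to_undirected(g)
  nodes <- g$nodes |> mutate(ec_key = trimws(.data$ec))
  excluded <- nodes |> filter(!nzchar(.data$ec_key) |
                                (!include_partial & grepl("-", .data$ec_key, fixed = TRUE)))
  nodes <- nodes |> filter(!.data$enzyme_id %in% excluded$enzyme_id)
  key_of <- stats::setNames(nodes$ec_key, nodes$enzyme_id)
  edges <- g$edges |>
    filter(.data$from %in% names(key_of), .data$to %in% names(key_of)) |>
    mutate(ka = key_of[.data$from], kb = key_of[.data$to]) |>
    mutate(u = pmin(.data$ka, .data$kb), v = pmax(.data$ka, .data$kb)) |>
    filter(.data$u != .data$v) |>
    distinct(.data$u, .data$v) |>
    arrange(.data$u, .data$v)
  list(keys = lex_sort(unique(nodes$ec_key)), edges = edges,
       n_excluded = nrow(excluded))
}

#' Cross-species overlap of two enzyme networks keyed on EC number
#'
#' Entity ids are species-specific, so networks from different organisms
#' are compared on the species-independent EC number. Each network is
#' collapsed to one node per EC (enzymes without an EC are excluded and
#' counted; partial ECs such as "2.4.1.-" match only under exact string
#' equality unless excluded via `include_partial = FALSE`). The overlap
#' graph has the shared ECs as nodes and an edge iff the EC pair is
#' adjacent in **both** networks.
#'
#' @param g1,g2 `gecn` objects with EC-annotated nodes.
#' @param key Node key; only `"ec"` is supported.
#' @param include_partial Keep partial ECs as exact-match keys? Default
#'   `TRUE`.
#' @return An `overlap_result`: list with `shared_keys`, `graph` (an
#'   undirected `gecn` keyed by EC), `components` (its
#'   [connected_components()]), and `n_excluded` per input.
#' @export
cross_species_overlap <- function(g1, g2, key = "ec", include_partial = TRUE) {
  stopifnot(identical(key, "ec"))
  c1 <- ec_collapse(g1, include_partial)
  c2 <- ec_collapse(g2, include_partial)
  shared <- intersect(c1$keys, c2$keys)
  e1 <- c1$edges |> filter(.data$u %in% shared, .data$v %in% shared)
  e2 <- c2$edges |> filter(.data$u %in% shared, .data$v %in% shared)
  edges <- inner_join(e1, e2, by = c("u", "v")) |> arrange(.data$u, .data$v)
  graph <- new_gecn(
    nodes = tibble(enzyme_id = lex_sort(shared), ec = lex_sort(shared),
                   gene_ids = rep(list(character()), length(shared))),
    edges = tibble(from = edges$u, to = edges$v,
                   linking_compounds = rep(list(character()), nrow(edges))),
    directed = FALSE)
  structure(
    list(shared_keys = lex_sort(shared), graph = graph,
         components = connected_components(graph),
         n_excluded = c(g1 = c1$n_excluded, g2 = c2$n_excluded)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> ", length(x$shared_keys), " shared EC(s), ",
      nrow(x$graph$edges), " shared edge(s), ",
      nrow(x$components$components), " component(s)\n", sep = "")
  invisible(x)
}

#' Node degrees of an enzyme network
#'
#' Directed networks are collapsed to undirected first. Rows are ordered by
#' degree descending then node id; the summary (min/median/max) is attached
#' and available via [glance()].
#'
#' @param g A `gecn` or `subnetwork`.
#' @return A tibble with columns `node`, `degree`.
#' @export
degree_stats <- function(g) {
  if (g$directed) g <- collapse_to_undirected(g)
  nodes <- g$nodes$enzyme_id
  deg <- stats::setNames(rep(0L, length(nodes)), nodes)
  if (nrow(g$edges) > 0) {
    tab <- table(c(g$edges$from, g$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  out <- tibble(node = nodes, degree = as.integer(deg)) |>
    arrange(desc(.data$degree), .data$node)
  attr(out, "summary") <- tibble(
    min_degree = if (length(deg)) min(deg) else NA_integer_,
    median_degree = if (length(deg)) stats::median(deg) else NA_real_,
    max_degree = if (length(deg)) max(deg) else NA_integer_)
  out
}
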