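# Directed reaction-to-reaction coupling graph: r1 -> r2 iff some
# (effective) product of r1 is an (effective) substrate of r2 and the
# compound is not currency. Reversible reactions contribute both
# orientations of their substrate/product sets.
reaction_link_graph <- function(db, currency = default_currency_set(),
                                reaction_ids = NULL) {
  rx <- db$reactions
  if (!is.null(reaction_ids)) rx <- rx[rx$reaction_id %in% reaction_ids, , drop = FALSE]
  if (nrow(rx) == 0) {
    return(list(nodes = character(),
                edges = tibble(from = character(), to = character(),
                               linking_compounds = list())))
  }
  long <- purrr::pmap_dfr(
    list(rx$reaction_id, rx$substrate_ids, rx$product_ids, rx$reversible),
    function(rid, subs, prods, rev) {
      p <- unique(c(prods, if (rev) subs))
      s <- unique(c(subs, if (rev) prods))
      bind_rows(
        if (length(p)) tibble(reaction_id = rid, compound_id = p, role = "product"),
        if (length(s)) tibble(reaction_id = rid, compound_id = s, role = "substrate")
      )
    }
  )
  edges <- tibble(from = character(), to = character(), linking_compounds = list())
  if (nrow(long) > 0) {
    long <- long |>
      filter(!in_currency(.data$compound_id, currency)) |>
      mutate(key = norm_token(.data$compound_id))
    pairs <- inner_join(
      long |> filter(.data$role == "product") |>
        select("key", from = "reaction_id", "compound_id"),
      long |> filter(.data$role == "substrate") |>
        select("key", to = "reaction_id"),
      by = "key", relationship = "many-to-many"
    ) |>
      filter(.data$from != .data$to)
    if (nrow(pairs) > 0) {
      edges <- pairs |>
        distinct(.data$from, .data$to, .data$compound_id) |>
        arrange(.data$from, .data$to, .data$compound_id) |>
        summarise(linking_compounds = list(unique(.data$compound_id)),
                  .by = c("from", "to"))
    }
  }
  list(nodes = lex_sort(rx$reaction_id), edges = edges)
}

# Adjacency as named list of lexicographically sorted successor vectors.
adj_list <- function(nodes, edges, reverse = FALSE) {
  out <- stats::setNames(rep(list(character()), length(nodes)), nodes)
  if (nrow(edges) > 0) {
    sp <- if (reverse) split(edges$from, edges$to) else split(edges$to, edges$from)
    for (k in names(sp)) out[[k]] <- lex_sort(unique(sp[[k]]))
  }
  out
}

# Remove edges until the digraph is acyclic: repeatedly delete the
# lexicographically smallest (from, to) edge lying inside a non-trivial
# strongly connected component. Deterministic; warns once.
break_cycles <- function(nodes, edges) {
  removed <- 0L
  while (nrow(edges) > 0) {
    ig <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                        directed = TRUE, vertices = nodes)
    comp <- igraph::components(ig, mode = "strong")
    if (comp$no == length(nodes)) break
    memb <- comp$membership[nodes]
    cyc <- edges |>
      filter(memb[.data$from] == memb[.data$to]) |>
      arrange(.data$from, .data$to)
    if (nrow(cyc) == 0) break
    drop_from <- cyc$from[1]; drop_to <- cyc$to[1]
    edges <- edges |> filter(!(.data$from == drop_from & .data$to == drop_to))
    removed <- removed + 1L
  }
  if (removed > 0) {
    warn(paste0("cycle(s) in reaction coupling graph: cut ", removed,
                " back-edge(s) (lexicographically smallest first)"))
  }
  edges
}

# All maximal simple paths in a digraph, capped. A path is maximal when it
# cannot be extended at either end by a node not already on it. Returns
# list(paths = list of character vectors, truncated = flag). Paths are
# sorted by length descending, then by first node id.
maximal_simple_paths <- function(nodes, edges, max_paths = 10000L) {
  if (length(nodes) == 0) return(list(paths = list(), truncated = FALSE))
  succ <- adj_list(nodes, edges)
  pred <- adj_list(nodes, edges, reverse = TRUE)
  paths <- list()
  explored <- 0L
  truncated <- FALSE

  extend <- function(path) {
    if (truncated) return()
    explored <<- explored + 1L
    if (explored > max_paths) { truncated <<- TRUE; return() }
    tail_nb <- setdiff(succ[[path[length(path)]]], path)
    head_nb <- setdiff(pred[[path[1]]], path)
    if (length(tail_nb) == 0 && length(head_nb) == 0) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (nxt in tail_nb) extend(c(path, nxt))
    # Paths whose head is still extendable are enumerated from the earlier
    # start node instead; only recurse forward.
  }

  # Start from every node whose in-neighborhood does not force a longer
  # path through it (sources), plus every node at all (covers cycles and
  # ensures maximal paths whose head in-neighbors all lie on the path).
  for (v in lex_sort(nodes)) extend(v)

  # Deduplicate (a path can be reached from several starts only if equal).
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths <- paths[!duplicated(keys)]
  ord <- order(-vapply(paths, length, integer(1)),
               vapply(paths, `[`, character(1), 1), method = "radix")
  list(paths = paths[ord], truncated = truncated)
}

chain_steps <- function(db, rxn_ids, currency, re = NULL) {
  re <- re %||% reaction_enzymes(db)
  rx <- db$reactions[match(rxn_ids, db$reactions$reaction_id), , drop = FALSE]
  n <- length(rxn_ids)
  link <- rep(NA_character_, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      p <- unique(c(rx$product_ids[[i]], if (rx$reversible[i]) rx$substrate_ids[[i]]))
      s <- unique(c(rx$substrate_ids[[i + 1]],
                    if (rx$reversible[i + 1]) rx$product_ids[[i + 1]]))
      common <- p[norm_token(p) %in% norm_token(s)]
      common <- common[!in_currency(common, currency)]
      link[i] <- if (length(common) > 0) lex_sort(common)[1] else NA_character_
    }
  }
  tibble(
    step = seq_len(n),
    reaction_id = rxn_ids,
    ec = rx$ec,
    enzyme_ids = lapply(rxn_ids, function(r) lex_sort(re$enzyme_id[re$reaction_id == r])),
    substrate_ids = rx$substrate_ids,
    product_ids = rx$product_ids,
    link_to_next = link
  )
}

#' Reconstruct the reaction chain(s) of a declared pathway
#'
#' Orders a pathway's reactions into consecutive-step chains in which each
#' step's product is the next step's substrate via a non-currency linking
#' metabolite. If the pathway table declares a `reaction_order`, that order
#' is used as a single chain. Otherwise the order is inferred as maximal
#' paths of the product-to-substrate coupling graph (a topological order;
#' ties broken by lexicographic reaction id); a branched pathway yields a
#' chain cover — one chain per maximal path. Cycles are cut at the
#' lexicographically smallest back-edge with a warning.
#'
#' @param db A [pathway_db()].
#' @param pathway_id Pathway id present in `db`.
#' @param currency A [currency_set()].
#' @return A `pathway_chain`: list with `pathway_id` and `chains`, a list
#'   of step tibbles (`step`, `reaction_id`, `ec`, `enzyme_ids`,
#'   `substrate_ids`, `product_ids`, `link_to_next`) sorted by length
#'   descending then first reaction id.
#' @export
pathway_chain <- function(db, pathway_id, currency = default_currency_set()) {
  stopifnot(inherits(db, "pathway_db"))
  declared <- character()
  pw_row <- which(db$pathways$pathway_id == pathway_id)
  if (length(pw_row) == 1) declared <- db$pathways$reaction_order[[pw_row]]
  members <- db$reactions$reaction_id[
    vapply(db$reactions$pathway_ids, function(p) pathway_id %in% p, logical(1))]
  rxn_ids <- unique(c(declared, members))
  if (length(rxn_ids) == 0) abort(paste0("unknown or empty pathway: ", pathway_id))

  if (length(declared) > 0) {
    chains <- list(chain_steps(db, declared, currency))
  } else {
    glue <- reaction_link_graph(db, currency, reaction_ids = rxn_ids)
    edges <- break_cycles(glue$nodes, glue$edges)
    mp <- maximal_simple_paths(glue$nodes, edges)
    chains <- lapply(mp$paths, chain_steps, db = db, currency = currency)
  }
  structure(list(pathway_id = pathway_id, chains = chains),
            class = "pathway_chain")
}

#' @export
print.pathway_chain <- function(x, ...) {
  cat("<pathway_chain> pathway ", x$pathway_id, ": ", length(x$chains),
      " chain(s); longest ", if (length(x$chains)) nrow(x$chains[[1]]) else 0L,
      " reaction(s)\n", sep = "")
  invisible(x)
}

#' Number of reactions in the longest chain of a pathway chain cover
#' @param chain A `pathway_chain`.
#' @return Integer.
#' @export
chain_length <- function(chain) {
  stopifnot(inherits(chain, "pathway_chain"))
  if (length(chain$chains) == 0) 0L else nrow(chain$chains[[1]])
}

new_route <- function(steps) structure(list(steps = steps), class = "route")

#' @export
print.route <- function(x, ...) {
  cat("<route> ", nrow(x$steps), " reaction(s): ",
      paste(x$steps$reaction_id, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Length of a route in reactions
#' @param route A `route`.
#' @return Integer.
#' @export
route_length <- function(route) nrow(route$steps)

#' Extract maximal DEG-covered consecutive-step routes
#'
#' The "guilt by association" core: a route is an ordered sequence of
#' distinct reactions in which every consecutive pair shares a non-currency
#' metabolite (the product of one step feeding the substrate of the next)
#' and every step is catalyzed by at least one DEG-encoded enzyme (any
#' isozyme gene qualifying makes the step qualify). Returned routes are
#' maximal: not extendable at either end by another qualifying step.
#'
#' @param x Where to search: a `pathway_chain` (or list of them) restricts
#'   the search to those reactions; a `subnetwork` or `gecn` restricts it
#'   to reactions catalyzed by the network's enzymes; a `pathway_db`
#'   searches all reactions.
#' @param degs A `deg_set` (or character vector of DEG gene ids).
#' @param db The [pathway_db()] supplying reactions and gene-enzyme links.
#' @param currency A [currency_set()].
#' @param max_paths Enumeration cap (>= 1); when hit, the result carries
#'   `truncated = TRUE` rather than failing silently.
#' @param min_len Drop maximal routes shorter than this many reactions.
#' @return A `route_set`: list with `routes` (list of `route`, sorted by
#'   length descending then first reaction id) and `truncated`.
#' @export
find_maximal_routes <- function(x, degs, db, currency = default_currency_set(),
                                max_paths = 10000L, min_len = 1L) {
  stopifnot(inherits(db, "pathway_db"), max_paths >= 1)
  re <- reaction_enzymes(db)

  candidate <- if (inherits(x, "pathway_chain")) {
    unique(unlist(lapply(x$chains, function(ch) ch$reaction_id)))
  } else if (is.list(x) && length(x) > 0 && all(vapply(x, inherits, logical(1), "pathway_chain"))) {
    unique(unlist(lapply(x, function(pc) unlist(lapply(pc$chains, function(ch) ch$reaction_id)))))
  } else if (inherits(x, "gecn")) {
    unique(re$reaction_id[re$enzyme_id %in% x$nodes$enzyme_id])
  } else if (inherits(x, "pathway_db")) {
    x$reactions$reaction_id
  } else {
    abort("x must be a pathway_chain (or list of them), a gecn/subnetwork, or a pathway_db")
  }

  dmap <- map_degs_to_enzymes(degs, db)
  covered <- unique(re$reaction_id[re$enzyme_id %in% dmap$enzyme_ids])
  qualifying <- intersect(candidate, covered)

  glue <- reaction_link_graph(db, currency, reaction_ids = qualifying)
  mp <- maximal_simple_paths(glue$nodes, glue$edges, max_paths = max_paths)
  routes <- lapply(mp$paths, function(p) {
    steps <- chain_steps(db, p, currency, re = re)
    steps$deg_enzyme_ids <- lapply(steps$enzyme_ids, intersect, y = dmap$enzyme_ids)
    steps$deg_gene_ids <- lapply(steps$deg_enzyme_ids, function(ez) {
      lex_sort(unique(dmap$mapping$gene_id[dmap$mapping$enzyme_id %in% ez]))
    })
    new_route(steps)
  })
  routes <- routes[vapply(routes, route_length, integer(1)) >= min_len]
  structure(list(routes = routes, truncated = mp$truncated), class = "route_set")
}

#' @export
print.route_set <- function(x, ...) {
  cat("<route_set> ", length(x$routes), " maximal route(s)",
      if (x$truncated) " [TRUNCATED at enumeration cap]" else "", "\n", sep = "")
  for (r in utils::head(x$routes, 10)) {
    cat("  [", route_length(r), "] ",
        paste(r$steps$reaction_id, collapse = " -> "), "\n", sep = "")
  }
  if (length(x$routes) > 10) cat("  ...\n")
  invisible(x)
}

#' Longest route in a route set
#' @param routes A `route_set`.
#' @return The longest `route`, or `NULL` when empty.
#' @export
longest_route <- function(routes) {
  stopifnot(inherits(routes, "route_set"))
  if (length(routes$routes) == 0) NULL else routes$routes[[1]]
}

#' Per-step, per-gene expression report for a route
#'
#' One row per (step, DEG gene) giving the EC, enzyme, gene, the contrast
#' where the gene qualified with its log2 fold change and FDR, and the
#' linking compound to the next step. When a gene qualifies in several
#' contrasts the row shows the one with the smallest FDR (ties broken by
#' larger |log2fc|, then contrast label). Genes missing from the DEG table
#' get blank statistics with a warning.
#'
#' @param route A `route` from [find_maximal_routes()].
#' @param deg_table Tibble with `gene_id`, `contrast`, `log2fc`, `fdr`.
#' @return A tibble ordered by step, enzyme, gene.
#' @export
route_report <- function(route, deg_table) {
  stopifnot(inherits(route, "route"))
  steps <- route$steps
  rows <- purrr::pmap_dfr(
    list(steps$step, steps$reaction_id, steps$ec, steps$deg_enzyme_ids,
         steps$deg_gene_ids, steps$link_to_next),
    function(st, rid, ec, enzymes, genes, link) {
      if (length(genes) == 0) return(NULL)
      tibble(step = st, reaction_id = rid, ec = ec,
             enzyme_id = paste(enzymes, collapse = ";"),
             gene_id = genes, link_to_next = link)
    }
  )
  if (nrow(rows) == 0) {
    return(tibble(step = integer(), reaction_id = character(), ec = character(),
                  enzyme_id = character(), gene_id = character(),
                  link_to_next = character(), contrast = character(),
                  log2fc = double(), fdr = double()))
  }
  best <- as_tibble(deg_table) |>
    filter(.data$gene_id %in% rows$gene_id) |>
    arrange(.data$gene_id, .data$fdr, -abs(.data$log2fc), .data$contrast) |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    select("gene_id", "contrast", "log2fc", "fdr")
  out <- left_join(rows, best, by = "gene_id") |>
    arrange(.data$step, .data$enzyme_id, .data$gene_id)
  if (anyNA(out$fdr)) {
    warn(paste0(sum(is.na(out$fdr)), " route gene(s) missing from the DEG table"))
  }
  out
}
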