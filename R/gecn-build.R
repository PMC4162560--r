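#' Currency metabolites excluded as linking compounds
#'
#' Ubiquitous small molecules (ATP, NAD(P)(H), CoA, O2, CO2, ...) take part
#' in so many reactions that using them as enzyme-coupling links would
#' connect nearly everything; they are therefore excluded when building the
#' enzyme correlation network.
#'
#' The default set holds the fourteen standard tokens H+, ADH, NADP, NADPH,
#' NH3, ATP, ADP, AMP, NAD, CoA, O2, CO2, Glu and pyrophosphate, plus the
#' token NADH: "ADH" in cofactor shorthand is read as a variant of NADH
#' (alcohol dehydrogenase is an enzyme, not a metabolite), so both spellings
#' are excluded by default; drop either token to change that. "Glu" carries
#' the alias "L-glutamate" so that glutamate is excluded as a *linking*
#' metabolite under either spelling.
#'
#' Membership is by exact token after trimming and case-folding — never by
#' substring, so e.g. `acetyl-CoA` is not currency.
#'
#' @param tokens Character vector of currency compound tokens.
#' @param aliases Additional tokens treated as members (alias spellings).
#' @return A `currency_set`.
#' @export
currency_set <- function(tokens, aliases = character()) {
  structure(unique(as.character(tokens)),
            aliases = unique(as.character(aliases)),
            class = "currency_set")
}

#' @rdname currency_set
#' @export
default_currency_set <- function() {
  currency_set(
    c("H+", "ADH", "NADP", "NADPH", "NH3", "ATP", "ADP", "AMP",
      "NAD", "CoA", "O2", "CO2", "Glu", "pyrophosphate", "NADH"),
    aliases = "L-glutamate"
  )
}

#' @rdname currency_set
#' @param x Compound id(s) to test.
#' @param currency A `currency_set`.
#' @return `in_currency()` returns a logical vector.
#' @export
in_currency <- function(x, currency) {
  norm_token(x) %in% norm_token(c(unclass(currency), attr(currency, "aliases")))
}

#' Read a currency set from a file of one token per line
#' @param path Input path (`#` comments and blank lines ignored).
#' @return A `currency_set`.
#' @export
read_currency_set <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  currency_set(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' @export
print.currency_set <- function(x, ...) {
  cat("<currency_set> ", length(x), " token(s): ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  al <- attr(x, "aliases")
  if (length(al) > 0) cat("  aliases: ", paste(al, collapse = ", "), "\n", sep = "")
  invisible(x)
}

new_gecn <- function(nodes, edges, directed) {
  structure(list(nodes = nodes, edges = edges, directed = directed),
            class = "gecn")
}

#' Build a genome-scale enzyme correlation network
#'
#' Enzymes are nodes. A directed edge runs from enzyme E1 to enzyme E2
#' (E1 != E2) iff some product of a reaction catalyzed by E1 is a substrate
#' of a reaction catalyzed by E2 and that compound is not a currency
#' metabolite: the producer's output feeds the consumer's input, so the two
#' enzymes act on consecutive steps. Reversible reactions contribute both
#' orientations of their substrate/product sets. The linking compounds are
#' recorded on each edge; with `directed = FALSE` the two orientations are
#' merged and their linking sets unioned.
#'
#' Enzymes with no reactions (no EC match) are retained as degree-0 nodes.
#'
#' @param db A [pathway_db()].
#' @param currency A [currency_set()]; defaults to the standard small
#'   molecules.
#' @param directed Keep the product-to-substrate direction? Default `TRUE`.
#' @return A `gecn`: list with `nodes` (tibble `enzyme_id`, `ec`,
#'   `gene_ids` list-column), `edges` (tibble `from`, `to`,
#'   `linking_compounds` list-column) and `directed`.
#' @export
build_gecn <- function(db, currency = default_currency_set(), directed = TRUE) {
  stopifnot(inherits(db, "pathway_db"))
  genes <- enzyme_gene_list(db)
  nodes <- tibble(
    enzyme_id = db$enzymes$enzyme_id,
    ec = db$enzymes$ec,
    gene_ids = lapply(db$enzymes$enzyme_id, function(e) genes[[e]] %||% character())
  ) |> arrange(.data$enzyme_id)

  re <- reaction_enzymes(db)
  orphan <- setdiff(nodes$enzyme_id, re$enzyme_id)
  if (length(orphan) > 0) {
    inform(paste0(length(orphan), " enzyme(s) with no catalyzed reactions retained at degree 0"))
  }

  # Per-reaction effective substrate/product sets (reversible -> both ways),
  # exploded to (enzyme, compound, role) pairs.
  rx <- db$reactions
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
  if (nrow(long) > 0 && nrow(re) > 0) {
    long <- long |>
      filter(!in_currency(.data$compound_id, currency)) |>
      inner_join(re, by = "reaction_id", relationship = "many-to-many") |>
      distinct(.data$enzyme_id, .data$compound_id, .data$role) |>
      mutate(key = norm_token(.data$compound_id))
    producers <- long |> filter(.data$role == "product")
    consumers <- long |> filter(.data$role == "substrate")
    pairs <- inner_join(
      producers |> select("key", from = "enzyme_id", "compound_id"),
      consumers |> select("key", to = "enzyme_id"),
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
  g <- new_gecn(nodes, edges, directed = TRUE)
  if (directed) g else collapse_to_undirected(g)
}

#' Collapse a directed enzyme network to its undirected view
#'
#' Merges the two orientations of each enzyme pair into a single undirected
#' edge whose linking-compound set is the union; node set unchanged. This is
#' the view used for topology statistics and SIF export.
#'
#' @param g A directed `gecn`.
#' @return An undirected `gecn` (endpoints stored with `from` < `to`).
#' @export
collapse_to_undirected <- function(g) {
  stopifnot(inherits(g, "gecn"))
  if (!g$directed) return(g)
  edges <- g$edges
  if (nrow(edges) > 0) {
    edges <- edges |>
      mutate(u = pmin(.data$from, .data$to), v = pmax(.data$from, .data$to)) |>
      summarise(linking_compounds = list(lex_sort(unique(unlist(.data$linking_compounds)))),
                .by = c("u", "v")) |>
      arrange(.data$u, .data$v) |>
      select(from = "u", to = "v", "linking_compounds")
  }
  new_gecn(g$nodes, edges, directed = FALSE)
}

#' @export
print.gecn <- function(x, ...) {
  cat("<gecn> ", nrow(x$nodes), " enzyme node(s), ", nrow(x$edges),
      if (x$directed) " directed" else " undirected", " edge(s)\n", sep = "")
  invisible(x)
}

#' Export an enzyme network as SIF edges
#'
#' @param g A `gecn` (or `subnetwork`).
#' @param relation Interaction label written on every edge; the Cytoscape
#'   convention for the enzyme-coupling relation here is `"cc"`.
#' @return A tibble with columns `source`, `relation`, `target`, sorted.
#' @export
sif_edges <- function(g, relation = "cc") {
  stopifnot(inherits(g, "gecn"))
  if (nrow(g$edges) == 0) {
    return(tibble(source = character(), relation = character(), target = character()))
  }
  tibble(source = g$edges$from, relation = relation, target = g$edges$to) |>
    arrange(.data$source, .data$target)
}
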