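#' Call differentially expressed genes from a DEG table
#'
#' A gene qualifies if, in at least one contrast, its absolute log2 fold
#' change is at least `log2(fc_min)` **and** its FDR is at most `fdr_max`;
#' both comparisons are inclusive, matching the conventional criteria
#' "fold change >= 2 and FDR <= 1e-10". Qualification is an OR over
#' contrasts; the per-contrast qualifying rows are retained for reporting.
#'
#' @param deg_table Tibble with columns `gene_id`, `contrast`, `log2fc`,
#'   `fdr` (one row per gene x contrast).
#' @param fc_min Minimum linear-scale fold change (>= 1). Default 2.
#' @param fdr_max Maximum FDR (in (0, 1]). Default 1e-10.
#' @return A `deg_set`: list with `genes` (character, sorted), `hits`
#'   (tibble of the qualifying rows) and the thresholds used.
#' @export
call_degs <- function(deg_table, fc_min = 2, fdr_max = 1e-10) {
  deg_table <- as_tibble(deg_table)
  stopifnot(all(c("gene_id", "contrast", "log2fc", "fdr") %in% names(deg_table)),
            fc_min >= 1, fdr_max > 0, fdr_max <= 1)
  bad <- is.na(deg_table$log2fc) | is.na(deg_table$fdr)
  if (any(bad)) {
    warn(paste0("skipped ", sum(bad), " DEG row(s) with missing log2fc/fdr"))
    deg_table <- deg_table[!bad, , drop = FALSE]
  }
  hits <- deg_table |>
    filter(abs(.data$log2fc) >= log2(fc_min), .data$fdr <= fdr_max)
  structure(
    list(genes = lex_sort(unique(hits$gene_id)), hits = hits,
         fc_min = fc_min, fdr_max = fdr_max),
    class = "deg_set"
  )
}

#' @export
print.deg_set <- function(x, ...) {
  cat("<deg_set> ", length(x$genes), " gene(s) passing |log2fc| >= log2(",
      x$fc_min, "), fdr <= ", format(x$fdr_max), " in >= 1 contrast\n", sep = "")
  invisible(x)
}

#' Genes in a DEG set
#' @param degs A `deg_set` (or a plain character vector of gene ids).
#' @return Character vector of gene ids.
#' @export
deg_genes <- function(degs) {
  if (inherits(degs, "deg_set")) degs$genes else as.character(degs)
}

#' Map DEGs to the enzymes they encode
#'
#' An enzyme is DEG-encoded iff at least one of its genes is in the DEG
#' set. Genes mapping to several enzymes count once per enzyme; the summary
#' reports distinct genes and distinct enzymes separately, plus the DEGs
#' that encode no enzyme in the database.
#'
#' @param degs A `deg_set` from [call_degs()], or a character vector of
#'   gene ids.
#' @param db A [pathway_db()].
#' @return A `deg_enzyme_map`: list with `mapping` (tibble `enzyme_id`,
#'   `gene_id`), `enzyme_ids`, and counts `n_genes_mapped`, `n_enzymes`,
#'   `n_genes_unmapped`.
#' @export
map_degs_to_enzymes <- function(degs, db) {
  stopifnot(inherits(db, "pathway_db"))
  genes <- deg_genes(degs)
  mapping <- db$gene_enzyme |>
    filter(.data$gene_id %in% genes) |>
    distinct(.data$enzyme_id, .data$gene_id) |>
    arrange(.data$enzyme_id, .data$gene_id)
  structure(
    list(mapping = mapping,
         enzyme_ids = lex_sort(unique(mapping$enzyme_id)),
         n_genes_mapped = dplyr::n_distinct(mapping$gene_id),
         n_enzymes = dplyr::n_distinct(mapping$enzyme_id),
         n_genes_unmapped = length(setdiff(genes, mapping$gene_id))),
    class = "deg_enzyme_map"
  )
}

#' @export
print.deg_enzyme_map <- function(x, ...) {
  cat("<deg_enzyme_map> ", x$n_genes_mapped, " gene(s) encoding ",
      x$n_enzymes, " enzyme(s); ", x$n_genes_unmapped,
      " DEG(s) with no enzyme\n", sep = "")
  invisible(x)
}

#' Induce the sub-network of an enzyme network on a set of enzymes
#'
#' Keeps an edge iff both endpoints are in `enzymes`; with
#' `drop_isolated = TRUE` (the default) nodes left without any incident
#' edge are removed. Dropping isolated nodes is what distinguishes the
#' count of mapped enzymes from the (smaller) node count of the
#' sub-interaction network.
#'
#' @param g A `gecn`.
#' @param enzymes Enzyme ids (a character vector, or a `deg_enzyme_map`);
#'   ids not in the network are ignored with a warning.
#' @param drop_isolated Remove degree-0 nodes from the induced graph?
#' @return A `subnetwork` (a `gecn` whose nodes carry a `deg_genes`
#'   list-column when a `deg_enzyme_map` was supplied).
#' @export
induce_subnetwork <- function(g, enzymes, drop_isolated = TRUE) {
  stopifnot(inherits(g, "gecn"))
  node_genes <- NULL
  if (inherits(enzymes, "deg_enzyme_map")) {
    node_genes <- enzymes$mapping
    enzymes <- enzymes$enzyme_ids
  }
  enzymes <- unique(as.character(enzymes))
  unknown <- setdiff(enzymes, g$nodes$enzyme_id)
  if (length(unknown) > 0) {
    warn(paste0("ignoring ", length(unknown), " id(s) not in the network: ",
                paste(utils::head(lex_sort(unknown), 5), collapse = ", "),
                if (length(unknown) > 5) ", ..." else ""))
    enzymes <- setdiff(enzymes, unknown)
  }
  edges <- g$edges |> filter(.data$from %in% enzymes, .data$to %in% enzymes)
  keep <- if (drop_isolated) unique(c(edges$from, edges$to)) else enzymes
  nodes <- g$nodes |> filter(.data$enzyme_id %in% keep)
  if (!is.null(node_genes)) {
    nodes <- nodes |>
      mutate(deg_genes = lapply(.data$enzyme_id, function(e) {
        lex_sort(node_genes$gene_id[node_genes$enzyme_id == e])
      }))
  }
  structure(list(nodes = nodes, edges = edges, directed = g$directed),
            class = c("subnetwork", "gecn"))
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("<subnetwork> ", nrow(x$nodes), " enzyme node(s), ", nrow(x$edges),
      if (x$directed) " directed" else " undirected", " edge(s)\n", sep = "")
  invisible(x)
}

#' Interaction partners of a protein that are DEGs
#'
#' Looks up the neighbors of `protein` in a binary protein-protein
#' interaction edge list and returns those that are in the DEG set.
#'
#' @param protein A protein/gene id.
#' @param ppi Tibble from [read_ppi()] (columns `a`, `b`).
#' @param degs A `deg_set` or character vector of DEG ids.
#' @return Sorted character vector of DEG partner ids.
#' @export
ppi_deg_neighbors <- function(protein, ppi, degs) {
  genes <- deg_genes(degs)
  nb <- c(ppi$b[ppi$a == protein], ppi$a[ppi$b == protein])
  lex_sort(unique(nb[nb %in% genes]))
}
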