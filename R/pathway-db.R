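#' Construct an in-memory pathway genome database
#'
#' A `pathway_db` is the relational core of the pipeline: tables of
#' compounds, reactions (with substrate/product compound sets, EC number,
#' reversibility and pathway membership), enzymes, a gene-to-enzyme map and
#' (optionally) named pathways with a declared reaction order.
#'
#' Cross-references are resolved on construction. Substrates or products
#' citing an unknown compound are auto-registered as compounds with an empty
#' name (with a warning); gene-to-enzyme rows citing an unknown enzyme are
#' dropped (with a warning). Real pathway-database dumps are dirty, so
#' neither situation is fatal.
#'
#' @param compounds tibble with columns `compound_id`, `name`.
#' @param reactions tibble with columns `reaction_id`, `ec`,
#'   `substrate_ids` (list of character), `product_ids` (list of character),
#'   `reversible` (logical), `pathway_ids` (list of character).
#' @param enzymes tibble with columns `enzyme_id`, `ec`, `name`.
#' @param gene_enzyme tibble with columns `gene_id`, `enzyme_id`.
#' @param pathways tibble with columns `pathway_id`, `name`,
#'   `reaction_order` (list of character; may be empty).
#' @return An object of class `pathway_db`.
#' @export
pathway_db <- function(compounds = empty_compounds(),
                       reactions = empty_reactions(),
                       enzymes = empty_enzymes(),
                       gene_enzyme = empty_gene_enzyme(),
                       pathways = empty_pathways()) {
  compounds <- as_tibble(compounds)
  reactions <- as_tibble(reactions)
  enzymes <- as_tibble(enzymes)
  gene_enzyme <- as_tibble(gene_enzyme)
  pathways <- as_tibble(pathways)

  for (col in c("compound_id", "name")) {
    if (!col %in% names(compounds)) abort(paste0("compounds: missing column '", col, "'"))
  }
  for (col in c("reaction_id", "ec", "substrate_ids", "product_ids", "reversible", "pathway_ids")) {
    if (!col %in% names(reactions)) abort(paste0("reactions: missing column '", col, "'"))
  }
  for (col in c("enzyme_id", "ec", "name")) {
    if (!col %in% names(enzymes)) abort(paste0("enzymes: missing column '", col, "'"))
  }
  for (col in c("gene_id", "enzyme_id")) {
    if (!col %in% names(gene_enzyme)) abort(paste0("gene_enzyme: missing column '", col, "'"))
  }

  compounds <- distinct(compounds, .data$compound_id, .keep_all = TRUE)
  enzymes <- distinct(enzymes, .data$enzyme_id, .keep_all = TRUE)
  reactions <- distinct(reactions, .data$reaction_id, .keep_all = TRUE)
  pathways <- distinct(pathways, .data$pathway_id, .keep_all = TRUE)
  gene_enzyme <- distinct(gene_enzyme)

  # Auto-register compounds cited by reactions but absent from the table.
  cited <- unique(c(unlist(reactions$substrate_ids), unlist(reactions$product_ids)))
  missing_cpd <- setdiff(norm_token(cited), norm_token(compounds$compound_id))
  if (length(missing_cpd) > 0) {
    new_ids <- cited[norm_token(cited) %in% missing_cpd]
    new_ids <- new_ids[!duplicated(norm_token(new_ids))]
    warn(paste0("auto-registered ", length(new_ids),
                " compound(s) cited by reactions but not declared: ",
                paste(utils::head(lex_sort(new_ids), 5), collapse = ", "),
                if (length(new_ids) > 5) ", ..." else ""))
    compounds <- bind_rows(compounds, tibble(compound_id = new_ids, name = ""))
  }

  # Drop gene->enzyme rows whose enzyme is unknown.
  dangling <- !gene_enzyme$enzyme_id %in% enzymes$enzyme_id
  if (any(dangling)) {
    warn(paste0("dropped ", sum(dangling),
                " gene_enzyme row(s) citing unknown enzymes"))
    gene_enzyme <- gene_enzyme[!dangling, , drop = FALSE]
  }

  # Substrate and product sets should be disjoint within one orientation.
  overlap <- purrr::map2_lgl(reactions$substrate_ids, reactions$product_ids,
                             function(s, p) length(intersect(norm_token(s), norm_token(p))) > 0)
  if (any(overlap)) {
    warn(paste0("reaction(s) with overlapping substrate/product sets: ",
                paste(reactions$reaction_id[overlap], collapse = ", ")))
  }

  structure(
    list(compounds = compounds, reactions = reactions, enzymes = enzymes,
         gene_enzyme = gene_enzyme, pathways = pathways),
    class = "pathway_db"
  )
}

empty_compounds <- function() tibble(compound_id = character(), name = character())
empty_reactions <- function() {
  tibble(reaction_id = character(), ec = character(),
         substrate_ids = list(), product_ids = list(),
         reversible = logical(), pathway_ids = list())
}
empty_enzymes <- function() tibble(enzyme_id = character(), ec = character(), name = character())
empty_gene_enzyme <- function() tibble(gene_id = character(), enzyme_id = character())
empty_pathways <- function() tibble(pathway_id = character(), name = character(), reaction_order = list())

#' An empty pathway database
#' @return A `pathway_db` with zero rows in every table.
#' @export
empty_pathway_db <- function() pathway_db()

#' @export
print.pathway_db <- function(x, ...) {
  cat("<pathway_db> ", nrow(x$compounds), " compounds, ",
      nrow(x$reactions), " reactions, ", nrow(x$enzymes), " enzymes, ",
      nrow(x$gene_enzyme), " gene-enzyme links, ",
      nrow(x$pathways), " pathways\n", sep = "")
  invisible(x)
}

#' Validate a pathway database against its structural invariants
#'
#' Checks id uniqueness per table, resolution of every substrate/product and
#' gene-enzyme reference, and substrate/product disjointness.
#'
#' @param db A `pathway_db`.
#' @return `TRUE` invisibly; aborts with a message describing the first
#'   violated invariant otherwise.
#' @export
validate_pathway_db <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  if (anyDuplicated(db$compounds$compound_id)) abort("duplicate compound ids")
  if (anyDuplicated(db$reactions$reaction_id)) abort("duplicate reaction ids")
  if (anyDuplicated(db$enzymes$enzyme_id)) abort("duplicate enzyme ids")
  cited <- norm_token(unique(c(unlist(db$reactions$substrate_ids),
                               unlist(db$reactions$product_ids))))
  if (!all(cited %in% norm_token(db$compounds$compound_id))) {
    abort("unresolved compound reference in reactions")
  }
  if (!all(db$gene_enzyme$enzyme_id %in% db$enzymes$enzyme_id)) {
    abort("unresolved enzyme reference in gene_enzyme")
  }
  invisible(TRUE)
}

# Reaction <-> enzyme linkage. The relational schema carries EC numbers on
# both reactions and enzymes; an enzyme catalyzes a reaction iff the EC
# strings are identical after trimming (partial ECs like "2.4.1.-" included;
# enzymes without an EC pair only with reactions without an EC).
reaction_enzymes <- function(db) {
  rx <- tibble(reaction_id = db$reactions$reaction_id,
               ec_key = norm_token(db$reactions$ec))
  ez <- tibble(enzyme_id = db$enzymes$enzyme_id,
               ec_key = norm_token(db$enzymes$ec))
  inner_join(rx, ez, by = "ec_key", relationship = "many-to-many") |>
    select("reaction_id", "enzyme_id") |>
    distinct()
}

# Genes attached to each enzyme, as a named list keyed by enzyme_id.
enzyme_gene_list <- function(db) {
  ge <- db$gene_enzyme
  out <- split(ge$gene_id, ge$enzyme_id)
  lapply(out, unique)
}
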