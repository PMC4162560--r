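#' Parse a BioCyc-style attribute-value flat file
#'
#' The attribute-value dialect is the common public pathway-genome-database
#' dump format: records are separated by a line consisting of `//`;
#' attribute lines read `NAME - value`; lines beginning `/` continue the
#' previous value; lines beginning `#` are comments. Attribute names are
#' upper-cased; the order of repeated values is preserved.
#'
#' Blocks without a `UNIQUE-ID` attribute are skipped with a warning, as are
#' attribute lines without a `" - "` separator.
#'
#' @param path Path to a text file.
#' @return A tibble with columns `record_id`, `attribute`, `value`, one row
#'   per attribute occurrence, in file order.
#' @export
parse_attribute_value <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read attribute-value file: ", path))
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- list(attribute = character(), value = character())
  n_skipped_lines <- 0L
  n_skipped_blocks <- 0L

  flush_block <- function(cur) {
    if (length(cur$attribute) == 0) return(NULL)
    uid <- cur$value[cur$attribute == "UNIQUE-ID"]
    if (length(uid) == 0 || !nzchar(uid[1])) return(NA)
    tibble(record_id = uid[1], attribute = cur$attribute, value = cur$value)
  }

  for (ln in lines) {
    if (startsWith(ln, "#")) next
    if (trimws(ln) == "//") {
      blk <- flush_block(cur)
      if (is.null(blk)) {
      } else if (identical(blk, NA)) {
        n_skipped_blocks <- n_skipped_blocks + 1L
      } else {
        recs[[length(recs) + 1L]] <- blk
      }
      cur <- list(attribute = character(), value = character())
      next
    }
    if (startsWith(ln, "/")) {
      # continuation of the previous value
      if (length(cur$value) > 0) {
        cur$value[length(cur$value)] <-
          paste(cur$value[length(cur$value)], trimws(substring(ln, 2)))
      }
      next
    }
    if (!nzchar(trimws(ln))) next
    sep <- regexpr(" - ", ln, fixed = TRUE)
    if (sep < 0) {
      n_skipped_lines <- n_skipped_lines + 1L
      next
    }
    cur$attribute <- c(cur$attribute, toupper(trimws(substr(ln, 1, sep - 1))))
    cur$value <- c(cur$value, trimws(substring(ln, sep + 3)))
  }
  # trailing block without // terminator
  blk <- flush_block(cur)
  if (identical(blk, NA)) n_skipped_blocks <- n_skipped_blocks + 1L
  else if (!is.null(blk)) recs[[length(recs) + 1L]] <- blk

  if (n_skipped_lines > 0) warn(paste0("skipped ", n_skipped_lines, " malformed attribute line(s)"))
  if (n_skipped_blocks > 0) warn(paste0("skipped ", n_skipped_blocks, " block(s) lacking UNIQUE-ID"))
  if (length(recs) == 0) {
    return(tibble(record_id = character(), attribute = character(), value = character()))
  }
  bind_rows(recs)
}

#' Serialize attribute-value records
#'
#' Writes the normalized form of [parse_attribute_value()] output: one
#' `NAME - value` line per row, records terminated by `//`. Re-parsing the
#' written file reproduces the input tibble exactly.
#'
#' @param records Tibble as returned by [parse_attribute_value()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attribute_value <- function(records, path) {
  ids <- unique(records$record_id)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in ids) {
    block <- records[records$record_id == id, , drop = FALSE]
    writeLines(paste(block$attribute, "-", block$value), con)
    writeLines("//", con)
  }
  invisible(path)
}

tsv_bundle_files <- c(compounds = "compounds.tsv", reactions = "reactions.tsv",
                      enzymes = "enzymes.tsv", gene_enzyme = "gene_enzyme.tsv")

read_bundle_tsv <- function(path, required_cols) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  miss <- setdiff(required_cols, names(tb))
  if (length(miss) > 0) {
    abort(paste0("file '", basename(path), "': missing column(s) ",
                 paste(miss, collapse = ", ")))
  }
  tb
}

#' Load a pathway genome database
#'
#' Two on-disk dialects are supported, autodetected from the directory
#' contents:
#'
#' * **Canonical TSV bundle** — a directory holding `compounds.tsv`,
#'   `reactions.tsv`, `enzymes.tsv`, `gene_enzyme.tsv` and optionally
#'   `pathways.tsv`, tab-delimited with header rows; multi-valued fields
#'   are semicolon-joined.
#' * **Attribute-value flat files** — a directory holding `compounds.dat`,
#'   `reactions.dat` and `enzymes.dat` (or `proteins.dat`), optionally
#'   `pathways.dat`, in the dialect of [parse_attribute_value()]. Reaction
#'   substrates/products come from `LEFT`/`RIGHT`, reversibility from a
#'   `REACTION-DIRECTION` containing `REVERSIBLE`, enzyme gene links from
#'   repeated `GENE` attributes.
#'
#' @param source Directory path.
#' @param format `"auto"`, `"tsv"` or `"attr"`.
#' @return A [pathway_db()].
#' @export
load_pathway_db <- function(source, format = c("auto", "tsv", "attr")) {
  format <- match.arg(format)
  if (!dir.exists(source)) abort(paste0("no such directory: ", source))
  files <- list.files(source)
  if (format == "auto") {
    format <- if (any(grepl("\\.tsv$", files))) "tsv"
              else if (any(grepl("\\.dat$", files))) "attr"
              else abort(paste0("cannot detect bundle format in ", source,
                                ": no .tsv or .dat files"))
  }
  if (format == "tsv") load_pathway_db_tsv(source) else load_pathway_db_attr(source)
}

load_pathway_db_tsv <- function(source) {
  paths <- file.path(source, tsv_bundle_files)
  names(paths) <- names(tsv_bundle_files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(paste0("missing mandatory file(s): ",
                 paste(tsv_bundle_files[missing], collapse = ", ")))
  }
  compounds <- read_bundle_tsv(paths["compounds"], c("compound_id", "name")) |>
    mutate(name = dplyr::coalesce(.data$name, ""))
  rx <- read_bundle_tsv(paths["reactions"],
                        c("reaction_id", "ec", "substrates", "products", "reversible"))
  reactions <- tibble(
    reaction_id = rx$reaction_id,
    ec = dplyr::coalesce(rx$ec, ""),
    substrate_ids = split_semis(rx$substrates),
    product_ids = split_semis(rx$products),
    reversible = rx$reversible %in% c("1", "true", "TRUE"),
    pathway_ids = if ("pathways" %in% names(rx)) split_semis(rx$pathways)
                  else rep(list(character()), nrow(rx))
  )
  enzymes <- read_bundle_tsv(paths["enzymes"], c("enzyme_id", "ec", "name")) |>
    mutate(ec = dplyr::coalesce(.data$ec, ""), name = dplyr::coalesce(.data$name, ""))
  gene_enzyme <- read_bundle_tsv(paths["gene_enzyme"], c("gene_id", "enzyme_id"))
  pw_path <- file.path(source, "pathways.tsv")
  pathways <- if (file.exists(pw_path)) {
    pw <- read_bundle_tsv(pw_path, c("pathway_id", "name"))
    tibble(pathway_id = pw$pathway_id,
           name = dplyr::coalesce(pw$name, ""),
           reaction_order = if ("reaction_order" %in% names(pw)) split_semis(pw$reaction_order)
                            else rep(list(character()), nrow(pw)))
  } else empty_pathways()
  pathway_db(compounds, reactions, enzymes, gene_enzyme, pathways)
}

attr_values <- function(block, attribute) block$value[block$attribute == attribute]
attr_value1 <- function(block, attribute, default = "") {
  v <- attr_values(block, attribute)
  if (length(v) == 0) default else v[1]
}

load_pathway_db_attr <- function(source) {
  need <- function(cands) {
    for (f in cands) if (file.exists(file.path(source, f))) return(file.path(source, f))
    abort(paste0("missing mandatory file: one of ", paste(cands, collapse = "/"),
                 " in ", source))
  }
  cpd_recs <- parse_attribute_value(need("compounds.dat"))
  rxn_recs <- parse_attribute_value(need("reactions.dat"))
  enz_recs <- parse_attribute_value(need(c("enzymes.dat", "proteins.dat")))

  per_record <- function(recs, f) {
    if (nrow(recs) == 0) return(list())
    ids <- unique(recs$record_id)
    lapply(ids, function(id) f(recs[recs$record_id == id, , drop = FALSE], id))
  }

  compounds <- bind_rows(per_record(cpd_recs, function(b, id) {
    tibble(compound_id = id, name = attr_value1(b, "COMMON-NAME"))
  }))
  if (nrow(compounds) == 0) compounds <- empty_compounds()

  reactions <- bind_rows(per_record(rxn_recs, function(b, id) {
    tibble(reaction_id = id,
           ec = attr_value1(b, "EC-NUMBER"),
           substrate_ids = list(attr_values(b, "LEFT")),
           product_ids = list(attr_values(b, "RIGHT")),
           reversible = grepl("REVERSIBLE", attr_value1(b, "REACTION-DIRECTION"), fixed = TRUE),
           pathway_ids = list(attr_values(b, "IN-PATHWAY")))
  }))
  if (nrow(reactions) == 0) reactions <- empty_reactions()

  enz_blocks <- per_record(enz_recs, function(b, id) {
    list(enzyme = tibble(enzyme_id = id, ec = attr_value1(b, "EC-NUMBER"),
                         name = attr_value1(b, "COMMON-NAME")),
         genes = tibble(gene_id = attr_values(b, "GENE"), enzyme_id = id))
  })
  enzymes <- bind_rows(lapply(enz_blocks, `[[`, "enzyme"))
  gene_enzyme <- bind_rows(lapply(enz_blocks, `[[`, "genes"))
  if (nrow(enzymes) == 0) enzymes <- empty_enzymes()
  if (is.null(gene_enzyme) || nrow(gene_enzyme) == 0) gene_enzyme <- empty_gene_enzyme()

  pw_path <- file.path(source, "pathways.dat")
  pathways <- if (file.exists(pw_path)) {
    pw_recs <- parse_attribute_value(pw_path)
    out <- bind_rows(per_record(pw_recs, function(b, id) {
      tibble(pathway_id = id, name = attr_value1(b, "COMMON-NAME"),
             reaction_order = list(attr_values(b, "REACTION-LIST")))
    }))
    if (nrow(out) == 0) empty_pathways() else out
  } else empty_pathways()

  pathway_db(compounds, reactions, enzymes, gene_enzyme, pathways)
}

#' Export a pathway database as a canonical TSV bundle
#'
#' Inverse of the TSV branch of [load_pathway_db()]: reloading the exported
#' bundle reproduces the database.
#'
#' @param db A `pathway_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pathway_db <- function(db, dir) {
  stopifnot(inherits(db, "pathway_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(db$compounds, file.path(dir, "compounds.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble(reaction_id = db$reactions$reaction_id,
           ec = db$reactions$ec,
           substrates = join_semis(db$reactions$substrate_ids),
           products = join_semis(db$reactions$product_ids),
           reversible = as.integer(db$reactions$reversible),
           pathways = join_semis(db$reactions$pathway_ids)),
    file.path(dir, "reactions.tsv"), progress = FALSE)
  readr::write_tsv(db$enzymes, file.path(dir, "enzymes.tsv"), progress = FALSE)
  readr::write_tsv(db$gene_enzyme, file.path(dir, "gene_enzyme.tsv"), progress = FALSE)
  if (nrow(db$pathways) > 0) {
    readr::write_tsv(
      tibble(pathway_id = db$pathways$pathway_id, name = db$pathways$name,
             reaction_order = join_semis(db$pathways$reaction_order)),
      file.path(dir, "pathways.tsv"), progress = FALSE)
  }
  invisible(dir)
}

#' Read a table of differential-expression results
#'
#' @param path TSV with columns `gene_id`, `contrast`, `log2fc`, `fdr`.
#' @return A tibble with those columns (`log2fc`, `fdr` numeric).
#' @export
read_deg_table <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), contrast = readr::col_character(),
    log2fc = readr::col_double(), fdr = readr::col_double()), progress = FALSE)
  miss <- setdiff(c("gene_id", "contrast", "log2fc", "fdr"), names(tb))
  if (length(miss) > 0) abort(paste0("DEG table: missing column(s) ", paste(miss, collapse = ", ")))
  bad <- !is.na(tb$fdr) & (tb$fdr < 0 | tb$fdr > 1)
  if (any(bad)) abort("DEG table: fdr outside [0, 1]")
  tb
}

#' @rdname read_deg_table
#' @param deg_table Tibble with the DEG-table columns.
#' @export
write_deg_table <- function(deg_table, path) {
  readr::write_tsv(deg_table, path, progress = FALSE)
  invisible(path)
}

#' Read a binary protein-protein interaction edge list
#'
#' Two whitespace-separated protein ids per line; pairs are undirected,
#' deduplicated regardless of order, and self-pairs are rejected with a
#' warning.
#'
#' @param path Input path.
#' @return A tibble with columns `a`, `b` where `a < b` lexicographically.
#' @export
read_ppi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(tibble(a = character(), b = character()))
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(toks, length, integer(1)) != 2
  if (any(bad)) {
    abort(paste0("PPI line ", which(bad)[1], ": expected 2 ids, got ",
                 length(toks[[which(bad)[1]]])))
  }
  a <- vapply(toks, `[`, character(1), 1)
  b <- vapply(toks, `[`, character(1), 2)
  self <- a == b
  if (any(self)) {
    warn(paste0("dropped ", sum(self), " PPI self-pair(s)"))
    a <- a[!self]; b <- b[!self]
  }
  ppi_pairs(a, b)
}

ppi_pairs <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  tibble(a = lo, b = hi) |> distinct() |> arrange(.data$a, .data$b)
}

#' Read and write Cytoscape SIF files
#'
#' SIF lines are whitespace-delimited `source relation target`. Writing
#' then reading returns the identical edge multiset.
#'
#' @param edges Tibble (or data frame) with columns `source`, `relation`,
#'   `target`.
#' @param path File path.
#' @return `read_sif()` returns the edge tibble; `write_sif()` returns
#'   `path` invisibly.
#' @export
write_sif <- function(edges, path) {
  edges <- as_tibble(edges)
  stopifnot(all(c("source", "relation", "target") %in% names(edges)))
  writeLines(paste(edges$source, edges$relation, edges$target, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(source = character(), relation = character(), target = character()))
  }
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- vapply(toks, length, integer(1)) != 3
  if (any(bad)) {
    abort(paste0("SIF line ", which(bad)[1], ": expected 3 tokens, got ",
                 length(toks[[which(bad)[1]]])))
  }
  tibble(source = vapply(toks, `[`, character(1), 1),
         relation = vapply(toks, `[`, character(1), 2),
         target = vapply(toks, `[`, character(1), 3))
}
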