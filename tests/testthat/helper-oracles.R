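# Independent reference implementations used as oracles. These deliberately
# re-derive results by naive enumeration (double loops, BFS, exhaustive path
# search) and share no code with the package internals they check.

norm_tok <- function(x) tolower(trimws(x))

# Naive attribute-value interpreter: split raw text on "//" lines, then
# scan each block line by line.
oracle_parse_av <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(trimws(lines) == "//"))
  rows <- list()
  for (blk in blocks) {
    blk <- blk[trimws(blk) != "//"]
    attrs <- character(); vals <- character()
    for (ln in blk) {
      if (startsWith(ln, "#") || !nzchar(trimws(ln))) next
      if (startsWith(ln, "/")) {
        if (length(vals) > 0) {
          vals[length(vals)] <- paste(vals[length(vals)], trimws(substring(ln, 2)))
        }
        next
      }
      m <- regexpr(" - ", ln, fixed = TRUE)
      if (m < 0) next
      attrs <- c(attrs, toupper(trimws(substr(ln, 1, m - 1))))
      vals <- c(vals, trimws(substring(ln, m + 3)))
    }
    uid <- vals[attrs == "UNIQUE-ID"]
    if (length(uid) >= 1 && nzchar(uid[1])) {
      rows[[length(rows) + 1]] <-
        data.frame(record_id = uid[1], attribute = attrs, value = vals)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(record_id = character(), attribute = character(),
                      value = character()))
  }
  do.call(rbind, rows)
}

# Effective substrate/product sets of a reaction row (reversible -> union).
.eff_sets <- function(rx, i) {
  s <- rx$substrate_ids[[i]]; p <- rx$product_ids[[i]]
  if (rx$reversible[i]) list(s = union(s, p), p = union(s, p)) else list(s = s, p = p)
}

# Brute-force ordered-pair scan for the enzyme coupling rule.
oracle_gecn_edges <- function(db, currency) {
  cur <- norm_tok(c(unclass(currency), attr(currency, "aliases")))
  ez <- db$enzymes
  rx <- db$reactions
  # reaction ids per enzyme via exact EC equality
  rx_of <- lapply(seq_len(nrow(ez)), function(j) {
    which(norm_tok(rx$ec) == norm_tok(ez$ec[j]))
  })
  prods <- lapply(rx_of, function(idx) {
    unique(unlist(lapply(idx, function(i) .eff_sets(rx, i)$p)))
  })
  subs <- lapply(rx_of, function(idx) {
    unique(unlist(lapply(idx, function(i) .eff_sets(rx, i)$s)))
  })
  out <- list()
  for (a in seq_len(nrow(ez))) for (b in seq_len(nrow(ez))) {
    if (a == b) next
    link <- prods[[a]][norm_tok(prods[[a]]) %in% norm_tok(subs[[b]])]
    link <- link[!norm_tok(link) %in% cur]
    if (length(link) > 0) {
      out[[length(out) + 1]] <- data.frame(
        from = ez$enzyme_id[a], to = ez$enzyme_id[b],
        linking = paste(sort(unique(link), method = "radix"), collapse = ";"))
    }
  }
  if (length(out) == 0) {
    return(data.frame(from = character(), to = character(), linking = character()))
  }
  df <- do.call(rbind, out)
  df[order(df$from, df$to, method = "radix"), , drop = FALSE]
}

# BFS component labeling on an undirected edge list.
oracle_components <- function(nodes, from, to) {
  lab <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  nxt <- 0L
  adj <- stats::setNames(rep(list(character()), length(nodes)), nodes)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- c(adj[[from[i]]], to[i])
    adj[[to[i]]] <- c(adj[[to[i]]], from[i])
  }
  for (v in nodes) {
    if (!is.na(lab[v])) next
    nxt <- nxt + 1L
    queue <- v
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(lab[u])) next
      lab[u] <- nxt
      queue <- c(queue, adj[[u]][is.na(lab[adj[[u]]])])
    }
  }
  lab
}

# Connected-pairs count by explicit all-pairs reachability.
oracle_connected_pairs <- function(nodes, from, to) {
  if (length(nodes) < 2) return(0L)
  lab <- oracle_components(nodes, from, to)
  count <- 0L
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i < j && lab[nodes[i]] == lab[nodes[j]]) count <- count + 1L
  }
  count
}

# Row-by-row reference DEG filter.
oracle_deg_filter <- function(tb, fc_min, fdr_max) {
  keep <- character()
  for (i in seq_len(nrow(tb))) {
    if (is.na(tb$log2fc[i]) || is.na(tb$fdr[i])) next
    if (abs(tb$log2fc[i]) >= log2(fc_min) && tb$fdr[i] <= fdr_max) {
      keep <- c(keep, tb$gene_id[i])
    }
  }
  sort(unique(keep), method = "radix")
}

# Exhaustive simple-path enumeration; returns all maximal simple paths
# (not extendable at either end) as a list of character vectors.
oracle_maximal_paths <- function(nodes, from, to) {
  succ <- stats::setNames(rep(list(character()), length(nodes)), nodes)
  pred <- stats::setNames(rep(list(character()), length(nodes)), nodes)
  for (i in seq_along(from)) {
    succ[[from[i]]] <- union(succ[[from[i]]], to[i])
    pred[[to[i]]] <- union(pred[[to[i]]], from[i])
  }
  all_paths <- list()
  grow <- function(path) {
    all_paths[[length(all_paths) + 1]] <<- path
    for (nxt in setdiff(succ[[path[length(path)]]], path)) grow(c(path, nxt))
  }
  for (v in nodes) grow(v)
  is_max <- vapply(all_paths, function(p) {
    length(setdiff(succ[[p[length(p)]]], p)) == 0 &&
      length(setdiff(pred[[p[1]]], p)) == 0
  }, logical(1))
  mx <- all_paths[is_max]
  mx[!duplicated(vapply(mx, paste, character(1), collapse = "\r"))]
}

# Random undirected edge tibble on n nodes (for component tests).
random_graph_edges <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  if (n_edges == 0 || n_nodes < 2) {
    return(list(nodes = nodes, from = character(), to = character()))
  }
  a <- sample(nodes, n_edges, replace = TRUE)
  b <- sample(nodes, n_edges, replace = TRUE)
  keep <- a != b
  list(nodes = nodes, from = a[keep], to = b[keep])
}

# Small helper: gecn object from plain edge lists (for topology tests).
toy_gecn <- function(nodes, from = character(), to = character(),
                     ec = rep("", length(nodes)), directed = FALSE) {
  structure(list(
    nodes = tibble::tibble(enzyme_id = nodes, ec = ec,
                           gene_ids = rep(list(character()), length(nodes))),
    edges = tibble::tibble(from = from, to = to,
                           linking_compounds = rep(list(character()), length(from))),
    directed = directed), class = "gecn")
}

# Minimal db builder for hand-written reaction sets.
toy_db <- function(reactions, enzymes, gene_enzyme = NULL, pathways = NULL) {
  suppressWarnings(gecn::pathway_db(
    reactions = reactions, enzymes = enzymes,
    gene_enzyme = gene_enzyme %||% tibble::tibble(gene_id = character(),
                                                  enzyme_id = character()),
    pathways = pathways %||% tibble::tibble(pathway_id = character(),
                                            name = character(),
                                            reaction_order = list())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
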