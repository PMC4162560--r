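#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enzyme network into its edge table
#'
#' @param x A `gecn` or `subnetwork`.
#' @param ... Unused.
#' @return Tibble with `from`, `to` and `linking_compounds` collapsed to a
#'   semicolon-joined string.
#' @method tidy gecn
#' @export
tidy.gecn <- function(x, ...) {
  tibble(from = x$edges$from, to = x$edges$to,
         linking_compounds = join_semis(x$edges$linking_compounds))
}

#' @rdname tidy.gecn
#' @method glance gecn
#' @export
glance.gecn <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         directed = x$directed,
         n_components = nrow(connected_components(x)$components),
         connected_pairs = connected_pairs_count(x))
}

#' @rdname tidy.gecn
#' @method glance subnetwork
#' @export
glance.subnetwork <- function(x, ...) {
  out <- NextMethod()
  out$n_deg_genes <- if ("deg_genes" %in% names(x$nodes)) {
    length(unique(unlist(x$nodes$deg_genes)))
  } else NA_integer_
  out
}

#' Tidy a DEG set into its qualifying rows
#' @param x A `deg_set`.
#' @param ... Unused.
#' @method tidy deg_set
#' @export
tidy.deg_set <- function(x, ...) as_tibble(x$hits)

#' @rdname tidy.deg_set
#' @method glance deg_set
#' @export
glance.deg_set <- function(x, ...) {
  tibble(n_genes = length(x$genes),
         n_contrasts = dplyr::n_distinct(x$hits$contrast),
         fc_min = x$fc_min, fdr_max = x$fdr_max)
}

#' Tidy a route into its step table
#' @param x A `route`.
#' @param ... Unused.
#' @method tidy route
#' @export
tidy.route <- function(x, ...) {
  tibble(step = x$steps$step, reaction_id = x$steps$reaction_id,
         ec = x$steps$ec,
         enzyme_ids = join_semis(x$steps$enzyme_ids),
         deg_gene_ids = join_semis(x$steps$deg_gene_ids),
         link_to_next = x$steps$link_to_next)
}

#' @rdname tidy.route
#' @method glance route
#' @export
glance.route <- function(x, ...) {
  tibble(n_reactions = route_length(x),
         n_deg_genes = length(unique(unlist(x$steps$deg_gene_ids))))
}

#' Tidy a route set into one row per route
#' @param x A `route_set`.
#' @param ... Unused.
#' @method tidy route_set
#' @export
tidy.route_set <- function(x, ...) {
  purrr::imap_dfr(x$routes, function(r, i) {
    tibble(route = i, length = route_length(r),
           first_reaction = r$steps$reaction_id[1],
           reactions = paste(r$steps$reaction_id, collapse = ";"))
  })
}

#' @rdname tidy.route_set
#' @method glance route_set
#' @export
glance.route_set <- function(x, ...) {
  tibble(n_routes = length(x$routes),
         longest = if (length(x$routes)) route_length(x$routes[[1]]) else 0L,
         truncated = x$truncated)
}

#' Tidy a component decomposition into its membership table
#' @param x A `component_decomposition`.
#' @param ... Unused.
#' @method tidy component_decomposition
#' @export
tidy.component_decomposition <- function(x, ...) x$membership

#' @rdname tidy.component_decomposition
#' @method glance component_decomposition
#' @export
glance.component_decomposition <- function(x, ...) {
  tibble(n_components = nrow(x$components),
         n_nodes = sum(x$components$n_nodes),
         n_edges = sum(x$components$n_edges),
         connected_pairs = connected_pairs_count(x))
}

#' Tidy a cross-species overlap result into its shared edge table
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble(from = x$graph$edges$from, to = x$graph$edges$to)
}

#' @rdname tidy.overlap_result
#' @method glance overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble(n_shared_keys = length(x$shared_keys),
         n_shared_edges = nrow(x$graph$edges),
         n_components = nrow(x$components$components),
         n_excluded_g1 = unname(x$n_excluded["g1"]),
         n_excluded_g2 = unname(x$n_excluded["g2"]))
}

#' Plot an enzyme network
#'
#' Draws the undirected view with a deterministic force-directed layout;
#' node size scales with degree.
#'
#' @param object A `gecn` or `subnetwork`.
#' @param label_nodes Draw node labels? Default for small networks only.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gecn
#' @export
autoplot.gecn <- function(object, label_nodes = nrow(object$nodes) <= 50, ...) {
  g <- if (object$directed) collapse_to_undirected(object) else object
  ig <- gecn_igraph(g)
  xy <- with_seed(1L, igraph::layout_with_fr(ig))
  nodes <- tibble(node = g$nodes$enzyme_id, x = xy[, 1], y = xy[, 2]) |>
    left_join(degree_stats(g), by = "node")
  seg <- g$edges |>
    left_join(nodes |> select("node", x0 = "x", y0 = "y"), by = c(from = "node")) |>
    left_join(nodes |> select("node", x1 = "x", y1 = "y"), by = c(to = "node"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree),
                        color = "steelblue") +
    ggplot2::scale_size_continuous(range = c(1, 5)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0("Enzyme correlation network (",
                                 nrow(g$nodes), " nodes, ", nrow(g$edges), " edges)"))
  if (label_nodes) {
    p <- p + ggplot2::geom_text(data = nodes,
                                ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
                                size = 2.5, vjust = -1)
  }
  p
}

#' Plot component sizes of a decomposition
#' @param object A `component_decomposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot component_decomposition
#' @export
autoplot.component_decomposition <- function(object, ...) {
  ggplot2::ggplot(object$components,
                  ggplot2::aes(x = factor(.data$component), y = .data$n_nodes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "component (size rank)", y = "nodes",
                  title = "Connected component sizes") +
    ggplot2::theme_minimal()
}

#' Plot per-step expression of a route report
#'
#' Shows each DEG gene's log2 fold change along the consecutive steps of a
#' route, the view used to judge whether co-expressed enzymes rise or fall
#' together along a metabolic route.
#'
#' @param report Tibble from [route_report()].
#' @return A ggplot object.
#' @export
plot_route_profile <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$step, y = .data$log2fc,
                               group = .data$gene_id, color = .data$ec)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_continuous(breaks = unique(report$step)) +
    ggplot2::labs(x = "route step", y = "log2 fold change",
                  title = "DEG expression along the route") +
    ggplot2::theme_minimal()
}
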