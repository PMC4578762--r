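# Conserved motif-gene networks and motif-arrangement comparison.

#' Build a category-restricted conserved motif-gene network
#'
#' Nodes are motifs and the shared 1:1 ortholog target genes of
#' overlap-passing MAG pairs whose GO term belongs to the category;
#' edges are conserved motif-to-gene associations annotated with their
#' supporting terms. The filtered view removes nodes whose degree in
#' the unfiltered network is below `min_degree` (a single pass on
#' original degrees, not iterative pruning); both views are returned.
#'
#' @param mags A `mag_pairs` tibble from [shared_mags()]; only rows
#'   with `passes_overlap` are used.
#' @param category_terms Character vector of GO terms defining the
#'   category (e.g. neurogenesis-related terms).
#' @param category Category label attached to the result.
#' @param min_degree Degree threshold for the filtered view (default 5).
#' @return A list of class `conserved_network`: `category`, `edges` /
#'   `nodes` (unfiltered), `edges_filtered` / `nodes_filtered`,
#'   `min_degree`, and `graph` (unfiltered [igraph::graph]).
#' @export
build_category_network <- function(mags, category_terms,
                                   category = "category",
                                   min_degree = 5L) {
  use <- mags[mags$passes_overlap & mags$term %in% category_terms, ,
              drop = FALSE]
  edges <- if (nrow(use)) {
    tidyr::unnest(
      dplyr::select(use, "motif_id", "term", "shared_orthologs"),
      "shared_orthologs"
    ) %>%
      dplyr::rename(gene_id = "shared_orthologs") %>%
      dplyr::group_by(.data$motif_id, .data$gene_id) %>%
      dplyr::summarise(terms = paste(sort(unique(.data$term)),
                                     collapse = ","),
                       .groups = "drop")
  } else {
    tibble::tibble(motif_id = character(), gene_id = character(),
                   terms = character())
  }
  nodes <- tibble::tibble(
    node = c(unique(edges$motif_id), unique(edges$gene_id)),
    type = c(rep("motif", length(unique(edges$motif_id))),
             rep("gene", length(unique(edges$gene_id))))
  )
  deg <- table(c(edges$motif_id, edges$gene_id))
  nodes$degree <- as.integer(deg[nodes$node])
  keep_nodes <- nodes$node[nodes$degree >= min_degree]
  edges_f <- edges[edges$motif_id %in% keep_nodes &
                     edges$gene_id %in% keep_nodes, , drop = FALSE]
  nodes_f <- nodes[nodes$node %in% keep_nodes, , drop = FALSE]
  g <- if (nrow(edges)) {
    igraph::graph_from_data_frame(
      edges[, c("motif_id", "gene_id", "terms")],
      directed = TRUE, vertices = nodes
    )
  } else {
    igraph::make_empty_graph()
  }
  structure(
    list(category = category, edges = edges, nodes = nodes,
         edges_filtered = edges_f, nodes_filtered = nodes_f,
         min_degree = as.integer(min_degree), graph = g),
    class = "conserved_network"
  )
}

#' @export
print.conserved_network <- function(x, ...) {
  cat(sprintf("<conserved_network: %s>\n", x$category))
  cat(sprintf("  unfiltered: %d nodes, %d edges\n", nrow(x$nodes),
              nrow(x$edges)))
  cat(sprintf("  degree >= %d: %d nodes, %d edges\n", x$min_degree,
              nrow(x$nodes_filtered), nrow(x$edges_filtered)))
  invisible(x)
}

#' @rdname build_category_network
#' @param x A `conserved_network`.
#' @param ... Unused.
#' @exportS3Method
tidy.conserved_network <- function(x, ...) {
  x$edges
}

#' @rdname build_category_network
#' @exportS3Method
glance.conserved_network <- function(x, ...) {
  tibble::tibble(
    category = x$category,
    n_motifs = sum(x$nodes$type == "motif"),
    n_genes = sum(x$nodes$type == "gene"),
    n_edges = nrow(x$edges),
    n_motifs_filtered = sum(x$nodes_filtered$type == "motif"),
    n_genes_filtered = sum(x$nodes_filtered$type == "gene"),
    min_degree = x$min_degree
  )
}

#' Bipartite layout plot of a conserved network
#'
#' @param object A `conserved_network`.
#' @param filtered Plot the degree-filtered view (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.conserved_network <- function(object, filtered = TRUE, ...) {
  edges <- if (filtered) object$edges_filtered else object$edges
  nodes <- if (filtered) object$nodes_filtered else object$nodes
  if (nrow(edges) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "empty network") +
             ggplot2::theme_void())
  }
  mot <- sort(unique(edges$motif_id))
  gen <- sort(unique(edges$gene_id))
  pos <- dplyr::bind_rows(
    tibble::tibble(node = mot, x = 0,
                   y = seq(0, 1, length.out = max(length(mot), 2L))[
                     seq_along(mot)]),
    tibble::tibble(node = gen, x = 1,
                   y = seq(0, 1, length.out = max(length(gen), 2L))[
                     seq_along(gen)])
  )
  pos <- dplyr::left_join(pos, nodes, by = "node")
  seg <- edges %>%
    dplyr::left_join(pos[, c("node", "x", "y")],
                     by = c(motif_id = "node")) %>%
    dplyr::rename(x0 = "x", y0 = "y") %>%
    dplyr::left_join(pos[, c("node", "x", "y")],
                     by = c(gene_id = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$type),
      size = 2
    ) +
    ggplot2::scale_x_continuous(breaks = c(0, 1),
                                labels = c("motifs", "genes"),
                                limits = c(-0.2, 1.2)) +
    ggplot2::labs(title = object$category, y = NULL, x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Export a conserved network as JSON and GraphML
#'
#' @param network A `conserved_network`.
#' @param json_path,graphml_path Output paths (either may be `NULL`).
#' @export
write_network <- function(network, json_path = NULL,
                          graphml_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(category = network$category, nodes = network$nodes,
           edges = network$edges, min_degree = network$min_degree,
           nodes_filtered = network$nodes_filtered,
           edges_filtered = network$edges_filtered),
      json_path, dataframe = "rows", auto_unbox = TRUE
    )
  }
  if (!is.null(graphml_path) && igraph::gorder(network$graph) > 0L) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  invisible(network)
}

#' Classify conservation of motif arrangement around an ortholog pair
#'
#' Given the motif hits around an orthologous gene pair (gene-relative
#' positions: distance from the gene start on the gene's strand), the
#' shared motifs' arrangement is `order+position` when their rank order
#' matches and every shared motif's offset differs by at most
#' `tolerance_bp`; `order_only` / `position_only` when only one holds;
#' `neither` otherwise; `not_applicable` with fewer than two shared
#' motifs.
#'
#' @param hits_a,hits_b Tibbles with `motif_id` and `position`
#'   (gene-relative bp) for the two genes. Multiple hits per motif are
#'   reduced to the most proximal (smallest position).
#' @param tolerance_bp Positional tolerance in bp (default 200).
#' @return One of `"order+position"`, `"order_only"`,
#'   `"position_only"`, `"neither"`, `"not_applicable"`.
#' @export
motif_arrangement <- function(hits_a, hits_b, tolerance_bp = 200) {
  pa <- hits_a %>%
    dplyr::group_by(.data$motif_id) %>%
    dplyr::summarise(position = min(.data$position), .groups = "drop")
  pb <- hits_b %>%
    dplyr::group_by(.data$motif_id) %>%
    dplyr::summarise(position = min(.data$position), .groups = "drop")
  shared <- dplyr::inner_join(pa, pb, by = "motif_id",
                              suffix = c("_a", "_b"))
  if (nrow(shared) < 2L) {
    return("not_applicable")
  }
  order_ok <- identical(order(shared$position_a),
                        order(shared$position_b))
  pos_ok <- all(abs(shared$position_a - shared$position_b) <=
                  tolerance_bp)
  if (order_ok && pos_ok) {
    "order+position"
  } else if (order_ok) {
    "order_only"
  } else if (pos_ok) {
    "position_only"
  } else {
    "neither"
  }
}
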