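#' Tidy a stability scan
#'
#' One row per (view, Q) with the bootstrap-mean ARI.
#'
#' @param x A `consistency_table`.
#' @param ... Unused.
#' @return Tibble with `shuffle`, `Q`, `ari`, `stable`.
#' @export
tidy.consistency_table <- function(x, ...) {
  tb <- tibble::as_tibble(x$ari)
  tb$shuffle <- seq_len(nrow(x$ari))
  out <- tidyr::pivot_longer(tb, -"shuffle", names_to = "Q",
                             values_to = "ari")
  out$Q <- as.integer(out$Q)
  out$stable <- out$ari >= x$threshold
  dplyr::arrange(out, .data$shuffle, .data$Q)
}

#' One-row summary of a stability scan
#'
#' @param x A `consistency_table`.
#' @param ... Unused.
#' @return Tibble with `q_star`, `n_views`, `n_stable`, `p_star`,
#'   `threshold`, `n_bootstrap`.
#' @export
glance.consistency_table <- function(x, ...) {
  tibble::tibble(q_star = x$q_star,
                 n_views = nrow(x$ari),
                 n_stable = length(x$s_star),
                 p_star = x$P$P[match(x$q_star, x$P$Q)],
                 threshold = x$threshold,
                 n_bootstrap = x$B)
}

#' Tidy a Ball Mapper graph
#'
#' @param x A `ball_mapper`.
#' @param ... Unused.
#' @return The node tibble (`node`, `landmark_index`, `size`).
#' @export
tidy.ball_mapper <- function(x, ...) x$nodes

#' @export
glance.ball_mapper <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_points = x$n_points, epsilon = x$cover$epsilon)
}

#' @export
tidy.locality_report <- function(x, ...) x$violations

#' @export
glance.locality_report <- function(x, ...) {
  tibble::tibble(n_violations = nrow(x$violations),
                 n_rums = sum(x$summary$n_rums),
                 n_neighbors = sum(x$summary$n_neighbors))
}

#' Plot the consistency profile of a stability scan
#'
#' Bar chart of `P(Q)` — the number of views whose `Q`-cluster solution is
#' bootstrap-stable — with the consensus `Q*` highlighted.
#'
#' @param object A `consistency_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consistency_table <- function(object, ...) {
  df <- dplyr::mutate(object$P, consensus = .data$Q == object$q_star)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$Q), y = .data$P,
                                   fill = .data$consensus)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "number of clusters Q",
                  y = sprintf("P(Q): stable views out of %d",
                              nrow(object$ari)),
                  title = sprintf("Consensus cluster number Q* = %d",
                                  object$q_star)) +
    ggplot2::theme_minimal()
}

#' Plot a Ball Mapper graph
#'
#' Force-directed layout of the cover graph; node area scales with ball
#' occupancy and an optional numeric colouring (for instance
#' [color_by_total_intensity()]) maps onto the fill.
#'
#' @param object A `ball_mapper`.
#' @param color Optional numeric vector, one value per node.
#' @param color_name Legend title for `color`.
#' @param seed Layout seed (layouts are themselves randomised).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ball_mapper <- function(object, color = NULL,
                                 color_name = "value", seed = 1, ...) {
  g <- as_igraph(object)
  xy <- with_seed_local(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- dplyr::mutate(object$edges,
                         x = nodes$x[.data$from], y = nodes$y[.data$from],
                         xend = nodes$x[.data$to], yend = nodes$y[.data$to])
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      color = "grey70")
  if (is.null(color)) {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size),
      color = "#2166ac", alpha = 0.85)
  } else {
    nodes$color <- color
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size,
                   color = .data$color),
      alpha = 0.9) +
      ggplot2::scale_color_viridis_c(name = color_name)
  }
  p + ggplot2::scale_size_area(max_size = 10, name = "ball size") +
    ggplot2::theme_void()
}

#' Composition of representative groups by a metadata field
#'
#' Stacked bars, one per representative group, showing how the group's
#' members distribute over the categories of a metadata field (country,
#' winery, ...). Bar height is the group size; the label carries the
#' recurrence `phi`.
#'
#' @param groups A `rep_groups` tibble.
#' @param metadata Metadata tibble with `sample_id` and `by`.
#' @param by Metadata column to colour by; default `"country"`.
#' @param top Plot at most this many groups (default 20).
#' @return A ggplot.
#' @export
plot_group_composition <- function(groups, metadata, by = "country",
                                   top = 20) {
  stopifnot(by %in% names(metadata))
  gg <- utils::head(groups, top)
  df <- purrr::map_dfr(seq_len(nrow(gg)), function(i) {
    tibble::tibble(rank = gg$rank[i], phi = gg$phi[i],
                   sample_id = gg$members[[i]])
  })
  df <- dplyr::left_join(df, metadata, by = "sample_id")
  df$group_label <- sprintf("RG%d (phi=%d)", df$rank, df$phi)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$group_label, .data$rank),
    fill = .data[[by]])) +
    ggplot2::geom_bar() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "group size", fill = by) +
    ggplot2::theme_minimal()
}
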