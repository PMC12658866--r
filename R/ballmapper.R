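#' Greedy epsilon-net over an ordered point set
#'
#' Walks the points in the given order; every time an uncovered point is
#' met it becomes a landmark and all points strictly within `epsilon` of it
#' are marked covered. The result is an epsilon-net: the open balls of
#' radius `epsilon` around the landmarks cover the data, and landmarks are
#' pairwise at distance greater than `epsilon` (a tie at exactly `epsilon`
#' leaves a point uncovered, so it is promoted to a landmark itself).
#' Because "first uncovered" depends on the ordering, different orderings
#' give different — equally valid — nets; ensembles over random orderings
#' are exploited deliberately by [frequency_matrix()].
#'
#' @param points Numeric matrix, one point per row (Euclidean metric).
#' @param epsilon Ball radius, `> 0`.
#' @param ordering Optional permutation of `1:nrow(points)` giving the
#'   visiting order; default is the native row order.
#' @return A `ball_cover`: list with `epsilon`, `landmarks` (row indices in
#'   discovery order) and `membership` (for each landmark, the row indices
#'   strictly within `epsilon` of it).
#' @examples
#' x <- matrix(c(0, 0.05, 0.2), ncol = 1)
#' greedy_epsilon_net(x, 0.08)$landmarks  # 1 and 3
#' @export
greedy_epsilon_net <- function(points, epsilon, ordering = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) stop("Cannot build an epsilon-net over zero points.",
                   call. = FALSE)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon > 0)
  if (is.null(ordering)) ordering <- seq_len(n)
  stopifnot(length(ordering) == n, all(sort(ordering) == seq_len(n)))

  sq <- rowSums(points^2)
  covered <- logical(n)
  landmarks <- integer(0)
  membership <- list()
  for (i in ordering) {
    if (covered[i]) next
    # squared distances from candidate landmark i to all points
    d2 <- pmax(sq + sq[i] - 2 * drop(points %*% points[i, ]), 0)
    inside <- which(d2 < epsilon^2)
    covered[inside] <- TRUE
    covered[i] <- TRUE  # guards the exact-epsilon tie against fp noise
    landmarks <- c(landmarks, i)
    membership[[length(membership) + 1L]] <- inside
  }
  structure(list(epsilon = epsilon, landmarks = landmarks,
                 membership = membership),
            class = "ball_cover")
}

#' @export
print.ball_cover <- function(x, ...) {
  cat(sprintf("<ball_cover> %d landmarks at radius %.4g\n",
              length(x$landmarks), x$epsilon))
  invisible(x)
}

#' Ball Mapper cover graph
#'
#' Builds the Ball Mapper graph of a point cloud: one node per landmark of
#' a greedy epsilon-net, holding the points inside that landmark's open
#' ball, and an edge between two nodes whenever at least one point lies in
#' both balls. Nodes are local clusters; edges encode continuity between
#' them. Larger `epsilon` merges structure into fewer, broader nodes.
#'
#' @param points Numeric matrix of points (rows).
#' @param epsilon Ball radius; ignored when `cover` is supplied.
#' @param ordering Optional visiting order (see [greedy_epsilon_net()]).
#' @param cover Optionally a precomputed `ball_cover` for `points`.
#' @return A `ball_mapper` object: `cover`, `nodes` (tibble `node`,
#'   `landmark_index`, `size`), `edges` (tibble `from`, `to` of node ids),
#'   `n_points`.
#' @examples
#' x <- matrix(c(0, 0.07, 0.14), ncol = 1)
#' g <- ball_mapper(x, epsilon = 0.08)
#' nrow(g$edges)  # the middle point bridges the two balls
#' @export
ball_mapper <- function(points, epsilon = NULL, ordering = NULL,
                        cover = NULL) {
  points <- as.matrix(points)
  if (is.null(cover)) {
    if (is.null(epsilon)) stop("Supply `epsilon` or a `cover`.", call. = FALSE)
    cover <- greedy_epsilon_net(points, epsilon, ordering)
  }
  stopifnot(inherits(cover, "ball_cover"))
  L <- length(cover$landmarks)
  nodes <- tibble::tibble(
    node = seq_len(L),
    landmark_index = cover$landmarks,
    size = vapply(cover$membership, length, 1L))

  # edge iff two balls share a point: collect node pairs through each point
  node_of_point <- vector("list", nrow(points))
  for (l in seq_len(L)) {
    for (p in cover$membership[[l]]) {
      node_of_point[[p]] <- c(node_of_point[[p]], l)
    }
  }
  pairs <- unique(do.call(rbind, lapply(node_of_point, function(ls) {
    if (length(ls) < 2) return(NULL)
    t(utils::combn(sort(ls), 2))
  })))
  edges <- if (is.null(pairs)) {
    tibble::tibble(from = integer(0), to = integer(0))
  } else {
    tibble::tibble(from = pairs[, 1], to = pairs[, 2])
  }
  structure(list(cover = cover, nodes = nodes, edges = edges,
                 n_points = nrow(points)),
            class = "ball_mapper")
}

#' @export
print.ball_mapper <- function(x, ...) {
  cat(sprintf("<ball_mapper> %d nodes, %d edges over %d points (epsilon %.4g)\n",
              nrow(x$nodes), nrow(x$edges), x$n_points, x$cover$epsilon))
  invisible(x)
}

#' Colour nodes by mean total intensity
#'
#' For unit-normalised spectra the component sum of a vector is its "total
#' intensity" on the sphere; averaging it over a node's members gives a
#' scalar per node that mirrors the colour scale of a normalised GC x GC
#' chromatogram.
#'
#' @param graph A `ball_mapper`.
#' @param points The matrix the graph was built on.
#' @return Numeric vector, one value per node.
#' @export
color_by_total_intensity <- function(graph, points) {
  stopifnot(inherits(graph, "ball_mapper"))
  points <- as.matrix(points)
  totals <- rowSums(points)
  vapply(graph$cover$membership, function(mem) mean(totals[mem]), 1.0)
}

#' Colour nodes by label proportions
#'
#' For each node and each category of a point labelling, the fraction of
#' the node's members carrying that category. A node made up purely of one
#' category has proportion 1 there and 0 elsewhere; mixed nodes shade in
#' between. Proportions sum to one per node.
#'
#' @param graph A `ball_mapper`.
#' @param labels Vector of point labels, length `graph$n_points`, no `NA`.
#' @return Tibble with columns `node`, `label`, `proportion`.
#' @export
color_by_label_proportion <- function(graph, labels) {
  stopifnot(inherits(graph, "ball_mapper"),
            length(labels) == graph$n_points)
  if (anyNA(labels)) stop("Every point must be labelled.", call. = FALSE)
  labels <- as.character(labels)
  cats <- sort(unique(labels))
  purrr::map_dfr(seq_len(nrow(graph$nodes)), function(l) {
    mem <- graph$cover$membership[[l]]
    tab <- table(factor(labels[mem], levels = cats))
    tibble::tibble(node = l, label = cats,
                   proportion = as.numeric(tab) / length(mem))
  })
}

#' Convert a Ball Mapper graph to igraph
#'
#' @param graph A `ball_mapper`.
#' @return An [igraph::graph] with node attributes `landmark_index`, `size`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "ball_mapper"))
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = graph$nodes$node,
                          landmark_index = graph$nodes$landmark_index,
                          size = graph$nodes$size))
  g
}

#' Export a Ball Mapper graph
#'
#' Writes GraphML (via igraph) or a small JSON dialect
#' `{epsilon, nodes: [{id, landmark_index, size, members?, colors?}],
#' edges: [[i, j], ...]}`.
#'
#' @param graph A `ball_mapper`.
#' @param path Output file; format chosen by extension (`.graphml`/`.json`).
#' @param members Include per-node membership lists in JSON output
#'   (can be large); default `FALSE`.
#' @param colors Optional named list of node attribute vectors to embed.
#' @return `path`, invisibly.
#' @export
write_ball_mapper <- function(graph, path, members = FALSE, colors = NULL) {
  stopifnot(inherits(graph, "ball_mapper"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "graphml") {
    g <- as_igraph(graph)
    if (!is.null(colors)) {
      for (nm in names(colors)) {
        g <- igraph::set_vertex_attr(g, nm, value = colors[[nm]])
      }
    }
    igraph::write_graph(g, path, format = "graphml")
  } else if (ext == "json") {
    nodes <- lapply(seq_len(nrow(graph$nodes)), function(l) {
      nd <- list(id = l,
                 landmark_index = graph$nodes$landmark_index[l],
                 size = graph$nodes$size[l])
      if (members) nd$members <- graph$cover$membership[[l]]
      if (!is.null(colors)) {
        nd$colors <- lapply(colors, function(v) v[l])
      }
      nd
    })
    edges <- unname(apply(as.matrix(graph$edges), 1, as.list))
    jsonlite::write_json(
      list(epsilon = graph$cover$epsilon, nodes = nodes, edges = edges),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("Unsupported extension '", ext, "'; use .graphml or .json.",
         call. = FALSE)
  }
  invisible(path)
}
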