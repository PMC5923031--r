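#' Overlap graph over aligned gene parts
#'
#' Candidate exons from all gene regions are compared by their column spans
#' in the protein multiple alignment of the prototype models. Two parts are
#' connected iff one overlaps the other by at least a third of its length
#' (in alignment columns, gap columns inside a span counting toward its
#' length).
#'
#' @param spans Data frame with columns `id` (unique part id), `start`,
#'   `end` (0-based half-open alignment column spans).
#' @return An `igraph` undirected graph with one vertex per part.
#' @export
build_overlap_graph <- function(spans) {
  n <- nrow(spans)
  stopifnot(!anyDuplicated(spans$id))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(spans$id))
  if (n > 1L) {
    len <- spans$end - spans$start
    edges <- integer()
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        ov <- min(spans$end[i], spans$end[j]) - max(spans$start[i], spans$start[j])
        if (ov >= ceiling(len[i] / 3) || ov >= ceiling(len[j] / 3))
          edges <- c(edges, i, j)
      }
    }
    if (length(edges)) g <- igraph::add_edges(g, edges)
  }
  g
}

#' Partition parts into ordered adjacency groups
#'
#' Maximal cliques of the overlap graph are enumerated; each part is
#' assigned to exactly one clique (the clique with the smallest order key,
#' then the largest clique, then lexicographically smallest member ids),
#' and the resulting groups are sorted by (minimum start column, minimum
#' end column) of their members.
#'
#' @param graph Output of [build_overlap_graph()].
#' @param spans The same data frame given to [build_overlap_graph()].
#' @return A list of character vectors of part ids, in ascending order.
#' @export
adjacency_groups <- function(graph, spans) {
  ids <- igraph::V(graph)$name
  if (!length(ids)) return(list())
  cliques <- igraph::max_cliques(graph)
  members <- lapply(cliques, function(cl) sort(ids[as.integer(cl)]))
  key_start <- vapply(members, function(m)
    min(spans$start[match(m, spans$id)]), numeric(1))
  key_end <- vapply(members, function(m)
    min(spans$end[match(m, spans$id)]), numeric(1))
  sizes <- lengths(members)
  lex <- vapply(members, paste, "", collapse = "\r")
  ord <- order(key_start, key_end, -sizes, lex)
  assigned <- character()
  groups <- list()
  for (ci in ord) {
    take <- setdiff(members[[ci]], assigned)
    if (length(take)) {
      groups[[length(groups) + 1L]] <- take
      assigned <- c(assigned, take)
    }
  }
  gs <- vapply(groups, function(m) min(spans$start[match(m, spans$id)]), numeric(1))
  ge <- vapply(groups, function(m) min(spans$end[match(m, spans$id)]), numeric(1))
  groups[order(gs, ge)]
}
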