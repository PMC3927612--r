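## Directed TSS similarity networks and their strong/weak component
## structure. Graph machinery is delegated to igraph; the package's tests
## check the decomposition against an independent transitive-closure oracle.

#' Build the directed similarity graph of a TSS dataset
#'
#' Vertices are all proteins with at least one qualifying hit at the
#' dataset's cutoff (identical for every `k`); a directed edge `u -> v` is
#' drawn for every ranked subject `v` in `u`'s top-`k` list. Subjects that
#' never appear as queries are vertices with out-degree 0.
#'
#' @param tss A [build_tss_dataset()] result.
#' @return An `igraph` directed graph with graph attributes `k` and
#'   `cutoff`.
#' @export
build_graph <- function(tss) {
  stopifnot(inherits(tss, "tss_dataset"))
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(tss$vertex_ids), name = tss$vertex_ids)
  if (nrow(tss$ranks)) {
    edges <- rbind(match(tss$ranks$query_id, tss$vertex_ids),
                   match(tss$ranks$subject_id, tss$vertex_ids))
    g <- igraph::add_edges(g, as.vector(edges))
  }
  g <- igraph::set_graph_attr(g, "k", tss$k)
  g <- igraph::set_graph_attr(g, "cutoff", tss$cutoff)
  g
}

component_partition <- function(graph, mode) {
  igraph_mode <- c(STRONG = "strong", WEAK = "weak")[[mode]]
  comp <- igraph::components(graph, mode = igraph_mode)
  membership <- comp$membership
  names(membership) <- igraph::V(graph)$name
  comps <- split(names(membership), membership)
  sizes <- lengths(comps)
  structure(list(
    mode = mode,
    k = igraph::graph_attr(graph, "k"),
    membership = membership,
    components = unname(comps),
    n_vertices = length(membership),
    n_components = length(comps),
    n_components_ge2 = sum(sizes >= 2L),
    lcc_size = if (length(sizes)) max(sizes) else 0L
  ), class = "component_partition")
}

#' Strong components of a TSS similarity graph
#'
#' A strong component is a maximal set of vertices with a directed path in
#' both directions between every pair — the network proxy for a cluster of
#' true paralogs. A protein in a singleton strong component has no paralog
#' identified at this `k`.
#'
#' @param graph An igraph object from [build_graph()].
#' @return A `component_partition` (mode `"STRONG"`) with the full
#'   partition, per-component member lists and the summary statistics
#'   `n_components_ge2` and `lcc_size`.
#' @export
strong_components <- function(graph) component_partition(graph, "STRONG")

#' Weak components of a TSS similarity graph
#'
#' Components of the underlying undirected graph. Weak components connect
#' everything reachable by edges in either direction, which makes them
#' prone to absorbing epaktologs through one-directional similarity links.
#'
#' @inheritParams strong_components
#' @return A `component_partition` (mode `"WEAK"`).
#' @export
weak_components <- function(graph) component_partition(graph, "WEAK")

#' @export
print.component_partition <- function(x, ...) {
  cat(sprintf("%s components at k = %s: %d vertices, %d components (%d with >= 2 members), LCC size %d\n",
              x$mode, x$k %||% "?", x$n_vertices, x$n_components,
              x$n_components_ge2, x$lcc_size))
  invisible(x)
}

#' Component of a given protein
#'
#' @param partition A `component_partition`.
#' @param id Protein id.
#' @return Character vector of component members (including `id`).
#' @export
component_of <- function(partition, id) {
  stopifnot(inherits(partition, "component_partition"))
  m <- partition$membership
  if (!id %in% names(m)) stop_config("'%s' is not a vertex of this graph", id)
  names(m)[m == m[[id]]]
}

#' Component-structure profile across TSS depths
#'
#' Recomputes strong and weak components for every `k` in `k_range` and
#' tabulates the vertex count, the number of components with at least two
#' members and the largest-component size. As `k` grows edges are only
#' added, so weak/strong component counts are non-increasing and the weak
#' LCC size is non-decreasing — the profile locates the depth at which
#' clusters of paralogs fuse into the shuffled-domain giant component.
#'
#' @param hits A hit table ([read_hit_table()] input).
#' @param k_range Integer vector of TSS depths (default 1:20).
#' @param cutoff Homology e-value cutoff.
#' @return Data frame with one row per (`k`, `mode`): `k`, `mode`,
#'   `n_vertices`, `n_components`, `n_components_ge2`, `lcc_size`.
#' @export
component_profile <- function(hits, k_range = 1:20, cutoff = 1e-5) {
  if (!length(k_range)) stop_config("k_range must be non-empty")
  if (!inherits(hits, "similarity_hits")) hits <- read_hit_table(hits)
  rows <- lapply(sort(unique(as.integer(k_range))), function(k) {
    g <- build_graph(build_tss_dataset(hits, k, cutoff))
    do.call(rbind, lapply(list(strong_components(g), weak_components(g)),
      function(p) data.frame(k = k, mode = p$mode, n_vertices = p$n_vertices,
                             n_components = p$n_components,
                             n_components_ge2 = p$n_components_ge2,
                             lcc_size = p$lcc_size,
                             stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trace one query's component membership across TSS depths
#'
#' Follows the cluster of a single protein as more top-scoring matches are
#' admitted, and flags the depth at which the query's component first
#' exceeds a configurable fraction of all vertices — the point where the
#' query is absorbed into the giant component of shuffled-domain proteins.
#'
#' @param hits Hit table.
#' @param query_id Protein id; must occur in the hit table.
#' @param k_range TSS depths to scan.
#' @param mode `"STRONG"` or `"WEAK"`.
#' @param cutoff Homology e-value cutoff.
#' @param giant_fraction Component size (as a fraction of all vertices) at
#'   and above which the absorbed flag is set (default 0.2).
#' @return Data frame ordered by `k`: `k`, `mode`, `component_size`,
#'   `absorbed`, `members` (comma-collapsed).
#' @export
trace_query <- function(hits, query_id, k_range = 1:20,
                        mode = c("STRONG", "WEAK"), cutoff = 1e-5,
                        giant_fraction = 0.2) {
  mode <- match.arg(mode)
  if (!inherits(hits, "similarity_hits")) hits <- read_hit_table(hits)
  if (!query_id %in% c(hits$query_id, hits$subject_id)) {
    stop_config("query '%s' not present in the hit table", query_id)
  }
  rows <- lapply(sort(unique(as.integer(k_range))), function(k) {
    g <- build_graph(build_tss_dataset(hits, k, cutoff))
    p <- if (mode == "STRONG") strong_components(g) else weak_components(g)
    if (!query_id %in% names(p$membership)) {
      # solitary at this cutoff: no qualifying hits at all
      return(data.frame(k = k, mode = mode, component_size = 1L,
                        absorbed = FALSE, members = query_id,
                        stringsAsFactors = FALSE))
    }
    comp <- component_of(p, query_id)
    data.frame(k = k, mode = mode, component_size = length(comp),
               absorbed = length(comp) >= giant_fraction * p$n_vertices,
               members = paste(sort(comp), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a component partition as a long table
#'
#' @param partition A `component_partition`.
#' @param file Optional TSV path.
#' @return Data frame `protein_id`, `mode`, `k`, `component_id`.
#' @export
partition_table <- function(partition, file = NULL) {
  stopifnot(inherits(partition, "component_partition"))
  out <- data.frame(protein_id = names(partition$membership),
                    mode = partition$mode,
                    k = partition$k %||% NA_integer_,
                    component_id = unname(partition$membership),
                    stringsAsFactors = FALSE)
  out <- out[order(out$component_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
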