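## Interspecies best-hit clustering: query proteins that share their best
## match in a target proteome are candidate paralogs whose duplication
## postdates the divergence of the target species.

#' Best hit of each query in a target proteome
#'
#' Keeps, per query, the single subject with the highest bit-score among
#' hits passing the homology cutoff (ties: lowest e-value, then
#' lexicographic subject id). Queries with no qualifying hit are absent.
#'
#' @param hits Query-vs-one-target-proteome hit table
#'   ([read_hit_table()] input). Self matches are excluded.
#' @param cutoff Homology e-value cutoff (strict `<`; default 1e-5).
#' @param species Optional target species label stored on the result.
#' @return Data frame of class `best_hit_map`: `query_id`, `subject_id`,
#'   `bitscore`, `evalue`; attribute `species`.
#' @export
best_hits <- function(hits, cutoff = 1e-5, species = NA_character_) {
  if (!inherits(hits, "similarity_hits")) hits <- read_hit_table(hits)
  qual <- hits[hits$evalue < cutoff & hits$query_id != hits$subject_id, ,
               drop = FALSE]
  if (nrow(qual)) {
    o <- order(qual$query_id, -qual$bitscore, qual$evalue, qual$subject_id)
    qual <- qual[o, , drop = FALSE]
    qual <- qual[!duplicated(qual$query_id), , drop = FALSE]
  }
  out <- data.frame(query_id = qual$query_id, subject_id = qual$subject_id,
                    bitscore = qual$bitscore, evalue = qual$evalue,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "species") <- species
  class(out) <- c("best_hit_map", "data.frame")
  out
}

#' Cluster queries sharing the same best hit
#'
#' Groups query proteins whose best match is the same target entry. Groups
#' with at least two members are the candidate paralog clusters (their
#' duplication postdates the split with the target species); unique matches
#' are reported separately as putative 1:1 orthologs. This grouping equals
#' the weak components of the bipartite query/best-subject graph restricted
#' to query vertices.
#'
#' @param map A [best_hits()] result.
#' @return List of class `interspecies_clusters`: `clusters` (data frame
#'   `anchor_subject_id`, `member`, `n_members` for clusters of >= 2),
#'   `one_to_one` (data frame `query_id`, `subject_id`), `species`.
#' @export
cluster_by_best_hit <- function(map) {
  stopifnot(inherits(map, "best_hit_map"))
  species <- attr(map, "species")
  if (!nrow(map)) {
    return(structure(list(
      clusters = data.frame(anchor_subject_id = character(0),
                            member = character(0), n_members = integer(0),
                            stringsAsFactors = FALSE),
      one_to_one = data.frame(query_id = character(0),
                              subject_id = character(0),
                              stringsAsFactors = FALSE),
      species = species), class = "interspecies_clusters"))
  }
  grp <- split(map$query_id, map$subject_id)
  sizes <- lengths(grp)
  big <- grp[sizes >= 2L]
  clusters <- if (length(big)) {
    data.frame(anchor_subject_id = rep(names(big), lengths(big)),
               member = unlist(big, use.names = FALSE),
               n_members = rep(lengths(big), lengths(big)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(anchor_subject_id = character(0), member = character(0),
               n_members = integer(0), stringsAsFactors = FALSE)
  }
  ones <- grp[sizes == 1L]
  one_to_one <- data.frame(query_id = unlist(ones, use.names = FALSE) %||% character(0),
                           subject_id = names(ones) %||% character(0),
                           stringsAsFactors = FALSE)
  o <- order(clusters$anchor_subject_id, clusters$member)
  clusters <- clusters[o, , drop = FALSE]
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, one_to_one = one_to_one,
                 species = species), class = "interspecies_clusters")
}

#' @export
print.interspecies_clusters <- function(x, ...) {
  cat(sprintf("Interspecies best-hit clustering%s: %d clusters (>= 2 members), %d clustered queries, %d one-to-one matches\n",
              if (is.na(x$species %||% NA)) "" else paste0(" vs ", x$species),
              length(unique(x$clusters$anchor_subject_id)),
              nrow(x$clusters), nrow(x$one_to_one)))
  invisible(x)
}

#' Clustering profile across target species
#'
#' Applies best-hit clustering against each target proteome and tabulates,
#' per species in the supplied divergence order, the number of clusters
#' with at least two members and the number of clustered query proteins.
#' Species whose duplications postdate their split cluster more queries, so
#' the profile has a time dimension.
#'
#' @param hit_tables Named list of hit tables (one per target species).
#' @param divergence_order Character vector of species names, ordered by
#'   decreasing divergence time; must name entries of `hit_tables`.
#' @param cutoff Homology e-value cutoff.
#' @return Data frame, one row per species in order: `species`,
#'   `n_clusters_ge2`, `n_clustered_queries`, `n_one_to_one`.
#' @export
cluster_profile_across_species <- function(hit_tables, divergence_order,
                                           cutoff = 1e-5) {
  if (!length(divergence_order)) stop_config("need at least one species")
  missing <- setdiff(divergence_order, names(hit_tables))
  if (length(missing)) {
    stop_config("species missing from hit_tables: %s",
                paste(missing, collapse = ", "))
  }
  rows <- lapply(divergence_order, function(sp) {
    cl <- cluster_by_best_hit(best_hits(hit_tables[[sp]], cutoff, species = sp))
    data.frame(species = sp,
               n_clusters_ge2 = length(unique(cl$clusters$anchor_subject_id)),
               n_clustered_queries = length(unique(cl$clusters$member)),
               n_one_to_one = nrow(cl$one_to_one),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Date a gene duplication from the change in clustering pattern
#'
#' A query clustered with a relative by species that split at time `t`
#' implies the duplication is more recent than `t`; a 1:1 match in a
#' species implies the duplication predates that split. Scanning species
#' from the most to the least divergent, the transition from "clustered"
#' to "1:1" brackets the duplication between the youngest clustering split
#' and the oldest 1:1 split.
#'
#' @param status Data frame with columns `species`, `time_my` (split time,
#'   My) and `clustered` (logical: `TRUE` if the query is clustered with at
#'   least one other query by that species, `FALSE` if it is a 1:1 match).
#' @return List with `status` (`"BRACKETED"`, `"OPEN"`, or `"UNRESOLVED"`
#'   for non-monotone patterns, as caused by incomplete target proteomes)
#'   and the bracketing interval `upper_my` / `lower_my` (duplication time
#'   `t` satisfies `lower_my < t <= upper_my`; `upper_my` may be `Inf`).
#' @export
duplication_timing <- function(status) {
  stopifnot(is.data.frame(status),
            all(c("species", "time_my", "clustered") %in% names(status)))
  if (!nrow(status)) stop_config("empty clustering status")
  status <- status[order(-status$time_my), , drop = FALSE]
  cl <- status$clustered
  # a split older than the duplication leaves a single ancestral gene, so
  # old species cluster the paralogs and young species match 1:1; walking
  # from the oldest split to the youngest the pattern must be
  # TRUE... then FALSE..., with at most one change of state
  flips <- sum(diff(as.integer(cl)) != 0L)
  if (flips > 1L || (flips == 1L && !cl[1L])) {
    return(list(status = "UNRESOLVED", upper_my = NA_real_, lower_my = NA_real_))
  }
  if (all(cl)) {
    # clustered even by the youngest split: duplication postdates it
    return(list(status = "OPEN", upper_my = min(status$time_my), lower_my = 0))
  }
  if (!any(cl)) {
    # 1:1 everywhere: duplication predates the oldest sampled split
    return(list(status = "OPEN", upper_my = Inf, lower_my = max(status$time_my)))
  }
  list(status = "BRACKETED",
       upper_my = min(status$time_my[cl]),
       lower_my = max(status$time_my[!cl]))
}
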