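## Aggregate statistics over classified homolog pairs: cluster homogeneity,
## positional distributions, domain-count spectra and rates of DA change.

#' Domain-architecture homogeneity of clusters
#'
#' A cluster is homogeneous when every within-cluster pair has identical
#' architecture at the strict cutoff. Because that statistic hides cluster
#' size, the percent of all within-cluster pairwise comparisons that differ
#' in architecture is reported alongside it.
#'
#' @param clusters List of character vectors of protein ids (clusters of
#'   size < 2 are skipped with a warning).
#' @param annotations Annotation table covering the clustered proteins.
#' @param cutoff Architecture cutoff (default 1e-5).
#' @return List: `pct_clusters_identical`, `pct_comparisons_different`,
#'   `n_clusters`, `n_pairs` (both percentages are `NaN` when nothing
#'   qualifies).
#' @export
aggregate_homogeneity <- function(clusters, annotations, cutoff = 1e-5) {
  ann <- read_domain_annotations(annotations)
  by_prot <- split(ann, ann$protein_id)
  arch_of <- function(id) {
    rows <- by_prot[[id]]
    if (is.null(rows)) character(0) else build_architecture(rows, cutoff)$domains
  }
  sizes <- lengths(clusters)
  if (any(sizes < 2L)) {
    warning(sprintf("skipping %d cluster(s) with fewer than 2 members",
                    sum(sizes < 2L)), call. = FALSE)
    clusters <- clusters[sizes >= 2L]
  }
  n_clusters <- length(clusters)
  n_pairs <- 0L
  n_diff <- 0L
  n_homog <- 0L
  for (cl in clusters) {
    archs <- lapply(cl, arch_of)
    idx <- utils::combn(length(cl), 2L)
    diffs <- vapply(seq_len(ncol(idx)), function(k) {
      !identical(archs[[idx[1L, k]]], archs[[idx[2L, k]]])
    }, logical(1))
    n_pairs <- n_pairs + length(diffs)
    n_diff <- n_diff + sum(diffs)
    if (!any(diffs)) n_homog <- n_homog + 1L
  }
  list(pct_clusters_identical = 100 * n_homog / n_clusters,
       pct_comparisons_different = 100 * n_diff / n_pairs,
       n_clusters = n_clusters, n_pairs = n_pairs)
}

record_list <- function(records) {
  if (inherits(records, "da_difference")) records <- list(records)
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, logical(1), "da_difference")))
  records
}

#' Positional distribution of DA differences
#'
#' Pools the per-cutoff category assignments of classified pairs (each
#' assignment contributes each of its categories once, so the total may
#' exceed four times the number of pairs) and reports the proportion of
#' each category among non-IDENTICAL assignments, optionally stratified by
#' transition type.
#'
#' @param records List of [classify_pair_multicutoff()] results.
#' @param stratify_by_transition If `TRUE`, one distribution per
#'   `TYPE1`/`TYPE2`/`TYPE3` stratum (records with `NA` transition are
#'   dropped).
#' @return Data frame `category`, `count`, `proportion_pct` (plus
#'   `transition` when stratified). When every assignment is IDENTICAL the
#'   result has zero rows and attribute `all_identical = TRUE`.
#' @export
positional_distribution <- function(records, stratify_by_transition = FALSE) {
  records <- record_list(records)
  tally <- function(recs) {
    cats <- unlist(lapply(recs, function(r) unlist(r$categories)),
                   use.names = FALSE)
    cats <- cats[cats != "IDENTICAL"]
    lv <- setdiff(DA_CATEGORIES, "IDENTICAL")
    cnt <- table(factor(cats, levels = lv))
    data.frame(category = lv, count = as.integer(cnt),
               proportion_pct = if (sum(cnt)) 100 * as.integer(cnt) / sum(cnt)
                                else rep(NaN, length(lv)),
               stringsAsFactors = FALSE)
  }
  if (!stratify_by_transition) {
    out <- tally(records)
    if (!sum(out$count)) {
      out <- out[0, , drop = FALSE]
      attr(out, "all_identical") <- TRUE
    }
    return(out)
  }
  tt <- vapply(records, function(r) r$transition_type %||% NA_character_,
               character(1))
  strata <- c("TYPE1", "TYPE2", "TYPE3")
  out <- do.call(rbind, lapply(strata, function(s) {
    recs <- records[!is.na(tt) & tt == s]
    if (!length(recs)) return(NULL)
    cbind(transition = s, tally(recs), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Distribution of domain-count differences
#'
#' Frequencies of the absolute domain-count difference at the strict
#' cutoff, binned as 1, 2, 3 and >= 4, over pairs that differ in at least
#' one domain.
#'
#' @param records List of [classify_pair_multicutoff()] results.
#' @return Data frame `bin`, `count`, `proportion_pct`; zero rows with
#'   attribute `all_identical = TRUE` when no pair differs.
#' @export
domain_count_diff_distribution <- function(records) {
  records <- record_list(records)
  d <- vapply(records, `[[`, numeric(1), "n_domain_diff")
  d <- d[d >= 1]
  bins <- c("1", "2", "3", ">=4")
  if (!length(d)) {
    out <- data.frame(bin = character(0), count = integer(0),
                      proportion_pct = numeric(0), stringsAsFactors = FALSE)
    attr(out, "all_identical") <- TRUE
    return(out)
  }
  binned <- cut(d, breaks = c(0.5, 1.5, 2.5, 3.5, Inf), labels = bins)
  cnt <- table(binned)
  data.frame(bin = bins, count = as.integer(cnt),
             proportion_pct = 100 * as.integer(cnt) / sum(cnt),
             stringsAsFactors = FALSE)
}

#' Lower-bound rate of domain architecture change
#'
#' Given the percent of pairwise comparisons within paralog clusters that
#' differ in architecture and an upper bound on the divergence time of the
#' underlying duplications, the ratio is a lower bound on the percent DA
#' change per million years, reported to two significant figures.
#'
#' @param pct_da_diff Percent of differing comparisons (0-100).
#' @param t_upper_my Upper bound on duplication age (My, > 0).
#' @return Object of class `rate_estimate`: `pct_da_diff`, `t_upper_my`,
#'   `rate_lb` (percent DA change per My).
#' @examples
#' rate_per_my(28, 910)  # >= 0.031 %/My
#' rate_per_my(23, 800)  # >= 0.029 %/My
#' @export
rate_per_my <- function(pct_da_diff, t_upper_my) {
  if (!is.numeric(t_upper_my) || t_upper_my <= 0) {
    stop_config("t_upper_my must be > 0")
  }
  if (!is.numeric(pct_da_diff) || pct_da_diff < 0 || pct_da_diff > 100) {
    stop_config("pct_da_diff must be in [0, 100]")
  }
  structure(list(pct_da_diff = pct_da_diff, t_upper_my = t_upper_my,
                 rate_lb = signif(pct_da_diff / t_upper_my, 2)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("(%g%% / <%g My) >%g%% DA change/My\n",
              x$pct_da_diff, x$t_upper_my, x$rate_lb))
  invisible(x)
}
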