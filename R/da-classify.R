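## Positional classification of domain architecture differences.

DA_CATEGORIES <- c("N_TERMINAL", "C_TERMINAL", "INTERNAL", "DUPLICATION",
                   "UNASSIGNED", "IDENTICAL")

DEFAULT_DA_CUTOFFS <- c(1e-2, 1e-3, 1e-4, 1e-5)

#' Classify the difference between two aligned domain architectures
#'
#' Assigns the pair to one or more positional difference categories:
#'
#' * `IDENTICAL` — no unmatched domain on either side;
#' * `UNASSIGNED` — no shared domain at all (nothing to anchor positions);
#' * otherwise each unmatched domain contributes one category:
#'   `N_TERMINAL` if it lies before the first matched position on its side,
#'   `C_TERMINAL` if after the last, `INTERNAL` in between — except that an
#'   unmatched domain lying in a contiguous run of its own family that also
#'   contains a matched domain is an extra tandem copy and is classified
#'   `DUPLICATION` instead of positionally.
#'
#' The result is the union over all unmatched domains, so a pair can be,
#' e.g., both `N_TERMINAL` and `INTERNAL`. Labels refer to sequence
#' position only. Because the leftmost-LCS tie-break depends on argument
#' order, the categories are computed for both orientations of the pair and
#' united, which makes the classification symmetric in the two proteins.
#'
#' @param alignment A [align_architectures()] result (may be omitted if
#'   `da_a`/`da_b` are given).
#' @param da_a,da_b The architectures that were aligned (used when
#'   `alignment` is missing).
#' @return Character vector of categories (subset of `DA_CATEGORIES`).
#' @export
classify_difference <- function(alignment = NULL, da_a = NULL, da_b = NULL) {
  if (is.null(alignment)) alignment <- align_architectures(da_a, da_b)
  stopifnot(inherits(alignment, "da_alignment"))
  sort(unique(c(classify_one_orientation(alignment),
                classify_one_orientation(
                  align_architectures(alignment$b, alignment$a)))))
}

classify_one_orientation <- function(alignment) {
  a <- alignment$a; b <- alignment$b
  if (!length(alignment$unmatched_a) && !length(alignment$unmatched_b)) {
    return("IDENTICAL")
  }
  if (!nrow(alignment$pairs)) return("UNASSIGNED")

  side <- function(tokens, unmatched, matched) {
    if (!length(unmatched)) return(character(0))
    vapply(unmatched, function(i) {
      # tandem run of the same family around position i
      lo <- i; while (lo > 1L && tokens[lo - 1L] == tokens[i]) lo <- lo - 1L
      hi <- i; while (hi < length(tokens) && tokens[hi + 1L] == tokens[i]) hi <- hi + 1L
      if (any(matched >= lo & matched <= hi)) return("DUPLICATION")
      if (i < min(matched)) "N_TERMINAL"
      else if (i > max(matched)) "C_TERMINAL"
      else "INTERNAL"
    }, character(1))
  }
  cats <- c(side(a, alignment$unmatched_a, alignment$pairs[, 1L]),
            side(b, alignment$unmatched_b, alignment$pairs[, 2L]))
  sort(unique(cats))
}

#' Transition type of a single-domain count change
#'
#' Pairs differing by exactly one domain are typed by the smaller
#' architecture: 1 <-> 2 domains is type 1 (where any change is terminal by
#' construction), 2 <-> 3 is type 2, and N <-> N+1 with N > 2 is type 3
#' (where internal positions dominate). Any other count difference gives
#' `NA`.
#'
#' @param count_a,count_b Domain counts (>= 0).
#' @return `"TYPE1"`, `"TYPE2"`, `"TYPE3"` or `NA_character_`.
#' @export
transition_type <- function(count_a, count_b) {
  stopifnot(count_a >= 0, count_b >= 0)
  if (abs(count_a - count_b) != 1L) return(NA_character_)
  m <- min(count_a, count_b)
  if (m == 1L) "TYPE1" else if (m == 2L) "TYPE2" else if (m >= 3L) "TYPE3"
  else NA_character_
}

#' Classify a homolog pair at the four standard e-value cutoffs
#'
#' Builds both architectures, aligns them and classifies the difference at
#' each cutoff (defaults 1e-2, 1e-3, 1e-4, 1e-5), so each pair receives
#' four category-set assignments; domains detected only at permissive
#' cutoffs can move a pair between categories across the series. The
#' domain-count difference and the transition type are evaluated at the
#' strictest cutoff.
#'
#' @param annotations_a,annotations_b Annotation rows for the two proteins.
#' @param cutoffs Numeric vector of e-value cutoffs.
#' @param strict_cutoff Cutoff at which `n_domain_diff` and
#'   `transition_type` are computed (default `min(cutoffs)`).
#' @return Object of class `da_difference`: list with `pair` (the two
#'   protein ids), `categories` (named list: one character vector per
#'   cutoff), `n_domain_diff`, `transition_type`.
#' @export
classify_pair_multicutoff <- function(annotations_a, annotations_b,
                                      cutoffs = DEFAULT_DA_CUTOFFS,
                                      strict_cutoff = min(cutoffs)) {
  stopifnot(length(cutoffs) >= 1L)
  ids <- c(
    if ("protein_id" %in% names(annotations_a) && nrow(annotations_a))
      annotations_a$protein_id[1L] else NA_character_,
    if ("protein_id" %in% names(annotations_b) && nrow(annotations_b))
      annotations_b$protein_id[1L] else NA_character_)
  cats <- lapply(cutoffs, function(ct) {
    da_a <- build_architecture(annotations_a, ct)
    da_b <- build_architecture(annotations_b, ct)
    classify_difference(align_architectures(da_a, da_b))
  })
  names(cats) <- format(cutoffs, scientific = TRUE, trim = TRUE)
  da_a <- build_architecture(annotations_a, strict_cutoff)
  da_b <- build_architecture(annotations_b, strict_cutoff)
  nd <- abs(length(da_a$domains) - length(da_b$domains))
  structure(list(pair = ids, categories = cats, n_domain_diff = nd,
                 transition_type = transition_type(length(da_a$domains),
                                                   length(da_b$domains))),
            class = "da_difference")
}

#' @export
print.da_difference <- function(x, ...) {
  cat(sprintf("DA difference %s vs %s (count diff %d, transition %s)\n",
              x$pair[1L], x$pair[2L], x$n_domain_diff,
              x$transition_type %||% "NA"))
  for (ct in names(x$categories)) {
    cat(sprintf("  e < %s: %s\n", ct, paste(x$categories[[ct]], collapse = ", ")))
  }
  invisible(x)
}
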