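## Domain architectures: cutoff-dependent domain strings built from
## annotation tables, and their alignment by longest common subsequence.

#' Read a domain annotation table
#'
#' Tab-separated with a header line and columns `protein_id`, `family_id`,
#' `start`, `end`, `evalue` (1-based inclusive coordinates), as written by
#' [emit_domain_annotations()].
#'
#' @param source File path or data frame with those columns.
#' @return Data frame with the five columns.
#' @export
read_domain_annotations <- function(source) {
  ann <- if (is.character(source) && length(source) == 1L) {
    utils::read.table(source, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else if (is.data.frame(source)) {
    source
  } else {
    stop_config("source must be a file path or a data frame")
  }
  need <- c("protein_id", "family_id", "start", "end", "evalue")
  if (!all(need %in% names(ann))) {
    stop_config("annotation table needs columns: %s", paste(need, collapse = ", "))
  }
  ann[need]
}

#' Read HMMER per-domain output (domtblout) as an annotation table
#'
#' Maps the whitespace-separated `--domtblout` columns of `hmmscan` to the
#' package's annotation fields: target name -> `protein_id`, query (model)
#' name -> `family_id`, envelope from/to -> `start`/`end`, independent
#' e-value -> `evalue`.
#'
#' @param path Path to a domtblout file.
#' @return Annotation data frame (`protein_id`, `family_id`, `start`,
#'   `end`, `evalue`).
#' @export
read_domtblout <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!startsWith(raw, "#") & nzchar(trimws(raw))]
  if (!length(raw)) {
    return(data.frame(protein_id = character(0), family_id = character(0),
                      start = integer(0), end = integer(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(raw), "[[:space:]]+")
  if (any(lengths(parts) < 21L)) {
    stop_config("domtblout rows need >= 21 whitespace-separated columns")
  }
  get <- function(i) vapply(parts, `[[`, character(1), i)
  data.frame(protein_id = get(1L), family_id = get(4L),
             start = as.integer(get(20L)), end = as.integer(get(21L)),
             evalue = as.numeric(get(13L)), stringsAsFactors = FALSE)
}

#' Build the domain architecture of a protein at an e-value cutoff
#'
#' Keeps annotation hits with `evalue < cutoff`, then eliminates
#' overlapping hits: candidates are visited in order of ascending e-value
#' (ties: longer hit, then smaller start) and a hit is accepted only if its
#' overlap with every previously accepted hit is at most `max_overlap` of
#' the shorter hit's length. Accepted hits, ordered by start coordinate,
#' form the architecture — the protein's linear sequence of domain family
#' tokens at this stringency.
#'
#' @param annotations Annotation rows for a single protein (the
#'   `protein_id` column may be omitted if unambiguous).
#' @param cutoff E-value cutoff (strict `<`).
#' @param max_overlap Tolerated pairwise overlap as a fraction of the
#'   shorter hit (default 0.3).
#' @return Object of class `domain_architecture`: list with `protein_id`,
#'   `cutoff`, `domains` (character vector, possibly empty) and `table`
#'   (the accepted rows).
#' @export
build_architecture <- function(annotations, cutoff = 1e-5, max_overlap = 0.3) {
  ann <- read_domain_annotations(
    if ("protein_id" %in% names(annotations)) annotations
    else cbind(protein_id = NA_character_, annotations))
  if (length(unique(ann$protein_id)) > 1L) {
    stop_config("build_architecture() expects annotations for one protein; got %d",
                length(unique(ann$protein_id)))
  }
  if (any(ann$start > ann$end)) stop_config("annotation with start > end")
  pid <- if (nrow(ann)) ann$protein_id[1L] else NA_character_
  ann <- ann[ann$evalue < cutoff, , drop = FALSE]
  if (nrow(ann)) {
    len <- ann$end - ann$start + 1L
    o <- order(ann$evalue, -len, ann$start)
    ann <- ann[o, , drop = FALSE]
    len <- len[o]
    keep <- logical(nrow(ann))
    for (i in seq_len(nrow(ann))) {
      ok <- TRUE
      for (j in which(keep)) {
        ov <- min(ann$end[i], ann$end[j]) - max(ann$start[i], ann$start[j]) + 1L
        if (ov > max_overlap * min(len[i], len[j])) { ok <- FALSE; break }
      }
      keep[i] <- ok
    }
    ann <- ann[keep, , drop = FALSE]
    ann <- ann[order(ann$start), , drop = FALSE]
  }
  rownames(ann) <- NULL
  structure(list(protein_id = pid, cutoff = cutoff,
                 domains = ann$family_id %||% character(0), table = ann),
            class = "domain_architecture")
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat(sprintf("%s @ e < %g: %s\n", x$protein_id %||% "?", x$cutoff,
              if (length(x$domains)) paste(x$domains, collapse = "-") else "(empty)"))
  invisible(x)
}

da_tokens <- function(x) {
  if (inherits(x, "domain_architecture")) x$domains else as.character(x)
}

#' Align two domain architectures
#'
#' Token-level longest common subsequence over domain family ids; among
#' equal-length LCSs the leftmost one (greedily smallest indices in the
#' first architecture, then the second) is chosen for determinism.
#'
#' @param da_a,da_b `domain_architecture` objects or plain character
#'   vectors of family tokens.
#' @return Object of class `da_alignment`: `pairs` (2-column integer
#'   matrix of matched positions, strictly increasing in both rows),
#'   `unmatched_a`, `unmatched_b` (integer positions), plus the two token
#'   vectors `a` and `b`.
#' @export
align_architectures <- function(da_a, da_b) {
  a <- da_tokens(da_a); b <- da_tokens(da_b)
  n <- length(a); m <- length(b)
  # suffix LCS lengths: L[i, j] = LCS of a[i..n], b[j..m]
  L <- matrix(0L, n + 1L, m + 1L)
  if (n && m) {
    for (i in n:1) {
      for (j in m:1) {
        L[i, j] <- if (a[i] == b[j]) L[i + 1L, j + 1L] + 1L
                   else max(L[i + 1L, j], L[i, j + 1L])
      }
    }
  }
  pairs <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("a", "b")))
  i <- 1L; j <- 1L
  while (i <= n && j <= m && L[i, j] > 0L) {
    if (a[i] == b[j] && L[i, j] == L[i + 1L, j + 1L] + 1L) {
      pairs <- rbind(pairs, c(i, j))
      i <- i + 1L; j <- j + 1L
    } else if (L[i + 1L, j] >= L[i, j + 1L]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(seq_len(n), pairs[, 1L]),
                 unmatched_b = setdiff(seq_len(m), pairs[, 2L]),
                 a = a, b = b), class = "da_alignment")
}
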