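## Readers for all-against-all similarity hits and construction of the
## ranked top-scoring-sequence (TSS) datasets.

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read an all-against-all hit table (BLAST tabular, outfmt 6)
#'
#' Accepts a path to a 12-column tab-separated file (comment lines starting
#' with `#` are skipped) or an already-parsed data frame with at least the
#' outfmt-6 columns `qseqid`, `sseqid`, `evalue`, `bitscore`. Multiple HSPs
#' for the same query/subject pair are collapsed to the row with the lowest
#' e-value (ties: highest bit-score). Self matches are retained here; they
#' are removed when TSS datasets are built.
#'
#' @param source File path or data frame.
#' @return Data frame of class `similarity_hits` with columns `query_id`,
#'   `subject_id`, `evalue`, `bitscore`, one row per pair.
#' @export
read_hit_table <- function(source) {
  if (is.character(source) && length(source) == 1L) {
    raw <- readLines(source, warn = FALSE)
    keep <- !startsWith(raw, "#") & nzchar(trimws(raw))
    lineno <- which(keep)
    raw <- raw[keep]
    if (!length(raw)) {
      warning("empty hit table: ", source, call. = FALSE)
      return(empty_hits())
    }
    parts <- strsplit(raw, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 12L)) {
      stop_config("malformed hit table %s: line(s) %s have fewer than 12 columns",
                  source, paste(lineno[nf < 12L], collapse = ", "))
    }
    ev <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 11L)))
    bs <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 12L)))
    bad <- is.na(ev) | is.na(bs)
    if (any(bad)) {
      stop_config("malformed hit table %s: non-numeric evalue/bitscore at line(s) %s",
                  source, paste(lineno[bad], collapse = ", "))
    }
    hits <- data.frame(query_id = vapply(parts, `[[`, character(1), 1L),
                       subject_id = vapply(parts, `[[`, character(1), 2L),
                       evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
  } else if (is.data.frame(source)) {
    nm <- names(source)
    if (all(c("qseqid", "sseqid", "evalue", "bitscore") %in% nm)) {
      hits <- data.frame(query_id = as.character(source$qseqid),
                         subject_id = as.character(source$sseqid),
                         evalue = as.numeric(source$evalue),
                         bitscore = as.numeric(source$bitscore),
                         stringsAsFactors = FALSE)
    } else if (all(c("query_id", "subject_id", "evalue", "bitscore") %in% nm)) {
      hits <- source[, c("query_id", "subject_id", "evalue", "bitscore")]
    } else {
      stop_config("data frame source needs qseqid/sseqid/evalue/bitscore columns")
    }
    if (!nrow(hits)) {
      warning("empty hit table", call. = FALSE)
      return(empty_hits())
    }
    if (anyNA(hits$evalue) || anyNA(hits$bitscore)) {
      stop_config("non-numeric evalue/bitscore in hit table")
    }
  } else {
    stop_config("source must be a file path or a data frame")
  }
  if (any(hits$evalue < 0)) stop_config("negative e-values in hit table")
  collapse_hsps(hits)
}

empty_hits <- function() {
  structure(data.frame(query_id = character(0), subject_id = character(0),
                       evalue = numeric(0), bitscore = numeric(0),
                       stringsAsFactors = FALSE),
            class = c("similarity_hits", "data.frame"))
}

# best HSP per (query, subject): lowest evalue, tie-break highest bitscore
collapse_hsps <- function(hits) {
  o <- order(hits$query_id, hits$subject_id, hits$evalue, -hits$bitscore)
  hits <- hits[o, , drop = FALSE]
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  hits <- hits[!duplicated(key), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("similarity_hits", "data.frame")
  hits
}

#' Build a TSS = k dataset from a hit table
#'
#' For each query, ranks its non-self hits passing the homology cutoff
#' (e-value < `cutoff`) by decreasing bit-score — ties broken by ascending
#' e-value, then lexicographic subject id — and keeps the top `k`. Queries
#' with no qualifying hit are absent from the ranked lists: they are the
#' "solitary" proteins. The vertex universe (any id involved in a
#' qualifying hit) is recorded so that similarity graphs built at different
#' `k` share one vertex set.
#'
#' @param hits A `similarity_hits` table (or anything [read_hit_table()]
#'   accepts).
#' @param k Number of top-scoring sequences to keep per query (>= 1).
#' @param cutoff Homology e-value cutoff (strict `<`; default 1e-5).
#' @return Object of class `tss_dataset`: list with `k`, `cutoff`, `ranks`
#'   (data frame `query_id`, `rank`, `subject_id`, `bitscore`, `evalue`)
#'   and `vertex_ids`.
#' @export
build_tss_dataset <- function(hits, k, cutoff = 1e-5) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop_config("k must be a single integer >= 1")
  }
  k <- as.integer(k)
  if (!inherits(hits, "similarity_hits")) hits <- read_hit_table(hits)
  qual <- hits[hits$evalue < cutoff & hits$query_id != hits$subject_id, ,
               drop = FALSE]
  vertex_ids <- sort(unique(c(qual$query_id, qual$subject_id)))
  if (nrow(qual)) {
    o <- order(qual$query_id, -qual$bitscore, qual$evalue, qual$subject_id)
    qual <- qual[o, , drop = FALSE]
    rk <- stats::ave(seq_len(nrow(qual)), qual$query_id, FUN = seq_along)
    qual$rank <- rk
    qual <- qual[qual$rank <= k, , drop = FALSE]
    ranks <- data.frame(query_id = qual$query_id, rank = qual$rank,
                        subject_id = qual$subject_id, bitscore = qual$bitscore,
                        evalue = qual$evalue, stringsAsFactors = FALSE)
  } else {
    ranks <- data.frame(query_id = character(0), rank = integer(0),
                        subject_id = character(0), bitscore = numeric(0),
                        evalue = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(ranks) <- NULL
  structure(list(k = k, cutoff = cutoff, ranks = ranks,
                 vertex_ids = vertex_ids), class = "tss_dataset")
}

#' @export
print.tss_dataset <- function(x, ...) {
  cat(sprintf("TSS = %d dataset (cutoff e < %g): %d queries, %d vertices\n",
              x$k, x$cutoff, length(unique(x$ranks$query_id)),
              length(x$vertex_ids)))
  invisible(x)
}

#' Export a TSS dataset as TSV
#'
#' @param tss A `tss_dataset`.
#' @param file Output path.
#' @export
write_tss_dataset <- function(tss, file) {
  stopifnot(inherits(tss, "tss_dataset"))
  utils::write.table(tss$ranks, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
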