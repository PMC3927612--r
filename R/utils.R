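`%||%` <- function(a, b) if (is.null(a)) b else a

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' @noRd
as_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x)) {
    stop_config("'%s' must be a single integer, got %s", name, deparse(x))
  }
  as.integer(x)
}

# canonical unordered pair key, independent of argument order
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# fraction of identical positions between two equal-length residue vectors
seq_identity <- function(x, y) {
  if (length(x) != length(y)) stop("sequences of unequal length")
  mean(x == y)
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
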