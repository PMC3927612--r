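# Independent oracles and fixture builders used across the suite.

# --- brute-force component oracle (transitive closure by boolean powers) ----

closure <- function(A) {
  n <- nrow(A)
  R <- A | diag(TRUE, n)
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) return(R)
    R <- R2
  }
}

# canonical partition: sorted list of sorted member vectors
canon <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[[`, character(1), 1L))]
}

# strong/weak components of a digraph given as an edge data frame
# (from, to) over vertex names; brute force, independent of igraph
oracle_components <- function(vertices, edges, mode) {
  n <- length(vertices)
  A <- matrix(FALSE, n, n, dimnames = list(vertices, vertices))
  if (nrow(edges)) A[cbind(edges$from, edges$to)] <- TRUE
  if (mode == "WEAK") A <- A | t(A)
  R <- closure(A)
  mutual <- if (mode == "STRONG") R & t(R) else R
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    members <- which(mutual[i, ] & mutual[, i])
    comps[[length(comps) + 1L]] <- vertices[members]
    seen[members] <- TRUE
  }
  canon(comps)
}

# --- random graph fixtures ---------------------------------------------------

# random digraph as a hit table whose TSS at k >= n reproduces its edges
random_digraph_hits <- function(n, p) {
  v <- sprintf("v%02d", seq_len(n))
  pairs <- expand.grid(from = v, to = v, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  hits <- if (nrow(pairs)) {
    data.frame(query_id = pairs$from, subject_id = pairs$to,
               evalue = 1e-20, bitscore = 500 - seq_len(nrow(pairs)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(query_id = character(0), subject_id = character(0),
               evalue = numeric(0), bitscore = numeric(0),
               stringsAsFactors = FALSE)
  }
  list(vertices = v, edges = pairs, hits = hits)
}

as_hits <- function(df) {
  structure(df, class = c("similarity_hits", "data.frame"))
}

empty_hits_df <- function() {
  as_hits(data.frame(query_id = character(0), subject_id = character(0),
                     evalue = numeric(0), bitscore = numeric(0),
                     stringsAsFactors = FALSE))
}

# random weighted hit table: scores decay with |i - j| so that top-k
# neighbourhoods grow smoothly with k
random_hit_table <- function(n_proteins = 60, n_hits_per_query = 12) {
  v <- sprintf("p%03d", seq_len(n_proteins))
  rows <- lapply(seq_len(n_proteins), function(i) {
    subj <- sample(setdiff(seq_len(n_proteins), i), n_hits_per_query)
    bs <- round(400 * exp(-abs(i - subj) / n_proteins) + stats::rnorm(n_hits_per_query, 0, 5), 1)
    data.frame(query_id = v[i], subject_id = v[subj],
               evalue = 10^(-bs / 25), bitscore = bs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# --- brute-force LCS oracle --------------------------------------------------

# length of the longest common subsequence by exhaustive enumeration of all
# subsequences of the shorter sequence (tiny inputs only)
lcs_length_bruteforce <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  is_subseq <- function(s, x) {
    j <- 1L
    for (t in x) {
      if (j <= length(s) && s[j] == t) j <- j + 1L
    }
    j > length(s)
  }
  best <- 0L
  for (mask in 0:(2^length(a) - 1)) {
    s <- a[bitwAnd(mask, 2^(seq_along(a) - 1L)) > 0]
    if (length(s) > best && is_subseq(s, b)) best <- length(s)
  }
  best
}

# --- misc --------------------------------------------------------------------

# annotation rows for one protein from a compact spec list:
# list(c(family, start, end, evalue), ...)
ann_rows <- function(protein_id, ...) {
  specs <- list(...)
  do.call(rbind, lapply(specs, function(s) {
    data.frame(protein_id = protein_id, family_id = s[[1]],
               start = as.integer(s[[2]]), end = as.integer(s[[3]]),
               evalue = as.numeric(s[[4]]), stringsAsFactors = FALSE)
  }))
}

# simple architecture-only annotations: consecutive 100-aa domains, all at
# the given e-value
arch_ann <- function(protein_id, tokens, evalue = 1e-20) {
  n <- length(tokens)
  data.frame(protein_id = protein_id, family_id = tokens,
             start = 110L * (seq_len(n) - 1L) + 1L,
             end = 110L * (seq_len(n) - 1L) + 100L,
             evalue = evalue, stringsAsFactors = FALSE)
}

classify_tokens <- function(a, b) {
  classify_difference(align_architectures(a, b))
}
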