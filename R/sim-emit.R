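## Emitters: turn a simulated proteome into the standard interchange files
## (FASTA, domain-annotation TSV, BLAST-style tabular hits).

#' Write simulated protein sequences as FASTA
#'
#' One record per protein; the id line carries the protein id only.
#'
#' @param proteome A `sim_proteome`.
#' @param file Optional path; if `NULL` the FASTA text is returned invisibly
#'   as a character vector (one element per line).
#' @return The FASTA lines, invisibly.
#' @export
emit_sequences <- function(proteome, file = NULL) {
  stopifnot(inherits(proteome, "sim_proteome"))
  p <- proteome$proteins
  if (!nrow(p)) stop_config("proteome has no proteins")
  lines <- as.vector(rbind(paste0(">", p$protein_id), p$sequence))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

# default pseudo e-value model for domain annotations: one order of
# magnitude per 1/slope percent identity above the detection floor
default_annotation_evalue <- function(floor_pct = 35, slope = 0.4,
                                      e_floor = 1e-180, e_ceiling = 10) {
  function(identity_pct) {
    clamp(10^(-(identity_pct - floor_pct) * slope), e_floor, e_ceiling)
  }
}

#' Emit per-protein domain annotations
#'
#' Produces one row per *detected* domain instance with 1-based inclusive
#' coordinates on the assembled protein sequence, ordered by start, and a
#' pseudo e-value that decreases monotonically with the instance's percent
#' identity to its family template. Instances below the detection floor are
#' omitted, so heavily diverged domains drop out of strict-cutoff
#' architectures first — which is what gives the multi-cutoff architecture
#' comparison its resolution.
#'
#' @param proteome A `sim_proteome`.
#' @param evalue_model Function mapping percent identity to an e-value;
#'   must be monotone decreasing. Defaults to
#'   `10^-((identity - floor) * slope)` with the config's floor and slope.
#' @param file Optional TSV path.
#' @return Data frame with columns `protein_id`, `family_id`, `start`,
#'   `end`, `evalue`.
#' @export
emit_domain_annotations <- function(proteome, evalue_model = NULL, file = NULL) {
  stopifnot(inherits(proteome, "sim_proteome"))
  cfg <- proteome$config
  floor_pct <- cfg$detection_floor_identity %||% 35
  if (is.null(evalue_model)) {
    evalue_model <- default_annotation_evalue(floor_pct,
                                              cfg$annotation_evalue_slope %||% 0.4)
  }
  rows <- lapply(proteome$architectures, function(a) {
    keep <- a$identity_pct >= floor_pct
    a <- a[keep, , drop = FALSE]
    if (!nrow(a)) return(NULL)
    data.frame(protein_id = a$protein_id, family_id = a$family_id,
               start = a$start, end = a$end,
               evalue = evalue_model(a$identity_pct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), family_id = character(0),
                      start = integer(0), end = integer(0),
                      evalue = numeric(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# best colinear chain of same-family instance pairs; weights are
# identity * length * scale. Returns score plus the chained length and
# matched-residue count for the pident/length hit columns.
chain_score <- function(seqs_a, fams_a, seqs_b, fams_b, scale) {
  n <- length(seqs_a); m <- length(seqs_b)
  S <- matrix(0, n + 1L, m + 1L)
  Lc <- matrix(0L, n + 1L, m + 1L)  # chained residue length
  Mc <- matrix(0, n + 1L, m + 1L)   # matched residues
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- S[i, j + 1L]; bl <- Lc[i, j + 1L]; bm <- Mc[i, j + 1L]
      if (S[i + 1L, j] > best) {
        best <- S[i + 1L, j]; bl <- Lc[i + 1L, j]; bm <- Mc[i + 1L, j]
      }
      if (fams_a[i] == fams_b[j]) {
        len <- length(seqs_a[[i]])
        matched <- sum(seqs_a[[i]] == seqs_b[[j]])
        w <- matched * scale
        cand <- S[i, j] + w
        if (cand > best) {
          best <- cand; bl <- Lc[i, j] + len; bm <- Mc[i, j] + matched
        }
      }
      S[i + 1L, j + 1L] <- best; Lc[i + 1L, j + 1L] <- bl; Mc[i + 1L, j + 1L] <- bm
    }
  }
  list(score = S[n + 1L, m + 1L], length = Lc[n + 1L, m + 1L],
       matched = Mc[n + 1L, m + 1L])
}

#' All-against-all similarity scoring of simulated proteins
#'
#' Emulates an all-against-all sequence comparison at the level the
#' simulator is exact about: domain instances. The bit-score of a pair is
#' the best chained sum over colinear same-family instance pairs of
#' `identity x length x scale`, so tandem arrays of a shared mobile domain
#' add up — reproducing the score inflation that makes epaktologs with long
#' tandem arrays outscore true paralogs. Scores are symmetric; both hit
#' directions (and self hits) are emitted. Pairs sharing neither a domain
#' family nor an ancestral gene yield no row.
#'
#' @param proteome A `sim_proteome`.
#' @param scorer A [scorer_config()]; defaults to the one in the simulation
#'   config.
#' @return Data frame in BLAST `outfmt 6` column order (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`); unused columns are 0.
#' @export
score_all_pairs <- function(proteome, scorer = NULL) {
  stopifnot(inherits(proteome, "sim_proteome"))
  scorer <- scorer %||% proteome$config$scorer %||% scorer_config()
  p <- proteome$proteins
  if (nrow(p) < 2L) stop_config("need at least two proteins to score")
  ids <- p$protein_id
  arch <- proteome$architectures[ids]
  seqs <- lapply(arch, function(a) lapply(a$seq, chars))
  fams <- lapply(arch, function(a) a$family_id)
  famsets <- lapply(fams, unique)

  qs <- character(0); ss <- character(0)
  sc <- numeric(0); ln <- integer(0); mt <- numeric(0)
  add <- function(q, s, r) {
    qs <<- c(qs, q); ss <<- c(ss, s)
    sc <<- c(sc, r$score); ln <<- c(ln, r$length); mt <<- c(mt, r$matched)
  }
  n <- length(ids)
  for (i in seq_len(n)) {
    # self hit: perfect chain over own instances
    self_len <- sum(lengths(seqs[[i]]))
    add(ids[i], ids[i], list(score = self_len * scorer$scale,
                             length = self_len, matched = self_len))
    if (i == n) next
    for (j in seq((i + 1L), n)) {
      shares_family <- length(intersect(famsets[[i]], famsets[[j]])) > 0L
      shares_lineage <- p$root_gene[i] == p$root_gene[j]
      if (!shares_family && !shares_lineage) next
      r <- chain_score(seqs[[i]], fams[[i]], seqs[[j]], fams[[j]], scorer$scale)
      if (r$score <= 0) next
      add(ids[i], ids[j], r)
      add(ids[j], ids[i], r)
    }
  }
  evalue <- clamp(10^(-sc / scorer$s0), scorer$e_floor, scorer$e_ceiling)
  data.frame(
    qseqid = qs, sseqid = ss,
    pident = ifelse(ln > 0, round(100 * mt / ln, 2), 0),
    length = ln, mismatch = 0L, gapopen = 0L,
    qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
    evalue = evalue, bitscore = round(sc, 1),
    stringsAsFactors = FALSE
  )
}

#' Write a hit table in BLAST outfmt 6 layout
#'
#' Tab-separated, no header, as produced by `blastp -outfmt 6`.
#'
#' @param hits Data frame with the 12 outfmt-6 columns.
#' @param file Output path.
#' @export
write_hit_table <- function(hits, file) {
  utils::write.table(hits, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Simulate homolog pairs differing by one uniformly placed domain insertion
#'
#' Generates pairs (B, B') where B has `n` domains of distinct families and
#' B' carries one extra domain of a fresh family inserted at a uniformly
#' chosen position among the `n + 1` possible slots. Used to quantify the
#' positional capacity of N-domain to N+1-domain transitions: with uniform
#' placement, internal slots outnumber each terminal slot whenever n >= 2.
#'
#' @param n_pairs Number of pairs.
#' @param n_domains_range Inclusive range for the smaller architecture size.
#' @param seed Integer seed.
#' @return Data frame with columns `n_domains`, `slot` (0 = N-terminal
#'   insertion, `n_domains` + 1 = C-terminal)... plus the two architectures
#'   as comma-collapsed strings (`arch_a`, `arch_b`).
#' @export
simulate_insertion_pairs <- function(n_pairs, n_domains_range = c(3L, 6L),
                                     seed = 1L) {
  set.seed(as_count(seed, "seed"))
  n_pairs <- as_count(n_pairs, "n_pairs")
  lo <- n_domains_range[1]; hi <- n_domains_range[2]
  stopifnot(lo >= 1, hi >= lo)
  n_dom <- sample(lo:hi, n_pairs, replace = TRUE)
  slot <- vapply(n_dom, function(n) sample.int(n + 1L, 1L) - 1L, integer(1))
  arch_a <- character(n_pairs); arch_b <- character(n_pairs)
  for (k in seq_len(n_pairs)) {
    base <- sprintf("D%d", seq_len(n_dom[k]))
    ins <- "DX"
    arch_a[k] <- paste(base, collapse = ",")
    arch_b[k] <- paste(append(base, ins, after = slot[k]), collapse = ",")
  }
  data.frame(n_domains = n_dom, slot = slot, arch_a = arch_a, arch_b = arch_b,
             stringsAsFactors = FALSE)
}
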