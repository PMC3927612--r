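test_that("a rates-free configuration yields unrelated single-domain proteins", {
  p <- generate_proteome(sim_config(n_ancestral_families = 3, seed = 11))
  expect_equal(nrow(p$proteins), 3L)
  expect_true(all(p$proteins$n_domains == 1L))
  expect_true(all(p$labels$relation == "UNRELATED"))
  expect_equal(nrow(p$labels), 3L)
})

test_that("degenerate configurations are rejected before simulation", {
  expect_error(sim_config(n_ancestral_families = 0), "ancestral family")
  expect_error(sim_config(n_species = 0), "n_species")
  expect_error(sim_config(rates = list(domain_loss = -1)), "rates")
  expect_error(sim_config(rates = list(shuffling_insertion = 1e-3),
                          n_mobile_families = 0), "mobile")
  expect_error(generate_proteome(list()), "sim_config")
})

test_that("the shuffle_internal preset reproduces the canonical epaktolog scenario", {
  p <- generate_proteome(preset_config("shuffle_internal", seed = 2))
  expect_equal(p$architectures[["A1_sp1"]]$family_id, c("a", "s", "s", "s", "s", "b"))
  expect_equal(p$architectures[["A2_sp1"]]$family_id, c("a", "b"))
  expect_equal(p$architectures[["X2_sp1"]]$family_id, c("x", "s", "s", "s", "s", "z"))
  expect_equal(p$architectures[["X1_sp1"]]$family_id, c("x", "z"))
  expect_equal(pair_relation(p, "A1_sp1", "A2_sp1"), "PARALOG")
  expect_equal(pair_relation(p, "X1_sp1", "X2_sp1"), "PARALOG")
  expect_equal(pair_relation(p, "A1_sp1", "X2_sp1"), "EPAKTOLOG")
  expect_equal(pair_relation(p, "X2_sp1", "A1_sp1"), "EPAKTOLOG")  # symmetric
  expect_equal(pair_relation(p, "A1_sp1", "X1_sp1"), "UNRELATED")
  expect_equal(pair_relation(p, "A2_sp1", "X2_sp1"), "UNRELATED")
})

test_that("shuffle_terminal places the shuffled array terminally", {
  p <- generate_proteome(preset_config("shuffle_terminal", seed = 2))
  expect_equal(p$architectures[["A1_sp1"]]$family_id, c("s", "s", "s", "s", "a", "b"))
  expect_equal(p$architectures[["X2_sp1"]]$family_id, c("x", "z", "s", "s", "s", "s"))
  expect_equal(pair_relation(p, "A1_sp1", "X2_sp1"), "EPAKTOLOG")
})

test_that("every pair carries exactly one relation and labels are exhaustive", {
  p <- generate_proteome(preset_config("shuffle_internal", seed = 5))
  n <- nrow(p$proteins)
  expect_equal(nrow(p$labels), choose(n, 2))
  expect_true(all(p$labels$relation %in%
                    c("ORTHOLOG", "PARALOG", "EPAKTOLOG", "UNRELATED")))
})

test_that("the same seed gives identical output and the event log replays exactly", {
  for (cfg in list(preset_config("shuffle_internal", seed = 7),
                   sim_config(n_ancestral_families = 5, n_mobile_families = 2,
                              ancestral_arch_size = 2,
                              rates = list(gene_duplication = 1e-3,
                                           domain_gain_terminal = 3e-4,
                                           domain_gain_internal = 3e-4,
                                           domain_loss = 3e-4,
                                           tandem_duplication = 3e-4,
                                           shuffling_insertion = 5e-4),
                              seed = 7))) {
    p1 <- generate_proteome(cfg)
    p2 <- generate_proteome(cfg)
    expect_identical(p1$proteins, p2$proteins)
    expect_identical(p1$labels, p2$labels)
    rp <- replay_event_log(p1)
    expect_identical(rp$proteins, p1$proteins)
    expect_identical(rp$architectures, p1$architectures)
    expect_true(all(vapply(p1$event_log, function(e)
      e$kind %in% c(paranet:::SIM_EVENT_KINDS, "substitutions", "speciation"),
      logical(1))))
  }
})

test_that("FASTA emission is additive in domain and linker lengths and round-trips", {
  cfg <- sim_config(families = data.frame(family_id = c("u", "v"),
                                          length_aa = c(50L, 50L),
                                          mobile = FALSE),
                    ancestral_genes = list(list(gene_id = "G", arch = c("u", "v"))),
                    linker_length_aa = 10, substitution_rate = 0, seed = 1)
  p <- generate_proteome(cfg)
  expect_equal(nchar(p$proteins$sequence), 110L)
  cfg0 <- cfg; cfg0$linker_length_aa <- 0L
  expect_equal(nchar(generate_proteome(cfg0)$proteins$sequence), 100L)

  skip_if_not_installed("Biostrings")
  big <- generate_proteome(preset_config("shuffle_internal", seed = 3))
  fa <- tempfile(fileext = ".fasta")
  emit_sequences(big, fa)
  parsed <- Biostrings::readAAStringSet(fa)
  expect_setequal(names(parsed), big$proteins$protein_id)
  expect_equal(unname(Biostrings::width(parsed)[match(big$proteins$protein_id,
                                                      names(parsed))]),
               big$proteins$length_aa)
})

test_that("annotations are ordered, non-overlapping and cutoff-graded", {
  p <- generate_proteome(preset_config("shuffle_internal", seed = 4))
  ann <- emit_domain_annotations(p)
  expect_true(all(ann$start <= ann$end))
  for (pid in unique(ann$protein_id)) {
    rows <- ann[ann$protein_id == pid, ]
    expect_true(all(diff(rows$start) > 0))
    if (nrow(rows) > 1) expect_true(all(utils::head(rows$end, -1) < rows$start[-1]))
  }
  # undiverged instances get an e-value at or below the model floor region
  cfg <- sim_config(n_ancestral_families = 2, substitution_rate = 0, seed = 1)
  ann0 <- emit_domain_annotations(generate_proteome(cfg))
  expect_true(all(ann0$evalue <= 1e-10))
  # instances below the detection floor are dropped
  pid <- p$proteins$protein_id[1]
  a <- p$architectures[[pid]]
  p2 <- p
  p2$architectures[[pid]]$identity_pct[1] <- 20
  ann2 <- emit_domain_annotations(p2)
  expect_equal(sum(ann2$protein_id == pid),
               sum(ann$protein_id == pid) - 1L)
})

test_that("the e-value model is monotone decreasing in identity", {
  m <- paranet:::default_annotation_evalue()
  ids <- seq(35, 100, by = 5)
  expect_true(all(diff(m(ids)) < 0))
})

test_that("pair scores grow with the number of shared tandem mobile domains", {
  scores <- vapply(1:4, function(t) {
    p <- generate_proteome(preset_config("shuffle_internal", seed = 9, n_tandem = t - 1L))
    h <- score_all_pairs(p)
    h$bitscore[h$qseqid == "A1_sp1" & h$sseqid == "X2_sp1"][1]
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("scoring is symmetric, maximal for self, and absent without shared families", {
  p <- generate_proteome(preset_config("shuffle_internal", seed = 2))
  h <- score_all_pairs(p)
  # symmetry
  key <- paste(pmin(h$qseqid, h$sseqid), pmax(h$qseqid, h$sseqid))
  for (k in unique(key)) {
    expect_equal(length(unique(h$bitscore[key == k])), 1L)
  }
  # self hit is the top row of each query
  for (q in unique(h$qseqid)) {
    rows <- h[h$qseqid == q, ]
    expect_equal(max(rows$bitscore), rows$bitscore[rows$sseqid == q])
  }
  # disjoint family sets, unrelated lineages: no row
  expect_false(any(h$qseqid == "A2_sp1" & h$sseqid == "X1_sp1"))
  expect_false(any(h$qseqid == "A1_sp1" & h$sseqid == "X1_sp1"))
})

test_that("the epaktolog pair outscores the true paralog pair in most seeds", {
  n <- 15
  confused <- vapply(seq_len(n), function(i) {
    p <- generate_proteome(preset_config("shuffle_internal", seed = 100 + i))
    h <- score_all_pairs(p)
    sc <- function(q, s) h$bitscore[h$qseqid == q & h$sseqid == s][1]
    sc("A1_sp1", "X2_sp1") > sc("A1_sp1", "A2_sp1")
  }, logical(1))
  expect_gte(mean(confused), 0.9)
})
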