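test_that("architectures keep non-overlapping hits ordered by start", {
  da <- build_architecture(ann_rows("p", list("a", 1, 50, 1e-10),
                                    list("b", 60, 120, 1e-8)))
  expect_equal(da$domains, c("a", "b"))
  # heavy overlap: the better hit wins
  da2 <- build_architecture(ann_rows("p", list("a", 1, 50, 1e-10),
                                     list("a2", 10, 55, 1e-6)))
  expect_equal(da2$domains, "a")
  # mild overlap (<= 30% of the shorter hit) is tolerated
  da3 <- build_architecture(ann_rows("p", list("a", 1, 50, 1e-10),
                                     list("b", 41, 100, 1e-6)))
  expect_equal(da3$domains, c("a", "b"))
  expect_error(build_architecture(ann_rows("p", list("a", 50, 10, 1e-10))),
               "start > end")
})

test_that("cutoff semantics are strict and architectures grow as cutoffs loosen", {
  ann <- ann_rows("p", list("a", 1, 50, 1e-10), list("w", 60, 120, 1e-4))
  expect_equal(build_architecture(ann, 1e-5)$domains, "a")
  expect_equal(build_architecture(ann, 1e-2)$domains, c("a", "w"))
  # monotone cutoff property on simulated annotations
  p <- generate_proteome(sim_config(
    n_ancestral_families = 5, ancestral_arch_size = 2,
    rates = list(gene_duplication = 1e-3), root_age_my = 1500, seed = 21))
  annall <- emit_domain_annotations(p)
  for (pid in unique(annall$protein_id)) {
    rows <- annall[annall$protein_id == pid, ]
    prev <- character(0)
    for (ct in rev(DEFAULT_DA_CUTOFFS)) {   # strict to permissive
      cur <- build_architecture(rows, ct)$domains
      expect_true(all(prev %in% cur))
      expect_gte(length(cur), length(prev))
      prev <- cur
    }
  }
})

test_that("architecture alignment is an LCS with deterministic tie-breaking", {
  al <- align_architectures(c("a", "b"), c("a", "b"))
  expect_equal(nrow(al$pairs), 2L)
  expect_length(al$unmatched_a, 0L)
  al2 <- align_architectures(c("a", "s", "b"), c("a", "b"))
  expect_equal(al2$unmatched_a, 2L)
  expect_length(al2$unmatched_b, 0L)
  # the worked tandem case: LCS length 2 by exhaustive enumeration
  a <- c("x", "s", "s", "z"); b <- c("a", "s", "s", "b")
  al3 <- align_architectures(a, b)
  expect_equal(nrow(al3$pairs), lcs_length_bruteforce(a, b))
  expect_equal(a[al3$pairs[, 1]], c("s", "s"))
  # oracle check on random token vectors
  set.seed(31)
  for (rep in 1:40) {
    ta <- sample(letters[1:4], sample(0:7, 1), replace = TRUE)
    tb <- sample(letters[1:4], sample(0:7, 1), replace = TRUE)
    al <- align_architectures(ta, tb)
    expect_equal(nrow(al$pairs), lcs_length_bruteforce(ta, tb))
    if (nrow(al$pairs) > 1) {
      expect_true(all(diff(al$pairs[, 1]) > 0))
      expect_true(all(diff(al$pairs[, 2]) > 0))
    }
  }
})

test_that("difference classification covers all six categories", {
  expect_equal(classify_tokens(c("a", "b"), c("a", "b")), "IDENTICAL")
  expect_equal(classify_tokens(c("s", "a", "b"), c("a", "b")), "N_TERMINAL")
  expect_equal(classify_tokens(c("a", "b", "s"), c("a", "b")), "C_TERMINAL")
  expect_equal(classify_tokens(c("a", "s", "b"), c("a", "b")), "INTERNAL")
  expect_equal(classify_tokens(c("a", "s", "s", "b"), c("a", "s", "b")),
               "DUPLICATION")
  expect_equal(classify_tokens(c("x", "s", "s", "z"), c("a", "s", "s", "b")),
               c("C_TERMINAL", "N_TERMINAL"))
  expect_equal(classify_tokens(c("a", "b"), c("x", "z")), "UNASSIGNED")
  # category sets can mix, and terminal tandem copies count as duplications
  expect_setequal(classify_tokens(c("s", "a", "q", "b"), c("a", "b")),
                  c("N_TERMINAL", "INTERNAL"))
  expect_equal(classify_tokens(c("s", "s", "a"), c("s", "a")), "DUPLICATION")
})

test_that("classification is symmetric in the two proteins", {
  set.seed(93)
  for (rep in 1:50) {
    ta <- sample(letters[1:5], sample(1:6, 1), replace = TRUE)
    tb <- sample(letters[1:5], sample(1:6, 1), replace = TRUE)
    expect_setequal(classify_tokens(ta, tb), classify_tokens(tb, ta))
  }
})

test_that("transition types follow the smaller architecture", {
  expect_equal(transition_type(1, 2), "TYPE1")
  expect_equal(transition_type(2, 3), "TYPE2")
  expect_equal(transition_type(5, 6), "TYPE3")
  expect_equal(transition_type(6, 5), "TYPE3")
  expect_true(is.na(transition_type(3, 3)))
  expect_true(is.na(transition_type(2, 4)))
  expect_true(is.na(transition_type(0, 1)))
})

test_that("the four-cutoff protocol re-classifies weakly supported domains", {
  ann_a <- ann_rows("pa", list("a", 1, 100, 1e-20), list("w", 110, 170, 5e-4))
  ann_b <- ann_rows("pb", list("a", 1, 100, 1e-20))
  rec <- classify_pair_multicutoff(ann_a, ann_b)
  expect_length(rec$categories, 4L)
  expect_equal(rec$categories[["1e-05"]], "IDENTICAL")
  expect_equal(rec$categories[["1e-04"]], "IDENTICAL")
  expect_equal(rec$categories[["1e-03"]], "C_TERMINAL")
  expect_equal(rec$categories[["1e-02"]], "C_TERMINAL")
  # the strict cutoff drives count difference and transition type
  expect_equal(rec$n_domain_diff, 0L)
  expect_true(is.na(rec$transition_type))
  rec2 <- classify_pair_multicutoff(arch_ann("pa", "a"),
                                    arch_ann("pb", c("a", "b")))
  expect_equal(rec2$n_domain_diff, 1L)
  expect_equal(rec2$transition_type, "TYPE1")
  # identical at every cutoff
  rec3 <- classify_pair_multicutoff(arch_ann("pa", c("a", "b")),
                                    arch_ann("pb", c("a", "b")))
  expect_true(all(vapply(rec3$categories, identical, logical(1), "IDENTICAL")))
})

test_that("homogeneity statistics count clusters and comparisons correctly", {
  ann <- rbind(arch_ann("p1", c("a", "b")), arch_ann("p2", c("a", "b")),
               arch_ann("p3", c("a", "b")), arch_ann("p4", c("a", "b")),
               arch_ann("p5", "a"))
  h1 <- aggregate_homogeneity(list(c("p1", "p2")), ann)
  expect_equal(h1$pct_clusters_identical, 100)
  expect_equal(h1$pct_comparisons_different, 0)
  # {AB, AB, A}: 2 of 3 pairs differ, cluster not homogeneous
  h2 <- aggregate_homogeneity(list(c("p1", "p2", "p5")), ann)
  expect_equal(h2$pct_clusters_identical, 0)
  expect_equal(h2$pct_comparisons_different, 200 / 3, tolerance = 1e-10)
  # both clusters: 1 of 2 homogeneous; 2 of the 4 pooled pairs differ
  h3 <- aggregate_homogeneity(list(c("p3", "p4"), c("p1", "p2", "p5")), ann)
  expect_equal(h3$pct_clusters_identical, 50)
  expect_equal(h3$n_pairs, 4L)
  expect_equal(h3$pct_comparisons_different, 50)
  expect_warning(aggregate_homogeneity(list(c("p1", "p2"), "p3"), ann),
                 "fewer than 2")
})

test_that("positional distributions pool per-cutoff assignments", {
  rec_nc <- classify_pair_multicutoff(arch_ann("pa", c("x", "s", "s", "z")),
                                      arch_ann("pb", c("a", "s", "s", "b")))
  pd <- positional_distribution(list(rec_nc))
  expect_equal(pd$proportion_pct[pd$category == "N_TERMINAL"], 50)
  expect_equal(pd$proportion_pct[pd$category == "C_TERMINAL"], 50)
  rec_n <- classify_pair_multicutoff(arch_ann("pa", c("s", "a", "b")),
                                     arch_ann("pb", c("a", "b")))
  pd2 <- positional_distribution(list(rec_n))
  expect_equal(pd2$proportion_pct[pd2$category == "N_TERMINAL"], 100)
  # all-identical records give an empty, flagged distribution
  rec_id <- classify_pair_multicutoff(arch_ann("pa", c("a", "b")),
                                      arch_ann("pb", c("a", "b")))
  pd3 <- positional_distribution(list(rec_id))
  expect_equal(nrow(pd3), 0L)
  expect_true(attr(pd3, "all_identical"))
  # stratification keys on transition type
  pd4 <- positional_distribution(list(rec_n), stratify_by_transition = TRUE)
  expect_equal(unique(pd4$transition), "TYPE2")  # 3 vs 2 domains
  rec_t1 <- classify_pair_multicutoff(arch_ann("pa", c("s", "a")),
                                      arch_ann("pb", "a"))
  pd5 <- positional_distribution(list(rec_t1), stratify_by_transition = TRUE)
  expect_equal(unique(pd5$transition), "TYPE1")
})

test_that("domain-count differences are binned as 1 / 2 / 3 / >=4", {
  mk <- function(n) classify_pair_multicutoff(
    arch_ann("pa", letters[1:5]), arch_ann("pb", letters[1:(5 + n)]))
  recs <- list(mk(1), mk(1), mk(2), mk(4))
  d <- domain_count_diff_distribution(recs)
  expect_equal(d$proportion_pct, c(50, 25, 0, 25))
  d7 <- domain_count_diff_distribution(list(mk(7)))
  expect_equal(d7$proportion_pct[d7$bin == ">=4"], 100)
  d0 <- domain_count_diff_distribution(list(mk(0)))
  expect_equal(nrow(d0), 0L)
  expect_true(attr(d0, "all_identical"))
})

test_that("rate estimates reproduce the reference arithmetic", {
  expect_equal(rate_per_my(28, 910)$rate_lb, 0.031)
  expect_equal(rate_per_my(23, 800)$rate_lb, 0.029)
  expect_equal(rate_per_my(0, 910)$rate_lb, 0)
  expect_error(rate_per_my(28, 0), "t_upper_my")
  expect_error(rate_per_my(120, 910), "pct")
})

test_that("domtblout columns map onto the annotation fields", {
  f <- tempfile()
  writeLines(c(
    "# comment",
    "prot1 - 500 KR - 62 1e-40 100 0.1 1 2 1e-13 1e-12 50 0.1 1 62 10 70 10 70 0.9",
    "prot1 - 500 FN2 - 48 1e-30 80 0.1 2 2 1e-05 1e-04 30 0.1 1 48 110 160 110 160 0.8"),
    f)
  ann <- read_domtblout(f)
  expect_equal(ann$protein_id, c("prot1", "prot1"))
  expect_equal(ann$family_id, c("KR", "FN2"))
  expect_equal(ann$start, c(10L, 110L))
  expect_equal(ann$evalue, c(1e-12, 1e-4))
  da <- build_architecture(ann, 1e-5)
  expect_equal(da$domains, "KR")
})
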