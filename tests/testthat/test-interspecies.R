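test_that("best hits pick the top-scoring qualifying subject", {
  hits <- read_hit_table(data.frame(
    query_id = c("q1", "q1", "q2"), subject_id = c("t1", "t2", "t3"),
    evalue = c(1e-30, 1e-20, 1e-4), bitscore = c(300, 200, 50)))
  m <- best_hits(hits)
  expect_equal(m$subject_id[m$query_id == "q1"], "t1")
  # q2's only hit misses the cutoff
  expect_false("q2" %in% m$query_id)
  # bitscore tie: lexicographically smaller subject
  tie <- read_hit_table(data.frame(
    query_id = "q1", subject_id = c("tB", "tA"),
    evalue = 1e-20, bitscore = 200))
  expect_equal(best_hits(tie)$subject_id, "tA")
})

test_that("clustering groups queries by shared best hit and reports 1:1 matches", {
  m <- best_hits(read_hit_table(data.frame(
    query_id = c("q1", "q2", "q3"), subject_id = c("t1", "t1", "t2"),
    evalue = 1e-30, bitscore = c(300, 280, 260))))
  cl <- cluster_by_best_hit(m)
  expect_equal(sort(cl$clusters$member), c("q1", "q2"))
  expect_equal(unique(cl$clusters$anchor_subject_id), "t1")
  expect_equal(cl$one_to_one$query_id, "q3")
  # all-distinct best hits: no clusters
  m2 <- best_hits(read_hit_table(data.frame(
    query_id = c("q1", "q2"), subject_id = c("t1", "t2"),
    evalue = 1e-30, bitscore = 300)))
  expect_equal(nrow(cluster_by_best_hit(m2)$clusters), 0L)
})

test_that("best-hit clusters equal weak components of the bipartite graph", {
  set.seed(88)
  for (rep in 1:20) {
    n_q <- sample(3:12, 1); n_t <- sample(2:6, 1)
    map <- data.frame(query_id = sprintf("q%02d", seq_len(n_q)),
                      subject_id = sprintf("t%02d", sample(n_t, n_q, replace = TRUE)),
                      bitscore = 300, evalue = 1e-30, stringsAsFactors = FALSE)
    class(map) <- c("best_hit_map", "data.frame")
    attr(map, "species") <- "x"
    cl <- cluster_by_best_hit(map)
    # oracle: weak components of the query--subject graph, restricted to
    # queries, ignoring singleton queries
    edges <- data.frame(from = map$query_id, to = map$subject_id)
    comps <- oracle_components(c(map$query_id, unique(map$subject_id)), edges, "WEAK")
    comps <- lapply(comps, function(cc) sort(intersect(cc, map$query_id)))
    comps <- comps[lengths(comps) >= 2L]
    got <- lapply(split(cl$clusters$member, cl$clusters$anchor_subject_id), sort)
    expect_identical(canon(unname(got)), canon(comps))
  }
})

test_that("a pre-duplication outgroup proteome clusters the paralog pair", {
  p <- generate_proteome(preset_config("shuffle_internal", seed = 6, outgroup_split_my = 750))
  h <- score_all_pairs(p)
  q <- p$proteins$protein_id[p$proteins$species_id == "sp1"]
  t <- p$proteins$protein_id[p$proteins$species_id == "sp2"]
  hh <- read_hit_table(h)
  cl <- cluster_by_best_hit(best_hits(as_hits(
    hh[hh$query_id %in% q & hh$subject_id %in% t, ])))
  a_cluster <- cl$clusters$member[cl$clusters$anchor_subject_id == "A_sp2"]
  expect_setequal(a_cluster, c("A1_sp1", "A2_sp1"))
  expect_equal(pair_relation(p, a_cluster[1], a_cluster[2]), "PARALOG")
})

test_that("older splits cluster at least as many queries as younger ones", {
  p <- generate_proteome(preset_config("ladder3", seed = 3))
  h <- read_hit_table(score_all_pairs(p))
  q <- p$proteins$protein_id[p$proteins$species_id == "sp1"]
  tabs <- lapply(c(sp2 = "sp2", sp3 = "sp3"), function(sp) {
    t <- p$proteins$protein_id[p$proteins$species_id == sp]
    as_hits(h[h$query_id %in% q & h$subject_id %in% t, ])
  })
  prof <- cluster_profile_across_species(tabs, c("sp3", "sp2"))
  expect_equal(prof$species, c("sp3", "sp2"))
  expect_gte(prof$n_clustered_queries[1], prof$n_clustered_queries[2])
  # the P duplication (450 My) is visible: clustered by sp3, 1:1 by sp2
  expect_true("P1_sp1" %in%
    cluster_by_best_hit(best_hits(tabs$sp3))$clusters$member)
  expect_true("P1_sp1" %in%
    cluster_by_best_hit(best_hits(tabs$sp2))$one_to_one$query_id)
  # empty and single-species inputs
  empty <- suppressWarnings(cluster_profile_across_species(
    list(spX = empty_hits_df()), "spX"))
  expect_equal(empty$n_clusters_ge2, 0L)
  expect_error(cluster_profile_across_species(tabs, c("sp2", "spZ")), "missing")
})

test_that("deleting the true ortholog reassigns queries to paralog anchors", {
  p <- generate_proteome(preset_config("ladder3", seed = 9))
  h <- read_hit_table(score_all_pairs(p))
  q <- p$proteins$protein_id[p$proteins$species_id == "sp1"]
  t <- p$proteins$protein_id[p$proteins$species_id == "sp2"]
  full <- as_hits(h[h$query_id %in% q & h$subject_id %in% t, ])
  cl_full <- cluster_by_best_hit(best_hits(full))
  # drop P1's ortholog from the target proteome
  incomplete <- as_hits(full[full$subject_id != "P1_sp2", ])
  cl_inc <- cluster_by_best_hit(best_hits(incomplete))
  m <- best_hits(incomplete)
  expect_false("P1_sp2" %in% m$subject_id)
  # P1 is remapped to its paralog's ortholog, not dropped
  expect_equal(m$subject_id[m$query_id == "P1_sp1"], "P2_sp2")
  expect_gte(nrow(cl_inc$clusters), nrow(cl_full$clusters))
})

test_that("duplication timing brackets, opens, or flags the clustering pattern", {
  br <- duplication_timing(data.frame(
    species = c("A", "B", "C"), time_my = c(910, 800, 430),
    clustered = c(TRUE, TRUE, FALSE)))
  expect_equal(br$status, "BRACKETED")
  expect_equal(br$upper_my, 800)
  expect_equal(br$lower_my, 430)
  # clustered everywhere: duplication younger than the youngest split
  op <- duplication_timing(data.frame(
    species = c("A", "B"), time_my = c(910, 430), clustered = TRUE))
  expect_equal(op$status, "OPEN")
  expect_equal(op$upper_my, 430)
  expect_equal(op$lower_my, 0)
  # 1:1 everywhere: older than the oldest sampled split
  op2 <- duplication_timing(data.frame(
    species = c("A", "B"), time_my = c(910, 430), clustered = FALSE))
  expect_equal(op2$status, "OPEN")
  expect_equal(op2$lower_my, 910)
  expect_true(is.infinite(op2$upper_my))
  # non-monotone pattern is flagged, not an error
  un <- duplication_timing(data.frame(
    species = c("A", "B", "C"), time_my = c(910, 800, 430),
    clustered = c(TRUE, FALSE, TRUE)))
  expect_equal(un$status, "UNRESOLVED")
})
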