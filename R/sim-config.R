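#' Scoring model for the built-in all-against-all comparer
#'
#' Controls how chained domain-level identity is converted into a bit-score
#' and a pseudo e-value. The bit-score of a protein pair is the best chained
#' sum, over colinear pairs of homologous domain instances, of
#' `identity * length * scale`; the pseudo e-value is `10^(-score / s0)`,
#' clamped to `[e_floor, e_ceiling]`. Only the ordering of scores and the
#' position of the homology cutoff (e-value < 1e-5) matter downstream, so the
#' mapping is deliberately simple.
#'
#' @param scale Score units per aligned identical residue (default 2,
#'   roughly bits per residue as in BLOSUM-scored alignments).
#' @param s0 E-value decay constant: the score that lowers the pseudo
#'   e-value by one order of magnitude is `s0`.
#' @param e_floor,e_ceiling Clamp bounds for the pseudo e-value.
#' @return A list of class `scorer_config`.
#' @export
scorer_config <- function(scale = 2, s0 = 30, e_floor = 1e-180, e_ceiling = 10) {
  stopifnot(scale > 0, s0 > 0, e_floor > 0, e_ceiling >= e_floor)
  structure(list(scale = scale, s0 = s0, e_floor = e_floor,
                 e_ceiling = e_ceiling), class = "scorer_config")
}

SIM_EVENT_KINDS <- c("gene_duplication", "domain_gain_terminal",
                     "domain_gain_internal", "domain_loss",
                     "tandem_duplication", "shuffling_insertion")

#' Configuration for the multidomain protein evolution simulator
#'
#' Defines the study conditions for a forward simulation: an ultrametric
#' ladder species tree, a pool of domain families (a subset of which are
#' mobile, i.e. available for shuffling), ancestral multidomain genes, and
#' per-lineage event rates (per gene per million years).
#'
#' Domain shuffling (`shuffling_insertion`) is the only event that marks a
#' family as *acquired by shuffling* in a lineage; two extant proteins from
#' duplication-unconnected lineages are labelled epaktologs if and only if
#' they share at least one mobile family that each of them acquired through
#' such an insertion. Plain `domain_gain_*` events model ordinary gain and do
#' not create epaktology labels.
#'
#' @param n_ancestral_families Number of non-mobile ancestral domain
#'   families. By default each founds one single-domain ancestral gene.
#' @param n_mobile_families Number of mobile families available to
#'   `shuffling_insertion` events.
#' @param n_species Number of extant species (>= 1). Species `sp1` is the
#'   focal species at the end of the backbone lineage.
#' @param species_splits_my Divergence times (My before present) at which
#'   species `sp2`, `sp3`, ... leave the backbone; length `n_species - 1`.
#' @param root_age_my Age of the root (My). Defaults to 100 My older than
#'   the oldest split, or 800 My for a single-species simulation.
#' @param rates Named list of per-gene per-My event rates; see
#'   `SIM_EVENT_KINDS` for the six kinds. Missing entries default to 0.
#' @param substitution_rate Substitutions per site per My.
#' @param linker_length_aa Length of the glycine linker concatenated between
#'   consecutive domain instances.
#' @param ancestral_arch_size Number of domains per default ancestral gene.
#' @param family_length_range,mobile_length_range Integer ranges (aa) from
#'   which non-mobile / mobile family lengths are drawn.
#' @param detection_floor_identity Percent identity to the family template
#'   below which a domain instance is no longer recognisable by the
#'   annotation emitter.
#' @param annotation_evalue_slope Orders of magnitude of pseudo e-value per
#'   percent identity above the detection floor.
#' @param scorer A [scorer_config()].
#' @param families Optional explicit family table
#'   (`family_id`, `length_aa`, `mobile`); templates are always drawn from
#'   the seed.
#' @param ancestral_genes Optional explicit list of ancestral genes, each
#'   `list(gene_id =, arch = <character vector of family ids>)`.
#' @param scripted_events Optional data frame of deterministic events on the
#'   backbone lineage (`time_my`, `kind`, `gene_id`, `family_id`,
#'   `position`, `new_gene_id`), applied at fixed times instead of being
#'   drawn from the rates. Used by the bundled presets.
#' @param seed Integer seed; fully determines the simulation output.
#' @return A list of class `evolution_config`.
#' @seealso [preset_config()] for ready-made scenarios,
#'   [generate_proteome()] to run the simulation.
#' @export
sim_config <- function(n_ancestral_families = 4,
                       n_mobile_families = 1,
                       n_species = 1,
                       species_splits_my = numeric(0),
                       root_age_my = NULL,
                       rates = list(),
                       substitution_rate = 5e-4,
                       linker_length_aa = 10,
                       ancestral_arch_size = 1,
                       family_length_range = c(100L, 180L),
                       mobile_length_range = c(40L, 90L),
                       detection_floor_identity = 35,
                       annotation_evalue_slope = 0.4,
                       scorer = scorer_config(),
                       families = NULL,
                       ancestral_genes = NULL,
                       scripted_events = NULL,
                       seed = 1L) {
  full_rates <- stats::setNames(rep(0, length(SIM_EVENT_KINDS)), SIM_EVENT_KINDS)
  if (length(rates)) {
    bad <- setdiff(names(rates), SIM_EVENT_KINDS)
    if (length(bad)) stop_config("unknown rate(s): %s", paste(bad, collapse = ", "))
    full_rates[names(rates)] <- unlist(rates)
  }
  if (any(full_rates < 0)) stop_config("all event rates must be >= 0")

  n_species <- as_count(n_species, "n_species")
  if (n_species < 1L) stop_config("n_species must be >= 1")
  if (length(species_splits_my) != n_species - 1L) {
    stop_config("species_splits_my must have length n_species - 1 (= %d)",
                n_species - 1L)
  }
  if (any(species_splits_my <= 0)) stop_config("species splits must be positive times (My)")

  if (is.null(families)) {
    n_ancestral_families <- as_count(n_ancestral_families, "n_ancestral_families")
    n_mobile_families <- as_count(n_mobile_families, "n_mobile_families")
    if (n_ancestral_families < 1L) stop_config("need at least one ancestral family")
  } else {
    stopifnot(is.data.frame(families),
              all(c("family_id", "length_aa", "mobile") %in% names(families)))
    if (anyDuplicated(families$family_id)) stop_config("family_id must be unique")
    if (any(families$length_aa < 10)) stop_config("family lengths must be >= 10 aa")
    if (!any(!families$mobile)) stop_config("need at least one non-mobile family")
  }
  if (full_rates[["shuffling_insertion"]] > 0 &&
      is.null(families) && n_mobile_families < 1L) {
    stop_config("shuffling_insertion rate > 0 requires at least one mobile family")
  }
  if (!is.null(ancestral_genes)) {
    stopifnot(is.list(ancestral_genes), length(ancestral_genes) >= 1L)
  }
  if (!is.null(scripted_events)) {
    stopifnot(is.data.frame(scripted_events))
    need <- c("time_my", "kind")
    if (!all(need %in% names(scripted_events))) {
      stop_config("scripted_events needs columns: %s", paste(need, collapse = ", "))
    }
    if (!all(scripted_events$kind %in% SIM_EVENT_KINDS)) {
      stop_config("scripted_events$kind must be one of: %s",
                  paste(SIM_EVENT_KINDS, collapse = ", "))
    }
  }
  if (is.null(root_age_my)) {
    root_age_my <- if (length(species_splits_my)) max(species_splits_my) + 100 else 800
  }
  if (length(species_splits_my) && root_age_my <= max(species_splits_my)) {
    stop_config("root_age_my must predate the oldest species split")
  }
  if (!is.null(scripted_events) && nrow(scripted_events) &&
      any(scripted_events$time_my >= root_age_my)) {
    stop_config("scripted events must postdate the root")
  }
  stopifnot(substitution_rate >= 0, linker_length_aa >= 0)

  structure(list(
    n_ancestral_families = if (is.null(families)) n_ancestral_families else NA_integer_,
    n_mobile_families = if (is.null(families)) n_mobile_families else NA_integer_,
    n_species = n_species,
    species_splits_my = species_splits_my,
    root_age_my = root_age_my,
    rates = as.list(full_rates),
    substitution_rate = substitution_rate,
    linker_length_aa = as.integer(linker_length_aa),
    ancestral_arch_size = as_count(ancestral_arch_size, "ancestral_arch_size"),
    family_length_range = as.integer(family_length_range),
    mobile_length_range = as.integer(mobile_length_range),
    detection_floor_identity = detection_floor_identity,
    annotation_evalue_slope = annotation_evalue_slope,
    scorer = scorer,
    families = families,
    ancestral_genes = ancestral_genes,
    scripted_events = scripted_events,
    seed = as_count(seed, "seed")
  ), class = "evolution_config")
}

#' Ready-made simulation scenarios
#'
#' * `"shuffle_internal"` / `"shuffle_terminal"`: the canonical epaktolog-confusion scenario. Two
#'   unrelated two-domain ancestors, `A` (architecture a-b) and `X` (x-z),
#'   evolve in one genome. An old duplication of `A` yields distant paralogs
#'   `A1`/`A2`; the `X` gene duplicates twice, recently, yielding close
#'   paralogs `X1`/`X2`/`X3`. A mobile domain `s` is independently inserted
#'   into `A1` (anciently) and `X2` (recently) and then tandem-duplicated
#'   `n_tandem` times in each, so that `A1` and `X2` are epaktologs whose
#'   shared s-array outscores the true paralog pair `A1`/`A2`, while `X2`
#'   still scores highest against its own recent paralogs. In `"shuffle_internal"` the
#'   insertions are internal (a-s..s-b / x-s..s-z); in `"shuffle_terminal"` they are
#'   terminal (s..s-a-b / x-z-s..s). With `outgroup_split_my` set, a second
#'   species diverges before all duplications and supplies single-copy
#'   orthologs of `A` and `X` for interspecies best-hit clustering.
#' * `"ladder3"`: three species (`sp3` split 600 My ago, `sp2` 300 My ago)
#'   and three two-domain genes; gene `P` duplicates 450 My ago (between the
#'   two splits), gene `Q` 150 My ago (after both), gene `R` never. Used to
#'   study how clustering patterns across species of increasing divergence
#'   date gene duplications.
#'
#' @param name One of `"shuffle_internal"`, `"shuffle_terminal"`, `"ladder3"`.
#' @param seed Integer seed.
#' @param n_tandem Number of tandem duplications of the inserted mobile
#'   domain per lineage (shuffling presets; default 3, giving 4 copies).
#' @param outgroup_split_my Optional outgroup divergence time (My) for the
#'   shuffling presets; `NULL` keeps them single-species.
#' @return An [sim_config()] object.
#' @export
preset_config <- function(name = c("shuffle_internal", "shuffle_terminal", "ladder3"),
                          seed = 1L, n_tandem = 3L, outgroup_split_my = NULL) {
  name <- match.arg(name)
  if (name %in% c("shuffle_internal", "shuffle_terminal")) {
    n_tandem <- as_count(n_tandem, "n_tandem")
    fams <- data.frame(
      family_id = c("a", "b", "x", "z", "s"),
      length_aa = c(150L, 150L, 150L, 150L, 60L),
      mobile = c(FALSE, FALSE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
    genes <- list(list(gene_id = "A", arch = c("a", "b")),
                  list(gene_id = "X", arch = c("x", "z")))
    # insertion position: shuffle_internal internal (between the two ancestral domains),
    # shuffle_terminal terminal (N-terminal in the A lineage, C-terminal in the X lineage)
    pos_a <- if (name == "shuffle_internal") 2L else 1L
    pos_x <- if (name == "shuffle_internal") 2L else 3L
    ev <- rbind(
      data.frame(time_my = 700, kind = "gene_duplication", gene_id = "A",
                 family_id = NA, position = NA, new_gene_id = "A2",
                 stringsAsFactors = FALSE),
      data.frame(time_my = 450, kind = "shuffling_insertion", gene_id = "A1",
                 family_id = "s", position = pos_a, new_gene_id = NA,
                 stringsAsFactors = FALSE),
      if (n_tandem >= 1L)
        data.frame(time_my = 450 - 20 * seq_len(n_tandem),
                   kind = "tandem_duplication", gene_id = "A1",
                   family_id = NA, position = pos_a, new_gene_id = NA,
                   stringsAsFactors = FALSE),
      data.frame(time_my = 80, kind = "gene_duplication", gene_id = "X",
                 family_id = NA, position = NA, new_gene_id = "X2",
                 stringsAsFactors = FALSE),
      data.frame(time_my = 60, kind = "gene_duplication", gene_id = "X1",
                 family_id = NA, position = NA, new_gene_id = "X3",
                 stringsAsFactors = FALSE),
      data.frame(time_my = 50, kind = "shuffling_insertion", gene_id = "X2",
                 family_id = "s", position = pos_x, new_gene_id = NA,
                 stringsAsFactors = FALSE),
      if (n_tandem >= 1L)
        data.frame(time_my = 50 - 5 * seq_len(n_tandem),
                   kind = "tandem_duplication", gene_id = "X2",
                   family_id = NA, position = pos_x, new_gene_id = NA,
                   stringsAsFactors = FALSE)
    )
    # the duplication of A renames the retained copy: model keeps the parent
    # lineage on copy 1, so relabel A -> A1 and X -> X1 at duplication time
    ev$rename_parent <- ev$kind == "gene_duplication" &
      ev$gene_id %in% c("A", "X")
    n_sp <- if (is.null(outgroup_split_my)) 1L else 2L
    splits <- if (is.null(outgroup_split_my)) numeric(0) else outgroup_split_my
    sim_config(n_species = n_sp, species_splits_my = splits, root_age_my = 800,
               families = fams, ancestral_genes = genes, scripted_events = ev,
               seed = seed)
  } else { # ladder3
    fams <- data.frame(
      family_id = sprintf("f%d", 1:6),
      length_aa = rep(150L, 6),
      mobile = rep(FALSE, 6),
      stringsAsFactors = FALSE
    )
    genes <- list(list(gene_id = "P", arch = c("f1", "f2")),
                  list(gene_id = "Q", arch = c("f3", "f4")),
                  list(gene_id = "R", arch = c("f5", "f6")))
    ev <- data.frame(
      time_my = c(450, 150),
      kind = "gene_duplication",
      gene_id = c("P", "Q"),
      family_id = NA_character_,
      position = NA_integer_,
      new_gene_id = c("P2", "Q2"),
      rename_parent = TRUE,
      stringsAsFactors = FALSE
    )
    sim_config(n_species = 3L, species_splits_my = c(300, 600),
               root_age_my = 700, families = fams, ancestral_genes = genes,
               scripted_events = ev, seed = seed)
  }
}
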