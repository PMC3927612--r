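## Forward simulator of multidomain protein family evolution.
##
## The engine separates *drawing* events from *applying* them: every random
## choice (event kind, target gene, insertion position, substituted sites) is
## resolved into a fully explicit event record before it is applied, and
## `replay_event_log()` re-applies the same records to the ancestral state
## with no RNG. The returned proteome is therefore reproducible both from the
## seed and from its own event log.

new_gene <- function(gene_id, lineage_id, root_gene, instances,
                     shuffled = character(0)) {
  list(gene_id = gene_id, lineage_id = lineage_id, root_gene = root_gene,
       shuffled = shuffled, instances = instances)
}

new_instance <- function(family_id, instance_id, seq) {
  list(family_id = family_id, instance_id = instance_id, seq = seq)
}

## -- ancestral state ---------------------------------------------------------

build_ancestral_state <- function(config) {
  fams <- config$families
  if (is.null(fams)) {
    n_a <- config$n_ancestral_families
    n_m <- config$n_mobile_families
    fams <- data.frame(
      family_id = c(sprintf("FAM%02d", seq_len(n_a)),
                    if (n_m > 0) sprintf("MOB%02d", seq_len(n_m))),
      length_aa = c(
        sample(seq(config$family_length_range[1], config$family_length_range[2]),
               n_a, replace = TRUE),
        if (n_m > 0)
          sample(seq(config$mobile_length_range[1], config$mobile_length_range[2]),
                 n_m, replace = TRUE)),
      mobile = c(rep(FALSE, n_a), rep(TRUE, max(n_m, 0))),
      stringsAsFactors = FALSE
    )
  }
  fams$template <- vapply(fams$length_aa, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  }, character(1))

  inst_counter <- new.env(parent = emptyenv())
  inst_counter$n <- 0L
  next_instance_id <- function() {
    inst_counter$n <- inst_counter$n + 1L
    sprintf("i%04d", inst_counter$n)
  }

  template_of <- function(fam) {
    row <- match(fam, fams$family_id)
    if (is.na(row)) stop_config("unknown family '%s' in ancestral architecture", fam)
    chars(fams$template[row])
  }

  gene_specs <- config$ancestral_genes
  if (is.null(gene_specs)) {
    nonmobile <- fams$family_id[!fams$mobile]
    m <- config$ancestral_arch_size
    gene_specs <- lapply(seq_along(nonmobile), function(i) {
      arch <- if (m == 1L) nonmobile[i] else {
        c(nonmobile[i], sample(nonmobile, m - 1L, replace = FALSE))
      }
      list(gene_id = sprintf("G%d", i), arch = arch)
    })
  }
  genes <- lapply(gene_specs, function(gs) {
    inst <- lapply(gs$arch, function(fam) {
      new_instance(fam, next_instance_id(), template_of(fam))
    })
    new_gene(gs$gene_id, gs$gene_id, gs$gene_id, inst)
  })
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")

  list(families = fams, genes = genes, inst_counter = inst_counter)
}

## -- event application (pure; shared by engine and replay) -------------------

apply_sim_event <- function(genome, ev, families) {
  g_idx <- match(ev$gene_id, names(genome))
  if (ev$kind != "speciation" && is.na(g_idx)) {
    stop("event refers to unknown gene ", ev$gene_id)
  }
  switch(ev$kind,
    gene_duplication = {
      g <- genome[[g_idx]]
      copy2 <- g
      copy2$gene_id <- ev$new_gene_id
      copy2$lineage_id <- ev$new_gene_id
      if (isTRUE(ev$rename_parent)) g$gene_id <- paste0(ev$gene_id, "1")
      genome[[g_idx]] <- g
      names(genome)[g_idx] <- g$gene_id
      genome[[copy2$gene_id]] <- copy2
      genome
    },
    domain_gain_terminal = ,
    domain_gain_internal = ,
    shuffling_insertion = {
      g <- genome[[g_idx]]
      fam_row <- match(ev$family_id, families$family_id)
      inst <- new_instance(ev$family_id, ev$instance_id,
                           chars(families$template[fam_row]))
      p <- ev$position
      g$instances <- append(g$instances, list(inst), after = p - 1L)
      if (ev$kind == "shuffling_insertion") {
        g$shuffled <- union(g$shuffled, ev$family_id)
      }
      genome[[g_idx]] <- g
      genome
    },
    tandem_duplication = {
      g <- genome[[g_idx]]
      p <- ev$position
      inst <- g$instances[[p]]
      inst$instance_id <- ev$instance_id
      g$instances <- append(g$instances, list(inst), after = p)
      genome[[g_idx]] <- g
      genome
    },
    domain_loss = {
      g <- genome[[g_idx]]
      g$instances[[ev$position]] <- NULL
      genome[[g_idx]] <- g
      genome
    },
    substitutions = {
      g <- genome[[g_idx]]
      inst <- g$instances[[ev$position]]
      stopifnot(inst$instance_id == ev$instance_id)
      inst$seq[ev$sites] <- ev$residues
      g$instances[[ev$position]] <- inst
      genome[[g_idx]] <- g
      genome
    },
    stop("unknown event kind: ", ev$kind)
  )
}

## -- engine ------------------------------------------------------------------

# draws substitutions for `elapsed` My on every instance of every gene in the
# branch genome; returns list(genome, events)
drift_genome <- function(genome, elapsed, rate, branch, time_my) {
  if (elapsed <= 0 || rate <= 0) return(list(genome = genome, events = list()))
  lambda <- rate * elapsed
  events <- list()
  for (gi in seq_along(genome)) {
    g <- genome[[gi]]
    for (pi in seq_along(g$instances)) {
      inst <- g$instances[[pi]]
      n_events <- stats::rpois(length(inst$seq), lambda)
      hot <- which(n_events > 0L)
      if (!length(hot)) next
      changed_sites <- integer(0)
      changed_res <- character(0)
      for (site in hot) {
        cur <- inst$seq[site]
        for (k in seq_len(n_events[site])) {
          cur <- sample(AA_ALPHABET[AA_ALPHABET != cur], 1L)
        }
        if (cur != inst$seq[site]) {
          changed_sites <- c(changed_sites, site)
          changed_res <- c(changed_res, cur)
        }
      }
      if (!length(changed_sites)) next
      ev <- list(kind = "substitutions", time_my = time_my, branch = branch,
                 gene_id = g$gene_id, position = pi,
                 instance_id = inst$instance_id,
                 sites = changed_sites, residues = changed_res)
      inst$seq[changed_sites] <- changed_res
      g$instances[[pi]] <- inst
      events[[length(events) + 1L]] <- ev
    }
    genome[[gi]] <- g
  }
  list(genome = genome, events = events)
}

# resolves a stochastic event drawn by the Gillespie loop into an explicit
# record, or NULL if the drawn event is impossible on its target (thinning)
draw_event_record <- function(genome, families, rates, time_my, branch, state) {
  g_idx <- sample.int(length(genome), 1L)
  g <- genome[[g_idx]]
  kinds <- names(rates)
  w <- unlist(rates)
  kind <- sample(kinds, 1L, prob = w)
  len <- length(g$instances)
  base <- list(kind = kind, time_my = time_my, branch = branch,
               gene_id = g$gene_id, rename_parent = FALSE)
  next_iid <- function() {
    state$inst_counter$n <- state$inst_counter$n + 1L
    sprintf("i%04d", state$inst_counter$n)
  }
  switch(kind,
    gene_duplication = {
      state$dup_counter <- state$dup_counter + 1L
      c(base, list(new_gene_id = sprintf("%s.%d", g$gene_id, state$dup_counter)))
    },
    domain_gain_terminal = {
      fam <- sample(families$family_id, 1L)
      pos <- if (stats::runif(1) < 0.5) 1L else len + 1L
      c(base, list(family_id = fam, position = pos, instance_id = next_iid()))
    },
    domain_gain_internal = {
      if (len < 2L) return(NULL)
      fam <- sample(families$family_id, 1L)
      pos <- sample(2:len, 1L)
      c(base, list(family_id = fam, position = pos, instance_id = next_iid()))
    },
    domain_loss = {
      if (len < 2L) return(NULL)
      c(base, list(position = sample.int(len, 1L)))
    },
    tandem_duplication = {
      c(base, list(position = sample.int(len, 1L), instance_id = next_iid()))
    },
    shuffling_insertion = {
      mob <- families$family_id[families$mobile]
      if (!length(mob)) return(NULL)
      fam <- if (length(mob) == 1L) mob else sample(mob, 1L)
      pos <- sample.int(len + 1L, 1L)
      c(base, list(family_id = fam, position = pos, instance_id = next_iid()))
    }
  )
}

# evolves one branch segment from t_hi to t_lo (My before present);
# scripted events are honoured only on the backbone
evolve_segment <- function(genome, t_hi, t_lo, branch, config, state) {
  events <- list()
  scripted <- NULL
  if (identical(branch, "backbone") && !is.null(config$scripted_events)) {
    se <- config$scripted_events
    keep <- se$time_my <= t_hi & se$time_my > t_lo
    if (any(keep)) scripted <- se[keep, , drop = FALSE][order(-se$time_my[keep]), , drop = FALSE]
  }
  rate_sum <- sum(unlist(config$rates))
  sub_rate <- config$substitution_rate
  t_cur <- t_hi
  s_ptr <- 1L

  push <- function(evs) events[seq_along(evs) + length(events)] <<- evs

  repeat {
    t_script <- if (!is.null(scripted) && s_ptr <= nrow(scripted)) {
      scripted$time_my[s_ptr]
    } else -Inf
    t_stoch <- if (rate_sum > 0 && length(genome) > 0) {
      t_cur - stats::rexp(1L, rate_sum * length(genome))
    } else -Inf
    t_next <- max(t_script, t_stoch)
    if (t_next <= t_lo) break

    d <- drift_genome(genome, t_cur - t_next, sub_rate, branch, t_next)
    genome <- d$genome
    push(d$events)

    if (t_script >= t_stoch) {
      row <- scripted[s_ptr, ]
      s_ptr <- s_ptr + 1L
      ev <- list(kind = row$kind, time_my = row$time_my, branch = branch,
                 gene_id = row$gene_id,
                 family_id = if (!is.na(row$family_id)) row$family_id else NULL,
                 position = if (!is.na(row$position)) as.integer(row$position) else NULL,
                 new_gene_id = if (!is.na(row$new_gene_id)) row$new_gene_id else NULL,
                 rename_parent = isTRUE(row$rename_parent))
      if (ev$kind %in% c("domain_gain_terminal", "domain_gain_internal",
                         "shuffling_insertion", "tandem_duplication")) {
        state$inst_counter$n <- state$inst_counter$n + 1L
        ev$instance_id <- sprintf("i%04d", state$inst_counter$n)
      }
      genome <- apply_sim_event(genome, ev, state$families)
      push(list(ev))
    } else {
      ev <- draw_event_record(genome, state$families, config$rates, t_stoch,
                              branch, state)
      if (!is.null(ev)) {
        genome <- apply_sim_event(genome, ev, state$families)
        push(list(ev))
      }
    }
    t_cur <- t_next
  }

  d <- drift_genome(genome, t_cur - t_lo, sub_rate, branch, t_lo)
  genome <- d$genome
  push(d$events)
  list(genome = genome, events = events)
}

## -- top level ---------------------------------------------------------------

#' Simulate the evolution of a multidomain proteome
#'
#' Runs the forward simulator defined by an [sim_config()]: ancestral
#' multidomain genes evolve along an ultrametric ladder species tree under
#' gene duplication, terminal/internal domain gain, domain loss, tandem
#' domain duplication, domain shuffling and residue substitution. Returns the
#' extant proteins of every species together with all-pairs ground-truth
#' homology labels (computed from the event history, never from sequences)
#' and a replayable event log.
#'
#' Pair labels: `ORTHOLOG` -- same gene lineage in different species;
#' `PARALOG` -- lineages joined by a gene duplication; `EPAKTOLOG` --
#' duplication-unconnected lineages that share at least one mobile domain
#' family acquired by independent shuffling insertions (and still present in
#' both architectures); `UNRELATED` otherwise.
#'
#' @param config An [sim_config()] or [preset_config()] object.
#' @return An object of class `sim_proteome`: a list with elements
#'   `proteins` (data frame of protein metadata and assembled sequences),
#'   `architectures` (per-protein data frame of ordered domain instances
#'   with 1-based coordinates and percent identity to the family template),
#'   `families`, `labels`, `event_log`, `ancestral` and `config`.
#' @seealso [replay_event_log()], [emit_sequences()],
#'   [emit_domain_annotations()], [score_all_pairs()]
#' @export
generate_proteome <- function(config) {
  if (!inherits(config, "evolution_config")) {
    stop_config("config must be created by sim_config() or preset_config()")
  }
  set.seed(config$seed)
  anc <- build_ancestral_state(config)
  state <- new.env(parent = emptyenv())
  state$families <- anc$families
  state$inst_counter <- anc$inst_counter
  state$dup_counter <- 0L

  log <- list()
  push <- function(evs) log[seq_along(evs) + length(log)] <<- evs

  genomes <- list(backbone = anc$genes)
  splits <- config$species_splits_my
  species_names <- if (length(splits)) sprintf("sp%d", seq_along(splits) + 1L) else character(0)
  ord <- order(splits, decreasing = TRUE)
  t_cur <- config$root_age_my

  for (i in ord) {
    t_s <- splits[i]
    sp <- species_names[i]
    seg <- evolve_segment(genomes$backbone, t_cur, t_s, "backbone", config, state)
    genomes$backbone <- seg$genome
    push(seg$events)
    push(list(list(kind = "speciation", time_my = t_s, branch = "backbone",
                   new_branch = sp)))
    genomes[[sp]] <- genomes$backbone
    off <- evolve_segment(genomes[[sp]], t_s, 0, sp, config, state)
    genomes[[sp]] <- off$genome
    push(off$events)
    t_cur <- t_s
  }
  seg <- evolve_segment(genomes$backbone, t_cur, 0, "backbone", config, state)
  genomes$backbone <- seg$genome
  push(seg$events)

  res <- assemble_proteome(genomes, anc$families, config)
  res$event_log <- structure(log, class = "sim_event_log")
  res$ancestral <- list(families = anc$families, genes = anc$genes)
  res$config <- config
  res$labels <- ground_truth_labels(res)
  res
}

branch_species <- function(branch) if (branch == "backbone") "sp1" else branch

assemble_proteome <- function(genomes, families, config) {
  linker <- strrep("G", config$linker_length_aa)
  meta <- list()
  archs <- list()
  for (branch in names(genomes)) {
    sp <- branch_species(branch)
    for (g in genomes[[branch]]) {
      pid <- paste(g$gene_id, sp, sep = "_")
      seqs <- vapply(g$instances, function(i) paste(i$seq, collapse = ""), character(1))
      lens <- nchar(seqs)
      n <- length(lens)
      starts <- cumsum(c(1L, utils::head(lens, -1L) + config$linker_length_aa))
      ends <- starts + lens - 1L
      fam_rows <- match(vapply(g$instances, `[[`, character(1), "family_id"),
                        families$family_id)
      ident <- vapply(seq_along(g$instances), function(i) {
        100 * seq_identity(g$instances[[i]]$seq,
                           chars(families$template[fam_rows[i]]))
      }, numeric(1))
      archs[[pid]] <- data.frame(
        protein_id = pid,
        family_id = vapply(g$instances, `[[`, character(1), "family_id"),
        instance_id = vapply(g$instances, `[[`, character(1), "instance_id"),
        start = starts, end = ends,
        identity_pct = ident,
        seq = seqs,
        stringsAsFactors = FALSE
      )
      meta[[pid]] <- data.frame(
        protein_id = pid, species_id = sp, gene_id = g$gene_id,
        lineage_id = g$lineage_id, root_gene = g$root_gene,
        shuffled = paste(g$shuffled, collapse = ","),
        n_domains = n,
        length_aa = sum(lens) + config$linker_length_aa * max(n - 1L, 0L),
        sequence = paste(seqs, collapse = linker),
        stringsAsFactors = FALSE
      )
    }
  }
  proteins <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  proteins <- proteins[order(proteins$protein_id), , drop = FALSE]
  rownames(proteins) <- NULL
  structure(list(proteins = proteins, architectures = archs,
                 families = families), class = "sim_proteome")
}

# all-pairs relation labels, derived from lineage metadata only
ground_truth_labels <- function(proteome) {
  p <- proteome$proteins
  n <- nrow(p)
  if (n < 2L) {
    return(data.frame(protein_id_a = character(0), protein_id_b = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  }
  shuffled_present <- lapply(seq_len(n), function(i) {
    sh <- strsplit(p$shuffled[i], ",", fixed = TRUE)[[1]]
    intersect(sh, proteome$architectures[[p$protein_id[i]]]$family_id)
  })
  idx <- utils::combn(n, 2L)
  relation <- character(ncol(idx))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1L, k]; j <- idx[2L, k]
    relation[k] <- if (p$lineage_id[i] == p$lineage_id[j] &&
                       p$species_id[i] != p$species_id[j]) {
      "ORTHOLOG"
    } else if (p$root_gene[i] == p$root_gene[j]) {
      "PARALOG"
    } else if (length(intersect(shuffled_present[[i]], shuffled_present[[j]]))) {
      "EPAKTOLOG"
    } else "UNRELATED"
  }
  data.frame(protein_id_a = p$protein_id[idx[1L, ]],
             protein_id_b = p$protein_id[idx[2L, ]],
             relation = relation, stringsAsFactors = FALSE)
}

#' Look up the ground-truth relation of a protein pair
#'
#' Labels are symmetric, so the order of the two ids does not matter.
#'
#' @param proteome A `sim_proteome`.
#' @param a,b Protein ids.
#' @return One of `"ORTHOLOG"`, `"PARALOG"`, `"EPAKTOLOG"`, `"UNRELATED"`.
#' @export
pair_relation <- function(proteome, a, b) {
  lab <- proteome$labels
  hit <- which(pair_key(lab$protein_id_a, lab$protein_id_b) == pair_key(a, b))
  if (!length(hit)) stop_config("no such pair: %s / %s", a, b)
  lab$relation[hit[1L]]
}

#' Replay a simulation event log against the ancestral state
#'
#' Applies the recorded events, in order and with no random number use, to
#' the ancestral genes. Returns the extant proteome, which is identical to
#' the one produced by [generate_proteome()] — the self-consistency contract
#' of the simulator.
#'
#' @param proteome A `sim_proteome` (source of ancestral state, log and
#'   configuration).
#' @return A `sim_proteome` with `proteins`, `architectures`, `families`.
#' @export
replay_event_log <- function(proteome) {
  stopifnot(inherits(proteome, "sim_proteome"))
  families <- proteome$ancestral$families
  genomes <- list(backbone = proteome$ancestral$genes)
  for (ev in proteome$event_log) {
    if (ev$kind == "speciation") {
      genomes[[ev$new_branch]] <- genomes[[ev$branch]]
    } else {
      genomes[[ev$branch]] <- apply_sim_event(genomes[[ev$branch]], ev, families)
    }
  }
  assemble_proteome(genomes, families, proteome$config)
}

#' @export
print.sim_proteome <- function(x, ...) {
  cat(sprintf("Simulated proteome: %d proteins, %d species, %d domain families\n",
              nrow(x$proteins), length(unique(x$proteins$species_id)),
              nrow(x$families)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels$relation)
    cat("pair labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
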