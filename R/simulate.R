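# Seeded synthetic-data generator: emits a complete, internally consistent
# set of pipeline inputs (protein table, genus profiles, interaction table,
# OBO ontology) plus a ground-truth record for parameter-recovery tests.

#' Default synthetic domain catalogue
#'
#' The 32 S100B partner domains of the packaged interaction fixture plus 20
#' background ("decoy") domains that are never partners, so that screening
#' retains a proper subset of each proteome. Background occurrence rates
#' mirror the qualitative tiering seen in real bacterial screens at a
#' few-thousand-protein problem size: a handful of common domains, a
#' mid-frequency tier, a rare tier, seven near-zero domains and sixteen
#' domains absent from bacteria (rate 0, e.g. interleukins or the S100
#' domain itself).
#'
#' @return Data frame with columns `accession`, `rate` (per-protein
#'   Bernoulli probability of carrying >= 1 copy) and `partner` (logical:
#'   member of the query's partner set).
#' @export
default_domain_catalogue <- function() {
  tested <- data.frame(
    accession = c("PF00149", "PF00069", "PF13202", "PF13499", "PF00036",
                  "PF13895", "PF00612", "PF13405", "PF00063"),
    rate = c(0.07, 0.055, 0.006, 0.002, 0.0015,
             0.0012, 0.001, 0.001, 0.0005),
    stringsAsFactors = FALSE)
  near_zero <- data.frame(
    accession = c("PF00167", "PF00168", "PF00992", "PF01267", "PF01372",
                  "PF01387", "PF01576"),
    rate = 2e-4, stringsAsFactors = FALSE)
  absent <- data.frame(
    accession = c("PF00340", "PF02888", "PF03520", "PF08763", "PF10163",
                  "PF12209", "PF13833", "PF00307", "PF00531", "PF00613",
                  "PF01023", "PF05002", "PF08457", "PF11522", "PF12424",
                  "PF12515"),
    rate = 0, stringsAsFactors = FALSE)
  partners <- rbind(tested, near_zero, absent)
  partners$partner <- TRUE
  decoys <- data.frame(
    accession = sprintf("PF9%04d", seq_len(20L)),
    rate = rep(c(0.30, 0.15, 0.08, 0.04, 0.02), each = 4L),
    partner = FALSE, stringsAsFactors = FALSE)
  rbind(partners, decoys)
}

#' Simulation configuration
#'
#' Defines a three-group synthetic gut community. The default genus overlap
#' structure emulates the healthy/CD/UC study design: 15 genera common to
#' all three groups, 13 control-only, 9 CD-only, 8 UC-only, and pairwise
#' overlaps (CT&CD 2, CT&UC 2, CD&UC 25) chosen so the per-group totals are
#' 32 (CT), 51 (CD) and 50 (UC) of 74 genera overall.
#'
#' @param seed Integer; fully determines the generator's output.
#' @param groups Three group labels.
#' @param n_shared_genera Genera common to all three groups.
#' @param n_specific_genera Named integer (one per group): exclusive
#'   genera.
#' @param n_pairwise_genera Named integer over the three pairs
#'   (`"A_B"` with A before B in `groups`): genera in exactly those two
#'   groups.
#' @param proteins_per_genus Proteins generated per genus.
#' @param domain_catalogue Data frame `accession`/`rate`/`partner`; see
#'   [default_domain_catalogue()].
#' @param effects Optional data frame `domain`, `group`, `factor`:
#'   multiplicative rate modifiers. A genus belonging to several groups
#'   takes the mean of its groups' factors (exact for group-exclusive
#'   genera). Default: no effects (all factors 1).
#' @param query_domain Synthetic query-domain accession used as the key of
#'   the emitted interaction table.
#' @param include_go Generate the GO DAG and annotations (disable for
#'   domain-only simulation studies).
#' @param go_terms_per_namespace Terms per namespace in the generated DAG.
#' @param go_branching Maximum `is_a` parents per non-root term.
#' @param go_terms_per_protein Expected number of direct leaf annotations
#'   per protein.
#' @param planted_enriched_terms Optional data frame `term` (GO ID or `NA`
#'   to auto-pick the first leaf of `namespace`), `namespace`, `group`,
#'   `factor`: leaf-probability multipliers applied to screened interactors
#'   of that group's genera, planting study-vs-universe enrichment.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              groups = c("CT", "CD", "UC"),
                              n_shared_genera = 15L,
                              n_specific_genera = c(CT = 13L, CD = 9L,
                                                    UC = 8L),
                              n_pairwise_genera = c(CT_CD = 2L, CT_UC = 2L,
                                                    CD_UC = 25L),
                              proteins_per_genus = 200L,
                              domain_catalogue = default_domain_catalogue(),
                              effects = NULL,
                              query_domain = "PF99001",
                              include_go = TRUE,
                              go_terms_per_namespace = 15L,
                              go_branching = 2L,
                              go_terms_per_protein = 2,
                              planted_enriched_terms = NULL) {
  stopifnot(length(groups) == 3L, !anyDuplicated(groups))
  stopifnot(setequal(names(n_specific_genera), groups))
  expected_pairs <- c(paste(groups[1L], groups[2L], sep = "_"),
                      paste(groups[1L], groups[3L], sep = "_"),
                      paste(groups[2L], groups[3L], sep = "_"))
  stopifnot(setequal(names(n_pairwise_genera), expected_pairs))
  stopifnot(is.data.frame(domain_catalogue),
            all(c("accession", "rate", "partner") %in%
                  names(domain_catalogue)))
  if (any(domain_catalogue$rate < 0 | domain_catalogue$rate > 1)) {
    stop("catalogue rates must lie in [0, 1]")
  }
  if (anyDuplicated(domain_catalogue$accession)) {
    stop("duplicate accessions in domain catalogue")
  }
  if (!is.null(effects)) {
    stopifnot(all(c("domain", "group", "factor") %in% names(effects)))
    if (any(!effects$group %in% groups)) stop("unknown group in effects")
    if (any(effects$factor < 0)) stop("effect factors must be >= 0")
  }
  structure(list(
    seed = as.integer(seed), groups = groups,
    n_shared_genera = as.integer(n_shared_genera),
    n_specific_genera = n_specific_genera[groups],
    n_pairwise_genera = n_pairwise_genera[expected_pairs],
    proteins_per_genus = as.integer(proteins_per_genus),
    domain_catalogue = domain_catalogue, effects = effects,
    query_domain = query_domain, include_go = isTRUE(include_go),
    go_terms_per_namespace = as.integer(go_terms_per_namespace),
    go_branching = as.integer(go_branching),
    go_terms_per_protein = go_terms_per_protein,
    planted_enriched_terms = planted_enriched_terms),
    class = "simulation_config")
}

# genus -> group membership table implied by the overlap structure
#' @noRd
genus_membership <- function(config) {
  g <- config$groups
  regions <- list()
  add <- function(regions, label, count, members) {
    if (count > 0L) {
      regions[[label]] <- list(count = count, members = members)
    }
    regions
  }
  regions <- add(regions, "common", config$n_shared_genera, g)
  for (gg in g) {
    regions <- add(regions, paste0("only_", gg),
                   config$n_specific_genera[[gg]], gg)
  }
  for (pair in names(config$n_pairwise_genera)) {
    members <- strsplit(pair, "_", fixed = TRUE)[[1L]]
    regions <- add(regions, paste0("pair_", pair),
                   config$n_pairwise_genera[[pair]], members)
  }
  rows <- list()
  for (label in names(regions)) {
    r <- regions[[label]]
    for (i in seq_len(r$count)) {
      rows[[length(rows) + 1L]] <- list(
        genus = sprintf("Genus_%s_%02d", label, i), groups = r$members)
    }
  }
  data.frame(
    genus = vapply(rows, `[[`, character(1L), "genus"),
    groups = I(lapply(rows, `[[`, "groups")),
    stringsAsFactors = FALSE)
}

# Random single-rooted DAG per namespace; every non-root term links to
# 1..branching earlier terms of the same namespace.
#' @noRd
make_go_dag_spec <- function(n_per_ns, branching) {
  namespaces <- c("biological_process", "cellular_component",
                  "molecular_function")
  terms <- list()
  counter <- 0L
  for (ns in namespaces) {
    ids <- character(n_per_ns)
    parents <- vector("list", n_per_ns)
    for (j in seq_len(n_per_ns)) {
      counter <- counter + 1L
      ids[j] <- sprintf("GO:%07d", 1000000L + counter)
      parents[[j]] <- if (j == 1L) character(0) else {
        np <- sample.int(min(branching, j - 1L), 1L)
        ids[sample.int(j - 1L, np)]
      }
    }
    terms[[ns]] <- list(ids = ids, parents = parents)
  }
  lines <- c("format-version: 1.2", "ontology: synthetic-go", "")
  leaves <- list()
  n_edges <- 0L
  for (ns in namespaces) {
    t <- terms[[ns]]
    all_parents <- unlist(t$parents, use.names = FALSE)
    leaves[[ns]] <- t$ids[!t$ids %in% all_parents]
    for (j in seq_along(t$ids)) {
      lines <- c(lines, "[Term]",
                 sprintf("id: %s", t$ids[j]),
                 sprintf("name: synthetic %s term %d", ns, j),
                 sprintf("namespace: %s", ns))
      for (p in t$parents[[j]]) {
        lines <- c(lines, sprintf("is_a: %s ! parent", p))
        n_edges <- n_edges + 1L
      }
      lines <- c(lines, "")
    }
  }
  lines <- c(lines, "[Term]", "id: GO:0999999",
             "name: synthetic obsolete term",
             "namespace: biological_process", "is_obsolete: true", "")
  list(obo_lines = lines, leaves = leaves, n_edges = n_edges,
       n_terms = 3L * n_per_ns + 1L,
       ids = unlist(lapply(terms, `[[`, "ids"), use.names = FALSE))
}

#' Generate a synthetic metaproteome with known ground truth
#'
#' Draws, from a single seeded RNG stream, a complete set of pipeline
#' inputs: an annotated protein table (independent Bernoulli domain
#' assignment per catalogue domain, so multi-domain proteins arise
#' naturally), per-group genus profiles with abundances, an interaction
#' table keying the synthetic query domain to the catalogue's partner
#' domains, a GO ontology in OBO format with leaf-level annotations, and a
#' truth record holding the realised (not merely configured) per-group
#' domain counts and planted-term counts.
#'
#' Identical configurations yield identical objects, and
#' [write_simulation()] serialises them byte-identically.
#'
#' @param config A [simulation_config()].
#' @return Object of class `metaproteome_sim`: list with `config`,
#'   `records` (a `protein_table`), `taxa_profiles` (data frame
#'   group/genus/abundance), `interaction_table` (data frame),
#'   `obo_lines` (character, empty when `include_go = FALSE`) and `truth`.
#' @export
simulate_metaproteome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cat_df <- config$domain_catalogue
  groups <- config$groups
  # feasibility before any draw: rate x factor must stay a probability
  fac_gd <- matrix(1, nrow(cat_df), length(groups),
                   dimnames = list(cat_df$accession, groups))
  if (!is.null(config$effects)) {
    for (i in seq_len(nrow(config$effects))) {
      e <- config$effects[i, ]
      if (!e$domain %in% cat_df$accession) {
        stop(sprintf("effect on unknown domain %s", e$domain))
      }
      fac_gd[e$domain, e$group] <- e$factor
    }
  }
  max_rate <- cat_df$rate * apply(fac_gd, 1L, max)
  if (any(max_rate > 1)) {
    stop(sprintf("infeasible rate after effects for domain %s",
                 cat_df$accession[which.max(max_rate)]))
  }
  planted <- config$planted_enriched_terms
  if (!is.null(planted) && any(planted$factor < 0)) {
    stop("planted factors must be >= 0")
  }

  set.seed(config$seed)
  membership <- genus_membership(config)
  n_genera <- nrow(membership)
  npg <- config$proteins_per_genus
  K <- nrow(cat_df)
  partner_set <- cat_df$accession[cat_df$partner]

  dag_spec <- NULL
  leaf_ids <- character(0)
  leaf_ns <- character(0)
  base_leaf_prob <- 0
  if (config$include_go) {
    dag_spec <- make_go_dag_spec(config$go_terms_per_namespace,
                                 config$go_branching)
    leaf_ids <- unlist(dag_spec$leaves, use.names = FALSE)
    leaf_ns <- rep(names(dag_spec$leaves), lengths(dag_spec$leaves))
    base_leaf_prob <- min(1, config$go_terms_per_protein / length(leaf_ids))
    if (!is.null(planted)) {
      planted$term <- as.character(planted$term)
      for (i in seq_len(nrow(planted))) {
        if (is.na(planted$term[i])) {
          cand <- dag_spec$leaves[[planted$namespace[i]]]
          if (!length(cand)) stop("no leaf available in planted namespace")
          planted$term[i] <- cand[1L]
        }
        if (!planted$term[i] %in% leaf_ids) {
          stop(sprintf("planted term %s is not a leaf of the generated DAG",
                       planted$term[i]))
        }
      }
      if (any(base_leaf_prob * planted$factor > 1)) {
        stop("infeasible leaf probability after planted factor")
      }
    }
  } else if (!is.null(planted)) {
    stop("planted_enriched_terms requires include_go = TRUE")
  }
  # per-leaf, per-group planted factors (mean rule mirrors domain effects)
  leaf_fac_g <- matrix(1, length(leaf_ids), length(groups),
                       dimnames = list(leaf_ids, groups))
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      leaf_fac_g[planted$term[i], planted$group[i]] <- planted$factor[i]
    }
  }

  acc_all <- character(0)
  genus_all <- character(0)
  domains_all <- list()
  go_all <- list()
  loc_all <- list()
  loc_pool <- c("membrane", "cytoplasm", "secreted", "")
  for (gi in seq_len(n_genera)) {
    genus <- membership$genus[gi]
    in_groups <- membership$groups[[gi]]
    fac <- rowMeans(fac_gd[, in_groups, drop = FALSE])
    p_vec <- pmin(1, cat_df$rate * fac)
    draws <- matrix(stats::rbinom(npg * K, 1L, rep(p_vec, each = npg)),
                    nrow = npg, ncol = K) == 1L
    dom_list <- split(cat_df$accession[col(draws)[draws]],
                      factor(row(draws)[draws], levels = seq_len(npg)))
    dom_list <- lapply(dom_list, as.character)
    acc <- sprintf("SYN%03d_%05d", gi, seq_len(npg))
    interactor <- vapply(dom_list, function(d) any(d %in% partner_set),
                         logical(1L))
    if (config$include_go) {
      L <- length(leaf_ids)
      lf <- rowMeans(leaf_fac_g[, in_groups, drop = FALSE])
      P <- matrix(rep(base_leaf_prob, npg * L), nrow = npg)
      if (any(lf != 1)) {
        P[interactor, ] <- matrix(rep(pmin(1, base_leaf_prob * lf),
                                      each = sum(interactor)),
                                  nrow = sum(interactor))
      }
      gdraws <- matrix(stats::rbinom(npg * L, 1L, as.vector(P)),
                       nrow = npg, ncol = L) == 1L
      go_list <- split(leaf_ids[col(gdraws)[gdraws]],
                       factor(row(gdraws)[gdraws], levels = seq_len(npg)))
      go_list <- lapply(go_list, as.character)
    } else {
      go_list <- replicate(npg, character(0), simplify = FALSE)
    }
    loc <- sample(loc_pool, npg, replace = TRUE,
                  prob = c(0.3, 0.4, 0.1, 0.2))
    acc_all <- c(acc_all, acc)
    genus_all <- c(genus_all, rep(genus, npg))
    domains_all <- c(domains_all, unname(dom_list))
    go_all <- c(go_all, unname(go_list))
    loc_all <- c(loc_all, lapply(loc, function(x) {
      if (nzchar(x)) x else character(0)
    }))
  }
  records <- protein_table(acc_all, genus_all, domains = domains_all,
                           go_terms = go_all, localisation = loc_all)

  # genus profiles with exponential relative abundances per group
  profile_rows <- list()
  for (g in groups) {
    genera_g <- membership$genus[vapply(membership$groups,
                                        function(m) g %in% m, logical(1L))]
    ab <- stats::rexp(length(genera_g))
    ab <- round(ab / sum(ab), 6L)
    profile_rows[[g]] <- data.frame(group = g, genus = genera_g,
                                    abundance = ab,
                                    stringsAsFactors = FALSE)
  }
  taxa_profiles <- do.call(rbind, profile_rows)
  rownames(taxa_profiles) <- NULL

  interaction_table <- data.frame(
    domain_acc = config$query_domain, partner_acc = sort(partner_set),
    description = "synthetic partner assignment",
    stringsAsFactors = FALSE)

  # realised truth: tallies recomputed from the emitted table itself
  group_sizes <- integer(0)
  domain_observed <- matrix(0L, K, length(groups),
                            dimnames = list(cat_df$accession, groups))
  interactor_counts <- integer(0)
  planted_counts <- NULL
  for (g in groups) {
    genera_g <- unique(taxa_profiles$genus[taxa_profiles$group == g])
    sel <- genus_all %in% genera_g
    group_sizes[g] <- sum(sel)
    doms <- lapply(domains_all[sel], unique)
    u <- unlist(doms, use.names = FALSE)
    tab <- table(factor(u, levels = cat_df$accession))
    domain_observed[, g] <- as.integer(tab)
    is_int <- vapply(domains_all[sel], function(d) any(d %in% partner_set),
                     logical(1L))
    interactor_counts[g] <- sum(is_int)
    if (!is.null(planted)) {
      gos <- go_all[sel]
      for (i in seq_len(nrow(planted))) {
        term <- planted$term[i]
        has_term <- vapply(gos, function(x) term %in% x, logical(1L))
        planted_counts <- rbind(planted_counts, data.frame(
          term = term, group = g,
          universe_annotated = sum(has_term),
          study_observed = sum(has_term & is_int),
          study_size = sum(is_int), universe_size = sum(sel),
          stringsAsFactors = FALSE))
      }
    }
  }

  truth <- list(
    seed = config$seed,
    group_sizes = as.list(group_sizes),
    n_genera = n_genera,
    domain_observed = domain_observed,
    interactor_counts = as.list(interactor_counts),
    partner_set = sort(partner_set),
    dag = if (config$include_go) list(
      n_terms = dag_spec$n_terms, n_edges = dag_spec$n_edges,
      leaves = dag_spec$leaves) else NULL,
    planted = if (!is.null(planted)) planted else NULL,
    planted_counts = planted_counts)

  structure(list(config = config, records = records,
                 taxa_profiles = taxa_profiles,
                 interaction_table = interaction_table,
                 obo_lines = if (config$include_go) dag_spec$obo_lines
                   else character(0),
                 truth = truth),
            class = "metaproteome_sim")
}

#' Write a simulation to disk
#'
#' Emits `proteins.tsv`, `taxa_profiles.tsv`, `interactions.tsv`,
#' `ontology.obo` (when GO was generated) and `truth.json` into `dir`.
#' Output is byte-identical for identical simulation objects.
#'
#' @param sim A `metaproteome_sim`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "metaproteome_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteins.tsv"),
             taxa = file.path(dir, "taxa_profiles.tsv"),
             interactions = file.path(dir, "interactions.tsv"),
             truth = file.path(dir, "truth.json"))
  write_protein_table(sim$records, paths[["proteins"]])
  write_tsv(sim$taxa_profiles, paths[["taxa"]])
  write_tsv(sim$interaction_table, paths[["interactions"]])
  if (length(sim$obo_lines)) {
    paths[["obo"]] <- file.path(dir, "ontology.obo")
    writeLines(sim$obo_lines, paths[["obo"]])
  }
  truth <- sim$truth
  truth$domain_observed <- as.data.frame(truth$domain_observed)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Build the per-group virtual proteomes of a simulation
#'
#' Convenience wrapper: applies [build_virtual_proteome()] to the
#' simulation's own protein table and genus profiles.
#'
#' @param sim A `metaproteome_sim`.
#' @return Named list of `virtual_proteome` objects, one per group.
#' @export
sim_group_proteomes <- function(sim) {
  stopifnot(inherits(sim, "metaproteome_sim"))
  groups <- unique(sim$taxa_profiles$group)
  lapply(stats::setNames(groups, groups), function(g) {
    genera <- sim$taxa_profiles$genus[sim$taxa_profiles$group == g]
    build_virtual_proteome(sim$records, taxon_profile(g, genera))
  })
}
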