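# Shared fixtures and independent oracles used across the suite.
# Oracles deliberately avoid the code paths they check.

fixture <- function(name) {
  system.file("extdata", name, package = "ddiscreen", mustWork = TRUE)
}

s100b_map <- function() parse_interaction_table(fixture("s100b_ddi.tsv"))

# Published per-domain occurrence counts for the S100B screen (observed and
# expected per CT/CD/UC group) as a domain_occurrence_table.
published_occurrence <- function() {
  df <- read.delim(fixture("s100b_domain_occurrence.tsv"),
                   stringsAsFactors = FALSE)
  O <- as.matrix(df[, c("CT_observed", "CD_observed", "UC_observed")])
  E <- as.matrix(df[, c("CT_expected", "CD_expected", "UC_expected")])
  dimnames(O) <- dimnames(E) <- list(df$domain, c("CT", "CD", "UC"))
  occurrence_table(O, expected = E)
}

published_group_sizes <- function() {
  df <- read.delim(fixture("s100b_group_summary.tsv"),
                   stringsAsFactors = FALSE)
  setNames(df$total_proteins, df$group)
}

# Hypergeometric upper tail by explicit enumeration over all 2x2 tables
# with the given margins, using only choose().
oracle_fisher_enum <- function(observed, study, annotated, universe) {
  lo <- max(0L, study + annotated - universe)
  hi <- min(study, annotated)
  x <- lo:hi
  prob <- choose(annotated, x) * choose(universe - annotated, study - x) /
    choose(universe, study)
  sum(prob[x >= observed])
}

# Monte-Carlo chi-squared GOF p-value under the multinomial null with cell
# probabilities proportional to the expected counts. The null distribution
# is discrete, so the atom at the observed statistic is split (mid-p) when
# comparing against the continuous chi-squared tail.
oracle_chi2_mc <- function(O, E, n_draws = 1e5) {
  draws <- stats::rmultinom(n_draws, size = sum(O), prob = E / sum(E))
  chi2 <- colSums((draws - E)^2 / E)
  obs <- sum((O - E)^2 / E)
  mean(chi2 > obs + 1e-9) + 0.5 * mean(abs(chi2 - obs) <= 1e-9)
}

# Breadth-first ancestor closure over a parent-link list (includes self).
oracle_ancestors <- function(parents, term) {
  seen <- character(0)
  queue <- term
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, parents[[v]])
  }
  sort(seen)
}

# A small in-code protein table spanning several genera.
tiny_protein_table <- function() {
  protein_table(
    accession = c("A1", "A2", "B1", "B2", "C1"),
    genus = c("Bacteroides", "Bacteroides", "Prevotella", "Prevotella",
              "Roseburia"),
    domains = list(c("PF00149", "PF90001"), c("PF90001", "PF90001"),
                   c("PF00069", "PF00149"), character(0), "PF90002"),
    go_terms = list("GO:1000003", character(0), "GO:1000003",
                    "GO:1000002", character(0)))
}

# Random protein table with per-domain Bernoulli rates; used with
# brute-force scan oracles.
random_protein_table <- function(n, genera, domain_rates, seed) {
  set.seed(seed)
  genus <- sample(genera, n, replace = TRUE)
  doms <- lapply(seq_len(n), function(i) {
    names(domain_rates)[runif(length(domain_rates)) < domain_rates]
  })
  protein_table(sprintf("P%05d", seq_len(n)), genus, domains = doms)
}

as_proteome <- function(records, group = "G") {
  build_virtual_proteome(records,
                         taxon_profile(group, unique(records$genus)))
}

# Three-term is_a chain: 3 -> 2 -> 1 (all molecular_function).
chain_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:1000001", "name: root",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:1000002", "name: mid",
    "namespace: molecular_function", "is_a: GO:1000001 ! root", "",
    "[Term]", "id: GO:1000003", "name: leaf",
    "namespace: molecular_function", "is_a: GO:1000002 ! mid", "")
}

# Random DAG over n terms in one namespace; returns obo lines + parent list.
random_obo <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("GO:2%06d", seq_len(n))
  parents <- vector("list", n)
  names(parents) <- ids
  lines <- c("format-version: 1.2", "")
  for (j in seq_len(n)) {
    parents[[j]] <- if (j == 1L) character(0) else
      ids[sample.int(j - 1L, sample.int(min(3L, j - 1L), 1L))]
    lines <- c(lines, "[Term]", sprintf("id: %s", ids[j]),
               sprintf("name: t%d", j), "namespace: biological_process",
               sprintf("is_a: %s ! p", parents[[j]]), "")
  }
  list(lines = lines, parents = parents, ids = ids)
}
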