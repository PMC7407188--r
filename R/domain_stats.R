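# Per-domain observed/expected occurrence across groups, Pearson chi-squared
# tests and the absent / near-zero / significant classification.

#' Count per-domain protein occurrence in a virtual proteome
#'
#' O(d) = number of distinct proteins carrying at least one copy of domain
#' d (presence, not occurrence: multiple copies in one protein count once).
#'
#' @param proteome A `virtual_proteome`.
#' @param domain_set Character vector of Pfam accessions to tally.
#' @return Named integer vector over `sort(unique(domain_set))`.
#' @export
count_domain_occurrence <- function(proteome, domain_set) {
  stopifnot(inherits(proteome, "virtual_proteome"))
  domain_set <- sort(unique(as.character(domain_set)))
  per_protein <- lapply(proteome$records$domains, unique)
  u <- unlist(per_protein, use.names = FALSE)
  tab <- table(factor(u[u %in% domain_set], levels = domain_set))
  stats::setNames(as.integer(tab), domain_set)
}

#' Estimate a per-domain background occurrence rate
#'
#' f(d) = reference_observed / reference_size: the fraction of reference
#' proteins carrying the domain. The reference is either the pooled groups
#' (default elsewhere) or an external whole-database count.
#'
#' @param reference_observed Non-negative count(s) of proteins carrying the
#'   domain in the reference.
#' @param reference_size Positive reference proteome size.
#' @return Numeric rate(s) in `[0, 1]`.
#' @export
estimate_background_rate <- function(reference_observed, reference_size) {
  if (any(reference_size <= 0)) stop("reference_size must be positive")
  if (any(reference_observed < 0)) stop("reference_observed must be >= 0")
  reference_observed / reference_size
}

#' Expected occurrence counts under the background model
#'
#' E(d,c) = f(d) x N(c): the count expected "by chance" if domain d occurred
#' in group c's proteome at its background rate. By construction
#' E(d,c)/E(d,c') = N(c)/N(c') for every group pair.
#'
#' @param rates Named non-negative numeric vector f(d) per domain.
#' @param group_sizes Named positive integer vector N(c) per group.
#' @return Matrix (domains x groups) of expected counts, full precision.
#' @export
compute_expected <- function(rates, group_sizes) {
  if (any(rates < 0)) stop("background rates must be non-negative")
  if (any(group_sizes <= 0)) stop("group sizes must be positive")
  outer(rates, group_sizes)
}

#' Assemble a domain occurrence table across group proteomes
#'
#' Tabulates O(d,c) for every domain of `domain_set` over the supplied
#' proteomes, derives background rates f(d) (pooled across groups by
#' default, or from an external reference count table) and the expected
#' counts E(d,c) = f(d) x N(c).
#'
#' @param proteomes Named list of `virtual_proteome` objects (names are the
#'   group labels; at least 2 groups).
#' @param domain_set Character vector of Pfam accessions (the partner set).
#' @param background `"pooled"` (f(d) = total observed / total proteins
#'   across the groups) or `"external"` (supply `background_counts` and
#'   `background_size`).
#' @param background_counts Named numeric: reference occurrence count per
#'   domain (external mode).
#' @param background_size Reference proteome size (external mode).
#' @return Object of class `domain_occurrence_table`: list with `domains`,
#'   `groups`, `observed` (matrix), `group_sizes`, `rates`, `expected`.
#' @export
build_occurrence_table <- function(proteomes, domain_set,
                                   background = c("pooled", "external"),
                                   background_counts = NULL,
                                   background_size = NULL) {
  background <- match.arg(background)
  stopifnot(length(proteomes) >= 2L)
  groups <- names(proteomes)
  if (is.null(groups) || any(!nzchar(groups))) {
    groups <- vapply(proteomes, function(p) p$group, character(1L))
  }
  if (anyDuplicated(groups)) stop("duplicate group labels")
  domain_set <- sort(unique(as.character(domain_set)))
  observed <- vapply(proteomes, count_domain_occurrence,
                     integer(length(domain_set)), domain_set = domain_set)
  if (length(domain_set) == 1L) {
    observed <- matrix(observed, nrow = 1L,
                       dimnames = list(domain_set, groups))
  }
  colnames(observed) <- groups
  sizes <- stats::setNames(
    vapply(proteomes, function(p) p$n_proteins, integer(1L)), groups)
  rates <- if (background == "pooled") {
    if (sum(sizes) > 0) rowSums(observed) / sum(sizes) else
      stats::setNames(rep(0, length(domain_set)), domain_set)
  } else {
    if (is.null(background_counts) || is.null(background_size)) {
      stop("external background requires background_counts and background_size")
    }
    cnt <- stats::setNames(rep(0, length(domain_set)), domain_set)
    known <- intersect(names(background_counts), domain_set)
    cnt[known] <- background_counts[known]
    estimate_background_rate(cnt, background_size)
  }
  expected <- if (all(sizes > 0)) compute_expected(rates, sizes) else
    outer(rates, pmax(sizes, 0))
  occurrence_table(observed, group_sizes = sizes, rates = rates,
                   expected = expected)
}

#' Construct a domain occurrence table from matrices
#'
#' Lower-level constructor used both by [build_occurrence_table()] and when
#' the observed/expected counts come from an external report (e.g. a
#' published occurrence table).
#'
#' @param observed Integer matrix, domains x groups, with dimnames.
#' @param group_sizes Optional named vector N(c); if given, O(d,c) <= N(c)
#'   is enforced.
#' @param rates Optional named background rates f(d).
#' @param expected Optional matrix E(d,c); computed from `rates` and
#'   `group_sizes` when absent.
#' @return A `domain_occurrence_table`.
#' @export
occurrence_table <- function(observed, group_sizes = NULL, rates = NULL,
                             expected = NULL) {
  observed <- as.matrix(observed)
  if (is.null(rownames(observed)) || is.null(colnames(observed))) {
    stop("observed matrix needs domain rownames and group colnames")
  }
  if (any(observed < 0)) stop("observed counts must be non-negative")
  if (!is.null(group_sizes)) {
    group_sizes <- group_sizes[colnames(observed)]
    bad <- sweep(observed, 2L, group_sizes, `>`)
    if (any(bad)) stop("observed count exceeds its group size")
  }
  if (is.null(expected)) {
    if (is.null(rates) || is.null(group_sizes)) {
      stop("either expected, or rates plus group_sizes, must be supplied")
    }
    expected <- compute_expected(rates[rownames(observed)], group_sizes)
  }
  expected <- as.matrix(expected)
  if (any(expected < 0)) stop("expected counts must be non-negative")
  stopifnot(identical(dim(observed), dim(expected)))
  structure(list(domains = rownames(observed), groups = colnames(observed),
                 observed = observed, group_sizes = group_sizes,
                 rates = rates, expected = expected),
            class = "domain_occurrence_table")
}

#' Pearson chi-squared goodness-of-fit test for one domain row
#'
#' chi2 = sum over groups of (O - E)^2 / E, with the upper-tail p-value of
#' the chi-squared distribution. The default df convention is k - 1 (k
#' groups; the expectation model is fitted from the data via the pooled
#' rate); `df_mode = "k"` treats the expectations as externally fixed.
#'
#' @param observed,expected Numeric vectors of equal length k >= 2; all
#'   expected values must be strictly positive.
#' @param df_mode `"k_minus_1"` (default) or `"k"`.
#' @return List with `chi2`, `df` and `p`.
#' @export
chisq_row_test <- function(observed, expected,
                           df_mode = c("k_minus_1", "k")) {
  df_mode <- match.arg(df_mode)
  k <- length(observed)
  stopifnot(k >= 2L, length(expected) == k)
  if (any(expected <= 0)) {
    stop("expected count <= 0: exclude this domain from testing")
  }
  chi2 <- sum((observed - expected)^2 / expected)
  df <- if (df_mode == "k_minus_1") k - 1L else k
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Classify domains by occurrence pattern
#'
#' Reproduces the published screen's per-domain triage: domains never seen
#' in any group are `absent`; domains with a total occurrence below
#' `near_zero_min` are `near_zero` and excluded from testing; the rest are
#' chi-squared-tested and labelled `significant` (p < `alpha_sig`),
#' `not_significant` (p > `ns_threshold`) or `intermediate`. Each tested
#' domain also gets a per-group direction profile, the signs of O - E
#' collapsed into a string such as `"+--"` (group order = table order).
#'
#' @param tab A `domain_occurrence_table`.
#' @param alpha_sig Significance threshold (default 0.01).
#' @param ns_threshold Non-significance threshold (default 0.5).
#' @param near_zero_min Minimum total observed count for testing
#'   (default 10).
#' @param df_mode Passed to [chisq_row_test()].
#' @return Data frame with one row per domain: `domain`, `total_observed`,
#'   `chi2`, `df`, `p`, `class`, `direction`.
#' @export
classify_domain_rows <- function(tab, alpha_sig = 0.01, ns_threshold = 0.5,
                                 near_zero_min = 10,
                                 df_mode = c("k_minus_1", "k")) {
  stopifnot(inherits(tab, "domain_occurrence_table"))
  stopifnot(alpha_sig > 0, alpha_sig < 1, ns_threshold > 0, ns_threshold < 1,
            near_zero_min >= 0)
  df_mode <- match.arg(df_mode)
  n <- length(tab$domains)
  res <- data.frame(
    domain = tab$domains,
    total_observed = as.integer(rowSums(tab$observed)),
    chi2 = rep(NA_real_, n), df = rep(NA_integer_, n), p = rep(NA_real_, n),
    class = rep(NA_character_, n), direction = rep("", n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    O <- tab$observed[i, ]
    E <- tab$expected[i, ]
    total <- res$total_observed[i]
    if (total == 0L) {
      res$class[i] <- "absent"
      next
    }
    res$direction[i] <- paste(
      ifelse(O > E, "+", ifelse(O < E, "-", "0")), collapse = "")
    if (total < near_zero_min) {
      res$class[i] <- "near_zero"
      next
    }
    if (any(E <= 0)) {
      stop(sprintf(
        "domain %s has a non-positive expected count: exclude it from testing",
        tab$domains[i]))
    }
    t <- chisq_row_test(O, E, df_mode = df_mode)
    res$chi2[i] <- t$chi2; res$df[i] <- t$df; res$p[i] <- t$p
    res$class[i] <- if (t$p < alpha_sig) "significant"
      else if (t$p > ns_threshold) "not_significant"
      else "intermediate"
  }
  res
}

#' Write the domain occurrence/test table
#'
#' One row per domain mirroring the published layout: per-group observed
#' and expected counts (expected rounded to integer for display, full
#' precision in a sidecar column), chi-squared statistic, df, p, class and
#' direction profile.
#'
#' @param tab A `domain_occurrence_table`.
#' @param results Output of [classify_domain_rows()] on `tab`.
#' @param path Output TSV path.
#' @export
write_domain_stats <- function(tab, results, path) {
  out <- data.frame(domain = tab$domains, stringsAsFactors = FALSE)
  for (g in tab$groups) {
    out[[paste0(g, "_observed")]] <- as.integer(tab$observed[, g])
    out[[paste0(g, "_expected")]] <- round(tab$expected[, g])
    out[[paste0(g, "_expected_exact")]] <- tab$expected[, g]
  }
  m <- match(out$domain, results$domain)
  out$chi2 <- results$chi2[m]
  out$df <- results$df[m]
  out$p <- results$p[m]
  out$class <- results$class[m]
  out$direction <- results$direction[m]
  write_tsv(out[order(out$domain), , drop = FALSE], path)
}
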