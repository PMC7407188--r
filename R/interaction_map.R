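# Query-domain architecture parsing and partner-domain expansion.

#' Parse an hmmscan per-domain table (domtblout)
#'
#' Reads the space-delimited `--domtblout` output of HMMER 3.x `hmmscan`
#' (query protein searched against Pfam profiles) and returns one row per
#' retained domain hit. Rows whose independent (i-)E-value exceeds
#' `evalue_max` are dropped; the order of appearance is preserved.
#'
#' @param input Path to a domtblout file, a single string containing the
#'   file's text, or a character vector of lines.
#' @param evalue_max Maximum independent E-value for a hit to be retained.
#'   Default 0.01, the conventional Pfam significance cut-off.
#' @return A data frame with columns `query_id`, `domain_accession`
#'   (versionless Pfam accession, `PF#####`), `domain_name`, `env_start`,
#'   `env_end` (1-based inclusive envelope coordinates),
#'   `independent_evalue` and `bit_score`.
#' @examples
#' f <- system.file("extdata", "P04271_pfam.domtblout", package = "ddiscreen")
#' parse_hmmscan_domtblout(f)
#' @export
parse_hmmscan_domtblout <- function(input, evalue_max = 0.01) {
  stopifnot(is.numeric(evalue_max), length(evalue_max) == 1L, evalue_max >= 0)
  lines <- read_text_lines(input)
  data_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  hits <- vector("list", length(data_idx))
  for (j in seq_along(data_idx)) {
    i <- data_idx[j]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 22L) {
      stop(sprintf(
        "malformed domtblout row at line %d: %d fields found, >= 22 required",
        i, length(f)))
    }
    env_start <- suppressWarnings(as.integer(f[20L]))
    env_end <- suppressWarnings(as.integer(f[21L]))
    if (is.na(env_start) || is.na(env_end)) {
      stop(sprintf("non-numeric envelope coordinate at line %d", i))
    }
    ievalue <- suppressWarnings(as.numeric(f[13L]))
    score <- suppressWarnings(as.numeric(f[14L]))
    if (is.na(ievalue) || is.na(score)) {
      stop(sprintf("non-numeric E-value or score at line %d", i))
    }
    acc <- sub("\\.[0-9]+$", "", f[2L])
    if (!is_pfam_accession(acc)) {
      stop(sprintf("target accession '%s' at line %d is not a Pfam accession",
                   f[2L], i))
    }
    if (env_start < 1L || env_start > env_end) {
      stop(sprintf("invalid envelope %d-%d at line %d", env_start, env_end, i))
    }
    if (ievalue < 0) stop(sprintf("negative E-value at line %d", i))
    hits[[j]] <- data.frame(
      query_id = f[4L], domain_accession = acc, domain_name = f[1L],
      env_start = env_start, env_end = env_end,
      independent_evalue = ievalue, bit_score = score,
      stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    query_id = character(0), domain_accession = character(0),
    domain_name = character(0), env_start = integer(0), env_end = integer(0),
    independent_evalue = numeric(0), bit_score = numeric(0),
    stringsAsFactors = FALSE)
  out <- out[out$independent_evalue <= evalue_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_ddi_map <- function(edges, source = "user", version = NA_character_,
                        symmetric = FALSE) {
  edges <- lapply(edges, function(p) sort(unique(as.character(p))))
  edges <- edges[order(names(edges))]
  structure(
    list(edges = edges,
         metadata = list(source = source, version = version,
                         symmetric = symmetric)),
    class = "ddi_map")
}

#' Parse a domain-domain interaction table
#'
#' Reads an iPfam-style two-column partner list (TSV: `domain_acc`,
#' `partner_acc`, optional free-text `description`) into a
#' `ddi_map` lookup. Duplicate pairs are collapsed; self-partners (e.g. the
#' S100 domain, which homo-multimerises) are permitted.
#'
#' @param input Path, text or lines (see [parse_hmmscan_domtblout()]).
#' @param source,version Provenance strings stored in the map's metadata.
#' @param symmetrize If `TRUE`, add the reverse of every edge so that
#'   `a %in% partners(b)` iff `b %in% partners(a)`. Off by default: a curated
#'   table keyed by the query's domains is directional by construction.
#' @return An object of class `ddi_map`: a list with `edges` (named list
#'   mapping each domain accession to its sorted, deduplicated partner set)
#'   and `metadata`.
#' @examples
#' f <- system.file("extdata", "s100b_ddi.tsv", package = "ddiscreen")
#' map <- parse_interaction_table(f)
#' ddi_partners(map, "PF01023")
#' @export
parse_interaction_table <- function(input, source = "user",
                                    version = NA_character_,
                                    symmetrize = FALSE) {
  lines <- read_text_lines(input)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) && grepl("^domain_acc\\b", lines[1L])) {
    lines <- lines[-1L]
  }
  edges <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) {
      stop(sprintf("interaction table line %d has fewer than 2 columns", i))
    }
    a <- trimws(f[1L]); b <- trimws(f[2L])
    if (!is_pfam_accession(a) || !is_pfam_accession(b)) {
      stop(sprintf(
        "non-Pfam accession token at interaction table line %d: '%s' / '%s'",
        i, a, b))
    }
    edges[[a]] <- c(edges[[a]], b)
    if (symmetrize) edges[[b]] <- c(edges[[b]], a)
  }
  new_ddi_map(edges, source = source, version = version,
              symmetric = symmetrize)
}

#' Partner set of one domain
#'
#' @param map A `ddi_map`.
#' @param domain A Pfam accession.
#' @return Sorted character vector of partner accessions (empty if the
#'   domain is not a key of the map).
#' @export
ddi_partners <- function(map, domain) {
  stopifnot(inherits(map, "ddi_map"))
  map$edges[[domain]] %||% character(0)
}

#' Domains keyed in an interaction map
#' @param map A `ddi_map`.
#' @return Sorted character vector of key accessions.
#' @export
ddi_domains <- function(map) {
  stopifnot(inherits(map, "ddi_map"))
  names(map$edges)
}

#' @export
print.ddi_map <- function(x, ...) {
  cat(sprintf("Domain-domain interaction map (%d query domains, %d edges)\n",
              length(x$edges), sum(lengths(x$edges))))
  cat(sprintf("  source: %s  version: %s\n",
              x$metadata$source, x$metadata$version))
  for (d in names(x$edges)) {
    cat(sprintf("  %s -> %d partners\n", d, length(x$edges[[d]])))
  }
  invisible(x)
}

#' Serialise an interaction map back to TSV
#'
#' Inverse of [parse_interaction_table()]: re-parsing the written file
#' reproduces identical edges.
#'
#' @param map A `ddi_map`.
#' @param path Output file path.
#' @export
write_interaction_table <- function(map, path) {
  stopifnot(inherits(map, "ddi_map"))
  df <- data.frame(
    domain_acc = rep(names(map$edges), lengths(map$edges)),
    partner_acc = unlist(map$edges, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Expand query domains into their potentially interacting partner set
#'
#' Returns the union of the partner sets of all query domains under the
#' given interaction map, sorted lexicographically. For the packaged S100B
#' fixture, the S100 domain (PF01023) contributes 9 partners, the EF-hand
#' domain (PF00036) contributes 27, and the union holds 32 unique
#' accessions.
#'
#' A query domain absent from the map is treated as having an empty partner
#' set, with a warning (not an error): bacterial screens routinely query
#' architectures whose domains have no structurally characterised partners.
#'
#' @param query_domains Character vector of Pfam accessions (may be empty).
#' @param map A `ddi_map`.
#' @return Sorted character vector of unique partner accessions, with a
#'   `provenance` attribute: a named list mapping each partner to the query
#'   domain(s) that contributed it.
#' @export
expand_partner_domains <- function(query_domains, map) {
  stopifnot(inherits(map, "ddi_map"))
  query_domains <- unique(as.character(query_domains))
  prov <- list()
  for (q in query_domains) {
    p <- map$edges[[q]]
    if (is.null(p)) {
      warning(sprintf(
        "query domain %s is absent from the interaction map; no partners", q))
      next
    }
    for (d in p) prov[[d]] <- sort(unique(c(prov[[d]], q)))
  }
  out <- if (length(prov)) sort(names(prov)) else character(0)
  attr(out, "provenance") <- prov[out]
  out
}

#' Write an expanded partner-domain list
#'
#' One row per partner accession with a provenance column listing the query
#' domain(s) that contributed it (comma-separated).
#'
#' @param partners Result of [expand_partner_domains()].
#' @param path Output TSV path.
#' @export
write_partner_list <- function(partners, path) {
  prov <- attr(partners, "provenance")
  contributed <- if (is.null(prov)) rep("", length(partners)) else
    vapply(as.character(partners),
           function(d) paste(prov[[d]] %||% character(0), collapse = ","),
           character(1L))
  write_tsv(data.frame(partner_acc = as.character(partners),
                       contributed_by = contributed,
                       stringsAsFactors = FALSE), path)
}
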