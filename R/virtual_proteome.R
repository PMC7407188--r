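# Per-group virtual metaproteomes: genus filtering, interactor screening
# and the cross-group Venn partition.

#' Construct a protein table
#'
#' In-memory constructor for the annotated bacterial protein table the
#' pipeline consumes: one row per protein with its genus of provenance, a
#' multiset of Pfam domain accessions, a set of GO term identifiers and an
#' optional localisation annotation. This is the "minimum annotation" a
#' UniProt taxonomic slice provides.
#'
#' @param accession Character vector of unique, non-empty accessions.
#' @param genus Character vector, non-empty genus names.
#' @param domains List of character vectors (duplicates allowed: a protein
#'   may carry several copies of the same domain).
#' @param go_terms List of character vectors of GO IDs.
#' @param localisation Optional list of character vectors.
#' @return A data frame of class `protein_table` with list columns
#'   `domains`, `go_terms` and `localisation`.
#' @export
protein_table <- function(accession, genus, domains = NULL, go_terms = NULL,
                          localisation = NULL) {
  n <- length(accession)
  accession <- as.character(accession)
  genus <- as.character(genus)
  if (n == 0L) {
    df <- data.frame(accession = character(0), genus = character(0),
                     stringsAsFactors = FALSE)
    df$domains <- list(); df$go_terms <- list(); df$localisation <- list()
    class(df) <- c("protein_table", "data.frame")
    return(df)
  }
  stopifnot(length(genus) == n)
  if (any(!nzchar(accession)) || anyNA(accession)) {
    stop("protein accessions must be non-empty")
  }
  if (any(!nzchar(genus)) || anyNA(genus)) stop("genus must be non-empty")
  dup <- unique(accession[duplicated(accession)])
  if (length(dup)) {
    stop(sprintf("duplicate protein accession(s): %s",
                 paste(utils::head(dup, 5L), collapse = ", ")))
  }
  empty <- replicate(n, character(0), simplify = FALSE)
  df <- data.frame(accession = accession, genus = genus,
                   stringsAsFactors = FALSE)
  df$domains <- domains %||% empty
  df$go_terms <- go_terms %||% empty
  df$localisation <- localisation %||% empty
  stopifnot(length(df$domains) == n, length(df$go_terms) == n)
  class(df) <- c("protein_table", "data.frame")
  df
}

#' Load an annotated protein table from TSV
#'
#' Expects a header `accession  genus  domains  go  location`; the `domains`
#' and `go` fields are pipe-separated lists and may be empty. `location` is
#' optional.
#'
#' @param input Path, text or lines.
#' @return A `protein_table` (see [protein_table()]).
#' @export
load_protein_table <- function(input) {
  lines <- read_text_lines(input)
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  mandatory <- c("accession", "genus", "domains", "go")
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    stop(sprintf("protein table is missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  loc <- if ("location" %in% names(df)) split_pipe(df$location) else NULL
  protein_table(df$accession, df$genus,
                domains = split_pipe(df$domains),
                go_terms = split_pipe(df$go),
                localisation = loc)
}

#' Write a protein table to TSV
#' @param records A `protein_table`.
#' @param path Output path.
#' @export
write_protein_table <- function(records, path) {
  out <- data.frame(
    accession = records$accession,
    genus = records$genus,
    domains = join_pipe(records$domains),
    go = join_pipe(records$go_terms),
    location = join_pipe(records$localisation),
    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Load per-group genus profiles
#'
#' TSV with header `group  genus` and an optional non-negative `abundance`
#' column (the genus-level output of a metataxonomic pipeline such as
#' QIIME2, collapsed per sample group).
#'
#' @param input Path, text or lines.
#' @return Named list of `taxon_profile` objects, one per group, each with
#'   `group`, `genera` (unique names) and `abundances` (named numeric or
#'   `NULL`).
#' @export
load_taxa_profiles <- function(input) {
  lines <- read_text_lines(input)
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("group", "genus") %in% names(df))) {
    stop("taxa profile table needs columns 'group' and 'genus'")
  }
  has_ab <- "abundance" %in% names(df)
  if (has_ab && any(!is.na(df$abundance) & df$abundance < 0)) {
    stop("abundances must be non-negative")
  }
  groups <- unique(as.character(df$group))
  out <- lapply(groups, function(g) {
    sub <- df[df$group == g, , drop = FALSE]
    genera <- as.character(sub$genus)
    if (anyDuplicated(genera)) {
      stop(sprintf("duplicated genus in profile for group %s", g))
    }
    ab <- NULL
    if (has_ab && !all(is.na(sub$abundance))) {
      ab <- stats::setNames(as.numeric(sub$abundance), genera)
    }
    taxon_profile(g, genera, ab)
  })
  stats::setNames(out, groups)
}

#' Construct a taxon profile
#' @param group Group label (e.g. "CT", "CD", "UC").
#' @param genera Character vector of genus names.
#' @param abundances Optional named non-negative numeric covering exactly
#'   `genera`.
#' @return A `taxon_profile` object.
#' @export
taxon_profile <- function(group, genera, abundances = NULL) {
  genera <- as.character(genera)
  if (!is.null(abundances)) {
    if (!setequal(names(abundances), genera)) {
      stop("abundances must cover exactly the listed genera")
    }
    if (any(abundances < 0)) stop("abundances must be non-negative")
  }
  structure(list(group = as.character(group), genera = genera,
                 abundances = abundances),
            class = "taxon_profile")
}

#' Build a group's virtual proteome by genus filtering
#'
#' Retains exactly the proteins whose genus matches a profile genus by
#' case-insensitive exact string equality — the virtual-metaproteome
#' construction step: the community's taxonomic signature selects, from the
#' reference protein table, the proteins the community could express.
#' Abundances, when present, are carried along but not used for filtering
#' or weighting (the screen is presence-based).
#'
#' @param records A `protein_table`.
#' @param profile A `taxon_profile`.
#' @return An object of class `virtual_proteome`: list with `group`,
#'   `records` (the retained `protein_table` rows), `n_proteins` and
#'   `n_genera` (distinct genera actually represented).
#' @export
build_virtual_proteome <- function(records, profile) {
  stopifnot(inherits(profile, "taxon_profile"))
  sel <- tolower(records$genus) %in% tolower(profile$genera)
  sub <- records[sel, , drop = FALSE]
  class(sub) <- c("protein_table", "data.frame")
  structure(
    list(group = profile$group, records = sub,
         n_proteins = nrow(sub),
         n_genera = length(unique(tolower(sub$genus)))),
    class = "virtual_proteome")
}

#' @export
print.virtual_proteome <- function(x, ...) {
  cat(sprintf("Virtual proteome '%s': %d proteins from %d genera\n",
              x$group, x$n_proteins, x$n_genera))
  invisible(x)
}

#' Screen a virtual proteome for potential interactors
#'
#' Retains the proteins carrying at least one domain from the partner set
#' (presence, not occurrence: a protein with several partner domains, or
#' several copies of one, is retained once).
#'
#' @param proteome A `virtual_proteome`.
#' @param partner_set Character vector of Pfam accessions, typically from
#'   [expand_partner_domains()].
#' @return An object of class `screen_result`: list with `group`,
#'   `retained` (sorted accessions) and `partner_set_used`.
#' @export
screen_interactors <- function(proteome, partner_set) {
  stopifnot(inherits(proteome, "virtual_proteome"))
  partner_set <- unique(as.character(partner_set))
  hit <- vapply(proteome$records$domains,
                function(d) any(d %in% partner_set), logical(1L))
  structure(
    list(group = proteome$group,
         retained = sort(proteome$records$accession[hit]),
         partner_set_used = sort(partner_set)),
    class = "screen_result")
}

#' Partition screened interactors across three groups
#'
#' Accession-identity Venn partition of the union of the three retained
#' sets into the 7 regions (each group alone, each pair alone, all three).
#'
#' @param screens List of exactly three `screen_result` objects with
#'   distinct group labels.
#' @return Object of class `group_partition`: list with `labels`,
#'   `region_counts` (named integer, 7 regions), `union_size` and
#'   `fractions` (region counts / union size; zero if the union is empty).
#' @export
partition_groups <- function(screens) {
  if (length(screens) != 3L) stop("exactly 3 group screens are required")
  labels <- vapply(screens, function(s) s$group, character(1L))
  if (anyDuplicated(labels)) stop("duplicate group labels in screens")
  sets <- lapply(screens, function(s) s$retained)
  all_acc <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_acc %in% s,
                   logical(length(all_acc)))
  if (length(all_acc) == 1L) member <- matrix(member, nrow = 1L)
  if (length(all_acc) == 0L) member <- matrix(logical(0), ncol = 3L)
  region_names <- c(paste0(labels, "_only"),
                    paste(labels[1L], labels[2L], sep = "_"),
                    paste(labels[1L], labels[3L], sep = "_"),
                    paste(labels[2L], labels[3L], sep = "_"),
                    paste(labels, collapse = "_"))
  patterns <- list(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                   c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                   c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
                   c(TRUE, TRUE, TRUE))
  counts <- vapply(patterns, function(p) {
    sum(member[, 1L] == p[1L] & member[, 2L] == p[2L] & member[, 3L] == p[3L])
  }, integer(1L))
  names(counts) <- region_names
  union_size <- length(all_acc)
  fractions <- if (union_size > 0L) counts / union_size else
    stats::setNames(rep(0, 7L), region_names)
  structure(list(labels = labels, region_counts = counts,
                 union_size = union_size, fractions = fractions),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf("Interactor partition over %s: %d unique accessions\n",
              paste(x$labels, collapse = "/"), x$union_size))
  for (r in names(x$region_counts)) {
    cat(sprintf("  %-12s %8d  (%s%%)\n", r, x$region_counts[[r]],
                fmt_pct1(x$fractions[[r]])))
  }
  invisible(x)
}

#' Write a screen result (one accession per line, sorted)
#' @param screen A `screen_result`.
#' @param path Output TSV path.
#' @export
write_screen_result <- function(screen, path) {
  write_tsv(data.frame(accession = screen$retained,
                       stringsAsFactors = FALSE), path)
}

#' Write a group partition report
#'
#' Counts plus percentages of the union rendered to 1 decimal place.
#'
#' @param partition A `group_partition`.
#' @param path Output TSV path.
#' @export
write_partition <- function(partition, path) {
  write_tsv(data.frame(
    region = names(partition$region_counts),
    count = as.integer(partition$region_counts),
    percent = fmt_pct1(partition$fractions),
    stringsAsFactors = FALSE), path)
}
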