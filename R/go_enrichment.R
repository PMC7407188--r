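# Gene-ontology machinery: OBO 1.2 subset reader, true-path-rule
# propagation, one-sided Fisher term tests and per-namespace enrichment
# with Benjamini-Hochberg adjustment.

#' Parse a GO ontology in OBO 1.2 format (subset)
#'
#' Reads `[Term]` stanzas and their `id`, `name`, `namespace`, `is_a` and
#' `is_obsolete` tags; all other tags are ignored. The `is_a` graph must be
#' acyclic; a detected cycle aborts with one offending cycle listed.
#' Obsolete terms are kept (so they can be recognised) but carry no parents
#' and may not be annotated.
#'
#' @param input Path, text or lines.
#' @return Object of class `go_dag`: list with `terms` (data frame: `id`,
#'   `name`, `namespace`, `obsolete`), `parents` (named list of `is_a`
#'   parents) and `closure` (named list: each term's ancestors including
#'   itself, the sets the true-path rule propagates over).
#' @export
parse_obo <- function(input) {
  lines <- read_text_lines(input)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  in_term <- FALSE
  for (raw in lines) {
    line <- sub("\\s+$", "", raw)
    if (line == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(0), obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", line)) {          # [Typedef] or other stanza
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(line)) next
    if (grepl("^id:", line)) {
      cur$id <- trimws(sub("^id:", "", line))
    } else if (grepl("^name:", line)) {
      cur$name <- trimws(sub("^name:", "", line))
    } else if (grepl("^namespace:", line)) {
      cur$namespace <- trimws(sub("^namespace:", "", line))
    } else if (grepl("^is_a:", line)) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", line)))
      cur$parents <- c(cur$parents, tgt)
    } else if (grepl("^is_obsolete:", line)) {
      cur$obsolete <- grepl("true", line, fixed = TRUE)
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("no [Term] stanzas found in OBO input")
  ids <- names(terms)
  df <- data.frame(
    id = ids,
    name = vapply(terms, function(t) t$name %||% "", character(1L)),
    namespace = vapply(terms, function(t) t$namespace %||% "",
                       character(1L)),
    obsolete = vapply(terms, function(t) isTRUE(t$obsolete), logical(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  parents <- lapply(terms, function(t) {
    if (isTRUE(t$obsolete)) character(0) else
      unique(t$parents[t$parents %in% ids])
  })
  # Kahn topological sort to certify acyclicity; on failure report a cycle.
  indeg <- stats::setNames(lengths(parents), ids)
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) for (p in parents[[id]]) {
    children[[p]] <- c(children[[p]], id)
  }
  queue <- ids[indeg == 0L]
  order <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(ids)) {
    rem <- setdiff(ids, order)
    cyc <- find_one_cycle(parents, rem)
    stop(sprintf("is_a graph contains a cycle: %s",
                 paste(cyc, collapse = " -> ")))
  }
  closure <- stats::setNames(vector("list", length(ids)), ids)
  for (id in order) {
    anc <- unlist(closure[parents[[id]]], use.names = FALSE)
    closure[[id]] <- sort(unique(c(id, anc)))
  }
  # cross-namespace is_a links would break per-namespace enrichment
  for (id in ids) {
    ns <- df$namespace[df$id == id]
    for (p in parents[[id]]) {
      if (!identical(df$namespace[df$id == p], ns)) {
        warning(sprintf("is_a link %s -> %s crosses namespaces", id, p))
      }
    }
  }
  structure(list(terms = df, parents = parents, closure = closure),
            class = "go_dag")
}

# Walk parent links from any remaining node until one repeats.
#' @noRd
find_one_cycle <- function(parents, candidates) {
  v <- candidates[1L]
  path <- character(0)
  while (!(v %in% path)) {
    path <- c(path, v)
    nxt <- intersect(parents[[v]], candidates)
    v <- nxt[1L]
  }
  c(path[which(path == v):length(path)], v)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO DAG: %d terms (%d obsolete), %d is_a edges\n",
              nrow(x$terms), sum(x$terms$obsolete),
              sum(lengths(x$parents))))
  print(table(x$terms$namespace[!x$terms$obsolete]))
  invisible(x)
}

#' Propagate annotations under the true-path rule
#'
#' A protein annotated to a term is implicitly annotated to all its `is_a`
#' ancestors; this closes every protein's direct annotation set upward.
#' Annotations to unknown or obsolete terms are skipped with a warning (or
#' an error when `on_unknown = "error"`).
#'
#' @param dag A `go_dag`.
#' @param direct Named list: protein accession -> character vector of GO
#'   IDs.
#' @param on_unknown `"warn"` (default) or `"error"`.
#' @return Named list of the same shape, each set closed under ancestry
#'   (sorted, unique). Idempotent: propagating a propagated map is a
#'   no-op.
#' @export
propagate_true_path <- function(dag, direct, on_unknown = c("warn", "error")) {
  stopifnot(inherits(dag, "go_dag"))
  on_unknown <- match.arg(on_unknown)
  valid <- dag$terms$id[!dag$terms$obsolete]
  unknown_seen <- character(0)
  out <- lapply(direct, function(ts) {
    ts <- as.character(ts)
    bad <- setdiff(ts, valid)
    if (length(bad)) unknown_seen <<- unique(c(unknown_seen, bad))
    ts <- ts[ts %in% valid]
    if (!length(ts)) return(character(0))
    sort(unique(unlist(dag$closure[ts], use.names = FALSE)))
  })
  if (length(unknown_seen)) {
    msg <- sprintf("annotation(s) to unknown or obsolete term(s): %s",
                   paste(utils::head(unknown_seen, 5L), collapse = ", "))
    if (on_unknown == "error") stop(msg) else warning(msg)
  }
  out
}

#' One-sided Fisher exact test for term enrichment
#'
#' Tests over-representation of a GO term in a study set drawn from a
#' universe: the p-value is the hypergeometric upper tail
#' P(X >= observed) with X ~ Hypergeometric(annotated, universe -
#' annotated, study). Vectorised over its arguments.
#'
#' @param observed Proteins in the study set carrying the term.
#' @param study_size Study set size.
#' @param annotated Universe proteins carrying the term.
#' @param universe_size Universe size.
#' @return p-value(s) in `[0, 1]`.
#' @export
fisher_term_test <- function(observed, study_size, annotated,
                             universe_size) {
  if (any(universe_size < study_size)) {
    stop("universe must be at least as large as the study set")
  }
  if (any(annotated > universe_size)) {
    stop("annotated count exceeds universe size")
  }
  if (any(observed > pmin(study_size, annotated))) {
    stop("observed count exceeds min(study size, annotated)")
  }
  if (any(observed < 0) || any(annotated < 0)) {
    stop("counts must be non-negative")
  }
  stats::phyper(observed - 1, annotated, universe_size - annotated,
                study_size, lower.tail = FALSE)
}

#' GO enrichment of a screened interactor set
#'
#' "Classic" Fisher enrichment on true-path-propagated annotations: within
#' each namespace, the universe is the group's virtual proteome restricted
#' to proteins with at least one (propagated) annotation in that namespace
#' (configurable to the screened set itself via `universe`), the study set
#' is the screened interactors inside that universe, and every term
#' annotated to >= 1 universe protein is tested one-sidedly for
#' over-representation. Benjamini-Hochberg adjustment is applied within
#' each namespace independently.
#'
#' @param screen A `screen_result` (or a character vector of study
#'   accessions).
#' @param proteome The group's `virtual_proteome` (the annotation source
#'   and default universe).
#' @param dag A `go_dag`.
#' @param annotations Optional named list accession -> GO IDs (direct);
#'   defaults to the proteome records' `go_terms` column.
#' @param q_max Adjusted-p threshold for the `significant_q` flag
#'   (default 0.01).
#' @param p_max Raw-p threshold for the `significant_p` flag
#'   (default 0.01). Both flags are reported; neither filters rows.
#' @param universe `"proteome"` (default) or `"screened"`.
#' @return Data frame sorted by namespace, then p, then GO ID: `namespace`,
#'   `go_id`, `name`, `annotated`, `observed`, `expected`
#'   (= annotated x study/universe), `p`, `q`, `significant_q`,
#'   `significant_p`. Zero rows (with a warning) when the study is empty.
#' @export
enrich <- function(screen, proteome, dag, annotations = NULL, q_max = 0.01,
                   p_max = 0.01, universe = c("proteome", "screened")) {
  stopifnot(inherits(dag, "go_dag"))
  universe <- match.arg(universe)
  study_acc <- if (inherits(screen, "screen_result")) screen$retained
    else as.character(screen)
  if (is.null(annotations)) {
    stopifnot(inherits(proteome, "virtual_proteome"))
    annotations <- stats::setNames(proteome$records$go_terms,
                                   proteome$records$accession)
  }
  empty_out <- data.frame(
    namespace = character(0), go_id = character(0), name = character(0),
    annotated = integer(0), observed = integer(0), expected = numeric(0),
    p = numeric(0), q = numeric(0), significant_q = logical(0),
    significant_p = logical(0), stringsAsFactors = FALSE)
  if (!length(study_acc)) {
    warning("empty study set: no enrichment rows")
    return(empty_out)
  }
  prop <- propagate_true_path(dag, annotations)
  if (universe == "screened") prop <- prop[names(prop) %in% study_acc]
  term_ns <- stats::setNames(dag$terms$namespace, dag$terms$id)
  term_name <- stats::setNames(dag$terms$name, dag$terms$id)
  namespaces <- sort(unique(dag$terms$namespace[!dag$terms$obsolete]))
  blocks <- list()
  for (ns in namespaces) {
    ns_terms <- names(term_ns)[term_ns == ns]
    prop_ns <- lapply(prop, function(ts) ts[ts %in% ns_terms])
    has_ns <- lengths(prop_ns) > 0L
    universe_acc <- names(prop_ns)[has_ns]
    if (!length(universe_acc)) next
    study_ns <- intersect(study_acc, universe_acc)
    ann_u <- table(unlist(prop_ns[universe_acc], use.names = FALSE))
    obs_s <- table(unlist(prop_ns[study_ns], use.names = FALSE))
    terms_here <- sort(names(ann_u))
    annotated <- as.integer(ann_u[terms_here])
    observed <- as.integer(obs_s[terms_here])
    observed[is.na(observed)] <- 0L
    n_u <- length(universe_acc)
    n_s <- length(study_ns)
    p <- fisher_term_test(observed, n_s, annotated, n_u)
    q <- stats::p.adjust(p, method = "BH")
    block <- data.frame(
      namespace = ns, go_id = terms_here,
      name = unname(term_name[terms_here]),
      annotated = annotated, observed = observed,
      expected = annotated * n_s / n_u,
      p = p, q = q,
      significant_q = q <= q_max,
      significant_p = p < p_max,
      stringsAsFactors = FALSE)
    block <- block[order(block$p, block$go_id), , drop = FALSE]
    blocks[[ns]] <- block
  }
  if (!length(blocks)) return(empty_out)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Write an enrichment table
#' @param rows Output of [enrich()].
#' @param path Output TSV path.
#' @export
write_enrichment <- function(rows, path) {
  write_tsv(rows, path)
}
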