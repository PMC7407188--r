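# End-to-end orchestration: config reading, staged execution with
# stage-named failures and partial-output cleanup, deterministic report
# writers and a machine-readable run manifest.

pipeline_defaults <- function() {
  list(
    query_domtblout = NULL, query_domains = NULL,
    interactions = NULL, proteins = NULL, taxa = NULL, obo = NULL,
    evalue_max = 0.01, alpha_sig = 0.01, ns_threshold = 0.5,
    near_zero_min = 10, df_mode = "k_minus_1",
    background_mode = "pooled", background_counts = NULL,
    q_max = 0.01, p_max = 0.01,
    out_dir = "ddiscreen_out", log_level = "info", seed = 1L)
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; every threshold is explicit and unknown keys are
#' rejected. Keys: `query_domtblout` or `query_domains`, `interactions`,
#' `proteins`, `taxa`, `obo`, `evalue_max`, `alpha_sig`, `ns_threshold`,
#' `near_zero_min`, `df_mode` (`k_minus_1`/`k`), `background_mode`
#' (`pooled`/`external`), `background_counts` (TSV `domain  count  size`),
#' `q_max`, `p_max`, `out_dir`, `log_level`, `seed`.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file's values.
#' @return Validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user[names(overrides)] <- overrides
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(user)] <- user
  for (key in c("alpha_sig", "ns_threshold", "q_max", "p_max",
                "evalue_max")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v <= 0 || (key != "evalue_max" && v >= 1)) {
      stop(sprintf("config key %s must lie in (0, 1)", key))
    }
  }
  if (cfg$near_zero_min < 0) stop("near_zero_min must be >= 0")
  if (!cfg$df_mode %in% c("k_minus_1", "k")) {
    stop("df_mode must be 'k_minus_1' or 'k'")
  }
  if (!cfg$background_mode %in% c("pooled", "external")) {
    stop("background_mode must be 'pooled' or 'external'")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the whole screening pipeline
#'
#' Executes every stage in order — query-domain expansion, virtual-proteome
#' construction, interactor screening, cross-group partition, per-domain
#' occurrence statistics, GO enrichment — and writes one report per stage
#' plus a run manifest (`manifest.json`: input MD5 hashes, configuration,
#' package and R versions, timestamp). A stage failure aborts with an error
#' naming the stage and removes any partial outputs of this run.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]).
#' @return Invisibly, a list with all intermediate objects (`partners`,
#'   `proteomes`, `screens`, `partition`, `occurrence`, `domain_results`,
#'   `enrichment`) and the written file paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(path) {
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  partners <- stage("expand", {
    query <- if (!is.null(config$query_domtblout)) {
      hits <- parse_hmmscan_domtblout(config$query_domtblout,
                                      evalue_max = config$evalue_max)
      unique(hits$domain_accession)
    } else if (!is.null(config$query_domains)) {
      unlist(config$query_domains)
    } else stop("either query_domtblout or query_domains is required")
    map <- parse_interaction_table(config$interactions)
    p <- expand_partner_domains(query, map)
    write_partner_list(p, note(file.path(out_dir, "partner_domains.tsv")))
    p
  })

  built <- stage("build-proteome", {
    records <- load_protein_table(config$proteins)
    profiles <- load_taxa_profiles(config$taxa)
    proteomes <- lapply(profiles, function(pr) {
      build_virtual_proteome(records, pr)
    })
    list(records = records, proteomes = proteomes)
  })
  proteomes <- built$proteomes

  screens <- stage("screen", {
    s <- lapply(proteomes, screen_interactors,
                partner_set = as.character(partners))
    summary <- data.frame(
      group = names(proteomes),
      n_proteins = vapply(proteomes, function(p) p$n_proteins, integer(1L)),
      n_genera = vapply(proteomes, function(p) p$n_genera, integer(1L)),
      n_interacting = vapply(s, function(x) length(x$retained),
                             integer(1L)),
      stringsAsFactors = FALSE)
    write_tsv(summary, note(file.path(out_dir, "proteome_summary.tsv")))
    for (g in names(s)) {
      write_screen_result(
        s[[g]], note(file.path(out_dir, sprintf("screen_%s.tsv", g))))
    }
    s
  })

  partition <- stage("partition", {
    if (length(screens) == 3L) {
      p <- partition_groups(unname(screens))
      write_partition(p, note(file.path(out_dir, "partition.tsv")))
      p
    } else NULL
  })

  dom <- stage("domain-stats", {
    bg_counts <- NULL
    bg_size <- NULL
    if (config$background_mode == "external") {
      bg <- utils::read.delim(config$background_counts,
                              stringsAsFactors = FALSE)
      bg_counts <- stats::setNames(bg$count, bg$domain)
      bg_size <- bg$size[1L]
    }
    tab <- build_occurrence_table(
      proteomes, as.character(partners),
      background = config$background_mode,
      background_counts = bg_counts, background_size = bg_size)
    results <- classify_domain_rows(
      tab, alpha_sig = config$alpha_sig,
      ns_threshold = config$ns_threshold,
      near_zero_min = config$near_zero_min, df_mode = config$df_mode)
    write_domain_stats(tab, results,
                       note(file.path(out_dir, "domain_stats.tsv")))
    list(table = tab, results = results)
  })

  enrichment <- if (is.null(config$obo)) NULL else stage("go-enrich", {
    dag <- parse_obo(config$obo)
    res <- list()
    for (g in names(proteomes)) {
      rows <- if (length(screens[[g]]$retained)) {
        enrich(screens[[g]], proteomes[[g]], dag,
               q_max = config$q_max, p_max = config$p_max)
      } else {
        data.frame(namespace = character(0), go_id = character(0),
                   name = character(0), annotated = integer(0),
                   observed = integer(0), expected = numeric(0),
                   p = numeric(0), q = numeric(0),
                   significant_q = logical(0), significant_p = logical(0),
                   stringsAsFactors = FALSE)
      }
      write_enrichment(
        rows, note(file.path(out_dir, sprintf("go_enrichment_%s.tsv", g))))
      res[[g]] <- rows
    }
    res
  })

  manifest <- stage("manifest", {
    inputs <- c(query_domtblout = config$query_domtblout,
                interactions = config$interactions,
                proteins = config$proteins, taxa = config$taxa,
                obo = config$obo,
                background_counts = config$background_counts)
    inputs <- inputs[!vapply(inputs, is.null, logical(1L))]
    hashes <- vapply(unlist(inputs), function(f) {
      unname(tools::md5sum(f))
    }, character(1L))
    m <- list(
      package = "ddiscreen",
      version = as.character(utils::packageVersion("ddiscreen")),
      r_version = R.version.string,
      config = unclass(config)[!vapply(unclass(config), is.null,
                                       logical(1L))],
      input_md5 = as.list(hashes),
      outputs = basename(written),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    m
  })

  invisible(list(partners = partners, records = built$records,
                 proteomes = proteomes, screens = screens,
                 partition = partition, occurrence = dom$table,
                 domain_results = dom$results, enrichment = enrichment,
                 manifest = manifest,
                 files = c(written, file.path(out_dir, "manifest.json"))))
}
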