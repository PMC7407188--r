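# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
read_text_lines <- function(input) {
  if (inherits(input, "connection")) return(readLines(input, warn = FALSE))
  input <- as.character(input)
  if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
      file.exists(input)) {
    return(readLines(input, warn = FALSE))
  }
  if (length(input) == 1L) return(strsplit(input, "\n", fixed = TRUE)[[1L]])
  input
}

#' @noRd
is_pfam_accession <- function(x) grepl("^PF[0-9]{5}$", x)

# "a|b|c" -> c("a","b","c"); "" or NA -> character(0)
#' @noRd
split_pipe <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, "|", fixed = TRUE)[[1L]]
  })
}

#' @noRd
join_pipe <- function(lst) {
  vapply(lst, paste, character(1L), collapse = "|")
}

# Deterministic TSV writer: no quoting, no row names, "." decimal.
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @noRd
fmt_pct1 <- function(x) sprintf("%.1f", 100 * x)
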