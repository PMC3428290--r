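# Tabular output: TSV with a header line, preceded by '#'-prefixed
# provenance comments. Numbers are fixed to 6 significant digits so
# re-running an identical configuration reproduces byte-identical files.

#' Write a data.frame as TSV with provenance comments
#'
#' @param df data.frame; numeric columns are formatted to 6 significant
#'   digits (`Inf` rendered as `inf`).
#' @param path output path.
#' @param comments character vector of provenance lines (written with a
#'   leading `# `), e.g. the generating parameters and seed.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comments = character(0)) {
  df <- as.data.frame(df)
  df$present <- NULL # per-frame logical list column is not tabular
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) {
      v <- df[[cn]]
      out <- ifelse(is.infinite(v), ifelse(v > 0, "inf", "-inf"),
        formatC(signif(v, 6), format = "g", digits = 6)
      )
      out[is.na(v)] <- "NA"
      df[[cn]] <- out
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0) {
    writeLines(paste0("# ", comments), con)
  }
  utils::write.table(df, con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame (comment lines skipped, `inf` restored to `Inf`).
#' @export
read_tsv <- function(path) {
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, comment.char = "#",
    stringsAsFactors = FALSE
  )
  for (cn in names(df)) {
    if (is.character(df[[cn]]) && all(df[[cn]] %in%
      c("inf", "-inf", "NA") | !is.na(suppressWarnings(as.numeric(df[[cn]]))))) {
      v <- df[[cn]]
      v[v == "inf"] <- "Inf"
      v[v == "-inf"] <- "-Inf"
      df[[cn]] <- as.numeric(v)
    }
  }
  df
}
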