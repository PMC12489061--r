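#' Write a `#`-prefixed provenance header
#'
#' All tabular outputs of the pipeline start with comment lines recording the
#' package version and the parameters of the run, so any output can be traced
#' back to its configuration.
#'
#' @param path File to create/overwrite.
#' @param ... `key = value` pairs to record (vectors are comma-joined).
#' @return `path`, invisibly.
#' @keywords internal
write_provenance_header <- function(path, ...) {
  fields <- list(...)
  lines <- c(
    sprintf("# paralogrisk %s", as.character(packageVersion("paralogrisk"))),
    sprintf("# date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  for (k in names(fields)) {
    v <- fields[[k]]
    if (is.null(v)) next
    lines <- c(lines, sprintf("# %s: %s", k, paste(format(v), collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

append_tsv <- function(df, path) {
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Write a data frame as TSV with a provenance header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param ... Provenance `key = value` pairs.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(df, path, ...) {
  write_provenance_header(path, ...)
  append_tsv(df, path)
}
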