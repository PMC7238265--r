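#' Read a flat key/value configuration file
#'
#' The configuration dialect is one `key = value` pair per line with dotted
#' namespaces (`pk.bud.Vc = 216`). Blank lines and lines starting with `#`
#' are ignored; values are numeric where they parse as numbers, otherwise
#' kept as strings.
#'
#' @param path Path to the config file.
#' @return A named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line (no '='): ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (!nzchar(key)) stop("malformed config line (empty key): ", ln)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a flat key/value configuration file
#'
#' @param config Named list of scalar values.
#' @param path Output path.
#' @param header Optional comment lines written at the top.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path, header = NULL) {
  stopifnot(is.list(config), !is.null(names(config)), all(nzchar(names(config))))
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }, character(1))
  lines <- paste(names(config), "=", vals)
  if (!is.null(header)) lines <- c(paste("#", header), lines)
  writeLines(lines, path)
  invisible(path)
}
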