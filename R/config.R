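# Plain-text structured configuration: INI-style sections.  A section whose
# lines contain "=" becomes a named list (values auto-typed); otherwise the
# section is a character vector of items.  "#" starts a comment.

#' Read an INI-style plain-text configuration file
#'
#' Sections are introduced by `[name]`.  Lines of the form `key = value`
#' yield a named list for the section (numbers and TRUE/FALSE auto-typed,
#' comma-separated values become vectors); bare lines yield a character
#' vector of items.  `#` starts a comment; blank lines are ignored.
#'
#' @param path file path.
#' @return named list of sections.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (is.null(out[[section]])) out[[section]] <- character(0)
      next
    }
    if (is.null(section))
      stop("config line outside any [section]: ", ln, call. = FALSE)
    if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (is.character(out[[section]]) && length(out[[section]]) == 0L)
        out[[section]] <- list()
      out[[section]][[key]] <- .autotype(val)
    } else {
      out[[section]] <- c(out[[section]], ln)
    }
  }
  out
}

.autotype <- function(v) {
  parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) return("")
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) return(num)
  lg <- toupper(parts)
  if (all(lg %in% c("TRUE", "FALSE"))) return(lg == "TRUE")
  if (length(parts) == 1L) parts[[1L]] else parts
}
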