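#' @import data.table
#' @importFrom stats quantile rbinom rlnorm runif setNames rnorm
#' @importFrom utils head tail
NULL

# Quarterly FAERS ASCII dialect: "$"-delimited, single header row, no quoting,
# UTF-8 (bad bytes replaced).  Only the PRIMARYID-era schema is supported;
# legacy ISR-keyed files (pre-2012Q3) are out of scope.

.FAERS_PREFIXES <- c("DEMO", "DRUG", "REAC", "THER", "OUTC", "INDI", "RPSR")
.FAERS_MANDATORY <- c("DEMO", "DRUG", "REAC")

# canonical (lower-case) columns retained per dataset; extra columns are
# preserved by the reader but ignored by the analysis
.FAERS_COLUMNS <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "occp_cod",
           "reporter_country", "age", "age_cod"),
  drug = c("primaryid", "drug_seq", "drugname", "role_cod"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
  outc = c("primaryid", "outc_cod"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt"),
  rpsr = c("primaryid", "rpsr_cod")
)

# legacy header aliases, matched case-insensitively
.FAERS_ALIASES <- c(gndr_cod = "sex", drugname_text = "drugname")

#' Parse FAERS partial date strings
#'
#' FAERS date fields hold `YYYYMMDD`, but truncated (`YYYYMM`, `YYYY`),
#' empty, or garbage values occur.  This is a total function: no input
#' throws; anything that does not resolve to at least a calendar-valid year
#' yields all-`NA` components.
#'
#' @param x character vector of raw date strings.
#' @return a `data.table` with integer columns `year`, `month`, `day`
#'   (`NA` where the component is absent or the value is invalid), one row
#'   per element of `x`.
#' @examples
#' faers_parse_date(c("20200213", "202002", "2020", "00000000", ""))
#' @export
faers_parse_date <- function(x) {
  x <- trimws(as.character(x))
  n <- length(x)
  year <- month <- day <- rep(NA_integer_, n)

  digits <- grepl("^[0-9]+$", x)
  nc <- nchar(x)

  y4 <- digits & nc == 4L
  y6 <- digits & nc == 6L
  y8 <- digits & nc == 8L

  year[y4] <- as.integer(x[y4])
  year[y6] <- as.integer(substr(x[y6], 1L, 4L))
  month[y6] <- as.integer(substr(x[y6], 5L, 6L))
  year[y8] <- as.integer(substr(x[y8], 1L, 4L))
  month[y8] <- as.integer(substr(x[y8], 5L, 6L))
  day[y8] <- as.integer(substr(x[y8], 7L, 8L))

  bad_year <- !is.na(year) & (year < 1900L | year > 2100L)
  year[bad_year] <- NA_integer_
  bad_month <- is.na(year) | (!is.na(month) & (month < 1L | month > 12L))
  month[bad_month] <- NA_integer_

  # day validity checked against the real calendar
  has_day <- !is.na(day) & !is.na(month)
  if (any(has_day)) {
    iso <- sprintf("%04d-%02d-%02d", year[has_day], month[has_day], day[has_day])
    ok <- !is.na(as.Date(iso, format = "%Y-%m-%d"))
    day[has_day][!ok] <- NA_integer_
  }
  day[is.na(month)] <- NA_integer_

  data.table(year = year, month = month, day = day)
}

# integer day count (epoch-based) for full dates only; NA otherwise
.date_to_days <- function(pd) {
  out <- rep(NA_integer_, nrow(pd))
  full <- !is.na(pd$year) & !is.na(pd$month) & !is.na(pd$day)
  if (any(full)) {
    iso <- sprintf("%04d-%02d-%02d", pd$year[full], pd$month[full], pd$day[full])
    out[full] <- as.integer(as.Date(iso, format = "%Y-%m-%d"))
  }
  out
}

# sortable numeric key for possibly-partial dates: YYYYMMDD with missing
# components as 00, so "2020" sorts before any dated 2020 record
.date_sort_key <- function(pd) {
  ifelse(is.na(pd$year), NA_real_,
         pd$year * 10000 +
           ifelse(is.na(pd$month), 0, pd$month) * 100 +
           ifelse(is.na(pd$day), 0, pd$day))
}

# Read one "$"-delimited file.  Malformed rows (more fields than the header)
# are counted, not silently dropped; short rows are padded with "".
.read_dollar_file <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- iconv(raw, from = "UTF-8", to = "UTF-8", sub = "�")
  if (length(raw) == 0L || !nzchar(trimws(raw[1L])))
    stop("unparseable header in ", basename(path), call. = FALSE)
  header <- strsplit(raw[1L], "$", fixed = TRUE)[[1L]]
  header <- tolower(trimws(header))
  if (any(!nzchar(header)) || anyDuplicated(header))
    stop("unparseable header in ", basename(path), call. = FALSE)
  ncol <- length(header)

  body <- raw[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    tab <- as.data.table(setNames(rep(list(character(0)), ncol), header))
    attr(tab, "n_malformed") <- 0L
    return(tab)
  }
  fields <- strsplit(body, "$", fixed = TRUE)
  lens <- lengths(fields)
  bad <- lens > ncol
  fields <- fields[!bad]
  lens <- lens[!bad]
  # pad trailing empties dropped by strsplit
  cells <- character(length(fields) * ncol)
  dim(cells) <- c(length(fields), ncol)
  cells[] <- ""
  for (j in seq_len(ncol)) {
    has <- lens >= j
    cells[has, j] <- vapply(fields[has], `[[`, "", j)
  }
  tab <- as.data.table(setNames(lapply(seq_len(ncol), function(j) cells[, j]),
                                header))
  attr(tab, "n_malformed") <- sum(bad)
  tab
}

.locate_quarter_files <- function(dir_or_files) {
  if (length(dir_or_files) == 1L && dir.exists(dir_or_files)) {
    files <- list.files(dir_or_files, full.names = TRUE)
  } else {
    files <- dir_or_files
  }
  files <- files[file.exists(files)]
  out <- list()
  for (p in .FAERS_PREFIXES) {
    hit <- files[startsWith(toupper(basename(files)), p)]
    if (length(hit)) out[[tolower(p)]] <- sort(hit)
  }
  out
}

.canonicalize <- function(tab, dataset) {
  nm <- names(tab)
  ali <- .FAERS_ALIASES[nm]
  nm[!is.na(ali)] <- ali[!is.na(ali)]
  setnames(tab, nm)
  want <- .FAERS_COLUMNS[[dataset]]
  for (w in want) if (!w %in% names(tab)) tab[, (w) := ""]
  tab
}

#' Read a FAERS-format quarterly file set
#'
#' Loads the `"$"`-delimited ASCII datasets of one or more quarters into
#' typed tables.  Files are matched by name prefix (`DEMO*`, `DRUG*`,
#' `REAC*`, `THER*`, `OUTC*`, `INDI*`, `RPSR*`); several files with the same
#' prefix (multiple quarters) are stacked in file-name order, so record
#' source order is stable across re-reads.  `DEMO`, `DRUG` and `REAC` are
#' mandatory.  Column names are matched case-insensitively; unknown extra
#' columns are carried along but ignored.  Rows with more `$`-separated
#' fields than the header are counted as malformed and reported via
#' `attr(, "malformed")` and a message — never silently dropped without
#' trace.
#'
#' @param dir_or_files a directory containing the quarterly files, or an
#'   explicit character vector of file paths.
#' @return an object of class `faers_tables`: a list with `data.table`
#'   elements `demo`, `drug`, `reac` (always) and `ther`, `outc`, `indi`,
#'   `rpsr` (when present), plus attributes `malformed` (named integer
#'   vector of malformed-row counts) and `files`.
#' @export
faers_read_quarter <- function(dir_or_files) {
  found <- .locate_quarter_files(dir_or_files)
  missing <- setdiff(tolower(.FAERS_MANDATORY), names(found))
  if (length(missing))
    stop("missing mandatory FAERS file(s): ",
         paste(toupper(missing), collapse = ", "), call. = FALSE)

  tables <- list()
  malformed <- integer(0)
  for (ds in names(found)) {
    parts <- lapply(found[[ds]], .read_dollar_file)
    nbad <- sum(vapply(parts, attr, 0L, "n_malformed"))
    tab <- rbindlist(parts, use.names = TRUE, fill = TRUE)
    for (j in names(tab)) if (!is.character(tab[[j]])) tab[[j]] <- as.character(tab[[j]])
    tab <- .canonicalize(tab, ds)
    tables[[ds]] <- tab
    malformed[[ds]] <- nbad
    if (nbad > 0L)
      message(sprintf("faers_read_quarter: %d malformed row(s) in %s", nbad,
                      toupper(ds)))
  }
  if (anyDuplicated(tables$demo$primaryid))
    warning("duplicate PRIMARYID within loaded DEMO data", call. = FALSE)
  structure(tables,
            class = "faers_tables",
            malformed = malformed,
            files = found)
}

#' @export
print.faers_tables <- function(x, ...) {
  cat("<faers_tables>\n")
  for (ds in names(x))
    cat(sprintf("  %-5s %8d rows\n", toupper(ds), nrow(x[[ds]])))
  mb <- attr(x, "malformed")
  if (!is.null(mb) && sum(mb) > 0)
    cat("  malformed rows:", sum(mb), "\n")
  invisible(x)
}
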