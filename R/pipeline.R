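# End-to-end orchestration: ingest -> dedup -> cohort -> disproportionality
# -> time-to-onset/descriptives, with a machine-readable manifest and
# per-stage stderr logging.  Also the command-line entry point.

#' Build and validate a pipeline run configuration
#'
#' Exactly one input source must be given: a directory of FAERS-format
#' quarterly files, or a simulation config (the pipeline then generates its
#' own input in memory).
#'
#' @param input_dir directory with quarterly files, or `NULL`.
#' @param simulate a [faers_sim_config()], or `NULL`.
#' @param lexicon_path drug-lexicon configuration file.
#' @param target_pts target preferred terms.
#' @param output_dir where result tables, figures and the manifest go;
#'   `NULL` for in-memory results only.
#' @param unit counting unit for contingency tables (`"report"`/`"pair"`).
#' @param precedence regimen precedence order.
#' @param chi_correct Yates correction for subgroup chi-square tests?
#' @param quantile_type onset quantile rule.
#' @param z CI quantile constant.
#' @param figures write figure files (forest plot, onset CDF, outcome
#'   bars)?  Requires `output_dir`.
#' @param seed integer seed (used only as metadata in file mode; in
#'   simulate mode the simulation config's own seed governs).
#' @return list of class `run_config`.
#' @export
faers_run_config <- function(input_dir = NULL, simulate = NULL,
                             lexicon_path = system.file(
                               "extdata", "bv_lexicon.cfg",
                               package = "faersignal"),
                             target_pts = default_target_pts(),
                             output_dir = NULL,
                             unit = c("report", "pair"),
                             precedence = .DEFAULT_PRECEDENCE,
                             chi_correct = FALSE,
                             quantile_type = 7L,
                             z = 1.96,
                             figures = FALSE,
                             seed = 1L) {
  if (is.null(input_dir) == is.null(simulate))
    stop("run config: exactly one of input_dir or simulate must be set",
         call. = FALSE)
  structure(list(input_dir = input_dir, simulate = simulate,
                 lexicon_path = lexicon_path, target_pts = target_pts,
                 output_dir = output_dir, unit = match.arg(unit),
                 precedence = precedence, chi_correct = chi_correct,
                 quantile_type = as.integer(quantile_type), z = z,
                 figures = figures, seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, in_n, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  out_n <- attr(res, "out_n")
  message(sprintf("[stage %s] in=%s out=%s elapsed=%.2fs", name,
                  in_n, if (is.null(out_n)) "-" else out_n,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' Executes ingest, dedup, cohort construction, disproportionality
#' analysis and time-to-onset/descriptive summaries, logging one
#' machine-parsable line per stage to stderr.  With an `output_dir` it
#' writes tab-delimited result tables, optional figures and a JSON run
#' manifest (configuration echo, package version, seed, analysis decisions
#' in effect) sufficient to re-run bit-identically in simulate mode.
#'
#' @param config a [faers_run_config()].
#' @return list with `flow` (flow-count table mirroring the selection
#'   diagram), `signals`, `comparisons` (chi-square vs the monotherapy
#'   group), `cohort_summary`, `onset` (records), `onset_summaries`
#'   (overall and per regimen), `manifest`, and in simulate mode `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lexicon <- read_drug_lexicon(config$lexicon_path)

  truth <- NULL
  tables <- .stage("ingest", "-", {
    if (!is.null(config$simulate)) {
      sim <- faers_simulate(config$simulate)
      truth <- sim$truth
      tb <- sim$tables
    } else {
      tb <- faers_read_quarter(config$input_dir)
    }
    attr(tb, "out_n") <- nrow(tb$demo)
    tb
  })
  rows_read <- nrow(tables$demo)

  dd <- .stage("dedup", rows_read, {
    r <- faers_dedup(tables$demo)
    attr(r, "out_n") <- nrow(r$kept)
    r
  })
  tables$demo <- dd$kept

  ch <- .stage("cohort", nrow(dd$kept), {
    r <- build_cohort(tables, lexicon = lexicon,
                      target_pts = config$target_pts,
                      precedence = config$precedence)
    attr(r, "out_n") <- nrow(r$cohort)
    r
  })
  cohort <- ch$cohort
  target_cohort <- cohort[is_target == TRUE]

  signals <- .stage("signal_stats", nrow(cohort), {
    r <- signal_table(cohort, ch$background, z = config$z,
                      unit = config$unit, reac = tables$reac,
                      target_pts = config$target_pts)
    attr(r, "out_n") <- nrow(r)
    r
  })

  comparisons <- .stage("subgroup_tests", nrow(signals), {
    mono <- signals[group == "MONO"]
    rows <- list()
    if (nrow(mono) == 1L && mono$a + mono$b > 0) {
      tm <- list(a = mono$a, b = mono$b, c = mono$c, d = mono$d)
      for (g in setdiff(signals$group, c("ALL", "MONO"))) {
        s <- signals[group == g]
        # skip degenerate 2x2s (an empty group or event margin)
        if (s$a + s$b == 0 || s$a + tm$a == 0 || s$b + tm$b == 0) next
        tg <- list(a = s$a, b = s$b, c = s$c, d = s$d)
        cmp <- suppressWarnings(
          compare_groups(tg, tm, correct = config$chi_correct))
        rows[[g]] <- data.table(group = g, reference = "MONO",
                                chi2 = cmp$chi2, p_value = cmp$p_value,
                                low_expected = cmp$low_expected)
      }
    }
    r <- if (length(rows)) rbindlist(rows) else
      data.table(group = character(0), reference = character(0),
                 chi2 = numeric(0), p_value = numeric(0),
                 low_expected = logical(0))
    attr(r, "out_n") <- nrow(r)
    r
  })

  onset <- .stage("time_to_onset", nrow(target_cohort), {
    r <- compute_onset(cohort, tables, lexicon = lexicon)
    attr(r, "out_n") <- sum(!is.na(r$onset_days))
    r
  })
  onset_summaries <- c(
    list(ALL = summarize_onset(onset, quantile_type = config$quantile_type)),
    lapply(setNames(.REGIMEN_LEVELS, .REGIMEN_LEVELS), function(l)
      summarize_onset(onset, group = l,
                      quantile_type = config$quantile_type)))

  cohort_summary <- .stage("descriptives", nrow(target_cohort), {
    r <- summarize_cohort(target_cohort, outc = tables$outc,
                          indi = tables$indi)
    attr(r, "out_n") <- nrow(r)
    r
  })

  flow <- .flow_counts(rows_read, dd, cohort, target_cohort)
  manifest <- .build_manifest(config)

  res <- list(flow = flow, signals = signals, comparisons = comparisons,
              cohort_summary = cohort_summary, onset = onset,
              onset_summaries = onset_summaries, manifest = manifest,
              truth = truth)
  if (!is.null(config$output_dir))
    .write_outputs(res, config)
  invisible(res)
}

.flow_counts <- function(rows_read, dd, cohort, target_cohort) {
  per_reg <- table(cohort$regimen)
  per_reg_t <- table(target_cohort$regimen)
  data.table(
    step = c("rows_read", "unique_after_dedup", "index_reports",
             "target_event_reports",
             paste0("index_", names(per_reg)),
             paste0("target_", names(per_reg_t))),
    n = c(rows_read, nrow(dd$kept), nrow(cohort), nrow(target_cohort),
          as.integer(per_reg), as.integer(per_reg_t)))
}

.serialize_sim_config <- function(sc) {
  if (is.null(sc)) return(NULL)
  out <- unclass(sc)
  out$group_specs <- lapply(out$group_specs, unclass)
  out$outcome_probs <- as.list(out$outcome_probs)
  out
}

.build_manifest <- function(config) {
  list(
    package = "faersignal",
    version = as.character(utils::packageVersion("faersignal")),
    seed = config$seed,
    input = if (is.null(config$simulate)) list(mode = "files",
                                               dir = config$input_dir)
            else list(mode = "simulate",
                      config = .serialize_sim_config(config$simulate)),
    lexicon_path = config$lexicon_path,
    target_pts = config$target_pts,
    decisions = list(counting_unit = config$unit,
                     precedence = config$precedence,
                     chi_square_correction = config$chi_correct,
                     quantile_type = config$quantile_type,
                     z_quantile = config$z,
                     dedup_rule = "latest FDA_DT, then highest PRIMARYID",
                     zero_cells = "non-estimable (no continuity correction)")
  )
}

.write_outputs <- function(res, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$output_dir
  fwrite(res$flow, file.path(od, "flow_counts.tsv"), sep = "\t")
  fwrite(res$signals, file.path(od, "signal_table.tsv"), sep = "\t")
  fwrite(res$comparisons, file.path(od, "subgroup_tests.tsv"), sep = "\t")
  fwrite(res$cohort_summary, file.path(od, "cohort_summary.tsv"),
         sep = "\t")
  fwrite(res$onset, file.path(od, "onset_records.tsv"), sep = "\t")
  osum <- rbindlist(lapply(names(res$onset_summaries), function(g) {
    s <- res$onset_summaries[[g]]
    data.table(group = g, n_used = s$n_used, n_excluded = s$n_excluded,
               median_days = s$median_days, q1_days = s$q1_days,
               q3_days = s$q3_days)
  }))
  fwrite(osum, file.path(od, "onset_summary.tsv"), sep = "\t")
  cdf <- rbindlist(lapply(names(res$onset_summaries), function(g) {
    s <- res$onset_summaries[[g]]
    if (s$n_used == 0) return(NULL)
    data.table(group = g, s$cdf)
  }))
  if (!is.null(cdf) && nrow(cdf))
    fwrite(cdf, file.path(od, "onset_cdf.tsv"), sep = "\t")
  jsonlite::write_json(res$manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (isTRUE(config$figures)) .write_figures(res, od)
  invisible(od)
}

.write_figures <- function(res, od) {
  est <- res$signals[!is.na(ror)]
  if (nrow(est)) {
    grDevices::pdf(file.path(od, "forest_plot.pdf"), width = 6, height = 4)
    y <- rev(seq_len(nrow(est)))
    graphics::plot(est$ror, y, log = "x", pch = 15,
                   xlim = range(c(est$ci_low, est$ci_high, 1)),
                   ylim = c(0.5, nrow(est) + 0.5), yaxt = "n",
                   xlab = "ROR (log scale)", ylab = "",
                   main = "Reporting odds ratio by regimen")
    graphics::segments(est$ci_low, y, est$ci_high, y)
    graphics::abline(v = 1, lty = 2)
    graphics::axis(2, at = y, labels = est$group, las = 1, cex.axis = 0.7)
    grDevices::dev.off()
  }
  s <- res$onset_summaries$ALL
  if (s$n_used > 0) {
    grDevices::pdf(file.path(od, "onset_cdf.pdf"), width = 6, height = 4)
    graphics::plot(s$cdf$days, s$cdf$cum_frac, type = "s",
                   xlab = "days since therapy start",
                   ylab = "cumulative fraction",
                   main = "Time to onset, empirical CDF")
    grDevices::dev.off()
  }
  oc <- res$cohort_summary[characteristic == "Serious outcome" &
                             group != "Overall"]
  if (nrow(oc)) {
    m <- dcast(oc, category ~ group, value.var = "n", fill = 0)
    mat <- as.matrix(m[, -1]); rownames(mat) <- m$category
    grDevices::pdf(file.path(od, "outcome_bars.pdf"), width = 6, height = 4)
    graphics::barplot(mat, legend.text = rownames(mat),
                      main = "Serious outcomes by regimen", las = 2,
                      cex.names = 0.7)
    grDevices::dev.off()
  }
  invisible(od)
}

# ---- command-line interface -------------------------------------------------

.cli_flags <- function(args) {
  flags <- list()
  for (a in args) {
    if (!startsWith(a, "--")) next
    kv <- sub("^--", "", a)
    key <- gsub("-", "_", sub("=.*$", "", kv))
    val <- if (grepl("=", kv, fixed = TRUE)) sub("^[^=]*=", "", kv) else "TRUE"
    flags[[key]] <- .autotype(val)
  }
  flags
}

.sim_config_from_flags <- function(flags, file_cfg = list()) {
  take <- function(key, default) {
    if (!is.null(flags[[key]])) flags[[key]]
    else if (!is.null(file_cfg$simulation[[key]])) file_cfg$simulation[[key]]
    else default
  }
  groups <- .default_group_specs()
  gsec <- grep("^group\\.", names(file_cfg), value = TRUE)
  if (length(gsec)) {
    groups <- lapply(gsec, function(s) {
      g <- file_cfg[[s]]
      sim_group(sub("^group\\.", "", s), g$drugs,
                g$marginal_prob, if (is.null(g$multiplier)) 1 else
                  g$multiplier)
    })
  }
  faers_sim_config(
    n_reports = take("n_reports", 5000),
    baseline_event_prob = take("baseline_event_prob", 0.02),
    group_specs = groups,
    duplicate_rate = take("duplicate_rate", 0.15),
    partial_date_rate = take("partial_date_rate", 0.30),
    missing_event_date_rate = take("missing_event_date_rate", 0.30),
    onset_median_days = take("onset_median_days", 43),
    onset_dispersion = take("onset_dispersion", 4.5),
    seed = take("seed", 20230401))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic quarterly file set),
#' `ingest` (read + dedup, print flow counts), `analyze` (full pipeline on
#' a file set), `all` (simulate, then analyze the simulated files),
#' `report` (pretty-print the result tables of a previous run).  Flags are
#' `--key=value`; `--config=FILE` points at an INI-style file whose
#' `[simulation]` / `[group.*]` / `[run]` sections provide defaults that
#' flags override.
#'
#' @param args character vector of CLI arguments (defaults to the real
#'   command line).
#' @return exit status, invisibly.
#' @export
faers_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: faersignal <simulate|ingest|analyze|all|report> [--flags]\n")
    return(invisible(1L))
  }
  cmd <- args[[1L]]
  flags <- .cli_flags(args[-1L])
  file_cfg <- if (!is.null(flags$config)) read_config_file(flags$config)
              else list()
  get <- function(key, default = NULL) {
    if (!is.null(flags[[key]])) flags[[key]]
    else if (!is.null(file_cfg$run[[key]])) file_cfg$run[[key]]
    else default
  }

  if (cmd == "simulate") {
    out <- get("out"); if (is.null(out)) stop("simulate needs --out=DIR")
    sc <- .sim_config_from_flags(flags, file_cfg)
    truth <- faers_generate(sc, out)
    message("wrote ", length(attr(truth, "files")), " files to ", out)
    return(invisible(0L))
  }
  if (cmd == "ingest") {
    ind <- get("in"); if (is.null(ind)) stop("ingest needs --in=DIR")
    tb <- faers_read_quarter(ind)
    dd <- faers_dedup(tb$demo)
    cat(sprintf("rows_read\t%d\nunique_after_dedup\t%d\n",
                nrow(tb$demo), nrow(dd$kept)))
    out <- get("out")
    if (!is.null(out)) write_dedup_log(dd$decisions, out)
    return(invisible(0L))
  }
  if (cmd %in% c("analyze", "all")) {
    out <- get("out"); if (is.null(out)) stop(cmd, " needs --out=DIR")
    if (cmd == "all") {
      sc <- .sim_config_from_flags(flags, file_cfg)
      data_dir <- file.path(out, "data")
      faers_generate(sc, data_dir)
      ind <- data_dir
    } else {
      ind <- get("in"); if (is.null(ind)) stop("analyze needs --in=DIR")
    }
    rc <- faers_run_config(
      input_dir = ind,
      lexicon_path = get("lexicon", system.file("extdata", "bv_lexicon.cfg",
                                                package = "faersignal")),
      output_dir = file.path(out, "results"),
      unit = get("unit", "report"),
      chi_correct = isTRUE(get("chi_correct", FALSE)),
      quantile_type = get("quantile_type", 7),
      figures = isTRUE(get("figures", FALSE)),
      seed = get("seed", 1))
    run_pipeline(rc)
    message("results written to ", file.path(out, "results"))
    return(invisible(0L))
  }
  if (cmd == "report") {
    out <- get("out"); if (is.null(out)) stop("report needs --out=DIR")
    for (f in c("flow_counts.tsv", "signal_table.tsv", "onset_summary.tsv")) {
      p <- file.path(out, "results", f)
      if (!file.exists(p)) p <- file.path(out, f)
      if (file.exists(p)) {
        cat("==", f, "==\n")
        cat(readLines(p), sep = "\n")
        cat("\n")
      }
    }
    return(invisible(0L))
  }
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
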