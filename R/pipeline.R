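#' Pipeline configuration
#'
#' Paths and parameters for a full simulate/score/evaluate run.  When
#' `input` is `NULL` the periods are simulated from `sim`; otherwise they
#' are read from the CSV at `input`.
#'
#' @param out_dir Report directory (created if needed).
#' @param input Optional path to an existing period CSV.
#' @param sim An [sim_config()]; used only when `input` is `NULL`.
#' @param scoring An [score_config()].
#' @param likert_threshold Overcrowding reference-standard threshold,
#'   2..6.
#' @param ci_method AUC CI method, see [roc_auc()].
#' @param verbose Log progress to stderr.
#' @return A list of class `ed_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input = NULL, sim = sim_config(),
                            scoring = score_config(),
                            likert_threshold = 5,
                            ci_method = "hanley", verbose = TRUE) {
  if (!is.null(input) && identical(normalizePath(input, mustWork = FALSE),
                                   normalizePath(out_dir, mustWork = FALSE))) {
    stop("input and output paths must be distinct", call. = FALSE)
  }
  stopifnot(inherits(sim, "ed_sim_config"),
            inherits(scoring, "ed_score_config"))
  if (!(likert_threshold %in% 2:6)) {
    stop("likert_threshold must be in 2..6", call. = FALSE)
  }
  structure(list(out_dir = out_dir, input = input, sim = sim,
                 scoring = scoring, likert_threshold = likert_threshold,
                 ci_method = ci_method, verbose = verbose),
            class = "ed_pipeline_config")
}

#' Run the full crowding-evaluation pipeline
#'
#' Simulate (or read) the period table, score every period, evaluate the
#' scores against perception and adverse events, and write the report
#' bundle to `config$out_dir`: `periods.csv`, `scores.csv`, `table1.csv`,
#' `table2.csv`, `table3.csv`, `correlations.csv`, one `roc_<score>.csv`
#' per score, and `manifest.txt` recording configuration, seed and row
#' counts.  Deterministic given the input (or seed) and configuration; the
#' manifest carries no timestamp so reruns are byte-identical.
#'
#' @param config An [pipeline_config()] object.
#' @return The [evaluate_study()] report, invisibly, with the written
#'   report directory in attribute `"out_dir"`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(out_dir = tempfile("edcrowd-report-"),
#'                        sim = sim_config(n_periods = 60, seed = 3))
#' run_pipeline(cfg)
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ed_pipeline_config"))
  log_msg <- function(...) {
    if (config$verbose) message("[edcrowd] ", sprintf(...))
  }
  if (is.null(config$input)) {
    log_msg("simulating %d periods (seed %d)", config$sim$n_periods,
            config$sim$seed)
    periods <- simulate_study(config$sim)
  } else {
    log_msg("reading periods from %s", config$input)
    periods <- read_periods(config$input)
  }
  log_msg("scoring %d periods", nrow(periods))
  scores <- withCallingHandlers(
    score_all(periods, config$scoring),
    message = function(m) {
      if (config$verbose) message("[edcrowd] ", conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  log_msg("evaluating against Likert >= %d and adverse events",
          config$likert_threshold)
  report <- evaluate_study(periods, scores,
                           likert_threshold = config$likert_threshold,
                           config = config$scoring,
                           ci_method = config$ci_method)
  write_report(report, config$out_dir, periods = periods, scores = scores,
               config = config)
  log_msg("report written to %s", config$out_dir)
  attr(report, "out_dir") <- config$out_dir
  invisible(report)
}

#' Write an evaluation report bundle
#'
#' @param report An [evaluate_study()] result.
#' @param out_dir Output directory, created if needed.
#' @param periods,scores Optional tables to include in the bundle.
#' @param config Optional [pipeline_config()] recorded in the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, periods = NULL, scores = NULL,
                         config = NULL) {
  stopifnot(inherits(report, "ed_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  num2 <- function(df) {  # report-layer rounding: 2 decimals
    for (cl in names(df)) {
      if (is.numeric(df[[cl]])) df[[cl]] <- round(df[[cl]], 4)
    }
    df
  }
  wr <- function(df, name) {
    write.csv(num2(df), file.path(out_dir, name), row.names = FALSE,
              na = "")
  }
  if (!is.null(periods)) write_periods(periods,
                                       file.path(out_dir, "periods.csv"))
  if (!is.null(scores)) write_scores(scores,
                                     file.path(out_dir, "scores.csv"))
  wr(report$table1, "table1.csv")
  wr(report$table2, "table2.csv")
  if (!is.null(report$table3)) wr(report$table3, "table3.csv")
  wr(report$correlations, "correlations.csv")
  for (nm in names(report$rocs)) {
    roc <- report$rocs[[nm]]
    wr(data.frame(threshold = roc$thresholds,
                  sensitivity = roc$sensitivity,
                  specificity = roc$specificity),
       paste0("roc_", nm, ".csv"))
  }
  manifest <- c(
    paste0("edcrowd version: ", as.character(packageVersion("edcrowd"))),
    paste0("periods: ", report$n_periods),
    paste0("patients: ", report$n_patients),
    paste0("likert threshold: ", report$likert_threshold),
    paste0("reference positive: ", report$n_reference_positive, " (",
           report$reference_positive_pct, "%)"),
    paste0("periods with any adverse event: ", report$n_any_ae),
    if (!is.null(scores)) {
      paste0("undefined EDWIN periods: ",
             attr(scores, "n_undefined_edwin") %||% 0L)
    },
    if (!is.null(config) && is.null(config$input)) {
      paste0("simulation seed: ", config$sim$seed)
    },
    if (!is.null(config) && !is.null(config$input)) {
      paste0("input: ", config$input)
    },
    paste0("note: ", report$notes)
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the worked-example toy inputs
#'
#' Writes a small handcrafted period CSV (covering all three shifts, an
#' empty-ED period and a degenerate all-bays-boarded period) plus a
#' matching scoring/simulation config file, the fixtures used in examples
#' and tests.
#'
#' @param dir Target directory, created if needed.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  periods <- toy_periods()
  periods_path <- file.path(dir, "toy_periods.csv")
  write_periods(periods, periods_path)
  config_path <- file.path(dir, "toy_config.txt")
  writeLines(c(
    "# site parameters of the worked example",
    "licensed_beds_edor = 15",
    "treatment_bays = 16",
    "likert_threshold = 5",
    "",
    "[simulation]",
    "n_periods = 459",
    "seed = 1"
  ), config_path)
  invisible(c(periods = periods_path, config = config_path))
}

# six handcrafted periods: typical morning/evening/night, an empty ED, a
# heavily boarded period, and a bays-full period with undefined EDWIN
toy_periods <- function() {
  data.frame(
    period_index = 0:5,
    shift = c("morning", "morning", "evening", "evening", "night", "night"),
    ctas1 = c(1, 0, 1, 2, 0, 4),
    ctas2 = c(2, 0, 3, 4, 1, 6),
    ctas3 = c(4, 0, 5, 6, 3, 4),
    ctas4 = c(1, 0, 2, 3, 1, 2),
    ctas5 = c(0, 0, 0, 1, 0, 0),
    physicians = c(4, 5, 4, 4, 3, 3),
    nurses = c(6, 6, 6, 6, 5, 5),
    bays = rep(16L, 6),
    waiting = c(0, 0, 0, 2, 0, 0),
    boarding = c(1, 0, 2, 6, 1, 16),
    referrals = c(1, 0, 0, 1, 0, 0),
    likert = c(3, 1, 4, 5, 2, 6),
    code_stroke = c(1, 0, 0, 1, 0, 2),
    code_stemi = c(0, 0, 1, 0, 0, 0),
    code_sepsis = c(0, 0, 0, 2, 1, 1),
    code_tbi = c(0, 0, 0, 0, 0, 1),
    ae_stroke = c(0, 0, 0, 1, 0, 2),
    ae_stemi = c(0, 0, 0, 0, 0, 0),
    ae_sepsis = c(0, 0, 0, 1, 0, 1),
    ae_tbi = c(0, 0, 0, 0, 0, 1),
    ae_ihca = c(0, 0, 0, 0, 0, 1),
    stringsAsFactors = FALSE
  )
}
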