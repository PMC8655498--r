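# Orchestration: session validation, master-seed fan-out, and the full
# analysis pipeline producing per-unit tables and a cohort report.

#' Derive per-stage child seeds from one master seed
#'
#' The master seed seeds R's RNG once and draws one integer (< 2^31) per
#' named stage, so each stage is reproducible in isolation and stages
#' stay decoupled.
#'
#' @param master_seed Integer.
#' @param stages Character vector of stage names.
#' @return Named integer vector of child seeds.
#' @export
derive_stage_seeds <- function(master_seed,
                               stages = c("simulate", "detect", "running",
                                          "tuning", "behavior", "waveforms")) {
  set.seed(master_seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

#' Validate a session bundle
#'
#' Checks spike-time sanity (finite, nonnegative, sorted), trial-window
#' sanity (within the session, non-overlapping), running-trace coverage,
#' and waveform shape. Returns diagnostics rather than failing.
#'
#' @param session A `pertflow_session`.
#' @return List: `ok` flag and character vector `diagnostics`.
#' @export
validate_session <- function(session) {
  d <- character(0)
  tr <- session$trials
  for (i in seq_along(session$units)) {
    st <- session$units[[i]]$spike_times
    if (any(!is.finite(st))) d <- c(d, sprintf("unit %d: non-finite spike times", i))
    if (any(st < 0)) d <- c(d, sprintf("unit %d: negative spike time", i))
    if (is.unsorted(st)) d <- c(d, sprintf("unit %d: unsorted spike times", i))
    w <- session$units[[i]]$waveform
    if (length(w) < 10 || all(w >= 0))
      d <- c(d, sprintf("unit %d: degenerate waveform", i))
  }
  ends <- tr$onset_time + tr$n_frames / FRAME_RATE
  if (any(tr$onset_time[-1] < ends[-nrow(tr)]))
    d <- c(d, sprintf("trial %d overlaps its neighbor",
                      which(tr$onset_time[-1] < ends[-nrow(tr)])[1] + 1L))
  if (max(ends) > session$duration + 1e-9)
    d <- c(d, "trials extend past the session duration")
  if (length(session$running$speed) < session$duration * session$running$fs - 1)
    d <- c(d, "running trace does not cover the session")
  if (any(session$running$speed < 0)) d <- c(d, "negative running speed")
  list(ok = length(d) == 0, diagnostics = d)
}

#' Run the full analysis pipeline on one session
#'
#' Validation, perturbation detection (classifier + shuffle null),
#' running-state analysis, grating and perturbation tuning, behavioral
#' speed analysis, and waveform typing, each stage seeded from one
#' master seed. Summaries in the report are all recomputable from the
#' per-unit tables.
#'
#' @param session A main-protocol `pertflow_session`.
#' @param n_shuffles Label shuffles per unit (default 1000).
#' @param n_boot Bootstrap draws for the running test (default 1000).
#' @param seed Master seed.
#' @param log_fn Optional function(message) for structured logging of
#'   filter decisions; default silently discards.
#' @return List (class `pertflow_report`): `per_unit` (merged per-unit
#'   table), `speed`, `report` (cohort summary list), `validation`.
#' @export
run_full_analysis <- function(session, n_shuffles = 1000, n_boot = 1000,
                              seed = 1, log_fn = NULL) {
  log1 <- function(...) if (!is.null(log_fn))
    log_fn(jsonlite::toJSON(list(...), auto_unbox = TRUE))
  val <- validate_session(session)
  if (!val$ok) for (m in val$diagnostics) log1(event = "validation", message = m)
  seeds <- derive_stage_seeds(seed)
  rates <- session_rates(session)

  pert <- analyze_perturbation(session, rates, n_shuffles = n_shuffles,
                               seed = seeds[["detect"]])
  run <- analyze_running(session, rates, pert_table = pert$table,
                         n_boot = n_boot, seed = seeds[["running"]])
  tun <- analyze_tuning(session, rates)
  beh <- analyze_behavior(session, pert, n_shuffles = n_shuffles,
                          seed = seeds[["behavior"]])
  wav <- analyze_waveforms(session)

  per_unit <- Reduce(function(a, b) merge(a, b, by = "unit_id", all = TRUE),
                     list(pert$table, run, tun$table,
                          wav[, c("unit_id", "trough_to_peak_ms", "cluster")]))
  if (!is.null(beh$table)) {
    bt <- beh$table
    names(bt)[names(bt) != "unit_id"] <-
      paste0("speed_cor_", names(bt)[names(bt) != "unit_id"])
    per_unit <- merge(per_unit, bt, by = "unit_id", all = TRUE)
  }
  rel <- per_unit$reliable %in% TRUE
  report <- list(
    n_units = nrow(per_unit),
    fraction_reliable = mean(rel),
    fraction_positive = mean(per_unit$sign %in% "positive"),
    fraction_negative = mean(per_unit$sign %in% "negative"),
    fraction_significant_running = mean(per_unit$significant_running %in% TRUE),
    fraction_mismatch_like = mean(per_unit$mismatch_like %in% TRUE),
    fraction_ori_tuned = mean(per_unit$ori_tuned %in% TRUE),
    delta_ori_hist = if (any(rel)) table(cut(per_unit$delta_ori[rel],
                                             breaks = seq(0, 90, by = 15),
                                             include.lowest = TRUE)) else NULL,
    speed_change_reliable = if (isTRUE(beh$speed$evaluable)) beh$speed$reliable else NA,
    fraction_speed_correlated = if (!is.null(beh$table))
      mean(beh$table$significant %in% TRUE) else NA_real_
  )
  structure(list(per_unit = per_unit, speed = beh$speed, report = report,
                 validation = val),
            class = "pertflow_report")
}

#' @export
print.pertflow_report <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0(
    "<pertflow_report: %d units | reliable %.1f%% (pos %.1f%%, neg %.1f%%) | ",
    "running-enhanced %.1f%% | mismatch-like %.1f%%>\n"),
    r$n_units, 100 * r$fraction_reliable, 100 * r$fraction_positive,
    100 * r$fraction_negative, 100 * r$fraction_significant_running,
    100 * r$fraction_mismatch_like))
  invisible(x)
}

#' Write the per-unit table and cohort report to disk
#'
#' @param result A `pertflow_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "per_unit.csv")
  utils::write.csv(result$per_unit, p1, row.names = FALSE)
  p2 <- file.path(dir, "cohort_report.json")
  rep <- result$report
  rep$delta_ori_hist <- if (!is.null(rep$delta_ori_hist))
    as.list(stats::setNames(as.integer(rep$delta_ori_hist),
                            names(rep$delta_ori_hist)))
  jsonlite::write_json(rep, p2, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(p1, p2))
}
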