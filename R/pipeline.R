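#' Extract micro-movement series from a pointing session
#'
#' End-to-end kinematic extraction for one session: derives the
#' angular-acceleration magnitude from the `ang_rate` channel, the
#' speed profile from the position channels, segments every trial into
#' forward/backward at the minimum hand-to-target distance, and
#' collects amplitude (AM) and timing (NTM) micro-movements separately
#' for the deliberate forward and spontaneous backward segments,
#' pooled across all trials of the session (the estimation window is
#' the whole session).
#'
#' @param session a [session_record()] with channels `pos_x`,
#'   `pos_y`, `pos_z`, `ang_rate`.
#' @param target_pos 3-vector, target position (cm).
#' @param min_prominence peak-detection prominence threshold
#'   (deg/s^2); 0 keeps every sign change.
#' @param ntm_mode forwarded to [compute_ntm()].
#' @param smooth_window,poly_order differentiation controls.
#' @return List with `am` (list `forward`/`backward` of
#'   `micromovement_series`), `ntm` (same structure), `segments`,
#'   `metrics` (from [behavioral_metrics()]), `accel`, `speed`.
#' @export
extract_session <- function(session, target_pos = c(12, 30.5, 22),
                            min_prominence = 0,
                            ntm_mode = "series_minima",
                            smooth_window = 21, poly_order = 3) {
  stopifnot(inherits(session, "session_record"),
            all(c("pos_x", "pos_y", "pos_z", "ang_rate") %in%
                  names(session$channels)))
  ch <- session$channels
  traj <- trajectory(ch$pos_x$t,
                     cbind(ch$pos_x$v, ch$pos_y$v, ch$pos_z$v),
                     ang_rate = ch$ang_rate$v, fs = ch$pos_x$fs)
  speed <- compute_speed(traj, smooth_window, poly_order)
  accel <- compute_angular_acceleration(traj, smooth_window, poly_order)
  prompts <- vapply(session$trials, function(tr)
    tr$event_times$prompt %||% NA_real_, numeric(1))
  ends <- c(prompts[-1], traj$t[length(traj$t)])
  segments <- lapply(seq_along(session$trials), function(i)
    segment_trial(traj, session$trials[[i]], target_pos, speed = speed,
                  t_end = ends[i]))
  pool <- function(kind) {
    pts <- lapply(segments, function(sg) {
      seg <- sg[[kind]]
      idx <- seg$start:(seg$end - 1L)
      if (length(idx) < 3) return(NULL)
      sub <- timeseries(accel$v[idx], t = accel$t[idx], fs = accel$fs,
                        units = accel$units)
      detect_extrema(sub, min_prominence = min_prominence)
    })
    pts[!vapply(pts, is.null, logical(1))]
  }
  collect_am <- function(trains) {
    parts <- lapply(trains, function(pt)
      suppressWarnings(compute_am(pt)))
    vals <- unlist(lapply(parts, `[[`, "values"))
    raw <- unlist(lapply(parts, `[[`, "raw_values"))
    tms <- unlist(lapply(parts, `[[`, "peak_times"))
    new_micromovement_series(vals, "AM", raw, tms, trains[[1]]$units)
  }
  collect_ntm <- function(trains) {
    tm_all <- unlist(lapply(trains, function(pt)
      if (length(pt$peak_idx) >= 2) diff(pt$peak_times) else numeric(0)))
    suppressWarnings(compute_ntm(tm_all, mode = ntm_mode))
  }
  fwd <- pool("forward"); bwd <- pool("backward")
  metrics <- behavioral_metrics(session, segments, accel,
                                min_prominence = min_prominence)
  list(am = list(forward = collect_am(fwd), backward = collect_am(bwd)),
       ntm = list(forward = collect_ntm(fwd), backward = collect_ntm(bwd)),
       segments = segments, metrics = metrics, accel = accel, speed = speed)
}

#' Validate a pipeline run configuration
#'
#' Fails fast — before any computation — when required fields are
#' missing or inconsistent. Unknown fields are rejected to catch
#' typos.
#'
#' @param config a named list; see [run_pipeline()] for the fields.
#' @return The config, with defaults filled in.
#' @export
validate_config <- function(config) {
  known <- c("input_dir", "output_dir", "target_pos", "conf_level",
             "ntm_mode", "log_base", "min_prominence", "seed",
             "filter_low_hz", "filter_high_hz", "filter_order",
             "scale_max_s", "make_plots")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("validation failure: unknown config field(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  need <- c("input_dir", "output_dir", "target_pos")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("validation failure: missing config field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(config$target_pos) != 3)
    stop("validation failure: 'target_pos' must be a 3-vector", call. = FALSE)
  defaults <- list(conf_level = 0.95, ntm_mode = "series_minima",
                   log_base = "natural", min_prominence = 0,
                   seed = NA, filter_low_hz = 5, filter_high_hz = 30,
                   filter_order = 2, scale_max_s = 1.0, make_plots = FALSE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

#' Run the full analysis pipeline over a directory of sessions
#'
#' Orchestrates every stage for a cohort laid out as one session
#' directory per participant x condition (as written by
#' [write_session_csv()]; an `ecg.csv` channel, when present, feeds
#' the inter-beat-interval branch): extraction, Gamma fits with CIs
#' for AM/NTM (forward and backward) and IBI, per-signal condition
#' shift reports, and a plane-point table, all written to
#' `output_dir` as JSON/CSV. Outputs are deterministic: rerunning
#' with identical config and inputs reproduces identical files.
#'
#' @param config named list (see [validate_config()]): `input_dir`
#'   with one subdirectory per session, `output_dir`, `target_pos`,
#'   and the optional tuning fields.
#' @return Invisibly, a list with `fits`, `plane_points` (data.frame)
#'   and the per-session extraction summaries. Partial outputs are
#'   retained next to a `FAILED` marker file if a stage errors.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) file.create(file.path(config$output_dir, "FAILED")))
  dirs <- list.dirs(config$input_dir, recursive = FALSE)
  if (!length(dirs)) stop("no session directories in ", config$input_dir,
                          call. = FALSE)
  # provenance hash covers the analysis parameters, not filesystem paths,
  # so identical analyses of identical inputs yield identical reports
  analysis_cfg <- config[setdiff(names(config), c("input_dir", "output_dir"))]
  fits <- list()
  pp_rows <- list()
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  for (d in dirs) {
    session <- read_session_csv(d)
    key <- paste(session$participant_id, session$condition, sep = ".")
    ex <- extract_session(session, target_pos = config$target_pos,
                          min_prominence = config$min_prominence,
                          ntm_mode = config$ntm_mode)
    sig_list <- list(AM.forward = ex$am$forward, AM.backward = ex$am$backward,
                     NTM.forward = ex$ntm$forward,
                     NTM.backward = ex$ntm$backward)
    for (nm in names(sig_list)) {
      mm <- sig_list[[nm]]
      if (length(mm$values) < 10) {
        note("%s %s: only %d values, skipping fit", key, nm, length(mm$values))
        next
      }
      if (length(mm$values) < 100)
        note("%s %s: n = %d < 100, CIs will be wide", key, nm,
             length(mm$values))
      fit <- suppressWarnings(
        fit_gamma_mle(mm$values, conf_level = config$conf_level,
                      sample_label = sub("\\..*", "", nm)))
      fits[[paste(key, nm, sep = ".")]] <- fit
      pp_rows[[paste(key, nm, sep = ".")]] <- plane_point(
        fit, session$participant_id, session$condition, nm,
        raw_median = mm$raw_median)
      write_report_json(fit,
                        file.path(config$output_dir,
                                  paste0(key, ".", nm, ".fit.json")),
                        seed = config$seed, config = analysis_cfg)
      write_micromovements_csv(mm,
                               file.path(config$output_dir,
                                         paste0(key, ".", nm, ".mm.csv")))
    }
    ecg_path <- file.path(d, "ecg.csv")
    if (file.exists(ecg_path)) {
      ecg <- read_timeseries_csv(ecg_path, units = "mV", channel_id = "ecg")
      spec <- filter_spec(config$filter_low_hz, config$filter_high_hz,
                          config$filter_order)
      beats <- detect_rpeaks(preprocess_ecg(ecg, spec))
      ibi <- compute_ibi(beats)
      write_ibi_csv(ibi, file.path(config$output_dir,
                                   paste0(key, ".ibi.csv")))
      if (length(ibi$ibi) >= 10) {
        fit <- suppressWarnings(
          fit_gamma_mle(ibi$ibi, conf_level = config$conf_level,
                        sample_label = "IBI"))
        fits[[paste(key, "IBI", sep = ".")]] <- fit
        pp_rows[[paste(key, "IBI", sep = ".")]] <- plane_point(
          fit, session$participant_id, session$condition, "IBI",
          raw_median = stats::median(ibi$ibi))
        write_report_json(fit,
                          file.path(config$output_dir,
                                    paste0(key, ".IBI.fit.json")),
                          seed = config$seed, config = analysis_cfg)
      }
      note("%s: %d beats, %d flagged intervals", key,
           length(ibi$beat_times), sum(ibi$flags))
    }
    note("%s: %d trials, %d AM fwd peaks", key, length(session$trials),
         length(ex$am$forward$values))
  }
  pp <- do.call(rbind, lapply(pp_rows, function(p)
    data.frame(participant_id = p$participant_id, condition = p$condition,
               kind = p$kind, shape = p$shape, scale = p$scale,
               ci_shape_lo = p$ci_shape[1], ci_shape_hi = p$ci_shape[2],
               ci_scale_lo = p$ci_scale[1], ci_scale_hi = p$ci_scale[2],
               raw_median = p$raw_median, n = p$n)))
  utils::write.csv(pp, file.path(config$output_dir, "plane_points.csv"),
                   row.names = FALSE, quote = FALSE)
  if (isTRUE(config$make_plots) && length(pp_rows))
    plot_gamma_plane(pp_rows, file.path(config$output_dir,
                                        "gamma_plane.pdf"))
  writeLines(log_lines, file.path(config$output_dir, "pipeline.log"))
  ok <- TRUE
  invisible(list(fits = fits, plane_points = pp, log = log_lines))
}
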