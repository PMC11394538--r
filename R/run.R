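#' Pipeline commands
#'
#' The `run_*` functions wire simulate -> track -> evaluate -> compare
#' and the format conversions; the shell entry point at
#' `inst/scripts/herdtrack` is a thin wrapper over them.  Every command
#' writes a YAML run manifest echoing its full effective configuration
#' so any output is regenerable from the manifest alone.  Configuration
#' precedence is flags (arguments) > config file > preset defaults;
#' unknown keys are rejected.
#'
#' @name cli_app
NULL

merge_config <- function(defaults, file_cfg, overrides, what) {
  unknown <- setdiff(names(file_cfg), names(defaults))
  if (length(unknown))
    stop("unknown ", what, " config key(s): ", paste(unknown, collapse = ", "))
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown ", what, " option(s): ", paste(unknown, collapse = ", "))
  defaults[names(file_cfg)] <- file_cfg
  defaults[names(overrides)] <- overrides
  defaults
}

read_run_config <- function(config_file, section) {
  if (is.null(config_file)) return(list())
  cfg <- yaml::read_yaml(config_file)
  if (!is.null(cfg[[section]])) cfg[[section]] else cfg
}

write_manifest <- function(dir, command, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(c(list(command = command), config),
                   file.path(dir, paste0(command, "_manifest.yaml")))
}

#' Simulate a scenario and write its files
#'
#' @param out_dir output directory for `gt.txt`, `det.txt`,
#'   `features.txt`, `truth_log.txt` and the manifest.
#' @param preset scenario preset name (see [scenario_preset()]).
#' @param config_file optional YAML file; its `simulator` section (or
#'   the whole file) overrides preset defaults.
#' @param ... direct [scenario_config()] overrides (highest
#'   precedence), e.g. `n_frames`, `seed`.
#' @return Invisibly, the named vector of file paths.
#' @export
run_simulate <- function(out_dir, preset = "sparse", config_file = NULL, ...) {
  defaults <- unclass(scenario_preset(preset))
  cfg <- merge_config(defaults, read_run_config(config_file, "simulator"),
                      list(...), "simulator")
  cfg <- do.call(scenario_config, cfg)
  sim <- simulate_sequence(cfg)
  paths <- write_sequence(sim, out_dir)
  write_manifest(out_dir, "simulate",
                 list(preset = preset, simulator = unclass(cfg)))
  invisible(paths)
}

#' Track a detection file
#'
#' @param det_file MOT-16 detection file.
#' @param out result file path.
#' @param features_file optional feature sidecar aligned with
#'   `det_file`.
#' @param config_file optional YAML file; `tracker` section overrides
#'   defaults.
#' @param ... direct [tracker_config()] overrides (highest precedence).
#' @return Invisibly, the result data.frame.
#' @export
run_track <- function(det_file, out, features_file = NULL,
                      config_file = NULL, ...) {
  cfg <- merge_config(formals_defaults(tracker_config),
                      read_run_config(config_file, "tracker"),
                      list(...), "tracker")
  cfg <- do.call(tracker_config, cfg)
  dets <- read_mot(det_file, kind = "det")
  emb <- if (!is.null(features_file))
    read_feature_sidecar(features_file, nrow(dets))
  res <- track_sequence(dets, emb, cfg)
  write_mot(res, out)
  write_manifest(dirname(out), "track",
                 list(det_file = det_file,
                      features_file = features_file %||% NA,
                      out = out, tracker = unclass(cfg)))
  invisible(res)
}

formals_defaults <- function(fn) {
  fr <- formals(fn)
  lapply(fr, function(v)
    if (is.language(v)) eval(v, envir = environment(fn)) else v)
}

#' Evaluate a result file against ground truth
#'
#' Prints the four tracking metrics (IDF1, IDS, MOTA, MOTP) to three
#' decimals and optionally writes a machine-readable JSON report.
#'
#' @param gt_file MOT-16 ground-truth file.
#' @param result_file MOT-16 result file.
#' @param out optional JSON report path.
#' @param iou_threshold correspondence threshold (default 0.5).
#' @return Invisibly, the named metric vector.
#' @export
run_evaluate <- function(gt_file, result_file, out = NULL,
                         iou_threshold = 0.5) {
  ev <- evaluate_tracking(gt_file, result_file, iou_threshold)
  cat(ev$text, "\n")
  if (!is.null(out)) {
    jsonlite::write_json(as.list(ev$summary), out, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(ev$summary)
}

#' Compare baseline and improved tracker configurations
#'
#' Runs the simulator over a set of seeds and tracks each sequence
#' twice: the baseline arm (secondary IOU pass and admission gate both
#' off, i.e. classic Deep SORT behaviour) and the improved arm (both
#' on), then evaluates both and tabulates per-seed and aggregate IDF1,
#' IDS, MOTA and MOTP with deltas.
#'
#' @param seeds integer vector of scenario seeds.
#' @param preset scenario preset name (default `"distant_dense"`).
#' @param n_frames override of the preset sequence length (optional).
#' @param tracker_overrides named list of [tracker_config()] overrides
#'   applied to both arms.
#' @param ... [scenario_config()] overrides applied to every seed.
#' @return A data.frame with one row per (seed, arm) plus
#'   `"aggregate"` rows (IDS summed, other metrics averaged).
#' @export
run_compare <- function(seeds, preset = "distant_dense", n_frames = NULL,
                        tracker_overrides = list(), ...) {
  if (!length(seeds)) stop("need at least one seed")
  arms <- list(
    baseline = utils::modifyList(list(secondary_iou_enabled = FALSE,
                                      admission_gate_enabled = FALSE),
                                 tracker_overrides),
    improved = utils::modifyList(list(secondary_iou_enabled = TRUE,
                                      admission_gate_enabled = TRUE),
                                 tracker_overrides))
  rows <- list()
  for (seed in seeds) {
    over <- list(...)
    over$seed <- seed
    if (!is.null(n_frames)) over$n_frames <- n_frames
    sim <- simulate_sequence(do.call(scenario_preset,
                                     c(list(name = preset), over)))
    gt <- sim$gt
    gt$conf <- 1
    for (arm in names(arms)) {
      cfg <- do.call(tracker_config, arms[[arm]])
      res <- track_sequence(sim$detections, sim$embeddings, cfg,
                            n_frames = sim$config$n_frames)
      ev <- evaluate_tracking(gt, res)
      rows[[length(rows) + 1L]] <-
        data.frame(seed = seed, arm = arm,
                   IDF1 = ev$summary[["IDF1"]], IDS = ev$summary[["IDS"]],
                   MOTA = ev$summary[["MOTA"]], MOTP = ev$summary[["MOTP"]])
    }
  }
  tab <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(tab, tab$arm), function(d)
    data.frame(seed = NA_integer_, arm = d$arm[1L],
               IDF1 = mean(d$IDF1), IDS = sum(d$IDS),
               MOTA = mean(d$MOTA), MOTP = mean(d$MOTP))))
  out <- rbind(tab, agg)
  rownames(out) <- NULL
  out
}

#' Convert a DarkLabel CSV to MOT-16 ground truth
#'
#' @inheritParams convert_darklabel
#' @return `out`, invisibly.
#' @export
run_convert <- function(path, out, dialect = darklabel_dialect()) {
  convert_darklabel(path, out, dialect)
}
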