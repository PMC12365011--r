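#' Run the fork-analysis pipeline end to end
#'
#' Orchestrates simulate-or-read, segmentation, and per-fork metrics, writing
#' all intermediates and a JSON run manifest to an output directory. Stages
#' run in dependency order; a stage failure halts the run after writing a
#' partial manifest naming the failed stage. All intermediates are plain
#' text and append-only: no stage rewrites another stage's output.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed used for simulation.
#' @param sim A [simulation_config()] to generate input, or `NULL` to read
#'   an existing detect file.
#' @param detect Path to a detect-format file (required when `sim` is
#'   `NULL`).
#' @param seg,speed,stall Parameter objects for the three stages.
#' @param run_id,condition,replicate Provenance labels stamped on every row
#'   of the metrics table.
#' @param min_length Minimum mapped read length accepted when reading.
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(out_dir, seed = 1L, sim = simulation_config(),
                         detect = NULL,
                         seg = segmentation_params(),
                         speed = speed_params(),
                         stall = stall_params("v3"),
                         run_id = "run1", condition = "untreated",
                         replicate = "rep1", min_length = 20000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "forktrace",
    version = as.character(utils::packageVersion("forktrace")),
    seed = seed, run_id = run_id, condition = condition,
    replicate = replicate,
    params = list(segmentation = unclass(seg), speed = unclass(speed),
                  stall = unclass(stall),
                  simulation = if (!is.null(sim)) unclass(sim)),
    stages = list())
  fail <- function(stage, msg) {
    manifest$failed_stage <- stage
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    stop("pipeline halted at stage '", stage, "': ", msg, call. = FALSE)
  }

  # stage 1: obtain tracks
  if (!is.null(sim)) {
    sim_out <- simulate_experiment(sim, seed)
    tracks <- sim_out$tracks
    detect <- file.path(out_dir, "reads.detect")
    write_tracks(tracks, detect)
    utils::write.table(sim_out$truth$forks,
                       file.path(out_dir, "truth_forks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$simulate <- list(n_reads = length(tracks),
                                     n_truth_forks = nrow(sim_out$truth$forks))
  } else {
    if (is.null(detect) || !file.exists(detect))
      fail("read", paste0("detect file not found: ",
                          if (is.null(detect)) "<missing>" else detect))
    tracks <- tryCatch(read_tracks(detect, min_length = min_length),
                       error = function(e) fail("read", conditionMessage(e)))
  }
  manifest$input <- list(detect = detect,
                         md5 = unname(tools::md5sum(detect)))
  manifest$stages$read <- list(n_reads = length(tracks))

  # stage 2: segmentation and fork calling
  calls <- tryCatch(call_forks_all(tracks, seg),
                    error = function(e) fail("segmentation",
                                             conditionMessage(e)))
  write_fork_bed(calls$forks, file.path(out_dir, "forks.bed"))
  iv_bed <- function(df, path) {
    if (nrow(df)) df <- df[order(df$chrom, df$start), ]
    utils::write.table(df[, c("chrom", "start", "end", "read_id")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  iv_bed(calls$origins, file.path(out_dir, "origins.bed"))
  iv_bed(calls$terminations, file.path(out_dir, "terminations.bed"))
  manifest$stages$segmentation <- list(n_forks = nrow(calls$forks),
                                       n_origins = nrow(calls$origins),
                                       n_terminations = nrow(calls$terminations))

  # stage 3: per-fork metrics with provenance columns
  metrics <- tryCatch(fork_metrics(tracks, calls$forks, speed, stall),
                      error = function(e) fail("metrics",
                                               conditionMessage(e)))
  metrics$run_id <- run_id
  metrics$condition <- condition
  metrics$replicate <- replicate
  utils::write.table(metrics, file.path(out_dir, "fork_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$metrics <- list(
    n_forks = nrow(metrics),
    n_speeds = sum(!is.na(metrics$speed)),
    n_stall_scores = sum(is.na(metrics$stall_declined)))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
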