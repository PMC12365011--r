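#' Configuration for the pulse-chase simulator
#'
#' The simulator emulates the labelling protocol behind the analytics: a
#' 5-minute EdU pulse, a 10-minute BrdU pulse, then a thymidine chase. Active
#' forks lay an EdU track followed by a BrdU track; during the chase, BrdU
#' incorporation decays exponentially as the intracellular analogue pool
#' depletes, which is what gives unstalled forks their gradual BrdU tail. A
#' stalled fork instead stops dead at a drawn stall time, producing the
#' abrupt BrdU drop the stall score is designed to detect.
#'
#' @param n_reads Number of simulated reads.
#' @param genome_length Length of each synthetic chromosome (bp).
#' @param n_chroms Number of synthetic chromosomes reads are drawn from.
#' @param read_n50 Target read-length N50 in bp (length-weighted median of
#'   the lognormal read-length distribution). Default 90000, a typical
#'   ultra-long nanopore run.
#' @param read_sdlog Lognormal sdlog of read lengths.
#' @param min_read_length Reads shorter than this are resampled (the fork
#'   caller requires 20 kb mapped length).
#' @param at_fraction AT fraction of the synthetic genome; thymidines are
#'   placed per-base with probability `at_fraction / 2`. Default 0.6.
#' @param fork_rate_per_mb Expected single (origin-distal) forks per Mb of
#'   read.
#' @param origin_rate_per_mb Expected origins firing during the pulse per Mb
#'   (each yields two diverging forks).
#' @param termination_rate_per_mb Expected terminations during the pulse per
#'   Mb (two converging forks).
#' @param fork_speed_mean,fork_speed_sd Normal fork-speed distribution in
#'   kb/min. Defaults 1.4 and 0.3, matching unperturbed human cells.
#' @param stall_probability Probability that a fork stalls during the pulse.
#' @param stall_time_range Uniform range (minutes from EdU-pulse start) from
#'   which a stalled fork's stop time is drawn.
#' @param pulse Named numeric vector `c(edu=, brdu=, chase=)` of pulse/chase
#'   durations in minutes.
#' @param emission Named vector `c(a_pos=, b_pos=, a_neg=, b_neg=)`: Beta
#'   parameters for the called probability at labelled and unlabelled
#'   thymidines. Defaults Beta(8,2) and Beta(2,8).
#' @param noise_free If `TRUE`, labelled positions get probability exactly 1,
#'   unlabelled exactly 0, and the chase tail is omitted — ideal calls for
#'   ground-truth recovery tests.
#' @param chase_tau Time constant (minutes) of the exponential decay of BrdU
#'   incorporation during the chase.
#' @param event_gap Unlabelled gap in bp left between the two EdU tracks of
#'   an origin and between the two BrdU tracks of a termination, emulating
#'   the detection gap analogue callers leave where diverging or converging
#'   segments meet. Default 3000.
#' @param indel_rate Expected indel annotations per kb of read.
#' @param indel_meanlog,indel_sdlog Lognormal parameters of indel lengths.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_reads = 40L, genome_length = 10e6,
                              n_chroms = 2L, read_n50 = 90000,
                              read_sdlog = 0.35, min_read_length = 20000,
                              at_fraction = 0.6,
                              fork_rate_per_mb = 10,
                              origin_rate_per_mb = 0.5,
                              termination_rate_per_mb = 0.5,
                              fork_speed_mean = 1.4, fork_speed_sd = 0.3,
                              stall_probability = 0,
                              stall_time_range = c(0, 15),
                              pulse = c(edu = 5, brdu = 10, chase = 20),
                              emission = c(a_pos = 8, b_pos = 2,
                                           a_neg = 2, b_neg = 8),
                              noise_free = FALSE, chase_tau = 3,
                              event_gap = 3000,
                              indel_rate = 0, indel_meanlog = log(50),
                              indel_sdlog = 0.5) {
  stopifnot(n_reads >= 1, genome_length > 0, read_n50 > 0,
            at_fraction > 0, at_fraction < 1,
            fork_rate_per_mb >= 0, origin_rate_per_mb >= 0,
            termination_rate_per_mb >= 0,
            fork_speed_mean > 0, fork_speed_sd >= 0,
            stall_probability >= 0, stall_probability <= 1,
            all(pulse[c("edu", "brdu")] > 0), chase_tau > 0,
            indel_rate >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

# Lay one fork's label intervals. x0 = position of the fork at EdU-pulse
# start; dir = +1 rightward, -1 leftward; v in bp/min. Returns absolute
# half-open intervals for the EdU and BrdU regions (NULL if empty) plus the
# chase-tail extent.
.fork_layout <- function(x0, dir, v, t_stop, pulse, chase_tau, noise_free) {
  t_edu <- min(t_stop, pulse[["edu"]])
  t_brdu_end <- min(t_stop, pulse[["edu"]] + pulse[["brdu"]])
  edu_len <- v * t_edu
  brdu_len <- v * max(0, t_brdu_end - pulse[["edu"]])
  stalled_in_pulse <- t_stop < pulse[["edu"]] + pulse[["brdu"]]
  tail_t <- if (noise_free || stalled_in_pulse) 0 else
    min(pulse[["chase"]], 6 * chase_tau)
  tail_len <- v * tail_t
  iv <- function(a, b) if (b > a) c(a, b) else NULL
  if (dir > 0) {
    list(edu = iv(x0, x0 + edu_len),
         brdu = iv(x0 + edu_len, x0 + edu_len + brdu_len),
         tail = iv(x0 + edu_len + brdu_len, x0 + edu_len + brdu_len + tail_len),
         extent = c(x0, x0 + edu_len + brdu_len + tail_len))
  } else {
    list(edu = iv(x0 - edu_len, x0),
         brdu = iv(x0 - edu_len - brdu_len, x0 - edu_len),
         tail = iv(x0 - edu_len - brdu_len - tail_len, x0 - edu_len - brdu_len),
         extent = c(x0 - edu_len - brdu_len - tail_len, x0))
  }
}

#' Simulate a pulse-chase nanopore experiment with ground truth
#'
#' Generates detect-format analogue tracks for `config$n_reads` synthetic
#' reads, together with a full ground-truth record of every simulated fork,
#' origin and termination. Deterministic for a given seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; all randomness derives from it.
#' @return A list with `tracks` (list of [analogue_track()]), `truth` (list
#'   with data.frames `forks`, `origins`, `terminations`), and `config`.
#' @export
simulate_experiment <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cfg <- config
  pulse <- cfg$pulse
  t_pulse_end <- pulse[["edu"]] + pulse[["brdu"]]
  meanlog <- log(cfg$read_n50) - cfg$read_sdlog^2
  tracks <- vector("list", cfg$n_reads)
  truth_forks <- list(); truth_origins <- list(); truth_terms <- list()
  for (r in seq_len(cfg$n_reads)) {
    repeat {
      L <- round(stats::rlnorm(1, meanlog, cfg$read_sdlog))
      if (L >= cfg$min_read_length && L < cfg$genome_length) break
    }
    chrom <- paste0("chr", 1L + (r - 1L) %% cfg$n_chroms)
    ref_start <- floor(stats::runif(1, 0, cfg$genome_length - L))
    ref_end <- ref_start + L
    read_id <- sprintf("read_%04d", r)
    mb <- L / 1e6
    n_single <- stats::rpois(1, cfg$fork_rate_per_mb * mb)
    n_origin <- stats::rpois(1, cfg$origin_rate_per_mb * mb)
    n_term <- stats::rpois(1, cfg$termination_rate_per_mb * mb)
    events <- c(rep("single", n_single), rep("origin", n_origin),
                rep("termination", n_term))
    if (length(events)) events <- sample(events)
    placed <- matrix(numeric(0), ncol = 2)  # occupied [start,end] intervals
    margin <- 3000; buffer <- 6000
    for (ev in events) {
      v <- max(0.3, stats::rnorm(1, cfg$fork_speed_mean, cfg$fork_speed_sd)) * 1000
      fks <- switch(ev,
        single = {
          dir <- sample(c(1, -1), 1)
          stalled <- stats::runif(1) < cfg$stall_probability
          t_stop <- if (stalled)
            stats::runif(1, cfg$stall_time_range[1], cfg$stall_time_range[2])
            else Inf
          list(list(dir = dir, v = v, t_stop = t_stop, event = "single"))
        },
        origin = {
          t_fire <- stats::runif(1, 0, pulse[["edu"]] * 0.8)
          list(list(dir = -1, v = v, t_stop = Inf, event = "origin",
                    t_fire = t_fire),
               list(dir = 1, v = v, t_stop = Inf, event = "origin",
                    t_fire = t_fire))
        },
        termination = {
          t_meet <- stats::runif(1, pulse[["edu"]] + 2, t_pulse_end - 1)
          t_stop <- t_meet - cfg$event_gap / (2 * v)
          list(list(dir = 1, v = v, t_stop = t_stop, event = "termination"),
               list(dir = -1, v = v, t_stop = t_stop, event = "termination"))
        })
      # extent of the whole event, anchored at 0, before placement
      lay0 <- lapply(seq_along(fks), function(k) {
        f <- fks[[k]]
        x0 <- 0
        if (ev == "origin") {
          # forks start event_gap/2 either side of the origin point; label
          # begins when the origin fires
          t0 <- f$t_fire
          lay <- .fork_layout(f$dir * cfg$event_gap / 2, f$dir, f$v,
                              if (is.finite(f$t_stop)) f$t_stop - t0 else Inf,
                              c(edu = pulse[["edu"]] - t0, brdu = pulse[["brdu"]],
                                chase = pulse[["chase"]]),
                              cfg$chase_tau, cfg$noise_free)
        } else if (ev == "termination") {
          # forks converge on 0, stopping event_gap/2 short of it
          lay <- .fork_layout(-f$dir * (f$v * f$t_stop + cfg$event_gap / 2),
                              f$dir, f$v, f$t_stop,
                              pulse, cfg$chase_tau, cfg$noise_free)
        } else {
          lay <- .fork_layout(0, f$dir, f$v, f$t_stop, pulse, cfg$chase_tau,
                              cfg$noise_free)
        }
        lay
      })
      ext <- range(unlist(lapply(lay0, `[[`, "extent")))
      width <- ext[2] - ext[1]
      lo <- ref_start + margin - ext[1]
      hi <- ref_end - margin - ext[2]
      if (hi <= lo) next
      ok_x <- NA
      for (try in 1:50) {
        x <- stats::runif(1, lo, hi)
        iv <- c(ext[1] + x - buffer, ext[2] + x + buffer)
        if (!nrow(placed) || all(placed[, 2] < iv[1] | placed[, 1] > iv[2])) {
          ok_x <- x; break
        }
      }
      if (is.na(ok_x)) next
      placed <- rbind(placed, c(ext[1] + ok_x, ext[2] + ok_x))
      shift <- function(i) if (is.null(i)) NULL else i + ok_x
      for (k in seq_along(fks)) {
        f <- fks[[k]]; lay <- lay0[[k]]
        edu <- shift(lay$edu); brdu <- shift(lay$brdu); tl <- shift(lay$tail)
        truth_forks[[length(truth_forks) + 1L]] <- data.frame(
          read_id = read_id, chrom = chrom,
          direction = if (f$dir > 0) "rightward" else "leftward",
          speed = f$v / 1000,
          edu_start = if (is.null(edu)) NA_real_ else round(edu[1]),
          edu_end = if (is.null(edu)) NA_real_ else round(edu[2]),
          brdu_start = if (is.null(brdu)) NA_real_ else round(brdu[1]),
          brdu_end = if (is.null(brdu)) NA_real_ else round(brdu[2]),
          event = f$event,
          stalled = is.finite(f$t_stop) && f$event == "single",
          stall_time = if (is.finite(f$t_stop) && f$event == "single")
            f$t_stop else NA_real_)
        fks[[k]]$edu <- edu; fks[[k]]$brdu <- brdu; fks[[k]]$tail <- tl
      }
      if (ev == "origin") {
        truth_origins[[length(truth_origins) + 1L]] <- data.frame(
          chrom = chrom, start = round(ok_x - cfg$event_gap / 2),
          end = round(ok_x + cfg$event_gap / 2), read_id = read_id)
      }
      if (ev == "termination") {
        truth_terms[[length(truth_terms) + 1L]] <- data.frame(
          chrom = chrom, start = round(ok_x - cfg$event_gap / 2),
          end = round(ok_x + cfg$event_gap / 2), read_id = read_id)
      }
      # stash label intervals on the read-local list
      if (!exists("read_labels", inherits = FALSE)) read_labels <- list()
      read_labels[[length(read_labels) + 1L]] <- fks
    }
    # thymidine positions and emissions
    pos <- ref_start + which(stats::runif(L) < cfg$at_fraction / 2) - 1L
    lab_e <- rep(FALSE, length(pos))
    p_lab_b <- rep(0, length(pos))  # probability each position is BrdU-labelled
    if (exists("read_labels", inherits = FALSE)) {
      for (fks in read_labels) for (f in fks) {
        if (!is.null(f$edu))
          lab_e <- lab_e | (pos >= f$edu[1] & pos < f$edu[2])
        if (!is.null(f$brdu))
          p_lab_b[pos >= f$brdu[1] & pos < f$brdu[2]] <- 1
        if (!is.null(f$tail)) {
          sel <- pos >= f$tail[1] & pos < f$tail[2]
          if (any(sel)) {
            d <- if (f$dir > 0) pos[sel] - f$tail[1] else f$tail[2] - pos[sel]
            p_lab_b[sel] <- pmax(p_lab_b[sel],
                                 exp(-d / (f$v * cfg$chase_tau)))
          }
        }
      }
      rm(read_labels)
    }
    lab_b <- stats::runif(length(pos)) < p_lab_b
    em <- cfg$emission
    n <- length(pos)
    if (cfg$noise_free) {
      p_edu <- as.numeric(lab_e)
      p_brdu <- as.numeric(lab_b)
    } else {
      p_edu <- ifelse(lab_e, stats::rbeta(n, em[["a_pos"]], em[["b_pos"]]),
                      stats::rbeta(n, em[["a_neg"]], em[["b_neg"]]))
      p_brdu <- ifelse(lab_b, stats::rbeta(n, em[["a_pos"]], em[["b_pos"]]),
                       stats::rbeta(n, em[["a_neg"]], em[["b_neg"]]))
    }
    gaps <- NULL
    if (cfg$indel_rate > 0) {
      ng <- stats::rpois(1, cfg$indel_rate * L / 1000)
      if (ng > 0)
        gaps <- data.frame(
          pos = as.integer(floor(stats::runif(ng, ref_start, ref_end - 1))),
          length = as.integer(ceiling(stats::rlnorm(ng, cfg$indel_meanlog,
                                                    cfg$indel_sdlog))))
    }
    tracks[[r]] <- analogue_track(read_id, chrom, ref_start, ref_end, "+",
                                  pos, p_edu, p_brdu, gaps = gaps,
                                  min_length = 0L)
  }
  tf <- if (length(truth_forks)) do.call(rbind, truth_forks) else
    data.frame(read_id = character(0), chrom = character(0),
               direction = character(0), speed = numeric(0),
               edu_start = numeric(0), edu_end = numeric(0),
               brdu_start = numeric(0), brdu_end = numeric(0),
               event = character(0), stalled = logical(0),
               stall_time = numeric(0))
  tf$track_start <- ifelse(tf$direction == "rightward", tf$edu_start,
                           tf$brdu_start)
  tf$track_end <- ifelse(tf$direction == "rightward", tf$brdu_end,
                         tf$edu_end)
  if (!nrow(tf))
    warning("simulation produced zero forks")
  list(tracks = tracks,
       truth = list(
         forks = tf,
         origins = if (length(truth_origins)) do.call(rbind, truth_origins)
           else data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), read_id = character(0)),
         terminations = if (length(truth_terms)) do.call(rbind, truth_terms)
           else data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), read_id = character(0))),
       config = cfg, seed = seed)
}

#' Compare fork calls against simulator ground truth
#'
#' A call matches a truth fork if they are on the same read, agree in
#' direction, and both track boundaries are within `tolerance` bp. Matching
#' is greedy by total boundary offset and one-to-one.
#'
#' @param calls Fork-call data.frame (needs `read_id`, `direction`,
#'   `track_start`, `track_end`).
#' @param truth Ground-truth fork data.frame from [simulate_experiment()];
#'   forks lacking either analogue segment in truth are not expected to be
#'   called and are excluded from recall.
#' @param tolerance Boundary tolerance in bp.
#' @return A list: `precision`, `recall` (NA when undefined),
#'   `mean_boundary_error`, `n_calls`, `n_truth`, `n_matched`.
#' @export
truth_compare <- function(calls, truth, tolerance = 1000) {
  truth <- truth[!is.na(truth$edu_start) & !is.na(truth$brdu_start), ,
                 drop = FALSE]
  n_calls <- if (is.null(calls)) 0L else nrow(calls)
  n_truth <- nrow(truth)
  if (n_calls == 0L)
    return(list(precision = NA_real_, recall = if (n_truth) 0 else NA_real_,
                mean_boundary_error = NA_real_, n_calls = 0L,
                n_truth = n_truth, n_matched = 0L))
  pairs <- NULL
  for (i in seq_len(n_calls)) {
    cand <- which(truth$read_id == calls$read_id[i] &
                    truth$direction == calls$direction[i])
    for (j in cand) {
      d1 <- abs(calls$track_start[i] - truth$track_start[j])
      d2 <- abs(calls$track_end[i] - truth$track_end[j])
      if (d1 <= tolerance && d2 <= tolerance)
        pairs <- rbind(pairs, c(i, j, (d1 + d2) / 2))
    }
  }
  matched_c <- logical(n_calls); matched_t <- logical(n_truth)
  errs <- numeric(0); n_matched <- 0L
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (matched_c[i] || matched_t[j]) next
      matched_c[i] <- matched_t[j] <- TRUE
      errs <- c(errs, pairs[k, 3]); n_matched <- n_matched + 1L
    }
  }
  list(precision = n_matched / n_calls,
       recall = if (n_truth) n_matched / n_truth else NA_real_,
       mean_boundary_error = if (n_matched) mean(errs) else NA_real_,
       n_calls = n_calls, n_truth = n_truth, n_matched = n_matched)
}
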