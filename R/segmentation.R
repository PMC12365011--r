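#' Segmentation parameters
#'
#' Parameters controlling how reads are segmented into analogue-positive
#' tracks and how tracks are paired into forks.
#'
#' @param call_threshold Probability above which (strictly) a per-thymidine
#'   analogue call is positive. Default 0.5.
#' @param window_size Sliding-window width in genomic bp used for candidate
#'   detection and trimming. Default 1000.
#' @param window_fraction_floor Minimum positive-call fraction for a window to
#'   be analogue-positive. Default 0.3.
#' @param min_track_length Candidate segments shorter than this (bp) are
#'   discarded. Default 1000.
#' @param max_pair_gap Maximum gap (bp) between an EdU and a BrdU segment for
#'   them to be paired into one fork. Default 5000.
#' @param min_window_thymidines Minimum thymidines a window must contain to be
#'   scored; guards AT-poor windows. Default 5.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(call_threshold = 0.5, window_size = 1000L,
                                window_fraction_floor = 0.3,
                                min_track_length = 1000L,
                                max_pair_gap = 5000L,
                                min_window_thymidines = 5L) {
  stopifnot(call_threshold > 0, call_threshold < 1, window_size > 0,
            window_fraction_floor > 0, window_fraction_floor < 1,
            min_track_length >= 0, max_pair_gap >= 0,
            min_window_thymidines >= 1)
  structure(list(call_threshold = call_threshold,
                 window_size = as.integer(window_size),
                 window_fraction_floor = window_fraction_floor,
                 min_track_length = as.integer(min_track_length),
                 max_pair_gap = as.integer(max_pair_gap),
                 min_window_thymidines = as.integer(min_window_thymidines)),
            class = "segmentation_params")
}

#' Positive analogue calls on a track
#'
#' A thymidine position is a positive call for an analogue iff its probability
#' strictly exceeds the threshold.
#'
#' @param track An [analogue_track()].
#' @param analogue `"EdU"` or `"BrdU"`.
#' @param threshold Call threshold in (0, 1). Default 0.5.
#' @return Logical vector, one element per thymidine position.
#' @export
positive_calls <- function(track, analogue = c("EdU", "BrdU"),
                           threshold = 0.5) {
  analogue <- match.arg(analogue)
  stopifnot(threshold > 0, threshold < 1)
  p <- if (analogue == "EdU") track$p_edu else track$p_brdu
  p > threshold
}

# Window scan shared by candidate detection and trimming: for anchor index i,
# the window covers thymidines in [pos[i], pos[i] + w). Returns the index of
# the last thymidine in each window and cumulative call counts.
.window_ends <- function(positions, w) {
  findInterval(positions + w - 1e-9, positions)
}

#' Candidate analogue-positive segments on a read
#'
#' Slides a genomic window across the thymidine positions; a window is
#' positive for the analogue if it holds at least `min_window_thymidines`
#' thymidines, its positive-call fraction is at least
#' `window_fraction_floor`, and that fraction exceeds the positive-call
#' fraction of the other analogue in the same window. Maximal runs of
#' positions covered by positive windows become candidate segments; runs
#' shorter than `min_track_length` are dropped.
#'
#' @inheritParams positive_calls
#' @param params A [segmentation_params()] object.
#' @return A data.frame with columns `read_id`, `chrom`, `start`, `end`,
#'   `analogue` (0-based half-open coordinates); zero rows if none.
#' @export
candidate_segments <- function(track, analogue = c("EdU", "BrdU"), params = segmentation_params()) {
  analogue <- match.arg(analogue)
  pos <- track$positions
  n <- length(pos)
  empty <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      analogue = character(0))
  if (n == 0L) return(empty)
  calls_a <- positive_calls(track, analogue, params$call_threshold)
  other <- if (analogue == "EdU") "BrdU" else "EdU"
  calls_b <- positive_calls(track, other, params$call_threshold)
  ends <- .window_ends(pos, params$window_size)
  cum_a <- cumsum(calls_a); cum_b <- cumsum(calls_b)
  cnt <- ends - seq_len(n) + 1L
  sum_a <- cum_a[ends] - c(0, cum_a)[seq_len(n)]
  sum_b <- cum_b[ends] - c(0, cum_b)[seq_len(n)]
  frac_a <- sum_a / cnt; frac_b <- sum_b / cnt
  ok <- cnt >= params$min_window_thymidines &
    frac_a >= params$window_fraction_floor & frac_a > frac_b
  if (!any(ok)) return(empty)
  # positions covered by any qualifying window, via a difference array
  cov <- integer(n + 1L)
  oi <- which(ok)
  for (i in oi) { cov[i] <- cov[i] + 1L; cov[ends[i] + 1L] <- cov[ends[i] + 1L] - 1L }
  covered <- cumsum(cov[seq_len(n)]) > 0L
  r <- rle(covered)
  run_end <- cumsum(r$lengths); run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  segs <- data.frame(read_id = track$read_id, chrom = track$chrom,
                     start = pos[run_start[keep]],
                     end = pos[run_end[keep]] + 1L,
                     analogue = analogue)
  segs[segs$end - segs$start >= params$min_track_length, , drop = FALSE]
}

#' Trim a candidate segment to its incorporation plateau
#'
#' Computes the positive-call fraction over the middle third of the segment
#' and advances a window of `window_size` bp inward from each end until the
#' window's positive fraction reaches that reference level; the trimmed
#' segment spans from the start of the first qualifying window on the left to
#' the end of the first qualifying window on the right. Segments too short to
#' hold a middle third plus a window at each end are returned unchanged with
#' attribute `trimmed = FALSE`.
#'
#' @param track The segment's [analogue_track()].
#' @param segment One row of the data.frame from [candidate_segments()].
#' @param params A [segmentation_params()].
#' @return A one-row segment data.frame (same columns), with attribute
#'   `trimmed`.
#' @export
trim_segment <- function(track, segment, params = segmentation_params()) {
  w <- params$window_size
  s <- segment$start; e <- segment$end
  if (e - s < 3L * w) {
    attr(segment, "trimmed") <- FALSE
    return(segment)
  }
  pos <- track$positions
  calls <- positive_calls(track, segment$analogue, params$call_threshold)
  in_seg <- pos >= s & pos < e
  idx <- which(in_seg)
  if (!length(idx)) { attr(segment, "trimmed") <- FALSE; return(segment) }
  third <- (e - s) / 3
  mid <- pos >= s + third & pos < e - third
  f_star <- mean(calls[mid])
  if (!is.finite(f_star)) { attr(segment, "trimmed") <- FALSE; return(segment) }
  p_in <- pos[idx]; c_in <- calls[idx]
  m <- length(p_in)
  cum <- c(0, cumsum(c_in))
  # left scan: windows [p_in[i], p_in[i] + w)
  ends <- findInterval(p_in + w - 1e-9, p_in)
  frac_l <- (cum[ends + 1L] - cum[seq_len(m)]) / (ends - seq_len(m) + 1L)
  li <- which(frac_l >= f_star & p_in + w <= e)
  # right scan: windows (p_in[j] + 1 - w, p_in[j] + 1]
  starts <- findInterval(p_in + 1 - w, p_in) + 1L
  frac_r <- (cum[seq_len(m) + 1L] - cum[starts]) / (seq_len(m) - starts + 1L)
  ri <- which(frac_r >= f_star & p_in + 1L - w >= s)
  if (!length(li) || !length(ri)) {
    attr(segment, "trimmed") <- FALSE
    return(segment)
  }
  new_s <- p_in[min(li)]
  new_e <- p_in[max(ri)] + 1L
  if (new_e <= new_s) { attr(segment, "trimmed") <- FALSE; return(segment) }
  segment$start <- max(s, new_s)
  segment$end <- min(e, new_e)
  attr(segment, "trimmed") <- TRUE
  segment
}

# Trim every row of a segment data.frame.
.trim_all <- function(track, segs, params) {
  if (!nrow(segs)) return(segs)
  out <- lapply(seq_len(nrow(segs)), function(i)
    trim_segment(track, segs[i, , drop = FALSE], params))
  do.call(rbind, out)
}

#' Call replication forks, origins and terminations on one read
#'
#' Segments the read into EdU- and BrdU-positive tracks (candidate detection
#' plus plateau trimming), then pairs adjacent EdU/BrdU segments separated by
#' at most `max_pair_gap` into forks. An EdU segment upstream of its BrdU
#' partner (in reference coordinates) makes a rightward fork; downstream makes
#' a leftward fork — the EdU pulse precedes the BrdU pulse, so the EdU track
#' marks where the fork started. Two diverging forks whose EdU segments are
#' adjacent are called an origin; two converging forks whose BrdU segments
#' are adjacent are called a termination. Each segment joins at most one
#' fork; when a segment could pair on both sides the smaller gap wins.
#'
#' @param track An [analogue_track()].
#' @param params A [segmentation_params()].
#' @return A list with elements `forks` (data.frame: read_id, chrom,
#'   direction, edu_start, edu_end, brdu_start, brdu_end, track_start,
#'   track_end, ref_start, ref_end, and logical flag columns), `origins` and
#'   `terminations` (data.frames: chrom, start, end, read_id).
#' @export
call_forks <- function(track, params = segmentation_params()) {
  segs_e <- .trim_all(track, candidate_segments(track, "EdU", params), params)
  segs_b <- .trim_all(track, candidate_segments(track, "BrdU", params), params)
  empty_iv <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), read_id = character(0))
  mk_forks <- function(rows) {
    if (!length(rows)) return(.empty_forks())
    do.call(rbind, rows)
  }
  if (!nrow(segs_e) || !nrow(segs_b))
    return(list(forks = .empty_forks(), origins = empty_iv,
                terminations = empty_iv))
  # candidate pairings: every ordered (EdU, BrdU) pair with gap at most
  # max_pair_gap; window-edge noise can make adjacent segments overlap
  # slightly, so an overlap of up to one window is tolerated
  tol <- params$window_size
  cand <- NULL
  for (i in seq_len(nrow(segs_e))) for (j in seq_len(nrow(segs_b))) {
    e <- segs_e[i, ]; b <- segs_b[j, ]
    if (b$start >= e$end - tol && b$start > e$start && b$end > e$end) {
      gap <- b$start - e$end           # EdU then BrdU: rightward
      dir <- "rightward"
    } else if (e$start >= b$end - tol && e$start > b$start && e$end > b$end) {
      gap <- e$start - b$end           # BrdU then EdU: leftward
      dir <- "leftward"
    } else next
    if (gap <= params$max_pair_gap)
      cand <- rbind(cand, data.frame(i = i, j = j, gap = gap, dir = dir))
  }
  if (is.null(cand))
    return(list(forks = .empty_forks(), origins = empty_iv,
                terminations = empty_iv))
  cand <- cand[order(cand$gap), ]
  used_e <- logical(nrow(segs_e)); used_b <- logical(nrow(segs_b))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used_e[i] || used_b[j]) next
    used_e[i] <- TRUE; used_b[j] <- TRUE
    e <- segs_e[i, ]; b <- segs_b[j, ]
    right <- cand$dir[k] == "rightward"
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = track$read_id, chrom = track$chrom,
      direction = cand$dir[k],
      edu_start = e$start, edu_end = e$end,
      brdu_start = b$start, brdu_end = b$end,
      track_start = if (right) e$start else b$start,
      track_end = if (right) b$end else e$end,
      ref_start = track$ref_start, ref_end = track$ref_end,
      on_read_with_origin = FALSE, on_read_with_termination = FALSE,
      origin_member = FALSE, termination_member = FALSE)
  }
  forks <- mk_forks(rows)
  if (!nrow(forks))
    return(list(forks = forks, origins = empty_iv, terminations = empty_iv))
  forks <- forks[order(forks$track_start), ]
  rownames(forks) <- NULL
  origins <- empty_iv; terminations <- empty_iv
  if (nrow(forks) >= 2L) {
    for (k in seq_len(nrow(forks) - 1L)) {
      f1 <- forks[k, ]; f2 <- forks[k + 1L, ]
      if (f1$direction == "leftward" && f2$direction == "rightward" &&
          f2$edu_start >= f1$edu_end - tol &&
          f2$edu_start - f1$edu_end <= params$max_pair_gap) {
        origins <- rbind(origins, data.frame(
          chrom = track$chrom, start = min(f1$edu_end, f2$edu_start),
          end = f2$edu_start, read_id = track$read_id))
        forks$origin_member[c(k, k + 1L)] <- TRUE
      }
      if (f1$direction == "rightward" && f2$direction == "leftward" &&
          f2$brdu_start >= f1$brdu_end - tol &&
          f2$brdu_start - f1$brdu_end <= params$max_pair_gap) {
        terminations <- rbind(terminations, data.frame(
          chrom = track$chrom, start = min(f1$brdu_end, f2$brdu_start),
          end = f2$brdu_start, read_id = track$read_id))
        forks$termination_member[c(k, k + 1L)] <- TRUE
      }
    }
  }
  if (nrow(origins)) forks$on_read_with_origin <- TRUE
  if (nrow(terminations)) forks$on_read_with_termination <- TRUE
  list(forks = forks, origins = origins, terminations = terminations)
}

.empty_forks <- function() {
  data.frame(read_id = character(0), chrom = character(0),
             direction = character(0),
             edu_start = integer(0), edu_end = integer(0),
             brdu_start = integer(0), brdu_end = integer(0),
             track_start = integer(0), track_end = integer(0),
             ref_start = integer(0), ref_end = integer(0),
             on_read_with_origin = logical(0),
             on_read_with_termination = logical(0),
             origin_member = logical(0), termination_member = logical(0))
}

#' Call forks on a collection of tracks
#'
#' Convenience wrapper applying [call_forks()] to each track and binding the
#' results.
#'
#' @param tracks List of [analogue_track()] objects.
#' @param params A [segmentation_params()].
#' @return As [call_forks()], with rows from all reads.
#' @export
call_forks_all <- function(tracks, params = segmentation_params()) {
  res <- lapply(tracks, call_forks, params = params)
  list(forks = do.call(rbind, c(lapply(res, `[[`, "forks"),
                                list(make.row.names = FALSE))),
       origins = do.call(rbind, lapply(res, `[[`, "origins")),
       terminations = do.call(rbind, lapply(res, `[[`, "terminations")))
}
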