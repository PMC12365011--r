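#' Fork-speed parameters
#'
#' @param pulse_minutes Total analogue pulse duration in minutes (5 min EdU +
#'   10 min BrdU = 15 by default).
#' @param read_end_margin Forks starting or ending within this many bp of the
#'   read end are excluded from speed analysis. Default 3000.
#' @return A list of class `speed_params`.
#' @export
speed_params <- function(pulse_minutes = 15, read_end_margin = 3000L) {
  stopifnot(pulse_minutes > 0, read_end_margin >= 0)
  structure(list(pulse_minutes = pulse_minutes,
                 read_end_margin = as.integer(read_end_margin)),
            class = "speed_params")
}

#' Stall-score parameters
#'
#' The two published parameter presets for the nonlinear stall-score scaling
#' are available as `stall_params("v3")` (alpha 1.55, beta 3; the v3.1.2
#' calibration) and `stall_params("v4")` (alpha 2.63, beta 1; the v4.0.3
#' calibration for the cleaner R10.4.1 calls).
#'
#' @param preset `"v3"` or `"v4"`, or `NULL` to set `alpha`/`beta` directly.
#' @param alpha,beta Positive scaling parameters (override the preset).
#' @param window Genomic window in bp over which the BrdU-call frequencies B
#'   and A are measured. Default 2000.
#' @param call_threshold Positive-call threshold. Default 0.5.
#' @param max_indel Largest tolerated insertion/deletion (bp) inside either
#'   window; larger indels decline the score. Default 100.
#' @param min_thymidines Minimum thymidines required in each window. Default
#'   10.
#' @return A list of class `stall_params`.
#' @export
stall_params <- function(preset = c("v3", "v4"), alpha = NULL, beta = NULL,
                         window = 2000L, call_threshold = 0.5,
                         max_indel = 100L, min_thymidines = 10L) {
  if (is.null(alpha) || is.null(beta)) {
    preset <- match.arg(preset)
    ab <- switch(preset, v3 = c(1.55, 3), v4 = c(2.63, 1))
    if (is.null(alpha)) alpha <- ab[1L]
    if (is.null(beta)) beta <- ab[2L]
  }
  stopifnot(alpha > 0, beta > 0, window > 0, call_threshold > 0,
            call_threshold < 1, max_indel >= 0, min_thymidines >= 1)
  structure(list(alpha = alpha, beta = beta, window = as.integer(window),
                 call_threshold = call_threshold,
                 max_indel = as.integer(max_indel),
                 min_thymidines = as.integer(min_thymidines)),
            class = "stall_params")
}

#' Fork speed with exclusion rules
#'
#' Speed is the fork-track length (far end of the EdU segment to far end of
#' the BrdU segment) divided by the total pulse duration. Fork tracks are
#' artificially short when the fork fired from an origin during the pulse,
#' met another fork in a termination, or ran off the sequenced molecule, so
#' forks on a read with a called origin or termination, and forks starting or
#' ending within `read_end_margin` of the read end, are excluded rather than
#' reported.
#'
#' @param forks Fork-call data.frame from [call_forks()]/[call_forks_all()].
#' @param params A [speed_params()].
#' @return `forks` with added columns `speed` (kb/min; `NA` when excluded)
#'   and `speed_exclusion` (`NA`, `"origin_on_read"`,
#'   `"termination_on_read"`, or `"near_read_end"`).
#' @export
fork_speed <- function(forks, params = speed_params()) {
  if (!nrow(forks)) {
    forks$speed <- numeric(0); forks$speed_exclusion <- character(0)
    return(forks)
  }
  m <- params$read_end_margin
  excl <- rep(NA_character_, nrow(forks))
  near <- forks$track_start < forks$ref_start + m |
    forks$track_end > forks$ref_end - m
  excl[near] <- "near_read_end"
  excl[forks$on_read_with_termination] <- "termination_on_read"
  excl[forks$on_read_with_origin] <- "origin_on_read"
  speed <- (forks$track_end - forks$track_start) / 1000 / params$pulse_minutes
  speed[!is.na(excl)] <- NA_real_
  forks$speed <- speed
  forks$speed_exclusion <- excl
  forks
}

#' BrdU-call frequencies inside and outside the BrdU end of a fork
#'
#' Measures the frequency of positive BrdU calls over one genomic window just
#' inside the BrdU end of the fork track (`B`) and one immediately outside it
#' (`A`). The BrdU end is the fork's leading edge at the end of the pulse:
#' the right end of the BrdU segment for a rightward fork, the left end for a
#' leftward fork.
#'
#' @param track The fork's [analogue_track()].
#' @param fork One row of a fork-call data.frame.
#' @param params A [stall_params()].
#' @return A list with `B`, `A`, `n_inside`, `n_outside`, and `declined`
#'   (`NA` or one of `"termination_member"`, `"off_read"`,
#'   `"indel_in_window"`, `"too_few_thymidines"`).
#' @export
stall_windows <- function(track, fork, params = stall_params("v3")) {
  w <- params$window
  declined <- function(reason) list(B = NA_real_, A = NA_real_,
                                    n_inside = NA_integer_,
                                    n_outside = NA_integer_,
                                    declined = reason)
  if (isTRUE(fork$termination_member)) return(declined("termination_member"))
  right <- fork$direction == "rightward"
  if (right) {
    inside <- c(fork$brdu_end - w, fork$brdu_end)
    outside <- c(fork$brdu_end, fork$brdu_end + w)
  } else {
    inside <- c(fork$brdu_start, fork$brdu_start + w)
    outside <- c(fork$brdu_start - w, fork$brdu_start)
  }
  if (outside[1L] < track$ref_start || outside[2L] > track$ref_end ||
      inside[1L] < track$ref_start || inside[2L] > track$ref_end)
    return(declined("off_read"))
  if (!is.null(track$gaps) && nrow(track$gaps)) {
    g <- track$gaps
    g_end <- g$pos + g$length
    hits <- function(win) any(g$length > params$max_indel &
                                g$pos < win[2L] & g_end > win[1L])
    if (hits(inside) || hits(outside)) return(declined("indel_in_window"))
  }
  pos <- track$positions
  calls <- track$p_brdu > params$call_threshold
  in_i <- pos >= inside[1L] & pos < inside[2L]
  in_o <- pos >= outside[1L] & pos < outside[2L]
  n_i <- sum(in_i); n_o <- sum(in_o)
  if (n_i < params$min_thymidines || n_o < params$min_thymidines)
    return(declined("too_few_thymidines"))
  list(B = sum(calls[in_i]) / n_i, A = sum(calls[in_o]) / n_o,
       n_inside = n_i, n_outside = n_o, declined = NA_character_)
}

#' Nonlinear scaling of the raw stall score
#'
#' Maps the raw score R = (B - A)/B onto a stall score in \[0, 1\] via the
#' shifted-softplus transform
#' `alpha * log(1 + exp(beta * (R - 1))) - alpha * log(1 + exp(-beta))`,
#' clamped below at 0. The transform is monotone in R, exactly 0 at R = 0,
#' and both published presets map R = 1 to just under 1: raw scores in the
#' 0.2-0.4 range typical of unstalled forks are pushed towards 0 while only
#' high raw scores keep values near 1.
#'
#' @param R Raw score(s), at most 1 (may be negative when A > B).
#' @param params A [stall_params()] carrying `alpha` and `beta`.
#' @return Stall score(s) in \[0, 1\].
#' @export
stall_scale <- function(R, params = stall_params("v3")) {
  if (any(R > 1 + 1e-12, na.rm = TRUE)) stop("raw stall score R must be <= 1")
  a <- params$alpha; b <- params$beta
  pmax(0, a * log1p(exp(b * (R - 1))) - a * log1p(exp(-b)))
}

#' Stall score of one fork
#'
#' Chains [stall_windows()] and [stall_scale()]: computes the BrdU-call
#' frequencies B (inside window) and A (outside window), the raw score
#' R = (B - A)/B, and the scaled stall score. Declines propagate; a fork with
#' B = 0 is declined (`zero_B`) since R is undefined there.
#'
#' @inheritParams stall_windows
#' @return A list of class `stall_result` with fields `B`, `A`, `R`, `score`,
#'   `declined`.
#' @export
stall_score <- function(track, fork, params = stall_params("v3")) {
  win <- stall_windows(track, fork, params)
  out <- list(B = win$B, A = win$A, R = NA_real_, score = NA_real_,
              declined = win$declined)
  if (is.na(win$declined)) {
    if (win$B == 0) {
      out$declined <- "zero_B"
    } else {
      out$R <- (win$B - win$A) / win$B
      out$score <- stall_scale(out$R, params)
    }
  }
  class(out) <- "stall_result"
  out
}

#' @export
print.stall_result <- function(x, ...) {
  if (!is.na(x$declined)) {
    cat("<stall_result> declined:", x$declined, "\n")
  } else {
    cat(sprintf("<stall_result> B=%.3f A=%.3f R=%.3f score=%.3f\n",
                x$B, x$A, x$R, x$score))
  }
  invisible(x)
}

#' Per-fork metrics table
#'
#' Runs speed and stall scoring over all called forks and returns one row per
#' fork, the table consumed by the signature, timing and treatment-effect
#' stages.
#'
#' @param tracks List of [analogue_track()] objects.
#' @param forks Fork-call data.frame (from [call_forks_all()] on `tracks`).
#' @param speed_par A [speed_params()].
#' @param stall_par A [stall_params()].
#' @return Data.frame: fork-call columns plus `speed`, `speed_exclusion`,
#'   `B`, `A`, `R`, `stall`, `stall_declined`.
#' @export
fork_metrics <- function(tracks, forks, speed_par = speed_params(),
                         stall_par = stall_params("v3")) {
  forks <- fork_speed(forks, speed_par)
  if (!nrow(forks)) {
    forks$B <- forks$A <- forks$R <- forks$stall <- numeric(0)
    forks$stall_declined <- character(0)
    return(forks)
  }
  track_by_id <- stats::setNames(tracks, vapply(tracks, `[[`, "", "read_id"))
  res <- lapply(seq_len(nrow(forks)), function(i) {
    tr <- track_by_id[[forks$read_id[i]]]
    if (is.null(tr))
      stop("no track found for read ", forks$read_id[i])
    stall_score(tr, forks[i, ], stall_par)
  })
  forks$B <- vapply(res, `[[`, 0, "B")
  forks$A <- vapply(res, `[[`, 0, "A")
  forks$R <- vapply(res, `[[`, 0, "R")
  forks$stall <- vapply(res, `[[`, 0, "score")
  forks$stall_declined <- vapply(res, `[[`, "", "declined")
  forks
}
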