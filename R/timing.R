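#' Fit Trep (median replication time) to one bin's timing signal
#'
#' Takes the per-S-phase-fraction replication signal of one genomic bin,
#' forms the cumulative fraction replicated (normalised to \[0, 1\]), and
#' fits the logistic curve S(t) = 1 / (1 + exp(-k (t - Trep))) by least
#' squares. Trep is the half-replicated time in hours. The fit is invariant
#' to uniform rescaling of the raw signal because of the normalisation.
#'
#' @param signal Numeric vector of per-fraction signal (one value per
#'   S-phase fraction), non-negative.
#' @param hours Numeric vector, same length: hour in S-phase of each
#'   fraction.
#' @param max_resid Root-mean-square residual above which the fit is
#'   rejected. Default 0.15.
#' @return Trep in hours, or `NA_real_` if the signal is degenerate or the
#'   fit fails/exceeds `max_resid`.
#' @export
fit_trep <- function(signal, hours, max_resid = 0.15) {
  stopifnot(length(signal) == length(hours))
  if (length(signal) < 4 || anyNA(signal) || all(signal == 0) ||
      any(signal < 0))
    return(NA_real_)
  s <- cumsum(signal) / sum(signal)
  # crude midpoint from the first 0.5 crossing, for initialisation
  i <- which(s >= 0.5)[1]
  t0 <- if (i == 1) hours[1] else {
    stats::approx(s[c(i - 1, i)], hours[c(i - 1, i)], xout = 0.5)$y
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(k = 1, trep = t0),
                       fn = function(p) s - 1 / (1 + exp(-p[1] * (hours - p[2]))),
                       lower = c(1e-3, min(hours) - 5),
                       upper = c(100, max(hours) + 5),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  if (sqrt(mean(fit$fvec^2)) > max_resid) return(NA_real_)
  unname(fit$par[["trep"]])
}

#' Compute Trep for every bin of a multi-fraction timing profile
#'
#' @param profile Data.frame with columns `chrom`, `bin_start`, and one
#'   numeric column per S-phase fraction.
#' @param hours Hour-in-S-phase of each fraction column, in column order.
#' @param fraction_cols Names of the fraction columns; defaults to every
#'   column except `chrom` and `bin_start`.
#' @return `profile` with an added `trep` column (`NA` where the fit failed).
#' @export
trep_profile <- function(profile, hours, fraction_cols = NULL) {
  if (is.null(fraction_cols))
    fraction_cols <- setdiff(names(profile), c("chrom", "bin_start"))
  stopifnot(length(fraction_cols) == length(hours))
  sig <- as.matrix(profile[, fraction_cols, drop = FALSE])
  profile$trep <- apply(sig, 1, fit_trep, hours = hours)
  profile
}

#' Annotate forks with the Trep of their genomic bin
#'
#' Each fork is assigned the Trep of the fixed-width bin containing its
#' fork-track midpoint (midpoints exactly on a boundary go to the right,
#' half-open, bin). Forks in bins with no or failed Trep, or on chromosomes
#' absent from the profile, are dropped with a warning.
#'
#' @param forks Fork data.frame with `chrom`, `track_start`, `track_end`.
#' @param profile Output of [trep_profile()] (needs `chrom`, `bin_start`,
#'   `trep`).
#' @param bin_size Bin width in bp. Default 50000.
#' @return `forks` rows that mapped, with an added `trep` column.
#' @export
assign_trep <- function(forks, profile, bin_size = 50000L) {
  mid <- floor((forks$track_start + forks$track_end) / 2)
  bin <- floor(mid / bin_size) * bin_size
  key <- paste(forks$chrom, bin)
  pkey <- paste(profile$chrom, profile$bin_start)
  trep <- profile$trep[match(key, pkey)]
  drop <- is.na(trep)
  if (any(drop))
    warning(sum(drop), " fork(s) dropped: bin missing or Trep fit failed")
  out <- forks[!drop, , drop = FALSE]
  out$trep <- trep[!drop]
  out
}

#' S-phase trend of a per-fork metric
#'
#' Groups forks by integer hour of Trep, takes the per-hour median of the
#' metric, and regresses median on hour by ordinary least squares. Reports
#' the Pearson correlation of the medians, the slope, and a one-sided
#' p-value under the stated alternative (slope greater than zero is the
#' natural alternative for fork speed, less than zero for stall score).
#'
#' @param forks Data.frame with a `trep` column (see [assign_trep()]) and
#'   the metric column.
#' @param metric Name of the metric column (e.g. `"speed"` or `"stall"`).
#' @param alternative `"greater"` or `"less"`: direction of the slope under
#'   the alternative hypothesis.
#' @param min_forks_per_hour Hours with fewer forks than this are dropped.
#'   Default 5.
#' @return An object of class `sphase_trend`: list with `medians`
#'   (data.frame hour/median/n), `pearson_r`, `slope`, `intercept`,
#'   `p_value`, `alternative`.
#' @export
sphase_trend <- function(forks, metric = c("speed", "stall"),
                         alternative = c("greater", "less"),
                         min_forks_per_hour = 5L) {
  metric <- match.arg(metric)
  alternative <- match.arg(alternative)
  y <- forks[[metric]]
  ok <- !is.na(y) & !is.na(forks$trep)
  hour <- floor(forks$trep[ok]); y <- y[ok]
  med <- stats::aggregate(y, list(hour = hour), stats::median)
  n <- stats::aggregate(y, list(hour = hour), length)
  keep <- n$x >= min_forks_per_hour
  med <- med[keep, ]; n <- n[keep, ]
  if (nrow(med) < 3)
    stop("need at least 3 S-phase hours with >= ", min_forks_per_hour,
         " forks each; got ", nrow(med))
  fit <- stats::lm(x ~ hour, data = med)
  sm <- summary(fit)
  slope <- sm$coefficients["hour", "Estimate"]
  tval <- sm$coefficients["hour", "t value"]
  df <- fit$df.residual
  p <- stats::pt(tval, df, lower.tail = (alternative == "less"))
  structure(list(medians = data.frame(hour = med$hour, median = med$x,
                                      n = n$x),
                 pearson_r = stats::cor(med$hour, med$x),
                 slope = slope,
                 intercept = sm$coefficients["(Intercept)", "Estimate"],
                 p_value = p, alternative = alternative, metric = metric),
            class = "sphase_trend")
}

#' @export
print.sphase_trend <- function(x, ...) {
  cat("<sphase_trend> ", x$metric, " vs Trep over ", nrow(x$medians),
      " hours\n", sep = "")
  cat(sprintf("  Pearson R = %.3f, slope = %.4f per hour, one-sided p (slope %s 0) = %.4g\n",
              x$pearson_r, x$slope,
              if (x$alternative == "greater") ">" else "<", x$p_value))
  invisible(x)
}
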