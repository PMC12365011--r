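#' Construct an analogue-probability track for one read
#'
#' An analogue track holds the mapped coordinates of a single nanopore read
#' together with the probability of BrdU and of EdU at every thymidine
#' position, as produced by a base-analogue caller. All coordinates are
#' 0-based, half-open, on the reference.
#'
#' @param read_id Read identifier (single string, no whitespace).
#' @param chrom Reference sequence name.
#' @param ref_start,ref_end Mapped interval of the read on the reference (bp).
#' @param strand `"+"` or `"-"`. Strand is recorded for provenance; fork
#'   direction is always defined on reference coordinates.
#' @param positions Strictly increasing integer vector of thymidine reference
#'   coordinates, all within `[ref_start, ref_end)`.
#' @param p_edu,p_brdu Numeric vectors, same length as `positions`, each value
#'   in `[0, 1]`: per-position probability that the thymidine is EdU / BrdU.
#' @param gaps Optional two-column data.frame (`pos`, `length`) of alignment
#'   insertions/deletions of at least 1 bp. `NULL` means "no indel
#'   information", which disables the indel-based stall decline rule.
#' @param min_length Minimum mapped length in bp accepted for fork calling
#'   (default 20000, matching the 20 kb minimum mapping length used for
#'   analogue detection). Set to 0 to accept short synthetic fixtures.
#' @return An object of class `analogue_track`.
#' @export
analogue_track <- function(read_id, chrom, ref_start, ref_end, strand = "+",
                           positions, p_edu, p_brdu, gaps = NULL,
                           min_length = 20000L) {
  stopifnot(length(read_id) == 1L, length(chrom) == 1L)
  ref_start <- as.integer(ref_start); ref_end <- as.integer(ref_end)
  positions <- as.integer(positions)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  if (ref_end - ref_start < min_length)
    stop("read ", read_id, ": mapped length ", ref_end - ref_start,
         " bp is below the minimum of ", min_length, " bp")
  n <- length(positions)
  if (length(p_edu) != n || length(p_brdu) != n)
    stop("read ", read_id, ": positions, p_edu and p_brdu must be equal length")
  if (n > 0L) {
    if (any(diff(positions) <= 0L))
      stop("read ", read_id, ": positions must be strictly increasing")
    if (positions[1L] < ref_start || positions[n] >= ref_end)
      stop("read ", read_id, ": positions must lie in [ref_start, ref_end)")
  }
  if (any(p_edu < 0 | p_edu > 1) || any(p_brdu < 0 | p_brdu > 1))
    stop("read ", read_id, ": probabilities must lie in [0, 1]")
  if (!is.null(gaps)) {
    gaps <- as.data.frame(gaps)
    stopifnot(all(c("pos", "length") %in% names(gaps)))
    gaps$pos <- as.integer(gaps$pos); gaps$length <- as.integer(gaps$length)
    if (nrow(gaps) && any(gaps$length < 1L))
      stop("read ", read_id, ": gap lengths must be >= 1 bp")
  }
  structure(list(read_id = read_id, chrom = chrom,
                 ref_start = ref_start, ref_end = ref_end, strand = strand,
                 positions = positions,
                 p_edu = as.numeric(p_edu), p_brdu = as.numeric(p_brdu),
                 gaps = gaps),
            class = "analogue_track")
}

#' @export
print.analogue_track <- function(x, ...) {
  cat("<analogue_track> ", x$read_id, "  ", x$chrom, ":", x$ref_start, "-",
      x$ref_end, " (", x$strand, ")  ", length(x$positions),
      " thymidine positions", sep = "")
  if (!is.null(x$gaps) && nrow(x$gaps)) cat(", ", nrow(x$gaps), " gap(s)", sep = "")
  cat("\n")
  invisible(x)
}

#' Read analogue tracks from a detect-format text file
#'
#' The detect dialect is plain text: an optional `# forktrace detect v1`
#' banner, then per read a header line `>read_id chrom ref_start ref_end
#' strand` followed by one line per thymidine, `pos<TAB>p_EdU<TAB>p_BrdU`.
#' Gap (indel) annotations are carried as `#gap pos length` lines inside a
#' record; any other `#`-prefixed line is a comment. Column order is declared
#' in the banner so other dialects can be declared rather than guessed.
#'
#' @param path Path to a detect-format file.
#' @param min_length Minimum mapped read length in bp (see
#'   [analogue_track()]).
#' @return A list of [analogue_track()] objects, in file order.
#' @export
read_tracks <- function(path, min_length = 20000L) {
  if (!file.exists(path)) stop("detect file not found: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx))
    stop("no record headers ('>') found in ", path)
  bounds <- c(hdr_idx, length(lines) + 1L)
  tracks <- vector("list", length(hdr_idx))
  for (r in seq_along(hdr_idx)) {
    i0 <- hdr_idx[r]
    fields <- strsplit(sub("^>", "", lines[i0]), "[ \t]+")[[1L]]
    if (length(fields) != 5L)
      stop("malformed header at line ", i0, " (record ", r,
           "): expected 'read_id chrom ref_start ref_end strand'")
    body <- lines[seq.int(i0 + 1L, bounds[r + 1L] - 1L)]
    if (i0 + 1L > bounds[r + 1L] - 1L) body <- character(0)
    gap_lines <- grep("^#gap\\b", body, value = TRUE)
    data_lines <- body[!grepl("^#", body) & nzchar(body)]
    gaps <- NULL
    if (length(gap_lines)) {
      gp <- do.call(rbind, strsplit(sub("^#gap[ \t]+", "", gap_lines), "[ \t]+"))
      gaps <- data.frame(pos = as.integer(gp[, 1L]),
                         length = as.integer(gp[, 2L]))
    }
    if (length(data_lines)) {
      mat <- matrix(suppressWarnings(
        as.numeric(unlist(strsplit(data_lines, "\t", fixed = TRUE)))),
        ncol = 3L, byrow = TRUE)
      if (anyNA(mat))
        stop("unparseable track line in record ", r, " of ", path)
      pos <- mat[, 1L]; pe <- mat[, 2L]; pb <- mat[, 3L]
    } else {
      pos <- integer(0); pe <- numeric(0); pb <- numeric(0)
    }
    if (length(pos) > 1L && any(diff(pos) <= 0))
      stop("non-monotonic positions in record ", r, " (read ", fields[1L],
           ") of ", path)
    if (length(pe) && (any(pe < 0 | pe > 1) || any(pb < 0 | pb > 1)))
      stop("probability outside [0,1] in record ", r, " (read ", fields[1L],
           ") of ", path)
    tracks[[r]] <- analogue_track(
      read_id = fields[1L], chrom = fields[2L],
      ref_start = as.integer(fields[3L]), ref_end = as.integer(fields[4L]),
      strand = fields[5L], positions = pos, p_edu = pe, p_brdu = pb,
      gaps = gaps, min_length = min_length)
  }
  tracks
}

#' Write analogue tracks to a detect-format text file
#'
#' Inverse of [read_tracks()]: probabilities are written with six decimal
#' places, gap annotations as `#gap pos length` lines.
#'
#' @param tracks A list of [analogue_track()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# forktrace detect v1",
               "# columns: pos p_EdU p_BrdU"), con)
  for (tr in tracks) {
    writeLines(paste(">", tr$read_id, " ", tr$chrom, " ", tr$ref_start, " ",
                     tr$ref_end, " ", tr$strand, sep = ""), con)
    if (!is.null(tr$gaps) && nrow(tr$gaps))
      writeLines(sprintf("#gap %d %d", tr$gaps$pos, tr$gaps$length), con)
    if (length(tr$positions))
      writeLines(sprintf("%d\t%.6f\t%.6f", tr$positions, tr$p_edu, tr$p_brdu),
                 con)
  }
  invisible(path)
}

#' Write fork calls to a BED6+ file
#'
#' One line per fork: `chrom  track_start  track_end  read_id  0  strand
#' direction  flags`, where strand is `+` for rightward and `-` for leftward
#' forks and `flags` is a comma-joined list (or `.`). Output is sorted by
#' chrom then start. Coordinates are 0-based half-open throughout.
#'
#' @param forks A fork-call data.frame as returned by [call_forks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fork_bed <- function(forks, path) {
  if (is.null(forks) || nrow(forks) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (any(forks$track_start > forks$track_end))
    stop("refusing fork record(s) with start > end: ",
         paste(which(forks$track_start > forks$track_end), collapse = ", "))
  flag_cols <- c("on_read_with_origin", "on_read_with_termination",
                 "origin_member", "termination_member")
  flag_cols <- intersect(flag_cols, names(forks))
  flags <- apply(forks[, flag_cols, drop = FALSE], 1L, function(fl) {
    s <- flag_cols[as.logical(fl)]
    if (length(s)) paste(s, collapse = ",") else "."
  })
  out <- data.frame(chrom = forks$chrom,
                    start = forks$track_start, end = forks$track_end,
                    name = forks$read_id, score = 0L,
                    strand = ifelse(forks$direction == "rightward", "+", "-"),
                    direction = forks$direction, flags = flags)
  out <- out[order(out$chrom, out$start), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
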