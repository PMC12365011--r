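# Build a small analogue track with labelled regions laid out explicitly.
# edu/brdu are lists of c(start, end) intervals (0-based half-open, absolute
# reference coordinates). fp/fn are per-position false-positive and
# false-negative call probabilities applied to the binary label before the
# probability is emitted as 0.9x (positive) or 0.0x (negative).
make_track <- function(ref_start = 0L, ref_end = 30000L, density = 0.3,
                       edu = list(), brdu = list(), fp = 0, fn = 0,
                       gaps = NULL, read_id = "readA", chrom = "chr1",
                       seed = 1L) {
  set.seed(seed)
  L <- ref_end - ref_start
  pos <- ref_start + which(runif(L) < density) - 1L
  in_any <- function(p, ivs) {
    out <- rep(FALSE, length(p))
    for (iv in ivs) out <- out | (p >= iv[1] & p < iv[2])
    out
  }
  emit <- function(lab) {
    lab <- xor(lab, runif(length(lab)) < ifelse(lab, fn, fp))
    ifelse(lab, 0.9 + runif(length(lab)) * 0.09,
           0.01 + runif(length(lab)) * 0.09)
  }
  analogue_track(read_id, chrom, ref_start, ref_end, "+", pos,
                 p_edu = emit(in_any(pos, edu)),
                 p_brdu = emit(in_any(pos, brdu)),
                 gaps = gaps, min_length = 0L)
}

# One clean rightward fork: EdU [e1, e2), BrdU [e2, b2).
make_fork_track <- function(edu_start = 6000, edu_len = 7000,
                            brdu_len = 14000, ref_start = 0,
                            ref_end = 40000, ...) {
  e2 <- edu_start + edu_len
  make_track(ref_start, ref_end,
             edu = list(c(edu_start, e2)),
             brdu = list(c(e2, e2 + brdu_len)), ...)
}

# Assemble a one-row fork data.frame by hand (coordinates as stated, no
# segmentation involved).
manual_fork <- function(track, direction, edu_start, edu_end, brdu_start,
                        brdu_end, termination_member = FALSE,
                        on_read_with_origin = FALSE,
                        on_read_with_termination = FALSE) {
  right <- direction == "rightward"
  data.frame(read_id = track$read_id, chrom = track$chrom,
             direction = direction,
             edu_start = edu_start, edu_end = edu_end,
             brdu_start = brdu_start, brdu_end = brdu_end,
             track_start = if (right) edu_start else brdu_start,
             track_end = if (right) brdu_end else edu_end,
             ref_start = track$ref_start, ref_end = track$ref_end,
             on_read_with_origin = on_read_with_origin,
             on_read_with_termination = on_read_with_termination,
             origin_member = FALSE,
             termination_member = termination_member)
}
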