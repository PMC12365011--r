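# Brute-force window oracle: for every thymidine anchor, score the genomic
# window [pos, pos + w) directly, then take maximal runs of covered
# positions. Used to cross-check the cumulative-sum implementation.
oracle_segments <- function(track, analogue, params) {
  pos <- track$positions
  p_a <- if (analogue == "EdU") track$p_edu else track$p_brdu
  p_b <- if (analogue == "EdU") track$p_brdu else track$p_edu
  covered <- rep(FALSE, length(pos))
  for (i in seq_along(pos)) {
    sel <- pos >= pos[i] & pos < pos[i] + params$window_size
    if (sum(sel) < params$min_window_thymidines) next
    fa <- mean(p_a[sel] > params$call_threshold)
    fb <- mean(p_b[sel] > params$call_threshold)
    if (fa >= params$window_fraction_floor && fa > fb) covered[sel] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- NULL
  for (k in which(r$values)) {
    s <- pos[starts[k]]; e <- pos[ends[k]] + 1
    if (e - s >= params$min_track_length) out <- rbind(out, c(s, e))
  }
  out
}

test_that("positive calls use a strict threshold", {
  tr <- analogue_track("r", "c", 0, 1000, "+", c(10, 20, 30),
                       p_edu = c(0.9, 0.5, 0.1), p_brdu = c(0, 0, 0),
                       min_length = 0)
  expect_identical(positive_calls(tr, "EdU", 0.5), c(TRUE, FALSE, FALSE))
  expect_identical(positive_calls(tr, "BrdU", 0.5), c(FALSE, FALSE, FALSE))
})

test_that("positive-call rate in a labelled region matches the emission model", {
  # labelled positions draw Beta(8, 2); P(call) = P(X > 0.5)
  sim <- simulate_experiment(
    simulation_config(n_reads = 4, fork_rate_per_mb = 8,
                      origin_rate_per_mb = 0, termination_rate_per_mb = 0),
    seed = 21)
  tpr <- 1 - pbeta(0.5, 8, 2)
  truth <- sim$truth$forks
  hits <- 0; total <- 0
  for (i in seq_len(nrow(truth))) {
    tr <- Filter(function(t) t$read_id == truth$read_id[i], sim$tracks)[[1]]
    sel <- tr$positions >= truth$edu_start[i] & tr$positions < truth$edu_end[i]
    hits <- hits + sum(tr$p_edu[sel] > 0.5); total <- total + sum(sel)
  }
  expect_gt(total, 500)
  se <- sqrt(tpr * (1 - tpr) / total)
  expect_lt(abs(hits / total - tpr), 3 * se + 0.01)
})

test_that("candidate segments match the brute-force window oracle", {
  params <- segmentation_params()
  # clean EdU region 5-15 kb
  tr <- make_track(0, 30000, edu = list(c(5000, 15000)), seed = 2)
  got <- candidate_segments(tr, "EdU", params)
  exp <- oracle_segments(tr, "EdU", params)
  expect_equal(nrow(got), nrow(exp))
  expect_equal(got$start, exp[, 1])
  expect_equal(got$end, exp[, 2])
  # boundaries within one window of the true region
  expect_lt(abs(got$start - 5000), params$window_size)
  expect_lt(abs(got$end - 15000), params$window_size)

  # noisy track, 5% false positives, no labelled region: no window reaches
  # the 0.3 floor
  tr2 <- make_track(0, 30000, fp = 0.05, seed = 3)
  expect_identical(nrow(candidate_segments(tr2, "EdU", params)), 0L)
  expect_null(oracle_segments(tr2, "EdU", params))

  # two labelled regions separated by blank track: two maximal runs
  tr3 <- make_track(0, 40000, brdu = list(c(5000, 12000), c(20000, 27000)),
                    seed = 4)
  got3 <- candidate_segments(tr3, "BrdU", params)
  exp3 <- oracle_segments(tr3, "BrdU", params)
  expect_identical(nrow(got3), 2L)
  expect_equal(got3$start, exp3[, 1])
  expect_equal(got3$end, exp3[, 2])
})

test_that("candidate segments agree with the oracle on noisy tracks", {
  params <- segmentation_params()
  for (s in 1:5) {
    tr <- make_track(0, 40000, edu = list(c(8000, 16000)),
                     brdu = list(c(16000, 30000)), fp = 0.05, fn = 0.15,
                     seed = s)
    for (an in c("EdU", "BrdU")) {
      got <- candidate_segments(tr, an, params)
      exp <- oracle_segments(tr, an, params)
      expect_equal(got$start, if (is.null(exp)) integer(0) else exp[, 1],
                   info = paste("seed", s, an))
      expect_equal(got$end, if (is.null(exp)) integer(0) else exp[, 2])
    }
  }
})

test_that("trimming pulls segment edges back to the plateau incorporation", {
  params <- segmentation_params()
  # uniform incorporation: every window already meets the middle-third level
  tr <- make_track(0, 30000, edu = list(c(5000, 15000)), seed = 5)
  seg <- data.frame(read_id = "readA", chrom = "chr1", start = 5000L,
                    end = 15000L, analogue = "EdU")
  trm <- trim_segment(tr, seg, params)
  expect_equal(trm$start, seg$start, tolerance = 0.01)
  expect_lt(abs(trm$end - seg$end), 150)

  # first 2 kb at half the plateau incorporation: start advances ~2 kb
  set.seed(6)
  tr2 <- make_track(0, 30000, edu = list(c(5000, 15000)), seed = 6)
  dilute <- tr2$positions >= 5000 & tr2$positions < 7000 & runif(length(tr2$positions)) < 0.5
  tr2$p_edu[dilute] <- 0.05
  trm2 <- trim_segment(tr2, seg, params)
  expect_gt(trm2$start, 6000)
  expect_lt(trm2$start, 7600)

  # all-negative 1-kb edges inside the segment are removed
  tr3 <- make_track(0, 30000, edu = list(c(6000, 14000)), seed = 7)
  seg3 <- data.frame(read_id = "readA", chrom = "chr1", start = 5000L,
                     end = 15000L, analogue = "EdU")
  trm3 <- trim_segment(tr3, seg3, params)
  expect_gt(trm3$start, 5800)
  expect_lt(trm3$start, 6500)
  expect_gt(trm3$end, 13500)
  expect_lt(trm3$end, 14200)

  # too short to trim: returned unchanged with the flag
  seg4 <- data.frame(read_id = "readA", chrom = "chr1", start = 5000L,
                     end = 7000L, analogue = "EdU")
  trm4 <- trim_segment(tr, seg4, params)
  expect_identical(trm4$start, seg4$start)
  expect_false(attr(trm4, "trimmed"))
})

test_that("trimming is idempotent on clean tracks and always shrinking", {
  params <- segmentation_params()
  for (s in 1:5) {
    tr <- make_track(0, 30000, edu = list(c(5000, 15000)), seed = s)
    seg <- candidate_segments(tr, "EdU", params)
    t1 <- trim_segment(tr, seg[1, ], params)
    t2 <- trim_segment(tr, t1, params)
    expect_identical(t2$start, t1$start, info = paste("seed", s))
    expect_identical(t2$end, t1$end)
  }
  # under call noise a re-trim may move within the plateau, but trimming
  # never grows a segment
  for (s in 1:5) {
    tr <- make_track(0, 30000, edu = list(c(5000, 15000)), fp = 0.03,
                     fn = 0.1, seed = s)
    seg <- candidate_segments(tr, "EdU", params)
    if (!nrow(seg)) next
    t1 <- trim_segment(tr, seg[1, ], params)
    expect_gte(t1$start, seg$start[1])
    expect_lte(t1$end, seg$end[1])
  }
})

test_that("EdU-then-BrdU pairs become forks with the protocol's direction", {
  tr <- make_track(0, 40000, edu = list(c(10000, 20000)),
                   brdu = list(c(20000, 35000)), seed = 8)
  res <- call_forks(tr)
  expect_identical(nrow(res$forks), 1L)
  expect_identical(res$forks$direction, "rightward")
  # track spans far end of EdU to far end of BrdU
  expect_lt(abs(res$forks$track_start - 10000), 1000)
  expect_lt(abs(res$forks$track_end - 35000), 1000)

  # mirrored layout gives a leftward fork
  tr2 <- make_track(0, 40000, brdu = list(c(5000, 20000)),
                    edu = list(c(20000, 30000)), seed = 9)
  res2 <- call_forks(tr2)
  expect_identical(res2$forks$direction, "leftward")
  expect_lt(abs(res2$forks$track_start - 5000), 1000)
  expect_lt(abs(res2$forks$track_end - 30000), 1000)
})

test_that("diverging forks yield an origin call between their EdU tracks", {
  tr <- make_track(0, 80000,
                   brdu = list(c(5000, 20000), c(50000, 65000)),
                   edu = list(c(20000, 33000), c(37000, 50000)),
                   seed = 10)
  res <- call_forks(tr)
  expect_identical(nrow(res$forks), 2L)
  expect_identical(sort(res$forks$direction), c("leftward", "rightward"))
  expect_identical(nrow(res$origins), 1L)
  expect_gt(res$origins$start, 30000)
  expect_lt(res$origins$end, 40000)
  expect_true(all(res$forks$on_read_with_origin))
  expect_true(all(res$forks$origin_member))
})

test_that("converging forks yield a termination call between their BrdU tracks", {
  tr <- make_track(0, 80000,
                   edu = list(c(5000, 15000), c(60000, 70000)),
                   brdu = list(c(15000, 36000), c(39000, 60000)),
                   seed = 11)
  res <- call_forks(tr)
  expect_identical(nrow(res$forks), 2L)
  expect_identical(nrow(res$terminations), 1L)
  expect_true(all(res$forks$termination_member))
})

test_that("an unpaired EdU segment makes no fork", {
  tr <- make_track(0, 40000, edu = list(c(10000, 20000)), seed = 12)
  res <- call_forks(tr)
  expect_identical(nrow(res$forks), 0L)
})

test_that("a BrdU segment beyond the pairing gap is not matched", {
  tr <- make_track(0, 60000, edu = list(c(5000, 15000)),
                   brdu = list(c(25000, 40000)), seed = 13)
  res <- call_forks(tr)  # 10 kb gap > default 5 kb
  expect_identical(nrow(res$forks), 0L)
  res2 <- call_forks(tr, segmentation_params(max_pair_gap = 12000))
  expect_identical(nrow(res2$forks), 1L)
})

test_that("called forks never overlap on a read", {
  sim <- simulate_experiment(
    simulation_config(n_reads = 25, origin_rate_per_mb = 1.5,
                      termination_rate_per_mb = 1.5), seed = 14)
  calls <- call_forks_all(sim$tracks)
  for (id in unique(calls$forks$read_id)) {
    f <- calls$forks[calls$forks$read_id == id, ]
    f <- f[order(f$track_start), ]
    if (nrow(f) > 1)
      expect_true(all(f$track_start[-1] >= f$track_end[-nrow(f)] - 1000))
  }
})

test_that("noise-free simulated forks are recovered within one window", {
  sim <- simulate_experiment(
    simulation_config(n_reads = 15, noise_free = TRUE), seed = 15)
  calls <- call_forks_all(sim$tracks)
  cmp <- truth_compare(calls$forks, sim$truth$forks, tolerance = 1000)
  expect_identical(cmp$precision, 1)
  expect_identical(cmp$recall, 1)
})
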