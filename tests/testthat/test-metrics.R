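# Independent high-precision oracle for the softplus stall scaling.
oracle_scale <- function(R, a, b) a * log(1 + exp(b * (R - 1))) -
  a * log(1 + exp(-b))

test_that("fork speed is track length over total pulse time", {
  tr <- make_fork_track(ref_end = 40000)
  fk <- manual_fork(tr, "rightward", 6000, 13000, 13000, 27000)
  out <- fork_speed(fk, speed_params())
  expect_equal(out$speed, 21 / 15)  # 21 kb over 15 min = 1.4 kb/min
  expect_true(is.na(out$speed_exclusion))
})

test_that("speed exclusion rules drop origin/termination reads and read ends", {
  tr <- make_track(0, 60000, seed = 1)
  base <- manual_fork(tr, "rightward", 10000, 17000, 17000, 31000)
  org <- base; org$on_read_with_origin <- TRUE
  trm <- base; trm$on_read_with_termination <- TRUE
  near_end <- manual_fork(tr, "rightward", 40000, 47000, 47000, 59000)
  near_start <- manual_fork(tr, "rightward", 2000, 9000, 9000, 23000)
  out <- fork_speed(rbind(base, org, trm, near_end, near_start),
                    speed_params())
  expect_identical(out$speed_exclusion,
                   c(NA, "origin_on_read", "termination_on_read",
                     "near_read_end", "near_read_end"))
  expect_identical(sum(!is.na(out$speed)), 1L)

  # a fork ending exactly at the 3 kb margin is kept; 1 bp inside is dropped
  at_margin <- manual_fork(tr, "rightward", 30000, 40000, 40000, 57000)
  inside <- manual_fork(tr, "rightward", 30000, 40000, 40000, 57001)
  out2 <- fork_speed(rbind(at_margin, inside), speed_params())
  expect_identical(out2$speed_exclusion, c(NA, "near_read_end"))
})

test_that("constructed exclusion fixture reports exactly the eligible speeds", {
  # 10 forks: 3 near read ends, 2 on origin-bearing reads, 5 eligible
  tr <- make_track(0, 100000, seed = 2)
  mk <- function(s, origin = FALSE)
    manual_fork(tr, "rightward", s, s + 7000, s + 7000, s + 21000,
                on_read_with_origin = origin)
  forks <- rbind(mk(1000),                   # starts < 3 kb from read start
                 mk(78000), mk(79000),       # end within 3 kb of read end
                 mk(10000, origin = TRUE), mk(35000, origin = TRUE),
                 mk(5000), mk(30000), mk(40000), mk(50000), mk(60000))
  out <- fork_speed(forks, speed_params())
  expect_identical(sum(!is.na(out$speed)), 5L)
  expect_equal(out$speed[!is.na(out$speed)], rep(21 / 15, 5))
})

test_that("stall windows count positive BrdU calls over thymidines", {
  # hand-built track: 20 thymidines per 2 kb window, 16/20 positive inside,
  # 4/20 positive outside the BrdU end at 20000
  pos <- c(seq(18050, 19950, by = 100), seq(20050, 21950, by = 100))
  p_brdu <- c(rep(0.9, 16), rep(0.1, 4), rep(0.9, 4), rep(0.1, 16))
  tr <- analogue_track("r", "chr1", 0, 30000, "+", pos,
                       p_edu = rep(0, 40), p_brdu = p_brdu, min_length = 0)
  fk <- manual_fork(tr, "rightward", 10000, 14000, 14000, 20000)
  win <- stall_windows(tr, fk, stall_params("v3"))
  expect_equal(win$B, 0.8)
  expect_equal(win$A, 0.2)
  res <- stall_score(tr, fk, stall_params("v3"))
  expect_equal(res$R, 0.75)
  expect_equal(res$score, oracle_scale(0.75, 1.55, 3), tolerance = 1e-12)
})

test_that("stall score declines follow the published rules", {
  tr <- make_fork_track(edu_start = 6000, edu_len = 7000, brdu_len = 14000,
                        ref_end = 28500, seed = 3)
  # BrdU end at 27000, outside window would run past ref_end 28500
  fk <- manual_fork(tr, "rightward", 6000, 13000, 13000, 27000)
  expect_identical(stall_score(tr, fk, stall_params("v3"))$declined,
                   "off_read")

  tr2 <- make_fork_track(ref_end = 40000, seed = 4)
  fk2 <- manual_fork(tr2, "rightward", 6000, 13000, 13000, 27000)
  expect_true(is.na(stall_score(tr2, fk2, stall_params("v3"))$declined))

  # 150 bp deletion annotation inside the outside window
  tr3 <- make_fork_track(ref_end = 40000, seed = 5,
                         gaps = data.frame(pos = 27500, length = 150))
  expect_identical(stall_score(tr3, fk2, stall_params("v3"))$declined,
                   "indel_in_window")
  # a 90 bp indel is tolerated (max_indel = 100)
  tr4 <- make_fork_track(ref_end = 40000, seed = 6,
                         gaps = data.frame(pos = 27500, length = 90))
  expect_true(is.na(stall_score(tr4, fk2, stall_params("v3"))$declined))

  # termination members are declined outright
  fk5 <- manual_fork(tr2, "rightward", 6000, 13000, 13000, 27000,
                     termination_member = TRUE)
  expect_identical(stall_score(tr2, fk5, stall_params("v3"))$declined,
                   "termination_member")

  # B = 0: raw score undefined
  tr6 <- make_track(0, 40000, seed = 7)  # no BrdU label at all
  expect_identical(stall_score(tr6, fk2, stall_params("v3"))$declined,
                   "zero_B")

  # AT-poor window: too few thymidines
  tr7 <- make_fork_track(ref_end = 40000, density = 0.002, seed = 8)
  expect_identical(stall_score(tr7, fk2, stall_params("v3"))$declined,
                   "too_few_thymidines")
})

test_that("leftward forks anchor the windows at their left BrdU end", {
  tr <- make_track(0, 40000, brdu = list(c(8000, 22000)),
                   edu = list(c(22000, 29000)), seed = 9)
  fk <- manual_fork(tr, "leftward", 22000, 29000, 8000, 22000)
  res <- stall_score(tr, fk, stall_params("v3"))
  expect_true(is.na(res$declined))
  expect_gt(res$B, 0.8)   # inside window [8000, 10000) is labelled
  expect_lt(res$A, 0.2)   # outside window [6000, 8000) is not
  expect_gt(res$score, 0.8)
})

test_that("stall scaling matches its closed form and published anchor points", {
  for (preset in c("v3", "v4")) {
    p <- stall_params(preset)
    grid <- seq(-1, 1, length.out = 401)
    expect_equal(stall_scale(grid, p),
                 pmax(0, oracle_scale(grid, p$alpha, p$beta)),
                 tolerance = 1e-12)
    expect_identical(stall_scale(0, p), 0)            # exact cancellation
    expect_gt(stall_scale(1, p), 0.99)
    expect_lte(stall_scale(1, p), 1)
  }
  # frozen spot values, computed from the closed form at high precision
  expect_equal(stall_scale(1, stall_params("v3")), 0.999067734928615,
               tolerance = 1e-12)
  expect_equal(stall_scale(0.5, stall_params("v3")), 0.236880185933966,
               tolerance = 1e-12)
  expect_equal(stall_scale(1, stall_params("v4")), 0.999098846699730,
               tolerance = 1e-12)
  expect_error(stall_scale(1.2, stall_params("v3")), "<= 1")
})

test_that("stall scaling is monotone non-decreasing in R", {
  for (preset in c("v3", "v4")) {
    s <- stall_scale(seq(-2, 1, length.out = 1501), stall_params(preset))
    expect_true(all(diff(s) >= 0))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("B = A gives raw score zero and stall score zero", {
  pos <- seq(18050, 21950, by = 100)
  p_brdu <- rep(c(0.9, 0.1), 20)
  tr <- analogue_track("r", "chr1", 0, 30000, "+", pos,
                       p_edu = rep(0, 40), p_brdu = p_brdu, min_length = 0)
  fk <- manual_fork(tr, "rightward", 10000, 14000, 14000, 20000)
  res <- stall_score(tr, fk, stall_params("v3"))
  expect_equal(res$R, 0)
  expect_identical(res$score, 0)
})

test_that("abruptly stopped forks score high, run-through forks low", {
  stalled <- simulate_experiment(
    simulation_config(n_reads = 35, fork_rate_per_mb = 8,
                      origin_rate_per_mb = 0, termination_rate_per_mb = 0,
                      stall_probability = 1, stall_time_range = c(8, 13)),
    seed = 31)
  smooth <- simulate_experiment(
    simulation_config(n_reads = 35, fork_rate_per_mb = 8,
                      origin_rate_per_mb = 0, termination_rate_per_mb = 0,
                      stall_probability = 0),
    seed = 32)
  get_scores <- function(sim) {
    calls <- call_forks_all(sim$tracks)
    m <- fork_metrics(sim$tracks, calls$forks)
    m$stall[is.na(m$stall_declined)]
  }
  s_stall <- get_scores(stalled); s_run <- get_scores(smooth)
  expect_gt(length(s_stall), 15)
  expect_gt(length(s_run), 15)
  expect_gt(median(s_stall), 0.8)
  expect_lt(median(s_run), 0.2)
})

test_that("simulated constant-speed forks are recovered within the window bound", {
  sim <- simulate_experiment(
    simulation_config(n_reads = 20, noise_free = TRUE, fork_rate_per_mb = 8,
                      origin_rate_per_mb = 0, termination_rate_per_mb = 0),
    seed = 33)
  calls <- call_forks_all(sim$tracks)
  m <- fork_speed(calls$forks, speed_params())
  truth <- sim$truth$forks
  j <- match(paste(m$read_id, m$direction, round(m$track_start / 2e4)),
             paste(truth$read_id, truth$direction,
                   round(truth$track_start / 2e4)))
  ok <- !is.na(m$speed) & !is.na(j)
  expect_gt(sum(ok), 10)
  err <- abs(m$speed[ok] - truth$speed[j[ok]])
  expect_true(all(err <= 2 * 1000 / 1000 / 15))  # 2 windows over the pulse
})
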