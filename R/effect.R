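#' Priors and ROPEs for the treatment-effect models
#'
#' Weakly informative defaults: Normal(1.5, 0.5) and Normal(0.7, 0.5) priors
#' on the untreated/treated group-mean fork speed, half-Normal(0.5) priors
#' on all speed standard deviations, a Beta(2, 5) prior on each group-mean
#' stall score, and Gamma(2, 0.1) priors on both precisions of the stall
#' hierarchy: the shared Beta precision of fork-level scores and the
#' concentration tying replicate-level means to their group mean. The
#' regions of practical equivalence are +/-0.1 kb/min for fork speed and
#' +/-0.05 for stall score.
#'
#' @param speed_mu_untreated,speed_mu_treated Normal prior `c(mean, sd)` on
#'   the group-mean speeds (kb/min).
#' @param speed_sd Scale of the half-Normal prior on speed SDs.
#' @param stall_mean Beta prior `c(alpha, beta)` on group-mean stall scores.
#' @param stall_precision Gamma prior `c(shape, rate)` on the Beta precision.
#' @param stall_kappa Gamma prior `c(shape, rate)` on the replicate-level
#'   concentration.
#' @param rope_speed,rope_stall Half-widths of the ROPEs.
#' @return A list of class `effect_priors`.
#' @export
effect_priors <- function(speed_mu_untreated = c(1.5, 0.5),
                          speed_mu_treated = c(0.7, 0.5),
                          speed_sd = 0.5,
                          stall_mean = c(2, 5),
                          stall_precision = c(2, 0.1),
                          stall_kappa = c(2, 0.1),
                          rope_speed = 0.1, rope_stall = 0.05) {
  structure(as.list(environment()), class = "effect_priors")
}

# Sufficient statistics per replicate within each condition.
.group_stats <- function(y, condition, replicate, logs = FALSE) {
  stopifnot(length(y) == length(condition), length(y) == length(replicate))
  cond <- factor(condition, levels = unique(condition))
  lv <- levels(cond)
  if (length(lv) != 2)
    stop("exactly two conditions required; got: ", paste(lv, collapse = ", "))
  out <- lapply(lv, function(g) {
    sel <- cond == g
    reps <- split(y[sel], factor(replicate[sel]))
    if (length(reps) < 2)
      stop("condition '", g, "' needs >= 2 replicates, has ", length(reps))
    if (logs) {
      lapply(reps, function(v) list(n = length(v), s1 = sum(log(v)),
                                    s2 = sum(log1p(-v))))
    } else {
      lapply(reps, function(v) list(n = length(v), s = sum(v),
                                    q = sum(v^2)))
    }
  })
  names(out) <- c("untreated", "treated")
  out
}

# Hierarchical normal model, non-centred so the replicate-level scale does
# not produce a funnel with few replicates. Unconstrained parameter vector:
# (mu_u, mu_t, log tau_u, log tau_t, log sig_u, log sig_t,
#  z_u[1..Ru], z_t[1..Rt]) with replicate means theta = mu + tau * z.
.speed_lpgrad <- function(stats_ut, priors) {
  Ru <- length(stats_ut$untreated); Rt <- length(stats_ut$treated)
  pu <- priors$speed_mu_untreated; pt_ <- priors$speed_mu_treated
  hs2 <- priors$speed_sd^2
  function(th) {
    mu <- th[1:2]
    tau <- exp(th[3:4]); sig <- exp(th[5:6])
    z <- list(th[7:(6 + Ru)], th[(7 + Ru):(6 + Ru + Rt)])
    lp <- -0.5 * (mu[1] - pu[1])^2 / pu[2]^2 -
      0.5 * (mu[2] - pt_[1])^2 / pt_[2]^2 -
      sum(tau^2) / (2 * hs2) + th[3] + th[4] -
      sum(sig^2) / (2 * hs2) + th[5] + th[6]
    g_mu <- c(-(mu[1] - pu[1]) / pu[2]^2, -(mu[2] - pt_[1]) / pt_[2]^2)
    g_ltau <- -tau^2 / hs2 + 1
    g_lsig <- -sig^2 / hs2 + 1
    g_z <- vector("list", 2)
    for (g in 1:2) {
      st <- stats_ut[[g]]
      zg <- z[[g]]
      thg <- mu[g] + tau[g] * zg
      lp <- lp - 0.5 * sum(zg^2)
      gz <- -zg
      for (r in seq_along(st)) {
        n <- st[[r]]$n; s <- st[[r]]$s; q <- st[[r]]$q
        rss <- q - 2 * thg[r] * s + n * thg[r]^2
        lp <- lp - n * th[4 + g] - rss / (2 * sig[g]^2)
        g_lsig[g] <- g_lsig[g] - n + rss / sig[g]^2
        dll <- (s - n * thg[r]) / sig[g]^2   # d loglik / d theta_r
        g_mu[g] <- g_mu[g] + dll
        g_ltau[g] <- g_ltau[g] + dll * tau[g] * zg[r]
        gz[r] <- gz[r] + dll * tau[g]
      }
      g_z[[g]] <- gz
    }
    list(lp = lp,
         grad = c(g_mu, g_ltau, g_lsig, g_z[[1]], g_z[[2]]))
  }
}

# Hierarchical Beta model, unconstrained parameters:
# (logit mu_u, logit mu_t, log kappa, log phi,
#  logit theta_u[1..Ru], logit theta_t[1..Rt])
.stall_lpgrad <- function(stats_ut, priors) {
  Ru <- length(stats_ut$untreated); Rt <- length(stats_ut$treated)
  a0 <- priors$stall_mean[1]; b0 <- priors$stall_mean[2]
  ga <- priors$stall_precision[1]; gb <- priors$stall_precision[2]
  ka <- priors$stall_kappa[1]; kb <- priors$stall_kappa[2]
  function(th) {
    mu <- stats::plogis(th[1:2])
    kap <- exp(th[3]); phi <- exp(th[4])
    lth <- list(th[5:(4 + Ru)], th[(5 + Ru):(4 + Ru + Rt)])
    # priors (with logit/log Jacobians folded in)
    lp <- sum(a0 * log(mu) + b0 * log1p(-mu)) +
      ka * log(kap) - kb * kap +
      ga * log(phi) - gb * phi
    g_lmu <- a0 * (1 - mu) - b0 * mu
    g_lkap <- ka - kb * kap
    g_lphi <- ga - gb * phi
    g_lth <- vector("list", 2)
    for (g in 1:2) {
      st <- stats_ut[[g]]
      theta <- stats::plogis(lth[[g]])
      a <- mu[g] * kap; b <- kap - a
      # replicate means ~ Beta(mu_g * kappa, (1 - mu_g) * kappa)
      lp <- lp + sum(a * log(theta) + b * log1p(-theta)) -
        length(theta) * (lgamma(a) + lgamma(b) - lgamma(kap))
      dla <- sum(log(theta)) - length(theta) * digamma(a)
      dlb <- sum(log1p(-theta)) - length(theta) * digamma(b)
      g_lmu[g] <- g_lmu[g] + (dla - dlb) * kap * mu[g] * (1 - mu[g])
      g_lkap <- g_lkap +
        (dla * mu[g] + dlb * (1 - mu[g]) + length(theta) * digamma(kap)) * kap
      gt <- a * (1 - theta) - b * theta
      for (r in seq_along(st)) {
        n <- st[[r]]$n; s1 <- st[[r]]$s1; s2 <- st[[r]]$s2
        ar <- theta[r] * phi; br <- phi - ar
        lp <- lp + n * (lgamma(phi) - lgamma(ar) - lgamma(br)) +
          (ar - 1) * s1 + (br - 1) * s2
        dth <- n * phi * (digamma(br) - digamma(ar)) + phi * (s1 - s2)
        gt[r] <- gt[r] + dth * theta[r] * (1 - theta[r])
        g_lphi <- g_lphi +
          (n * (digamma(phi) - theta[r] * digamma(ar) -
                  (1 - theta[r]) * digamma(br)) +
             theta[r] * s1 + (1 - theta[r]) * s2) * phi
      }
      g_lth[[g]] <- gt
    }
    list(lp = lp,
         grad = c(g_lmu, g_lkap, g_lphi, g_lth[[1]], g_lth[[2]]))
  }
}

# Turn NUTS output into a fork_effect object with natural-scale draws.
.make_effect <- function(fit, metric, extract, rope, n_by, priors, sampler) {
  nd <- dim(fit$draws)[1]; nc <- dim(fit$draws)[2]
  flat <- apply(fit$draws, 3, c)  # (nd*nc) x d
  nat <- extract(flat)
  delta1 <- nat$mu_t - nat$mu_u
  pair_absdiff <- function(m) {
    if (ncol(m) == 2) abs(m[, 1] - m[, 2]) else {
      cmb <- utils::combn(ncol(m), 2)
      rowMeans(abs(m[, cmb[1, ], drop = FALSE] - m[, cmb[2, ], drop = FALSE]))
    }
  }
  delta2 <- pair_absdiff(nat$theta_u)
  delta3 <- pair_absdiff(nat$theta_t)
  frac_outside <- mean(abs(delta1) > rope)
  if (max(fit$rhat) >= 1.01)
    warning("split-R-hat >= 1.01 for ", sum(fit$rhat >= 1.01),
            " parameter(s); inspect convergence")
  if (fit$divergences > 0.01 * nd * nc)
    warning(fit$divergences, " divergent transitions")
  structure(list(metric = metric,
                 draws = data.frame(mu_untreated = nat$mu_u,
                                    mu_treated = nat$mu_t,
                                    delta1 = delta1, delta2 = delta2,
                                    delta3 = delta3,
                                    adjusted = delta1 - delta2),
                 replicate_means = list(untreated = nat$theta_u,
                                        treated = nat$theta_t),
                 rope = rope,
                 frac_outside_rope = frac_outside,
                 significant = frac_outside >= 0.95,
                 rhat = fit$rhat, divergences = fit$divergences,
                 n = n_by, priors = priors, sampler = sampler),
            class = "fork_effect")
}

#' Hierarchical Bayesian treatment effect on fork speed
#'
#' Partial-pooling model: each fork's speed is Normal with a replicate-level
#' mean and a per-condition SD; replicate means are drawn from a
#' condition-level Normal. Priors are as in [effect_priors()]. The posterior
#' is sampled with the built-in No-U-Turn sampler; split-R-hat and divergence
#' counts are checked and surfaced as warnings, never as hard failures.
#'
#' @param speed Numeric vector of per-fork speeds (kb/min).
#' @param condition Two-level factor/character: the first level encountered
#'   is taken as untreated, the second as treated.
#' @param replicate Replicate label within condition (>= 2 per condition).
#' @param priors An [effect_priors()].
#' @param draws,tune Posterior draws per chain and tuning steps. Defaults
#'   2000 and 1000.
#' @param chains Number of chains. Default 4.
#' @param seed Integer seed.
#' @return A `fork_effect` object; see [effect_summary()].
#' @export
fit_speed_model <- function(speed, condition, replicate,
                            priors = effect_priors(),
                            draws = 2000L, tune = 1000L, chains = 4L,
                            seed = 1L) {
  st <- .group_stats(speed, condition, replicate, logs = FALSE)
  Ru <- length(st$untreated); Rt <- length(st$treated)
  lpg <- .speed_lpgrad(st, priors)
  rep_means <- function(g) vapply(g, function(r) r$s / r$n, 0)
  init <- c(mean(rep_means(st$untreated)), mean(rep_means(st$treated)),
            log(0.2), log(0.2), log(0.3), log(0.3),
            rep(0, Ru + Rt))
  fit <- nuts_sample(lpg, init, n_warmup = tune, n_draws = draws,
                     chains = chains, seed = seed)
  extract <- function(flat) list(
    mu_u = flat[, 1], mu_t = flat[, 2],
    theta_u = flat[, 1] + exp(flat[, 3]) * flat[, 7:(6 + Ru), drop = FALSE],
    theta_t = flat[, 2] + exp(flat[, 4]) *
      flat[, (7 + Ru):(6 + Ru + Rt), drop = FALSE])
  .make_effect(fit, "speed", extract, priors$rope_speed,
               n_by = lapply(st, function(g) vapply(g, `[[`, 0L, "n")),
               priors, list(draws = draws, tune = tune, chains = chains,
                            seed = seed))
}

#' Hierarchical Bayesian treatment effect on stall score
#'
#' Stall scores live on \[0, 1\], so each fork's score is modelled as Beta
#' with a replicate-level mean and a precision shared across all replicates
#' and conditions; replicate means are drawn from a Beta around the
#' condition mean with a half-Normal-prior concentration. Scores of exactly
#' 0 or 1 are nudged inward by `eps` to keep the likelihood finite.
#'
#' @inheritParams fit_speed_model
#' @param stall Numeric vector of per-fork stall scores in \[0, 1\].
#' @param eps Boundary nudge. Default 1e-4.
#' @return A `fork_effect` object.
#' @export
fit_stall_model <- function(stall, condition, replicate,
                            priors = effect_priors(),
                            draws = 2000L, tune = 1000L, chains = 4L,
                            seed = 1L, eps = 1e-4) {
  stopifnot(all(stall >= 0 & stall <= 1, na.rm = TRUE))
  stall <- pmin(pmax(stall, eps), 1 - eps)
  st <- .group_stats(stall, condition, replicate, logs = TRUE)
  Ru <- length(st$untreated); Rt <- length(st$treated)
  lpg <- .stall_lpgrad(st, priors)
  # moment-matched initial values from the per-replicate mean of log odds
  rep_means <- function(g) vapply(g, function(r)
    stats::plogis((r$s1 - r$s2) / r$n), 0)
  mu0 <- c(mean(rep_means(st$untreated)), mean(rep_means(st$treated)))
  init <- c(stats::qlogis(mu0), log(10), log(10),
            stats::qlogis(rep_means(st$untreated)),
            stats::qlogis(rep_means(st$treated)))
  fit <- nuts_sample(lpg, init, n_warmup = tune, n_draws = draws,
                     chains = chains, seed = seed)
  extract <- function(flat) list(
    mu_u = stats::plogis(flat[, 1]), mu_t = stats::plogis(flat[, 2]),
    theta_u = stats::plogis(flat[, 5:(4 + Ru), drop = FALSE]),
    theta_t = stats::plogis(flat[, (5 + Ru):(4 + Ru + Rt), drop = FALSE]))
  .make_effect(fit, "stall", extract, priors$rope_stall,
               n_by = lapply(st, function(g) vapply(g, `[[`, 0L, "n")),
               priors, list(draws = draws, tune = tune, chains = chains,
                            seed = seed))
}

#' Summarise a treatment-effect posterior against its ROPE
#'
#' Reports the treatment effect Delta1 (treated minus untreated group mean),
#' the replicate variabilities Delta2 (untreated) and Delta3 (treated), the
#' adjusted effect Delta1 - Delta2, the fraction of Delta1 draws outside the
#' region of practical equivalence, and the significance flag (at least 95%
#' of the posterior outside the ROPE; the 95% boundary itself counts as
#' significant). Delta3 is reported but plays no role in significance.
#'
#' @param object A `fork_effect` object.
#' @param rope Optional ROPE half-width overriding the fitted one.
#' @return A list of class `fork_effect_summary`.
#' @export
effect_summary <- function(object, rope = NULL) {
  stopifnot(inherits(object, "fork_effect"))
  if (nrow(object$draws) < 1000)
    stop("posterior has fewer than 1000 draws")
  if (is.null(rope)) rope <- object$rope
  d <- object$draws
  frac <- mean(abs(d$delta1) > rope)
  qs <- function(v) c(mean = mean(v),
                      stats::quantile(v, c(0.025, 0.5, 0.975)))
  structure(list(metric = object$metric, rope = rope,
                 delta1 = qs(d$delta1), delta2 = qs(d$delta2),
                 delta3 = qs(d$delta3), adjusted = qs(d$adjusted),
                 frac_outside_rope = frac,
                 significant = frac >= 0.95,
                 rhat_max = max(object$rhat),
                 divergences = object$divergences),
            class = "fork_effect_summary")
}

#' @export
print.fork_effect_summary <- function(x, ...) {
  cat("Treatment effect on", x$metric, "(ROPE +/-", x$rope, ")\n")
  tab <- rbind(delta1 = x$delta1, delta2 = x$delta2, delta3 = x$delta3,
               adjusted = x$adjusted)
  print(round(tab, 4))
  cat(sprintf("fraction of delta1 outside ROPE: %.3f -> %s\n",
              x$frac_outside_rope,
              if (x$significant) "significant" else "not significant"))
  cat(sprintf("max split-R-hat %.3f, %d divergence(s)\n",
              x$rhat_max, x$divergences))
  invisible(x)
}

#' @export
print.fork_effect <- function(x, ...) {
  print(effect_summary(x))
  invisible(x)
}

#' @export
summary.fork_effect <- function(object, ...) effect_summary(object)

#' @export
coef.fork_effect <- function(object, ...) {
  d <- object$draws
  c(mu_untreated = mean(d$mu_untreated), mu_treated = mean(d$mu_treated),
    delta1 = mean(d$delta1), delta2 = mean(d$delta2),
    delta3 = mean(d$delta3), adjusted = mean(d$adjusted))
}
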