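# No-U-Turn sampler with dual-averaging step-size adaptation and diagonal
# mass-matrix estimation (Hoffman & Gelman's slice-sampling formulation).
# Self-contained so the hierarchical treatment-effect models can be sampled
# with the gradient-based sampler family they were designed for.

# One leapfrog step. inv_mass is the diagonal inverse metric (estimated
# posterior variances).
.leapfrog <- function(theta, r, grad, eps, lp_grad, inv_mass) {
  r1 <- r + 0.5 * eps * grad
  theta1 <- theta + eps * inv_mass * r1
  lg <- lp_grad(theta1)
  r1 <- r1 + 0.5 * eps * lg$grad
  list(theta = theta1, r = r1, lp = lg$lp, grad = lg$grad)
}

.joint <- function(lp, r, inv_mass) lp - 0.5 * sum(r^2 * inv_mass)

# Reasonable initial step size (Hoffman & Gelman Algorithm 4).
.find_epsilon <- function(theta, lp_grad, inv_mass) {
  d <- length(theta)
  eps <- 0.1
  lg <- lp_grad(theta)
  r <- stats::rnorm(d) / sqrt(inv_mass)
  h0 <- .joint(lg$lp, r, inv_mass)
  step <- .leapfrog(theta, r, lg$grad, eps, lp_grad, inv_mass)
  h1 <- .joint(step$lp, step$r, inv_mass)
  if (!is.finite(h1)) h1 <- -Inf
  a <- if (h1 - h0 > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^a
    step <- .leapfrog(theta, r, lg$grad, eps, lp_grad, inv_mass)
    h1 <- .joint(step$lp, step$r, inv_mass)
    if (!is.finite(h1)) h1 <- -Inf
    if (a * (h1 - h0) < a * log(0.5)) break
  }
  eps
}

.build_tree <- function(theta, r, grad, logu, v, j, eps, h0, lp_grad,
                        inv_mass, delta_max = 1000) {
  if (j == 0L) {
    step <- .leapfrog(theta, r, grad, v * eps, lp_grad, inv_mass)
    h1 <- .joint(step$lp, step$r, inv_mass)
    if (!is.finite(h1)) h1 <- -Inf
    n1 <- as.integer(logu <= h1)
    s1 <- as.integer(logu < h1 + delta_max)
    list(theta_m = step$theta, r_m = step$r, grad_m = step$grad,
         theta_p = step$theta, r_p = step$r, grad_p = step$grad,
         theta1 = step$theta, lp1 = step$lp, n1 = n1, s1 = s1,
         alpha = min(1, exp(h1 - h0)), n_alpha = 1L,
         divergent = s1 == 0L)
  } else {
    t1 <- .build_tree(theta, r, grad, logu, v, j - 1L, eps, h0, lp_grad,
                      inv_mass, delta_max)
    if (t1$s1 == 1L) {
      if (v == -1) {
        t2 <- .build_tree(t1$theta_m, t1$r_m, t1$grad_m, logu, v, j - 1L,
                          eps, h0, lp_grad, inv_mass, delta_max)
        t1$theta_m <- t2$theta_m; t1$r_m <- t2$r_m; t1$grad_m <- t2$grad_m
      } else {
        t2 <- .build_tree(t1$theta_p, t1$r_p, t1$grad_p, logu, v, j - 1L,
                          eps, h0, lp_grad, inv_mass, delta_max)
        t1$theta_p <- t2$theta_p; t1$r_p <- t2$r_p; t1$grad_p <- t2$grad_p
      }
      if (t2$n1 > 0L &&
          stats::runif(1) < t2$n1 / max(1L, t1$n1 + t2$n1)) {
        t1$theta1 <- t2$theta1; t1$lp1 <- t2$lp1
      }
      dtheta <- t1$theta_p - t1$theta_m
      t1$s1 <- t2$s1 *
        as.integer(sum(dtheta * (inv_mass * t1$r_m)) >= 0) *
        as.integer(sum(dtheta * (inv_mass * t1$r_p)) >= 0)
      t1$n1 <- t1$n1 + t2$n1
      t1$alpha <- t1$alpha + t2$alpha
      t1$n_alpha <- t1$n_alpha + t2$n_alpha
      t1$divergent <- t1$divergent || t2$divergent
    }
    t1
  }
}

# Sample one chain. lp_grad(theta) must return list(lp =, grad =).
.nuts_chain <- function(lp_grad, init, n_warmup, n_draws, seed,
                        target_accept = 0.8, max_treedepth = 10L) {
  set.seed(seed)
  d <- length(init)
  theta <- init + stats::rnorm(d, 0, 0.1)
  inv_mass <- rep(1, d)
  lg <- lp_grad(theta)
  if (!is.finite(lg$lp)) { theta <- init; lg <- lp_grad(theta) }
  eps <- .find_epsilon(theta, lp_grad, inv_mass)
  # dual averaging state
  mu_da <- log(10 * eps); hbar <- 0; log_eps_bar <- log(eps)
  gamma <- 0.05; t0 <- 10; kappa <- 0.75; m_da <- 0L
  mass_window <- c(floor(n_warmup * 0.25), floor(n_warmup * 0.5))
  warm_store <- matrix(NA_real_, mass_window[2] - mass_window[1], d)
  total <- n_warmup + n_draws
  draws <- matrix(NA_real_, n_draws, d)
  divergences <- 0L
  for (m in seq_len(total)) {
    r0 <- stats::rnorm(d) / sqrt(inv_mass)
    h0 <- .joint(lg$lp, r0, inv_mass)
    logu <- h0 + log(stats::runif(1))
    tm <- theta; tp <- theta; rm_ <- r0; rp <- r0
    gm <- lg$grad; gp <- lg$grad
    theta1 <- theta; lp1 <- lg$lp
    n1 <- 1L; s1 <- 1L; j <- 0L
    alpha <- 0; n_alpha <- 0L; div <- FALSE
    while (s1 == 1L && j < max_treedepth) {
      v <- sample(c(-1, 1), 1)
      if (v == -1) {
        t2 <- .build_tree(tm, rm_, gm, logu, v, j, eps, h0, lp_grad, inv_mass)
        tm <- t2$theta_m; rm_ <- t2$r_m; gm <- t2$grad_m
      } else {
        t2 <- .build_tree(tp, rp, gp, logu, v, j, eps, h0, lp_grad, inv_mass)
        tp <- t2$theta_p; rp <- t2$r_p; gp <- t2$grad_p
      }
      if (t2$s1 == 1L && stats::runif(1) < t2$n1 / n1) {
        theta1 <- t2$theta1; lp1 <- t2$lp1
      }
      n1 <- n1 + t2$n1
      dtheta <- tp - tm
      s1 <- t2$s1 *
        as.integer(sum(dtheta * (inv_mass * rm_)) >= 0) *
        as.integer(sum(dtheta * (inv_mass * rp)) >= 0)
      alpha <- alpha + t2$alpha; n_alpha <- n_alpha + t2$n_alpha
      div <- div || t2$divergent
      j <- j + 1L
    }
    theta <- theta1
    lg <- lp_grad(theta)
    if (m <= n_warmup) {
      # dual averaging
      m_da <- m_da + 1L
      a_stat <- alpha / max(1L, n_alpha)
      hbar <- (1 - 1 / (m_da + t0)) * hbar +
        (target_accept - a_stat) / (m_da + t0)
      log_eps <- mu_da - sqrt(m_da) / gamma * hbar
      w <- m_da^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (m > mass_window[1] && m <= mass_window[2])
        warm_store[m - mass_window[1], ] <- theta
      if (m == mass_window[2]) {
        v_est <- apply(warm_store, 2, stats::var)
        v_est[!is.finite(v_est) | v_est <= 0] <- 1
        inv_mass <- v_est
        eps <- .find_epsilon(theta, lp_grad, inv_mass)
        mu_da <- log(10 * eps); hbar <- 0; log_eps_bar <- log(eps); m_da <- 0L
      }
      if (m == n_warmup) eps <- exp(log_eps_bar)
    } else {
      if (div) divergences <- divergences + 1L
      draws[m - n_warmup, ] <- theta
    }
  }
  list(draws = draws, step_size = eps, inv_mass = inv_mass,
       divergences = divergences)
}

#' Sample a log-density with the No-U-Turn sampler
#'
#' Multi-chain NUTS with dual-averaging step-size adaptation and a diagonal
#' mass matrix estimated during warmup. Intended for the smooth,
#' low-dimensional hierarchical posteriors this package fits; the interface
#' is a plain log-density-with-gradient function, so it is also usable on
#' its own.
#'
#' @param lp_grad Function of a parameter vector returning
#'   `list(lp = <log density>, grad = <gradient vector>)`.
#' @param init Initial parameter vector (unconstrained scale).
#' @param n_warmup Tuning iterations (discarded). Default 1000.
#' @param n_draws Posterior draws kept per chain. Default 2000.
#' @param chains Number of chains. Default 4.
#' @param seed Integer seed; chain `i` uses `seed + i - 1`.
#' @param target_accept Dual-averaging target acceptance statistic.
#' @param max_treedepth Maximum tree doublings per iteration.
#' @return List with `draws` (array: iterations x chains x parameters),
#'   `rhat` (split-R-hat per parameter), `divergences`, `step_size`.
#' @export
nuts_sample <- function(lp_grad, init, n_warmup = 1000L, n_draws = 2000L,
                        chains = 4L, seed = 1L, target_accept = 0.8,
                        max_treedepth = 10L) {
  res <- lapply(seq_len(chains), function(ch)
    .nuts_chain(lp_grad, init, n_warmup, n_draws, seed + ch - 1L,
                target_accept, max_treedepth))
  d <- length(init)
  arr <- array(NA_real_, c(n_draws, chains, d))
  for (ch in seq_len(chains)) arr[, ch, ] <- res[[ch]]$draws
  list(draws = arr,
       rhat = apply(arr, 3, split_rhat),
       divergences = sum(vapply(res, `[[`, 0L, "divergences")),
       step_size = vapply(res, `[[`, 0, "step_size"))
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction computed after splitting each chain in half,
#' so that within-chain trends are detected as well as between-chain
#' disagreement.
#'
#' @param x Matrix of draws (iterations x chains) for one parameter.
#' @return The split-R-hat statistic.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[seq.int(n - half + 1L, n), , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  b <- nn * stats::var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}
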