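# Shared fixtures and independent oracles for the test suite.

# cache simulated datasets so several tests can share one generation
.sim_cache <- new.env(parent = emptyenv())
cached_dataset <- function(name, cfg) {
  if (is.null(.sim_cache[[name]])) .sim_cache[[name]] <- simulate_dataset(cfg)
  .sim_cache[[name]]
}

tiny_config <- function(...) sim_config(n_per_group = 2, seed = 101, ...)

pair_pis_of <- function(dataset, ...) {
  summ <- summarize_trials(dataset, ...)
  flt <- filter_trials(summ)
  compute_pair_pis(flt$summaries)$pair_pis
}

# Brute-force exact signed-rank test: enumerate all 2^n sign patterns.
# Independent of stats::wilcox.test / psignrank.
brute_wilcoxon <- function(values, mu = 0) {
  d <- values - mu
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  patterns <- 0:(2^n - 1)
  Vs <- vapply(patterns, function(p) {
    signs <- bitwAnd(bitwShiftR(p, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(Vs <= V_obs)
  p_ge <- mean(Vs >= V_obs)
  list(V = V_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Dense-grid oracle for the JZS one-sample Bayes factor via the
# inverse-gamma mixture representation (Cauchy(0, r) on effect size is
# equivalent to g ~ InvGamma(1/2, r^2/2)), trapezoid rule on a mapped grid.
bf10_ttest_oracle <- function(t, n, r_scale = sqrt(2) / 2, n_grid = 20000) {
  nu <- n - 1
  u <- seq(1e-7, 1 - 1e-7, length.out = n_grid)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  dens_g <- r_scale / sqrt(2 * pi) * g^(-3 / 2) * exp(-r_scale^2 / (2 * g))
  m1 <- (1 + n * g)^(-1 / 2) *
    (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) * dens_g * jac
  du <- u[2] - u[1]
  int <- sum((m1[-1] + m1[-n_grid]) / 2) * du
  m0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  int / m0
}

# Gauss 2F1 via its Euler integral (substituting s = z^2 to remove the
# endpoint singularity), composite Simpson rule; used only by the
# correlation-BF oracle below.
gauss_2f1_euler <- function(cc, x, n_grid = 2001) {
  z <- seq(0, 1, length.out = n_grid)
  f <- outer(z, x, function(z, x) (1 - z^2)^(cc - 1.5) * (1 - x * z^2)^(-0.5))
  f[n_grid, ] <- 0  # integrand -> 0 at z = 1 for cc > 1.5
  h <- z[2] - z[1]
  # composite Simpson (n_grid odd): weights 1, 4, 2, 4, ..., 4, 1
  wfull <- c(1, rep(c(4, 2), length.out = n_grid - 2), 1)
  simpson <- as.vector(crossprod(f, wfull)) * h / 3
  gamma(cc) / (gamma(0.5) * gamma(cc - 0.5)) * 2 * simpson
}

# Dense-grid oracle for the stretched-beta correlation Bayes factor:
# trapezoid over rho with the Euler-integral 2F1.
bf10_cor_oracle <- function(r, n, kappa = 1 / 3,
                            direction = c("TWO_SIDED", "POSITIVE", "NEGATIVE"),
                            n_grid = 4001) {
  direction <- match.arg(direction)
  alpha <- 1 / kappa
  lims <- switch(direction, TWO_SIDED = c(-1, 1), POSITIVE = c(0, 1),
                 NEGATIVE = c(-1, 0))
  norm <- if (direction == "TWO_SIDED") 1 else 2
  rho <- seq(lims[1] + 1e-9, lims[2] - 1e-9, length.out = n_grid)
  cc <- n - 0.5
  hyp <- gauss_2f1_euler(cc, (rho * r + 1) / 2)
  lik <- (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^((3 - 2 * n) / 2) * hyp
  prior <- (1 - rho^2)^(alpha - 1) / (2^(2 * alpha - 1) * beta(alpha, alpha))
  f <- lik * norm * prior
  drho <- rho[2] - rho[1]
  int <- sum((f[-1] + f[-n_grid]) / 2) * drho
  f0 <- gauss_2f1_euler(cc, 0.5)
  int / f0
}

# Stochastic brute-force oracle for the dwell-chain proportion index:
# an independent re-simulation of the two-state chain (no off-screen
# process) counting emitted AOI samples over the window of interest.
chain_pi_oracle <- function(delta, stay_prob = 0.95, latency_mean = 300,
                            latency_sd = 100, onset = 3000,
                            window = c(368, 3505), transition_other = TRUE,
                            n_trials = 30000, seed = 99) {
  withr::with_seed(seed, {
    tg <- seq(-1000, 7000, length.out = 481)
    q <- 1 - stay_prob
    p_star <- 0.5 + delta
    lat <- rnorm(n_trials, latency_mean, latency_sd)
    while (any(lat < 0)) lat[lat < 0] <- rnorm(sum(lat < 0), latency_mean, latency_sd)
    state <- runif(n_trials) < 0.5
    n_t <- n_d <- numeric(n_trials)
    for (k in 2:length(tg)) {
      ps <- ifelse(tg[k] >= onset + lat, p_star, 0.5)
      leave <- ifelse(state, 2 * q * (1 - ps), 2 * q * ps)
      sw <- runif(n_trials) < leave
      state <- xor(state, sw)
      rel <- tg[k] - onset
      in_win <- rel >= window[1] & rel < window[2]
      counted <- in_win & !(transition_other & sw)
      n_t <- n_t + (counted & state)
      n_d <- n_d + (counted & !state)
    }
    p_hat <- n_t / (n_t + n_d)
    2 * (mean(p_hat, na.rm = TRUE) - 0.5)
  })
}

# direct one-sample t, used as the 1e-12 oracle for per-bin statistics
direct_t <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
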