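# Independent iterative least-squares oracle for the polarization
# modulation fit: brute-force grid start followed by Levenberg-Marquardt
# refinement of I = 0.5*i0*(1 + sd*sin(2*(theta - phi))). Shares no code
# with the closed-form harmonic estimator it cross-checks.
oracle_demodulate <- function(y, theta_deg) {
  sse <- function(i0, sd, phi)
    sum((y - 0.5 * i0 * (1 + sd * sin(2 * (theta_deg - phi) * pi / 180)))^2)
  grid <- expand.grid(sd = seq(0.05, 1.05, by = 0.1),
                      phi = seq(0, 175, by = 5))
  i0_start <- 2 * mean(y)
  k <- which.min(mapply(function(sd, phi) sse(i0_start, sd, phi),
                        grid$sd, grid$phi))
  df <- data.frame(y = y, th = theta_deg)
  fit <- minpack.lm::nlsLM(
    y ~ 0.5 * i0 * (1 + sd * sin(2 * (th - phi) * pi / 180)),
    data = df,
    start = list(i0 = i0_start, sd = grid$sd[k], phi = grid$phi[k]),
    lower = c(0, 0, -360), upper = c(Inf, 1.5, 720),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 500))
  p <- as.list(stats::coef(fit))
  p$phi <- p$phi %% 180
  p
}

# Angular distance modulo 180 degrees.
phi_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
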