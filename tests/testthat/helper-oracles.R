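# independent oracles used to cross-check the production code paths

# fixed-step Euler integration of the competition system, written directly
# from the differential equations; deliberately independent of integrate_lv()
euler_lv <- function(params, init, t_end, dt, sample_times) {
  X <- init[["X"]]; Y1 <- init[["Y1"]]; Y2 <- init[["Y2"]]
  n_steps <- ceiling(t_end / dt)
  out <- matrix(NA_real_, nrow = length(sample_times), ncol = 4,
                dimnames = list(NULL, c("t", "X", "Y1", "Y2")))
  next_sample <- 1L
  t <- 0
  record <- function(t, X, Y1, Y2) {
    while (next_sample <= length(sample_times) &&
           sample_times[next_sample] <= t + dt / 2) {
      out[next_sample, ] <<- c(sample_times[next_sample], X, Y1, Y2)
      next_sample <<- next_sample + 1L
    }
  }
  record(0, X, Y1, Y2)
  for (i in seq_len(n_steps)) {
    dX <- params$a * X * (1 - X / params$K)
    dY1 <- Y1 * (params$r1 * X - params$c11 * Y1 - params$c12 * Y2)
    dY2 <- Y2 * (params$r2 * X - params$c21 * Y1 - params$c22 * Y2)
    X <- max(X + dt * dX, 0)
    Y1 <- max(Y1 + dt * dY1, 0)
    Y2 <- max(Y2 + dt * dY2, 0)
    t <- i * dt
    record(t, X, Y1, Y2)
  }
  as.data.frame(out)
}

# logistic closed form for the decoupled female population
logistic_closed_form <- function(X0, a, K, t) {
  K * X0 * exp(a * t) / (K + X0 * (exp(a * t) - 1))
}
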