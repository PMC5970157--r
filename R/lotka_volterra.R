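#' Parameters of the shared-female Lotka-Volterra competition model
#'
#' Two male subpopulations `Y1`, `Y2` compete while sharing a single female
#' population `X` that grows logistically and is unaffected by the males:
#'
#' \deqn{dY_1/dt = Y_1 (r_1 X - c_{11} Y_1 - c_{12} Y_2)}
#' \deqn{dY_2/dt = Y_2 (r_2 X - c_{21} Y_1 - c_{22} Y_2)}
#' \deqn{dX/dt   = a X (1 - X/K)}
#'
#' `r_i` is male group i's growth response to female abundance, `c_ii` the
#' within-group and `c_ij` the between-group competition coefficient, `a` the
#' female logistic rate and `K` the female carrying capacity. All parameters
#' are strictly positive.
#'
#' @param r1,r2 Growth responses to female abundance.
#' @param c11,c12,c21,c22 Competition coefficients.
#' @param a Female logistic growth rate.
#' @param K Female carrying capacity.
#' @return An object of class `lv_params`.
#' @export
lv_params <- function(r1, r2, c11, c12, c21, c22, a, K) {
  p <- list(r1 = r1, r2 = r2, c11 = c11, c12 = c12, c21 = c21, c22 = c22,
            a = a, K = K)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Lotka-Volterra parameters must be strictly positive", call. = FALSE)
  structure(p, class = "lv_params")
}

#' @export
print.lv_params <- function(x, ...) {
  cat("<lv_params>\n")
  cat(sprintf("  r1 = %g, r2 = %g; c11 = %g, c12 = %g, c21 = %g, c22 = %g\n",
              x$r1, x$r2, x$c11, x$c12, x$c21, x$c22))
  cat(sprintf("  females: a = %g, K = %g; exclusion condition %s\n",
              x$a, x$K,
              if (check_exclusion_condition(x)) "holds" else "does not hold"))
  invisible(x)
}

#' Right-hand side of the competition system
#'
#' @param state Named numeric vector or list with nonnegative components
#'   `X`, `Y1`, `Y2`.
#' @param params An [lv_params()].
#' @return Named numeric vector `c(dX, dY1, dY2)`.
#' @examples
#' p <- lv_params(1, 1, 1, 2, 2, 1, a = 1, K = 1)
#' lv_derivatives(c(X = 1, Y1 = 0, Y2 = 0), p) # equilibrium
#' @export
lv_derivatives <- function(state, params) {
  X <- state[["X"]]; Y1 <- state[["Y1"]]; Y2 <- state[["Y2"]]
  c(
    dX = params$a * X * (1 - X / params$K),
    dY1 = Y1 * (params$r1 * X - params$c11 * Y1 - params$c12 * Y2),
    dY2 = Y2 * (params$r2 * X - params$c21 * Y1 - params$c22 * Y2)
  )
}

#' Competitive-exclusion condition
#'
#' `TRUE` when between-group competition strictly dominates within-group
#' competition, `min(c12, c21) > max(c11, c22)`; under this condition the
#' system almost always drives one male subpopulation to extinction (the
#' exception is the measure-zero symmetric separatrix).
#'
#' @param params An [lv_params()].
#' @return Logical scalar.
#' @export
check_exclusion_condition <- function(params) {
  min(params$c12, params$c21) > max(params$c11, params$c22)
}

#' Interior male equilibrium with females at carrying capacity
#'
#' Solves the linear system `r1 K = c11 Y1 + c12 Y2`, `r2 K = c21 Y1 + c22 Y2`
#' obtained by setting both male derivatives to zero at `X = K`. Returns the
#' equilibrium only if both components are strictly positive; returns `NULL`
#' for a singular system or a non-positive solution.
#'
#' @param params An [lv_params()].
#' @return Named numeric vector `c(Y1, Y2)`, or `NULL`.
#' @export
interior_equilibrium <- function(params) {
  A <- matrix(c(params$c11, params$c21, params$c12, params$c22), nrow = 2)
  b <- c(params$r1, params$r2) * params$K
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol)) || any(sol <= 0)) return(NULL)
  c(Y1 = sol[1], Y2 = sol[2])
}

#' Integrate the competition system
#'
#' Numerically integrates the system with `deSolve` (adaptive `lsoda` by
#' default), clamping components at zero from below (extinction is
#' absorbing; tiny negative undershoots are numerical artifacts).
#'
#' @param params An [lv_params()].
#' @param init Named numeric vector `c(X=, Y1=, Y2=)` of nonnegative initial
#'   sizes, or a list with those components.
#' @param t_end End time (> 0).
#' @param n_steps Number of output sample points after time 0.
#' @param method Integration method passed to [deSolve::ode()].
#' @return A tibble of class `lv_trajectory` with columns `t, X, Y1, Y2`;
#'   the parameters are attached as attribute `"params"`.
#' @examples
#' p <- lv_params(1, 1, 1, 2, 2, 1, a = 1, K = 1)
#' traj <- integrate_lv(p, c(X = 0.5, Y1 = 0.6, Y2 = 0.4), t_end = 50)
#' classify_outcome(traj)
#' @export
integrate_lv <- function(params, init, t_end, n_steps = 1000L, method = "lsoda") {
  init <- unlist(init)[c("X", "Y1", "Y2")]
  if (any(is.na(init)) || any(init < 0))
    stop("init must provide nonnegative X, Y1, Y2", call. = FALSE)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    list(lv_derivatives(y, p))
  }
  times <- seq(0, t_end, length.out = n_steps + 1L)
  sol <- deSolve::ode(y = init, times = times, func = rhs, parms = params,
                      method = method, rtol = 1e-9, atol = 1e-12)
  if (any(!is.finite(sol))) {
    bad <- which(apply(sol, 1, function(r) any(!is.finite(r))))[1]
    stop(sprintf("integration failed near t = %g", sol[max(bad - 1, 1), "time"]),
         call. = FALSE)
  }
  out <- tibble::tibble(
    t = sol[, "time"],
    X = pmax(sol[, "X"], 0),
    Y1 = pmax(sol[, "Y1"], 0),
    Y2 = pmax(sol[, "Y2"], 0)
  )
  attr(out, "params") <- params
  class(out) <- c("lv_trajectory", class(out))
  out
}

#' Classify the outcome of a competition trajectory
#'
#' A male subpopulation is declared extinct at the first time it falls below
#' `eps` and never recovers within the trajectory. If both stay above `eps`
#' and the derivatives at the end of the trajectory are numerically settled
#' (all below `settle_tol` in absolute value), the outcome is coexistence;
#' anything else is undecided.
#'
#' @param trajectory An `lv_trajectory` from [integrate_lv()].
#' @param eps Extinction threshold; defaults to `1e-6` times the larger
#'   initial male population.
#' @param settle_tol Settledness criterion on the end-of-trajectory
#'   derivatives.
#' @return An object of class `lv_outcome`: list with `outcome` (one of
#'   `"Y1_extinct"`, `"Y2_extinct"`, `"coexistence"`, `"undecided"`) and
#'   `extinction_time` (`NA` unless an extinction was declared).
#' @export
classify_outcome <- function(trajectory, eps = NULL, settle_tol = 1e-8) {
  params <- attr(trajectory, "params")
  if (is.null(eps)) eps <- 1e-6 * max(trajectory$Y1[1], trajectory$Y2[1], 1e-12)
  stopifnot(eps > 0)
  extinct_at <- function(y) {
    below <- y < eps
    if (!below[length(below)]) return(NA_real_)
    # first index after which the population never recovers
    first <- which(below & rev(cumprod(rev(below))) == 1)[1]
    if (is.na(first)) NA_real_ else trajectory$t[first]
  }
  t1 <- extinct_at(trajectory$Y1)
  t2 <- extinct_at(trajectory$Y2)
  if (!is.na(t1) && (is.na(t2) || t1 <= t2)) {
    out <- list(outcome = "Y1_extinct", extinction_time = t1)
  } else if (!is.na(t2)) {
    out <- list(outcome = "Y2_extinct", extinction_time = t2)
  } else {
    settled <- FALSE
    if (!is.null(params)) {
      last <- nrow(trajectory)
      d <- lv_derivatives(c(X = trajectory$X[last], Y1 = trajectory$Y1[last],
                            Y2 = trajectory$Y2[last]), params)
      settled <- all(abs(d) < settle_tol)
    }
    out <- list(
      outcome = if (settled) "coexistence" else "undecided",
      extinction_time = NA_real_
    )
  }
  structure(out, class = "lv_outcome")
}

#' @export
print.lv_outcome <- function(x, ...) {
  cat(sprintf("<lv_outcome> %s", x$outcome))
  if (!is.na(x$extinction_time)) cat(sprintf(" (t = %g)", x$extinction_time))
  cat("\n")
  invisible(x)
}

#' @rdname classify_outcome
#' @param x An `lv_outcome`.
#' @param ... Unused.
#' @export
tidy.lv_outcome <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, extinction_time = x$extinction_time)
}

#' @rdname integrate_lv
#' @param object An `lv_trajectory`.
#' @param ... Unused.
#' @export
autoplot.lv_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                              names_to = "population", values_to = "size")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$size,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "population size")
}
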