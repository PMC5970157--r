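#' Gini-Simpson diversity
#'
#' `1 - sum(p_i^2)`: the probability that two individuals drawn at random
#' belong to different classes. Bounded by `1 - 1/k` for `k` occupied
#' classes, attained exactly at the uniform distribution.
#'
#' @param counts Nonnegative numeric vector of class counts with a positive
#'   sum.
#' @return A single number in `[0, 1)`.
#' @examples
#' gini_simpson(c(3, 1)) # 0.375
#' gini_simpson(rep(100, 100)) # 0.99
#' @export
gini_simpson <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("diversity undefined for an empty count vector", call. = FALSE)
  p <- counts / total
  1 - sum(p^2)
}

#' Summarise a grid state
#'
#' The four quantities tracked per generation, plus the total population:
#' number of distinct (occupied) cultural groups and haplogroups, and the
#' Gini-Simpson diversity of the group-size and haplogroup-size marginals.
#'
#' @param state A `grid_state`.
#' @return A one-row tibble with columns `generation`, `total_pop`,
#'   `n_groups`, `n_haplogroups`, `group_diversity`, `haplogroup_diversity`.
#' @export
summarize_state <- function(state) {
  row_m <- rowSums(state$counts)
  col_m <- colSums(state$counts)
  total <- sum(row_m)
  if (total == 0) stop("diversity undefined for an empty grid", call. = FALSE)
  tibble::tibble(
    generation = state$generation,
    total_pop = as.integer(total),
    n_groups = sum(row_m > 0),
    n_haplogroups = sum(col_m > 0),
    group_diversity = gini_simpson(row_m[row_m > 0]),
    haplogroup_diversity = gini_simpson(col_m[col_m > 0])
  )
}

summary_quantities <- c("total_pop", "n_groups", "n_haplogroups",
                        "group_diversity", "haplogroup_diversity")

#' Run an ensemble of independent simulations
#'
#' Runs `n_runs` replicate simulations of one configuration, each from a
#' per-run seed spawned deterministically from the master seed, and
#' aggregates the per-generation mean, standard deviation and a mean +/- 2 SD
#' band for every summary quantity. Runs in which the whole population dies
#' are excluded from the aggregate and counted.
#'
#' @param config A [sim_config()].
#' @param n_runs Number of replicate runs (at least 1).
#' @param seed Master seed; defaults to `config$seed`.
#' @return An object of class `ensemble_result`: a list with `runs` (long
#'   tibble of every run's trajectory, with a `run` column), `stats` (long
#'   tibble `generation, quantity, mean, sd, lower, upper`), `n_runs`,
#'   `n_dead`, `config`, `seed`.
#' @examples
#' cfg <- sim_config(1000, 10, 50, 0.25, TRUE, n_generations = 5)
#' ens <- run_ensemble(cfg, n_runs = 3)
#' tidy(ens)
#' @export
run_ensemble <- function(config, n_runs, seed = config$seed) {
  stopifnot(n_runs >= 1)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  trajs <- vector("list", n_runs)
  n_dead <- 0L
  for (i in seq_len(n_runs)) {
    cfg_i <- config
    cfg_i$seed <- run_seeds[i]
    res <- tryCatch(run_simulation(cfg_i), patrisim_dead = function(e) NULL)
    if (is.null(res)) {
      n_dead <- n_dead + 1L
    } else {
      trajs[[i]] <- dplyr::mutate(res$summary, run = i, .before = 1)
    }
  }
  if (n_dead > 0)
    warning(sprintf("%d of %d runs went extinct and were excluded", n_dead, n_runs),
            call. = FALSE)
  runs <- dplyr::bind_rows(trajs)
  if (nrow(runs) == 0) stop("all ensemble runs went extinct", call. = FALSE)
  stats <- runs |>
    tidyr::pivot_longer(dplyr::all_of(summary_quantities),
                        names_to = "quantity", values_to = "value") |>
    dplyr::group_by(.data$generation, .data$quantity) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(lower = .data$mean - 2 * .data$sd,
                  upper = .data$mean + 2 * .data$sd)
  structure(
    list(runs = runs, stats = stats, n_runs = n_runs, n_dead = n_dead,
         config = config, seed = seed),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d runs (%d excluded as extinct), %s start\n",
              x$n_runs, x$n_dead,
              if (x$config$patrilineal) "PT" else "NPT"))
  final <- dplyr::filter(x$stats, .data$generation == max(.data$generation))
  for (i in seq_len(nrow(final)))
    cat(sprintf("  final %-21s mean %.4g (sd %.3g)\n",
                final$quantity[i], final$mean[i], final$sd[i]))
  invisible(x)
}

#' @rdname run_ensemble
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @export
tidy.ensemble_result <- function(x, ...) x$stats

#' @rdname run_ensemble
#' @export
glance.ensemble_result <- function(x, ...) {
  final <- dplyr::filter(x$stats, .data$generation == max(.data$generation))
  wide <- tidyr::pivot_wider(final[, c("quantity", "mean")],
                             names_from = "quantity", values_from = "mean",
                             names_prefix = "final_")
  dplyr::bind_cols(
    tibble::tibble(n_runs = x$n_runs, n_dead = x$n_dead,
                   patrilineal = x$config$patrilineal),
    wide
  )
}

#' @rdname run_ensemble
#' @param object An `ensemble_result`.
#' @export
autoplot.ensemble_result <- function(object, ...) {
  ggplot2::ggplot(object$stats, ggplot2::aes(.data$generation, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "red") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "generation", y = "ensemble mean (band: mean ± 2 SD)")
}
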