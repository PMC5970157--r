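#' Grid state of the simulator
#'
#' A grid state holds the `|C| x |H|` matrix of male counts per (cultural
#' group, haplogroup) cell, the current generation index, and the per-group
#' fitness multipliers used by the regeneration step.
#'
#' @param counts Nonnegative integer matrix, rows = cultural groups,
#'   columns = haplogroups.
#' @param generation Nonnegative integer step index (0 = initial state).
#' @param fitness Length-`nrow(counts)` vector of positive fitness
#'   multipliers; all 1 when cultural selection is off.
#' @return An object of class `grid_state`.
#' @export
grid_state <- function(counts, generation = 0L, fitness = rep(1, nrow(counts))) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("grid counts must be nonnegative", call. = FALSE)
  if (length(fitness) != nrow(counts) || any(fitness <= 0))
    stop("fitness must be positive and one value per group", call. = FALSE)
  structure(
    list(counts = counts, generation = as.integer(generation),
         fitness = as.numeric(fitness)),
    class = "grid_state"
  )
}

#' @export
print.grid_state <- function(x, ...) {
  sizes <- rowSums(x$counts)
  cat(sprintf("<grid_state> generation %d: %d males, %d/%d groups occupied, %d/%d haplogroups present\n",
              x$generation, sum(x$counts), sum(sizes > 0), nrow(x$counts),
              sum(colSums(x$counts) > 0), ncol(x$counts)))
  invisible(x)
}

group_sizes <- function(state) rowSums(state$counts)

#' Initialise the grid
#'
#' Builds the generation-0 grid for a configuration. Under a patrilineal (PT)
#' start, group `j` holds all `S0` of its males in haplogroup `j`: cultural
#' group identity completely determines haplogroup. Under a non-patrilineal
#' (NPT) start each group carries haplogroups `1..n_groups` spread as evenly
#' as possible (any remainder goes to the lowest column indices), so the
#' population-level haplogroup frequencies are identical to PT but within-group
#' distributions mirror the whole population. With cultural selection on, each
#' group independently draws fitness `1 + s` with probability 1/2, else 1,
#' using the current RNG stream.
#'
#' @param config A [sim_config()].
#' @return A `grid_state` at generation 0.
#' @examples
#' cfg <- sim_config(1000, 10, 50, 0.25, patrilineal = TRUE)
#' g <- init_grid(cfg)
#' rowSums(g$counts) # all equal to S0 = 100
#' @export
init_grid <- function(config) {
  validate_sim_config(config)
  C <- config$n_groups
  H <- config$n_haplogroups
  S0 <- config$n_total %/% C
  counts <- matrix(0L, nrow = C, ncol = H)
  if (config$patrilineal) {
    counts[cbind(seq_len(C), seq_len(C))] <- S0
  } else {
    per_cell <- S0 %/% C
    remainder <- S0 %% C
    row_fill <- rep.int(per_cell, C)
    if (remainder > 0) row_fill[seq_len(remainder)] <- row_fill[seq_len(remainder)] + 1L
    counts[, seq_len(C)] <- matrix(row_fill, nrow = C, ncol = C, byrow = TRUE)
  }
  fitness <- rep(1, C)
  if (config$cultural_selection) {
    favoured <- stats::runif(C) < 0.5
    fitness[favoured] <- 1 + config$selection_coefficient
  }
  grid_state(counts, generation = 0L, fitness = fitness)
}

#' Killing step: intergroup competition deaths
#'
#' Each nonempty group `c` of current size `N_c` suffers deaths at proportion
#' `p_c = min(1, D * S0 / N_c)`, where `D` is the configured death rate and
#' `S0` the initial group size; per cell `(c, h)` the number of deaths is
#' Poisson with mean `p_c * n_ch`, truncated at the cell count. The expected
#' decline of a group at its initial size is therefore exactly `D`, and the
#' expected proportion killed grows as the group shrinks, reflecting the
#' disadvantage of small groups in intergroup competition.
#'
#' @param state A `grid_state`.
#' @param config A [sim_config()].
#' @return A list with elements `state` (post-killing `grid_state`) and
#'   `report`, a list holding `deaths_per_group` (integer vector) and
#'   `groups_emptied` (indices of groups reduced to zero this step).
#' @export
killing_step <- function(state, config) {
  counts <- state$counts
  sizes <- rowSums(counts)
  pre_occupied <- sizes > 0
  S0 <- config$n_total / config$n_groups
  p <- numeric(length(sizes))
  p[pre_occupied] <- pmin(1, config$death_rate * S0 / sizes[pre_occupied])
  lambda <- counts * p[row(counts)]
  deaths <- matrix(rpois(length(lambda), lambda), nrow = nrow(counts))
  deaths <- pmin(deaths, counts)
  new_counts <- counts - deaths
  new_sizes <- rowSums(new_counts)
  out <- state
  out$counts <- new_counts
  storage.mode(out$counts) <- "integer"
  list(
    state = out,
    report = list(
      deaths_per_group = as.integer(rowSums(deaths)),
      groups_emptied = which(pre_occupied & new_sizes == 0)
    )
  )
}

#' Mutation step: haplogroup-defining mutations in the major haplogroup
#'
#' Within each nonempty group, `floor(mu * n)` carriers of the group's major
#' haplogroup (largest cell in the row; ties broken toward the lowest column)
#' mutate to other haplogroups while staying in their cultural group. Each
#' mutant lands in a column drawn uniformly among currently globally-empty
#' haplogroup columns (the birth of a new clade) if any exist, otherwise
#' uniformly among the other columns. When `mu * n < 1` no mutation occurs,
#' so sparsely occupied cells never mutate.
#'
#' @inheritParams killing_step
#' @return The post-mutation `grid_state`; row sums are conserved.
#' @export
mutation_step <- function(state, config) {
  mu <- config$mutation_rate
  if (mu == 0) return(state)
  counts <- state$counts
  H <- ncol(counts)
  col_occ <- colSums(counts) > 0
  for (g in seq_len(nrow(counts))) {
    row <- counts[g, ]
    if (all(row == 0L)) next
    h_major <- which.max(row) # ties -> lowest column index
    n_mut <- floor(mu * row[h_major])
    if (n_mut < 1) next
    for (k in seq_len(n_mut)) {
      empty <- which(!col_occ)
      if (length(empty) > 0) {
        dest <- empty[sample.int(length(empty), 1L)]
      } else {
        others <- seq_len(H)[-h_major]
        dest <- others[sample.int(length(others), 1L)]
      }
      counts[g, h_major] <- counts[g, h_major] - 1L
      counts[g, dest] <- counts[g, dest] + 1L
      col_occ[dest] <- TRUE
      if (counts[g, h_major] == 0L) col_occ[h_major] <- any(counts[, h_major] > 0L)
    }
  }
  out <- state
  out$counts <- counts
  out
}

#' Remove or fuse groups below the viability floor
#'
#' A cultural group whose size has dropped strictly below the viability
#' threshold is no longer a functioning social unit. Under the default
#' extirpation rule its row is zeroed (all members lost). Under the fusion
#' rule its members instead join the nearest viable group by row distance
#' (ties broken toward the row above); if no viable group exists the rule
#' falls back to extirpation.
#'
#' @inheritParams killing_step
#' @return The culled `grid_state`: every surviving nonzero group has size at
#'   least the threshold.
#' @export
cull_small_groups <- function(state, config) {
  theta <- config$extinction_threshold
  counts <- state$counts
  sizes <- rowSums(counts)
  doomed <- which(sizes > 0 & sizes < theta)
  if (length(doomed) == 0) return(state)
  if (config$extinction_rule == "fusion") {
    for (g in doomed) {
      sizes <- rowSums(counts)
      viable <- which(sizes >= theta)
      if (length(viable) > 0) {
        dist <- abs(viable - g)
        # nearest viable row; tie -> the row above (smaller index)
        cand <- viable[dist == min(dist)]
        target <- min(cand)
        counts[target, ] <- counts[target, ] + counts[g, ]
      }
      counts[g, ] <- 0L
    }
  } else {
    counts[doomed, ] <- 0L
  }
  out <- state
  out$counts <- counts
  out
}

#' Regeneration step: restore the total population size
#'
#' Scales the whole grid back up so the next generation again has exactly
#' `n_total` males: each cell's target share is proportional to its count
#' weighted by its group's fitness, and integer counts are assigned by
#' largest-remainder rounding (ties broken lexicographically by row then
#' column) so the total is met exactly. Cells at zero stay at zero, so no
#' haplogroup or group is resurrected by reproduction.
#'
#' @inheritParams killing_step
#' @return The regenerated `grid_state` with total exactly `n_total`.
#' @export
regeneration_step <- function(state, config) {
  counts <- state$counts
  w <- state$fitness
  weights <- counts * w[row(counts)]
  total_w <- sum(weights)
  if (total_w == 0) {
    stop(errorCondition("entire population extinct: nothing to regenerate",
                        class = "patrisim_dead"))
  }
  N <- config$n_total
  shares <- weights * (N / total_w)
  base <- floor(shares)
  frac <- shares - base
  remainder <- N - sum(base)
  if (remainder > 0) {
    nz <- which(weights > 0)
    r <- (nz - 1L) %% nrow(counts) + 1L
    co <- (nz - 1L) %/% nrow(counts) + 1L
    ord <- nz[order(-frac[nz], r, co)]
    take <- ord[seq_len(remainder)]
    base[take] <- base[take] + 1
  }
  out <- state
  out$counts <- matrix(as.integer(base), nrow = nrow(counts))
  out
}

# draw k individuals without replacement from a row of cell counts
# (multivariate hypergeometric); returns per-cell draws
draw_hypergeometric <- function(cells, k) {
  pool <- rep.int(seq_along(cells), cells)
  picked <- pool[sample.int(length(pool), k)]
  tabulate(picked, nbins = length(cells))
}

#' Fission step: the largest group splits into empty rows
#'
#' Whenever a cultural group has gone extinct (an empty row), the largest
#' surviving group splits in half: `floor(size / 2)` members, drawn without
#' replacement across its haplogroup cells, form a new group in the vacated
#' row, the rest remain. Empty rows are processed in increasing index order;
#' a split only happens while the largest group is at least twice the
#' viability threshold (so fission never creates an instantly non-viable
#' group); once that fails, remaining rows stay empty.
#'
#' @inheritParams killing_step
#' @return The post-fission `grid_state`; the total population is conserved.
#' @export
fission_step <- function(state, config) {
  counts <- state$counts
  theta <- config$extinction_threshold
  fitness <- state$fitness
  sizes <- rowSums(counts)
  for (g in which(sizes == 0)) {
    sizes <- rowSums(counts)
    largest <- which.max(sizes) # ties -> lowest row index
    if (sizes[largest] < 2 * theta) break
    k <- sizes[largest] %/% 2
    moved <- draw_hypergeometric(counts[largest, ], k)
    counts[largest, ] <- counts[largest, ] - as.integer(moved)
    counts[g, ] <- as.integer(moved)
    fitness[g] <- fitness[largest] # fission children inherit the parent's fitness
  }
  out <- state
  out$counts <- counts
  out$fitness <- fitness
  out
}

#' Advance the simulation by one generation
#'
#' Applies the five per-generation operators in their fixed order — killing,
#' mutation, removal of non-viable groups, regeneration, fission — and
#' increments the generation counter.
#'
#' @inheritParams killing_step
#' @return A list with the new `grid_state` (`state`) and the killing-step
#'   `report`.
#' @export
run_generation <- function(state, config) {
  killed <- killing_step(state, config)
  s <- mutation_step(killed$state, config)
  s <- cull_small_groups(s, config)
  s <- regeneration_step(s, config)
  s <- fission_step(s, config)
  s$generation <- state$generation + 1L
  list(state = s, report = killed$report)
}

#' Run a full simulation
#'
#' Seeds the RNG from the configuration, builds the initial grid, advances it
#' for `n_generations` generations, and records the per-generation summary
#' (total population, distinct group and haplogroup counts, Gini-Simpson
#' group and haplogroup diversities) at generation 0 and after every step.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_trajectory`: a list with `summary`
#'   (tibble of `n_generations + 1` rows), `final_state` (the last
#'   `grid_state`) and `config`. Dies with a condition of class
#'   `patrisim_dead` if the whole population goes extinct.
#' @examples
#' traj <- run_simulation(sim_config(1000, 10, 50, 0.25, TRUE, n_generations = 5))
#' tidy(traj)
#' @export
run_simulation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  state <- init_grid(config)
  records <- vector("list", config$n_generations + 1L)
  records[[1L]] <- summarize_state(state)
  if (config$n_generations > 0) {
    for (t in seq_len(config$n_generations)) {
      step <- tryCatch(
        run_generation(state, config),
        patrisim_dead = function(e) {
          stop(errorCondition(
            sprintf("population extinct at generation %d", t),
            class = "patrisim_dead"
          ))
        }
      )
      state <- step$state
      records[[t + 1L]] <- summarize_state(state)
    }
  }
  structure(
    list(summary = dplyr::bind_rows(records), final_state = state, config = config),
    class = "sim_trajectory"
  )
}

#' @export
print.sim_trajectory <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("<sim_trajectory> %d generations (%s start)\n",
              x$config$n_generations,
              if (x$config$patrilineal) "PT" else "NPT"))
  cat(sprintf("  final: %d males, %d groups, %d haplogroups, haplogroup diversity %.3f\n",
              last$total_pop, last$n_groups, last$n_haplogroups,
              last$haplogroup_diversity))
  invisible(x)
}

#' @rdname run_simulation
#' @param x A `sim_trajectory`.
#' @param ... Unused.
#' @export
tidy.sim_trajectory <- function(x, ...) x$summary

#' @rdname run_simulation
#' @export
glance.sim_trajectory <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  tibble::tibble(
    n_generations = x$config$n_generations,
    patrilineal = x$config$patrilineal,
    final_n_groups = last$n_groups,
    final_n_haplogroups = last$n_haplogroups,
    final_group_diversity = last$group_diversity,
    final_haplogroup_diversity = last$haplogroup_diversity
  )
}

#' @rdname run_simulation
#' @param object A `sim_trajectory`.
#' @export
autoplot.sim_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary, -"generation",
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL)
}
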