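test_that("patrilineal initial grid is monochromatic per group", {
  cfg <- reference_config(patrilineal = TRUE)
  g <- init_grid(cfg)
  expect_equal(dim(g$counts), c(100L, 500L))
  expect_equal(g$counts[cbind(1:100, 1:100)], rep(100L, 100))
  expect_equal(sum(g$counts), 10000L)
  expect_equal(sum(g$counts > 0), 100L) # diagonal only
  expect_equal(g$generation, 0L)
  expect_equal(g$fitness, rep(1, 100))
})

test_that("non-patrilineal initial grid mirrors population-level frequencies", {
  cfg <- reference_config(patrilineal = FALSE)
  g <- init_grid(cfg)
  # S0 = 100 spread over 100 haplogroups: every cell in the first block is 1
  expect_true(all(g$counts[, 1:100] == 1L))
  expect_true(all(g$counts[, 101:500] == 0L))
  # uneven S0: remainder goes to the lowest columns
  cfg2 <- sim_config(n_total = 35L * 10L, n_groups = 10L, n_haplogroups = 20L,
                     death_rate = 0.2, patrilineal = FALSE)
  g2 <- init_grid(cfg2)
  expect_equal(g2$counts[1, 1:10], c(4L, 4L, 4L, 4L, 4L, 3L, 3L, 3L, 3L, 3L))
  expect_true(all(rowSums(g2$counts) == 35L))
})

test_that("killing intensity scales inversely with group size", {
  cfg <- tiny_config(n_total = 100L, n_groups = 1L, n_haplogroups = 2L,
                     death_rate = 0.25)
  # zero death rate leaves the grid untouched
  cfg0 <- tiny_config(n_total = 100L, n_groups = 1L, n_haplogroups = 2L,
                      death_rate = 0)
  st <- single_group_state(100L)
  res0 <- killing_step(st, cfg0)
  expect_equal(res0$state$counts, st$counts)
  expect_equal(res0$report$deaths_per_group, 0L)

  # a group at half its initial size loses the same expected head count:
  # p_c = min(1, D * S0 / N_c) doubles as the group halves
  set.seed(11)
  n_rep <- 4000
  deaths_full <- replicate(n_rep, killing_step(st, cfg)$report$deaths_per_group)
  st_half <- single_group_state(50L)
  deaths_half <- replicate(n_rep, killing_step(st_half, cfg)$report$deaths_per_group)
  se <- sqrt(25 / n_rep) # Poisson(25) mean has sd sqrt(25)/sqrt(n)
  expect_lt(abs(mean(deaths_full) - 25), 3 * se)
  expect_lt(abs(mean(deaths_half) - 25), 3 * se)
  # mean proportion killed is ~twice as large for the half-size group
  expect_gt(mean(deaths_half) / 50, 1.8 * mean(deaths_full) / 100)
  # deaths never exceed the members present
  st_small <- single_group_state(c(3L, 2L))
  for (i in 1:200) {
    r <- killing_step(st_small, cfg)
    expect_true(all(r$state$counts >= 0L))
  }
})

test_that("mutation moves floor(mu * major-cell) individuals within the row", {
  cfg <- tiny_config(mutation_rate = 0.001)
  # mu = 0 is the identity
  st <- single_group_state(c(1000L, 5L), n_haplogroups = 6L)
  expect_equal(mutation_step(st, tiny_config(mutation_rate = 0))$counts, st$counts)
  # major cell 1000 at mu = 0.001 -> exactly one mutant, row sum conserved
  set.seed(1)
  out <- mutation_step(st, cfg)
  expect_equal(sum(out$counts), 1005L)
  expect_equal(out$counts[1, 1], 999L)
  # major cell 500 -> floor(0.5) = 0, untouched
  st500 <- single_group_state(500L)
  expect_equal(mutation_step(st500, cfg)$counts, st500$counts)
})

test_that("mutants preferentially found new clades in globally empty columns", {
  cfg <- tiny_config(mutation_rate = 0.001)
  counts <- matrix(0L, nrow = 2, ncol = 6)
  counts[1, 1] <- 2000L # two mutants
  counts[2, 2] <- 30L   # column 2 occupied by the other group
  st <- grid_state(counts)
  for (s in 1:50) {
    set.seed(s)
    out <- mutation_step(st, cfg)
    landed <- which(out$counts[1, -1] > 0) + 1L
    expect_true(all(landed %in% 3:6)) # never column 2 while empties remain
    expect_equal(rowSums(out$counts), rowSums(counts))
  }
  # with no empty column, destinations are among the other occupied columns
  full <- grid_state(matrix(c(2000L, 10L, 10L), nrow = 1))
  set.seed(2)
  outf <- mutation_step(full, cfg)
  expect_equal(outf$counts[1, 1], 1998L)
  expect_equal(sum(outf$counts), 2020L)
})

test_that("groups below the viability floor are extirpated or fused", {
  cfg <- tiny_config() # theta = 20
  counts <- matrix(0L, nrow = 3, ncol = 4)
  counts[1, 1] <- 19L
  counts[2, 2] <- 20L
  counts[3, 3] <- 100L
  st <- grid_state(counts)
  out <- cull_small_groups(st, cfg)
  expect_equal(sum(out$counts[1, ]), 0L)   # 19 < 20: removed
  expect_equal(sum(out$counts[2, ]), 20L)  # exactly at the floor: retained
  expect_equal(sum(out$counts[3, ]), 100L)

  # fusion: nearest viable row wins, tie broken toward the row above
  cfgf <- tiny_config(extinction_rule = "fusion")
  counts <- matrix(0L, nrow = 7, ncol = 3)
  counts[4, 1] <- 40L
  counts[5, 2] <- 10L
  counts[6, 3] <- 40L
  stf <- grid_state(counts)
  outf <- cull_small_groups(stf, cfgf)
  expect_equal(sum(outf$counts[5, ]), 0L)
  expect_equal(outf$counts[4, ], c(40L, 10L, 0L)) # merged into the row above
  expect_equal(sum(outf$counts), 90L)
  # no viable neighbour anywhere: fusion falls back to extirpation
  lone <- grid_state(matrix(c(0L, 10L, 0L, 0L, 5L, 0L), nrow = 3))
  outl <- cull_small_groups(lone, cfgf)
  expect_equal(sum(outl$counts), 0L)
})

test_that("regeneration restores the total exactly by largest remainder", {
  cfg1 <- tiny_config(n_total = 10000L, n_groups = 1L, n_haplogroups = 2L)
  st <- single_group_state(8000L)
  expect_equal(sum(regeneration_step(st, cfg1)$counts), 10000L)

  cfg2 <- tiny_config(n_total = 10000L, n_groups = 2L, n_haplogroups = 2L)
  counts <- matrix(0L, nrow = 2, ncol = 2)
  counts[1, 1] <- 3000L; counts[2, 2] <- 5000L
  out <- regeneration_step(grid_state(counts), cfg2)
  expect_equal(out$counts[1, 1], 3750L)
  expect_equal(out$counts[2, 2], 6250L)

  # fractional ties go to the lexicographically first (row, column) cell
  cfg3 <- tiny_config(n_total = 10L, n_groups = 1L, n_haplogroups = 3L)
  out3 <- regeneration_step(single_group_state(c(1L, 1L, 1L), 3L), cfg3)
  expect_equal(out3$counts[1, ], c(4L, 3L, 3L))

  # zero cells are never resurrected
  expect_true(all(regeneration_step(grid_state(counts), cfg2)$counts[
    counts == 0L] == 0L))

  # fully extinct grid cannot regenerate
  dead <- grid_state(matrix(0L, 2, 2))
  expect_error(regeneration_step(dead, cfg2), class = "patrisim_dead")
})

test_that("cultural selection tilts regeneration toward favoured groups", {
  cfg <- tiny_config(n_total = 2000L, n_groups = 2L, n_haplogroups = 2L,
                     cultural_selection = TRUE, selection_coefficient = 1)
  counts <- matrix(0L, nrow = 2, ncol = 2)
  counts[1, 1] <- 500L; counts[2, 2] <- 500L
  st <- grid_state(counts, fitness = c(2, 1)) # w1 = 1 + s
  out <- regeneration_step(st, cfg)
  # shares 2:1 -> 1333/667 after largest-remainder rounding
  expect_equal(sum(out$counts), 2000L)
  expect_equal(out$counts[1, 1], 1333L)
  expect_equal(out$counts[2, 2], 667L)
})

test_that("fission splits the largest group into vacated rows", {
  cfg <- tiny_config() # theta = 20
  counts <- matrix(0L, nrow = 2, ncol = 3)
  counts[1, 1] <- 101L
  st <- grid_state(counts)
  set.seed(3)
  out <- fission_step(st, cfg)
  expect_equal(sum(out$counts[1, ]), 51L)
  expect_equal(sum(out$counts[2, ]), 50L)
  expect_equal(sum(out$counts), 101L)
  # monochromatic parent yields a monochromatic child
  expect_equal(out$counts[2, 1], 50L)

  # no empty rows: identity
  full <- grid_state(matrix(c(50L, 60L), nrow = 2))
  expect_equal(fission_step(full, cfg)$counts, full$counts)

  # viability guard: a parent below 2 * theta does not split
  small <- matrix(0L, nrow = 2, ncol = 2)
  small[1, 1] <- 30L
  outs <- fission_step(grid_state(small), cfg)
  expect_equal(sum(outs$counts[2, ]), 0L)
  expect_equal(outs$counts[1, 1], 30L)
})

test_that("fission draws a random half without replacement across cells", {
  cfg <- tiny_config()
  counts <- matrix(0L, nrow = 2, ncol = 2)
  counts[1, ] <- c(60L, 40L)
  st <- grid_state(counts)
  set.seed(5)
  draws <- t(replicate(2000, fission_step(st, cfg)$counts[2, ]))
  expect_true(all(rowSums(draws) == 50L))
  # hypergeometric mean of the first cell: 50 * 60/100 = 30
  expect_lt(abs(mean(draws[, 1]) - 30), 3 * sd(draws[, 1]) / sqrt(2000))
  # no cell ever exceeds its source
  expect_true(all(draws[, 1] <= 60L & draws[, 2] <= 40L))
})

test_that("a generation composes the five steps and conserves the total", {
  # all-identity parameters change nothing but the clock
  cfg0 <- tiny_config(death_rate = 0, mutation_rate = 0)
  g <- init_grid(cfg0)
  out <- run_generation(g, cfg0)
  expect_equal(out$state$counts, g$counts)
  expect_equal(out$state$generation, 1L)

  # total is restored to n_total every generation
  cfg <- tiny_config(death_rate = 0.3)
  set.seed(9)
  st <- init_grid(cfg)
  for (i in 1:10) {
    st <- run_generation(st, cfg)$state
    expect_equal(sum(st$counts), cfg$n_total)
  }
})

test_that("without mutation a patrilineal start stays monochromatic", {
  cfg <- tiny_config(mutation_rate = 0, death_rate = 0.4, seed = 13L)
  set.seed(cfg$seed)
  st <- init_grid(cfg)
  for (i in 1:15) {
    st <- run_generation(st, cfg)$state
    per_row_haplos <- rowSums(st$counts > 0)
    expect_true(all(per_row_haplos <= 1L))
  }
})

test_that("full runs record T + 1 generations and are seed-deterministic", {
  cfg <- tiny_config(n_generations = 10L, seed = 99L)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_equal(nrow(a$summary), 11L)
  expect_identical(a$summary, b$summary)
  expect_identical(a$final_state$counts, b$final_state$counts)
  expect_false(identical(
    a$summary, run_simulation(tiny_config(n_generations = 10L, seed = 100L))$summary
  ))
  # T = 0 records only the initial condition
  z <- run_simulation(tiny_config(n_generations = 0L))
  expect_equal(nrow(z$summary), 1L)
  expect_equal(z$summary$generation, 0L)
  # broom-style accessors
  expect_identical(tidy(a), a$summary)
  expect_equal(glance(a)$final_n_groups, a$summary$n_groups[11])
  expect_s3_class(autoplot(a), "ggplot")
})
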