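sphere <- function(x) sum(x^2)

test_that("initialization sorts by cost and assigns the role partition", {
  p <- wcba_params(n_vars = 1, lower = -1, upper = 1, pop_size = 4, n_sr = 2,
                   seed = 3)
  st <- wcba_initialize(p, sphere)
  expect_equal(st$roles, c("sea", "river", "stream", "stream"))
  expect_true(all(diff(st$costs) >= 0))
  expect_true(all(st$positions >= -1 & st$positions <= 1))
  st2 <- wcba_initialize(p, sphere)
  expect_identical(st$positions, st2$positions)   # same seed, same state
})

test_that("flow intensity conserves the stream count and favors the sea", {
  p <- wcba_params(n_vars = 2, lower = 0, upper = 1, pop_size = 33, n_sr = 3,
                   seed = 1)
  st <- wcba_initialize(p, sphere)
  a <- wcba_flow_intensity(st, p)
  counts <- attr(a, "counts")
  expect_equal(sum(counts), 30)
  expect_length(a, 30)
  expect_equal(which.max(counts), 1L)   # sea attracts the most streams
  # degenerate equal costs: equal split with remainder to the sea
  st$costs <- rep(1, 33)
  a2 <- wcba_flow_intensity(st, p)
  expect_equal(sum(attr(a2, "counts")), 30)
  expect_equal(attr(a2, "counts"), c(10L, 10L, 10L))
  # odd stream count still conserved
  p31 <- wcba_params(n_vars = 2, lower = 0, upper = 1, pop_size = 33, n_sr = 2,
                     seed = 1)
  st31 <- wcba_initialize(p31, sphere)
  st31$costs <- rep(2, 33)
  expect_equal(sum(attr(wcba_flow_intensity(st31, p31), "counts")), 31)
})

test_that("the stream update follows its formula", {
  p <- wcba_params(n_vars = 3, lower = -10, upper = 10)
  pos <- c(1, 2, 3); guide <- c(4, 0, -2)
  expect_equal(wcba_update_stream(pos, guide, p, rand = 0), pos)
  expect_equal(wcba_update_stream(pos, guide, p, rand = 0.5), guide)  # rand*z = 1
  r <- 0.3
  expect_equal(wcba_update_stream(pos, guide, p, rand = r),
               pos + r * 2 * (guide - pos), tolerance = 1e-12)
})

test_that("bat frequency interpolates its bounds", {
  p <- wcba_params(n_vars = 1, lower = 0, upper = 1)
  expect_equal(bat_frequency(0, p), 0)
  expect_equal(bat_frequency(1, p), 100)
  expect_equal(bat_frequency(0.25, p), 25)
  expect_error(bat_frequency(1.5, p), "\\[0, 1\\]")
})

test_that("the river update follows the bat-blended formula", {
  p <- wcba_params(n_vars = 2, lower = -100, upper = 100)
  pos <- c(1, -2); prev <- c(0.5, -1); vel <- c(0.1, 0.2); sea <- c(0, 0)
  expect_equal(wcba_update_river(pos, prev, vel, sea, p, rand = 0, k = 0.5), pos)
  # rand*z = 1, l_b = 2 (k = 0.02): coefficient 1 - (2-2)/2 = 1
  out <- wcba_update_river(pos, prev, vel, sea, p, rand = 0.5, k = 0.02)
  expect_equal(out, pos + prev + vel, tolerance = 1e-12)
  # generic draw against a one-line evaluation
  r <- 0.37; k <- 0.61; l_b <- 100 * k
  expect_equal(wcba_update_river(pos, prev, vel, sea, p, rand = r, k = k),
               pos * (1 - r * 2 * (2 - l_b) / l_b) + r * 2 * (prev + vel),
               tolerance = 1e-12)
})

test_that("promotion puts the population minimum on the sea", {
  p <- wcba_params(n_vars = 2, lower = -5, upper = 5, pop_size = 12, n_sr = 3,
                   seed = 9)
  st <- wcba_initialize(p, sphere)
  # scramble costs so a stream is the global best
  set.seed(1)
  st$costs <- runif(12, 1, 2)
  st$costs[7] <- 0.01
  st <- wcba_promote(st, p)
  expect_equal(st$costs[1], min(st$costs))
  # already sorted population is a fixed point
  st2 <- wcba_initialize(p, sphere)
  st3 <- wcba_promote(st2, p)
  expect_identical(st2$positions, st3$positions)
})

test_that("evaporation is the Euclidean-distance test", {
  expect_true(wcba_evaporation(c(0, 0), c(0, 0), 0.1))
  expect_false(wcba_evaporation(c(5, 0), c(0, 0), 1))
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3); bm <- runif(1, 0, 3)
    expect_identical(wcba_evaporation(a, b, bm), sqrt(sum((a - b)^2)) < bm)
  }
})

test_that("raining re-scatters around the sea with spread delta", {
  p <- wcba_params(n_vars = 1, lower = -10, upper = 10, delta = 0.1, seed = 2)
  set.seed(2)
  draws <- replicate(1e4, wcba_raining(TRUE, p, sea_position = 1.5))
  expect_lt(abs(mean(draws) - 1.5), 3 * 0.1 / 100)
  expect_equal(sd(draws), 0.1, tolerance = 0.05)
  # delta -> 0 collapses onto the sea
  p0 <- wcba_params(n_vars = 3, lower = -1, upper = 1, delta = 1e-12)
  expect_equal(wcba_raining(TRUE, p0, sea_position = c(0.3, -0.2, 0)),
               c(0.3, -0.2, 0), tolerance = 1e-9)
  # uniform raining stays in the box
  set.seed(3)
  u <- replicate(100, wcba_raining(FALSE, p))
  expect_true(all(u >= -10 & u <= 10))
})

test_that("the evaporation threshold decays geometrically", {
  expect_equal(wcba_decay_bmax(1, 100), 0.99)
  expect_equal(wcba_decay_bmax(1, 1), 0)
  b <- 0.5
  for (i in 1:50) b <- wcba_decay_bmax(b, 50)
  expect_equal(b, 0.5 * (1 - 1 / 50)^50, tolerance = 1e-12)
  expect_error(wcba_decay_bmax(1, 0), "max_iter")
})

test_that("optimization contracts on the sphere and the trace is monotone", {
  p <- wcba_params(n_vars = 3, lower = -5, upper = 5, max_iter = 100, seed = 11)
  r <- wcba_optimize(sphere, p)
  expect_lt(r$best_cost, 1e-2)
  expect_true(all(diff(r$best_cost_trace) <= 0))
  expect_length(r$best_cost_trace, 100)
  # constant fitness: best equals the constant from the first iteration
  rc <- wcba_optimize(function(x) 7, wcba_params(n_vars = 2, lower = 0,
                                                 upper = 1, max_iter = 5,
                                                 seed = 1))
  expect_equal(rc$best_cost_trace, rep(7, 5))
  # reproducibility
  r2 <- wcba_optimize(sphere, p)
  expect_identical(r$best_cost_trace, r2$best_cost_trace)
})

test_that("positions remain within bounds through a whole run", {
  p <- wcba_params(n_vars = 2, lower = c(-1, 0), upper = c(1, 2),
                   max_iter = 40, seed = 5)
  r <- wcba_optimize(benchmark_objective("rastrigin"), p)
  pos <- r$state$positions
  expect_true(all(sweep(pos, 2, p$lower, `>=`)))
  expect_true(all(sweep(pos, 2, p$upper, `<=`)))
  expect_equal(nrow(pos), p$pop_size)
})
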