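#' Parameters of the water cycle bat optimizer
#'
#' The optimizer maintains a population of "raindrops" with the roles sea
#' (incumbent best), rivers, and streams. Streams flow toward their assigned
#' river or the sea; rivers move by a bat-algorithm-blended update whose step
#' is modulated by a random echolocation frequency; near-converged rivers and
#' sea-bound streams trigger evaporation and raining (re-scattering). The
#' evaporation radius `b_max0` decays geometrically over the run.
#'
#' @param n_vars Number of decision variables.
#' @param lower,upper Bound vectors (recycled to `n_vars`), `lower < upper`.
#' @param pop_size Population size (>= 4).
#' @param n_sr Number of rivers plus the sea (>= 1, < `pop_size`).
#' @param max_iter Iteration budget.
#' @param b_max0 Initial evaporation distance threshold; default
#'   `1e-2 * ||upper - lower||`.
#' @param delta Raining spread around the sea (standard-normal scale).
#' @param l_min,l_max Bat frequency bounds; the frequency is
#'   `l_min + (l_max - l_min) * k` with `k ~ U[0, 1]`.
#' @param z Step coefficient multiplying the uniform draw (canonical value 2).
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `"wcba_params"`.
#' @export
wcba_params <- function(n_vars, lower, upper, pop_size = 30L, n_sr = 4L,
                        max_iter = 300L, b_max0 = NULL, delta = 0.1,
                        l_min = 0, l_max = 100, z = 2, seed = 1L) {
  n_vars <- as.integer(n_vars)
  lower <- rep_len(as.numeric(lower), n_vars)
  upper <- rep_len(as.numeric(upper), n_vars)
  stopifnot(n_vars >= 1, all(lower < upper), pop_size >= 4,
            n_sr >= 1, n_sr < pop_size, max_iter >= 1, delta > 0, l_max >= l_min)
  if (is.null(b_max0)) b_max0 <- 1e-2 * sqrt(sum((upper - lower)^2))
  stopifnot(b_max0 > 0)
  structure(list(n_vars = n_vars, lower = lower, upper = upper,
                 pop_size = as.integer(pop_size), n_sr = as.integer(n_sr),
                 max_iter = as.integer(max_iter), b_max0 = b_max0,
                 delta = delta, l_min = l_min, l_max = l_max, z = z,
                 seed = as.integer(seed)), class = "wcba_params")
}

clip_bounds <- function(x, params) pmin(pmax(x, params$lower), params$upper)

#' Bat echolocation frequency
#'
#' `l_min + (l_max - l_min) * k` for `k` in \[0, 1\].
#'
#' @param k Scalar in \[0, 1\].
#' @param params A [wcba_params()].
#' @return The frequency.
#' @export
bat_frequency <- function(k, params) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > 1)
    stop("k must be a scalar in [0, 1]", call. = FALSE)
  params$l_min + (params$l_max - params$l_min) * k
}

#' Initialize the optimizer state
#'
#' Positions are uniform in the box; all costs are evaluated; the population
#' is sorted ascending by cost so the best member becomes the sea, the next
#' `n_sr - 1` become rivers, the rest streams. Velocities start at zero.
#'
#' @param params A [wcba_params()].
#' @param fitness Function mapping a position vector to a finite scalar.
#' @param max_redraws Retries for members whose initial cost is non-finite.
#' @return A list of class `"wcba_state"` with matrices `positions`,
#'   `velocities`, `prev_positions` (rows = members, sorted by cost), vector
#'   `costs`, `roles`, `b_max`, and the stream assignment.
#' @export
wcba_initialize <- function(params, fitness, max_redraws = 100L) {
  set.seed(params$seed)
  np <- params$pop_size; nv <- params$n_vars
  pos <- matrix(stats::runif(np * nv), np, nv)
  pos <- sweep(sweep(pos, 2, params$upper - params$lower, `*`), 2, params$lower, `+`)
  costs <- apply(pos, 1L, fitness)
  for (i in which(!is.finite(costs))) {
    for (tr in seq_len(max_redraws)) {
      pos[i, ] <- params$lower + stats::runif(nv) * (params$upper - params$lower)
      costs[i] <- fitness(pos[i, ])
      if (is.finite(costs[i])) break
    }
    if (!is.finite(costs[i])) stop("fitness non-finite after redraws", call. = FALSE)
  }
  ord <- order(costs)
  pos <- pos[ord, , drop = FALSE]; costs <- costs[ord]
  roles <- c("sea", rep("river", params$n_sr - 1L),
             rep("stream", np - params$n_sr))
  st <- list(positions = pos, costs = costs, roles = roles,
             velocities = matrix(0, np, nv), prev_positions = pos,
             b_max = params$b_max0, iteration = 0L,
             best_cost_trace = numeric(0))
  st$assignment <- wcba_flow_intensity(st, params)
  class(st) <- "wcba_state"
  st
}

#' Stream allocation by flow intensity
#'
#' Each of the `n_sr` sea/river entities attracts a number of streams
#' proportional to its shifted cost `Cs_i = B_i - B_(n_sr + 1)` (the cost gap
#' to the best stream), so better entities attract more streams; any rounding
#' remainder is absorbed by the sea. Returns, for every stream index, the
#' index (1 = sea) of its guide.
#'
#' @param state A `"wcba_state"` (costs sorted ascending).
#' @param params A [wcba_params()].
#' @return Integer vector of guide indices, one per stream, plus a
#'   `"counts"` attribute with the per-entity stream counts.
#' @export
wcba_flow_intensity <- function(state, params) {
  nsr <- params$n_sr
  n_streams <- params$pop_size - nsr
  cs <- state$costs[seq_len(nsr)] - state$costs[nsr + 1L]
  tot <- sum(cs)
  if (!is.finite(tot) || tot == 0) {
    counts <- rep(n_streams %/% nsr, nsr)
    counts[1] <- counts[1] + n_streams - sum(counts)
  } else {
    share <- cs / tot                      # cs <= 0, tot < 0 => shares >= 0
    counts <- round(share * n_streams)
    counts <- pmax(counts, 0)
    counts[1] <- n_streams - sum(counts[-1])
    while (counts[1] < 0) {                # over-allocation: trim worst rivers
      w <- which.max(counts[-1]) + 1L
      take <- min(counts[w], -counts[1])
      counts[w] <- counts[w] - take
      counts[1] <- counts[1] + take
    }
  }
  assign <- rep.int(seq_len(nsr), counts)
  attr(assign, "counts") <- as.integer(counts)
  assign
}

#' One stream move toward its guide
#'
#' `position + rand * z * (guide - position)`, `rand ~ U[0, 1]`, clipped to
#' the bounds.
#'
#' @param position,guide_position Position vectors.
#' @param params A [wcba_params()].
#' @param rand Optional fixed uniform draw (drawn internally when `NULL`).
#' @return The new position.
#' @export
wcba_update_stream <- function(position, guide_position, params, rand = NULL) {
  if (is.null(rand)) rand <- stats::runif(1)
  clip_bounds(position + rand * params$z * (guide_position - position), params)
}

#' One river move (bat-blended update)
#'
#' With `rand ~ U[0, 1]` and frequency `l_b` from [bat_frequency()]:
#' `new = position * (1 - rand * z * (2 - l_b) / l_b) +
#'  rand * z * (prev_position + velocity)`, clipped to bounds. When `l_b` is
#' numerically zero the plain water-cycle move toward the sea,
#' `position + rand * z * (sea - position)`, is used instead.
#'
#' @param position Current river position.
#' @param prev_position Its position at the previous iteration.
#' @param velocity Its velocity (displacement of the previous iteration).
#' @param sea_position Sea position, used by the degenerate-frequency
#'   fallback.
#' @param params A [wcba_params()].
#' @param rand,k Optional fixed draws for the uniform factor and the
#'   frequency coordinate (drawn internally when `NULL`).
#' @return The new position.
#' @export
wcba_update_river <- function(position, prev_position, velocity, sea_position,
                              params, rand = NULL, k = NULL) {
  if (is.null(rand)) rand <- stats::runif(1)
  if (is.null(k)) k <- stats::runif(1)
  l_b <- bat_frequency(k, params)
  if (abs(l_b) < 1e-8)
    return(clip_bounds(position + rand * params$z * (sea_position - position),
                       params))
  newp <- position * (1 - rand * params$z * (2 - l_b) / l_b) +
    rand * params$z * (prev_position + velocity)
  clip_bounds(newp, params)
}

#' Promote cheaper members
#'
#' Any stream cheaper than its guide swaps roles (positions stay with the
#' member; indices swap), then any river cheaper than the sea swaps with the
#' sea, so afterwards the sea holds the population minimum.
#'
#' @param state A `"wcba_state"`.
#' @param params A [wcba_params()].
#' @return The updated state.
#' @export
wcba_promote <- function(state, params) {
  nsr <- params$n_sr
  swap <- function(st, i, j) {
    for (f in c("positions", "velocities", "prev_positions")) {
      tmp <- st[[f]][i, ]; st[[f]][i, ] <- st[[f]][j, ]; st[[f]][j, ] <- tmp
    }
    tmp <- st$costs[i]; st$costs[i] <- st$costs[j]; st$costs[j] <- tmp
    st
  }
  for (s in seq_along(state$assignment)) {
    gi <- state$assignment[s]
    si <- nsr + s
    if (state$costs[si] < state$costs[gi]) state <- swap(state, si, gi)
  }
  if (nsr > 1) {
    br <- which.min(state$costs[2:nsr]) + 1L
    if (state$costs[br] < state$costs[1]) state <- swap(state, br, 1L)
  }
  state
}

#' Evaporation condition
#'
#' `TRUE` when the Euclidean distance between the sea and the river is below
#' the current threshold `b_max`.
#'
#' @param river_position,sea_position Position vectors.
#' @param b_max Current evaporation threshold.
#' @return Logical.
#' @export
wcba_evaporation <- function(river_position, sea_position, b_max) {
  sqrt(sum((sea_position - river_position)^2)) < b_max
}

#' Raining (re-scattering) positions
#'
#' Streams attached to a river are re-drawn uniformly in the box; streams
#' attached directly to the sea are re-drawn as
#' `sea + delta * rnorm(n_vars)`, clipped to bounds.
#'
#' @param to_sea `TRUE` for a sea-bound stream, `FALSE` for a river-bound
#'   one.
#' @param params A [wcba_params()].
#' @param sea_position Sea position (used when `to_sea`).
#' @return A new position vector.
#' @export
wcba_raining <- function(to_sea, params, sea_position = NULL) {
  if (to_sea) {
    clip_bounds(sea_position + params$delta * stats::rnorm(params$n_vars), params)
  } else {
    params$lower + stats::runif(params$n_vars) * (params$upper - params$lower)
  }
}

#' Decay the evaporation threshold
#'
#' `b_max - b_max / max_iter`; applied once per iteration, so after
#' `max_iter` iterations the threshold is `b_max0 * (1 - 1/max_iter)^max_iter`.
#'
#' @param b_max Current threshold.
#' @param max_iter Iteration budget (> 0).
#' @return The decayed threshold.
#' @export
wcba_decay_bmax <- function(b_max, max_iter) {
  if (!is.numeric(max_iter) || max_iter < 1) stop("max_iter must be >= 1",
                                                  call. = FALSE)
  b_max - b_max / max_iter
}

#' Run the water cycle bat optimizer
#'
#' Minimizes `fitness` over the box. Each iteration moves every stream toward
#' its guide, moves every river by the bat-blended update, promotes cheaper
#' members, applies evaporation/raining, and decays the evaporation
#' threshold. The returned trace is the best-so-far cost per iteration and is
#' non-increasing.
#'
#' @param fitness Function from a position vector to a finite scalar.
#' @param params A [wcba_params()].
#' @return A list with `best_position`, `best_cost`, `best_cost_trace`, and
#'   the final `"wcba_state"`.
#' @export
wcba_optimize <- function(fitness, params) {
  st <- wcba_initialize(params, fitness)
  nsr <- params$n_sr
  best_cost <- st$costs[1]; best_pos <- st$positions[1, ]
  trace <- numeric(params$max_iter)
  for (b in seq_len(params$max_iter)) {
    # streams flow to their guides
    for (s in seq_along(st$assignment)) {
      i <- nsr + s
      gi <- st$assignment[s]
      newp <- wcba_update_stream(st$positions[i, ], st$positions[gi, ], params)
      st$velocities[i, ] <- newp - st$positions[i, ]
      st$prev_positions[i, ] <- st$positions[i, ]
      st$positions[i, ] <- newp
      st$costs[i] <- fitness(newp)
    }
    # rivers flow to the sea (bat-blended)
    if (nsr > 1) for (i in 2:nsr) {
      newp <- wcba_update_river(st$positions[i, ], st$prev_positions[i, ],
                                st$velocities[i, ], st$positions[1, ], params)
      st$velocities[i, ] <- newp - st$positions[i, ]
      st$prev_positions[i, ] <- st$positions[i, ]
      st$positions[i, ] <- newp
      st$costs[i] <- fitness(newp)
    }
    st <- wcba_promote(st, params)
    # evaporation + raining
    for (s in seq_along(st$assignment)) {
      gi <- st$assignment[s]
      i <- nsr + s
      trigger <- if (gi == 1L) {
        wcba_evaporation(st$positions[i, ], st$positions[1, ], st$b_max)
      } else {
        wcba_evaporation(st$positions[gi, ], st$positions[1, ], st$b_max)
      }
      if (trigger) {
        newp <- wcba_raining(gi == 1L, params, st$positions[1, ])
        st$velocities[i, ] <- 0
        st$prev_positions[i, ] <- newp
        st$positions[i, ] <- newp
        st$costs[i] <- fitness(newp)
      }
    }
    st <- wcba_promote(st, params)
    st$b_max <- wcba_decay_bmax(st$b_max, params$max_iter)
    st$assignment <- wcba_flow_intensity(st, params)
    if (st$costs[1] < best_cost) {
      best_cost <- st$costs[1]; best_pos <- st$positions[1, ]
    }
    trace[b] <- best_cost
    st$iteration <- b
  }
  st$best_cost_trace <- trace
  list(best_position = best_pos, best_cost = best_cost,
       best_cost_trace = trace, state = st)
}

#' Named benchmark objectives
#'
#' `sphere` (optionally shifted), `rosenbrock`, `rastrigin`.
#'
#' @param name Objective name.
#' @param shift Optional shift vector subtracted from the position.
#' @return A function of a numeric vector.
#' @export
benchmark_objective <- function(name = c("sphere", "rosenbrock", "rastrigin"),
                                shift = 0) {
  name <- match.arg(name)
  switch(name,
    sphere = function(x) sum((x - shift)^2),
    rosenbrock = function(x) {
      x <- x - shift
      sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)
    },
    rastrigin = function(x) {
      x <- x - shift
      sum(x^2 - 10 * cos(2 * pi * x) + 10)
    })
}
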