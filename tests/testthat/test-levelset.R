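circle_phi <- function(h, cr, cc, radius) {
  rr <- matrix(seq_len(h), h, h)
  cl <- t(rr)
  sqrt((rr - cr)^2 + (cl - cc)^2) - radius
}

test_that("curvature vanishes on a straight interface", {
  h <- 32
  phi <- matrix(seq_len(h) - 16.5, h, h)      # signed distance to a line
  k <- ls_curvature(phi)
  expect_lt(max(abs(k[5:28, 5:28])), 1e-6)
})

test_that("curvature of a circle matches 1/r and is positive", {
  phi <- circle_phi(64, 32, 32, 20)
  k <- ls_curvature(phi)
  band <- abs(phi) < 2
  expect_equal(mean(k[band]), 1 / 20, tolerance = 0.1)
  # per-pixel agreement with the local analytic curvature 1/r
  r <- phi + 20
  expect_lt(max(abs(k[band] - 1 / r[band]) / (1 / r[band])), 0.1)
  expect_true(all(k[band] > 0))               # convex inside region
})

test_that("signed distance has unit gradient near the zero set and reinit preserves signs", {
  mask <- (circle_phi(64, 32, 32, 15) <= 0) * 1
  phi <- signed_distance(mask)
  expect_true(all(phi[mask == 1] < 0))
  expect_true(all(phi[mask == 0] > 0))
  gx <- (phi[3:64, ] - phi[1:62, ]) / 2
  gy <- (phi[, 3:64] - phi[, 1:62]) / 2
  gn <- sqrt(gx[, 2:63]^2 + gy[2:63, ]^2)
  band <- abs(phi[2:63, 2:63]) < 3 & abs(phi[2:63, 2:63]) > 0.6
  expect_lt(mean(abs(gn[band] - 1)), 0.1)
  lv <- reinitialize(level_set(phi * 7.3))     # arbitrary rescale
  expect_identical(sign(lv$phi[abs(phi) > 1]), sign(phi[abs(phi) > 1]))
})

test_that("uniform image with zero curvature weight is a Chan-Vese fixed point", {
  lv <- level_set(circle_phi(32, 16, 16, 8), curvature_weight = 0)
  out <- chan_vese_step(lv, matrix(0.4, 32, 32))
  expect_equal(unname(out$phi), unname(lv$phi), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Chan-Vese region means are the two true region means on a binary image", {
  phi <- circle_phi(32, 16, 16, 8)
  img <- (phi < 0) * 0.9 + (phi >= 0) * 0.1
  out <- chan_vese_step(level_set(phi), img)
  st <- attr(out$phi, "region_stats")
  expect_equal(unname(st["t_in"]), 0.9)
  expect_equal(unname(st["t_out"]), 0.1)
})

test_that("Chan-Vese warm-up recovers a two-intensity disk", {
  h <- 64
  phi0 <- circle_phi(h, 32, 32, 12)
  img <- 0.2 + 0.6 * (circle_phi(h, 32, 32, 18) <= 0)
  lv <- level_set(signed_distance((phi0 <= 0) * 1), dt = 1.0)
  for (s in 1:200) {
    lv <- chan_vese_step(lv, img)
    if (s %% 25 == 0) lv <- reinitialize(lv)
  }
  expect_gte(jaccard((lv$phi < 0) * 1, (img > 0.5) * 1), 0.95)
})

test_that("probability 1/2 with zero curvature weight is an evolution fixed point", {
  lv <- level_set(circle_phi(32, 16, 16, 8), curvature_weight = 0)
  prob <- structure(list(E = list(matrix(0.5, 32, 32), matrix(0.5, 32, 32)),
                         shape = c(32, 32)), class = "probability_map")
  prob <- multi_label_transform(prob)
  out <- evolve_step(lv, prob, 1L)
  expect_equal(out$phi, lv$phi, tolerance = 1e-12)
})

test_that("uniform probabilities drive monotone growth or shrinkage", {
  lv <- level_set(signed_distance((circle_phi(48, 24, 24, 8) <= 0) * 1),
                  dt = 0.5, curvature_weight = 0)
  grow <- structure(list(E = list(matrix(1, 48, 48), matrix(0, 48, 48)),
                         shape = c(48, 48)), class = "probability_map")
  grow <- multi_label_transform(grow)
  areas <- numeric(30)
  for (i in 1:30) { lv <- evolve_step(lv, grow, 1L); areas[i] <- sum(lv$phi < 0) }
  expect_true(all(diff(areas) >= 0))
  expect_gt(areas[30], areas[1])
  lv2 <- level_set(signed_distance((circle_phi(48, 24, 24, 8) <= 0) * 1),
                   dt = 0.5, curvature_weight = 0)
  shrink <- structure(list(E = list(matrix(0, 48, 48), matrix(1, 48, 48)),
                           shape = c(48, 48)), class = "probability_map")
  shrink <- multi_label_transform(shrink)
  areas2 <- numeric(30)
  for (i in 1:30) { lv2 <- evolve_step(lv2, shrink, 1L); areas2[i] <- sum(lv2$phi < 0) }
  expect_true(all(diff(areas2) <= 0))
})

test_that("the metaheuristic curve update follows the printed formula exactly", {
  set.seed(19)
  phi <- matrix(rnorm(64), 8, 8)
  prev <- matrix(rnorm(64), 8, 8)
  vel <- matrix(rnorm(64), 8, 8)
  speed <- matrix(rnorm(64), 8, 8)
  p <- wcba_params(n_vars = 1, lower = -1, upper = 1)
  lv <- level_set(phi, dt = 0.1)
  r <- 0.37; k <- 0.61; l_b <- 100 * k
  up <- wcba_curve_update(lv, prev, vel, speed, p, rand = r, k = k)
  D <- 1 - r * 2 * (2 - l_b)
  expected <- (D / (D - l_b)) * (0.1 * speed - r * 2 * l_b * (prev + vel) / D)
  expect_equal(up$level$phi, expected, tolerance = 1e-12)
  expect_equal(up$velocity_field, expected - phi, tolerance = 1e-12)
  expect_false(up$used_plain)
  # rand = 0: phi_new = (1/(1 - l_b)) * dt * speed per the printed form
  up0 <- wcba_curve_update(lv, prev, vel, speed, p, rand = 0, k = 0.4)
  expect_equal(up0$level$phi, (1 / (1 - 40)) * 0.1 * speed, tolerance = 1e-12)
  # near-singular denominator falls back to the plain Euler update
  # D = 1 - 2*rand*(2 - l_b) = l_b when rand = (1 - l_b)/(2*(2 - l_b))
  l_bs <- 0.5; rs <- (1 - l_bs) / (2 * (2 - l_bs))
  ups <- wcba_curve_update(lv, prev, vel, speed, p, rand = rs, k = l_bs / 100)
  expect_true(ups$used_plain)
  expect_equal(ups$level$phi, phi + 0.1 * speed, tolerance = 1e-12)
  # plain mode identity at zero speed
  upz <- wcba_curve_update(lv, prev, vel, matrix(0, 8, 8), p,
                           rand = rs, k = l_bs / 100)
  expect_equal(upz$level$phi, phi)
})
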