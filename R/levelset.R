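# Level-set machinery. Convention throughout: the inside region is where
# phi < 0; the curve is the zero set of phi.

shift_m <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Create a level-set state
#'
#' @param phi Signed scalar field (negative inside).
#' @param dt Time step.
#' @param curvature_weight Weight of the curve-length (curvature)
#'   regularization.
#' @param epsilon Smoothing width (pixels) of the regularized Dirac factor
#'   used by [chan_vese_step()].
#' @return A list of class `"level_set"`.
#' @export
level_set <- function(phi, dt = 0.1, curvature_weight = 1.0, epsilon = 1.5) {
  assert_image(phi, "phi")
  stopifnot(dt > 0, curvature_weight >= 0, epsilon > 0)
  structure(list(phi = phi, dt = dt, curvature_weight = curvature_weight,
                 epsilon = epsilon), class = "level_set")
}

#' Signed distance to a mask boundary
#'
#' Exact Euclidean distance transform of the mask and its complement,
#' combined so inside pixels are negative; boundary-adjacent pixels sit at
#' -0.5/+0.5 so the zero crossing lies between them.
#'
#' @param mask Binary matrix (1 = inside).
#' @return A signed distance matrix.
#' @export
signed_distance <- function(mask) {
  assert_binary(mask)
  if (all(mask == 1)) return(matrix(-1, nrow(mask), ncol(mask)))
  if (all(mask == 0)) return(matrix(1, nrow(mask), ncol(mask)))
  d_in <- as.matrix(EBImage::distmap(mask))        # >0 inside
  d_out <- as.matrix(EBImage::distmap(1 - mask))   # >0 outside
  (d_out - 0.5) * (mask == 0) - (d_in - 0.5) * (mask == 1)
}

#' Reinitialize a level set to a signed distance function
#'
#' Preserves the sign of `phi` at every pixel (hence the zero set up to pixel
#' resolution) while restoring the unit-gradient property the evolution
#' schemes assume.
#'
#' @param level A [level_set()].
#' @return The level set with `phi` replaced by the signed distance to its
#'   own zero set.
#' @export
reinitialize <- function(level) {
  level$phi <- signed_distance((level$phi < 0) * 1)
  level
}

#' Mean curvature of the level-set curve
#'
#' Central-difference `div(grad phi / |grad phi|)` with gradient norms
#' regularized by 1e-8 and replicate borders. Under the inside-negative
#' convention, a convex inside region has positive curvature on its boundary,
#' so adding `weight * kappa` to the time derivative shortens the curve.
#'
#' @param level A [level_set()] (or a bare matrix).
#' @return Matrix of curvature values.
#' @export
ls_curvature <- function(level) {
  phi <- if (inherits(level, "level_set")) level$phi else level
  px <- (shift_m(phi, 1L, 0L) - shift_m(phi, -1L, 0L)) / 2
  py <- (shift_m(phi, 0L, 1L) - shift_m(phi, 0L, -1L)) / 2
  pxx <- shift_m(phi, 1L, 0L) - 2 * phi + shift_m(phi, -1L, 0L)
  pyy <- shift_m(phi, 0L, 1L) - 2 * phi + shift_m(phi, 0L, -1L)
  pxy <- (shift_m(phi, 1L, 1L) - shift_m(phi, 1L, -1L) -
          shift_m(phi, -1L, 1L) + shift_m(phi, -1L, -1L)) / 4
  g2 <- px^2 + py^2
  k <- (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) / (g2^1.5 + 1e-8)
  # curvature beyond the grid resolution (|kappa| > 1/h, h = 1 px) is a
  # discretization artifact of flat-gradient plateaus; clip it
  pmin(pmax(k, -1), 1)
}

# smoothed Dirac (eps/pi) / (eps^2 + phi^2)
dirac_eps <- function(phi, eps) (eps / pi) / (eps^2 + phi^2)

#' One region-based (Chan-Vese-type) evolution step
#'
#' Computes the inside/outside mean intensities from the current sign of
#' `phi`, then takes one explicit Euler step of
#' `dphi/dt = delta_eps(phi) * (t_out - t_in) * (2 J - t_out - t_in)
#'  + curvature_weight * kappa`.
#' Pixels whose intensity is nearer the inside mean are pulled into the
#' inside region. An empty region's mean falls back to the global mean.
#'
#' @param level A [level_set()].
#' @param image Numeric matrix `J`.
#' @return The evolved level set, with the region means attached as the
#'   `"region_stats"` attribute of `phi`.
#' @export
chan_vese_step <- function(level, image) {
  assert_image(image)
  phi <- level$phi
  inside <- phi < 0
  t_in <- if (any(inside)) mean(image[inside]) else mean(image)
  t_out <- if (any(!inside)) mean(image[!inside]) else mean(image)
  force <- dirac_eps(phi, level$epsilon) *
    ((t_out - t_in) * (2 * image - t_out - t_in)) +
    level$curvature_weight * ls_curvature(phi)
  level$phi <- phi + level$dt * force
  attr(level$phi, "region_stats") <- c(t_in = t_in, t_out = t_out)
  level
}

# Upwind |grad phi| consistent with the sign of the speed F in F |grad phi|
upwind_gradnorm <- function(phi, speed) {
  dxm <- phi - shift_m(phi, -1L, 0L)
  dxp <- shift_m(phi, 1L, 0L) - phi
  dym <- phi - shift_m(phi, 0L, -1L)
  dyp <- shift_m(phi, 0L, 1L) - phi
  gp <- sqrt(pmax(dxm, 0)^2 + pmin(dxp, 0)^2 + pmax(dym, 0)^2 + pmin(dyp, 0)^2)
  gm <- sqrt(pmin(dxm, 0)^2 + pmax(dxp, 0)^2 + pmin(dym, 0)^2 + pmax(dyp, 0)^2)
  ifelse(speed > 0, gp, gm)
}

#' Speed field of the dictionary-driven evolution
#'
#' `dphi/dt = (1/2 - E_tilde + curvature_weight * kappa) * |grad phi|` with
#' upwind differences for the gradient norm. Where the transformed
#' probability is exactly 1/2 and the curvature weight is zero the field is
#' stationary.
#'
#' @param level A [level_set()].
#' @param e_tilde Transformed probability layer for this label.
#' @param extra Optional additional force field added inside the upwind
#'   product (e.g. a region-intensity term).
#' @return The per-pixel time derivative of `phi`.
#' @export
evolve_speed <- function(level, e_tilde, extra = 0) {
  f <- 0.5 - e_tilde + level$curvature_weight * ls_curvature(level$phi) + extra
  f * upwind_gradnorm(level$phi, f)
}

#' One plain dictionary-driven evolution step
#'
#' Explicit Euler: `phi <- phi + dt * evolve_speed(...)`.
#'
#' @param level A [level_set()].
#' @param prob A [multi_label_transform()]-ed probability map.
#' @param label_index Which label layer drives this level set.
#' @return The evolved level set.
#' @export
evolve_step <- function(level, prob, label_index = 1L) {
  et <- if (!is.null(prob$E_tilde)) prob$E_tilde[[label_index]]
        else prob$E[[label_index]]
  level$phi <- level$phi + level$dt * evolve_speed(level, et)
  level
}

#' Metaheuristic curve update
#'
#' The bat-blended water-cycle update applied to the level-set field, with
#' one scalar draw of the uniform factor and the bat frequency shared by all
#' pixels. With `D = 1 - rand * z * (2 - l_b)`:
#' `phi_new = (D / (D - l_b)) * (dt * speed - rand * z * l_b *
#'  (phi_prev + Q) / D)`.
#' When either denominator is within 1e-6 of zero the plain Euler update
#' `phi + dt * speed` is used for the whole step.
#'
#' @param level A [level_set()].
#' @param prev_phi The field of the previous iterate.
#' @param velocity_field Field velocity `Q` (previous displacement).
#' @param speed The right-hand side from [evolve_speed()].
#' @param params A [wcba_params()] (only `z` and the frequency bounds are
#'   used).
#' @param rand,k Optional fixed draws (drawn from the current RNG stream when
#'   `NULL`).
#' @return A list: the updated `level`, the new `velocity_field`
#'   (`phi_new - phi_old`), and `used_plain` (logical).
#' @export
wcba_curve_update <- function(level, prev_phi, velocity_field, speed,
                              params, rand = NULL, k = NULL) {
  if (is.null(rand)) rand <- stats::runif(1)
  if (is.null(k)) k <- stats::runif(1)
  l_b <- bat_frequency(k, params)
  D <- 1 - rand * params$z * (2 - l_b)
  old <- level$phi
  if (abs(D - l_b) < 1e-6 || abs(D) < 1e-6) {
    new_phi <- old + level$dt * speed
    used_plain <- TRUE
  } else {
    new_phi <- (D / (D - l_b)) *
      (level$dt * speed - rand * params$z * l_b * (prev_phi + velocity_field) / D)
    used_plain <- FALSE
  }
  level$phi <- new_phi
  list(level = level, velocity_field = new_phi - old, used_plain = used_plain,
       draw = c(rand = rand, l_b = l_b))
}
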