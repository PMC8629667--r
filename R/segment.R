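#' Configuration for dictionary-based deformable segmentation
#'
#' @param patch_size Patch side `T` (odd).
#' @param n_atoms Dictionary size `d`.
#' @param dt Level-set time step.
#' @param curvature_weight Curve-length regularization weight.
#' @param epsilon Dirac smoothing width of the warm-up stage.
#' @param tol Convergence threshold on the fraction of pixels changing label
#'   (met for 5 consecutive iterations).
#' @param max_iter Iteration cap of the dictionary-driven loop.
#' @param min_iter Iterations to run before convergence counting starts (the
#'   explicit scheme moves the curve less than a pixel per step, so early
#'   label-change fractions are uninformatively small).
#' @param cv_steps Number of region-based (Chan-Vese) warm-up steps.
#' @param cv_dt Time step of the warm-up stage.
#' @param reinit_every Reinitialize `phi` to a signed distance function every
#'   this many iterations.
#' @param region_weight Weight of the region-based (mean-intensity) force
#'   blended into the two-label evolution; the region means are recomputed
#'   from the current labels every iteration, so the intensity stage and the
#'   dictionary stage act together. Zero where the two regions have equal
#'   means, so purely textural boundaries are unaffected.
#' @param mode `"plain"` (Euler curve update) or `"wcba"` (metaheuristic
#'   update with greedy keep-if-better selection).
#' @param seed Integer seed (dictionary seeding and the `"wcba"` draws).
#' @return A list of class `"dictseg_config"`.
#' @export
dictseg_config <- function(patch_size = 9L, n_atoms = 50L, dt = 0.5,
                           curvature_weight = 1.0, epsilon = 1.5, tol = 1e-4,
                           max_iter = 500L, min_iter = 30L, cv_steps = 0L, cv_dt = 1.0,
                           reinit_every = 50L, region_weight = 1.0,
                           mode = c("plain", "wcba"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(patch_size %% 2 == 1, n_atoms >= 1, dt > 0, tol >= 0,
            max_iter >= 1, reinit_every >= 1)
  structure(list(patch_size = as.integer(patch_size),
                 n_atoms = as.integer(n_atoms), dt = dt,
                 curvature_weight = curvature_weight, epsilon = epsilon,
                 tol = tol, max_iter = as.integer(max_iter),
                 min_iter = as.integer(min_iter),
                 cv_steps = as.integer(cv_steps), cv_dt = cv_dt,
                 reinit_every = as.integer(reinit_every),
                 region_weight = region_weight, mode = mode,
                 seed = as.integer(seed)), class = "dictseg_config")
}

# label layers from the per-label level sets: label = argmax of -phi
layers_from_phis <- function(phis) {
  X <- length(phis)
  if (X == 2L) {
    inside <- (phis[[1]] < 0) * 1
    return(list(inside, 1 - inside))
  }
  arr <- simplify2array(phis)
  lab <- apply(-arr, c(1, 2), which.max)
  lapply(seq_len(X), function(x) (lab == x) * 1)
}

# disagreement energy between hard labels and transformed probabilities;
# the quantity the keep-if-better rule of the "wcba" mode minimizes
label_prob_energy <- function(layers, prob) {
  et <- prob$E_tilde %||% prob$E
  sum(vapply(seq_along(layers), function(x) sum((layers[[x]] - et[[x]])^2), 0))
}

#' Dictionary-based deformable segmentation
#'
#' Segments an image into `X` labels by evolving one level set per label
#' under texture probabilities from a k-means patch dictionary. The patch
#' dictionary and the pixel/dictionary biadjacency matrix are built once;
#' each iteration pushes the current hard labels to the dictionary
#' (frequency), area-normalizes them, pulls them back as per-pixel
#' probabilities (averaging), applies the multi-label transform, and moves
#' each level set one step. In `"wcba"` mode the metaheuristic field update
#' is proposed each step and kept only when it does not worsen the
#' label/probability disagreement; otherwise the plain Euler step is taken.
#'
#' The loop stops when the fraction of pixels changing label stays below
#' `tol` for 5 consecutive iterations, else at `max_iter` (with a
#' `converged = FALSE` flag). The final labeling is returned; the
#' label/probability disagreement per iteration is available in
#' `energy_trace`.
#'
#' @param image Numeric matrix (preprocessed slice).
#' @param init Either a binary matrix (two labels: inside/outside) or an
#'   integer label matrix with values `1..X`.
#' @param config A [dictseg_config()].
#' @param roi_mask Optional binary matrix; pixels outside it are clamped to
#'   the background (last) label throughout.
#' @return A list of class `"dictseg_result"`: `masks` (list of X binary
#'   matrices summing to 1 per pixel), `trace` (per-iteration label-change
#'   fraction), `energy_trace`, `converged`, `dictionary`, `n_labels`.
#' @export
dict_segment <- function(image, init, config = dictseg_config(),
                         roi_mask = NULL) {
  assert_image(image)
  set.seed(config$seed)
  if (all(init %in% c(0, 1))) {
    X <- 2L
    init_lab <- 2L - init              # 1 = inside, 2 = outside/background
  } else {
    X <- as.integer(max(init))
    init_lab <- init
  }
  if (length(unique(as.vector(init_lab))) < 2L)
    stop("degenerate initialization: fewer than two labels present", call. = FALSE)
  if (!is.null(roi_mask)) assert_binary(roi_mask, "roi_mask")

  clamp_roi <- function(phis) {
    if (is.null(roi_mask)) return(phis)
    out <- roi_mask == 0
    for (x in seq_len(X - 1L)) phis[[x]][out] <- pmax(phis[[x]][out], 1)
    phis[[X]][out] <- pmin(phis[[X]][out], -1)
    phis
  }

  # per-label level sets from the initial labels
  phis <- lapply(seq_len(X), function(x) signed_distance((init_lab == x) * 1))
  phis <- clamp_roi(phis)
  mk_level <- function(phi) level_set(phi, dt = config$dt,
                                      curvature_weight = config$curvature_weight,
                                      epsilon = config$epsilon)

  # optional region-based warm-up on the foreground level set
  if (config$cv_steps > 0L && X == 2L) {
    lv <- level_set(phis[[1]], dt = config$cv_dt,
                    curvature_weight = config$curvature_weight,
                    epsilon = config$epsilon)
    for (s in seq_len(config$cv_steps)) {
      lv <- chan_vese_step(lv, image)
      if (s %% 25L == 0L) lv <- reinitialize(lv)
    }
    phis[[1]] <- signed_distance((lv$phi < 0) * 1)
    phis[[2]] <- -phis[[1]]
    phis <- clamp_roi(phis)
  }

  # dictionary and biadjacency, built once; with an ROI the dictionary is
  # learned from patches fully inside it, so out-of-region texture cannot
  # pollute the atom statistics
  pe <- extract_patches(image, config$patch_size)
  if (!is.null(roi_mask)) {
    T_ <- config$patch_size
    h <- nrow(image); w <- ncol(image)
    II <- matrix(0, h + 1, w + 1)    # integral image of the outside indicator
    II[-1, -1] <- t(apply(apply(roi_mask == 0, 2, cumsum), 1, cumsum))
    r0 <- pe$origins[, 1]; c0 <- pe$origins[, 2]
    n_out <- II[cbind(r0 + T_, c0 + T_)] - II[cbind(r0, c0 + T_)] -
      II[cbind(r0 + T_, c0)] + II[cbind(r0, c0)]
    full_in <- n_out == 0
    if (sum(full_in) >= 4L * config$n_atoms) {
      pe$patches <- pe$patches[full_in, , drop = FALSE]
      pe$origins <- pe$origins[full_in, , drop = FALSE]
    }
  }
  dict <- build_dictionary(pe$patches, config$n_atoms,
                           seed = derive_seed(config$seed, "dict"))
  G <- build_biadjacency(dict, pe$origins, dim(image))
  coverage <- Matrix::rowSums(G)
  label_areas <- function(layers)
    vapply(layers, function(l) sum(l[coverage > 0]), 0)

  # region-based (mean intensity) force, recomputed from the current labels;
  # amplitude scales with the region contrast |t_in - t_out| relative to a
  # 0.1 intensity floor, so it pins intensity boundaries and fades out for
  # equal-mean (purely textural) regions
  region_force <- function(layers) {
    if (X != 2L || config$region_weight <= 0) return(0)
    sel <- if (is.null(roi_mask)) coverage > 0 else roi_mask == 1
    ins <- sel & layers[[1]] == 1
    out <- sel & layers[[1]] == 0
    t_in <- if (any(ins)) mean(image[ins]) else mean(image[sel])
    t_out <- if (any(out)) mean(image[out]) else mean(image[sel])
    config$region_weight *
      ((t_out - t_in) * (2 * image - t_out - t_in)) /
      (abs(t_in - t_out) + 0.1)
  }
  n_evolve <- if (X == 2L) 1L else X    # two labels share one level set

  wp <- wcba_params(n_vars = 1L, lower = -1, upper = 1)  # z, l_min, l_max only
  prev_phis <- phis
  vel <- lapply(phis, function(p) p * 0)
  layers <- layers_from_phis(phis)
  trace <- numeric(0); energy_trace <- numeric(0)
  calm <- 0L
  converged <- FALSE

  for (it in seq_len(config$max_iter)) {
    dl <- area_normalize(labels_to_dict(G, layers), label_areas(layers))
    prob <- multi_label_transform(dict_to_probabilities(G, dl, dim(image)))
    energy_trace <- c(energy_trace, label_prob_energy(layers, prob))

    new_phis <- phis
    new_vel <- vel
    if (config$mode == "plain") {
      for (x in seq_len(n_evolve)) {
        lv <- mk_level(phis[[x]])
        extra <- if (x == 1L) region_force(layers) else 0
        sp <- evolve_speed(lv, prob$E_tilde[[x]], extra)
        new_phis[[x]] <- phis[[x]] + config$dt * sp
        new_vel[[x]] <- new_phis[[x]] - phis[[x]]
      }
    } else {
      rand <- stats::runif(1); k <- stats::runif(1)
      plain_phis <- phis; prop_phis <- phis
      for (x in seq_len(n_evolve)) {
        lv <- mk_level(phis[[x]])
        extra <- if (x == 1L) region_force(layers) else 0
        sp <- evolve_speed(lv, prob$E_tilde[[x]], extra)
        plain_phis[[x]] <- phis[[x]] + config$dt * sp
        up <- wcba_curve_update(lv, prev_phis[[x]], vel[[x]], sp, wp,
                                rand = rand, k = k)
        prop_phis[[x]] <- up$level$phi
      }
      # Step-11 style feasibility check: accept the metaheuristic proposal
      # only when it lowers the disagreement energy AND stays a plausible
      # curve move (at most 5% of pixels relabelled in one step); the
      # rescaled field otherwise jumps the curve non-locally
      prop_layers <- layers_from_phis(clamp_roi(prop_phis))
      e_prop <- label_prob_energy(prop_layers, prob)
      e_plain <- label_prob_energy(layers_from_phis(clamp_roi(plain_phis)), prob)
      frac_prop <- sum(abs(prop_layers[[1]] - layers[[1]])) / length(layers[[1]])
      if (e_prop < e_plain && frac_prop <= 0.05) {
        # the accepted proposal rescales phi affinely; divide by the gradient
        # norm near the zero set so the slope returns to ~1 without moving
        # the (sub-pixel) zero crossing
        new_phis <- lapply(prop_phis, function(p) {
          gx <- (shift_m(p, 1L, 0L) - shift_m(p, -1L, 0L)) / 2
          gy <- (shift_m(p, 0L, 1L) - shift_m(p, 0L, -1L)) / 2
          gn <- sqrt(gx^2 + gy^2)
          band <- abs(p) <= stats::quantile(abs(p), 0.05)
          sc <- mean(gn[band])
          if (is.finite(sc) && sc > 1e-6) p / sc else p
        })
      } else new_phis <- plain_phis
      for (x in seq_len(X)) new_vel[[x]] <- new_phis[[x]] - phis[[x]]
    }
    if (X == 2L) { new_phis[[2]] <- -new_phis[[1]]; new_vel[[2]] <- -new_vel[[1]] }
    prev_phis <- phis
    phis <- clamp_roi(new_phis)
    vel <- new_vel
    if (it %% config$reinit_every == 0L)
      phis <- lapply(phis, function(p) signed_distance((p < 0) * 1))

    new_layers <- layers_from_phis(phis)
    changed <- sum(abs(new_layers[[1]] - layers[[1]])) /
      length(layers[[1]])
    if (X > 2L) {
      changed <- mean(vapply(seq_len(X), function(x)
        sum(abs(new_layers[[x]] - layers[[x]])), 0)) / length(layers[[1]])
    }
    trace <- c(trace, changed)
    layers <- new_layers
    if (it > config$min_iter && changed < config$tol) calm <- calm + 1L else calm <- 0L
    if (calm >= 5L) { converged <- TRUE; break }
  }

  if (!converged)
    warning("dict_segment did not converge; returning the final iterate")

  structure(list(masks = layers, trace = trace,
                 energy_trace = energy_trace, converged = converged,
                 dictionary = dict, n_labels = X), class = "dictseg_result")
}
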