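#' Parameters for Bayesian fuzzy clustering
#'
#' The lobe-extraction stage models pixel intensities as a fuzzy mixture of
#' `n_clusters` Gaussian prototypes with a symmetric Dirichlet prior on the
#' memberships. Alternating maximum-a-posteriori sweeps update memberships
#' and prototypes; the sweep with the best posterior score is returned.
#'
#' @param n_clusters Number of clusters (>= 1).
#' @param fuzzifier Membership exponent (> 1); 2 is the usual fuzzy-c-means
#'   softness.
#' @param dirichlet_concentration Symmetric Dirichlet concentration of the
#'   membership prior (> 0). With a symmetric prior this only shifts all
#'   cluster weights equally.
#' @param n_sweeps Number of alternating sweeps.
#' @param noise_sigma Gaussian likelihood scale, in intensity units.
#' @param seed Integer seed (used only for degenerate prototype resampling).
#' @return A list of class `"bfc_params"`.
#' @export
bfc_params <- function(n_clusters = 4L, fuzzifier = 2.0,
                       dirichlet_concentration = 1.0, n_sweeps = 50L,
                       noise_sigma = 0.05, seed = 1L) {
  stopifnot(n_clusters >= 1, fuzzifier > 1, dirichlet_concentration > 0,
            n_sweeps >= 1, noise_sigma >= 0)
  structure(list(n_clusters = as.integer(n_clusters), fuzzifier = fuzzifier,
                 dirichlet_concentration = dirichlet_concentration,
                 n_sweeps = as.integer(n_sweeps), noise_sigma = noise_sigma,
                 seed = as.integer(seed)), class = "bfc_params")
}

#' Deterministic prototype initialization
#'
#' Prototypes start at the intensity quantiles `(w + 0.5) / O`, `w = 0 ..
#' O - 1`, so the initialization is a pure function of the image.
#'
#' @param image Numeric matrix.
#' @param params A [bfc_params()].
#' @return Numeric vector of `n_clusters` prototypes.
#' @export
bfc_init_prototypes <- function(image, params) {
  assert_image(image)
  O <- params$n_clusters
  as.numeric(stats::quantile(as.vector(image), probs = (seq_len(O) - 0.5) / O,
                             type = 7, names = FALSE))
}

#' Membership update
#'
#' Per pixel, the membership of cluster `w` is proportional to
#' `(pi_w * N(x; t_w, sigma))^(1 / (fuzzifier - 1))`, normalized to sum to 1,
#' where `pi_w` is the (symmetric, hence constant) Dirichlet prior weight.
#' Computed in log space; a pixel whose unnormalized weights all underflow
#' gets a uniform membership.
#'
#' @param image Numeric matrix.
#' @param prototypes Numeric vector of cluster prototypes.
#' @param params A [bfc_params()].
#' @return An `n_pixels x n_clusters` membership matrix with unit row sums.
#' @export
bfc_memberships <- function(image, prototypes, params) {
  assert_image(image)
  x <- as.vector(image)
  O <- length(prototypes)
  if (O == 1L) return(matrix(1, length(x), 1L))
  sig <- max(params$noise_sigma, 1e-8)
  d2 <- outer(x, prototypes, function(a, b) (a - b)^2)
  logw <- (-d2 / (2 * sig^2)) / (params$fuzzifier - 1)  # symmetric prior cancels
  logw <- logw - apply(logw, 1L, max)
  wgt <- exp(logw)
  s <- rowSums(wgt)
  bad <- !is.finite(s) | s <= 0
  if (any(bad)) { wgt[bad, ] <- 1; s[bad] <- O }
  wgt / s
}

#' Prototype update
#'
#' Maximum-a-posteriori prototype under the Gaussian model and a flat
#' prototype prior: the membership-weighted mean
#' `t_w = sum(m^fuzzifier * x) / sum(m^fuzzifier)`. A cluster with zero total
#' membership mass is resampled uniformly in \[0, 1\] from the seeded stream.
#'
#' @param image Numeric matrix.
#' @param memberships Membership matrix from [bfc_memberships()].
#' @param params A [bfc_params()].
#' @return Numeric vector of updated prototypes.
#' @export
bfc_prototypes <- function(image, memberships, params) {
  assert_image(image)
  x <- as.vector(image)
  mf <- memberships ^ params$fuzzifier
  mass <- colSums(mf)
  t_w <- as.vector(crossprod(mf, x)) / mass
  dead <- !is.finite(t_w) | mass <= 0
  if (any(dead)) t_w[dead] <- stats::runif(sum(dead))
  t_w
}

# Posterior score used for sweep selection: fuzzified complete-data
# log-posterior (Gaussian likelihood + symmetric Dirichlet prior term).
bfc_log_posterior <- function(image, memberships, prototypes, params) {
  x <- as.vector(image)
  sig <- max(params$noise_sigma, 1e-8)
  d2 <- outer(x, prototypes, function(a, b) (a - b)^2)
  loglik <- -d2 / (2 * sig^2) - log(sig) - 0.5 * log(2 * pi)
  mf <- memberships ^ params$fuzzifier
  prior <- (params$dirichlet_concentration - 1) *
    sum(log(pmax(memberships, 1e-12)))
  sum(mf * loglik) + prior
}

#' Segment an image by Bayesian fuzzy clustering
#'
#' Runs `n_sweeps` alternating membership/prototype MAP sweeps from the
#' deterministic quantile initialization, scores every sweep by the joint
#' log-posterior, and returns the best-scoring state (the "enhanced
#' likelihood" selection). Labels are the per-pixel membership argmax.
#'
#' @param image Numeric matrix with intensities in \[0, 1\].
#' @param params A [bfc_params()].
#' @return A list of class `"bfc_result"`: `memberships` (pixels x clusters),
#'   `prototypes`, `labels` (matrix of 1-based cluster labels),
#'   `log_posterior_trace`.
#' @export
bfc_segment <- function(image, params = bfc_params()) {
  assert_image(image)
  set.seed(params$seed)
  proto <- bfc_init_prototypes(image, params)
  best <- NULL; trace <- numeric(params$n_sweeps)
  memb <- NULL
  for (s in seq_len(params$n_sweeps)) {
    memb <- bfc_memberships(image, proto, params)
    proto <- bfc_prototypes(image, memb, params)
    lp <- bfc_log_posterior(image, memb, proto, params)
    trace[s] <- lp
    if (is.null(best) || lp >= best$lp)
      best <- list(lp = lp, memb = memb, proto = proto)
  }
  labels <- matrix(max.col(best$memb, ties.method = "first"),
                   nrow(image), ncol(image))
  structure(list(memberships = best$memb, prototypes = best$proto,
                 labels = labels, log_posterior_trace = trace),
            class = "bfc_result")
}

#' Select lung-field regions from a clustering result
#'
#' Lung parenchyma appears as dark regions in the chest interior, while the
#' air around the body is equally dark but forms a frame touching all four
#' image borders. Starting with the darkest cluster (by prototype), connected
#' components touching all four borders are discarded; the first cluster (in
#' increasing prototype order) with any surviving component provides the lobe
#' mask. Pass your own mask downstream to bypass this heuristic.
#'
#' @param result A [bfc_segment()] result.
#' @param image The clustered image (used only for shape checks).
#' @param min_comp_frac Discard components smaller than this fraction of the
#'   image area (noise speckles).
#' @param min_total_frac A cluster only qualifies when its surviving
#'   components jointly cover at least this fraction of the image; otherwise
#'   the next-darkest cluster is tried (lung fields are large).
#' @return A binary matrix with interior holes filled (tumors and vessels
#'   cluster brighter than parenchyma but belong to the lung field); empty
#'   (with a warning) when no cluster qualifies.
#' @export
select_lung_rois <- function(result, image, min_comp_frac = 0.002,
                             min_total_frac = 0.02) {
  assert_image(image)
  ord <- order(result$prototypes)
  h <- nrow(image); w <- ncol(image)
  n <- h * w
  for (k in ord) {
    cl <- (result$labels == k) * 1
    if (!any(cl == 1)) next
    lab <- EBImage::bwlabel(cl)
    keep <- matrix(0, h, w)
    for (comp in seq_len(max(lab))) {
      sel <- lab == comp
      if (sum(sel) < max(9, min_comp_frac * n)) next
      touches <- c(any(sel[1, ]), any(sel[h, ]), any(sel[, 1]), any(sel[, w]))
      if (all(touches)) next   # border frame, not a lung field
      keep[sel] <- 1
    }
    if (sum(keep) >= min_total_frac * n) {
      return(matrix(as.numeric(as.matrix(EBImage::fillHull(keep)) > 0), h, w))
    }
  }
  warning("no interior dark component found; returning an empty lobe mask")
  matrix(0, h, w)
}
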