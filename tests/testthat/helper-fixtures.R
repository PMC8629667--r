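# Programmatic fixtures shared across tests.

# brute-force per-pixel median filter (independent oracle)
naive_median <- function(m, w, mode = "replicate") {
  k <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vs <- numeric(0)
    for (dr in -k:k) for (dc in -k:k) {
      rr <- r + dr; cc <- c + dc
      if (mode == "replicate") {
        rr <- min(max(rr, 1L), nr); cc <- min(max(cc, 1L), nc)
      } else {                       # symmetric reflect
        if (rr < 1L) rr <- 1L - rr
        if (rr > nr) rr <- 2L * nr + 1L - rr
        if (cc < 1L) cc <- 1L - cc
        if (cc > nc) cc <- 2L * nc + 1L - cc
      }
      vs <- c(vs, m[rr, cc])
    }
    out[r, c] <- stats::median(vs)
  }
  out
}

disk_mask <- function(h, w, cr, cc, radius) {
  rr <- matrix(seq_len(h), h, w)
  cl <- matrix(seq_len(w), h, w, byrow = TRUE)
  (sqrt((rr - cr)^2 + (cl - cc)^2) <= radius) * 1
}

# two-texture image: coarse-grain disk on fine-grain background, equal means
two_texture_image <- function(h = 96, seed = 1, radius = h / 3, amp = 0.12) {
  set.seed(seed)
  fine <- matrix(stats::rnorm(h * h), h, h)
  fine <- fine - mean(fine)
  coarse <- matrix(stats::rnorm(h * h), h, h)
  # smooth via repeated box means to stay independent of package internals
  for (i in 1:6) {
    p <- coarse[c(1, 1:h, h), c(1, 1:h, h)]
    coarse <- (p[1:h, 1:h] + p[1:h, 2:(h + 1)] + p[1:h, 3:(h + 2)] +
               p[2:(h + 1), 1:h] + p[2:(h + 1), 2:(h + 1)] + p[2:(h + 1), 3:(h + 2)] +
               p[3:(h + 2), 1:h] + p[3:(h + 2), 2:(h + 1)] + p[3:(h + 2), 3:(h + 2)]) / 9
  }
  fine <- fine / stats::sd(fine); coarse <- coarse / stats::sd(coarse)
  truth <- disk_mask(h, h, h / 2, h / 2, radius)
  img <- 0.5 + amp * ifelse(truth == 1, coarse, fine)
  list(image = pmin(pmax(img, 0), 1), truth = truth)
}

# best label agreement over all label permutations (small O only)
best_permutation_agreement <- function(labels, truth, O) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- 0
  for (p in perms(seq_len(O))) {
    mapped <- p[labels]
    best <- max(best, mean(mapped == truth))
  }
  best
}
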