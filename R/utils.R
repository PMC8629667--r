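# Internal helpers shared across modules. Images are plain numeric matrices,
# indexed [row, col], intensities in [0, 1].

`%||%` <- function(a, b) if (is.null(a)) b else a

is_image <- function(x) is.matrix(x) && is.numeric(x) && nrow(x) >= 1 && ncol(x) >= 1

assert_image <- function(x, what = "image") {
  if (!is_image(x)) stop(what, " must be a numeric matrix with >= 1 row and column",
                         call. = FALSE)
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

assert_binary <- function(x, what = "mask") {
  assert_image(x, what)
  if (!all(x %in% c(0, 1))) stop(what, " must contain only 0/1 values", call. = FALSE)
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Pad a matrix by `k` pixels on every side. Replicate repeats the edge row/col;
# reflect mirrors without repeating the edge (scipy-style "mirror" would repeat;
# here reflect duplicates the border pixel, i.e. symmetric half-sample padding).
pad_matrix <- function(m, k, mode = c("replicate", "reflect")) {
  mode <- match.arg(mode)
  nr <- nrow(m); nc <- ncol(m)
  if (mode == "replicate") {
    ri <- c(rep(1L, k), seq_len(nr), rep(nr, k))
    ci <- c(rep(1L, k), seq_len(nc), rep(nc, k))
  } else {
    refl <- function(n, k) {
      idx <- c(rev(seq_len(min(k, n))), seq_len(n), n + 1 - seq_len(min(k, n)))
      # if k > n, recycle the reflection (degenerate tiny images)
      while (length(idx) < n + 2 * k) idx <- c(idx[1], idx, idx[length(idx)])
      idx[seq_len(n + 2 * k)]
    }
    ri <- refl(nr, k); ci <- refl(nc, k)
  }
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian blur with replicate borders; sigma in pixels.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2)); k <- k / sum(k)
  conv_rows <- function(a) {
    nr <- nrow(a)
    ext <- pmin(pmax(outer(seq_len(nr), seq(-r, r), `+`), 1L), nr)  # replicate
    out <- matrix(0, nr, ncol(a))
    for (j in seq_along(x)) out <- out + k[j] * a[ext[, j], , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

# Local mean with a square box of odd side `w`, replicate borders.
box_mean <- function(m, w) {
  k <- (w - 1L) %/% 2L
  p <- pad_matrix(m, k, "replicate")
  cs <- apply(p, 2, cumsum)
  cs <- rbind(0, cs)
  rowsum_ <- cs[(w + 1):(w + nrow(m)), , drop = FALSE] - cs[1:nrow(m), , drop = FALSE]
  cs2 <- t(apply(rowsum_, 1, cumsum))
  cs2 <- cbind(0, cs2)
  (cs2[, (w + 1):(w + ncol(m)), drop = FALSE] - cs2[, 1:ncol(m), drop = FALSE]) / (w * w)
}

# Derive a bounded sub-seed from a base seed and a stage tag.
derive_seed <- function(seed, tag) {
  (as.integer(seed) %% 1000003L) * 1009L + sum(utf8ToInt(tag)) %% 1009L
}
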