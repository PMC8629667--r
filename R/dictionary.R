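#' Extract all fully contained square patches
#'
#' Slides a `T x T` window at stride 1 over the image; only windows fully
#' inside the image are taken (border pixels are simply covered by fewer
#' patches). Patches are ordered row-major by origin and each patch is
#' flattened column-major (the package-wide flattening convention, matching
#' R's matrix layout).
#'
#' @param image Numeric matrix.
#' @param patch_size Odd window side `T`, at most `min(dim(image))`.
#' @return A list with `patches` (`n_patches x T^2` matrix), `origins`
#'   (`n_patches x 2`, 1-based top-left `(row, col)`), `patch_size`.
#' @export
extract_patches <- function(image, patch_size) {
  assert_image(image)
  T_ <- as.integer(patch_size)
  if (T_ %% 2L == 0L || T_ < 1L) stop("patch_size must be odd and >= 1", call. = FALSE)
  if (T_ > min(dim(image))) stop("patch_size exceeds image size", call. = FALSE)
  nr <- nrow(image) - T_ + 1L; nc <- ncol(image) - T_ + 1L
  origins <- cbind(row = rep(seq_len(nr), each = nc),
                   col = rep(seq_len(nc), times = nr))
  t_len <- T_ * T_
  patches <- matrix(0, nrow(origins), t_len)
  # one column of `patches` per in-patch offset; vectorized over patches
  off <- 0L
  for (dc in 0:(T_ - 1L)) for (dr in 0:(T_ - 1L)) {
    off <- off + 1L
    patches[, off] <- image[cbind(origins[, 1] + dr, origins[, 2] + dc)]
  }
  # reorder offset columns to column-major within-patch order: offsets were
  # generated dr-fastest within dc, which IS column-major; nothing to do.
  list(patches = patches, origins = origins, patch_size = T_)
}

# k-means++ seeding on rows of x
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ], `-`)^2)
  if (k > 1) for (j in 2:k) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
    idx[j] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ], `-`)^2))
  }
  x[idx, , drop = FALSE]
}

#' Build a texture dictionary by k-means
#'
#' Clusters the patch vectors with Euclidean k-means (Lloyd iterations from a
#' seeded k-means++ initialization, run to convergence or 300 iterations).
#' Every patch is assigned to its nearest center; ties break toward the
#' lowest atom index.
#'
#' @param patches `n_patches x t` matrix from [extract_patches()].
#' @param n_atoms Number of dictionary atoms `d`.
#' @param seed Integer seed for the initialization.
#' @return A list of class `"patch_dictionary"` with `centers`
#'   (`d x t`), `assignments` (length `n_patches`), `n_atoms`, `patch_len`.
#' @export
build_dictionary <- function(patches, n_atoms, seed = 1L) {
  if (n_atoms < 1) stop("n_atoms must be >= 1", call. = FALSE)
  set.seed(seed)
  n_atoms <- as.integer(n_atoms)
  uniq <- unique(patches)
  if (n_atoms == 1L) {
    centers <- matrix(colMeans(patches), 1L)
  } else if (nrow(uniq) <= n_atoms) {
    centers <- uniq[seq_len(min(nrow(uniq), n_atoms)), , drop = FALSE]
    if (nrow(centers) < n_atoms)        # duplicate centers tolerated
      centers <- centers[rep_len(seq_len(nrow(centers)), n_atoms), , drop = FALSE]
  } else {
    init <- kmeanspp_centers(patches, n_atoms)
    km <- suppressWarnings(
      stats::kmeans(patches, centers = init, iter.max = 300L,
                    algorithm = "Lloyd"))
    centers <- km$centers
  }
  assignments <- nearest_center(patches, centers)
  structure(list(centers = unname(centers), assignments = assignments,
                 n_atoms = n_atoms, patch_len = ncol(patches)),
            class = "patch_dictionary")
}

# nearest row of `centers` for every row of x; ties -> lowest index
nearest_center <- function(x, centers) {
  cn <- rowSums(centers^2)
  d <- -2 * x %*% t(centers)
  d <- sweep(d, 2, cn, `+`)                    # squared distance up to ||x||^2
  max.col(-d, ties.method = "first")
}

#' Build the pixel/dictionary-pixel biadjacency matrix
#'
#' For every patch assigned to atom `a` and every in-patch offset
#' `j = 1 .. t`, the entry linking the covered image pixel to dictionary
#' pixel `(a - 1) * t + j` is set to 1. The matrix has one row per image
#' pixel (column-major linear index) and `d * t` columns; a pixel's row sum
#' equals the number of patches covering it.
#'
#' @param dictionary A [build_dictionary()] result.
#' @param origins Patch origins from [extract_patches()].
#' @param image_shape `c(height, width)`.
#' @return A sparse `dgCMatrix` (class from the Matrix package).
#' @export
build_biadjacency <- function(dictionary, origins, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  T_ <- as.integer(sqrt(dictionary$patch_len))
  if (any(origins[, 1] + T_ - 1L > h) || any(origins[, 2] + T_ - 1L > w) ||
      any(origins < 1L))
    stop("patch origins out of range for image_shape", call. = FALSE)
  t_len <- dictionary$patch_len
  n_p <- nrow(origins)
  # offsets in column-major within-patch order, matching extract_patches
  d_off <- rep(0:(T_ - 1L), times = T_)        # row offsets
  c_off <- rep(0:(T_ - 1L), each = T_)         # col offsets
  pr <- rep(origins[, 1], each = t_len) + d_off
  pc <- rep(origins[, 2], each = t_len) + c_off
  rows <- pr + (pc - 1L) * h
  cols <- rep((dictionary$assignments - 1L) * t_len, each = t_len) +
    rep(seq_len(t_len), times = n_p)
  # (pixel, dictionary-pixel) pairs are unique by construction: the offset
  # determines the patch origin given the pixel
  Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                       dims = c(h * w, dictionary$n_atoms * t_len))
}

#' Push label layers to dictionary labels
#'
#' For each dictionary pixel `j` and label layer `x`, the label value is the
#' frequency with which the image pixels related to `j` carry label `x`:
#' `g_x[j] = sum_p G[p, j] C_x[p] / sum_p G[p, j]`. Dictionary pixels with no
#' incident image pixel get the uninformative value `1 / X`.
#'
#' @param G Biadjacency matrix from [build_biadjacency()].
#' @param labels List of binary label layers (matrices summing to 1 per
#'   pixel).
#' @return A list of class `"dict_labels"`: `g` (matrix `d*t x X`),
#'   `coverage` (column sums of `G`).
#' @export
labels_to_dict <- function(G, labels) {
  X <- length(labels)
  colsum <- Matrix::colSums(G)
  g <- vapply(labels, function(cx) {
    as.vector(Matrix::crossprod(G, as.vector(cx)))
  }, numeric(ncol(G)))
  g <- sweep(g, 1, pmax(colsum, 1), `/`)
  g[colsum == 0, ] <- 1 / X
  structure(list(g = g, coverage = colsum, areas = vapply(labels, sum, 0)),
            class = "dict_labels")
}

#' Area-normalize dictionary labels
#'
#' Divides each label's dictionary values by that label's pixel area and
#' renormalizes per dictionary pixel, removing the bias toward large regions:
#' `g_tilde_x = (g_x / area_x) / sum_y (g_y / area_y)`. Zero-area labels
#' contribute nothing.
#'
#' @param dict_labels A [labels_to_dict()] result.
#' @param areas Per-label pixel counts (defaults to the areas recorded by
#'   [labels_to_dict()]).
#' @return The input with a `g_tilde` matrix added; `rowSums(g_tilde)` is 1.
#' @export
area_normalize <- function(dict_labels, areas = NULL) {
  areas <- areas %||% dict_labels$areas
  if (any(areas < 0) || all(areas == 0)) stop("invalid label areas", call. = FALSE)
  inv <- ifelse(areas > 0, 1 / areas, 0)
  gt <- sweep(dict_labels$g, 2, inv, `*`)
  s <- rowSums(gt)
  X <- ncol(gt)
  gt <- gt / ifelse(s > 0, s, 1)
  gt[s <= 0, ] <- 1 / X
  dict_labels$g_tilde <- gt
  dict_labels
}

#' Pull dictionary labels back to per-pixel probabilities
#'
#' Averages the (area-normalized) dictionary labels over the dictionary
#' pixels related to each image pixel:
#' `E_x[p] = sum_j G[p, j] g_tilde_x[j] / sum_j G[p, j]`. Pixels covered by
#' no patch get `1 / X`.
#'
#' @param G Biadjacency matrix.
#' @param dict_labels An area-normalized [labels_to_dict()] result.
#' @param shape `c(height, width)` of the image.
#' @return A list of class `"probability_map"` with `E`: a list of per-label
#'   probability matrices summing to 1 per pixel, and `shape`.
#' @export
dict_to_probabilities <- function(G, dict_labels, shape) {
  if (is.null(dict_labels$g_tilde))
    stop("dict_labels must be area-normalized first", call. = FALSE)
  rowsum_ <- Matrix::rowSums(G)
  X <- ncol(dict_labels$g_tilde)
  E <- lapply(seq_len(X), function(x) {
    e <- as.vector(G %*% dict_labels$g_tilde[, x]) / pmax(rowsum_, 1)
    e[rowsum_ == 0] <- 1 / X
    matrix(e, shape[1], shape[2])
  })
  structure(list(E = E, shape = shape), class = "probability_map")
}

#' Pixel-wise multi-label probability transform
#'
#' `E_tilde_x = e_x / (e_x + max of the other layers)` per pixel, so a layer
#' exceeds 1/2 exactly where it is the strict argmax; for two labels this is
#' `e_1 / (e_1 + e_2)`. Pixels where all layers are zero get `1 / X`.
#'
#' @param prob A [dict_to_probabilities()] result.
#' @return The input with an `E_tilde` list of matrices added.
#' @export
multi_label_transform <- function(prob) {
  X <- length(prob$E)
  if (X == 1L) { prob$E_tilde <- list(prob$E[[1]] * 0 + 1); return(prob) }
  arr <- simplify2array(prob$E)            # h x w x X
  Et <- vector("list", X)
  for (x in seq_len(X)) {
    others <- arr[, , -x, drop = FALSE]
    mx <- apply(others, c(1, 2), max)
    den <- arr[, , x] + mx
    e <- arr[, , x] / ifelse(den > 0, den, 1)
    e[den <= 0] <- 1 / X
    Et[[x]] <- e
  }
  prob$E_tilde <- Et
  prob
}
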