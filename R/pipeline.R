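#' Full pipeline configuration
#'
#' Bundles the per-stage parameters; all stage seeds derive deterministically
#' from the single `seed`.
#'
#' @param median_window Median-filter window (odd).
#' @param median_border Border mode for the median filter.
#' @param bfc A [bfc_params()].
#' @param dictseg A [dictseg_config()].
#' @param seed Global integer seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(median_window = 3L,
                            median_border = "replicate",
                            bfc = bfc_params(),
                            dictseg = dictseg_config(),
                            seed = 1L) {
  seed <- as.integer(seed)
  bfc$seed <- derive_seed(seed, "bfc")
  dictseg$seed <- derive_seed(seed, "dictseg")
  structure(list(median_window = as.integer(median_window),
                 median_border = median_border, bfc = bfc, dictseg = dictseg,
                 seed = seed), class = "pipeline_config")
}

# Tumor initialization inside the lobe mask: a tumor is a local anomaly of
# the parenchyma, either in intensity (local mean of the filtered slice) or
# in texture (log fine-band energy of the raw slice, which a median filter
# would erase). Both features are robust-z-scored against the lobe's
# median/MAD and combined into a squared radius s2. Hysteresis thresholds:
# pixels beyond the chi-square 99% radius seed the detection (largest
# component only: solitary-nodule assumption); the seed is grown through
# connected pixels beyond the 90% radius. Deterministic; plumbing the
# pipeline needs, independent of the phantom generator.
init_tumor_seed <- function(image_raw, filtered, lobe_mask,
                            z2_strong = stats::qchisq(0.99, df = 2),
                            z2_weak = stats::qchisq(0.90, df = 2),
                            feature_window = 9L) {
  sel <- lobe_mask == 1
  if (sum(sel) < 10) return(NULL)
  mu <- box_mean(filtered, feature_window)
  fine <- log(pmax(box_mean((image_raw - box_mean(image_raw, 3L))^2, 11L),
                   1e-12))
  rz <- function(v) {
    md <- stats::median(v[sel]); s <- stats::mad(v[sel])
    if (s <= 0) s <- 1e-9
    (v - md) / s
  }
  s2 <- rz(mu)^2 + rz(fine)^2
  strong <- matrix(0, nrow(filtered), ncol(filtered))
  strong[sel & s2 > z2_strong] <- 1
  lab <- EBImage::bwlabel(strong)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0 || max(sizes) < 9) return(NULL)
  core <- lab == which.max(sizes)
  weak <- matrix(0, nrow(filtered), ncol(filtered))
  weak[sel & s2 > z2_weak] <- 1
  wl <- EBImage::bwlabel(weak)
  ids <- unique(wl[core]); ids <- ids[ids > 0]
  seed_mask <- matrix(as.numeric(wl %in% ids), nrow(filtered), ncol(filtered))
  if (all(seed_mask[sel] == 1)) return(NULL)
  seed_mask
}

#' Run the full segmentation pipeline
#'
#' median filter -> lobe extraction by Bayesian fuzzy clustering -> lung ROI
#' selection -> dictionary-based deformable tumor segmentation restricted to
#' the lobe mask (pixels outside it are clamped to background). When ground
#' truth is supplied the overlap metrics are computed.
#'
#' @param input A numeric matrix, a file path (read via [read_gray()]), or a
#'   [phantom_spec()] (generated, with its masks used as ground truth).
#' @param config A [pipeline_config()].
#' @param lobe_mask Optional binary matrix overriding the clustering-based
#'   lobe extraction.
#' @param truth Optional binary tumor ground-truth matrix.
#' @return A list of class `"pipeline_result"`: `tumor_mask`, `lobe_mask`,
#'   `filtered`, `bfc`, `dictseg`, `metrics` (data frame or `NULL`), `log`
#'   (per-stage parameters and timings), and `status` (`"ok"` or
#'   `"empty_lobe"`).
#' @export
run_pipeline <- function(input, config = pipeline_config(), lobe_mask = NULL,
                         truth = NULL) {
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, t0, ...) {
    log[[name]] <<- c(list(seconds = round(tic() - t0, 3)), list(...))
  }

  if (inherits(input, "phantom_spec")) {
    ph <- phantom_generate(input)
    image <- ph$image
    if (is.null(truth)) truth <- ph$tumor_mask
  } else if (is.character(input)) {
    image <- read_gray(input)
  } else {
    image <- input
  }
  assert_image(image)

  t0 <- tic()
  filtered <- median_filter(image, config$median_window, config$median_border)
  stage("median_filter", t0, window = config$median_window,
        border = config$median_border)

  bfc_res <- NULL
  if (is.null(lobe_mask)) {
    t0 <- tic()
    bfc_res <- bfc_segment(filtered, config$bfc)
    lobe_mask <- select_lung_rois(bfc_res, filtered)
    stage("lobe_segmentation", t0, n_clusters = config$bfc$n_clusters,
          seed = config$bfc$seed)
  }
  if (!any(lobe_mask == 1)) {
    warning("empty lobe mask; tumor segmentation skipped")
    return(structure(list(tumor_mask = NULL, lobe_mask = lobe_mask,
                          filtered = filtered, bfc = bfc_res, dictseg = NULL,
                          metrics = NULL, log = log, status = "empty_lobe"),
                     class = "pipeline_result"))
  }

  t0 <- tic()
  init <- init_tumor_seed(image, filtered, lobe_mask)
  if (is.null(init)) {
    # fall back to a centered disk inside the largest lobe component
    lab <- EBImage::bwlabel(lobe_mask)
    big <- which.max(tabulate(lab[lab > 0]))
    idx <- which(lab == big, arr.ind = TRUE)
    ctr <- colMeans(idx)
    r <- max(3, sqrt(nrow(idx) / pi) / 3)
    init <- ellipse_mask(nrow(filtered), ncol(filtered),
                         c(ctr[1], ctr[2], r, r, 0)) * lobe_mask
  }
  stage("tumor_init", t0)

  t0 <- tic()
  seg <- dict_segment(filtered, init, config$dictseg, roi_mask = lobe_mask)
  tumor_mask <- seg$masks[[1]]
  stage("tumor_segmentation", t0, mode = config$dictseg$mode,
        patch_size = config$dictseg$patch_size,
        n_atoms = config$dictseg$n_atoms, seed = config$dictseg$seed,
        iterations = length(seg$trace), converged = seg$converged)

  metrics <- if (!is.null(truth)) seg_metrics(tumor_mask, truth) else NULL
  structure(list(tumor_mask = tumor_mask, lobe_mask = lobe_mask,
                 filtered = filtered, bfc = bfc_res, dictseg = seg,
                 metrics = metrics, log = log, status = "ok"),
            class = "pipeline_result")
}

#' Benchmark the pipeline on seeded phantoms
#'
#' Generates `n_phantoms` phantoms of the requested difficulty, runs the full
#' pipeline on each, and returns per-phantom metrics plus a mean row.
#'
#' @param config A [pipeline_config()]; each phantom gets a derived seed.
#' @param n_phantoms Number of phantoms.
#' @param difficulty `"easy"`, `"texture"` or `"noisy"` (see
#'   [phantom_suite()]).
#' @param size Phantom size.
#' @return A data frame with one row per phantom and a final `"mean"` row.
#' @export
run_benchmark <- function(config = pipeline_config(), n_phantoms = 5L,
                          difficulty = "easy", size = c(128L, 128L)) {
  stopifnot(n_phantoms >= 1)
  rows <- vector("list", n_phantoms)
  for (i in seq_len(n_phantoms)) {
    sp <- phantom_suite(seed = derive_seed(config$seed, paste0("bench", i)),
                        size = size)[[difficulty]]
    cfg_i <- config
    cfg_i <- pipeline_config(median_window = config$median_window,
                             median_border = config$median_border,
                             bfc = config$bfc, dictseg = config$dictseg,
                             seed = derive_seed(config$seed, paste0("run", i)))
    res <- run_pipeline(sp, cfg_i)
    m <- if (!is.null(res$metrics)) res$metrics else
      data.frame(tp = NA, tn = NA, fp = NA, fn = NA, accuracy = NA,
                 jaccard = NA, dice = NA)
    rows[[i]] <- cbind(data.frame(phantom = i, difficulty = difficulty), m)
  }
  out <- do.call(rbind, rows)
  mean_row <- cbind(data.frame(phantom = NA, difficulty = "mean"),
                    as.data.frame(t(colMeans(out[, -(1:2)], na.rm = TRUE))))
  rbind(out, mean_row)
}
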