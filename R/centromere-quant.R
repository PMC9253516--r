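#' Focus-detection parameters
#'
#' Detection works on the ACA (anti-centromere) reference channel:
#' difference-of-Gaussians band-pass enhancement, a robust threshold at
#' `median + k * MAD` of the enhanced image, connected components within an
#' area range, and intensity-weighted sub-pixel centroids. The centromere
#' mask for each focus comes from an Otsu threshold inside a square window
#' around the centroid (an absolute threshold may be supplied instead).
#'
#' @param dog_sigma_low_px,dog_sigma_high_px Band-pass Gaussian widths in
#'   pixels (spot scale and background scale).
#' @param k Robust-SD multiplier for the detection threshold.
#' @param min_area_px,max_area_px Connected-component area limits.
#' @param mask_window_px Side of the square window used to derive each
#'   focus's centromere mask (odd integer).
#' @param mask_threshold Optional absolute intensity threshold for the mask;
#'   `NULL` (default) uses Otsu within the window.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(dog_sigma_low_px = 1, dog_sigma_high_px = 3,
                             k = 5, min_area_px = 3, max_area_px = 400,
                             mask_window_px = 9, mask_threshold = NULL) {
  stopifnot(dog_sigma_low_px > 0, dog_sigma_high_px > dog_sigma_low_px,
            k > 0, min_area_px >= 1, max_area_px >= min_area_px,
            mask_window_px >= 3, mask_window_px %% 2 == 1)
  structure(list(dog_sigma_low_px = dog_sigma_low_px,
                 dog_sigma_high_px = dog_sigma_high_px, k = k,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 mask_window_px = mask_window_px,
                 mask_threshold = mask_threshold),
            class = "detection_params")
}

#' Detect centromere foci in the ACA channel
#'
#' @param aca_channel 2-D intensity matrix of the reference (ACA) channel.
#' @param params A [detection_params()].
#' @param pixel_size_um Pixel size used to report centroids in micrometres.
#' @return A tibble with one row per focus: `focus_id`, sub-pixel centroid
#'   (`x_px`, `y_px`, and `x_um`, `y_um`), `area_px`, and `mask` — a
#'   list-column of logical matrices the size of the image marking the
#'   centromere region. Deterministic: no random numbers are used.
#' @export
detect_foci <- function(aca_channel, params = detection_params(),
                        pixel_size_um = 0.0645) {
  stopifnot(is.matrix(aca_channel), length(aca_channel) > 0)
  empty <- tibble::tibble(focus_id = integer(), x_px = numeric(),
                          y_px = numeric(), x_um = numeric(), y_um = numeric(),
                          area_px = integer(), mask = list())

  dog <- EBImage::gblur(aca_channel, sigma = params$dog_sigma_low_px) -
    EBImage::gblur(aca_channel, sigma = params$dog_sigma_high_px)
  dog <- EBImage::imageData(dog)
  s <- stats::mad(dog)
  if (s == 0) {
    warning("enhanced image has zero robust spread (uniform or saturated); ",
            "no foci detected")
    return(empty)
  }
  thr <- stats::median(dog) + params$k * s
  bw <- dog > thr
  if (!any(bw)) return(empty)

  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  comps <- sort(unique(lab[lab > 0]))

  rows <- list()
  for (cc in comps) {
    idx <- which(lab == cc, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < params$min_area_px || area > params$max_area_px) next
    w <- aca_channel[idx]
    # pixel-centre convention: column j spans x in [j-1, j] px
    x_px <- sum((idx[, 2] - 0.5) * w) / sum(w)
    y_px <- sum((idx[, 1] - 0.5) * w) / sum(w)
    mask <- centromere_mask(aca_channel, x_px, y_px, params)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      focus_id = NA_integer_, x_px = x_px, y_px = y_px,
      x_um = x_px * pixel_size_um, y_um = y_px * pixel_size_um,
      area_px = sum(mask), mask = list(mask))
  }
  if (!length(rows)) return(empty)
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$x_px, out$y_px), ]
  out$focus_id <- seq_len(nrow(out))
  out
}

# centromere mask: Otsu (or absolute) threshold inside a window around the
# centroid, keeping the connected component containing the centroid pixel
centromere_mask <- function(img, x_px, y_px, params) {
  half <- (params$mask_window_px - 1L) / 2L
  ci <- max(1L, min(nrow(img), as.integer(ceiling(y_px))))
  cj <- max(1L, min(ncol(img), as.integer(ceiling(x_px))))
  ri <- max(1L, ci - half):min(nrow(img), ci + half)
  rj <- max(1L, cj - half):min(ncol(img), cj + half)
  win <- img[ri, rj, drop = FALSE]
  thr <- if (is.null(params$mask_threshold)) {
    rng <- range(win)
    if (diff(rng) == 0) rng[1] else {
      EBImage::otsu(EBImage::Image((win - rng[1]) / diff(rng))) * diff(rng) + rng[1]
    }
  } else {
    params$mask_threshold
  }
  local_bw <- win > thr
  if (!any(local_bw)) local_bw[which.max(win)] <- TRUE
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(local_bw * 1)))
  centre_lab <- lab[match(ci, ri), match(cj, rj)]
  if (is.na(centre_lab) || centre_lab == 0) {
    centre_lab <- lab[which.max(win * (lab > 0))]
  }
  mask <- matrix(FALSE, nrow(img), ncol(img))
  mask[ri, rj] <- lab == centre_lab
  mask
}

#' Ring measurement of marker intensity around a centromere
#'
#' Quantifies the mean marker fluorescence in a ring immediately outside the
#' centromere region (a 3-pixel-wide ring by default): the ring is the
#' morphological dilation of the centromere mask minus the mask itself, and
#' the reported value is the ring mean minus the mean over a cytoplasmic
#' background region.
#'
#' @param marker_channel 2-D intensity matrix of the marker channel.
#' @param focus One row of the [detect_foci()] tibble.
#' @param ring_width_px Ring width in pixels.
#' @param background_region Logical matrix (same size as the image) selecting
#'   cytoplasmic background pixels; `NULL` picks the modal-intensity region
#'   of the marker channel automatically (see [auto_background_region()]).
#' @return A one-row tibble: `focus_id`, `ring_mean`, `background_mean`,
#'   `corrected` (ring minus background), `n_ring_px` and `flagged` (true
#'   when the ring is clipped by the image border, or the corrected value is
#'   negative).
#' @export
measure_ring <- function(marker_channel, focus, ring_width_px = 3,
                         background_region = NULL) {
  stopifnot(is.matrix(marker_channel), ring_width_px >= 1)
  mask <- focus$mask[[1]]
  stopifnot(identical(dim(mask), dim(marker_channel)))
  if (is.null(background_region)) {
    background_region <- auto_background_region(marker_channel)
  }

  brush <- EBImage::makeBrush(2L * ring_width_px + 1L, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0
  ring <- dil & !mask

  idx <- which(mask, arr.ind = TRUE)
  clipped <- min(idx[, 1]) - ring_width_px < 1 ||
    min(idx[, 2]) - ring_width_px < 1 ||
    max(idx[, 1]) + ring_width_px > nrow(mask) ||
    max(idx[, 2]) + ring_width_px > ncol(mask)

  ring_mean <- mean(marker_channel[ring])
  bg_mean <- mean(marker_channel[background_region])
  corrected <- ring_mean - bg_mean
  tibble::tibble(focus_id = focus$focus_id, ring_mean = ring_mean,
                 background_mean = bg_mean, corrected = corrected,
                 n_ring_px = sum(ring),
                 flagged = clipped | corrected < 0)
}

#' Automatic cytoplasmic background region
#'
#' Selects the pixels whose intensity falls in the modal bin of the image's
#' intensity density — in a fluorescence image dominated by cytoplasmic
#' background this is the background plateau. A manually drawn region is
#' always accepted wherever a `background_region` argument exists.
#'
#' @param img 2-D intensity matrix.
#' @param max_px Cap on the number of selected pixels (the dimmest are kept).
#' @return Logical matrix selecting the background region.
#' @export
auto_background_region <- function(img, max_px = 10000L) {
  d <- stats::density(img, n = 512)
  mode_val <- d$x[which.max(d$y)]
  tol <- d$bw
  sel <- abs(img - mode_val) <= tol
  if (sum(sel) > max_px) {
    cut <- sort(abs(img[sel] - mode_val))[max_px]
    sel <- sel & abs(img - mode_val) <= cut
  }
  if (!any(sel)) sel[which.min(abs(img - mode_val))] <- TRUE
  sel
}

#' Quantify every focus of a cell image
#'
#' Convenience wrapper: detect foci on the ACA channel, ring-measure the
#' marker channel at each, and return one row per focus tagged with a cell id
#' and condition label, ready for [normalize_condition()] and the group
#' statistics.
#'
#' @param image Named list of channel matrices (needs `ACA` and
#'   `marker_channel`).
#' @param cell_id,condition Labels attached to every row.
#' @param marker_channel Name of the channel to quantify.
#' @param params [detection_params()].
#' @param ring_width_px Ring width in pixels.
#' @param background_region Optional logical matrix; `NULL` for automatic.
#' @param pixel_size_um Pixel size.
#' @return A tibble: `cell_id`, `condition`, `focus_id`, centroids, ring
#'   measurement columns.
#' @export
measure_cell <- function(image, cell_id, condition,
                         marker_channel = "marker",
                         params = detection_params(), ring_width_px = 3,
                         background_region = NULL,
                         pixel_size_um = 0.0645) {
  stopifnot("ACA" %in% names(image), marker_channel %in% names(image))
  foci <- detect_foci(image$ACA, params, pixel_size_um)
  if (nrow(foci) == 0) {
    return(tibble::tibble(cell_id = character(), condition = character(),
                          focus_id = integer(), x_um = numeric(),
                          y_um = numeric(), ring_mean = numeric(),
                          background_mean = numeric(), corrected = numeric(),
                          flagged = logical()))
  }
  if (is.null(background_region)) {
    background_region <- auto_background_region(image[[marker_channel]])
  }
  meas <- purrr::map_dfr(seq_len(nrow(foci)), function(i) {
    measure_ring(image[[marker_channel]], foci[i, ], ring_width_px,
                 background_region)
  })
  dplyr::bind_cols(
    tibble::tibble(cell_id = as.character(cell_id),
                   condition = as.character(condition))[rep(1, nrow(foci)), ],
    foci[, c("focus_id", "x_um", "y_um")],
    meas[, c("ring_mean", "background_mean", "corrected", "flagged")]
  )
}

#' Normalize corrected intensities to a reference condition
#'
#' Divides every background-corrected intensity by the mean corrected
#' intensity of the reference condition (for example a wild-type rescue), so
#' the reference mean maps to exactly 1. Flagged and negative measurements
#' are excluded from the reference and group means but retain a normalized
#' value.
#'
#' @param measurements Tibble with `condition`, `corrected` and optionally
#'   `flagged` columns (e.g. row-bound [measure_cell()] output).
#' @param reference_condition Label of the reference condition.
#' @return The input tibble with a `normalized` column added.
#' @export
normalize_condition <- function(measurements, reference_condition) {
  stopifnot(all(c("condition", "corrected") %in% names(measurements)))
  if (!reference_condition %in% measurements$condition) {
    stop("reference condition '", reference_condition, "' not present")
  }
  ok <- if ("flagged" %in% names(measurements)) {
    !measurements$flagged & measurements$corrected >= 0
  } else {
    measurements$corrected >= 0
  }
  ref <- measurements$corrected[measurements$condition == reference_condition & ok]
  ref_mean <- mean(ref)
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    stop("reference condition mean is not positive; cannot normalize")
  }
  dplyr::mutate(measurements, normalized = .data$corrected / ref_mean)
}

#' Recruitment ratio at a tethering focus
#'
#' For LacO/LacI tethering assays: the ratio of background-corrected marker
#' (e.g. Aurora B or Borealin) to background-corrected GFP bait intensity,
#' both measured over the focus mask itself (the LacO array focus, not a
#' ring).
#'
#' @param target_channel,gfp_channel Intensity matrices.
#' @param focus One row of [detect_foci()] output (detected on the GFP
#'   channel for tethering scenes).
#' @param target_background,gfp_background Logical background-region
#'   matrices; `NULL` for automatic selection per channel.
#' @return A one-row tibble: `target_corrected`, `gfp_corrected`, `ratio`
#'   and `flagged` (true, with `ratio = NA`, when the corrected GFP signal
#'   is not positive).
#' @export
recruitment_ratio <- function(target_channel, gfp_channel, focus,
                              target_background = NULL,
                              gfp_background = NULL) {
  mask <- focus$mask[[1]]
  if (is.null(target_background)) {
    target_background <- auto_background_region(target_channel)
  }
  if (is.null(gfp_background)) {
    gfp_background <- auto_background_region(gfp_channel)
  }
  target_corr <- mean(target_channel[mask]) - mean(target_channel[target_background])
  gfp_corr <- mean(gfp_channel[mask]) - mean(gfp_channel[gfp_background])
  if (!is.finite(gfp_corr) || gfp_corr <= 0) {
    return(tibble::tibble(target_corrected = target_corr,
                          gfp_corrected = gfp_corr, ratio = NA_real_,
                          flagged = TRUE))
  }
  tibble::tibble(target_corrected = target_corr, gfp_corrected = gfp_corr,
                 ratio = max(target_corr, 0) / gfp_corr, flagged = FALSE)
}

#' Scatter-with-mean panel of normalized intensities
#'
#' One jittered point per measurement grouped by condition with the group
#' mean as a bar — the conventional presentation of normalized centromere
#' intensities across rescue conditions.
#'
#' @param measurements Output of [normalize_condition()].
#' @return A ggplot object.
#' @export
plot_normalized <- function(measurements) {
  means <- dplyr::summarise(
    dplyr::group_by(measurements, .data$condition),
    m = mean(.data$normalized[!.data$flagged]), .groups = "drop")
  ggplot2::ggplot(measurements,
                  ggplot2::aes(.data$condition, .data$normalized)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_crossbar(data = means,
                           ggplot2::aes(y = .data$m, ymin = .data$m,
                                        ymax = .data$m),
                           colour = "red", width = 0.4) +
    ggplot2::labs(x = NULL, y = "normalized centromere intensity") +
    ggplot2::theme_classic()
}
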