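#' Pair kinetochore centroids by mutual nearest neighbours
#'
#' Two centroids form a kinetochore pair when each is the other's nearest
#' neighbour and their separation does not exceed `max_sep_um` (1.5 um by
#' default, the conventional sister-kinetochore cap). Mutual-nearest-neighbour
#' matching is local and deterministic; the input is first put into canonical
#' order (by x, then y) so the output is invariant to input permutation, and
#' distance ties are broken by lexicographic coordinate order of the
#' candidate partner.
#'
#' @param centroids A data frame with columns `x_um`, `y_um` (one row per
#'   detected centroid).
#' @param max_sep_um Maximum allowed pair separation in micrometres.
#' @return A list with `pairs` — a tibble with one row per pair (`pair_id`,
#'   endpoints `ax_um, ay_um, bx_um, by_um`, `mid_x_um, mid_y_um`, unit axis
#'   `axis_x, axis_y`, `separation_um`) — and `unpaired`, the tibble of
#'   unmatched centroids.
#' @examples
#' pts <- tibble::tibble(x_um = c(0, 1, 1.2), y_um = 0)
#' assign_pairs(pts)  # the 1.0/1.2 points pair; the origin stays unpaired
#' @export
assign_pairs <- function(centroids, max_sep_um = 1.5) {
  centroids <- tibble::as_tibble(centroids)
  stopifnot(all(c("x_um", "y_um") %in% names(centroids)), max_sep_um > 0)
  empty_pairs <- tibble::tibble(
    pair_id = integer(), ax_um = numeric(), ay_um = numeric(),
    bx_um = numeric(), by_um = numeric(), mid_x_um = numeric(),
    mid_y_um = numeric(), axis_x = numeric(), axis_y = numeric(),
    separation_um = numeric())
  n <- nrow(centroids)
  if (n < 2) {
    return(list(pairs = empty_pairs, unpaired = centroids))
  }
  ord <- order(centroids$x_um, centroids$y_um)
  pts <- centroids[ord, ]
  d <- as.matrix(stats::dist(cbind(pts$x_um, pts$y_um)))
  diag(d) <- Inf
  # nearest neighbour of each point; ties resolved by canonical (lexicographic)
  # index order, which which.min already honours after sorting
  nn <- apply(d, 1L, which.min)

  taken <- rep(FALSE, n)
  rows <- list()
  for (i in seq_len(n)) {
    j <- nn[i]
    if (i < j && nn[j] == i && d[i, j] <= max_sep_um) {
      a <- pts[i, ]; b <- pts[j, ]
      sep <- d[i, j]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pair_id = NA_integer_,
        ax_um = a$x_um, ay_um = a$y_um, bx_um = b$x_um, by_um = b$y_um,
        mid_x_um = (a$x_um + b$x_um) / 2, mid_y_um = (a$y_um + b$y_um) / 2,
        axis_x = (b$x_um - a$x_um) / sep, axis_y = (b$y_um - a$y_um) / sep,
        separation_um = sep)
      taken[c(i, j)] <- TRUE
    }
  }
  pairs <- if (length(rows)) dplyr::bind_rows(rows) else empty_pairs
  if (nrow(pairs)) pairs$pair_id <- seq_len(nrow(pairs))
  list(pairs = pairs, unpaired = pts[!taken, ])
}

#' Sample an intensity line profile through a kinetochore pair
#'
#' Intensities are sampled by bilinear interpolation at uniform steps along
#' the pair axis over a window of `length_um` (2 um by default) centred on
#' the pair midpoint, in every channel supplied. Each channel's profile is
#' additionally min-max normalized to \[0, 1\]; a flat profile cannot be
#' normalized and is flagged.
#'
#' @param image A single intensity matrix or a named list of per-channel
#'   matrices.
#' @param pair One row of the `pairs` tibble from [assign_pairs()] (or any
#'   data frame row with `mid_x_um`, `mid_y_um`, `axis_x`, `axis_y`).
#' @param pixel_size_um Pixel size of `image` in micrometres.
#' @param length_um Total profile length in micrometres.
#' @param step_um Sampling step; defaults to half a pixel (Nyquist of the
#'   sampled grid).
#' @return A tibble in long form: `position_um` (signed distance from the
#'   midpoint), `channel`, `intensity`, `normalized` and `flagged` (true when
#'   the window leaves the image or the profile is flat).
#' @export
extract_profile <- function(image, pair, pixel_size_um, length_um = 2,
                            step_um = pixel_size_um / 2) {
  if (is.matrix(image)) image <- list(channel = image)
  stopifnot(is.list(image), length_um > 0, step_um > 0)
  half <- length_um / 2
  pos <- seq(-half, half, by = step_um)
  px <- pair$mid_x_um + pos * pair$axis_x
  py <- pair$mid_y_um + pos * pair$axis_y

  out <- purrr::map_dfr(names(image), function(ch) {
    m <- image[[ch]]
    v <- bilinear_sample(m, px / pixel_size_um, py / pixel_size_um)
    flagged <- anyNA(v)
    rng <- range(v, na.rm = !all(is.na(v)))
    # dynamic range below float jitter counts as flat (degenerate)
    if (!flagged && diff(rng) > 1e-9 * max(abs(rng), 1)) {
      norm <- (v - rng[1]) / diff(rng)
    } else {
      norm <- rep(NA_real_, length(v))
      flagged <- TRUE
    }
    tibble::tibble(position_um = pos, channel = ch, intensity = v,
                   normalized = norm, flagged = flagged)
  })
  out
}

# bilinear interpolation at continuous pixel coordinates (units of pixels,
# pixel centres at i - 0.5); NA outside the pixel-centre hull
bilinear_sample <- function(m, x_px, y_px) {
  nr <- nrow(m); nc <- ncol(m)
  cx <- x_px + 0.5  # column coordinate where column j has centre j
  cy <- y_px + 0.5
  j0 <- floor(cx); i0 <- floor(cy)
  fx <- cx - j0; fy <- cy - i0
  ok <- j0 >= 1 & j0 + 1 <= nc & i0 >= 1 & i0 + 1 <= nr
  v <- rep(NA_real_, length(x_px))
  if (any(ok)) {
    j0k <- j0[ok]; i0k <- i0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    v00 <- m[cbind(i0k, j0k)]
    v01 <- m[cbind(i0k, j0k + 1)]
    v10 <- m[cbind(i0k + 1, j0k)]
    v11 <- m[cbind(i0k + 1, j0k + 1)]
    v[ok] <- v00 * (1 - fxk) * (1 - fyk) + v01 * fxk * (1 - fyk) +
      v10 * (1 - fxk) * fyk + v11 * fxk * fyk
  }
  v
}

# half-maximum crossings of a sampled profile by linear interpolation.
# baseline defaults to the profile minimum; the FWHM spans the OUTERMOST
# left and right crossings so dual-peak (inner + kinetochore-proximal)
# profiles report their full breadth.
fwhm_from_samples <- function(x, y, baseline = min(y)) {
  i_max <- which.max(y)
  peak <- y[i_max]
  if (!(peak > baseline)) {
    stop("profile has no peak above baseline; FWHM undefined")
  }
  half <- (peak + baseline) / 2
  above <- y >= half
  crossings <- numeric()
  for (k in seq_len(length(y) - 1L)) {
    if (xor(above[k], above[k + 1L])) {
      crossings <- c(crossings,
                     x[k] + (half - y[k]) / (y[k + 1L] - y[k]) * (x[k + 1L] - x[k]))
    }
  }
  left <- crossings[crossings < x[i_max]]
  right <- crossings[crossings > x[i_max]]
  if (!length(left) || !length(right)) {
    stop("half-maximum level is not crossed on both sides of the peak ",
         "(peak too close to the window boundary)")
  }
  list(left = min(left), right = max(right),
       fwhm = max(right) - min(left), n_crossings = length(crossings))
}

#' Full width at half maximum of a line profile
#'
#' The half-maximum level is `(max + baseline) / 2` with the baseline taken
#' as the profile minimum within the window; crossings are located by linear
#' interpolation between bracketing samples and the width spans the
#' outermost left and right crossings, so profiles with two resolved marker
#' pools report the full breadth of the signal. The result is invariant
#' under affine intensity transforms `I -> a*I + b` (a > 0).
#'
#' @param profile Long profile tibble from [extract_profile()].
#' @param channel Which channel's profile to measure (default `"marker"`).
#' @return A one-row tibble: `fwhm_um`, `left_cross_um`, `right_cross_um`,
#'   `n_crossings`.
#' @export
fwhm <- function(profile, channel = "marker") {
  p <- profile[profile$channel == channel, ]
  if (nrow(p) == 0) stop("channel '", channel, "' not present in the profile")
  res <- fwhm_from_samples(p$position_um, p$intensity)
  tibble::tibble(fwhm_um = res$fwhm, left_cross_um = res$left,
                 right_cross_um = res$right, n_crossings = res$n_crossings)
}

#' Line-profile overlay plot
#'
#' Normalized per-channel intensity against signed position along the pair
#' axis, one line per channel — the conventional way to display inner versus
#' kinetochore-proximal marker distributions across a kinetochore pair.
#'
#' @param profile Long profile tibble from [extract_profile()], or several
#'   such tibbles row-bound with a distinguishing `pair_id` column.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(.data$position_um, .data$normalized,
                               colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along pair axis (um)",
                  y = "normalized intensity") +
    ggplot2::theme_classic()
}
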