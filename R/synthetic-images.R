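#' Build a spot-truth table row
#'
#' A spot is an isotropic 2-D Gaussian focus with a per-channel amplitude map.
#' Spots model centromere/kinetochore foci: the ACA (anti-centromere
#' antibody) reference channel always carries one Gaussian per spot, while
#' the `marker` channel (Borealin, Aurora B or Sgo1) follows the spot's
#' `pool_model` — a single inner-centromere focus (`"inner_only"`), two
#' kinetochore-proximal foci (`"dual_pool"`), or all three (`"both"`).
#'
#' @param x_um,y_um Centroid in micrometres, image origin at the top-left
#'   corner, pixel centres at (i - 0.5) * pixel size.
#' @param sigma_um Gaussian width (standard deviation) in micrometres.
#' @param amplitude Named numeric vector of per-channel peak amplitudes,
#'   e.g. `c(ACA = 1000, marker = 800)`. Channels absent from the map get no
#'   signal from this spot.
#' @param pair_id Optional integer grouping sister foci (exactly two spots
#'   per id in a realized truth table; a single anchor row per id in a scene
#'   passed to [generate_spread_image()]).
#' @param pool_model One of `"inner_only"`, `"dual_pool"`, `"both"`.
#' @return A one-row tibble; bind rows to build a spot table.
#' @export
spot_truth <- function(x_um, y_um, sigma_um = 0.15,
                       amplitude = c(ACA = 1000),
                       pair_id = NA_integer_,
                       pool_model = c("inner_only", "dual_pool", "both")) {
  pool_model <- match.arg(pool_model)
  stopifnot(sigma_um > 0, all(amplitude >= 0), !is.null(names(amplitude)))
  tibble::tibble(
    x_um = x_um, y_um = y_um, sigma_um = sigma_um,
    amplitude = list(amplitude),
    pair_id = as.integer(pair_id),
    pool_model = pool_model
  )
}

#' Describe a synthetic multi-channel image scene
#'
#' A scene is the complete, seeded recipe for one synthetic fluorescence
#' image: geometry, channel list, spot table, per-channel background and
#' noise model. Rendering a scene twice with the same seed gives
#' bit-identical images.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Physical pixel size in micrometres. The default
#'   0.0645 corresponds to a 6.45 um camera pixel behind a 100x objective.
#' @param channels Ordered character vector of channel names, a subset of
#'   `c("ACA", "marker", "GFP", "DNA")`.
#' @param spots Spot table built from [spot_truth()] rows (may be empty).
#' @param background Per-channel background level: a single number or a
#'   named vector over `channels`.
#' @param noise_sd Per-channel additive Gaussian noise SD (single number or
#'   named vector). Zero disables noise.
#' @param poisson If `TRUE`, Poisson shot noise is applied to the noiseless
#'   intensity before the additive Gaussian term.
#' @param seed Integer seed used for every random draw during rendering.
#' @return An object of class `image_scene`.
#' @export
image_scene <- function(width_px = 128, height_px = 128,
                        pixel_size_um = 0.0645,
                        channels = c("ACA", "marker", "GFP", "DNA"),
                        spots = spot_truth(0, 0)[0, ],
                        background = 100,
                        noise_sd = 0,
                        poisson = FALSE,
                        seed = 1L) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be positive")
  }
  stopifnot(width_px >= 1, height_px >= 1,
            all(channels %in% c("ACA", "marker", "GFP", "DNA")),
            !anyDuplicated(channels))
  background <- expand_per_channel(background, channels, "background")
  noise_sd <- expand_per_channel(noise_sd, channels, "noise_sd")

  if (nrow(spots) > 0) {
    w_um <- width_px * pixel_size_um
    h_um <- height_px * pixel_size_um
    inside <- spots$x_um >= 0 & spots$x_um <= w_um &
      spots$y_um >= 0 & spots$y_um <= h_um
    if (!all(inside)) {
      stop("spot centroid(s) ", paste(which(!inside), collapse = ", "),
           " lie outside the ", round(w_um, 2), " x ", round(h_um, 2),
           " um image")
    }
    amp_channels <- unique(unlist(lapply(spots$amplitude, names)))
    if (!all(amp_channels %in% channels)) {
      stop("amplitude map names channel(s) not in the scene: ",
           paste(setdiff(amp_channels, channels), collapse = ", "))
    }
    ids <- spots$pair_id[!is.na(spots$pair_id)]
    if (length(ids) && any(table(ids) > 2)) {
      stop("a pair_id may group at most two sister spots")
    }
  }

  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_size_um = pixel_size_um, channels = channels, spots = spots,
         background = background, noise_sd = noise_sd,
         poisson = isTRUE(poisson), seed = as.integer(seed)),
    class = "image_scene"
  )
}

expand_per_channel <- function(x, channels, what) {
  if (length(x) == 1L && is.null(names(x))) {
    x <- stats::setNames(rep(as.numeric(x), length(channels)), channels)
  }
  if (!all(channels %in% names(x))) {
    stop(what, " must be a single number or a named vector covering all channels")
  }
  x[channels]
}

# peak-amplitude Gaussian on the pixel-centre grid (rows = y, cols = x)
render_gaussian <- function(width_px, height_px, pixel_size_um,
                            cx_um, cy_um, sigma_um, amp) {
  xs <- (seq_len(width_px) - 0.5) * pixel_size_um
  ys <- (seq_len(height_px) - 0.5) * pixel_size_um
  amp * exp(-outer((ys - cy_um)^2, (xs - cx_um)^2, "+") / (2 * sigma_um^2))
}

apply_noise <- function(img, noise_sd, poisson, channel_offset = 0L) {
  if (poisson) {
    img[] <- stats::rpois(length(img), lambda = pmax(img, 0))
  }
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise_sd)
  }
  img
}

#' Render a synthetic cell image
#'
#' Renders every channel of a scene as a 2-D intensity matrix: per-channel
#' constant background plus one isotropic Gaussian per spot per channel named
#' in its amplitude map, then the scene's noise model (seeded). For whole-cell
#' images the marker channel is placed at the spot centroid regardless of
#' `pool_model`; sub-diffraction pool structure only becomes resolvable on
#' chromosome spreads (see [generate_spread_image()]).
#'
#' @param scene An [image_scene()].
#' @return A list with `image` (named list of `height_px x width_px`
#'   matrices, one per channel) and `truth` (the spot table, one row per
#'   spot, with an added `peak_<channel>` column per amplitude channel).
#' @export
generate_cell_image <- function(scene) {
  stopifnot(inherits(scene, "image_scene"))
  imgs <- lapply(scene$channels, function(ch) {
    matrix(scene$background[[ch]], scene$height_px, scene$width_px)
  })
  names(imgs) <- scene$channels

  if (nrow(scene$spots) > 0) {
    for (i in seq_len(nrow(scene$spots))) {
      sp <- scene$spots[i, ]
      amp <- sp$amplitude[[1]]
      for (ch in names(amp)) {
        if (amp[[ch]] > 0) {
          imgs[[ch]] <- imgs[[ch]] + render_gaussian(
            scene$width_px, scene$height_px, scene$pixel_size_um,
            sp$x_um, sp$y_um, sp$sigma_um, amp[[ch]])
        }
      }
    }
  }

  imgs <- withr::with_seed(scene$seed, {
    for (ch in scene$channels) {
      imgs[[ch]] <- apply_noise(imgs[[ch]], scene$noise_sd[[ch]], scene$poisson)
    }
    imgs
  })

  list(image = imgs, truth = scene$spots)
}

#' Render a synthetic chromosome-spread image
#'
#' Each spot row of the scene is the anchor (midpoint) of one kinetochore
#' pair: two ACA foci are placed `inter_kt_sep_um` apart along a per-pair
#' axis, and the marker channel follows the anchor's `pool_model` —
#' `inner_only` puts one Gaussian at the midpoint, `dual_pool` two Gaussians
#' flanking the midpoint near each ACA focus (at `dual_offset_frac` of the
#' half-separation), `both` all three. The returned truth stores, per pair,
#' the analytic full width at half maximum of the marker profile along the
#' pair axis (outermost half-maximum crossings of the noiseless profile).
#'
#' @param scene An [image_scene()] whose spots are pair anchors, each with a
#'   distinct `pair_id`.
#' @param inter_kt_sep_um Sister-kinetochore separation in micrometres; must
#'   lie in (0, 1.5], the pairing cap used downstream.
#' @param dual_offset_frac Marker peak offset for `dual_pool`, as a fraction
#'   of the ACA half-separation (default 0.8, i.e. kinetochore-proximal).
#' @param axis_angle_rad Pair-axis orientation(s) in radians; a single value
#'   recycles over pairs; `NULL` (default) draws one per pair from the scene
#'   seed.
#' @return A list with `image` (named list of matrices), `truth` (one row per
#'   rendered ACA focus, exactly two per `pair_id`) and `pairs` (one row per
#'   pair: midpoint, axis, separation, pool model, marker sigma and
#'   `true_fwhm_um`).
#' @export
generate_spread_image <- function(scene, inter_kt_sep_um,
                                  dual_offset_frac = 0.8,
                                  axis_angle_rad = NULL) {
  stopifnot(inherits(scene, "image_scene"))
  if (!is.numeric(inter_kt_sep_um) || inter_kt_sep_um <= 0 ||
      inter_kt_sep_um > 1.5) {
    stop("inter_kt_sep_um must lie in (0, 1.5] um")
  }
  extent <- min(scene$width_px, scene$height_px) * scene$pixel_size_um
  if (inter_kt_sep_um > extent) {
    stop("separation exceeds the image extent")
  }
  anchors <- scene$spots
  if (nrow(anchors) == 0) stop("a spread scene needs at least one pair anchor")
  if (any(is.na(anchors$pair_id)) || anyDuplicated(anchors$pair_id)) {
    stop("every anchor must carry a distinct pair_id")
  }

  n <- nrow(anchors)
  angles <- if (is.null(axis_angle_rad)) {
    withr::with_seed(scene$seed, stats::runif(n, 0, pi))
  } else {
    rep_len(axis_angle_rad, n)
  }
  half <- inter_kt_sep_um / 2

  spot_rows <- list()
  pair_rows <- list()
  for (i in seq_len(n)) {
    an <- anchors[i, ]
    amp <- an$amplitude[[1]]
    ux <- cos(angles[i]); uy <- sin(angles[i])
    aca_amp <- amp[intersect(names(amp), "ACA")]
    marker_amp <- if ("marker" %in% names(amp)) amp[["marker"]] else 0

    # two sister ACA foci
    for (s in c(-1, 1)) {
      spot_rows[[length(spot_rows) + 1L]] <- spot_truth(
        an$x_um + s * half * ux, an$y_um + s * half * uy,
        sigma_um = an$sigma_um,
        amplitude = if (length(aca_amp)) aca_amp else c(ACA = 0),
        pair_id = an$pair_id, pool_model = an$pool_model)
    }

    # marker pools along the pair axis
    marker_positions <- switch(an$pool_model,
      inner_only = 0,
      dual_pool = c(-1, 1) * dual_offset_frac * half,
      both = c(-dual_offset_frac * half, 0, dual_offset_frac * half))
    if (marker_amp > 0) {
      for (d in marker_positions) {
        # pool Gaussians are not kinetochore foci: no pair_id, so the
        # two-sisters-per-pair invariant refers to the ACA spots only
        spot_rows[[length(spot_rows) + 1L]] <- spot_truth(
          an$x_um + d * ux, an$y_um + d * uy, sigma_um = an$sigma_um,
          amplitude = c(marker = marker_amp),
          pair_id = NA_integer_, pool_model = an$pool_model)
      }
    }

    pair_rows[[i]] <- tibble::tibble(
      pair_id = an$pair_id, mid_x_um = an$x_um, mid_y_um = an$y_um,
      axis_x = ux, axis_y = uy, separation_um = inter_kt_sep_um,
      pool_model = an$pool_model, marker_sigma_um = an$sigma_um,
      true_fwhm_um = analytic_profile_fwhm(marker_positions, an$sigma_um)
    )
  }

  all_spots <- dplyr::bind_rows(spot_rows)
  render_scene <- image_scene(
    width_px = scene$width_px, height_px = scene$height_px,
    pixel_size_um = scene$pixel_size_um, channels = scene$channels,
    spots = all_spots, background = scene$background,
    noise_sd = scene$noise_sd, poisson = scene$poisson, seed = scene$seed)
  out <- generate_cell_image(render_scene)
  list(image = out$image, truth = out$truth,
       pairs = dplyr::bind_rows(pair_rows))
}

# FWHM (outermost half-max crossings, zero baseline) of a sum of unit
# Gaussians centred at `positions` with common width sigma, evaluated densely
analytic_profile_fwhm <- function(positions, sigma_um, halfspan_um = 1) {
  t <- seq(-halfspan_um, halfspan_um, by = 1e-4)
  y <- rowSums(vapply(positions,
                      function(p) exp(-(t - p)^2 / (2 * sigma_um^2)),
                      numeric(length(t))))
  res <- fwhm_from_samples(t, y, baseline = 0)
  res$fwhm
}

#' Describe and sample a mass-photometry event mixture
#'
#' `mass_mixture()` specifies a Gaussian mixture of molecular-mass
#' populations; `generate_mass_events()` draws a seeded event list from it,
#' emulating per-particle mass measurements of a cross-linked sample.
#'
#' @param components A data frame with columns `mean_kD`, `sd_kD`, `weight`
#'   (weights are normalized to sum to one).
#' @param n_events Number of single-particle events to draw.
#' @param seed Integer seed.
#' @return `mass_mixture()` returns a `mass_mixture` object;
#'   `generate_mass_events()` a numeric vector of masses in kilodaltons.
#' @examples
#' mix <- mass_mixture(data.frame(mean_kD = 193, sd_kD = 29, weight = 1),
#'                     n_events = 5000, seed = 7)
#' head(generate_mass_events(mix))
#' @export
mass_mixture <- function(components, n_events, seed = 1L) {
  components <- tibble::as_tibble(components)
  if (nrow(components) == 0) stop("at least one mixture component is required")
  stopifnot(all(c("mean_kD", "sd_kD", "weight") %in% names(components)),
            all(components$sd_kD >= 0), all(components$weight > 0),
            n_events >= 1)
  components$weight <- components$weight / sum(components$weight)
  structure(list(components = components, n_events = as.integer(n_events),
                 seed = as.integer(seed)),
            class = "mass_mixture")
}

#' @rdname mass_mixture
#' @param mix A `mass_mixture`.
#' @export
generate_mass_events <- function(mix) {
  stopifnot(inherits(mix, "mass_mixture"))
  comp <- mix$components
  withr::with_seed(mix$seed, {
    idx <- sample.int(nrow(comp), mix$n_events, replace = TRUE,
                      prob = comp$weight)
    stats::rnorm(mix$n_events, comp$mean_kD[idx], comp$sd_kD[idx])
  })
}

#' Write / read a multi-channel scene image as TIFF
#'
#' One TIFF page per channel (channel name in the page description tag),
#' with a YAML sidecar recording channel order, pixel size and the intensity
#' scale used to map arbitrary intensity units into TIFF's unit range.
#'
#' @param image Named list of intensity matrices.
#' @param path Output TIFF path; the sidecar is written at `<path>.yaml`.
#' @param pixel_size_um Pixel size recorded in the sidecar.
#' @return `write_scene_tiff()` returns `path` invisibly; `read_scene_tiff()`
#'   returns a list with `image` (named matrices, original intensity scale)
#'   and `pixel_size_um`.
#' @export
write_scene_tiff <- function(image, path, pixel_size_um = NA_real_) {
  stopifnot(is.list(image), !is.null(names(image)))
  scale <- max(1, vapply(image, max, numeric(1)))
  pages <- lapply(names(image), function(ch) {
    m <- pmax(image[[ch]], 0) / scale
    attr(m, "description") <- ch
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(
    list(channels = names(image), intensity_scale = scale,
         pixel_size_um = pixel_size_um),
    paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_scene_tiff
#' @export
read_scene_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == length(meta$channels))
  image <- lapply(pages, function(p) p * meta$intensity_scale)
  names(image) <- meta$channels
  list(image = image, pixel_size_um = meta$pixel_size_um)
}

#' Write / read a spot-truth table as CSV
#'
#' The list-column amplitude map is flattened to `amp_<channel>` columns on
#' disk.
#'
#' @param truth Spot table from [spot_truth()] rows.
#' @param path CSV path.
#' @return `write_truth_csv()` returns `path` invisibly; `read_truth_csv()`
#'   the reconstructed spot table.
#' @export
write_truth_csv <- function(truth, path) {
  channels <- unique(unlist(lapply(truth$amplitude, names)))
  flat <- dplyr::select(truth, -"amplitude")
  for (ch in channels) {
    flat[[paste0("amp_", ch)]] <- vapply(
      truth$amplitude, function(a) if (ch %in% names(a)) a[[ch]] else 0,
      numeric(1))
  }
  readr::write_csv(flat, path)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE)
  amp_cols <- grep("^amp_", names(flat), value = TRUE)
  channels <- sub("^amp_", "", amp_cols)
  amplitude <- lapply(seq_len(nrow(flat)), function(i) {
    a <- as.numeric(flat[i, amp_cols])
    names(a) <- channels
    a[a > 0]
  })
  out <- dplyr::select(flat, -dplyr::all_of(amp_cols))
  out$amplitude <- amplitude
  out$pair_id <- as.integer(out$pair_id)
  dplyr::relocate(tibble::as_tibble(out), "amplitude",
                  .after = "sigma_um")
}
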