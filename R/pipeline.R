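#' Seeded random spot layout for a synthetic cell
#'
#' Places spot centroids uniformly in the image interior with a minimum
#' pairwise distance (rejection sampling) and a margin to the border, so
#' rendered foci stay well separated and rings never clip.
#'
#' @param n_spots Number of spots.
#' @param width_px,height_px,pixel_size_um Image geometry.
#' @param amplitude Named per-channel amplitude vector given to every spot.
#' @param sigma_um Spot width.
#' @param min_dist_um Minimum centre-to-centre distance.
#' @param margin_um Margin to the image border.
#' @param seed Integer seed.
#' @return A spot table acceptable to [image_scene()].
#' @export
random_scene_spots <- function(n_spots, width_px = 128, height_px = 128,
                               pixel_size_um = 0.0645,
                               amplitude = c(ACA = 1000, marker = 600),
                               sigma_um = 0.15, min_dist_um = 1.2,
                               margin_um = 1.1, seed = 1L) {
  w <- width_px * pixel_size_um
  h <- height_px * pixel_size_um
  stopifnot(w > 2 * margin_um, h > 2 * margin_um)
  pts <- withr::with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n_spots && tries < 20000L) {
      tries <- tries + 1L
      x <- stats::runif(1, margin_um, w - margin_um)
      y <- stats::runif(1, margin_um, h - margin_um)
      if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= min_dist_um^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    list(x = xs, y = ys)
  })
  if (length(pts$x) < n_spots) {
    stop("could not place ", n_spots, " spots at min_dist_um = ", min_dist_um,
         " in this field; reduce the density")
  }
  purrr::map_dfr(seq_len(n_spots), function(i) {
    spot_truth(pts$x[i], pts$y[i], sigma_um = sigma_um, amplitude = amplitude)
  })
}

#' Measure FWHM for every kinetochore pair of a spread image
#'
#' End-to-end spread analysis: detect foci on the ACA channel, pair them by
#' mutual nearest neighbours under the separation cap, extract the 2-um
#' marker line profile through each pair, and measure its full width at half
#' maximum.
#'
#' @param image Named list of channel matrices with `ACA` and
#'   `marker_channel`.
#' @param pixel_size_um Pixel size.
#' @param marker_channel Channel to profile.
#' @param params [detection_params()] for the ACA detection.
#' @param max_sep_um Pairing cap.
#' @return A tibble with one row per measured pair: `pair_id`,
#'   `separation_um`, `fwhm_um`, `n_crossings`. Pairs whose profile leaves
#'   the image or has no interior half-max crossings are dropped.
#' @export
analyze_spread <- function(image, pixel_size_um = 0.0645,
                           marker_channel = "marker",
                           params = detection_params(), max_sep_um = 1.5) {
  foci <- detect_foci(image$ACA, params, pixel_size_um)
  if (nrow(foci) < 2) return(tibble::tibble(
    pair_id = integer(), separation_um = numeric(), fwhm_um = numeric(),
    n_crossings = integer()))
  pr <- assign_pairs(foci[, c("x_um", "y_um")], max_sep_um)
  purrr::map_dfr(seq_len(nrow(pr$pairs)), function(i) {
    pair <- pr$pairs[i, ]
    prof <- extract_profile(image[marker_channel], pair, pixel_size_um)
    prof$channel <- marker_channel
    if (any(prof$flagged)) return(NULL)
    res <- tryCatch(fwhm(prof, marker_channel), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble::tibble(pair_id = pair$pair_id,
                                    separation_um = pair$separation_um), res)
  })
}

#' Generate and analyze one synthetic spread condition
#'
#' Renders as many spread images as needed to measure `n_pairs` kinetochore
#' pairs under one marker pool model, runs [analyze_spread()] on each, and
#' returns the per-pair FWHM table with the analytic truth attached.
#'
#' @param n_pairs Pairs to measure.
#' @param pool_model `"inner_only"`, `"dual_pool"` or `"both"`.
#' @param seed Integer seed (drives layout, axis angles and noise).
#' @param sep_um Sister separation.
#' @param sigma_um Marker/ACA spot width.
#' @param aca_amplitude,marker_amplitude Peak amplitudes.
#' @param background,noise_sd Image background and Gaussian noise SD.
#' @param pixel_size_um Pixel size.
#' @return A tibble: `condition` (the pool model), `pair_id`,
#'   `separation_um`, `fwhm_um`, `true_fwhm_um`.
#' @export
spread_condition <- function(n_pairs, pool_model, seed = 1L, sep_um = 1,
                             sigma_um = 0.15, aca_amplitude = 1000,
                             marker_amplitude = 800, background = 100,
                             noise_sd = 3, pixel_size_um = 0.0645) {
  anchors_per_image <- 4L
  n_images <- ceiling(n_pairs / anchors_per_image)
  # fixed 2x2 anchor grid: 2-um windows never clip a 8.25-um field or each other
  grid <- expand.grid(x = c(2.1, 6.1), y = c(2.1, 6.1))

  out <- purrr::map_dfr(seq_len(n_images), function(im) {
    spots <- purrr::map_dfr(seq_len(anchors_per_image), function(i) {
      spot_truth(grid$x[i], grid$y[i], sigma_um = sigma_um,
                 amplitude = c(ACA = aca_amplitude, marker = marker_amplitude),
                 pair_id = i, pool_model = pool_model)
    })
    scene <- image_scene(width_px = 128, height_px = 128,
                         pixel_size_um = pixel_size_um,
                         channels = c("ACA", "marker"), spots = spots,
                         background = background, noise_sd = noise_sd,
                         seed = seed + im)
    sp <- generate_spread_image(scene, inter_kt_sep_um = sep_um)
    meas <- analyze_spread(sp$image, pixel_size_um)
    meas$true_fwhm_um <- sp$pairs$true_fwhm_um[1]
    meas$image_id <- im
    meas
  })
  out <- utils::head(out, n_pairs)
  dplyr::bind_cols(tibble::tibble(condition = pool_model)[rep(1, nrow(out)), ,
                                                          drop = FALSE], out)
}

#' Generate and quantify one synthetic rescue condition
#'
#' Renders `n_cells` whole-cell images with randomly placed centromere foci
#' at a given marker amplitude and runs the ring quantification on each.
#'
#' @param condition Condition label attached to every measurement.
#' @param n_cells Number of cells (images).
#' @param n_spots Foci per cell.
#' @param marker_amplitude Marker peak amplitude (the generator's ground
#'   truth for relative abundance across conditions).
#' @param seed Integer seed; cell `i` uses `seed + i`.
#' @param aca_amplitude,background,noise_sd,sigma_um,pixel_size_um Scene
#'   parameters.
#' @param ring_width_px Ring width for [measure_ring()].
#' @return Row-bound [measure_cell()] output.
#' @export
cell_condition <- function(condition, n_cells = 10, n_spots = 20,
                           marker_amplitude = 600, seed = 1L,
                           aca_amplitude = 1000, background = 100,
                           noise_sd = 3, sigma_um = 0.15,
                           pixel_size_um = 0.0645, ring_width_px = 3) {
  purrr::map_dfr(seq_len(n_cells), function(i) {
    spots <- random_scene_spots(
      n_spots, amplitude = c(ACA = aca_amplitude, marker = marker_amplitude),
      sigma_um = sigma_um, pixel_size_um = pixel_size_um, seed = seed + i)
    scene <- image_scene(width_px = 128, height_px = 128,
                         pixel_size_um = pixel_size_um,
                         channels = c("ACA", "marker"), spots = spots,
                         background = background, noise_sd = noise_sd,
                         seed = seed + i)
    img <- generate_cell_image(scene)
    measure_cell(img$image, cell_id = paste0(condition, "_", i),
                 condition = condition, ring_width_px = ring_width_px,
                 pixel_size_um = pixel_size_um)
  })
}

validate_config <- function(config) {
  need <- function(cond, field) {
    if (!cond) stop("invalid pipeline config: field '", field,
                    "' is missing or invalid", call. = FALSE)
  }
  need(is.list(config), "(root)")
  need(!is.null(config$analysis) &&
         config$analysis %in% c("itc", "centromere", "spread", "tethering",
                                "massphot"), "analysis")
  need(!is.null(config[[config$analysis]]), config$analysis)
  sec <- config[[config$analysis]]
  switch(config$analysis,
    itc = {
      need(!is.null(sec$scheme$syringe_conc_uM), "itc.scheme.syringe_conc_uM")
      need(!is.null(sec$scheme$cell_conc_uM), "itc.scheme.cell_conc_uM")
      need(!is.null(sec$params$KD_nM), "itc.params.KD_nM")
      need(!is.null(sec$params$dH_kcal_mol), "itc.params.dH_kcal_mol")
    },
    centromere = {
      need(length(sec$conditions) >= 1, "centromere.conditions")
      for (i in seq_along(sec$conditions)) {
        need(!is.null(sec$conditions[[i]]$name),
             paste0("centromere.conditions[", i, "].name"))
        need(!is.null(sec$conditions[[i]]$marker_amplitude),
             paste0("centromere.conditions[", i, "].marker_amplitude"))
      }
      need(!is.null(sec$reference), "centromere.reference")
    },
    spread = {
      need(length(sec$conditions) >= 1, "spread.conditions")
      for (i in seq_along(sec$conditions)) {
        need(!is.null(sec$conditions[[i]]$pool_model),
             paste0("spread.conditions[", i, "].pool_model"))
      }
    },
    tethering = {
      need(length(sec$conditions) >= 1, "tethering.conditions")
      need(!is.null(sec$control), "tethering.control")
    },
    massphot = {
      need(!is.null(sec$components) || !is.null(sec$events_csv),
           "massphot.components")
    })
  invisible(TRUE)
}

#' Run one configured analysis end to end
#'
#' Configuration-driven orchestration of the five analyses (`itc`,
#' `centromere`, `spread`, `tethering`, `massphot`) on synthetic, seeded
#' inputs (or CSV inputs where the config names files). Deterministic given
#' the config and seed: running the same config twice produces identical
#' tables.
#'
#' @param config Path to a YAML config file, or an equivalent nested list.
#'   Top-level fields: `analysis`, `seed`, and one section named after the
#'   analysis. Schema violations are reported with their field path before
#'   any computation.
#' @param seed Optional integer overriding `config$seed`.
#' @return A named list of result tibbles (class `cpcquant_results`), ready
#'   for [write_report()].
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  sec <- config[[config$analysis]]

  results <- switch(config$analysis,
    itc = {
      sch_args <- sec$scheme
      if (!is.null(sch_args$injection_volumes_ul)) {
        sch_args$injection_volumes_ul <- as.numeric(sch_args$injection_volumes_ul)
      }
      scheme <- do.call(titration_scheme, sch_args)
      iso <- if (!is.null(sec$isotherm_csv)) {
        read_isotherm_csv(sec$isotherm_csv)
      } else {
        params <- binding_parameters(
          N = sec$params$N %||% 1,
          KD_M = sec$params$KD_nM * 1e-9,
          dH_kcal_mol = sec$params$dH_kcal_mol,
          dilution_offset_kcal_mol = sec$params$dilution_offset_kcal_mol %||% 0)
        simulate_isotherm(scheme, params,
                          noise_sd_kcal_mol = sec$noise_sd_kcal_mol %||% 0,
                          seed = seed)
      }
      fit <- fit_isotherm(iso, scheme)
      list(isotherm = iso, fit = glance(fit), fit_terms = tidy(fit),
           .fit_object = fit)
    },
    centromere = {
      meas <- purrr::map_dfr(seq_along(sec$conditions), function(i) {
        cnd <- sec$conditions[[i]]
        cell_condition(cnd$name,
                       n_cells = cnd$n_cells %||% 10,
                       n_spots = cnd$n_spots %||% 20,
                       marker_amplitude = cnd$marker_amplitude,
                       seed = seed + 1000L * i)
      })
      norm <- normalize_condition(meas, sec$reference)
      kept <- norm[!norm$flagged, ]
      kd <- if (length(unique(kept$condition)) >= 2) {
        kruskal_dunn(dplyr::transmute(kept, value = .data$normalized,
                                      group = .data$condition))
      } else NULL
      means <- dplyr::summarise(dplyr::group_by(kept, .data$condition),
                                mean_normalized = mean(.data$normalized),
                                n = dplyr::n(), .groups = "drop")
      c(list(measurements = norm, condition_means = means),
        if (!is.null(kd)) list(test = glance(kd), pairwise = tidy(kd)))
    },
    spread = {
      meas <- purrr::map_dfr(seq_along(sec$conditions), function(i) {
        cnd <- sec$conditions[[i]]
        spread_condition(n_pairs = cnd$n_pairs %||% 50,
                         pool_model = cnd$pool_model,
                         sep_um = cnd$sep_um %||% 1,
                         seed = seed + 1000L * i)
      })
      means <- dplyr::summarise(dplyr::group_by(meas, .data$condition),
                                mean_fwhm_um = mean(.data$fwhm_um),
                                n = dplyr::n(), .groups = "drop")
      kd <- if (length(unique(meas$condition)) >= 2) {
        kruskal_dunn(dplyr::transmute(meas, value = .data$fwhm_um,
                                      group = .data$condition))
      } else NULL
      c(list(pairs = meas, condition_means = means),
        if (!is.null(kd)) list(test = glance(kd), pairwise = tidy(kd)))
    },
    tethering = {
      ratios <- purrr::map_dfr(seq_along(sec$conditions), function(i) {
        cnd <- sec$conditions[[i]]
        n_foci <- cnd$n_foci %||% 20
        purrr::map_dfr(seq_len(n_foci), function(j) {
          s <- seed + 1000L * i + j
          spots <- spot_truth(4.1, 4.1, sigma_um = 0.2,
                              amplitude = c(GFP = cnd$gfp_amplitude %||% 500,
                                            marker = cnd$target_amplitude))
          scene <- image_scene(channels = c("marker", "GFP"), spots = spots,
                               background = 100, noise_sd = 3, seed = s)
          img <- generate_cell_image(scene)$image
          foci <- detect_foci(img$GFP)
          if (nrow(foci) != 1) return(NULL)
          rr <- recruitment_ratio(img$marker, img$GFP, foci[1, ])
          dplyr::bind_cols(tibble::tibble(condition = cnd$name, focus = j), rr)
        })
      })
      kept <- ratios[!ratios$flagged, ]
      ad <- if (length(unique(kept$condition)) >= 2) {
        anova_dunnett(dplyr::transmute(kept, value = .data$ratio,
                                       group = .data$condition),
                      control = sec$control)
      } else NULL
      c(list(ratios = ratios),
        if (!is.null(ad)) list(test = glance(ad), comparisons = tidy(ad)))
    },
    massphot = {
      masses <- if (!is.null(sec$events_csv)) {
        readr::read_csv(sec$events_csv, show_col_types = FALSE)$mass_kD
      } else {
        generate_mass_events(mass_mixture(
          purrr::map_dfr(sec$components, tibble::as_tibble),
          n_events = sec$n_events %||% 5000, seed = seed))
      }
      peaks <- kde_peaks(masses, bandwidth_kD = sec$bandwidth_kD %||% NULL)
      if (!is.null(sec$candidates)) {
        cand <- purrr::map(sec$candidates,
                           ~ purrr::map_dfr(.x, tibble::as_tibble))
        peaks <- assign_species(peaks, cand, tol_sd = sec$tol_sd %||% 1)
      }
      list(events = tibble::tibble(mass_kD = masses), peaks = peaks)
    })

  structure(c(results,
              list(.config = config, .seed = seed,
                   .analysis = config$analysis)),
            class = "cpcquant_results")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a report bundle from pipeline results
#'
#' Writes every result table as CSV into the output directory, a
#' `parameters.yaml` provenance file (config, seed, package version) and a
#' plain-text log. Optionally renders the analysis-appropriate figure
#' (isotherm with fit curve, normalized scatter panel, mass histogram) as a
#' PDF.
#'
#' @param results A `cpcquant_results` object from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param plots Render figures as well?
#' @return Invisibly, the character vector of files written.
#' @export
write_report <- function(results, dir, plots = FALSE) {
  stopifnot(inherits(results, "cpcquant_results"))
  tables <- results[!startsWith(names(results), ".")]
  tables <- tables[vapply(tables, is.data.frame, logical(1))]
  if (!length(tables)) stop("results contain no tables to report")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir)
  }
  files <- character()
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], f)
    files <- c(files, f)
  }
  prov <- file.path(dir, "parameters.yaml")
  yaml::write_yaml(list(analysis = results$.analysis, seed = results$.seed,
                        package_version = as.character(
                          utils::packageVersion("cpcquant")),
                        config = results$.config), prov)
  files <- c(files, prov)
  logf <- file.path(dir, "run.log")
  writeLines(c(paste("analysis:", results$.analysis),
               paste("seed:", results$.seed),
               paste("tables:", paste(names(tables), collapse = ", "))), logf)
  files <- c(files, logf)

  if (plots) {
    pf <- file.path(dir, "figure.pdf")
    p <- switch(results$.analysis,
      itc = if (!is.null(results$.fit_object)) autoplot(results$.fit_object),
      centromere = plot_normalized(results$measurements),
      massphot = plot_mass_events(results$events$mass_kD, results$peaks),
      spread = ggplot2::ggplot(results$pairs,
                               ggplot2::aes(.data$condition, .data$fwhm_um)) +
        ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
        ggplot2::labs(y = "FWHM (um)") + ggplot2::theme_classic(),
      tethering = ggplot2::ggplot(results$ratios[!results$ratios$flagged, ],
                                  ggplot2::aes(.data$condition, .data$ratio)) +
        ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
        ggplot2::labs(y = "marker / GFP ratio") + ggplot2::theme_classic())
    if (!is.null(p)) {
      ggplot2::ggsave(pf, p, width = 5, height = 4)
      files <- c(files, pf)
    }
  }
  invisible(files)
}
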