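#' Calculated mass of a protein complex
#'
#' Sums `copies x monomer_mass` over the components of a stated
#' stoichiometry, e.g. a 2:2 complex of two dimers. Additive and
#' order-independent.
#'
#' @param components A data frame with columns `name`, `monomer_mass_kD`,
#'   `copies`.
#' @return Total mass in kilodaltons.
#' @examples
#' complex_mass(data.frame(name = c("CPC_dimer", "Sgo1_dimer"),
#'                         monomer_mass_kD = c(108.8, 94.8),
#'                         copies = c(1, 1)))  # 203.6
#' @export
complex_mass <- function(components) {
  components <- tibble::as_tibble(components)
  if (nrow(components) == 0) stop("empty complex composition")
  stopifnot(all(c("monomer_mass_kD", "copies") %in% names(components)),
            all(components$monomer_mass_kD > 0),
            all(components$copies >= 1),
            all(components$copies == round(components$copies)))
  sum(components$monomer_mass_kD * components$copies)
}

#' Call peaks in a mass-photometry event sample
#'
#' Gaussian kernel density estimate over the event masses; peaks are local
#' density maxima above a floor (a fraction of the global maximum). Each
#' peak is summarized as mean +/- SD of the events within +/- 2 bandwidths
#' of the density maximum, with a weight equal to the fraction of events in
#' that window.
#'
#' @param masses Numeric vector of per-event masses in kilodaltons (at least
#'   10 events).
#' @param bandwidth_kD Kernel bandwidth; `NULL` (default) uses Silverman's
#'   rule of thumb on the event list.
#' @param weight_floor Minimum peak density as a fraction of the maximum
#'   density (default 0.05).
#' @return A tibble of peaks, strongest first: `location_kD` (density
#'   maximum), `mean_kD`, `sd_kD`, `weight`, `n_events`.
#' @examples
#' ev <- generate_mass_events(mass_mixture(
#'   data.frame(mean_kD = 193, sd_kD = 29, weight = 1), 5000, seed = 1))
#' kde_peaks(ev)
#' @export
kde_peaks <- function(masses, bandwidth_kD = NULL, weight_floor = 0.05) {
  stopifnot(is.numeric(masses), length(masses) >= 10)
  if (is.null(bandwidth_kD)) bandwidth_kD <- stats::bw.nrd0(masses)
  if (bandwidth_kD <= 0) {
    stop("bandwidth must be positive (all-identical masses need an explicit ",
         "bandwidth)")
  }
  d <- stats::density(masses, bw = bandwidth_kD, n = 2048)
  y <- d$y
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  is_peak <- is_peak & y >= weight_floor * max(y)
  locs <- d$x[is_peak]
  if (!length(locs)) return(tibble::tibble(
    location_kD = numeric(), mean_kD = numeric(), sd_kD = numeric(),
    weight = numeric(), n_events = integer()))

  out <- purrr::map_dfr(locs, function(loc) {
    sel <- masses >= loc - 2 * bandwidth_kD & masses <= loc + 2 * bandwidth_kD
    tibble::tibble(location_kD = loc,
                   mean_kD = mean(masses[sel]),
                   sd_kD = stats::sd(masses[sel]),
                   weight = mean(sel),
                   n_events = sum(sel))
  })
  out[order(-out$weight), ]
}

#' Assign species identities to mass peaks
#'
#' Matches each called peak to the candidate complex whose calculated mass
#' is closest, provided the distance does not exceed `tol_sd` peak standard
#' deviations; otherwise the peak is explicitly unassigned. Ties in distance
#' are broken towards the smaller calculated mass.
#'
#' @param peaks Peak tibble from [kde_peaks()] (needs `location_kD` and
#'   `sd_kD`).
#' @param candidates Named list of complex compositions (each a data frame
#'   accepted by [complex_mass()]).
#' @param tol_sd Assignment tolerance in units of the peak SD.
#' @return The peak tibble with `species` (candidate name or `NA`),
#'   `calc_mass_kD` and `distance_kD` columns added.
#' @export
assign_species <- function(peaks, candidates, tol_sd = 1) {
  if (!length(candidates)) stop("no candidate compositions supplied")
  stopifnot(!is.null(names(candidates)), tol_sd > 0)
  calc <- vapply(candidates, complex_mass, numeric(1))
  ord <- order(calc)  # ties in distance resolve to the smaller mass
  calc <- calc[ord]

  res <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    dist <- abs(peaks$location_kD[i] - calc)
    j <- which.min(dist)
    if (dist[j] <= tol_sd * peaks$sd_kD[i]) {
      tibble::tibble(species = names(calc)[j], calc_mass_kD = unname(calc[j]),
                     distance_kD = unname(dist[j]))
    } else {
      tibble::tibble(species = NA_character_, calc_mass_kD = NA_real_,
                     distance_kD = unname(dist[j]))
    }
  })
  dplyr::bind_cols(peaks, res)
}

#' Histogram-plus-KDE plot of a mass-event sample
#'
#' @param masses Numeric vector of event masses (kD).
#' @param peaks Optional peak tibble from [kde_peaks()] to annotate.
#' @param binwidth_kD Histogram bin width.
#' @return A ggplot object.
#' @export
plot_mass_events <- function(masses, peaks = NULL, binwidth_kD = 10) {
  p <- ggplot2::ggplot(tibble::tibble(mass_kD = masses),
                       ggplot2::aes(.data$mass_kD)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth_kD, fill = "grey80",
                            colour = "grey40") +
    ggplot2::geom_density(colour = "firebrick") +
    ggplot2::labs(x = "mass (kD)", y = "density") +
    ggplot2::theme_classic()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_vline(data = peaks,
                                 ggplot2::aes(xintercept = .data$location_kD),
                                 linetype = 2)
  }
  p
}
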