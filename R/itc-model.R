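#' Define an ITC titration scheme
#'
#' A titration scheme records the instrument-side design of a single
#' isothermal titration calorimetry (ITC) run: cell volume, syringe and cell
#' concentrations, the ordered injection series, injection spacing and
#' temperature. Defaults mirror a common small-volume protocol: a 200 ul cell
#' and 16 injections (one 0.5 ul pre-injection followed by 15 x 2.5 ul),
#' 180 s apart, at 20 C.
#'
#' @param cell_volume_ul Active cell volume in microlitres.
#' @param syringe_conc_uM Titrant (syringe) concentration in micromolar.
#' @param cell_conc_uM Analyte (cell) concentration in micromolar.
#' @param injection_volumes_ul Ordered injection volumes in microlitres.
#' @param spacing_s Time between injections in seconds (metadata only).
#' @param temperature_C Run temperature in degrees Celsius.
#' @param exclude_first Should the first (pre-)injection be excluded from
#'   fitting? The customary small first aliquot is diluted by diffusion across
#'   the syringe tip and carries an unreliable heat.
#' @return An object of class `titration_scheme`.
#' @examples
#' titration_scheme(syringe_conc_uM = 50, cell_conc_uM = 5)
#' @export
titration_scheme <- function(cell_volume_ul = 200,
                             syringe_conc_uM,
                             cell_conc_uM,
                             injection_volumes_ul = c(0.5, rep(2.5, 15)),
                             spacing_s = 180,
                             temperature_C = 20,
                             exclude_first = TRUE) {
  stopifnot(
    is.numeric(cell_volume_ul), length(cell_volume_ul) == 1L, cell_volume_ul > 0,
    is.numeric(syringe_conc_uM), syringe_conc_uM > 0,
    is.numeric(cell_conc_uM), cell_conc_uM > 0,
    is.numeric(injection_volumes_ul), length(injection_volumes_ul) >= 1L,
    all(injection_volumes_ul > 0)
  )
  if (sum(injection_volumes_ul) >= cell_volume_ul) {
    stop("cumulative injected volume (", sum(injection_volumes_ul),
         " ul) must stay below the cell volume (", cell_volume_ul, " ul)")
  }
  structure(
    list(
      cell_volume_ul = cell_volume_ul,
      syringe_conc_uM = syringe_conc_uM,
      cell_conc_uM = cell_conc_uM,
      injection_volumes_ul = injection_volumes_ul,
      spacing_s = spacing_s,
      temperature_C = temperature_C,
      exclude_first = isTRUE(exclude_first)
    ),
    class = "titration_scheme"
  )
}

#' @export
print.titration_scheme <- function(x, ...) {
  cat("ITC titration scheme\n")
  cat(sprintf("  cell: %g ul of %g uM analyte\n", x$cell_volume_ul, x$cell_conc_uM))
  cat(sprintf("  syringe: %g uM titrant, %d injections (%g ul total)\n",
              x$syringe_conc_uM, length(x$injection_volumes_ul),
              sum(x$injection_volumes_ul)))
  cat(sprintf("  %g s spacing, %g C, first injection %s\n",
              x$spacing_s, x$temperature_C,
              if (x$exclude_first) "excluded" else "included"))
  invisible(x)
}

#' Define single-site binding parameters
#'
#' Parameters of the 1:1 (single-site) binding model: stoichiometry `N`
#' (binding sites per analyte molecule), dissociation constant, binding
#' enthalpy per mole of titrant, and a constant heat-of-dilution offset per
#' mole injected.
#'
#' @param N Stoichiometry (sites per analyte molecule), dimensionless.
#' @param KD_M Dissociation constant in molar.
#' @param dH_kcal_mol Binding enthalpy, kcal per mole of titrant.
#' @param dilution_offset_kcal_mol Constant heat of dilution per mole
#'   injected, kcal/mol. Modelling dilution as a fitted constant is the usual
#'   alternative to explicit blank-titration subtraction.
#' @return An object of class `binding_parameters`.
#' @examples
#' binding_parameters(N = 1, KD_M = 52.83e-9, dH_kcal_mol = -6.58)
#' @export
binding_parameters <- function(N = 1, KD_M, dH_kcal_mol,
                               dilution_offset_kcal_mol = 0) {
  stopifnot(is.numeric(N), N > 0, is.numeric(KD_M), KD_M > 0,
            is.numeric(dH_kcal_mol), is.numeric(dilution_offset_kcal_mol))
  structure(
    list(N = N, KD_M = KD_M, dH_kcal_mol = dH_kcal_mol,
         dilution_offset_kcal_mol = dilution_offset_kcal_mol),
    class = "binding_parameters"
  )
}

# Forward model: per-injection normalized heats for a 1:1 binding isotherm.
#
# Total concentrations in the perfusion cell after cumulative injected volume
# V use the standard displacement corrections
#   M_i = M0 * (1 - V/2V0) / (1 + V/2V0)   (analyte)
#   X_i = Xs * (V/V0)      / (1 + V/2V0)   (titrant)
# and the bound complex concentration solves the single-site quadratic
#   [MX] = 1/2 * ( (N*M + X + KD) - sqrt((N*M + X + KD)^2 - 4*N*M*X) ).
# The heat content of the cell is Q_i = [MX]_i * dH * V0; the measured heat of
# injection i corrects for the aliquot of cell content displaced into the
# overflow at the mean of the before/after compositions:
#   dQ_i = Q_i - Q_{i-1} + (v_i/V0) * (Q_i + Q_{i-1}) / 2,
# normalized by the moles of titrant injected.
isotherm_heats <- function(scheme, N, KD_M, dH, offset = 0) {
  v  <- scheme$injection_volumes_ul          # ul
  V0 <- scheme$cell_volume_ul                # ul
  M0 <- scheme$cell_conc_uM * 1e-6           # M
  Xs <- scheme$syringe_conc_uM * 1e-6        # M
  V  <- cumsum(v)

  Mtot <- M0 * (1 - V / (2 * V0)) / (1 + V / (2 * V0))
  Xtot <- Xs * (V / V0) / (1 + V / (2 * V0))

  b  <- N * Mtot + Xtot + KD_M
  MX <- 0.5 * (b - sqrt(pmax(b^2 - 4 * N * Mtot * Xtot, 0)))

  Q  <- MX * dH * V0 * 1e-6                  # kcal (V0 ul -> litres)
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev + (v / V0) * (Q + Qprev) / 2
  moles_injected <- Xs * v * 1e-6            # mol per injection

  list(
    molar_ratio = Xtot / Mtot,
    q_per_mol = dQ / moles_injected + offset
  )
}

#' Simulate a 1:1 binding isotherm
#'
#' Generates per-injection normalized heats (kcal per mole of injectant) for a
#' titration scheme under the single-site binding model, with displacement
#' corrections for the volume expelled from the perfusion cell at each
#' injection, an optional constant heat-of-dilution offset, and additive
#' Gaussian noise.
#'
#' @param scheme A [titration_scheme()].
#' @param params A [binding_parameters()].
#' @param noise_sd_kcal_mol Standard deviation of additive Gaussian noise on
#'   the normalized heats, kcal/mol. Zero gives the exact model curve.
#' @param seed Integer seed for the noise draw; required when
#'   `noise_sd_kcal_mol > 0` so simulations are reproducible.
#' @return A tibble with one row per injection: `injection`, `volume_ul`,
#'   `molar_ratio` (cumulative titrant/analyte ratio in the cell),
#'   `q_per_mol` (kcal per mole injected) and `included` (logical fitting
#'   mask, honouring `scheme$exclude_first`).
#' @examples
#' sch <- titration_scheme(syringe_conc_uM = 50, cell_conc_uM = 5)
#' par <- binding_parameters(KD_M = 52.83e-9, dH_kcal_mol = -6.58)
#' simulate_isotherm(sch, par)
#' @export
simulate_isotherm <- function(scheme, params, noise_sd_kcal_mol = 0,
                              seed = NULL) {
  stopifnot(inherits(scheme, "titration_scheme"),
            inherits(params, "binding_parameters"),
            noise_sd_kcal_mol >= 0)
  fm <- isotherm_heats(scheme, params$N, params$KD_M, params$dH_kcal_mol,
                       params$dilution_offset_kcal_mol)
  q <- fm$q_per_mol
  if (noise_sd_kcal_mol > 0) {
    if (is.null(seed)) stop("a seed is required when simulating noisy heats")
    q <- q + withr::with_seed(seed,
                              stats::rnorm(length(q), 0, noise_sd_kcal_mol))
  }
  n <- length(q)
  tibble::tibble(
    injection = seq_len(n),
    volume_ul = scheme$injection_volumes_ul,
    molar_ratio = fm$molar_ratio,
    q_per_mol = q,
    included = if (scheme$exclude_first) c(FALSE, rep(TRUE, n - 1L)) else rep(TRUE, n)
  )
}

#' Decompose binding free energy
#'
#' Computes the Gibbs free energy of binding from the dissociation constant,
#' `dG = R * T * ln(KD)`, and the entropic term `-T*dS = dG - dH`, with
#' `R = 1.98720425e-3` kcal/(mol K).
#'
#' @param KD_M Dissociation constant in molar.
#' @param dH_kcal_mol Binding enthalpy, kcal/mol.
#' @param temperature_C Temperature in degrees Celsius.
#' @return A one-row tibble with `dG_kcal_mol` and `minus_TdS_kcal_mol`.
#' @examples
#' thermo_decompose(52.83e-9, -6.58, 20)  # minus_TdS ~ -3.18 kcal/mol
#' @export
thermo_decompose <- function(KD_M, dH_kcal_mol, temperature_C) {
  if (!is.numeric(KD_M) || any(KD_M <= 0)) {
    stop("KD_M must be positive")
  }
  R <- 1.98720425e-3  # kcal / (mol K)
  T_K <- temperature_C + 273.15
  dG <- R * T_K * log(KD_M)
  tibble::tibble(dG_kcal_mol = dG, minus_TdS_kcal_mol = dG - dH_kcal_mol)
}

#' Wiseman c-value of a titration design
#'
#' The dimensionless c-value `N * [analyte] / KD` governs the sharpness of the
#' isotherm sigmoid and hence the identifiability of the fit; designs with
#' c between roughly 1 and 1000 are fittable, with 5-500 the comfortable
#' range.
#'
#' @param scheme A [titration_scheme()].
#' @param KD_M Dissociation constant in molar.
#' @param N Stoichiometry; defaults to 1.
#' @return The c-value, a single number.
#' @examples
#' c_value(titration_scheme(syringe_conc_uM = 50, cell_conc_uM = 5), 52.83e-9)
#' @export
c_value <- function(scheme, KD_M, N = 1) {
  stopifnot(inherits(scheme, "titration_scheme"), KD_M > 0, N > 0)
  N * scheme$cell_conc_uM * 1e-6 / KD_M
}
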