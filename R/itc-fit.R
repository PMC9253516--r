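#' Fit a 1:1 binding isotherm
#'
#' Least-squares fit of the single-site binding model to per-injection
#' normalized heats, estimating stoichiometry `N`, dissociation constant,
#' binding enthalpy and a constant heat-of-dilution offset. The optimizer is
#' damped least squares (Levenberg-Marquardt) with a deterministic multi-start
#' over a coarse log-spaced KD grid (1e-11 to 1e-4 M) to avoid local minima;
#' KD is fitted on the log10 scale. Asymptotic standard errors come from the
#' Jacobian at the optimum (KD by the delta method).
#'
#' @param iso Isotherm tibble as returned by [simulate_isotherm()] or
#'   [read_isotherm_csv()]: columns `molar_ratio`, `q_per_mol`, `included`.
#' @param scheme The [titration_scheme()] that produced the heats.
#' @param init Optional [binding_parameters()] used as a single starting
#'   point instead of the multi-start grid.
#' @return An object of class `itc_fit`: fitted parameters, standard errors,
#'   `dG_kcal_mol`, `minus_TdS_kcal_mol`, residual sum of squares, a
#'   `converged` flag and any diagnostic `warnings` (for example a c-value
#'   outside \[1, 1000\]). Inspect with [tidy()][generics::tidy],
#'   [glance()][generics::glance] or [ggplot2::autoplot()].
#' @examples
#' sch <- titration_scheme(syringe_conc_uM = 50, cell_conc_uM = 5)
#' iso <- simulate_isotherm(sch, binding_parameters(KD_M = 52.83e-9,
#'                                                  dH_kcal_mol = -6.58))
#' fit <- fit_isotherm(iso, sch)
#' glance(fit)
#' @export
fit_isotherm <- function(iso, scheme, init = NULL) {
  stopifnot(inherits(scheme, "titration_scheme"),
            all(c("molar_ratio", "q_per_mol", "included") %in% names(iso)))
  use <- which(iso$included)
  if (length(use) < 5L) {
    stop("at least 5 included injections are required to fit four parameters")
  }
  q_obs <- iso$q_per_mol[use]

  residual_fn <- function(p) {
    fm <- isotherm_heats(scheme, N = p[["N"]], KD_M = 10^p[["logKD"]],
                         dH = p[["dH"]], offset = p[["offset"]])
    fm$q_per_mol[use] - q_obs
  }

  # data-driven starts: offset from the saturated tail, dH from the initial
  # plateau, N near the molar ratio at mid-transition
  offset0 <- mean(utils::tail(q_obs, 2))
  dH0 <- q_obs[1] - offset0
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -1
  mr <- iso$molar_ratio[use]
  i_mid <- which.min(abs(q_obs - (q_obs[1] + offset0) / 2))
  N0 <- max(mr[i_mid], 1e-3)

  starts <- if (!is.null(init)) {
    list(c(N = init$N, logKD = log10(init$KD_M), dH = init$dH_kcal_mol,
           offset = init$dilution_offset_kcal_mol))
  } else {
    lapply(seq(-11, -4, by = 1), function(lk)
      c(N = N0, logKD = lk, dH = dH0, offset = offset0))
  }

  lower <- c(N = 1e-4, logKD = -13, dH = -Inf, offset = -Inf)
  upper <- c(N = 1e3, logKD = -1, dH = Inf, offset = Inf)

  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = residual_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("optimizer failed from every starting point")

  p <- best$par
  KD <- 10^p[["logKD"]]
  rss <- best$deviance
  dof <- length(use) - 4L

  se <- rep(NA_real_, 4)
  names(se) <- c("N", "logKD", "dH", "offset")
  if (dof > 0) {
    s2 <- rss / dof
    cv <- tryCatch(s2 * solve(crossprod(best$fjac)), error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  se_KD <- KD * log(10) * se[["logKD"]]

  warnings <- character()
  cval <- c_value(scheme, KD, N = p[["N"]])
  if (!is.finite(cval) || cval < 1 || cval > 1000) {
    warnings <- c(warnings, sprintf(
      "c-value %.3g outside [1, 1000]: the isotherm poorly constrains KD", cval))
  }

  # honesty checks: the optimizer must have stopped cleanly and the fitted
  # transition must rise above the residual noise floor
  resid_sd <- sqrt(rss / max(length(use) - 4L, 1L))
  q_span <- diff(range(q_obs))
  converged <- best$info %in% 1:4 &&
    is.finite(KD) && q_span > 0 &&
    abs(p[["dH"]]) > 3 * resid_sd

  td <- thermo_decompose(KD, p[["dH"]], scheme$temperature_C)

  structure(
    list(
      params = binding_parameters(N = p[["N"]], KD_M = KD,
                                  dH_kcal_mol = p[["dH"]],
                                  dilution_offset_kcal_mol = p[["offset"]]),
      se = c(N = unname(se[["N"]]), KD_M = unname(se_KD),
             dH_kcal_mol = unname(se[["dH"]]),
             dilution_offset_kcal_mol = unname(se[["offset"]])),
      dG_kcal_mol = td$dG_kcal_mol,
      minus_TdS_kcal_mol = td$minus_TdS_kcal_mol,
      rss = rss,
      converged = converged,
      warnings = warnings,
      c_value = unname(cval),
      isotherm = iso,
      scheme = scheme
    ),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("1:1 binding isotherm fit",
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat(sprintf("  N = %.4g, KD = %.4g nM, dH = %.4g kcal/mol, offset = %.4g\n",
              x$params$N, x$params$KD_M * 1e9, x$params$dH_kcal_mol,
              x$params$dilution_offset_kcal_mol))
  cat(sprintf("  dG = %.3f, -TdS = %.3f kcal/mol; rss = %.3g; c = %.3g\n",
              x$dG_kcal_mol, x$minus_TdS_kcal_mol, x$rss, x$c_value))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ITC fit into one row per parameter
#'
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("N", "KD_M", "dH_kcal_mol", "dilution_offset_kcal_mol"),
    estimate = c(x$params$N, x$params$KD_M, x$params$dH_kcal_mol,
                 x$params$dilution_offset_kcal_mol),
    std.error = unname(x$se)
  )
}

#' One-row summary of an ITC fit
#'
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return A one-row tibble: KD in nM, thermodynamic terms, stoichiometry,
#'   c-value, residual sum of squares and convergence flag.
#' @export
glance.itc_fit <- function(x, ...) {
  tibble::tibble(
    KD_nM = x$params$KD_M * 1e9,
    N = x$params$N,
    dH_kcal_mol = x$params$dH_kcal_mol,
    dG_kcal_mol = x$dG_kcal_mol,
    minus_TdS_kcal_mol = x$minus_TdS_kcal_mol,
    dilution_offset_kcal_mol = x$params$dilution_offset_kcal_mol,
    c_value = x$c_value,
    rss = x$rss,
    converged = x$converged
  )
}

#' Plot an isotherm fit
#'
#' Points are the measured normalized heats against molar ratio (open circle
#' for excluded injections); the line is the fitted 1:1 model evaluated on the
#' titration scheme.
#'
#' @param object An `itc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itc_fit <- function(object, ...) {
  iso <- object$isotherm
  fm <- isotherm_heats(object$scheme, object$params$N, object$params$KD_M,
                       object$params$dH_kcal_mol,
                       object$params$dilution_offset_kcal_mol)
  curve <- tibble::tibble(molar_ratio = fm$molar_ratio, q_per_mol = fm$q_per_mol)
  ggplot2::ggplot(iso, ggplot2::aes(.data$molar_ratio, .data$q_per_mol)) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$included), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "molar ratio (titrant / analyte)",
                  y = "kcal per mole of injectant",
                  title = sprintf("KD = %.3g nM, N = %.2f",
                                  object$params$KD_M * 1e9, object$params$N)) +
    ggplot2::theme_classic()
}

#' Read / write isotherm CSV files
#'
#' The on-disk format has one row per injection with columns
#' `injection_index`, `volume_ul`, `molar_ratio`, `q_per_mol_kcal`,
#' `included`.
#'
#' @param path File path.
#' @return `read_isotherm_csv()` returns the isotherm tibble in the in-memory
#'   layout (`injection`, `volume_ul`, `molar_ratio`, `q_per_mol`,
#'   `included`); `write_isotherm_csv()` returns `path` invisibly.
#' @export
read_isotherm_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(
    injection = as.integer(d$injection_index),
    volume_ul = d$volume_ul,
    molar_ratio = d$molar_ratio,
    q_per_mol = d$q_per_mol_kcal,
    included = as.logical(d$included)
  )
}

#' @rdname read_isotherm_csv
#' @param iso Isotherm tibble.
#' @export
write_isotherm_csv <- function(iso, path) {
  readr::write_csv(
    tibble::tibble(
      injection_index = iso$injection,
      volume_ul = iso$volume_ul,
      molar_ratio = iso$molar_ratio,
      q_per_mol_kcal = iso$q_per_mol,
      included = iso$included
    ),
    path
  )
  invisible(path)
}
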