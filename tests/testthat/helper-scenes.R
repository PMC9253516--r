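# shared fixtures, all generated in code

ref_titration_scheme <- function() {
  titration_scheme(cell_volume_ul = 200, syringe_conc_uM = 50,
                   cell_conc_uM = 5,
                   injection_volumes_ul = c(0.5, rep(2.5, 15)),
                   temperature_C = 20)
}

ref_titration_params <- function() {
  binding_parameters(N = 1, KD_M = 52.83e-9, dH_kcal_mol = -6.58)
}

one_spot_scene <- function(amp = c(ACA = 1000), noise_sd = 0, seed = 1L,
                           x_um = 4.13, y_um = 4.13, sigma_um = 0.15) {
  image_scene(width_px = 128, height_px = 128, channels = names(amp),
              spots = spot_truth(x_um, y_um, sigma_um = sigma_um,
                                 amplitude = amp),
              background = 100, noise_sd = noise_sd, seed = seed)
}

# independent mutual-nearest-neighbour oracle: direct O(n^2) distance scan,
# no shared code with assign_pairs()
brute_force_pairs <- function(x, y, cap) {
  n <- length(x)
  out <- list()
  if (n < 2) return(out)
  d <- as.matrix(dist(cbind(x, y)))
  diag(d) <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > cap) next
      if (all(d[i, -i] >= d[i, j]) && all(d[j, -j] >= d[i, j])) {
        out[[length(out) + 1L]] <- sort(c(round(x[i], 9), round(y[i], 9),
                                          round(x[j], 9), round(y[j], 9)))
      }
    }
  }
  out
}

canonical_pair_set <- function(pairs) {
  if (nrow(pairs) == 0) return(list())
  lapply(seq_len(nrow(pairs)), function(k) {
    sort(c(round(pairs$ax_um[k], 9), round(pairs$ay_um[k], 9),
           round(pairs$bx_um[k], 9), round(pairs$by_um[k], 9)))
  })
}
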