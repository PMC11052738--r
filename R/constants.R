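#' Physical decay constants for a nuclide
#'
#' Container for the physical half-life and decay constant used throughout
#' the pipeline (decay correction of the calibration image, the
#' voiding-bladder model, and the effective/biological half-life
#' decomposition). The default is Tc-99m.
#'
#' @param t_phys_h Physical half-life in hours (Tc-99m: 6.0067 h).
#' @return An object of class `decay_constants` with elements `t_phys_h`
#'   and `lambda_phys_per_h` (= ln 2 / `t_phys_h`).
#' @examples
#' decay_constants()          # Tc-99m
#' decay_constants(78.4)      # e.g. a longer-lived nuclide
#' @export
decay_constants <- function(t_phys_h = 6.0067) {
  stopifnot(is.numeric(t_phys_h), length(t_phys_h) == 1L, is.finite(t_phys_h))
  if (t_phys_h <= 0) stop("physical half-life must be positive")
  structure(
    list(t_phys_h = t_phys_h, lambda_phys_per_h = log(2) / t_phys_h),
    class = "decay_constants"
  )
}

#' @export
print.decay_constants <- function(x, ...) {
  cat(sprintf("Decay constants: T_phys = %.4f h (lambda = %.6f / h)\n",
              x$t_phys_h, x$lambda_phys_per_h))
  invisible(x)
}

# Tc-99m emission data used by the synthetic S-value kernel:
# mean energy per decay carried by electrons (conversion + Auger) and by
# photons, in MeV; soft-tissue attenuation and energy-absorption
# coefficients at 140 keV; whole-body photon absorbed fraction.
.tc99m_emissions <- list(
  e_electron_mev = 0.0162,
  e_photon_mev   = 0.1264,
  mu_per_cm      = 0.155,   # linear attenuation, soft tissue, 140 keV
  mu_en_cm2_g    = 0.0271,  # mass energy-absorption coefficient
  phi_total_body = 0.34     # photon absorbed fraction, whole body
)

# J emitted per MBq.h for an energy in MeV per decay
.j_per_mbq_h <- function(e_mev) e_mev * 1.602176634e-13 * 3.6e9

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
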