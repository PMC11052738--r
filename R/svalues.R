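#' S-value table
#'
#' Dose kernel of the MIRD schema: `S(target <- source)` in
#' mGy/(MBq.h), i.e. absorbed dose rate in the target region per unit
#' activity in the source region, for one nuclide in one phantom. A
#' `"total_body"` source column must be present for the remainder-of-body
#' correction.
#'
#' @param entries Data frame with columns `target`, `source`,
#'   `s_mGy_per_MBq_h` (all >= 0).
#' @param nuclide,phantom Labels.
#' @return An object of class `svalue_table`.
#' @export
svalue_table <- function(entries, nuclide = "Tc-99m",
                         phantom = "adult male") {
  need <- c("target", "source", "s_mGy_per_MBq_h")
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop("S-value entries missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(entries$s_mGy_per_MBq_h < 0)) stop("S-values must be >= 0")
  entries$target <- canonical_organ(entries$target, allow_unknown = TRUE)
  entries$source <- canonical_organ(entries$source, allow_unknown = TRUE)
  # warn (only) if any self-dose is not the largest entry for its target
  self <- entries[entries$target == entries$source, ]
  for (i in seq_len(nrow(self))) {
    rows <- entries$target == self$target[i] & entries$source != "total_body"
    if (any(entries$s_mGy_per_MBq_h[rows] > self$s_mGy_per_MBq_h[i] + 1e-12))
      warning("self-dose S(", self$target[i], ") is not the largest entry ",
              "for that target; check the table")
  }
  structure(list(nuclide = nuclide, phantom = phantom, entries = entries),
            class = "svalue_table")
}

# lookup S(target <- source); error if absent
s_lookup <- function(svals, target, source) {
  hit <- svals$entries$target == target & svals$entries$source == source
  if (!any(hit)) stop("no S-value for ", target, " <- ", source)
  svals$entries$s_mGy_per_MBq_h[which(hit)[1]]
}

#' @export
print.svalue_table <- function(x, ...) {
  cat(sprintf("S-value table: %s, %s phantom (%d entries, %d targets, %d sources)\n",
              x$nuclide, x$phantom, nrow(x$entries),
              length(unique(x$entries$target)),
              length(unique(x$entries$source))))
  invisible(x)
}

#' Load the synthetic adult-male phantom geometry
#'
#' Returns the bundled synthetic organ-geometry table (masses and
#' centroids) used to build the default Tc-99m S-value table. The
#' geometry is a plausible adult-male construction, not a published
#' phantom; see the file header of
#' `system.file("extdata", "synthetic_adult_male_phantom.csv")`.
#'
#' @return Data frame with columns `organ`, `mass_g`, `x_cm`, `y_cm`,
#'   `z_cm`, `kind`, `is_source`, `is_target`.
#' @export
phantom_geometry <- function() {
  path <- system.file("extdata", "synthetic_adult_male_phantom.csv",
                      package = "mirddose", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Build the synthetic Tc-99m adult-male S-value table
#'
#' Constructs a physically motivated S-value table from the bundled
#' synthetic phantom geometry using Tc-99m mean emission energies
#' (16.2 keV electrons, 126.4 keV photons per decay):
#' \itemize{
#'   \item self-dose: all electron energy absorbed locally plus a photon
#'     self-absorbed fraction `1 - exp(-mu_en * 4r/3)` for a sphere of
#'     the organ's mass (unit density);
#'   \item wall <- contents (urinary bladder): half the contents
#'     self-dose, the standard surface approximation;
#'   \item cross-dose between compact organs: point-source photon
#'     transport `E * mu_en * B(mu d) * exp(-mu d) / (4 pi d^2)` with a
#'     linear buildup factor `B = 1 + mu d` and the centre-to-centre
#'     distance floored at the mean of the two organ radii;
#'   \item distributed targets (muscle, skin) from compact sources, and
#'     any target from the `total_body` source: whole-body "bath" terms
#'     using the whole-body photon absorbed fraction;
#'   \item the `total_body` target row follows from energy conservation
#'     (all electron energy plus the whole-body photon absorbed fraction,
#'     divided by total-body mass).
#' }
#' This synthetic kernel reproduces the magnitude and ranking of
#' published Tc-99m adult-male S-values; it is not a substitute for a
#' validated phantom table when absolute organ doses matter.
#'
#' @param geometry Phantom geometry data frame ([phantom_geometry()]).
#' @return An [svalue_table()].
#' @export
tc99m_svalue_table <- function(geometry = phantom_geometry()) {
  em <- .tc99m_emissions
  e_el <- .j_per_mbq_h(em$e_electron_mev)   # J per MBq.h, electrons
  e_ph <- .j_per_mbq_h(em$e_photon_mev)     # J per MBq.h, photons
  # dose [mGy] = 1e6 * E_abs[J] / m[g]
  radius <- function(m) (3 * m / (4 * pi))^(1 / 3)       # cm, density 1
  phi_self <- function(m) 1 - exp(-em$mu_en_cm2_g * 4 * radius(m) / 3)
  s_self <- function(m) 1e6 * (e_el + e_ph * phi_self(m)) / m
  s_bath <- 1e6 * e_ph * em$phi_total_body / geometry$mass_g[
    geometry$organ == "total_body"]
  s_tb_source <- 1e6 * (e_el + e_ph * em$phi_total_body) / geometry$mass_g[
    geometry$organ == "total_body"]
  s_cross <- function(d_cm) {
    mu_d <- em$mu_per_cm * d_cm
    1e6 * e_ph * em$mu_en_cm2_g * (1 + mu_d) * exp(-mu_d) / (4 * pi * d_cm^2)
  }

  g <- geometry
  rownames(g) <- g$organ
  targets <- g$organ[g$is_target]
  sources <- g$organ[g$is_source]
  dist_cm <- function(a, b) {
    sqrt(sum((unlist(g[a, c("x_cm", "y_cm", "z_cm")]) -
                unlist(g[b, c("x_cm", "y_cm", "z_cm")]))^2))
  }

  rows <- list()
  for (tg in targets) {
    for (src in sources) {
      s <- if (tg == "total_body") {
        s_tb_source  # energy conservation: same for every source
      } else if (src == "total_body") {
        s_tb_source  # uniform whole-body source
      } else if (tg == src || (tg == "heart_wall" && src == "heart")) {
        s_self(g[src, "mass_g"])
      } else if (tg == "urinary_bladder_wall" &&
                 src == "urinary_bladder_contents") {
        s_self(g[src, "mass_g"]) / 2
      } else if (g[tg, "kind"] == "distributed") {
        s_bath
      } else {
        d <- dist_cm(tg, src)
        d <- max(d, (radius(g[tg, "mass_g"]) + radius(g[src, "mass_g"])) / 2)
        s_cross(d)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(target = tg, source = src, s_mGy_per_MBq_h = s)
    }
  }
  svalue_table(do.call(rbind, rows))
}

#' Reference masses from the synthetic phantom
#'
#' Convenience constructor of an [organ_mass_map()] from the bundled
#' phantom geometry.
#'
#' @param patient_mass_g Optional named patient organ masses (g).
#' @return An `organ_mass_map`.
#' @export
phantom_mass_map <- function(patient_mass_g = NULL) {
  g <- phantom_geometry()
  ref <- stats::setNames(g$mass_g, g$organ)
  tb <- ref[["total_body"]]
  ref <- ref[names(ref) != "total_body"]
  organ_mass_map(ref, total_body_mass_g = tb, patient_mass_g = patient_mass_g)
}
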