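#' Canonical organ labels
#'
#' The pipeline uses lower-case snake-case organ labels internally.
#' `canonical_organ()` normalises the label spellings found in typical
#' dose-report tables ("ULI Wall", "Red bone marrow", "Osteogenic Cells",
#' ...) to those keys and fails loudly on anything it cannot match, so a
#' typo in an input table cannot silently drop a source organ.
#'
#' @param x Character vector of organ labels.
#' @param allow_unknown If `TRUE`, unknown labels are passed through after
#'   basic normalisation instead of raising an error.
#' @return Character vector of canonical labels.
#' @examples
#' canonical_organ(c("ULI Wall", "Red bone marrow", "WB - Bladder"))
#' @export
canonical_organ <- function(x, allow_unknown = FALSE) {
  norm <- tolower(gsub("[^a-z0-9]+", "_", tolower(trimws(as.character(x)))))
  norm <- gsub("^_+|_+$", "", norm)
  alias <- c(
    wb = "whole_body", whole_body = "whole_body", total_body = "total_body",
    wb_bladder = "wb_minus_bladder", wb_minus_bladder = "wb_minus_bladder",
    red_bone_marrow = "red_marrow", red_marrow = "red_marrow", rbm = "red_marrow",
    marrow = "red_marrow",
    urinary_bladder = "urinary_bladder_contents",
    bladder = "urinary_bladder_contents",
    bladder_contents = "urinary_bladder_contents",
    urinary_bladder_contents = "urinary_bladder_contents",
    urinary_bladder_wall = "urinary_bladder_wall",
    bladder_wall = "urinary_bladder_wall",
    osteogenic_cells = "osteogenic_cells", bone_surfaces = "osteogenic_cells",
    bone_surface = "osteogenic_cells",
    uli_wall = "uli_wall", upper_large_intestine = "uli_wall",
    lli_wall = "lli_wall", lower_large_intestine = "lli_wall",
    gallbladder_wall = "gallbladder_wall", gb_wall = "gallbladder_wall",
    stomach_wall = "stomach_wall", stomach = "stomach_wall",
    heart_wall = "heart_wall", heart = "heart",
    small_intestine = "small_intestine", si = "small_intestine",
    l2_l4 = "l2_l4", lumbar_vertebrae_2_4 = "l2_l4",
    remainder = "remainder", remainder_of_body = "remainder",
    adrenals = "adrenals", brain = "brain", breasts = "breasts",
    breast = "breasts", kidneys = "kidneys", kidney = "kidneys",
    liver = "liver", lungs = "lungs", lung = "lungs", muscle = "muscle",
    pancreas = "pancreas", skin = "skin", spleen = "spleen",
    testes = "testes", thymus = "thymus", thyroid = "thyroid"
  )
  out <- unname(alias[norm])
  unknown <- is.na(out)
  if (any(unknown)) {
    if (!allow_unknown) {
      stop("unknown organ label(s): ",
           paste(unique(x[unknown]), collapse = ", "))
    }
    out[unknown] <- norm[unknown]
  }
  out
}

#' Organ mass map
#'
#' Reference (phantom) organ masses with optional patient-specific masses
#' from CT volumes. Patient masses drive the self-dose mass scaling in the
#' dose engine; organs without a patient mass fall back to the reference.
#'
#' @param reference_mass_g Named numeric vector of reference masses in g
#'   (canonical organ labels; see [canonical_organ()]).
#' @param total_body_mass_g Total-body mass in g.
#' @param patient_mass_g Optional named numeric vector of patient masses.
#' @return An object of class `organ_mass_map`.
#' @export
organ_mass_map <- function(reference_mass_g, total_body_mass_g,
                           patient_mass_g = NULL) {
  stopifnot(is.numeric(reference_mass_g), !is.null(names(reference_mass_g)))
  names(reference_mass_g) <- canonical_organ(names(reference_mass_g),
                                             allow_unknown = TRUE)
  if (any(reference_mass_g <= 0)) stop("organ masses must be positive")
  stopifnot(is.numeric(total_body_mass_g), total_body_mass_g > 0)
  if (!is.null(patient_mass_g)) {
    names(patient_mass_g) <- canonical_organ(names(patient_mass_g),
                                             allow_unknown = TRUE)
    if (any(patient_mass_g <= 0)) stop("patient organ masses must be positive")
  }
  structure(
    list(reference_mass_g = reference_mass_g,
         patient_mass_g = patient_mass_g,
         total_body_mass_g = total_body_mass_g),
    class = "organ_mass_map"
  )
}

# mass actually used for organ (patient if available, else reference)
organ_mass <- function(masses, organ, patient = TRUE) {
  m <- NA_real_
  if (patient && !is.null(masses$patient_mass_g) &&
      organ %in% names(masses$patient_mass_g)) {
    m <- masses$patient_mass_g[[organ]]
  } else if (organ %in% names(masses$reference_mass_g)) {
    m <- masses$reference_mass_g[[organ]]
  }
  if (is.na(m)) stop("no mass available for organ: ", organ)
  m
}
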