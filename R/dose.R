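#' TIAC set for one subject
#'
#' Source-organ TIACs together with the whole-body (excluding bladder
#' content) TIAC and the bladder-content TIAC, the inputs of the MIRD
#' dose computation.
#'
#' @param organ_tiac_h Named numeric vector of source-organ TIACs in
#'   hours (canonical organ labels; `NA` entries are dropped with a
#'   message, mirroring regions that could not be assessed).
#' @param whole_body_tiac_h Whole-body TIAC in hours *excluding* the
#'   bladder content (e.g. fitted from the whole-body-minus-bladder
#'   curve, `T_eff / ln 2` for a normalised mono-exponential).
#' @param bladder_tiac_h Bladder-content TIAC in hours
#'   (see [bladder_tiac()]).
#' @return An object of class `tiac_set`.
#' @export
tiac_set <- function(organ_tiac_h, whole_body_tiac_h, bladder_tiac_h) {
  stopifnot(is.numeric(organ_tiac_h), !is.null(names(organ_tiac_h)))
  if (any(is.na(organ_tiac_h))) {
    message("dropping ", sum(is.na(organ_tiac_h)),
            " organ TIAC(s) recorded as NA")
    organ_tiac_h <- organ_tiac_h[!is.na(organ_tiac_h)]
  }
  names(organ_tiac_h) <- canonical_organ(names(organ_tiac_h),
                                          allow_unknown = TRUE)
  stopifnot(all(organ_tiac_h >= 0), whole_body_tiac_h >= 0,
            bladder_tiac_h >= 0)
  if (sum(organ_tiac_h) > whole_body_tiac_h + 1e-9)
    stop("sum of organ TIACs exceeds the whole-body TIAC")
  structure(list(organ_tiac_h = organ_tiac_h,
                 whole_body_tiac_h = whole_body_tiac_h,
                 bladder_tiac_h = bladder_tiac_h),
            class = "tiac_set")
}

#' Remainder-of-body TIAC
#'
#' `tiac_rem = tiac_WB(excl. bladder) - sum(organ TIACs)`: the whole-body
#' activity not assigned to any delineated source organ.
#'
#' @param tiacs A [tiac_set()].
#' @return Remainder TIAC in hours.
#' @export
remainder_tiac <- function(tiacs) {
  stopifnot(inherits(tiacs, "tiac_set"))
  rem <- tiacs$whole_body_tiac_h - sum(tiacs$organ_tiac_h)
  if (rem < 0) stop("negative remainder TIAC: inconsistent inputs")
  rem
}

#' Remainder-of-body S-value by mass balance
#'
#' Builds the S-value for a uniformly distributed remainder source from
#' the total-body row:
#' `S(t <- rem) = (S(t <- TB) * M_TB - sum_src S(t <- src) * m_src) / M_rem`
#' with `M_rem = M_TB - sum m_src`. Negative results (possible with
#' inconsistent tables) are floored at 0 with a warning.
#'
#' @param target Target organ label.
#' @param svals An [svalue_table()] containing a `total_body` source.
#' @param masses An [organ_mass_map()] (reference masses are used:
#'   the remainder correction is a phantom-level construction).
#' @param sources Character vector of delineated source organs.
#' @return S-value in mGy/(MBq.h).
#' @export
remainder_svalue <- function(target, svals, masses, sources) {
  target <- canonical_organ(target, allow_unknown = TRUE)
  sources <- canonical_organ(sources, allow_unknown = TRUE)
  if (!any(svals$entries$source == "total_body"))
    stop("S-value table has no total_body source row")
  m_tb <- masses$total_body_mass_g
  s_tb <- s_lookup(svals, target, "total_body")
  if (length(sources) == 0L) return(s_tb)
  m_src <- vapply(sources, function(s) organ_mass(masses, s, patient = FALSE),
                  numeric(1))
  s_src <- vapply(sources, function(s) s_lookup(svals, target, s), numeric(1))
  m_rem <- m_tb - sum(m_src)
  if (m_rem <= 0) stop("source masses exceed total-body mass")
  s_rem <- (s_tb * m_tb - sum(s_src * m_src)) / m_rem
  if (s_rem < 0) {
    warning("negative remainder S-value for ", target, "; floored at 0")
    s_rem <- 0
  }
  s_rem
}

#' Mass scaling of the self-dose S-value
#'
#' Electron-dominated self-dose scales inversely with organ mass:
#' `S_self_patient = S_self_ref * m_ref / m_patient`. Cross-dose terms
#' are left unscaled.
#'
#' @param s_self Reference self-dose S-value.
#' @param m_ref,m_patient Reference and patient organ masses in g (> 0).
#' @return Scaled S-value.
#' @export
mass_scale_self_dose <- function(s_self, m_ref, m_patient) {
  stopifnot(m_ref > 0, m_patient > 0, s_self >= 0)
  s_self * m_ref / m_patient
}

#' MIRD organ absorbed-dose coefficients
#'
#' `D(target) = sum_src tiac_src * S(target <- src) + tiac_rem * S(target <- rem)`
#' over all delineated sources (including the bladder contents), with the
#' remainder TIAC and remainder S-value from [remainder_tiac()] and
#' [remainder_svalue()], and the self-dose term rescaled to the patient
#' organ mass when one is available.
#'
#' @param tiacs A [tiac_set()].
#' @param svals An [svalue_table()].
#' @param masses An [organ_mass_map()].
#' @param targets Target organs to evaluate; defaults to every target in
#'   the S-value table (excluding `total_body` sources-only labels).
#' @return Named numeric vector of class `organ_dose_set`, mGy/MBq.
#' @examples
#' svals <- tc99m_svalue_table()
#' masses <- phantom_mass_map()
#' tiacs <- tiac_set(c(kidneys = 0.065, liver = 0.063),
#'                   whole_body_tiac_h = 2.7, bladder_tiac_h = 0.67)
#' organ_doses(tiacs, svals, masses)[c("kidneys", "urinary_bladder_wall")]
#' @export
organ_doses <- function(tiacs, svals, masses,
                        targets = unique(svals$entries$target)) {
  stopifnot(inherits(tiacs, "tiac_set"), inherits(svals, "svalue_table"),
            inherits(masses, "organ_mass_map"))
  targets <- canonical_organ(targets, allow_unknown = TRUE)
  src_organs <- names(tiacs$organ_tiac_h)
  known_sources <- unique(svals$entries$source)
  unmatched <- setdiff(src_organs, known_sources)
  if (length(unmatched))
    stop("TIAC source organ(s) not in the S-value table: ",
         paste(unmatched, collapse = ", "))

  rem <- remainder_tiac(tiacs)
  all_sources <- c(src_organs,
                   if (tiacs$bladder_tiac_h > 0) "urinary_bladder_contents")
  src_tiac <- c(tiacs$organ_tiac_h,
                if (tiacs$bladder_tiac_h > 0)
                  stats::setNames(tiacs$bladder_tiac_h,
                                  "urinary_bladder_contents"))

  doses <- stats::setNames(numeric(length(targets)), targets)
  for (tg in targets) {
    d <- 0
    for (src in all_sources) {
      s <- s_lookup(svals, tg, src)
      if (tg == src && !is.null(masses$patient_mass_g) &&
          tg %in% names(masses$patient_mass_g)) {
        s <- mass_scale_self_dose(s, organ_mass(masses, tg, patient = FALSE),
                                  masses$patient_mass_g[[tg]])
      }
      d <- d + src_tiac[[src]] * s
    }
    d <- d + rem * remainder_svalue(tg, svals, masses, all_sources)
    doses[[tg]] <- d
  }
  structure(doses, class = c("organ_dose_set", "numeric"))
}

#' @export
print.organ_dose_set <- function(x, ...) {
  cat("Organ absorbed-dose coefficients [mGy/MBq]:\n")
  print(signif(unclass(x), 3))
  invisible(x)
}
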