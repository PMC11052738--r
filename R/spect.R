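#' SPECT calibration from a standard in the field of view
#'
#' @param counts_per_mbq Reconstructed counts per MBq measured on a
#'   standard of known activity (> 0).
#' @param standard_mbq Activity of the standard in MBq (> 0).
#' @return An object of class `spect_calibration`.
#' @export
spect_calibration <- function(counts_per_mbq, standard_mbq) {
  stopifnot(counts_per_mbq > 0, standard_mbq > 0)
  structure(list(counts_per_mbq = counts_per_mbq,
                 standard_mbq = standard_mbq),
            class = "spect_calibration")
}

#' SPECT VOI counts to fractions of injected activity
#'
#' Subtracts a background *concentration* (counts/mL, from a ~100 mL
#' reference sphere in muscle) scaled by the VOI volume, then divides by
#' the calibration factor and injected activity:
#' `fraction_id = max(0, counts - bg_conc * volume) / CF / injected_mbq`.
#' No decay correction is applied (effective values are carried through).
#'
#' @param vois Data frame with columns `subject_id`, `region_id`,
#'   `time_h`, `counts`, `volume_ml`, `bg_conc_counts_per_ml`.
#' @param cal A [spect_calibration()].
#' @param injected_mbq Injected activity in MBq.
#' @return The input data frame with a `fraction_id` column appended.
#' @export
voi_activity <- function(vois, cal, injected_mbq) {
  stopifnot(inherits(cal, "spect_calibration"), injected_mbq > 0)
  need <- c("counts", "volume_ml", "bg_conc_counts_per_ml", "time_h")
  miss <- setdiff(need, names(vois))
  if (length(miss)) stop("VOI table missing column(s): ",
                         paste(miss, collapse = ", "))
  stopifnot(all(vois$counts >= 0), all(vois$volume_ml > 0))
  net <- vois$counts - vois$bg_conc_counts_per_ml * vois$volume_ml
  if (any(net < 0)) {
    warning("VOI counts below background in ",
            sum(net < 0), " row(s); clamped to 0")
    net <- pmax(net, 0)
  }
  vois$fraction_id <- net / cal$counts_per_mbq / injected_mbq
  vois
}

#' SPECT VOI series to a time-activity curve
#'
#' @param vois VOI rows for one subject/region (see [voi_activity()]).
#' @inheritParams voi_activity
#' @return A [time_activity_curve()].
#' @export
voi_activity_series <- function(vois, cal, injected_mbq) {
  if (nrow(vois) == 0L) stop("empty VOI list")
  if (length(unique(vois$region_id)) != 1L)
    stop("voi_activity_series expects a single region")
  q <- voi_activity(vois, cal, injected_mbq)
  time_activity_curve(q$subject_id[1], q$region_id[1], q$time_h,
                      q$fraction_id)
}

#' Scale L2-L4 activity to whole red bone marrow
#'
#' Imaging-based red-marrow quantification assumes a fixed fraction
#' (default 6.7%) of the red bone marrow lies within lumbar vertebrae
#' L2-L4, so `rbm = l24 / f_l24`. Works on fractions of injected activity
#' and, by linearity, on TIACs.
#'
#' @param l24_fraction Fraction of injected activity (or TIAC) in L2-L4.
#' @param f_l24 Fraction of red marrow contained in L2-L4
#'   (0 < f_l24 <= 1; default 0.067).
#' @return Whole-red-marrow fraction (or TIAC).
#' @export
rbm_from_lumbar <- function(l24_fraction, f_l24 = 0.067) {
  if (!(f_l24 > 0 && f_l24 <= 1)) stop("f_l24 must be in (0, 1]")
  stopifnot(all(l24_fraction >= 0))
  l24_fraction / f_l24
}

#' Read a SPECT VOI count table from CSV
#'
#' Required columns: `subject_id`, `region_id`, `time_h`, `counts`,
#' `volume_ml`, `bg_conc_counts_per_ml`.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_spect_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "region_id", "time_h", "counts", "volume_ml",
            "bg_conc_counts_per_ml")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SPECT file missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}
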