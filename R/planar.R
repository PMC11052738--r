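#' Dual-energy-window scatter correction
#'
#' Subtracts an estimate of scattered counts in the photopeak window from
#' the photopeak counts: `net = max(0, peak - k * scatter * w_peak/w_scatter)`
#' where `w` are the energy-window widths. The defaults correspond to a
#' 140.5 keV +/- 10% photopeak (28.1 keV wide) and a 114-126 keV scatter
#' window (12 keV wide) with the conventional k = 0.5.
#'
#' @param counts_peak Photopeak-window counts (>= 0).
#' @param counts_scatter Scatter-window counts (>= 0).
#' @param k Scatter multiplier (>= 0).
#' @param width_peak_kev,width_scatter_kev Window widths in keV.
#' @return Net counts, clamped at 0 (clamping raises a warning).
#' @export
scatter_correct <- function(counts_peak, counts_scatter, k = 0.5,
                            width_peak_kev = 28.1, width_scatter_kev = 12) {
  stopifnot(all(counts_peak >= 0), all(counts_scatter >= 0), k >= 0)
  net <- counts_peak - k * counts_scatter * width_peak_kev / width_scatter_kev
  if (any(net < 0)) {
    warning("scatter correction produced negative counts; clamped to 0")
    net <- pmax(net, 0)
  }
  net
}

#' Background subtraction for a planar ROI
#'
#' `net = max(0, counts - bg_rate * roi_area_px)` with the background rate
#' taken from ROIs delineated outside the body, in counts per pixel.
#'
#' @param counts ROI counts (>= 0).
#' @param bg_rate Background counts per pixel (>= 0).
#' @param roi_area_px ROI area in pixels (> 0).
#' @return Net counts, clamped at 0.
#' @export
background_subtract <- function(counts, bg_rate, roi_area_px) {
  stopifnot(all(counts >= 0), all(bg_rate >= 0), all(roi_area_px > 0))
  pmax(counts - bg_rate * roi_area_px, 0)
}

#' Conjugate-view geometric mean
#'
#' `sqrt(anterior * posterior)` net counts; cancels first-order
#' depth-dependent attenuation when the anterior and posterior attenuation
#' factors multiply to a depth-independent constant.
#'
#' @param net_ant,net_post Net counts from the two views (>= 0).
#' @return Geometric-mean counts.
#' @export
geometric_mean <- function(net_ant, net_post) {
  stopifnot(all(net_ant >= 0), all(net_post >= 0))
  sqrt(net_ant * net_post)
}

# net geometric-mean counts for rows of a planar ROI table
planar_net_gm <- function(rois, scatter_enabled = FALSE, scatter_k = 0.5) {
  ant <- rois$counts_ant
  post <- rois$counts_post
  if (scatter_enabled) {
    sa <- rois$counts_scatter_ant
    sp <- rois$counts_scatter_post
    if (is.null(sa) || is.null(sp) || any(is.na(sa)) || any(is.na(sp)))
      stop("scatter correction enabled but scatter-window counts missing")
    ant <- scatter_correct(ant, sa, k = scatter_k)
    post <- scatter_correct(post, sp, k = scatter_k)
  }
  ant <- background_subtract(ant, rois$bg_rate_ant, rois$roi_area_px)
  post <- background_subtract(post, rois$bg_rate_post, rois$roi_area_px)
  geometric_mean(ant, post)
}

#' Planar calibration from the first pre-void whole-body image
#'
#' At the first whole-body image, acquired before any micturition, the
#' body still contains 100% of the injected activity apart from physical
#' decay. The calibration factor is therefore
#' `CF = net GM whole-body counts / (injected_mbq * exp(-lambda_phys * t))`
#' in counts per MBq.
#'
#' @param first_image_rois One-row planar ROI table (see
#'   [read_planar_csv()] for columns) for the whole-body region of the
#'   first image.
#' @param injected_mbq Injected activity in MBq (> 0).
#' @param constants [decay_constants()] for the nuclide.
#' @param void_times_h Recorded void times; the calibrating image must
#'   precede all of them.
#' @param scatter_enabled,scatter_k Scatter-correction configuration
#'   applied to the calibration image (must match the series).
#' @return An object of class `planar_calibration` with `counts_per_mbq`
#'   and `source_time_h`.
#' @export
calibrate_from_whole_body <- function(first_image_rois, injected_mbq,
                                      constants = decay_constants(),
                                      void_times_h = numeric(0),
                                      scatter_enabled = FALSE,
                                      scatter_k = 0.5) {
  stopifnot(nrow(first_image_rois) == 1L, injected_mbq > 0)
  t0 <- first_image_rois$time_h
  if (length(void_times_h) && t0 >= min(void_times_h))
    stop("calibrating image was taken after a recorded void; ",
         "whole-body self-calibration requires a pre-void image")
  gm <- planar_net_gm(first_image_rois, scatter_enabled, scatter_k)
  if (gm <= 0) stop("whole-body net counts are zero; cannot calibrate")
  cf <- gm / (injected_mbq * exp(-constants$lambda_phys_per_h * t0))
  structure(list(counts_per_mbq = cf, source_time_h = t0),
            class = "planar_calibration")
}

#' @export
print.planar_calibration <- function(x, ...) {
  cat(sprintf("Planar calibration: %.4g counts/MBq (image at %.3g h)\n",
              x$counts_per_mbq, x$source_time_h))
  invisible(x)
}

#' Planar ROI counts to a time-activity curve
#'
#' Converts a series of planar ROI measurements for one region into
#' fractions of injected activity:
#' `fraction_id(t) = net GM counts(t) / CF / injected_mbq`.
#' No decay correction is applied, so the resulting curve carries
#' *effective* kinetics.
#'
#' @param rois Planar ROI table rows for one subject/region.
#' @param cal A `planar_calibration`.
#' @param injected_mbq Injected activity in MBq.
#' @param scatter_enabled,scatter_k Scatter-correction configuration.
#' @return A [time_activity_curve()].
#' @export
roi_activity_series <- function(rois, cal, injected_mbq,
                                scatter_enabled = FALSE, scatter_k = 0.5) {
  if (nrow(rois) == 0L) stop("empty ROI list: no samples to convert")
  if (length(unique(rois$region_id)) != 1L ||
      length(unique(rois$subject_id)) != 1L)
    stop("roi_activity_series expects a single subject/region series")
  if (anyDuplicated(rois$time_h))
    stop("duplicate time points for region ", rois$region_id[1])
  gm <- planar_net_gm(rois, scatter_enabled, scatter_k)
  frac <- gm / cal$counts_per_mbq / injected_mbq
  time_activity_curve(rois$subject_id[1], rois$region_id[1],
                      rois$time_h, pmin(frac, 1))
}

#' Read a planar ROI count table from CSV
#'
#' Required columns: `subject_id`, `region_id`, `time_h`, `counts_ant`,
#' `counts_post`, `bg_rate_ant`, `bg_rate_post`, `roi_area_px`; optional:
#' `counts_scatter_ant`, `counts_scatter_post`, `duration_s`. Counts must
#' already be dwell-normalised to comparable count rates (scan-speed
#' differences are resolved upstream).
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_planar_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "region_id", "time_h", "counts_ant", "counts_post",
            "bg_rate_ant", "bg_rate_post", "roi_area_px")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("planar file missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}
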