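#' Ground-truth kinetics for the synthetic-data generator
#'
#' Defines a subject's true biodistribution: per-organ mono-exponential
#' effective kinetics, whole-body effective half-life, urinary excretion
#' and the voiding schedule. The defaults emulate the magnitudes observed
#' for a fast-clearing renally excreted Tc-99m tracer (organ amplitudes
#' of 0.2-2 %ID, effective half-lives of 1-4 h, whole-body effective
#' half-life 2 h, complete urinary excretion).
#'
#' @param organs Data frame with columns `region_id`, `A0` (fraction of
#'   injected activity at t = 0) and `half_life_eff_h`.
#' @param wb_half_life_eff_h Whole-body effective half-life in hours.
#' @param urine_fraction Fraction of biological clearance entering the
#'   bladder.
#' @param injected_mbq Injected activity in MBq.
#' @param schedule A [voiding_schedule()].
#' @param constants [decay_constants()].
#' @param f_l24 Fraction of red marrow in L2-L4 (drives the simulated
#'   L2-L4 SPECT region).
#' @return An object of class `ground_truth_kinetics`.
#' @export
ground_truth_kinetics <- function(
    organs = data.frame(
      region_id = c("kidneys", "liver", "red_marrow", "pancreas",
                    "heart", "spleen", "lungs"),
      A0 = c(0.0173, 0.0190, 0.0133, 0.0160, 0.0077, 0.0017, 0.0166),
      half_life_eff_h = c(2.6, 2.3, 3.7, 1.0, 1.7, 2.0, 1.0)),
    wb_half_life_eff_h = 2.0,
    urine_fraction = 1.0,
    injected_mbq = 772,
    schedule = voiding_schedule(),
    constants = decay_constants(),
    f_l24 = 0.067) {
  stopifnot(all(c("region_id", "A0", "half_life_eff_h") %in% names(organs)))
  if (sum(organs$A0) > 1) stop("organ amplitudes sum to more than 1")
  if (any(organs$half_life_eff_h <= 0) ||
      any(organs$half_life_eff_h >= constants$t_phys_h))
    stop("organ effective half-lives must lie in (0, T_phys)")
  stopifnot(wb_half_life_eff_h > 0, wb_half_life_eff_h < constants$t_phys_h,
            injected_mbq > 0)
  structure(list(organs = organs, wb_half_life_eff_h = wb_half_life_eff_h,
                 urine_fraction = urine_fraction,
                 injected_mbq = injected_mbq, schedule = schedule,
                 constants = constants, f_l24 = f_l24),
            class = "ground_truth_kinetics")
}

#' Simulate a noise-free biodistribution
#'
#' Evaluates the ground-truth model at the requested times: exact
#' mono-exponential organ fractions, bladder content from the
#' voiding-bladder model, the body retention (whole body excluding
#' bladder content) `W(t) = exp(-lambda_eff_wb * t)`, and the whole-body
#' ROI fraction `W(t) + B(t)`. Times that coincide with a void are
#' sampled immediately post-void (the bladder is empty at the sample).
#'
#' @param truth A [ground_truth_kinetics()].
#' @param times_h Sample times in hours.
#' @param subject_id Label for the generated curves.
#' @return Named list of [time_activity_curve()] objects: one per organ,
#'   plus `l2_l4` (= `f_l24` x red marrow, when red marrow is simulated),
#'   `urinary_bladder`, `whole_body` and `wb_minus_bladder`.
#' @export
simulate_biodistribution <- function(truth, times_h,
                                     subject_id = "SIM1") {
  stopifnot(inherits(truth, "ground_truth_kinetics"), all(times_h >= 0))
  times_h <- sort(unique(times_h))
  inp <- bladder_model_input(truth$wb_half_life_eff_h,
                             truth$urine_fraction, truth$constants)
  curves <- list()
  for (i in seq_len(nrow(truth$organs))) {
    o <- truth$organs[i, ]
    frac <- o$A0 * exp(-log(2) / o$half_life_eff_h * times_h)
    curves[[o$region_id]] <-
      time_activity_curve(subject_id, o$region_id, times_h, frac)
  }
  if ("red_marrow" %in% truth$organs$region_id) {
    curves[["l2_l4"]] <- time_activity_curve(
      subject_id, "l2_l4", times_h,
      truth$f_l24 * curves[["red_marrow"]]$fraction_id)
  }
  B <- bladder_content(times_h, inp, truth$schedule)
  # scans scheduled at a void time see the post-void (empty) bladder
  voids <- void_times_until(truth$schedule,
                            max(times_h) + truth$schedule$repeat_interval_h)
  B[times_h %in% voids] <- 0
  W <- exp(-log(2) / truth$wb_half_life_eff_h * times_h)
  organ_sum <- Reduce(`+`, lapply(
    truth$organs$region_id, function(r) curves[[r]]$fraction_id))
  if (any(organ_sum > W + 1e-9))
    stop("organ fractions exceed body retention at some sample time; ",
         "inconsistent ground truth")
  curves[["urinary_bladder"]] <-
    time_activity_curve(subject_id, "urinary_bladder", times_h, B)
  curves[["wb_minus_bladder"]] <-
    time_activity_curve(subject_id, "wb_minus_bladder", times_h, W)
  curves[["whole_body"]] <-
    time_activity_curve(subject_id, "whole_body", times_h, pmin(W + B, 1))
  curves
}

#' Acquisition model for the synthetic count tables
#'
#' Instrument and geometry parameters of the forward model: planar
#' system sensitivity, per-view attenuation factors (whose product is
#' depth-independent so the conjugate-view geometric mean is unbiased up
#' to noise), a scatter fraction feeding both the photopeak and the
#' scatter window, planar background, ROI areas, SPECT sensitivity and
#' VOI volumes, and the RNG seed. The default schedule is planar imaging
#' at 5, 30, 60, 120 and 240 min and SPECT at 60, 120 and 240 min.
#'
#' @param planar_times_h,spect_times_h Acquisition times in hours.
#' @param sensitivity_counts_per_mbq Planar counts per MBq in each view
#'   before attenuation.
#' @param att_ant,att_post Attenuation factors in (0, 1] applied to the
#'   anterior/posterior view.
#' @param scatter_fraction Scattered-to-primary ratio in the photopeak.
#' @param scatter_k Dual-energy-window multiplier the simulated scatter
#'   window is consistent with (see [scatter_correct()]).
#' @param bg_rate_per_px Planar background counts per pixel.
#' @param roi_area_px,wb_roi_area_px ROI areas in pixels.
#' @param spect_sensitivity_counts_per_mbq SPECT counts per MBq.
#' @param spect_bg_conc_counts_per_ml Background concentration in the
#'   reference sphere, counts/mL.
#' @param voi_volume_ml Named vector of VOI volumes (mL); regions absent
#'   from it default to 300 mL.
#' @param poisson Draw Poisson counts (`TRUE`) or emit noise-free means.
#' @param seed RNG seed for the Poisson draws.
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(
    planar_times_h = c(5, 30, 60, 120, 240) / 60,
    spect_times_h = c(1, 2, 4),
    sensitivity_counts_per_mbq = 2000,
    att_ant = 0.7, att_post = 0.7,
    scatter_fraction = 0.2, scatter_k = 0.5,
    bg_rate_per_px = 0.05,
    roi_area_px = 1500, wb_roi_area_px = 20000,
    spect_sensitivity_counts_per_mbq = 2000,
    spect_bg_conc_counts_per_ml = 2,
    voi_volume_ml = c(kidneys = 300, liver = 1800, spleen = 180,
                      pancreas = 95, heart = 500, lungs = 1000,
                      l2_l4 = 75),
    poisson = TRUE, seed = 1L) {
  stopifnot(sensitivity_counts_per_mbq > 0,
            all(att_ant > 0 & att_ant <= 1),
            all(att_post > 0 & att_post <= 1),
            scatter_fraction >= 0, bg_rate_per_px >= 0)
  structure(as.list(environment()), class = "acquisition_model")
}

#' Project a biodistribution into planar ROI count tables
#'
#' Forward model of the conjugate-view measurement. Per region and view,
#' the mean photopeak counts are
#' `fraction * injected * sensitivity * attenuation * (1 + scatter_fraction) + bg * area`,
#' and the scatter-window mean is chosen so that dual-energy-window
#' subtraction with the model's `scatter_k` removes the scatter
#' contribution in expectation. Realised counts are Poisson draws from
#' those means under the model's seed (bit-identical for identical
#' seeds).
#'
#' @param curves Curve list from [simulate_biodistribution()].
#' @param truth The [ground_truth_kinetics()] that produced `curves`.
#' @param acq An [acquisition_model()].
#' @return Planar ROI count table (see [read_planar_csv()] for columns).
#' @export
project_planar_counts <- function(curves, truth, acq = acquisition_model()) {
  regions <- setdiff(names(curves), c("l2_l4", "wb_minus_bladder"))
  w_peak <- 28.1; w_scat <- 12
  rows <- lapply(regions, function(r) {
    cu <- curves[[r]]
    idx <- match(round(acq$planar_times_h, 9), round(cu$time_h, 9))
    if (any(is.na(idx)))
      stop("curves lack samples at the planar acquisition times; ",
           "simulate_biodistribution() must include them")
    frac <- cu$fraction_id[idx]
    area <- if (r == "whole_body") acq$wb_roi_area_px else acq$roi_area_px
    primary <- frac * truth$injected_mbq * acq$sensitivity_counts_per_mbq
    mk <- function(att) {
      p <- primary * att
      list(peak = p * (1 + acq$scatter_fraction) + acq$bg_rate_per_px * area,
           scat = p * acq$scatter_fraction * w_scat / (acq$scatter_k * w_peak))
    }
    a <- mk(acq$att_ant); p <- mk(acq$att_post)
    data.frame(subject_id = cu$subject_id[1], region_id = r,
               time_h = acq$planar_times_h,
               counts_ant = a$peak, counts_post = p$peak,
               counts_scatter_ant = a$scat, counts_scatter_post = p$scat,
               bg_rate_ant = acq$bg_rate_per_px,
               bg_rate_post = acq$bg_rate_per_px,
               roi_area_px = area, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (acq$poisson) {
    cols <- c("counts_ant", "counts_post", "counts_scatter_ant",
              "counts_scatter_post")
    out[cols] <- with_seed(acq$seed, lapply(out[cols], function(m)
      stats::rpois(length(m), m)))
  }
  out
}

#' Simulate SPECT VOI count tables
#'
#' Mean VOI counts are
#' `fraction * injected * spect_sensitivity + bg_conc * volume`; realised
#' counts are Poisson draws under `seed + 1` (so planar and SPECT noise
#' are independent but both reproducible). The L2-L4 region carries
#' `f_l24` of the red-marrow activity.
#'
#' @inheritParams project_planar_counts
#' @return SPECT VOI count table (see [read_spect_csv()] for columns).
#' @export
simulate_spect_vois <- function(curves, truth, acq = acquisition_model()) {
  regions <- intersect(names(curves),
                       c("kidneys", "liver", "spleen", "pancreas", "heart",
                         "lungs", "l2_l4"))
  rows <- lapply(regions, function(r) {
    cu <- curves[[r]]
    idx <- match(round(acq$spect_times_h, 9), round(cu$time_h, 9))
    if (any(is.na(idx)))
      stop("curves lack samples at the SPECT acquisition times")
    frac <- cu$fraction_id[idx]
    vol <- if (r %in% names(acq$voi_volume_ml))
      acq$voi_volume_ml[[r]] else 300
    mean_counts <- frac * truth$injected_mbq *
      acq$spect_sensitivity_counts_per_mbq +
      acq$spect_bg_conc_counts_per_ml * vol
    data.frame(subject_id = cu$subject_id[1], region_id = r,
               time_h = acq$spect_times_h, counts = mean_counts,
               volume_ml = vol,
               bg_conc_counts_per_ml = acq$spect_bg_conc_counts_per_ml,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (acq$poisson)
    out$counts <- with_seed(acq$seed + 1L,
                            stats::rpois(nrow(out), out$counts))
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: evaluates the biodistribution at the union of the
#' planar and SPECT schedules and produces both count tables plus the
#' ground truth.
#'
#' @param truth A [ground_truth_kinetics()].
#' @param acq An [acquisition_model()].
#' @param subject_id Subject label.
#' @return List with `truth`, `curves`, `planar`, `spect`.
#' @export
simulate_study <- function(truth = ground_truth_kinetics(),
                           acq = acquisition_model(),
                           subject_id = "SIM1") {
  times <- sort(unique(c(acq$planar_times_h, acq$spect_times_h)))
  curves <- simulate_biodistribution(truth, times, subject_id)
  list(truth = truth, curves = curves,
       planar = project_planar_counts(curves, truth, acq),
       spect = simulate_spect_vois(curves, truth, acq))
}
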