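#' Cohort summary of a metric
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' per-patient metric; missing values are excluded and `n` adjusted, as
#' when a region could not be assessed for some patients.
#'
#' @param values Numeric vector, possibly containing `NA`.
#' @return List of class `cohort_summary` with `mean`, `sd` (`NA` for a
#'   single value), `n`.
#' @examples
#' cohort_summary(c(683, 739, 836, 828))  # mean 771.5, sd 73.6
#' @export
cohort_summary <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("all values missing; nothing to summarise")
  structure(list(mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                 n = length(v)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("mean %.6g, SD %s (n = %d)\n", x$mean,
              if (is.na(x$sd)) "-" else sprintf("%.6g", x$sd), x$n))
  invisible(x)
}

#' Append cohort mean and SD columns to a wide per-patient table
#'
#' @param df Data frame whose first column labels the metric (e.g.
#'   `organ`) and whose remaining columns are per-patient values.
#' @return `df` with `mean` and `sd` columns appended.
#' @export
summarize_table <- function(df) {
  vals <- as.matrix(df[, -1, drop = FALSE])
  s <- apply(vals, 1, function(r) {
    cs <- cohort_summary(as.numeric(r))
    c(cs$mean, cs$sd)
  })
  df$mean <- s[1, ]
  df$sd <- s[2, ]
  df
}

#' Read a wide per-patient example table
#'
#' Reads a CSV whose first column is `organ` and whose remaining columns
#' are per-patient values (the layout of the bundled
#' `example_effective_half_lives.csv` / `example_tiacs.csv` files).
#'
#' @param path CSV path.
#' @return Data frame with canonical organ labels.
#' @export
read_cohort_table_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (names(df)[1] != "organ") stop("first column must be 'organ'")
  df$organ <- canonical_organ(df$organ)
  df
}

# default pipeline configuration; user config entries override these
default_config <- function() {
  list(
    scatter = list(enabled = FALSE, k = 0.5),
    bladder = list(void_times_h = c(1, 2, 4), repeat_interval_h = 3.5,
                   urine_fraction = 1.0, wb_curve = "whole_body",
                   use_fitted_amplitude = FALSE),
    spect = list(enabled = TRUE, f_l24 = 0.067,
                 counts_per_mbq = NULL, standard_mbq = NULL,
                 prefer = TRUE),
    kinetics = list(weighting = "uniform"),
    t_phys_h = 6.0067,
    source_organs = c("heart", "kidneys", "liver", "lungs", "pancreas",
                      "red_marrow", "spleen"),
    schemes = c("ICRP103", "ICRP60")
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  merge_config(default_config(), config)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full dosimetry pipeline
#'
#' Orchestrates the whole chain for each subject in the input tables:
#' planar whole-body self-calibration, conjugate-view quantification,
#' optional SPECT VOI quantification (preferred over planar for regions
#' present in both, with provenance recorded), mono-exponential fitting,
#' TIACs, the voiding-bladder model, MIRD organ doses on the synthetic
#' Tc-99m S-value table, and ICRP 103/60 effective doses, plus cohort
#' summaries of every table.
#'
#' @param config A configuration list, or the path to a YAML/JSON file.
#'   Required entries: `planar_csv` (path) and `injected_mbq` (named
#'   vector/list per subject). Optional: `spect_csv`, plus any override
#'   of the defaults (`scatter$enabled`, `scatter$k`,
#'   `bladder$void_times_h`, `bladder$repeat_interval_h`,
#'   `bladder$urine_fraction`, `bladder$wb_curve` in
#'   `{"whole_body", "wb_minus_bladder"}`,
#'   `bladder$use_fitted_amplitude`, `spect$counts_per_mbq`,
#'   `spect$standard_mbq`, `spect$f_l24`, `source_organs`, `schemes`,
#'   `t_phys_h`).
#' @return A list of class `dosimetry_report`: `half_lives`, `tiacs`,
#'   `doses` (wide per-patient tables with mean/SD), `effective_dose`
#'   (per scheme and patient, mSv/MBq), `provenance`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  if (is.null(cfg$planar_csv)) stop("config$planar_csv is required")
  if (!file.exists(cfg$planar_csv))
    stop("planar input file not found: ", cfg$planar_csv)
  if (is.null(cfg$injected_mbq))
    stop("config$injected_mbq (named, per subject) is required")
  planar <- read_planar_csv(cfg$planar_csv)
  spect <- NULL
  if (!is.null(cfg$spect_csv)) {
    if (!file.exists(cfg$spect_csv))
      stop("SPECT input file not found: ", cfg$spect_csv)
    spect <- read_spect_csv(cfg$spect_csv)
  }
  constants <- decay_constants(cfg$t_phys_h)
  injected <- unlist(cfg$injected_mbq)
  subjects <- unique(planar$subject_id)
  miss_inj <- setdiff(subjects, names(injected))
  if (length(miss_inj))
    stop("no injected activity for subject(s): ",
         paste(miss_inj, collapse = ", "))

  svals <- tc99m_svalue_table()
  masses <- phantom_mass_map()
  schedule <- voiding_schedule(cfg$bladder$void_times_h,
                               cfg$bladder$repeat_interval_h)

  per_subject <- lapply(subjects, function(sid) {
    run_subject(sid, planar[planar$subject_id == sid, ],
                if (!is.null(spect)) spect[spect$subject_id == sid, ],
                injected[[sid]], cfg, constants, schedule, svals, masses)
  })
  names(per_subject) <- subjects

  wide <- function(field) {
    organs <- unique(unlist(lapply(per_subject, function(s)
      names(s[[field]]))))
    df <- data.frame(organ = organs, stringsAsFactors = FALSE)
    for (sid in subjects)
      df[[sid]] <- unname(per_subject[[sid]][[field]][organs])
    summarize_table(df)
  }
  ed <- do.call(rbind, lapply(cfg$schemes, function(sch) {
    v <- vapply(per_subject, function(s) s$ed[[sch]], numeric(1))
    cs <- cohort_summary(v)
    data.frame(scheme = sch, t(v), mean = cs$mean, sd = cs$sd)
  }))

  structure(list(
    half_lives = wide("half_lives"),
    tiacs = wide("tiacs"),
    doses = wide("doses"),
    effective_dose = ed,
    provenance = list(
      package = as.character(utils::packageVersion("mirddose")),
      config_hash = config_hash(cfg),
      inputs = c(planar = cfg$planar_csv, spect = cfg$spect_csv),
      subjects = subjects,
      tiac_source = per_subject[[1]]$tiac_source)
  ), class = "dosimetry_report")
}

# full chain for one subject
run_subject <- function(sid, planar, spect, injected_mbq, cfg, constants,
                        schedule, svals, masses) {
  sc_on <- isTRUE(cfg$scatter$enabled); sc_k <- cfg$scatter$k
  wb_rows <- planar[canonical_organ(planar$region_id,
                                    allow_unknown = TRUE) == "whole_body", ]
  if (nrow(wb_rows) == 0L) stop("subject ", sid, ": no whole_body region")
  first <- wb_rows[which.min(wb_rows$time_h), ]
  cal <- calibrate_from_whole_body(first, injected_mbq, constants,
                                   void_times_h = cfg$bladder$void_times_h,
                                   scatter_enabled = sc_on, scatter_k = sc_k)
  regions <- unique(planar$region_id)
  curves <- lapply(regions, function(r)
    roi_activity_series(planar[planar$region_id == r, ], cal, injected_mbq,
                        scatter_enabled = sc_on, scatter_k = sc_k))
  names(curves) <- canonical_organ(regions, allow_unknown = TRUE)
  tiac_source <- stats::setNames(rep("planar", length(curves)),
                                 names(curves))

  # whole-body-minus-bladder curve from the two planar ROIs
  if (all(c("whole_body", "urinary_bladder_contents") %in% names(curves))) {
    wb <- curves[["whole_body"]]; bl <- curves[["urinary_bladder_contents"]]
    curves[["wb_minus_bladder"]] <- time_activity_curve(
      sid, "wb_minus_bladder", wb$time_h,
      pmax(wb$fraction_id - bl$fraction_id, 0))
  }

  # SPECT quantification replaces planar curves where available
  if (!is.null(spect) && nrow(spect) > 0 && isTRUE(cfg$spect$enabled)) {
    if (is.null(cfg$spect$counts_per_mbq))
      stop("SPECT input given but spect$counts_per_mbq calibration missing")
    scal <- spect_calibration(cfg$spect$counts_per_mbq,
                              cfg$spect$standard_mbq %||% 1)
    for (r in unique(spect$region_id)) {
      cu <- voi_activity_series(spect[spect$region_id == r, ], scal,
                                injected_mbq)
      key <- canonical_organ(r, allow_unknown = TRUE)
      if (key == "l2_l4") {
        cu <- time_activity_curve(sid, "red_marrow", cu$time_h,
                                  rbm_from_lumbar(cu$fraction_id,
                                                  cfg$spect$f_l24))
        key <- "red_marrow"
      }
      if (isTRUE(cfg$spect$prefer) || !key %in% names(curves)) {
        curves[[key]] <- cu
        tiac_source[[key]] <- "spect"
      }
    }
  }

  fits <- lapply(curves, function(cu)
    tryCatch(fit_monoexponential(cu, weighting = cfg$kinetics$weighting),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]

  half_lives <- vapply(fits, function(f) f$half_life_eff_h, numeric(1))
  src <- intersect(canonical_organ(cfg$source_organs), names(fits))
  organ_tiacs <- vapply(fits[src], tiac_from_fit, numeric(1))

  wb_key <- if (cfg$bladder$wb_curve == "wb_minus_bladder" &&
                "wb_minus_bladder" %in% names(fits))
    "wb_minus_bladder" else "whole_body"
  wb_fit <- fits[[wb_key]]
  if (is.null(wb_fit)) stop("subject ", sid, ": whole-body fit unavailable")
  binput <- bladder_model_input(wb_fit$half_life_eff_h,
                                cfg$bladder$urine_fraction, constants)
  b_tiac <- bladder_tiac(binput, schedule)
  if (isTRUE(cfg$bladder$use_fitted_amplitude))
    b_tiac <- b_tiac * wb_fit$amplitude_A0

  wbmb_fit <- fits[["wb_minus_bladder"]] %||% fits[["whole_body"]]
  wb_amp <- if (isTRUE(cfg$bladder$use_fitted_amplitude))
    wbmb_fit$amplitude_A0 else 1
  wb_tiac <- wb_amp * wbmb_fit$half_life_eff_h / log(2)

  tiacs <- tiac_set(organ_tiacs, whole_body_tiac_h = wb_tiac,
                    bladder_tiac_h = b_tiac)
  doses <- organ_doses(tiacs, svals, masses)
  ed <- lapply(cfg$schemes, function(sch)
    effective_dose(doses, tissue_weighting_scheme(sch),
                   masses)$ed_msv_per_mbq)
  names(ed) <- cfg$schemes

  list(half_lives = half_lives,
       tiacs = c(organ_tiacs,
                 urinary_bladder_contents = b_tiac,
                 remainder = remainder_tiac(tiacs)),
       doses = stats::setNames(as.numeric(doses), names(doses)),
       ed = ed, tiac_source = tiac_source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dosimetry_report <- function(x, ...) {
  cat("Dosimetry report\n================\n\nEffective half-lives [h]:\n")
  print(round_table(x$half_lives, 2), row.names = FALSE)
  cat("\nTIACs [MBq.h/MBq]:\n")
  print(round_table(x$tiacs, 2, signif = TRUE), row.names = FALSE)
  cat("\nOrgan absorbed-dose coefficients [mGy/MBq]:\n")
  print(round_table(x$doses, 2, signif = TRUE), row.names = FALSE)
  cat("\nEffective dose [mSv/MBq]:\n")
  print(round_table(x$effective_dose, 2, signif = TRUE), row.names = FALSE)
  invisible(x)
}

round_table <- function(df, digits, signif = FALSE) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    if (signif) base::signif(v, digits) else base::round(v, digits))
  df
}

#' Write a dosimetry report bundle to disk
#'
#' Emits `half_lives.csv`, `tiacs.csv`, `doses.csv`,
#' `effective_dose.csv` and `provenance.json` into `dir`. Stored values
#' are full precision; rounding is applied only when printing.
#'
#' @param report A `dosimetry_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("half_lives", "tiacs", "doses", "effective_dose"))
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  writeLines(jsonlite::toJSON(report$provenance, auto_unbox = TRUE,
                              pretty = TRUE, force = TRUE),
             file.path(dir, "provenance.json"))
  invisible(dir)
}
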