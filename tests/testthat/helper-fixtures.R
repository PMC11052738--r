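# shared fixtures: small ground truths, synthetic S-value tables, paths

extdata <- function(file) {
  system.file("extdata", file, package = "mirddose", mustWork = TRUE)
}

# exact mono-exponential curve
monoexp_curve <- function(A0, t_eff, times = c(0.5, 1, 2, 4),
                          subject = "S", region = "r") {
  time_activity_curve(subject, region, times,
                      A0 * exp(-log(2) / t_eff * times))
}

# random synthetic S-value table over n organs + total_body, with masses.
# Self-dose entries are made the largest so the load-time sanity check
# stays quiet.
random_sv_fixture <- function(n = 4, seed = 1) {
  set.seed(seed)
  organs <- paste0("organ_", seq_len(n))
  grid <- expand.grid(target = organs, source = c(organs, "total_body"),
                      stringsAsFactors = FALSE)
  grid$s_mGy_per_MBq_h <- runif(nrow(grid), 1e-5, 1e-3)
  self <- grid$target == grid$source
  grid$s_mGy_per_MBq_h[self] <- runif(sum(self), 2e-3, 1e-2)
  # total-body rows large enough that the remainder mass balance stays
  # positive, as in a physical table
  tb <- grid$source == "total_body"
  grid$s_mGy_per_MBq_h[tb] <- runif(sum(tb), 5e-4, 1e-3)
  masses <- organ_mass_map(
    stats::setNames(runif(n, 50, 2000), organs),
    total_body_mass_g = 73000)
  list(svals = svalue_table(grid), masses = masses, organs = organs)
}

# paper-like default truth and a quiet acquisition model
default_truth <- function(...) ground_truth_kinetics(...)

# piecewise quadrature oracle for the bladder TIAC: integrates the
# content function interval by interval between voids
quad_bladder_tiac <- function(inp, sch, horizon = 200) {
  voids <- mirddose:::void_times_until(sch, horizon)
  edges <- c(0, voids[voids <= horizon], horizon)
  sum(vapply(seq_len(length(edges) - 1), function(i)
    integrate(function(tt) bladder_content(tt, inp, sch),
              edges[i], edges[i + 1], rel.tol = 1e-10)$value, numeric(1)))
}

noise_free_acq <- function(...) {
  acquisition_model(poisson = FALSE, scatter_fraction = 0,
                    bg_rate_per_px = 0, spect_bg_conc_counts_per_ml = 0, ...)
}
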