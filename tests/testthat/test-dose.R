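test_that("remainder TIAC is whole-body minus the delineated organs", {
  # patient P3: (WB - bladder) T_eff 2.1 h -> TIAC 2.1/ln2 = 3.030 h;
  # organ TIACs from the published per-patient column
  organs_p3 <- c(heart = 0.019, kidneys = 0.060, liver = 0.078,
                 pancreas = 0.021, red_marrow = 0.109, spleen = 0.003)
  ts <- tiac_set(organs_p3, whole_body_tiac_h = 2.1 / log(2),
                 bladder_tiac_h = 0.66)
  expect_equal(remainder_tiac(ts), 2.8, tolerance = 0.03)
  # zero organ TIACs: remainder equals the whole-body TIAC
  ts0 <- tiac_set(c(kidneys = 0), whole_body_tiac_h = 2.5,
                  bladder_tiac_h = 0)
  expect_equal(remainder_tiac(ts0), 2.5)
  expect_error(tiac_set(c(kidneys = 3), whole_body_tiac_h = 2.5,
                        bladder_tiac_h = 0), "exceeds")
})

test_that("remainder S-value reduces to known algebraic cases", {
  fx <- random_sv_fixture(4, seed = 21)
  # no delineated sources: remainder is the total-body row
  expect_equal(remainder_svalue("organ_1", fx$svals, fx$masses,
                                character(0)),
               mirddose:::s_lookup(fx$svals, "organ_1", "total_body"))
  # uniform table: remainder S-value equals the common value exactly
  uni <- fx$svals
  uni$entries$s_mGy_per_MBq_h <- 7e-4
  expect_equal(remainder_svalue("organ_2", uni, fx$masses, fx$organs), 7e-4)
})

test_that("remainder S-value equals the brute-force mass balance", {
  for (seed in c(1, 2, 3)) {
    fx <- random_sv_fixture(4, seed = seed)
    for (tg in fx$organs) {
      # independent evaluation of the defining mass-balance sum
      m_tb <- fx$masses$total_body_mass_g
      m_src <- fx$masses$reference_mass_g[fx$organs]
      s_tb <- mirddose:::s_lookup(fx$svals, tg, "total_body")
      s_src <- sapply(fx$organs, function(s)
        mirddose:::s_lookup(fx$svals, tg, s))
      oracle <- (s_tb * m_tb - sum(s_src * m_src)) / (m_tb - sum(m_src))
      expect_equal(remainder_svalue(tg, fx$svals, fx$masses, fx$organs),
                   max(oracle, 0))
    }
  }
})

test_that("remainder bookkeeping conserves total-body mass", {
  fx <- random_sv_fixture(5, seed = 4)
  m_src <- fx$masses$reference_mass_g[fx$organs]
  m_rem <- fx$masses$total_body_mass_g - sum(m_src)
  expect_equal(m_rem + sum(m_src), fx$masses$total_body_mass_g)
  expect_gt(m_rem, 0)
})

test_that("self-dose mass scaling is inverse in the patient mass", {
  expect_equal(mass_scale_self_dose(0.01, 300, 300), 0.01)
  expect_equal(mass_scale_self_dose(0.01, 300, 600), 0.005)
  m <- seq(100, 1000, by = 100)
  expect_true(all(diff(mass_scale_self_dose(0.01, 300, m)) < 0))
})

test_that("organ doses equal a brute-force double loop on random instances", {
  for (seed in c(10, 11)) {
    fx <- random_sv_fixture(5, seed = seed)
    set.seed(seed + 100)
    tiac <- stats::setNames(runif(5, 0.005, 0.1), fx$organs)
    wb <- sum(tiac) + runif(1, 0.5, 3)
    ts <- tiac_set(tiac, whole_body_tiac_h = wb, bladder_tiac_h = 0)
    doses <- organ_doses(ts, fx$svals, fx$masses, targets = fx$organs)
    rem <- wb - sum(tiac)
    for (tg in fx$organs) {
      oracle <- sum(sapply(fx$organs, function(s)
        tiac[[s]] * mirddose:::s_lookup(fx$svals, tg, s))) +
        rem * remainder_svalue(tg, fx$svals, fx$masses, fx$organs)
      expect_equal(unname(doses[tg]), oracle)
    }
  }
})

test_that("single self-irradiating source gives tiac * S", {
  entries <- data.frame(
    target = c("organ_1", "organ_1"),
    source = c("organ_1", "total_body"),
    s_mGy_per_MBq_h = c(0.001, 0.001))
  sv <- svalue_table(entries)
  masses <- organ_mass_map(c(organ_1 = 300), total_body_mass_g = 73000)
  ts <- tiac_set(c(organ_1 = 2), whole_body_tiac_h = 2, bladder_tiac_h = 0)
  d <- organ_doses(ts, sv, masses, targets = "organ_1")
  expect_equal(unname(d["organ_1"]), 0.002)
})

test_that("doses are linear in TIACs and monotone in sources", {
  fx <- random_sv_fixture(4, seed = 30)
  tiac <- stats::setNames(rep(0.05, 4), fx$organs)
  ts1 <- tiac_set(tiac, whole_body_tiac_h = 2, bladder_tiac_h = 0)
  ts2 <- tiac_set(2 * tiac, whole_body_tiac_h = 4, bladder_tiac_h = 0)
  d1 <- organ_doses(ts1, fx$svals, fx$masses, targets = fx$organs)
  d2 <- organ_doses(ts2, fx$svals, fx$masses, targets = fx$organs)
  expect_equal(unclass(d2), 2 * unclass(d1))
  expect_true(all(d1 >= 0))
})

test_that("removing a source organ never increases any dose", {
  tiac <- c(heart = 0.019, kidneys = 0.065, liver = 0.063, lungs = 0.024,
            pancreas = 0.023, red_marrow = 0.071, spleen = 0.005)
  svals <- tc99m_svalue_table(); masses <- phantom_mass_map()
  full <- organ_doses(tiac_set(tiac, 1.9 / log(2), 0.67), svals, masses)
  # drop the kidneys' activity from the body entirely
  less <- organ_doses(tiac_set(tiac[names(tiac) != "kidneys"],
                               1.9 / log(2) - tiac[["kidneys"]], 0.67),
                      svals, masses)
  expect_true(all(less <= full + 1e-12))
})

test_that("unknown TIAC sources fail loudly", {
  fx <- random_sv_fixture(3, seed = 40)
  ts <- tiac_set(c(not_an_organ = 0.1), whole_body_tiac_h = 2,
                 bladder_tiac_h = 0)
  expect_error(organ_doses(ts, fx$svals, fx$masses), "not_an_organ")
})

test_that("patient masses rescale only the self-dose term", {
  fx <- random_sv_fixture(3, seed = 50)
  tiac <- stats::setNames(rep(0.05, 3), fx$organs)
  ts <- tiac_set(tiac, whole_body_tiac_h = 2, bladder_tiac_h = 0)
  d_ref <- organ_doses(ts, fx$svals, fx$masses, targets = fx$organs[1])
  m1 <- fx$masses$reference_mass_g[[fx$organs[1]]]
  masses_p <- organ_mass_map(fx$masses$reference_mass_g,
                             total_body_mass_g = 73000,
                             patient_mass_g = stats::setNames(2 * m1,
                                                              fx$organs[1]))
  d_pat <- organ_doses(ts, fx$svals, masses_p, targets = fx$organs[1])
  s_self <- mirddose:::s_lookup(fx$svals, fx$organs[1], fx$organs[1])
  expect_equal(unname(d_ref[1] - d_pat[1]), 0.05 * s_self / 2)
})

test_that("bundled synthetic S table makes the bladder wall the critical organ", {
  tiacs <- tiac_set(
    c(heart = 0.019, kidneys = 0.065, liver = 0.063, lungs = 0.024,
      pancreas = 0.023, red_marrow = 0.071, spleen = 0.005),
    whole_body_tiac_h = 1.9 / log(2), bladder_tiac_h = 0.67)
  d <- organ_doses(tiacs, tc99m_svalue_table(), phantom_mass_map())
  expect_identical(names(which.max(d)), "urinary_bladder_wall")
  expect_equal(unname(d["urinary_bladder_wall"]), 0.028, tolerance = 0.25)
})
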