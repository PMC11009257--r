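test_that("generation is deterministic per seed and varies across seeds", {
  t1 <- case_template("one_sided_dominant", seed = 7)
  expect_identical(generate_cow(t1), generate_cow(t1))
  t2 <- case_template("one_sided_dominant", seed = 8)
  expect_false(identical(generate_cow(t1), generate_cow(t2)))
  # byte-identical after serialization too
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_network_spec(generate_cow(t1), f1)
  write_network_spec(generate_cow(t1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("template ranges are honoured by every realization", {
  for (seed in 1:10) {
    for (variant in c("one_sided_dominant", "balanced_a2",
                      "hypoplastic_a1")) {
      tpl <- case_template(variant, seed = seed)
      net <- build_network(generate_cow(tpl))
      q <- quartet_from_network(net)
      a1 <- max(q$r_left_a1, q$r_right_a1) / min(q$r_left_a1, q$r_right_a1)
      a2 <- max(q$r_left_a2, q$r_right_a2) / min(q$r_left_a2, q$r_right_a2)
      expect_gte(a1, tpl$a1_ratio_range[1]); expect_lte(a1, tpl$a1_ratio_range[2])
      expect_gte(a2, tpl$a2_ratio_range[1]); expect_lte(a2, tpl$a2_ratio_range[2])
      # dominant (low-resistance) A1 is on the template's dominant side
      expect_lt(q$r_left_a1, q$r_right_a1)
    }
  }
})

test_that("variant-defining bounds are enforced at template construction", {
  expect_error(case_template("one_sided_dominant",
                             a1_ratio_range = c(2, 3)), "infeasible")
  expect_error(case_template("balanced_a2", a2_ratio_range = c(1.2, 1.8)),
               "infeasible")
  expect_error(case_template("hypoplastic_a1", a1_ratio_range = c(5, 12)),
               "infeasible")
  expect_error(case_template("one_sided_dominant",
                             a1_ratio_range = c(4, 3)), "infeasible")
})

test_that("one-sided realizations are always classified as half models", {
  for (seed in 1:20) {
    net <- build_network(
      generate_cow(case_template("one_sided_dominant", seed = seed)))
    d <- select_model(quartet_from_network(net))
    expect_identical(d$model, "left_half")
  }
})

test_that("symmetric realizations are exactly mirror-symmetric for any seed", {
  wfs <- default_inlet_waveforms()
  for (seed in c(1, 99, 20260929)) {
    net <- build_network(generate_cow(case_template("symmetric",
                                                    seed = seed)))
    d <- select_model(quartet_from_network(net))
    expect_identical(d$model, "complete")
    expect_equal(d$a2_ratio, 1)
    f <- acom_inflow_fractions(solve_pulsatile(net, wfs))
    expect_equal(f[["f_left"]], 0.5, tolerance = 1e-9)
  }
})

test_that("packaged fixtures regenerate byte-identically to the shipped files", {
  fx <- generate_case_fixtures()
  for (nm in names(fx)) {
    shipped <- system.file("extdata", paste0(nm, ".json"),
                           package = "cowflow")
    expect_true(nzchar(shipped))
    tmp <- tempfile(fileext = ".json")
    write_network_spec(fx[[nm]], tmp)
    expect_identical(readLines(tmp), readLines(shipped))
  }
})

test_that("fixture 4 carries the printed overrides; decisions split 4 to 1", {
  fx <- generate_case_fixtures()
  seg4 <- fx$case4$segments
  ids <- vapply(seg4, `[[`, character(1), "id")
  expect_identical(seg4[[which(ids == "l_a1")]]$resistance_override, 0.113)
  expect_identical(seg4[[which(ids == "r_a2")]]$resistance_override, 0.079)
  models <- vapply(fx, function(spec) {
    suppressWarnings(
      select_model(quartet_from_network(build_network(spec)))$model)
  }, character(1))
  expect_identical(sum(models == "complete"), 1L)
  expect_identical(unname(models[["case5"]]), "complete")
})

test_that("generated waveforms satisfy their construction contracts", {
  flat <- generate_waveform(waveform_template("BA", amplitude = 0))
  expect_true(all(flat$flow == flat$flow[1]))
  expect_equal(flat$flow[1], 2.0e-6)

  for (amp in c(0.2, 0.5, 0.8)) {
    tpl <- waveform_template("left_ICA", amplitude = amp, peak_time = 0.15)
    wf <- generate_waveform(tpl)
    expect_true(all(wf$flow >= 0))
    # cycle integral equals mean * period
    expect_equal(waveform_mean(wf) * wf$period, 4.0e-6 * 1,
                 tolerance = 1e-9)
    # peak lands at the sample nearest the configured systolic time
    expect_lte(abs(wf$time[which.max(wf$flow)] - 0.15 * wf$period), 0.01)
    expect_equal(max(wf$flow), 4.0e-6 * (1 + amp), tolerance = 1e-12)
  }
  expect_error(waveform_template("left_ICA", amplitude = 1.2), "negative")
  # BA inflow sits below either ICA inflow
  wfs <- default_inlet_waveforms()
  expect_lt(waveform_mean(wfs$BA), waveform_mean(wfs$left_ICA))
  expect_lt(waveform_mean(wfs$BA), waveform_mean(wfs$right_ICA))
})

test_that("default realizations stay in the laminar physiologic Reynolds range", {
  net <- build_network(generate_cow(case_template("symmetric", seed = 6)))
  wfs <- default_inlet_waveforms()
  expect_no_warning(sol <- solve_pulsatile(net, wfs))
  main <- c("l_ica", "r_ica", "ba", "l_a1", "r_a1", "l_a2", "r_a2",
            "l_mca", "r_mca")
  re <- vapply(main, function(id) {
    r <- min(net$segments[[id]]$radius_profile$radius)
    max(reynolds_number(sol$flows[id, ], r, blood, warn = FALSE))
  }, numeric(1))
  expect_true(all(re >= 100 & re <= 2000))
})

test_that("network spec and waveform files round-trip through disk", {
  spec <- generate_cow(case_template("balanced_a2", seed = 9))
  tmp <- tempfile(fileext = ".json")
  write_network_spec(spec, tmp)
  net <- build_network(read_network_spec(tmp))
  expect_equal(quartet_from_network(net),
               quartet_from_network(build_network(spec)))

  wf <- generate_waveform(waveform_template("left_ICA"))
  wtmp <- tempfile(fileext = ".csv")
  write_waveform_csv(wf, wtmp)
  back <- read_waveform_csv(wtmp, period = 1, label = "left_ICA")
  expect_equal(back$flow, wf$flow)
  expect_equal(back$time, wf$time)
})
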