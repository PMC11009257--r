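test_that("steady solve on elementary networks matches hand reductions", {
  q <- 3e-6
  net <- single_segment_net(2e8)
  sol <- solve_steady(net, c(left_ICA = q))
  expect_equal(unname(sol$flows["s", 1]), q)
  expect_equal(unname(sol$pressures["in", 1]), q * 2e8)

  # symmetric Y: equal branch split
  soly <- solve_steady(y_net(1e8, 3e8, 3e8), c(left_ICA = q))
  expect_equal(unname(soly$flows["s1", 1]), q / 2)
  expect_equal(unname(soly$flows["s2", 1]), q / 2)

  # unequal branches split inversely to resistance (R1 = 2 R2 -> 1 : 2)
  sol2 <- solve_steady(y_net(1e8, 4e8, 2e8), c(left_ICA = q))
  expect_equal(unname(sol2$flows["s2", 1] / sol2$flows["s1", 1]), 2)
})

test_that("solver agrees with the series-parallel oracle to 1e-10", {
  q <- 5e-6
  R <- c(1e8, 2e8, 3e8, 1.5e8, 2.5e8, 4e8)
  net <- ladder_net(R)
  oracle <- ladder_oracle(q, R)
  sol <- solve_steady(net, c(left_ICA = q))
  expect_equal(sol$flows[names(oracle$flows), 1], oracle$flows,
               tolerance = 1e-10)
  expect_equal(sol$pressures[names(oracle$pressures), 1],
               oracle$pressures, tolerance = 1e-10)
  # and under pulsatile driving with a constant waveform
  wf <- waveform(seq(0, 0.98, by = 0.02), rep(q, 50), period = 1,
                 label = "left_ICA")
  psol <- solve_pulsatile(net, list(left_ICA = wf))
  expect_equal(max(abs(psol$flows[names(oracle$flows), ] -
                         oracle$flows)) / q, 0, tolerance = 1e-10)
})

test_that("mass is conserved at every node and time step", {
  wfs <- default_inlet_waveforms()
  for (spec in generate_case_fixtures()) {
    sol <- solve_pulsatile(build_network(spec), wfs)
    expect_lt(conservation_residual(sol), 1e-9)
    # total inflow equals total outflow at every instant
    outlet_ids <- c("l_a2", "r_a2", "l_mca", "r_mca", "l_pca", "r_pca")
    total_out <- colSums(sol$flows[outlet_ids, ])
    expect_equal(max(abs(total_out - sol$inlet_total)) /
                   max(sol$inlet_total), 0, tolerance = 1e-9)
  }
})

test_that("flows are invariant under global resistance scaling", {
  wfs <- default_inlet_waveforms()
  net <- build_network(generate_case_fixtures()$case4)
  sol <- solve_pulsatile(net, wfs)
  for (c_scale in c(1e-3, 7, 1e4)) {
    scaled <- scale_resistances(net, c_scale)
    ssol <- solve_pulsatile(scaled, wfs)
    expect_equal(ssol$flows, sol$flows, tolerance = 1e-9)
    expect_equal(ssol$pressures, sol$pressures * c_scale,
                 tolerance = 1e-9)
  }
})

test_that("pressure decreases along the flow direction of every segment", {
  wfs <- default_inlet_waveforms()
  net <- build_network(generate_case_fixtures()$case5)
  sol <- solve_pulsatile(net, wfs)
  for (id in names(net$segments)) {
    s <- net$segments[[id]]
    dp <- sol$pressures[s$from_node, ] - sol$pressures[s$to_node, ]
    expect_true(all(sign(dp) == sign(sol$flows[id, ]) |
                      sol$flows[id, ] == 0))
  }
})

test_that("constant waveforms reproduce the steady solution at every step", {
  net <- build_network(generate_cow(case_template("symmetric", seed = 2)))
  q <- steady_inflows
  wfs <- lapply(names(q), function(lab) {
    waveform(seq(0, 0.98, by = 0.02), rep(q[[lab]], 50), period = 1,
             label = lab)
  })
  names(wfs) <- names(q)
  psol <- solve_pulsatile(net, wfs)
  ssol <- solve_steady(net, q)
  for (k in seq_along(psol$times)) {
    expect_equal(psol$flows[, k], ssol$flows[, 1], tolerance = 1e-12)
  }
})

test_that("single-segment WSS follows the waveform shape (linearity)", {
  t <- seq(0, 0.98, by = 0.02)
  q <- 3e-6 * (1 + 0.4 * sin(2 * pi * t))
  wf <- waveform(t, q, period = 1, label = "left_ICA")
  net <- cow_network(
    nodes = data.frame(id = c("in", "out"), kind = c("inlet", "outlet")),
    segments = list(vessel_segment("s", "in", "out", length = 0.01,
                                   radius = 1.2e-3)),
    variant = "left_half", inlets = c("in" = "left_ICA"))
  sol <- solve_pulsatile(net, list(left_ICA = wf))
  qt <- waveform_at(wf, sol$times)
  expect_equal(sol$wss["s", ] / sol$wss["s", 1], qt / qt[1],
               tolerance = 1e-12)
})

test_that("Poiseuille WSS matches the closed form and its scalings", {
  s <- vessel_segment("s", "a", "b", length = 0.01, radius = 2e-3)
  expect_identical(segment_wss(0, s, blood), 0)
  w <- segment_wss(4e-6, s, blood)
  expect_equal(w, 2.55, tolerance = 1e-2)  # 4 mu Q / (pi r^3) by hand
  expect_equal(segment_wss(8e-6, s, blood), 2 * w)
  half_r <- vessel_segment("s", "a", "b", length = 0.01, radius = 1e-3)
  expect_equal(segment_wss(4e-6, half_r, blood), 8 * w)
  # tapered segments report the worst-case (minimum-radius) wall
  taper <- vessel_segment("s", "a", "b", length = 0.01,
                          radius = cbind(c(0, 0.01), c(2e-3, 1e-3)))
  expect_equal(segment_wss(4e-6, taper, blood), 8 * w)
})

test_that("aneurysm inflow fractions: single feeder, symmetry, bidirectional case", {
  wfs <- default_inlet_waveforms()
  # left-half model: the only feeder delivers everything
  net4 <- build_network(generate_case_fixtures()$case4)
  lh <- split_half(net4, "left")
  f <- acom_inflow_fractions(solve_pulsatile(lh, wfs))
  expect_identical(f[["f_left"]], 1)
  # mirror-symmetric network splits evenly
  sym <- build_network(generate_cow(case_template("symmetric", seed = 11)))
  fs <- acom_inflow_fractions(solve_pulsatile(sym, wfs))
  expect_equal(fs[["f_left"]], 0.5, tolerance = 1e-9)
  expect_equal(sum(fs), 1)
  # case-5 pattern: both sides contribute materially
  net5 <- build_network(generate_case_fixtures()$case5)
  f5 <- acom_inflow_fractions(solve_pulsatile(net5, wfs))
  expect_gt(f5[["f_left"]], 0.1)
  expect_gt(f5[["f_right"]], 0.1)
})

test_that("case-4 pattern crosses the ACom toward the right A2 at all times", {
  wfs <- default_inlet_waveforms()
  net4 <- build_network(generate_case_fixtures()$case4)
  sol <- solve_pulsatile(net4, wfs)
  # crossing = left A1 supply in excess of left A2 drainage, all of which
  # must leave through the contralateral (right) A2
  crossing <- sol$flows["l_a1", ] - sol$flows["l_a2", ]
  expect_true(all(crossing > 0))
  expect_true(all(sol$flows["r_a2", ] > 0))
})

test_that("raising right A1 resistance weakly increases left dominance", {
  wfs <- default_inlet_waveforms()
  spec <- generate_case_fixtures()$case4
  base_R <- 0.302
  f_prev <- -Inf
  for (mult in c(1, 2, 5, 20)) {
    net <- build_network(with_override(spec, "r_a1", base_R * mult))
    f <- acom_inflow_fractions(solve_pulsatile(net, wfs))[["f_left"]]
    expect_gte(f, f_prev)
    f_prev <- f
  }
  expect_gt(f_prev, 0.9)  # extreme asymmetry ends in one-sided feeding
})

test_that("solver input validation catches mismatched configurations", {
  net <- single_segment_net()
  expect_error(solve_steady(net, c(right_ICA = 1e-6)), "left_ICA")
  wf1 <- waveform(seq(0, 0.98, by = 0.02), rep(1e-6, 50), period = 1)
  wf2 <- waveform(seq(0, 0.4, by = 0.1), rep(1e-6, 5), period = 0.5)
  net3 <- build_network(generate_cow(case_template("symmetric", seed = 1)))
  expect_error(
    solve_pulsatile(net3, list(left_ICA = wf1, right_ICA = wf2, BA = wf1)),
    "period")
})
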