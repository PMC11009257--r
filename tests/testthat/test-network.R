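test_that("build_network accepts a minimal valid spec and rejects bad ones", {
  minimal <- list(
    nodes = list(list(id = "in", kind = "inlet"),
                 list(id = "out", kind = "outlet")),
    segments = list(list(id = "s", from = "in", to = "out",
                         length = 0.01, radius = 1e-3)),
    variant = "left_half",
    inlets = list(`in` = "left_ICA"))
  net <- build_network(minimal)
  expect_s3_class(net, "cow_network")
  expect_length(net$segments, 1L)

  bad <- minimal
  bad$segments[[1L]]$to <- "nowhere"
  expect_error(build_network(bad), "nowhere")

  bad2 <- minimal
  bad2$extra_key <- 1
  expect_error(build_network(bad2), "unknown key")

  bad3 <- minimal
  bad3$segments[[1L]]$typo <- TRUE
  expect_error(build_network(bad3), "unknown key")
})

test_that("disconnected graphs and dangling inlets are rejected", {
  expect_error(cow_network(
    nodes = data.frame(id = c("in", "out", "island"),
                       kind = c("inlet", "outlet", "junction")),
    segments = list(seg_R("s", "in", "out", 1e8)),
    variant = "left_half", inlets = c("in" = "left_ICA")),
    "disconnected")
  expect_error(cow_network(
    nodes = data.frame(id = c("in", "j", "out"),
                       kind = c("inlet", "junction", "outlet")),
    segments = list(seg_R("s1", "in", "j", 1e8),
                    seg_R("s2", "j", "out", 1e8),
                    seg_R("s3", "in", "out", 1e8)),
    variant = "left_half", inlets = c("in" = "left_ICA")),
    "exactly one incident")
})

test_that("case-5 fixture carries the published resistance quartet", {
  net <- build_network(generate_case_fixtures()$case5)
  q <- quartet_from_network(net)
  expect_identical(q$r_left_a1, 0.089)
  expect_identical(q$r_right_a1, 0.472)
  expect_identical(q$r_left_a2, 0.285)
  expect_identical(q$r_right_a2, 0.211)
})

test_that("half-model surgery keeps the aneurysm side tree and both A2s", {
  net <- build_network(generate_case_fixtures()$case4)
  before <- length(net$segments)

  lh <- split_half(net, "left")
  expect_identical(lh$variant, "left_half")
  expect_true("left_A1" %in% names(lh$roles))
  expect_false("right_A1" %in% names(lh$roles))
  expect_identical(quartet_from_network(net)$r_left_a1,
                   segment_resistance(lh$segments[[lh$roles$left_A1]],
                                      blood))
  # left half of the 13-segment complete model keeps exactly
  # left ICA + left A1 + both A2 + left MCA
  expect_identical(before, 13L)
  expect_setequal(names(lh$segments),
                  c("l_ica", "l_a1", "l_a2", "r_a2", "l_mca"))
  # aneurysm node and both A2 branches survive on both sides
  rh <- split_half(net, "right")
  for (half in list(lh, rh)) {
    expect_identical(sum(half$nodes$kind == "aneurysm"), 1L)
    expect_true(all(c("left_A2", "right_A2") %in% names(half$roles)))
  }
  # the two halves partition the A1 roles of the complete model
  expect_setequal(c(names(lh$roles), names(rh$roles)),
                  c("left_A1", "right_A1", "left_A2", "right_A2"))

  expect_error(split_half(lh, "left"), "complete")
})

test_that("split_half is pure: the input network is untouched", {
  net <- build_network(generate_case_fixtures()$case4)
  snapshot <- unserialize(serialize(net, NULL))
  invisible(split_half(net, "left"))
  invisible(split_half(net, "right", keep_posterior = TRUE))
  expect_identical(net, snapshot)
})

test_that("keep_posterior retains the basilar tree in the half model", {
  net <- build_network(generate_case_fixtures()$case4)
  lh <- split_half(net, "left", keep_posterior = TRUE)
  expect_true(all(c("ba", "l_pcom", "l_pca", "r_pca") %in%
                    names(lh$segments)))
  expect_false("r_a1" %in% names(lh$segments))
})

test_that("conductance system reduces single segments and junctions correctly", {
  sys1 <- conductance_system(single_segment_net(2e8), blood)
  expect_identical(dim(sys1$G), c(1L, 1L))
  expect_equal(sys1$G[1, 1], 1 / 2e8)

  # Y junction: eliminating outlets leaves parallel conductance at the fork
  sysy <- conductance_system(y_net(1e8, 2e8, 4e8), blood)
  expect_equal(sysy$G["j", "j"], 1 / 1e8 + 1 / 2e8 + 1 / 4e8)
  expect_equal(sysy$G["j", "in"], -1 / 1e8)
})

test_that("reduced conductance matrix is symmetric positive definite", {
  nets <- list(single_segment_net(), y_net(), ladder_net(),
               build_network(generate_case_fixtures()$case5))
  for (net in nets) {
    G <- conductance_system(net, blood)$G
    expect_equal(G, t(G))
    expect_true(all(eigen(G, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})
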