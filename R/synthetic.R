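# run code under a local RNG state, restoring the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Default CoW segment geometry
#'
#' Literature-typical adult dimensions (metres) for the synthetic generator:
#' A1 14 mm long, A2 22 mm, ICA radius 2.0 mm, A1/A2 radius 1.1 mm, plus
#' MCA, PCom, PCA and BA values that put the ACA share of ICA inflow near a
#' quarter and default Reynolds numbers in the physiologic few-hundred
#' range. All entries can be overridden per call.
#'
#' @return Named list of `c(length, radius)` pairs per vessel class.
#' @export
default_cow_geometry <- function() {
  list(ica = c(length = 0.020, radius = 2.0e-3),
       a1 = c(length = 0.014, radius = 1.1e-3),
       a2 = c(length = 0.022, radius = 1.1e-3),
       mca = c(length = 0.030, radius = 1.4e-3),
       pcom = c(length = 0.015, radius = 0.7e-3),
       pca = c(length = 0.030, radius = 1.0e-3),
       ba = c(length = 0.025, radius = 1.5e-3))
}

#' Synthetic case template
#'
#' Describes one anatomical variant of the anterior circulation in terms of
#' the left/right A1 and A2 resistance ratios it should realize:
#'
#' * `one_sided_dominant` — one A1 clearly lower in resistance (ratio above
#'   2.5) and the contralateral A2 clearly lower (A2 ratio above 2): the
#'   pattern where one side feeds the aneurysm and crosses to the opposite
#'   A2.
#' * `balanced_a2` — A2 resistances within 1.5x of each other while the A1s
#'   remain markedly asymmetric: both sides reach the aneurysm.
#' * `hypoplastic_a1` — one A1 at least tenfold higher in resistance
#'   (hypoplastic vessel), with the A2 ordering reversed (the low-resistance
#'   A2 on the dominant side).
#' * `symmetric` — mirror-symmetric network (both ratios 1; noise mirrored
#'   between sides so symmetry is exact for every seed).
#'
#' Ratios are realized exactly by scaling the higher-resistance side's
#' radius by `ratio^(-1/4)`; multiplicative log-normal noise perturbs the
#' radii of the non-discriminating segments (ICA, MCA, PCom, PCA, BA) only,
#' so a template's ratio guarantees hold for every seed.
#'
#' @param variant one of `"one_sided_dominant"`, `"balanced_a2"`,
#'   `"hypoplastic_a1"`, `"symmetric"`.
#' @param dominant_side which A1 has the lower resistance (`"left"` default,
#'   matching the described cases).
#' @param a1_ratio_range,a2_ratio_range numeric length-2 intervals for the
#'   larger-to-smaller resistance ratios; defaults depend on the variant and
#'   must respect its defining bounds.
#' @param a2_low_side side with the lower A2 resistance; default
#'   contralateral to `dominant_side` except for `hypoplastic_a1` where the
#'   ordering is reversed (ipsilateral).
#' @param noise relative s.d. of the log-normal radius perturbation.
#' @param seed integer seed making the realization deterministic.
#' @param geometry baseline dimensions, see [default_cow_geometry()].
#' @return An object of class `case_template`.
#' @export
case_template <- function(variant = c("one_sided_dominant", "balanced_a2",
                                      "hypoplastic_a1", "symmetric"),
                          dominant_side = "left",
                          a1_ratio_range = NULL, a2_ratio_range = NULL,
                          a2_low_side = NULL, noise = 0.05, seed = 1,
                          geometry = default_cow_geometry()) {
  variant <- match.arg(variant)
  dominant_side <- match.arg(dominant_side, c("left", "right"))
  defaults <- switch(variant,
    one_sided_dominant = list(a1 = c(2.8, 4.5), a2 = c(2.2, 3.2)),
    balanced_a2 = list(a1 = c(4.0, 6.5), a2 = c(1.05, 1.45)),
    hypoplastic_a1 = list(a1 = c(12, 18), a2 = c(2.2, 3.0)),
    symmetric = list(a1 = c(1, 1), a2 = c(1, 1)))
  if (is.null(a1_ratio_range)) a1_ratio_range <- defaults$a1
  if (is.null(a2_ratio_range)) a2_ratio_range <- defaults$a2
  chk <- function(rg, nm) {
    if (length(rg) != 2L || any(!is.finite(rg)) || rg[1L] > rg[2L] ||
        rg[1L] < 1) {
      stop("infeasible ", nm, ": need 1 <= lo <= hi", call. = FALSE)
    }
  }
  chk(a1_ratio_range, "a1_ratio_range"); chk(a2_ratio_range, "a2_ratio_range")
  ok <- switch(variant,
    one_sided_dominant = a1_ratio_range[1L] > 2.5 && a2_ratio_range[1L] > 2,
    balanced_a2 = a2_ratio_range[2L] <= 1.5,
    hypoplastic_a1 = a1_ratio_range[1L] >= 10,
    symmetric = all(c(a1_ratio_range, a2_ratio_range) == 1))
  if (!ok) {
    stop("infeasible ranges for variant '", variant,
         "': one_sided_dominant needs a1 > 2.5 and a2 > 2 throughout, ",
         "balanced_a2 needs a2 <= 1.5, hypoplastic_a1 needs a1 >= 10, ",
         "symmetric needs both ratios equal to 1", call. = FALSE)
  }
  if (is.null(a2_low_side)) {
    a2_low_side <- if (variant == "hypoplastic_a1") dominant_side
                   else setdiff(c("left", "right"), dominant_side)
  }
  a2_low_side <- match.arg(a2_low_side, c("left", "right"))
  if (!is.finite(noise) || noise < 0) {
    stop("`noise` must be a non-negative number", call. = FALSE)
  }
  structure(list(variant = variant, dominant_side = dominant_side,
                 a1_ratio_range = a1_ratio_range,
                 a2_ratio_range = a2_ratio_range,
                 a2_low_side = a2_low_side, noise = noise,
                 seed = as.integer(seed), geometry = geometry),
            class = "case_template")
}

# the fixed synthetic topology: three inflows, MCA outflow at each carotid
# terminus, aneurysm node joining both A1s and both A2s, posterior
# circulation reached through the PComs
.cow_spec_skeleton <- function(seg, name) {
  node <- function(id, kind) list(id = id, kind = kind)
  segment <- function(id, from, to, p) {
    out <- list(id = id, label = p$label, from = from, to = to,
                length = p$length, radius = p$radius)
    if (!is.null(p$override)) out$resistance_override <- p$override
    out
  }
  list(
    name = name,
    nodes = list(
      node("l_ica_in", "inlet"), node("r_ica_in", "inlet"),
      node("ba_in", "inlet"),
      node("l_jt", "junction"), node("r_jt", "junction"),
      node("ba_top", "junction"), node("an", "aneurysm"),
      node("l_mca_out", "outlet"), node("r_mca_out", "outlet"),
      node("l_a2_out", "outlet"), node("r_a2_out", "outlet"),
      node("l_pca_out", "outlet"), node("r_pca_out", "outlet")),
    segments = list(
      segment("l_ica", "l_ica_in", "l_jt", seg$l_ica),
      segment("r_ica", "r_ica_in", "r_jt", seg$r_ica),
      segment("ba", "ba_in", "ba_top", seg$ba),
      segment("l_a1", "l_jt", "an", seg$l_a1),
      segment("r_a1", "r_jt", "an", seg$r_a1),
      segment("l_a2", "an", "l_a2_out", seg$l_a2),
      segment("r_a2", "an", "r_a2_out", seg$r_a2),
      segment("l_mca", "l_jt", "l_mca_out", seg$l_mca),
      segment("r_mca", "r_jt", "r_mca_out", seg$r_mca),
      segment("l_pcom", "l_jt", "ba_top", seg$l_pcom),
      segment("r_pcom", "r_jt", "ba_top", seg$r_pcom),
      segment("l_pca", "ba_top", "l_pca_out", seg$l_pca),
      segment("r_pca", "ba_top", "r_pca_out", seg$r_pca)),
    roles = list(left_A1 = "l_a1", right_A1 = "r_a1",
                 left_A2 = "l_a2", right_A2 = "r_a2",
                 posterior = c("ba", "l_pcom", "r_pcom", "l_pca", "r_pca")),
    variant = "complete",
    inlets = list(l_ica_in = "left_ICA", r_ica_in = "right_ICA",
                  ba_in = "BA"))
}

#' Generate a synthetic CoW network specification
#'
#' Deterministically (per seed) realizes the template: samples the A1 and A2
#' resistance ratios uniformly inside the template ranges, sets the
#' higher-resistance side's radius to `base * ratio^(-1/4)` so the realized
#' ratio is exact, perturbs the remaining vessel radii with log-normal noise
#' (mirrored between sides for the symmetric variant), and emits a network
#' spec document that validates under [build_network()].
#'
#' @param template a [case_template()].
#' @return A network specification list (serializable with
#'   [write_network_spec()]).
#' @examples
#' spec <- generate_cow(case_template("one_sided_dominant", seed = 7))
#' net <- build_network(spec)
#' select_model(quartet_from_network(net))$model   # a half model
#' @export
generate_cow <- function(template) {
  stopifnot(inherits(template, "case_template"))
  g <- template$geometry
  .with_seed(template$seed, {
    a1_ratio <- stats::runif(1, template$a1_ratio_range[1L],
                             template$a1_ratio_range[2L])
    a2_ratio <- stats::runif(1, template$a2_ratio_range[1L],
                             template$a2_ratio_range[2L])
    jitter <- function(r) r * exp(stats::rnorm(1, 0, template$noise))
    mirrored <- template$variant == "symmetric"
    side_radius <- function(class) {
      rl <- jitter(g[[class]][["radius"]])
      rr <- if (mirrored) rl else jitter(g[[class]][["radius"]])
      c(left = rl, right = rr)
    }
    r_ica <- side_radius("ica"); r_mca <- side_radius("mca")
    r_pcom <- side_radius("pcom"); r_pca <- side_radius("pca")
    r_ba <- jitter(g$ba[["radius"]])

    a1_high <- setdiff(c("left", "right"), template$dominant_side)
    a2_high <- setdiff(c("left", "right"), template$a2_low_side)
    shrink <- function(base, ratio) base * ratio^(-1 / 4)
    r_a1 <- c(left = g$a1[["radius"]], right = g$a1[["radius"]])
    r_a1[[a1_high]] <- shrink(g$a1[["radius"]], a1_ratio)
    r_a2 <- c(left = g$a2[["radius"]], right = g$a2[["radius"]])
    r_a2[[a2_high]] <- shrink(g$a2[["radius"]], a2_ratio)

    p <- function(label, class, radius) {
      list(label = label, length = g[[class]][["length"]], radius = radius)
    }
    seg <- list(
      l_ica = p("left_ICA", "ica", r_ica[["left"]]),
      r_ica = p("right_ICA", "ica", r_ica[["right"]]),
      ba = p("BA", "ba", r_ba),
      l_a1 = p("left_A1", "a1", r_a1[["left"]]),
      r_a1 = p("right_A1", "a1", r_a1[["right"]]),
      l_a2 = p("left_A2", "a2", r_a2[["left"]]),
      r_a2 = p("right_A2", "a2", r_a2[["right"]]),
      l_mca = p("left_MCA", "mca", r_mca[["left"]]),
      r_mca = p("right_MCA", "mca", r_mca[["right"]]),
      l_pcom = p("left_PCom", "pcom", r_pcom[["left"]]),
      r_pcom = p("right_PCom", "pcom", r_pcom[["right"]]),
      l_pca = p("left_PCA", "pca", r_pca[["left"]]),
      r_pca = p("right_PCA", "pca", r_pca[["right"]]))
    .cow_spec_skeleton(seg,
                       name = sprintf("synthetic_%s_seed%d",
                                      template$variant, template$seed))
  })
}

#' Five packaged case fixtures
#'
#' Synthetic stand-ins for the five study cases. Cases 4 and 5 carry the
#' published A1/A2 resistance quartets verbatim as `resistance_override`
#' values (0.113/0.302/0.203/0.079 and 0.089/0.472/0.285/0.211, on the
#' publication's own scale); the surrounding segments receive overrides
#' equal to their default geometric resistances rescaled by one common
#' factor (chosen so the default A1 maps to 0.2, mid-scale of the printed
#' A1 values) so the whole network lives on a single consistent scale —
#' flows and all ratio-based logic are invariant to that common factor.
#' Cases 1-3 are deterministic template realizations: case 1 hypoplastic A1
#' (seed 101), cases 2-3 one-sided dominant (seeds 102, 103).
#'
#' @return Named list of five network specification lists
#'   (`case1` ... `case5`).
#' @examples
#' fx <- generate_case_fixtures()
#' sapply(fx, function(s) {
#'   d <- suppressWarnings(
#'     select_model(quartet_from_network(build_network(s))))
#'   d$model
#' })
#' @export
generate_case_fixtures <- function() {
  printed_case <- function(name, quartet) {
    g <- default_cow_geometry()
    blood <- fluid_properties()
    geom_R <- function(class) {
      8 * blood$viscosity * g[[class]][["length"]] /
        (pi * g[[class]][["radius"]]^4)
    }
    scale <- 0.2 / geom_R("a1")
    p <- function(label, class, override) {
      list(label = label, length = g[[class]][["length"]],
           radius = g[[class]][["radius"]], override = override)
    }
    seg <- list(
      l_ica = p("left_ICA", "ica", geom_R("ica") * scale),
      r_ica = p("right_ICA", "ica", geom_R("ica") * scale),
      ba = p("BA", "ba", geom_R("ba") * scale),
      l_a1 = p("left_A1", "a1", quartet[[1L]]),
      r_a1 = p("right_A1", "a1", quartet[[2L]]),
      l_a2 = p("left_A2", "a2", quartet[[3L]]),
      r_a2 = p("right_A2", "a2", quartet[[4L]]),
      l_mca = p("left_MCA", "mca", geom_R("mca") * scale),
      r_mca = p("right_MCA", "mca", geom_R("mca") * scale),
      l_pcom = p("left_PCom", "pcom", geom_R("pcom") * scale),
      r_pcom = p("right_PCom", "pcom", geom_R("pcom") * scale),
      l_pca = p("left_PCA", "pca", geom_R("pca") * scale),
      r_pca = p("right_PCA", "pca", geom_R("pca") * scale))
    .cow_spec_skeleton(seg, name = name)
  }
  list(
    case1 = generate_cow(case_template("hypoplastic_a1", seed = 101)),
    case2 = generate_cow(case_template("one_sided_dominant", seed = 102)),
    case3 = generate_cow(case_template("one_sided_dominant", seed = 103)),
    case4 = printed_case("case4_printed_resistances",
                         c(0.113, 0.302, 0.203, 0.079)),
    case5 = printed_case("case5_printed_resistances",
                         c(0.089, 0.472, 0.285, 0.211)))
}

#' Inlet waveform template
#'
#' Parametric stand-in for population-averaged pulsatile inflow curves:
#' `Q(t) = mean * (1 + amplitude * pulse(t))` where `pulse` is a smooth
#' single-peaked shape (periodic von Mises bump) with zero mean on the
#' sample grid and unit peak, peaking at the systolic peak time.
#'
#' @param label inlet label (`left_ICA`, `right_ICA`, `BA`).
#' @param mean_flow cycle-mean flow in m^3/s (> 0); defaults 4.0e-6 for the
#'   ICAs and 2.0e-6 for the BA (the BA carries less flow than either ICA).
#' @param amplitude pulsatility amplitude as a fraction of the mean, in
#'   `[0, 1)`.
#' @param peak_time systolic peak as a fraction of the cycle, in `[0, 1)`.
#' @param period cycle duration in s.
#' @param sharpness concentration of the systolic bump (von Mises kappa).
#' @return An object of class `waveform_template`.
#' @export
waveform_template <- function(label = "left_ICA",
                              mean_flow = if (label == "BA") 2.0e-6
                                          else 4.0e-6,
                              amplitude = 0.5, peak_time = 0.15,
                              period = 1, sharpness = 4) {
  if (!label %in% c("left_ICA", "right_ICA", "BA")) {
    stop("label must be left_ICA, right_ICA or BA", call. = FALSE)
  }
  if (mean_flow <= 0) stop("`mean_flow` must be positive", call. = FALSE)
  if (amplitude < 0 || amplitude >= 1) {
    stop("`amplitude` must lie in [0, 1): larger values force negative ",
         "inlet flow", call. = FALSE)
  }
  if (peak_time < 0 || peak_time >= 1) {
    stop("`peak_time` must lie in [0, 1) as a cycle fraction", call. = FALSE)
  }
  structure(list(label = label, mean_flow = mean_flow,
                 amplitude = amplitude, peak_time = peak_time,
                 period = period, sharpness = sharpness),
            class = "waveform_template")
}

#' Generate a one-cycle inlet waveform from a template
#'
#' Samples the template's pulse at the solver time step. The pulse is
#' normalized to zero mean on the uniform grid (so the cycle integral equals
#' `mean_flow * period` exactly under the trapezoidal rule) and unit peak
#' (so peak flow is `mean_flow * (1 + amplitude)`).
#'
#' @param template a [waveform_template()].
#' @param time_step sample spacing in s; must divide the period.
#' @return A [waveform()].
#' @export
generate_waveform <- function(template, time_step = 0.02) {
  stopifnot(inherits(template, "waveform_template"))
  n <- round(template$period / time_step)
  if (abs(n * time_step - template$period) > 1e-9 * template$period) {
    stop("time_step must divide the period", call. = FALSE)
  }
  t <- seq(0, n - 1L) * time_step
  phase <- 2 * pi * (t / template$period - template$peak_time)
  bump <- exp(template$sharpness * (cos(phase) - 1))
  pulse <- (bump - mean(bump)) / (max(bump) - mean(bump))
  q <- template$mean_flow * (1 + template$amplitude * pulse)
  if (any(q < 0)) {
    stop("amplitude forces negative flow; reduce `amplitude`",
         call. = FALSE)
  }
  waveform(t, q, period = template$period, label = template$label)
}

#' Default inlet waveform set
#'
#' The three inlet waveforms (left ICA, right ICA, BA) generated from the
#' default templates at the solver time step: identical pulse shape on both
#' ICAs, a weaker basilar inflow.
#'
#' @param time_step sample spacing in s.
#' @return Named list of three [waveform()]s keyed by label.
#' @export
default_inlet_waveforms <- function(time_step = 0.02) {
  labs <- c("left_ICA", "right_ICA", "BA")
  stats::setNames(lapply(labs, function(lab) {
    generate_waveform(waveform_template(lab), time_step = time_step)
  }), labs)
}
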