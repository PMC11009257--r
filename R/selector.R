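#' Resistance quartet of the anterior circulation
#'
#' The four vascular resistances the model-selection rule consumes: left and
#' right A1 (pre-communicating) and left and right A2 (post-communicating)
#' segments of the anterior cerebral arteries. Values need only share a
#' common scale — the rule uses ratios, which are scale-free — so resistances
#' read off angiographic reports can be used verbatim.
#'
#' @param r_left_a1,r_right_a1,r_left_a2,r_right_a2 resistances, all > 0,
#'   on any common scale.
#' @return An object of class `resistance_quartet`.
#' @examples
#' resistance_quartet(0.113, 0.302, 0.203, 0.079)
#' @export
resistance_quartet <- function(r_left_a1, r_right_a1, r_left_a2,
                               r_right_a2) {
  v <- c(r_left_a1 = r_left_a1, r_right_a1 = r_right_a1,
         r_left_a2 = r_left_a2, r_right_a2 = r_right_a2)
  if (!all(is.finite(v)) || any(v <= 0)) {
    stop("all four resistances must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(v), class = "resistance_quartet")
}

#' Extract the A1/A2 resistance quartet from a network
#'
#' Reads the four selector resistances off a network's role map, using
#' [segment_resistance()] (overrides included).
#'
#' @param net a [cow_network()] whose role map has all four A1/A2 roles.
#' @param fluid a [fluid_properties()].
#' @return A [resistance_quartet()].
#' @export
quartet_from_network <- function(net, fluid = fluid_properties()) {
  stopifnot(inherits(net, "cow_network"))
  need <- c("left_A1", "right_A1", "left_A2", "right_A2")
  miss <- need[!need %in% names(net$roles)]
  if (length(miss)) {
    stop("role map is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  r <- vapply(need, function(role) {
    segment_resistance(net$segments[[net$roles[[role]]]], fluid)
  }, numeric(1))
  resistance_quartet(r[[1L]], r[[2L]], r[[3L]], r[[4L]])
}

#' Two-step rule for choosing a complete or half CoW model
#'
#' Step one compares the two A2 resistances: when one side's A2 resistance
#' exceeds the other's by more than `threshold` (default twofold), flow
#' through the ACom is effectively one-way and a half model suffices;
#' otherwise both sides feed the aneurysm and the complete model is
#' required. Step two, taken only when a half model is indicated, picks the
#' side whose A1 resistance is lower — the dominant feeding artery. An A2
#' ratio exactly at the threshold resolves to the complete model, the
#' conservative choice. Because only ratios enter, the decision is invariant
#' under rescaling all four resistances by any positive constant.
#'
#' When the A1 resistances differ more than tenfold (hypoplastic A1
#' anatomy), a warning notes that extreme A1 asymmetry can override the A2
#' comparison and the decision deserves case-by-case review.
#'
#' @param resistances a [resistance_quartet()], or anything
#'   [resistance_quartet()] accepts as four positional values.
#' @param threshold A2 larger-to-smaller ratio above which a half model is
#'   selected (default 2).
#' @return An object of class `selection_decision` with fields `model`
#'   (`complete`, `left_half` or `right_half`), `a2_ratio`,
#'   `a1_dominant_side`, `threshold` and `rationale`.
#' @examples
#' select_model(resistance_quartet(0.113, 0.302, 0.203, 0.079))  # left_half
#' select_model(resistance_quartet(0.089, 0.472, 0.285, 0.211))  # complete
#' @export
select_model <- function(resistances, threshold = 2) {
  if (!inherits(resistances, "resistance_quartet")) {
    resistances <- do.call(resistance_quartet, as.list(resistances))
  }
  if (!is.finite(threshold) || threshold < 1) {
    stop("`threshold` must be a ratio >= 1", call. = FALSE)
  }
  q <- resistances
  a2_hi <- max(q$r_left_a2, q$r_right_a2)
  a2_lo <- min(q$r_left_a2, q$r_right_a2)
  a2_ratio <- a2_hi / a2_lo
  a1_ratio <- max(q$r_left_a1, q$r_right_a1) /
    min(q$r_left_a1, q$r_right_a1)
  a1_dominant_side <- if (q$r_left_a1 < q$r_right_a1) "left"
                      else if (q$r_right_a1 < q$r_left_a1) "right"
                      else "none"
  if (a1_ratio > 10) {
    warning("A1 resistances differ more than tenfold (hypoplastic A1?): ",
            "extreme A1 asymmetry may override the A2 comparison",
            call. = FALSE)
  }
  if (a2_ratio > threshold) {
    if (a1_dominant_side == "none") {
      stop("A2 ratio indicates a half model but the A1 resistances are ",
           "equal: no dominant side; choose the half model explicitly",
           call. = FALSE)
    }
    model <- paste0(a1_dominant_side, "_half")
    rationale <- sprintf(
      "A2 resistance ratio %.3g exceeds %.3g: one-sided ACom flow; %s A1 has the lower resistance and dominates",
      a2_ratio, threshold, a1_dominant_side)
  } else {
    model <- "complete"
    rationale <- sprintf(
      "A2 resistance ratio %.3g is within %.3g: both sides feed the aneurysm; complete model required",
      a2_ratio, threshold)
  }
  structure(list(model = model, a2_ratio = a2_ratio, a1_ratio = a1_ratio,
                 a1_dominant_side = a1_dominant_side, threshold = threshold,
                 rationale = rationale),
            class = "selection_decision")
}

#' @export
print.selection_decision <- function(x, ...) {
  cat(sprintf("<selection_decision> model = %s\n", x$model))
  cat(sprintf("  A2 ratio = %.3g (threshold %.3g), A1 ratio = %.3g, dominant side = %s\n",
              x$a2_ratio, x$threshold, x$a1_ratio, x$a1_dominant_side))
  cat(" ", x$rationale, "\n")
  invisible(x)
}

#' Flow-based dominance of one A1 side over the aneurysm
#'
#' Declares a side dominant when it delivers at least `dominance_threshold`
#' of the cycle-integrated inflow into the aneurysm node (default 0.9,
#' i.e. the other side contributes under a tenth); otherwise `"none"`. This
#' is the solver-side counterpart of the resistance-ratio rule: on networks
#' with one-sided resistance patterns the two should agree.
#'
#' @param sol a `flow_solution` over one full cycle.
#' @param roles role map (defaults to the solved network's).
#' @param dominance_threshold inflow fraction required for dominance,
#'   in `(0.5, 1]`.
#' @return `"left"`, `"right"` or `"none"`.
#' @export
dominance_from_flow <- function(sol, roles = sol$network$roles,
                                dominance_threshold = 0.9) {
  if (dominance_threshold <= 0.5 || dominance_threshold > 1) {
    stop("`dominance_threshold` must lie in (0.5, 1]", call. = FALSE)
  }
  f <- acom_inflow_fractions(sol, roles)
  if (f[["f_left"]] >= dominance_threshold) "left"
  else if (f[["f_right"]] >= dominance_threshold) "right"
  else "none"
}

#' Full model-selection report for a complete CoW network
#'
#' Runs the whole pipeline on a complete network: the resistance-ratio rule,
#' a pulsatile solve with flow-based dominance, surgical reduction to both
#' half models, and the complete-versus-half TAWSS differences over the
#' aneurysm feeder set. A flag marks disagreement between the rule-based and
#' flow-based conclusions.
#'
#' @param net a complete-variant [cow_network()] with a full role map.
#' @param waveforms named list of inlet [waveform()]s.
#' @param fluid a [fluid_properties()].
#' @param config a [solver_config()].
#' @param threshold A2 ratio threshold passed to [select_model()].
#' @param dominance_threshold passed to [dominance_from_flow()].
#' @return An object of class `selection_report`: the decision, the inflow
#'   fractions and flow dominance, TAWSS relative differences
#'   complete-vs-left-half and complete-vs-right-half (percent), and an
#'   agreement flag.
#' @export
selection_report <- function(net, waveforms, fluid = fluid_properties(),
                             config = solver_config(), threshold = 2,
                             dominance_threshold = 0.9) {
  stopifnot(inherits(net, "cow_network"))
  decision <- select_model(quartet_from_network(net, fluid), threshold)
  sol <- solve_pulsatile(net, waveforms, fluid, config)
  fractions <- acom_inflow_fractions(sol)
  dominance <- dominance_from_flow(sol,
                                   dominance_threshold = dominance_threshold)
  elements <- unlist(net$roles[c("left_A2", "right_A2")], use.names = FALSE)
  sum_complete <- summarize_hemodynamics(sol, elements)
  half_diff <- vapply(c("left", "right"), function(side) {
    half <- split_half(net, side)
    hsol <- solve_pulsatile(half, waveforms, fluid, config)
    compare_models(sum_complete, summarize_hemodynamics(hsol, elements))
  }, numeric(1))
  rule_side <- sub("_half", "", decision$model)   # "complete" if complete
  flow_side <- if (dominance == "none") "complete" else dominance
  structure(list(decision = decision, inflow_fractions = fractions,
                 flow_dominance = dominance,
                 tawss_diff_left_pct = half_diff[["left"]],
                 tawss_diff_right_pct = half_diff[["right"]],
                 agreement = identical(rule_side, flow_side)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n  rule decision:", x$decision$model,
      sprintf("(A2 ratio %.3g)", x$decision$a2_ratio), "\n")
  cat(sprintf("  flow dominance: %s (f_left = %.3f, f_right = %.3f)\n",
              x$flow_dominance, x$inflow_fractions[["f_left"]],
              x$inflow_fractions[["f_right"]]))
  cat(sprintf("  TAWSS rel. diff: complete vs left half %.1f%%, vs right half %.1f%%\n",
              x$tawss_diff_left_pct, x$tawss_diff_right_pct))
  if (!x$agreement) cat("  NOTE: rule-based and flow-based conclusions disagree\n")
  invisible(x)
}
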