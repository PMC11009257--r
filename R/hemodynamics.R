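#' Time-averaged wall shear stress
#'
#' Cycle average of the WSS magnitude, `TAWSS = (1/T) * integral |tau_w| dt`,
#' by the trapezoidal rule over one full cardiac cycle.
#'
#' @param wss numeric vector of (possibly signed) WSS samples in Pa.
#' @param times sample times in s spanning one full cycle (first to last
#'   sample exactly one period apart), or `NULL` for a single steady sample.
#' @return TAWSS in Pa, >= 0.
#' @examples
#' t <- seq(0, 1, by = 0.02)
#' tawss(sin(2 * pi * t), t)   # 2/pi
#' @export
tawss <- function(wss, times = NULL) {
  if (length(wss) == 0L) stop("empty WSS series", call. = FALSE)
  if (length(wss) == 1L) return(abs(wss))
  if (is.null(times) || length(times) != length(wss)) {
    stop("`times` must accompany a multi-sample series", call. = FALSE)
  }
  period <- times[length(times)] - times[1L]
  if (period <= 0) stop("times must span a positive interval", call. = FALSE)
  a <- abs(wss)
  sum(diff(times) * (a[-1L] + a[-length(a)]) / 2) / period
}

#' WSS at systole or diastole
#'
#' Extracts the WSS sample at the systolic or diastolic instant. By default
#' systole is the time of peak total inlet inflow and diastole the time of
#' minimum total inflow, the natural markers in a flow-driven model; explicit
#' instants can be supplied instead when an external definition (e.g. ECG
#' gating) is preferred.
#'
#' @param wss numeric WSS series (Pa).
#' @param phase `"systole"` or `"diastole"`.
#' @param inlet_total total inlet inflow series aligned with `wss` (used for
#'   the default instants).
#' @param at optional explicit index into the series overriding the default.
#' @return WSS value in Pa at the chosen instant.
#' @export
wss_at_phase <- function(wss, phase = c("systole", "diastole"),
                         inlet_total = NULL, at = NULL) {
  phase <- match.arg(phase)
  if (!is.null(at)) return(wss[[at]])
  if (is.null(inlet_total) || length(inlet_total) != length(wss)) {
    stop("need `inlet_total` aligned with the series (or explicit `at`)",
         call. = FALSE)
  }
  idx <- if (phase == "systole") which.max(inlet_total)
         else which.min(inlet_total)
  wss[[idx]]
}

#' Oscillatory shear index
#'
#' Degree of WSS direction reversal over the cycle,
#' `OSI = 0.5 * (1 - |integral tau_w dt| / integral |tau_w| dt)`,
#' in `[0, 0.5]`: 0 for unidirectional shear, 0.5 for perfectly balanced
#' reversal. Integrals are trapezoidal over one full cycle.
#'
#' @param wss signed WSS series in Pa (the sign carries flow direction).
#' @param times sample times spanning one full cycle.
#' @return OSI, dimensionless in `[0, 0.5]`.
#' @export
osi <- function(wss, times) {
  if (length(wss) < 2L || length(times) != length(wss)) {
    stop("need a multi-sample series with aligned times", call. = FALSE)
  }
  dt <- diff(times)
  signed_int <- sum(dt * (wss[-1L] + wss[-length(wss)]) / 2)
  abs_int <- sum(dt * (abs(wss)[-1L] + abs(wss)[-length(wss)]) / 2)
  if (abs_int <= 0) {
    stop("identically zero WSS series: OSI is undefined", call. = FALSE)
  }
  val <- 0.5 * (1 - abs(signed_int) / abs_int)
  min(max(val, 0), 0.5)
}

#' Relative residence time
#'
#' Combined stagnation surrogate `RRT = 1 / ((1 - 2 OSI) * TAWSS)`,
#' increasing with oscillatory shear and with low mean shear. Undefined at
#' `OSI = 0.5` or zero TAWSS.
#'
#' @param osi_value OSI in `[0, 0.5)`.
#' @param tawss_value TAWSS in Pa, > 0.
#' @return RRT in 1/Pa, > 0.
#' @examples
#' rrt(0.25, 1)   # 2
#' @export
rrt <- function(osi_value, tawss_value) {
  if (any(osi_value < 0 | osi_value >= 0.5)) {
    stop("RRT is undefined for OSI >= 0.5", call. = FALSE)
  }
  if (any(tawss_value <= 0)) {
    stop("RRT is undefined for non-positive TAWSS", call. = FALSE)
  }
  1 / ((1 - 2 * osi_value) * tawss_value)
}

#' Per-segment hemodynamic summary of a pulsatile solution
#'
#' Computes TAWSS, systolic and diastolic WSS, OSI and RRT for every segment
#' of a solved network over the reported cycle, plus aggregate means over a
#' named element set (by default the two A2 branches adjacent to the
#' aneurysm, the feeder set used for complete-versus-half comparisons).
#'
#' @param sol a `flow_solution` from [solve_pulsatile()].
#' @param elements character vector of segment ids for the aggregate block;
#'   `NULL` picks the A2 role segments when present.
#' @return An object of class `hemodynamic_summary`: a list with `per_segment`
#'   (data.frame, one row per segment) and `aggregate` (named means over
#'   `elements`).
#' @export
summarize_hemodynamics <- function(sol, elements = NULL) {
  stopifnot(inherits(sol, "flow_solution"))
  net <- sol$network
  if (is.null(elements)) {
    elements <- unlist(net$roles[c("left_A2", "right_A2")], use.names = FALSE)
  }
  ids <- rownames(sol$wss)
  one <- function(id) {
    seg <- net$segments[[id]]
    w_signed <- segment_wss_signed(sol$flows[id, ], seg,
                                   fluid_properties())
    w_abs <- sol$wss[id, ]
    ta <- tawss(w_abs, sol$times)
    os <- if (length(sol$times) > 1L && any(w_abs > 0)) {
      osi(w_signed, sol$times)
    } else NA_real_
    data.frame(
      segment = id, label = seg$label,
      tawss = ta,
      wss_systole = wss_at_phase(w_abs, "systole", sol$inlet_total),
      wss_diastole = wss_at_phase(w_abs, "diastole", sol$inlet_total),
      osi = os,
      rrt = if (!is.na(os) && os < 0.5 && ta > 0) rrt(os, ta) else NA_real_,
      stringsAsFactors = FALSE)
  }
  per_segment <- do.call(rbind, lapply(ids, one))
  rownames(per_segment) <- per_segment$segment
  missing_el <- setdiff(elements, ids)
  if (length(missing_el)) {
    stop("element set names unknown segment(s): ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  agg <- colMeans(per_segment[elements, c("tawss", "wss_systole",
                                          "wss_diastole"), drop = FALSE])
  structure(list(per_segment = per_segment, elements = elements,
                 aggregate = agg),
            class = "hemodynamic_summary")
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat("<hemodynamic_summary>\n")
  print(x$per_segment[, c("label", "tawss", "wss_systole", "wss_diastole",
                          "osi", "rrt")], digits = 4)
  cat(sprintf("aggregate over {%s}: TAWSS = %.4g Pa\n",
              paste(x$elements, collapse = ", "), x$aggregate[["tawss"]]))
  invisible(x)
}

#' Relative difference between complete- and half-model summaries
#'
#' Percentage difference of the aggregate statistic between a complete-model
#' and a half-model summary, normalized by the complete model:
#' `100 * |mean_complete - mean_half| / mean_complete`. The element sets of
#' the two summaries must describe the same anatomy (matched by segment id).
#'
#' @param complete,half [summarize_hemodynamics()] results.
#' @param statistic which aggregate statistic to compare (default
#'   `"tawss"`).
#' @return Relative difference in percent, >= 0.
#' @examples
#' # identical summaries differ by 0%
#' @export
compare_models <- function(complete, half, statistic = "tawss") {
  stopifnot(inherits(complete, "hemodynamic_summary"),
            inherits(half, "hemodynamic_summary"))
  if (!setequal(complete$elements, half$elements)) {
    stop("summaries aggregate different element sets", call. = FALSE)
  }
  mc <- complete$aggregate[[statistic]]
  mh <- half$aggregate[[statistic]]
  if (mc <= 0) {
    stop("complete-model mean is zero: relative difference undefined",
         call. = FALSE)
  }
  100 * abs(mc - mh) / mc
}
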