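#' Read a network specification from JSON
#'
#' @param path path to a network-spec JSON file.
#' @return The specification list (pass to [build_network()]).
#' @export
read_network_spec <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  # JSON arrays arrive as lists; normalize the few vector-valued fields
  if (!is.null(spec$roles)) {
    spec$roles <- lapply(spec$roles, function(v) as.character(unlist(v)))
  }
  spec$segments <- lapply(spec$segments, function(sg) {
    if (!is.null(sg$radius) && is.list(sg$radius)) {
      sg$radius <- if (length(sg$radius) && is.list(sg$radius[[1L]])) {
        lapply(sg$radius, function(p) as.numeric(unlist(p)))
      } else {
        as.numeric(unlist(sg$radius))
      }
    }
    sg
  })
  spec
}

#' Write a network specification to JSON
#'
#' @param spec a specification list (e.g. from [generate_cow()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_spec <- function(spec, path) {
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an inlet waveform from CSV
#'
#' Expects a header row and two columns `time_s`, `flow_m3s` covering one
#' cardiac cycle.
#'
#' @param path CSV path.
#' @param period cycle duration in s; default: last sample time plus one
#'   sample spacing (uniform grid assumed when not given).
#' @param label inlet label to attach.
#' @return A [waveform()].
#' @export
read_waveform_csv <- function(path, period = NULL, label = NA_character_) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "flow_m3s") %in% names(d))) {
    stop("waveform CSV needs columns time_s and flow_m3s", call. = FALSE)
  }
  if (is.null(period)) {
    dt <- if (nrow(d) > 1L) stats::median(diff(d$time_s)) else 1
    period <- d$time_s[nrow(d)] + dt
  }
  waveform(d$time_s, d$flow_m3s, period = period, label = label)
}

#' Write an inlet waveform to CSV
#'
#' @param wf a [waveform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wf, path) {
  stopifnot(inherits(wf, "cow_waveform"))
  utils::write.csv(data.frame(time_s = wf$time, flow_m3s = wf$flow),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a flow solution as tidy CSV
#'
#' One row per time point, element and quantity: nodal pressures (`Pa`),
#' segment flows (`m3_per_s`) and segment WSS (`Pa`).
#'
#' @param sol a `flow_solution`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_solution_csv <- function(sol, path) {
  stopifnot(inherits(sol, "flow_solution"))
  tidy <- function(m, quantity) {
    data.frame(time = rep(sol$times, each = nrow(m)),
               element = rep(rownames(m), times = ncol(m)),
               quantity = quantity, value = as.vector(m),
               stringsAsFactors = FALSE)
  }
  out <- rbind(tidy(sol$pressures, "pressure"),
               tidy(sol$flows, "flow"),
               tidy(sol$wss, "wss"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a hemodynamic summary as JSON
#'
#' @param summary a [summarize_hemodynamics()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "hemodynamic_summary"))
  jsonlite::write_json(
    list(per_segment = summary$per_segment,
         elements = summary$elements,
         aggregate = as.list(summary$aggregate)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
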