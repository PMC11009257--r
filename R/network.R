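#' Circle of Willis network
#'
#' Construct a validated CoW network from nodes and segments. Nodes are one
#' of four kinds: `inlet` (prescribed inflow: the two ICAs and the BA),
#' `outlet` (zero gauge pressure), `junction`, or `aneurysm`. The aneurysm
#' node represents the AComA sac collapsed onto the ACom junction: a purely
#' resistive network cannot carry intrasaccular recirculation, and the
#' inflow-dominance analysis only needs the flow directions at that junction.
#'
#' Most users build networks from a spec document via [build_network()] or
#' from the synthetic generator ([generate_cow()]); this constructor is the
#' common validated entry point.
#'
#' @param nodes data.frame with columns `id` and `kind`.
#' @param segments list of [vessel_segment()] objects.
#' @param variant one of `"complete"`, `"left_half"`, `"right_half"`.
#' @param inlets named character vector mapping inlet node ids to waveform
#'   labels (`left_ICA`, `right_ICA`, `BA`).
#' @param roles named list mapping anatomical roles (`left_A1`, `right_A1`,
#'   `left_A2`, `right_A2`, optionally `ACom`) to segment ids, plus an
#'   optional `posterior` character vector listing posterior-circulation
#'   segment ids (used by [split_half()]).
#' @param name optional network name.
#' @return An object of class `cow_network`.
#' @seealso [build_network()], [split_half()], [solve_steady()]
#' @export
cow_network <- function(nodes, segments, variant = "complete",
                        inlets = character(), roles = list(), name = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "kind") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  if (!all(nodes$kind %in% c("inlet", "outlet", "junction", "aneurysm"))) {
    stop("node kind must be one of inlet/outlet/junction/aneurysm",
         call. = FALSE)
  }
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(vapply(segments, inherits, logical(1), "vessel_segment"))) {
    stop("`segments` must be a list of vessel_segment objects", call. = FALSE)
  }
  ids <- vapply(segments, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate segment ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(segments) <- ids
  net <- structure(list(nodes = nodes, segments = segments,
                        variant = match.arg(variant,
                          c("complete", "left_half", "right_half")),
                        inlets = inlets, roles = roles, name = name),
                   class = "cow_network")
  validate_network(net)
  net
}

#' @export
print.cow_network <- function(x, ...) {
  cat(sprintf("<cow_network>%s variant = %s\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$variant))
  kinds <- table(x$nodes$kind)
  cat(sprintf("  %d nodes (%s), %d segments\n", nrow(x$nodes),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
              length(x$segments)))
  anat <- setdiff(names(x$roles), "posterior")
  if (length(anat)) {
    cat("  roles:", paste(sprintf("%s=%s", anat, unlist(x$roles[anat])),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

.segment_endpoints <- function(net) {
  data.frame(
    id = names(net$segments),
    from = vapply(net$segments, `[[`, character(1), "from_node"),
    to = vapply(net$segments, `[[`, character(1), "to_node"),
    stringsAsFactors = FALSE, row.names = NULL)
}

.node_degree <- function(net) {
  ep <- .segment_endpoints(net)
  tab <- table(factor(c(ep$from, ep$to), levels = net$nodes$id))
  as.integer(tab)[match(net$nodes$id, names(tab))]
}

#' Validate a CoW network
#'
#' Checks the structural invariants: endpoints exist, the undirected graph is
#' connected, inlet and outlet nodes have exactly one incident segment, a
#' complete variant carries the three named inflows (left ICA, right ICA,
#' BA), a half variant has no contralateral A1, there is at most one aneurysm
#' node, role entries point at existing segments, and every segment has a
#' computable positive resistance. Errors name the offending element.
#'
#' @param net a `cow_network`.
#' @return `net`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "cow_network"))
  ep <- .segment_endpoints(net)
  unknown <- setdiff(unique(c(ep$from, ep$to)), net$nodes$id)
  if (length(unknown)) {
    stop("segment endpoint(s) reference undeclared node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(ep) == 0L) stop("network has no segments", call. = FALSE)
  g <- igraph::graph_from_data_frame(ep[, c("from", "to")], directed = FALSE,
                                     vertices = net$nodes$id)
  if (igraph::components(g)$no != 1L) {
    stop("network graph is disconnected", call. = FALSE)
  }
  deg <- .node_degree(net)
  term <- net$nodes$kind %in% c("inlet", "outlet")
  bad <- net$nodes$id[term & deg != 1L]
  if (length(bad)) {
    stop("inlet/outlet node(s) must have exactly one incident segment: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  inlet_ids <- net$nodes$id[net$nodes$kind == "inlet"]
  if (length(net$inlets)) {
    if (!all(names(net$inlets) %in% inlet_ids)) {
      stop("inlet assignment names non-inlet node(s): ",
           paste(setdiff(names(net$inlets), inlet_ids), collapse = ", "),
           call. = FALSE)
    }
    if (!all(net$inlets %in% c("left_ICA", "right_ICA", "BA"))) {
      stop("inlet waveform labels must be left_ICA, right_ICA or BA",
           call. = FALSE)
    }
  }
  if (net$variant == "complete") {
    if (length(inlet_ids) != 3L ||
        !setequal(unname(net$inlets), c("left_ICA", "right_ICA", "BA"))) {
      stop("a complete CoW must have exactly three inlets assigned to ",
           "left_ICA, right_ICA and BA", call. = FALSE)
    }
  } else {
    contra_a1 <- if (net$variant == "left_half") "right_A1" else "left_A1"
    if (!is.null(net$roles[[contra_a1]])) {
      stop(net$variant, " network must not contain the contralateral A1 (",
           contra_a1, ")", call. = FALSE)
    }
  }
  if (sum(net$nodes$kind == "aneurysm") > 1L) {
    stop("at most one aneurysm node is allowed", call. = FALSE)
  }
  anat <- setdiff(names(net$roles), "posterior")
  role_ids <- unlist(net$roles[anat], use.names = FALSE)
  missing_seg <- setdiff(c(role_ids, net$roles$posterior),
                         names(net$segments))
  if (length(missing_seg)) {
    stop("role map references unknown segment(s): ",
         paste(missing_seg, collapse = ", "), call. = FALSE)
  }
  blood <- fluid_properties()
  for (s in net$segments) {
    r <- segment_resistance(s, blood)
    if (!is.finite(r) || r <= 0) {
      stop("segment '", s$id, "' has non-positive resistance", call. = FALSE)
    }
  }
  invisible(net)
}

.allowed_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
}

#' Build a CoW network from a specification document
#'
#' The spec is a plain list (typically parsed from JSON, see
#' [read_network_spec()]) with keys `nodes` (list of `{id, kind}`),
#' `segments` (list of `{id, label, from, to, length, radius,
#' resistance_override}` where `radius` is a single number in metres or a
#' list of `[arc_position, radius]` pairs), `roles`, `variant`, `inlets`,
#' and optionally `name`. Unknown keys anywhere are rejected so that typos
#' fail loudly rather than being silently ignored.
#'
#' @param spec the specification list.
#' @return A validated [cow_network()].
#' @examples
#' spec <- list(
#'   nodes = list(list(id = "in", kind = "inlet"),
#'                list(id = "out", kind = "outlet")),
#'   segments = list(list(id = "s", from = "in", to = "out",
#'                        length = 0.01, radius = 1e-3)),
#'   variant = "left_half",
#'   inlets = list(`in` = "left_ICA"))
#' build_network(spec)
#' @export
build_network <- function(spec) {
  if (!is.list(spec)) stop("network spec must be a list", call. = FALSE)
  .allowed_keys(spec, c("name", "nodes", "segments", "roles", "variant",
                        "inlets"), "network spec")
  if (is.null(spec$nodes) || is.null(spec$segments)) {
    stop("network spec must contain `nodes` and `segments`", call. = FALSE)
  }
  nodes <- do.call(rbind, lapply(spec$nodes, function(nd) {
    .allowed_keys(nd, c("id", "kind"), "node entry")
    if (is.null(nd$id) || is.null(nd$kind)) {
      stop("each node needs `id` and `kind`", call. = FALSE)
    }
    data.frame(id = nd$id, kind = nd$kind, stringsAsFactors = FALSE)
  }))
  segments <- lapply(spec$segments, function(sg) {
    .allowed_keys(sg, c("id", "label", "from", "to", "length", "radius",
                        "resistance_override"), "segment entry")
    if (is.null(sg$id) || is.null(sg$from) || is.null(sg$to)) {
      stop("each segment needs `id`, `from` and `to`", call. = FALSE)
    }
    radius <- sg$radius
    if (is.list(radius)) {
      radius <- do.call(rbind, lapply(radius, function(p) as.numeric(p)))
    }
    vessel_segment(id = sg$id, from_node = sg$from, to_node = sg$to,
                   length = sg$length, radius = radius,
                   label = if (is.null(sg$label)) sg$id else sg$label,
                   resistance_override = sg$resistance_override)
  })
  roles <- if (is.null(spec$roles)) list() else {
    .allowed_keys(spec$roles, c("left_A1", "right_A1", "left_A2", "right_A2",
                                "ACom", "posterior"), "roles")
    lapply(spec$roles, function(v) as.character(unlist(v)))
  }
  inlets <- character()
  if (!is.null(spec$inlets)) {
    inlets <- vapply(spec$inlets, function(v) as.character(v), character(1))
  }
  cow_network(nodes = nodes, segments = segments,
              variant = if (is.null(spec$variant)) "complete"
                        else spec$variant,
              inlets = inlets, roles = roles, name = spec$name)
}

#' Reduce a complete CoW model to an angiographic half model
#'
#' DSA contrast injected into one ICA opacifies only that side's inflow
#' tree, so half models retain the ipsilateral ICA and A1, the ACom junction
#' with the aneurysm, and both A2 outflow branches distal to it; the
#' contralateral A1 and ICA disappear, and (by default) so does the entire
#' posterior circulation. The posterior segments are the ones listed in
#' `roles$posterior`; set `keep_posterior = TRUE` to retain them (then the BA
#' inlet is kept too). The input network is never modified.
#'
#' @param net a complete-variant [cow_network()] with a role map.
#' @param side `"left"` or `"right"`: which ICA's tree to keep.
#' @param keep_posterior keep BA and posterior segments (default FALSE).
#' @return A new `cow_network` with variant `left_half` or `right_half`.
#' @examples
#' cw <- build_network(generate_cow(case_template("symmetric", seed = 1)))
#' lh <- split_half(cw, "left")
#' lh$variant
#' @export
split_half <- function(net, side = c("left", "right"),
                       keep_posterior = FALSE) {
  stopifnot(inherits(net, "cow_network"))
  side <- match.arg(side)
  if (net$variant != "complete") {
    stop("split_half requires a complete-variant network", call. = FALSE)
  }
  contra_a1 <- paste0(if (side == "left") "right" else "left", "_A1")
  ipsi_a1 <- paste0(side, "_A1")
  if (is.null(net$roles[[ipsi_a1]]) || is.null(net$roles[[contra_a1]])) {
    stop("split_half requires left_A1 and right_A1 in the role map",
         call. = FALSE)
  }
  drop_segs <- net$roles[[contra_a1]]
  if (!keep_posterior) drop_segs <- c(drop_segs, net$roles$posterior)
  keep <- net$segments[setdiff(names(net$segments), drop_segs)]

  # prune everything no longer connected to the kept ICA inlet
  ipsi_label <- paste0(side, "_ICA")
  ipsi_inlet <- names(net$inlets)[net$inlets == ipsi_label]
  if (length(ipsi_inlet) != 1L) {
    stop("complete network must assign exactly one inlet to ", ipsi_label,
         call. = FALSE)
  }
  ep <- data.frame(
    from = vapply(keep, `[[`, character(1), "from_node"),
    to = vapply(keep, `[[`, character(1), "to_node"),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ep, directed = FALSE,
                                     vertices = net$nodes$id)
  comp <- igraph::components(g)$membership
  reachable <- names(comp)[comp == comp[[ipsi_inlet]]]
  keep <- keep[vapply(keep, function(s) {
    s$from_node %in% reachable && s$to_node %in% reachable
  }, logical(1))]
  nodes <- net$nodes[net$nodes$id %in% reachable, , drop = FALSE]
  used <- unique(c(vapply(keep, `[[`, character(1), "from_node"),
                   vapply(keep, `[[`, character(1), "to_node")))
  nodes <- nodes[nodes$id %in% used, , drop = FALSE]

  roles <- net$roles
  roles[[contra_a1]] <- NULL
  roles <- lapply(roles, function(ids) ids[ids %in% names(keep)])
  roles <- roles[vapply(roles, length, integer(1)) > 0L]
  inlets <- net$inlets[names(net$inlets) %in% nodes$id]

  out <- cow_network(nodes = nodes, segments = keep,
                     variant = paste0(side, "_half"),
                     inlets = inlets, roles = roles,
                     name = if (is.null(net$name)) NULL
                            else paste0(net$name, "_", side, "_half"))
  for (role in c(paste0(side, "_A1"), "left_A2", "right_A2")) {
    if (!is.null(net$roles[[role]]) && is.null(out$roles[[role]])) {
      stop("half model lost required segment for role ", role, call. = FALSE)
    }
  }
  out
}

#' Assemble the nodal conductance system
#'
#' Kirchhoff conservation at every node with the Poiseuille flow law per
#' segment yields a weighted graph Laplacian in the segment conductances
#' `1/R`. Outlet nodes carry the zero-gauge Dirichlet condition and are
#' eliminated; rows remain for all interior and inlet nodes, with inflow
#' source terms entering on the right-hand side at inlet nodes. The reduced
#' matrix is symmetric positive definite for any connected network with at
#' least one outlet.
#'
#' @param net a [cow_network()].
#' @param fluid a [fluid_properties()].
#' @return A list with the reduced matrix `G` (free nodes x free nodes), the
#'   free and outlet node ids, and per-segment resistances.
#' @export
conductance_system <- function(net, fluid) {
  stopifnot(inherits(net, "cow_network"))
  node_ids <- net$nodes$id
  n <- length(node_ids)
  R <- vapply(net$segments, segment_resistance, numeric(1), fluid = fluid)
  if (any(R <= 0)) {
    stop("zero or negative segment resistance makes the system singular",
         call. = FALSE)
  }
  ep <- .segment_endpoints(net)
  i <- match(ep$from, node_ids)
  j <- match(ep$to, node_ids)
  G <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  for (k in seq_along(R)) {
    g <- 1 / R[k]
    G[i[k], i[k]] <- G[i[k], i[k]] + g
    G[j[k], j[k]] <- G[j[k], j[k]] + g
    G[i[k], j[k]] <- G[i[k], j[k]] - g
    G[j[k], i[k]] <- G[j[k], i[k]] - g
  }
  outlet <- node_ids[net$nodes$kind == "outlet"]
  if (length(outlet) == 0L) {
    stop("network has no outlet: pressure level is undetermined",
         call. = FALSE)
  }
  free <- setdiff(node_ids, outlet)
  list(G = G[free, free, drop = FALSE], free_nodes = free,
       outlet_nodes = outlet, resistance = R, endpoints = ep)
}
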