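# small fixture networks built in code; resistances set via overrides so
# expected values follow from series-parallel arithmetic

blood <- fluid_properties()

seg_R <- function(id, from, to, R) {
  vessel_segment(id, from, to, resistance_override = R)
}

# inlet -> outlet through one resistance
single_segment_net <- function(R = 1e8) {
  cow_network(
    nodes = data.frame(id = c("in", "out"),
                       kind = c("inlet", "outlet")),
    segments = list(seg_R("s", "in", "out", R)),
    variant = "left_half", inlets = c("in" = "left_ICA"))
}

# inlet -> junction -> two parallel outlet branches
y_net <- function(R0 = 1e8, R1 = 2e8, R2 = 2e8) {
  cow_network(
    nodes = data.frame(id = c("in", "j", "out1", "out2"),
                       kind = c("inlet", "junction", "outlet", "outlet")),
    segments = list(seg_R("s0", "in", "j", R0),
                    seg_R("s1", "j", "out1", R1),
                    seg_R("s2", "j", "out2", R2)),
    variant = "left_half", inlets = c("in" = "left_ICA"))
}

# six-segment series/parallel ladder with a hand-reducible solution
ladder_net <- function(R = c(1e8, 2e8, 3e8, 1.5e8, 2.5e8, 4e8)) {
  cow_network(
    nodes = data.frame(
      id = c("in", "a", "b", "c", "out1", "out2"),
      kind = c("inlet", "junction", "junction", "junction",
               "outlet", "outlet")),
    segments = list(seg_R("s1", "in", "a", R[1]),
                    seg_R("s2", "a", "b", R[2]),
                    seg_R("s3", "a", "b", R[3]),
                    seg_R("s4", "b", "c", R[4]),
                    seg_R("s5", "c", "out1", R[5]),
                    seg_R("s6", "c", "out2", R[6])),
    variant = "left_half", inlets = c("in" = "left_ICA"))
}

# independent oracle: symbolic series-parallel reduction of ladder_net
ladder_oracle <- function(q, R) {
  par2 <- function(a, b) a * b / (a + b)
  flows <- c(s1 = q,
             s2 = q * R[3] / (R[2] + R[3]),
             s3 = q * R[2] / (R[2] + R[3]),
             s4 = q,
             s5 = q * R[6] / (R[5] + R[6]),
             s6 = q * R[5] / (R[5] + R[6]))
  p_c <- q * par2(R[5], R[6])
  p_b <- p_c + q * R[4]
  p_a <- p_b + q * par2(R[2], R[3])
  p_in <- p_a + q * R[1]
  list(flows = flows,
       pressures = c("in" = p_in, a = p_a, b = p_b, c = p_c,
                     out1 = 0, out2 = 0))
}

# rebuild a network with every resistance multiplied by `factor`
scale_resistances <- function(net, factor) {
  segs <- lapply(net$segments, function(s) {
    vessel_segment(s$id, s$from_node, s$to_node,
                   length = s$length,
                   radius = s$radius_profile, label = s$label,
                   resistance_override =
                     segment_resistance(s, blood) * factor)
  })
  cow_network(net$nodes, segs, variant = net$variant,
              inlets = net$inlets, roles = net$roles, name = net$name)
}

# rebuild a fixture spec with one segment's resistance override replaced
with_override <- function(spec, seg_id, value) {
  spec$segments <- lapply(spec$segments, function(sg) {
    if (sg$id == seg_id) sg$resistance_override <- value
    sg
  })
  spec
}

scale_waveform <- function(wf, factor) {
  waveform(wf$time, wf$flow * factor, period = wf$period, label = wf$label)
}

steady_inflows <- c(left_ICA = 4e-6, right_ICA = 4e-6, BA = 2e-6)
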