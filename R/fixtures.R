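# Programmatic fixture networks. These are desk-scale analogs of the device
# families the simulator targets (gradient-generator trees, droplet ring
# networks, membrane test channels), generated entirely in code so every
# module can be exercised without external geometry data.

#' Steady-state concentration cascade
#'
#' Closed-form steady outlet concentrations of a loop-free transport network:
#' starting from the boundary inlet mixtures, the flow-rate-weighted mixing
#' rule is applied node by node in flow order until every node and channel
#' concentration is determined. This is pure algebra on the solved flow field
#' and involves none of the time-stepped slug machinery, which makes it the
#' reference the transient simulation must relax to.
#'
#' @param network an [mf_network()] whose flow graph is acyclic.
#' @param flow_state a [solve_flow()] result for it.
#' @return list with `node_mix` (nodes x species matrix) and `channel_conc`
#'   (channels x species matrix).
#' @export
cascade_concentrations <- function(network, flow_state) {
  sp <- network$species$id
  nd <- network$nodes$id
  ch <- network$channels
  q <- flow_state$channel_flows
  q_eps <- 1e-18
  inj <- active_injections(network, 0)
  known <- stats::setNames(rep(FALSE, length(nd)), nd)
  M <- matrix(0, length(nd), length(sp), dimnames = list(nd, sp))
  for (node in names(inj)) {
    M[node, names(inj[[node]])] <- inj[[node]]
    known[node] <- TRUE
  }
  # boundary nodes with no inflow at all carry pure carrier
  src_of <- function(cid) {
    i <- match(cid, ch$id)
    if (q[cid] > 0) ch$node_a[i] else ch$node_b[i]
  }
  repeat {
    progressed <- FALSE
    for (node in nd[!known]) {
      into <- c(ch$id[ch$node_b == node & q[ch$id] > q_eps],
                ch$id[ch$node_a == node & q[ch$id] < -q_eps])
      if (!length(into)) { known[node] <- TRUE; progressed <- TRUE; next }
      srcs <- vapply(into, src_of, character(1))
      if (!all(known[srcs])) next
      w <- abs(q[into])
      M[node, ] <- colSums(M[srcs, , drop = FALSE] * w) / sum(w)
      known[node] <- TRUE
      progressed <- TRUE
    }
    if (all(known)) break
    if (!progressed) stop("cascade requires an acyclic flow graph")
  }
  src <- vapply(ch$id, src_of, character(1))
  cc <- M[src, , drop = FALSE]
  rownames(cc) <- ch$id
  list(node_mix = M, channel_conc = cc)
}

#' Two-inlet Y junction
#'
#' Two identical inlet channels carrying pure tracer (`C = 1`) and pure
#' carrier (`C = 0`) merge into one outlet channel; both inlets are fed at
#' the same flow rate, so the merge yields a 50/50 mixture.
#'
#' @param Q flow rate of each inlet pump, m^3/s.
#' @param width,height,length channel dimensions, m.
#' @return an [mf_network()] with species `A` (tracer) and `B` (marker of the
#'   second inlet), sink node `"sink"`.
#' @export
make_y_junction <- function(Q = 1e-9, width = 100e-6, height = 50e-6,
                            length = 1e-3) {
  mf_network(
    nodes = list(mf_node("i1"), mf_node("i2"), mf_node("j"),
                 mf_node("sink", is_ground = TRUE, is_sink = TRUE)),
    channels = list(mf_channel("c1", "i1", "j", width, height, length),
                    mf_channel("c2", "i2", "j", width, height, length),
                    mf_channel("out", "j", "sink", width, height, length)),
    pumps = list(mf_pump("p1", "sink", "i1", "flow_rate", Q),
                 mf_pump("p2", "sink", "i2", "flow_rate", Q)),
    species = list(mf_species("A", 1e-9), mf_species("B", 1e-9)),
    injections = list(mf_injection("i1", c(A = 1)),
                      mf_injection("i2", c(B = 1))))
}

#' Two identical channels in parallel
#' @param Q pump flow rate, m^3/s.
#' @param width,height,length channel dimensions, m.
#' @export
make_parallel_pair <- function(Q = 1e-9, width = 100e-6, height = 50e-6,
                               length = 1e-3) {
  mf_network(
    nodes = list(mf_node("in"),
                 mf_node("out", is_ground = TRUE, is_sink = TRUE)),
    channels = list(mf_channel("c1", "in", "out", width, height, length),
                    mf_channel("c2", "in", "out", width, height, length)),
    pumps = list(mf_pump("p1", "out", "in", "flow_rate", Q)))
}

#' Channels in series
#' @param n_channels number of channels in the chain.
#' @param Q pump flow rate, m^3/s (flow-rate pump), or pressure in Pa if
#'   `kind = "pressure"`.
#' @param kind pump kind.
#' @param lengths channel lengths, recycled to `n_channels`.
#' @param width,height cross-section, m.
#' @param species,injections optional species/injection records threaded
#'   through (used for step-response transport tests).
#' @export
make_series_chain <- function(n_channels = 3, Q = 1e-9,
                              kind = c("flow_rate", "pressure"),
                              lengths = 1e-3, width = 100e-6, height = 50e-6,
                              species = list(), injections = list()) {
  kind <- match.arg(kind)
  lengths <- rep_len(lengths, n_channels)
  ids <- c("in", if (n_channels > 1) paste0("n", seq_len(n_channels - 1)),
           "out")
  nodes <- lapply(ids, function(x)
    mf_node(x, is_ground = x == "out", is_sink = x == "out"))
  channels <- lapply(seq_len(n_channels), function(i)
    mf_channel(paste0("c", i), ids[i], ids[i + 1], width, height, lengths[i]))
  mf_network(nodes, channels,
             pumps = list(mf_pump("p1", "out", "in", kind, Q)),
             species = species, injections = injections)
}

#' Gradient-generator splitter tree
#'
#' A splitter/combiner tree in the style of tree-type concentration gradient
#' generators: two inlets (tracer at `C = 1` and carrier at `C = 0`) feed a
#' triangular lattice of mixing stages; stage r has r+1 nodes, each interior
#' node merging the two channels from the stage above, and the final stage's
#' nodes drain through outlet channels into a common sink. Channel lengths
#' (hence stage resistances) can be randomized, which skews the flow splits
#' and thereby the outlet concentrations.
#'
#' The analytic outlet concentrations from [cascade_concentrations()] are
#' returned alongside the network; a symmetric tree with `n_outlets = 3`
#' yields (1, 0.5, 0).
#'
#' @param n_outlets number of outlet channels (>= 2).
#' @param Q flow rate of each of the two inlet pumps, m^3/s.
#' @param width,height channel cross-section, m.
#' @param lengths optional vector of channel lengths, m, in construction
#'   order; by default all 1 mm (symmetric), or uniformly random in
#'   `[0.5, 2]` mm when `randomize = TRUE`.
#' @param randomize logical, draw random stage lengths (uses the current RNG
#'   state; seed outside for reproducibility).
#' @return list with elements `network`, `expected` (named steady tracer
#'   concentration per outlet channel) and `outlet_channels`.
#' @export
make_gradient_tree <- function(n_outlets = 3, Q = 1e-9, width = 100e-6,
                               height = 50e-6, lengths = NULL,
                               randomize = FALSE) {
  if (n_outlets < 2) stop("n_outlets must be >= 2")
  m <- n_outlets - 1          # number of lattice stages below the inlets
  node_id <- function(r, j) if (r == 1) c("i1", "i2")[j] else
    paste0("n", r, "_", j)
  nodes <- list(mf_node("i1"), mf_node("i2"))
  channels <- list()
  add_ch <- function(from, to) {
    channels[[length(channels) + 1L]] <<- list(from = from, to = to)
  }
  if (m >= 2) {
    for (r in 2:m) {
      for (j in seq_len(r + 1)) {
        nodes[[length(nodes) + 1L]] <- mf_node(node_id(r, j))
        if (j - 1 >= 1 && j - 1 <= r) add_ch(node_id(r - 1, j - 1), node_id(r, j))
        if (j <= r) add_ch(node_id(r - 1, j), node_id(r, j))
      }
    }
  }
  nodes[[length(nodes) + 1L]] <- mf_node("sink", is_ground = TRUE,
                                         is_sink = TRUE)
  outlet_channels <- character(n_outlets)
  for (j in seq_len(m + 1)) {
    add_ch(node_id(m, j), "sink")
    outlet_channels[j] <- paste0("c", length(channels))
  }
  n_ch <- length(channels)
  if (is.null(lengths)) {
    lengths <- if (randomize) stats::runif(n_ch, 0.5e-3, 2e-3)
               else rep(1e-3, n_ch)
  }
  lengths <- rep_len(lengths, n_ch)
  ch_recs <- lapply(seq_len(n_ch), function(k)
    mf_channel(paste0("c", k), channels[[k]]$from, channels[[k]]$to,
               width, height, lengths[k]))
  net <- mf_network(
    nodes, ch_recs,
    pumps = list(mf_pump("p1", "sink", "i1", "flow_rate", Q),
                 mf_pump("p2", "sink", "i2", "flow_rate", Q)),
    species = list(mf_species("dye", 1e-9)),
    injections = list(mf_injection("i1", c(dye = 1)),
                      mf_injection("i2", c(dye = 0))))
  fs <- solve_flow(net)
  casc <- cascade_concentrations(net, fs)
  expected <- stats::setNames(casc$channel_conc[outlet_channels, "dye"],
                              outlet_channels)
  list(network = net, expected = expected, outlet_channels = outlet_channels)
}

#' Droplet ring network with bypass modules
#'
#' An injection channel feeds a chain of modules; in each module a short
#' bypass channel and a longer module channel run in parallel between the
#' same two junctions, and the chain drains into a sink. A free droplet
#' always takes the bypass (higher flow); a header droplet parked in the
#' bypass raises its effective resistance above the module channel's and
#' flips the next droplet's branch choice — the routing mechanism of
#' time-sensitive ring designs. The default lengths satisfy
#' `R_bypass < R_module < R_bypass + R_droplet` for the default droplet, so
#' the flip is realizable.
#'
#' @param n_modules number of bypass/module stages (>= 1).
#' @param Q pump flow rate, m^3/s.
#' @param width,height cross-section, m.
#' @param l_in,l_bypass,l_module,l_out channel lengths, m; `l_bypass` and
#'   `l_module` are recycled over modules.
#' @return an [mf_network()] without droplets (attach a schedule via the
#'   network's `droplets` field or [droplet_schedule_from_distances()]).
#' @export
make_ring_network <- function(n_modules = 1, Q = 1e-9, width = 100e-6,
                              height = 50e-6, l_in = 1e-3, l_bypass = 1e-3,
                              l_module = 1.3e-3, l_out = 1e-3) {
  if (n_modules < 1) stop("n_modules must be >= 1")
  l_bypass <- rep_len(l_bypass, n_modules)
  l_module <- rep_len(l_module, n_modules)
  jn <- paste0("j", seq_len(n_modules + 1))
  nodes <- c(list(mf_node("in")), lapply(jn, mf_node),
             list(mf_node("out", is_ground = TRUE, is_sink = TRUE)))
  channels <- list(mf_channel("c_in", "in", jn[1], width, height, l_in))
  for (k in seq_len(n_modules)) {
    channels[[length(channels) + 1L]] <-
      mf_channel(paste0("byp", k), jn[k], jn[k + 1], width, height,
                 l_bypass[k])
    channels[[length(channels) + 1L]] <-
      mf_channel(paste0("mod", k), jn[k], jn[k + 1], width, height,
                 l_module[k])
  }
  channels[[length(channels) + 1L]] <-
    mf_channel("c_out", jn[n_modules + 1], "out", width, height, l_out)
  mf_network(nodes, channels,
             pumps = list(mf_pump("p1", "out", "in", "flow_rate", Q)))
}

#' Single channel with a membrane-coupled tank
#'
#' One channel fed with a constant tracer concentration, with a porous
#' membrane patch along its full length connecting it to a tank of volume
#' `tank_volume`. With the channel held near the inlet concentration, the
#' tank concentration follows the closed form
#' \deqn{C_t(t) = C_c + (C_t(0) - C_c)\,e^{-t/(V_t R_M)},}
#' which is returned as the analytic target (`tau = V_t R_M`). The default
#' fixed step is half the channel residence time, commensurate with the
#' advection grid so slug counts stay bounded.
#'
#' @param Q pump flow rate, m^3/s.
#' @param width,height,length channel dimensions, m.
#' @param pore_radius,porosity,thickness membrane parameters (SI).
#' @param tank_volume tank volume, m^3.
#' @param C_c inlet tracer concentration, mol/m^3.
#' @param D tracer diffusivity, m^2/s.
#' @param horizon simulated horizon as a multiple of `tau`.
#' @return list with `network`, `R_M` (s/m^3), `tau` (s), and a matching
#'   [sim_config()].
#' @export
make_membrane_channel <- function(Q = 1e-9, width = 200e-6, height = 100e-6,
                                  length = 10e-3, pore_radius = 0.5e-6,
                                  porosity = 0.01, thickness = 100e-6,
                                  tank_volume = 1e-9, C_c = 1, D = 1e-9,
                                  horizon = 3) {
  area <- width * length
  net <- mf_network(
    nodes = list(mf_node("in"),
                 mf_node("out", is_ground = TRUE, is_sink = TRUE)),
    channels = list(mf_channel("c1", "in", "out", width, height, length)),
    pumps = list(mf_pump("p1", "out", "in", "flow_rate", Q)),
    species = list(mf_species("drug", D)),
    injections = list(mf_injection("in", c(drug = C_c))),
    membranes = list(mf_membrane("m1", "c1", area, pore_radius, porosity,
                                 thickness, tank_volume)),
    initial_mixture = c(drug = C_c))
  R_M <- as.numeric(membrane_resistance(area, pore_radius, porosity,
                                        thickness, D))
  tau <- tank_volume * R_M
  t_res <- net$channels$volume[1] / Q
  cfg <- sim_config(max_time = horizon * tau, fixed_step = t_res / 2)
  list(network = net, R_M = R_M, tau = tau, config = cfg)
}
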