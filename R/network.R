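# Network data model: nodes, rectangular channels, pumps, fluids, species,
# plus the per-channel hydraulic quantities used by the circuit analogy.

# Geometric prefactor of the rectangular-channel resistance,
# 12 * [1 - (192 h)/(pi^5 w) * tanh(pi w / (2 h))]^-1.
# Shared between the plain channel resistance and the droplet resistance.
rect_prefactor <- function(width, height) {
  12 / (1 - (192 * height / (pi^5 * width)) * tanh(pi * width / (2 * height)))
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("'", nm, "' must be positive and finite", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Hydraulic resistance of a rectangular microchannel
#'
#' Resistance of a straight channel of rectangular cross-section under
#' laminar, fully developed, incompressible flow (the regime in which the
#' pressure-flow relation is linear, \eqn{\Delta P = Q R}):
#' \deqn{R = 12\left[1 - \frac{192 h}{\pi^5 w}\tanh\frac{\pi w}{2h}\right]^{-1}
#'       \frac{\mu l}{w h^3}.}
#' The expression holds for flat channels with aspect ratio `height/width < 1`;
#' for `height/width -> 0` it reduces to \eqn{12 \mu l / (w h^3)}. A warning is
#' emitted above aspect ratio 0.9 where the truncation error of the single-term
#' series grows.
#'
#' All arguments are SI and vectorized.
#'
#' @param width channel width w in m (the wide side).
#' @param height channel height h in m, `height < width`.
#' @param length channel length l in m.
#' @param viscosity dynamic viscosity of the carrier fluid in Pa s.
#' @return hydraulic resistance in Pa s / m^3.
#' @examples
#' channel_resistance(100e-6, 50e-6, 1e-3, 1e-3)
#' @export
channel_resistance <- function(width, height, length, viscosity) {
  check_positive(width = width, height = height, length = length,
                 viscosity = viscosity)
  ar <- height / width
  if (any(ar >= 1)) {
    stop("channel_resistance() requires height/width < 1; ",
         "swap width and height for tall channels", call. = FALSE)
  }
  if (any(ar > 0.9)) {
    warning("aspect ratio height/width > 0.9: the rectangular-channel ",
            "resistance approximation degrades near square cross-sections")
  }
  rect_prefactor(width, height) * viscosity * length / (width * height^3)
}

#' Channel volume
#'
#' @inheritParams channel_resistance
#' @return volume in m^3.
#' @export
channel_volume <- function(width, height, length) {
  check_positive(width = width, height = height, length = length)
  width * height * length
}

#' Network element constructors
#'
#' Small record constructors for the parts of a microfluidic network:
#' nodes (junctions, inlets, sinks), rectangular channels, pumps, carrier
#' fluids, transported species, inlet mixture schedules, droplets, and
#' membrane-coupled tanks. [mf_network()] assembles them.
#'
#' `mf_channel()` normalizes the cross-section orientation: if the input gives
#' `height/width >= 1` but `width/height < 1` the two are swapped (the
#' resistance formula is written for the wide-flat orientation and the swap
#' preserves the physical cross-section); a message notes the swap.
#'
#' @param id unique identifier (character).
#' @param is_ground logical, pressure reference node (exactly one per network).
#' @param is_sink logical, open outlet at reference pressure.
#' @name network-elements
NULL

#' @rdname network-elements
#' @export
mf_node <- function(id, is_ground = FALSE, is_sink = FALSE) {
  data.frame(id = as.character(id), is_ground = isTRUE(is_ground),
             is_sink = isTRUE(is_sink), stringsAsFactors = FALSE)
}

#' @rdname network-elements
#' @param node_a,node_b ids of the channel end nodes; flow is reported
#'   positive from `node_a` to `node_b`.
#' @param width,height,length channel dimensions in m.
#' @export
mf_channel <- function(id, node_a, node_b, width, height, length) {
  check_positive(width = width, height = height, length = length)
  if (node_a == node_b) stop("channel '", id, "': node_a must differ from node_b")
  if (height / width >= 1 && width / height < 1) {
    message("channel '", id, "': swapping width and height to the wide-flat ",
            "orientation (height/width < 1)")
    tmp <- width; width <- height; height <- tmp
  }
  data.frame(id = as.character(id), node_a = as.character(node_a),
             node_b = as.character(node_b), width = width, height = height,
             length = length, stringsAsFactors = FALSE)
}

#' @rdname network-elements
#' @param node_from,node_to pump orientation: fluid is driven from `node_from`
#'   to `node_to`.
#' @param kind `"flow_rate"` (constant-current analog, `value` in m^3/s) or
#'   `"pressure"` (voltage-source analog, `value` in Pa).
#' @param value pump strength.
#' @export
mf_pump <- function(id, node_from, node_to, kind = c("flow_rate", "pressure"),
                    value) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || !is.finite(value)) stop("pump value must be finite")
  data.frame(id = as.character(id), node_from = as.character(node_from),
             node_to = as.character(node_to), kind = kind, value = value,
             stringsAsFactors = FALSE)
}

#' @rdname network-elements
#' @param viscosity dynamic viscosity in Pa s.
#' @export
mf_fluid <- function(id, viscosity) {
  check_positive(viscosity = viscosity)
  data.frame(id = as.character(id), viscosity = viscosity,
             stringsAsFactors = FALSE)
}

#' @rdname network-elements
#' @param diffusion_coefficient free diffusion coefficient in m^2/s.
#' @export
mf_species <- function(id, diffusion_coefficient) {
  check_positive(diffusion_coefficient = diffusion_coefficient)
  data.frame(id = as.character(id),
             diffusion_coefficient = diffusion_coefficient,
             stringsAsFactors = FALSE)
}

#' @rdname network-elements
#' @param node inlet node the mixture enters at (must be a pump outlet, not an
#'   interior junction).
#' @param concentrations named numeric vector, species id -> mol/m^3.
#' @param t_start,t_end activity window in s.
#' @export
mf_injection <- function(node, concentrations, t_start = 0, t_end = Inf) {
  if (any(concentrations < 0) || any(!is.finite(concentrations))) {
    stop("injection concentrations must be finite and >= 0")
  }
  list(node = as.character(node), concentrations = concentrations,
       t_start = t_start, t_end = t_end)
}

#' @rdname network-elements
#' @param channel id of the channel the droplet is injected into.
#' @param t_inject injection time in s.
#' @param b dimensionless droplet resistance factor; experimentally it usually
#'   lies between 2 and 5, default 3 (midpoint of that range).
#' @export
mf_droplet <- function(id, length, channel, t_inject = 0, b = 3) {
  check_positive(length = length, b = b)
  if (b < 2 || b > 5) {
    warning("droplet '", id, "': resistance factor b = ", b,
            " is outside the usual 2-5 range")
  }
  data.frame(id = as.character(id), length = length, b = b,
             channel = as.character(channel), t_inject = t_inject,
             stringsAsFactors = FALSE)
}

#' @rdname network-elements
#' @param area membrane surface area in m^2 (the patch shared with `channel`).
#' @param pore_radius pore radius in m.
#' @param porosity open-area fraction in (0, 1); 0 means impermeable.
#' @param thickness effective membrane thickness in m.
#' @param tank_volume volume of the attached tank compartment in m^3.
#' @export
mf_membrane <- function(id, channel, area, pore_radius, porosity, thickness,
                        tank_volume) {
  check_positive(area = area, pore_radius = pore_radius,
                 thickness = thickness, tank_volume = tank_volume)
  if (porosity < 0 || porosity >= 1) stop("porosity must lie in [0, 1)")
  data.frame(id = as.character(id), channel = as.character(channel),
             area = area, pore_radius = pore_radius, porosity = porosity,
             thickness = thickness, tank_volume = tank_volume,
             stringsAsFactors = FALSE)
}

#' Assemble a microfluidic network
#'
#' Combines nodes, channels, pumps, fluids, species and the optional module
#' inputs (inlet mixture schedules, droplet schedules, membrane/tank
#' attachments) into a single network object. Per-channel hydraulic
#' resistance and volume are computed on construction from the continuous
#' phase viscosity.
#'
#' If no node is marked as ground, the first sink node becomes the pressure
#' reference (with a warning): sinks are open outlets at atmospheric pressure
#' and the nodal analysis needs one reference.
#'
#' @param nodes,channels,pumps,fluids,species lists of the corresponding
#'   element records (see [mf_node()] and friends), or equivalent data frames.
#' @param injections list of [mf_injection()] records.
#' @param droplets list of [mf_droplet()] records.
#' @param membranes list of [mf_membrane()] records.
#' @param continuous_phase id of the carrier fluid whose viscosity sets the
#'   channel resistances; defaults to the first fluid.
#' @param initial_mixture named numeric vector (species -> mol/m^3) the
#'   channels are filled with at t = 0; defaults to pure carrier (all zero).
#' @return an object of class `mf_network`.
#' @seealso [validate_network()], [solve_flow()], [run_simulation()]
#' @export
mf_network <- function(nodes, channels, pumps,
                       fluids = list(mf_fluid("carrier", 1e-3)),
                       species = list(), injections = list(),
                       droplets = list(), membranes = list(),
                       continuous_phase = NULL, initial_mixture = NULL) {
  bind <- function(x, proto) {
    if (is.data.frame(x)) return(x)
    if (length(x) == 0) return(proto)
    do.call(rbind, x)
  }
  nodes <- bind(nodes, mf_node("x")[0, ])
  channels <- bind(channels, mf_channel("x", "a", "b", 2, 1, 1)[0, ])
  pumps <- bind(pumps, mf_pump("x", "a", "b", "flow_rate", 0)[0, ])
  fluids <- bind(fluids, mf_fluid("x", 1)[0, ])
  species <- bind(species, mf_species("x", 1)[0, ])
  droplets <- bind(droplets, mf_droplet("x", 1, "c")[0, ])
  membranes <- bind(membranes, mf_membrane("x", "c", 1, 1, 0.5, 1, 1)[0, ])

  if (!any(nodes$is_ground)) {
    if (any(nodes$is_sink)) {
      gid <- nodes$id[nodes$is_sink][1]
      warning("no ground node marked; using sink node '", gid,
              "' as pressure reference")
      nodes$is_ground[nodes$id == gid] <- TRUE
    }
  }
  if (is.null(continuous_phase)) continuous_phase <- fluids$id[1]
  mu <- fluids$viscosity[match(continuous_phase, fluids$id)]
  if (nrow(channels) > 0) {
    channels$resistance <- channel_resistance(channels$width, channels$height,
                                              channels$length, mu)
    channels$volume <- channel_volume(channels$width, channels$height,
                                      channels$length)
  } else {
    channels$resistance <- numeric(0)
    channels$volume <- numeric(0)
  }
  init <- stats::setNames(rep(0, nrow(species)), species$id)
  if (!is.null(initial_mixture)) {
    unknown <- setdiff(names(initial_mixture), species$id)
    if (length(unknown)) stop("initial_mixture names unknown species: ",
                              paste(unknown, collapse = ", "))
    init[names(initial_mixture)] <- initial_mixture
  }
  structure(list(nodes = nodes, channels = channels, pumps = pumps,
                 fluids = fluids, species = species, injections = injections,
                 droplets = droplets, membranes = membranes,
                 continuous_phase = continuous_phase, viscosity = mu,
                 initial_mixture = init),
            class = "mf_network")
}

#' @export
print.mf_network <- function(x, ...) {
  cat("<mf_network> ", nrow(x$nodes), " nodes, ", nrow(x$channels),
      " channels, ", nrow(x$pumps), " pumps", sep = "")
  if (nrow(x$species)) cat(", ", nrow(x$species), " species", sep = "")
  if (length(x$injections)) cat(", ", length(x$injections), " injections",
                                sep = "")
  if (nrow(x$droplets)) cat(", ", nrow(x$droplets), " droplets", sep = "")
  if (nrow(x$membranes)) cat(", ", nrow(x$membranes), " membranes", sep = "")
  cat("\n  carrier '", x$continuous_phase, "' (viscosity ", x$viscosity,
      " Pa s)\n", sep = "")
  invisible(x)
}

#' Validate a network description
#'
#' Checks structural well-formedness and returns the list of violations found
#' (an empty character vector means the network is valid): the channel/pump
#' graph must be connected, at least one pump must drive the network, exactly
#' one ground node must exist, every channel must satisfy `height/width < 1`,
#' all referenced ids must resolve, droplets must fit their injection channel,
#' and an injection node must be a pump outlet rather than an interior
#' junction (the node-mixing rule is undefined for a node that is both).
#'
#' @param network an [mf_network()].
#' @return character vector of violation messages (empty if valid).
#' @export
validate_network <- function(network) {
  v <- character(0)
  nd <- network$nodes; ch <- network$channels; pp <- network$pumps
  if (anyDuplicated(nd$id)) v <- c(v, "duplicate node ids")
  if (anyDuplicated(ch$id)) v <- c(v, "duplicate channel ids")
  if (nrow(pp) == 0) v <- c(v, "no source: network has no pump")
  ng <- sum(nd$is_ground)
  if (ng != 1) v <- c(v, paste0("expected exactly one ground node, found ", ng))
  bad <- ch$id[ch$height / ch$width >= 1]
  for (b in bad) v <- c(v, paste0("channel '", b, "' violates height/width < 1"))
  refs <- unique(c(ch$node_a, ch$node_b, pp$node_from, pp$node_to))
  miss <- setdiff(refs, nd$id)
  if (length(miss)) v <- c(v, paste0("unknown node id(s): ",
                                     paste(miss, collapse = ", ")))
  if (nrow(nd) > 1 && (nrow(ch) + nrow(pp)) > 0 && length(miss) == 0) {
    edges <- rbind(ch[, c("node_a", "node_b")],
                   stats::setNames(pp[, c("node_from", "node_to")],
                                   c("node_a", "node_b")))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nd$id)
    comp <- igraph::components(g)
    if (comp$no > 1) {
      memb <- comp$membership[nd$id]
      main <- as.integer(names(which.max(table(memb))))
      stray <- nd$id[memb != main]
      v <- c(v, paste0("graph not connected; floating node(s): ",
                       paste(stray, collapse = ", ")))
    }
  }
  for (inj in network$injections) {
    if (!inj$node %in% nd$id) {
      v <- c(v, paste0("injection at unknown node '", inj$node, "'"))
      next
    }
    if (!inj$node %in% pp$node_to) {
      v <- c(v, paste0("injection node '", inj$node,
                       "' must be a pump outlet, not an interior junction"))
    }
    unknown <- setdiff(names(inj$concentrations), network$species$id)
    if (length(unknown)) {
      v <- c(v, paste0("injection at '", inj$node, "' names unknown species: ",
                       paste(unknown, collapse = ", ")))
    }
  }
  if (nrow(network$droplets)) {
    m <- match(network$droplets$channel, ch$id)
    if (anyNA(m)) {
      v <- c(v, "droplet injection channel not found")
    } else {
      toolong <- network$droplets$length >= ch$length[m]
      for (d in network$droplets$id[toolong]) {
        v <- c(v, paste0("droplet '", d, "' does not fit its injection channel"))
      }
    }
  }
  if (nrow(network$membranes)) {
    miss <- setdiff(network$membranes$channel, ch$id)
    if (length(miss)) v <- c(v, paste0("membrane attached to unknown channel: ",
                                       paste(miss, collapse = ", ")))
  }
  v
}

#' Stop unless a network validates
#' @keywords internal
assert_valid_network <- function(network) {
  v <- validate_network(network)
  if (length(v)) {
    stop("invalid network:\n  - ", paste(v, collapse = "\n  - "), call. = FALSE)
  }
  invisible(network)
}
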