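# Instantaneous hydraulic circuit solver: Modified Nodal Analysis on the
# resistor-network analog (pressure <-> voltage, flow rate <-> current).

# Channels with vanishing resistance would make the nodal matrix singular;
# physically R > 0 always, so a floor is enforced.
.min_resistance <- 1e-30

#' Assemble the Modified Nodal Analysis system
#'
#' Builds the linear system for the instantaneous flow problem. Unknowns are
#' the pressures of all non-ground nodes plus one flow unknown per pressure
#' pump; equations are mass conservation at every non-ground node (the
#' current-law analog) plus one pressure constraint per pressure pump.
#' Flow-rate pumps enter the right-hand side as fixed injections
#' (constant-current sources).
#'
#' @param network an [mf_network()].
#' @param effective_resistances optional named vector of per-channel
#'   resistances R* in Pa s/m^3 overriding the geometric values (used by the
#'   droplet module); names are channel ids.
#' @return a list with the matrix `A`, right-hand side `b`, the unknown
#'   labels (`p:<node>` and `q:<pump>`), and index maps.
#' @export
assemble_system <- function(network, effective_resistances = NULL) {
  nd <- network$nodes; ch <- network$channels; pp <- network$pumps
  R <- effective_channel_resistances(network, effective_resistances)
  ground <- nd$id[nd$is_ground]
  if (length(ground) != 1) stop("exactly one ground node required")
  unk_nodes <- setdiff(nd$id, ground)
  ppumps <- pp[pp$kind == "pressure", , drop = FALSE]
  fpumps <- pp[pp$kind == "flow_rate", , drop = FALSE]
  n <- length(unk_nodes) + nrow(ppumps)
  A <- matrix(0, n, n)
  b <- numeric(n)
  nidx <- stats::setNames(seq_along(unk_nodes), unk_nodes)
  row_of <- function(node) if (node == ground) 0L else nidx[[node]]

  g <- 1 / pmax(R, .min_resistance)
  for (i in seq_len(nrow(ch))) {
    ia <- row_of(ch$node_a[i]); ib <- row_of(ch$node_b[i])
    if (ia > 0) A[ia, ia] <- A[ia, ia] + g[i]
    if (ib > 0) A[ib, ib] <- A[ib, ib] + g[i]
    if (ia > 0 && ib > 0) {
      A[ia, ib] <- A[ia, ib] - g[i]
      A[ib, ia] <- A[ib, ia] - g[i]
    }
  }
  # flow-rate pump from -> to: extracts at node_from, injects at node_to
  for (i in seq_len(nrow(fpumps))) {
    ifrom <- row_of(fpumps$node_from[i]); ito <- row_of(fpumps$node_to[i])
    if (ito > 0) b[ito] <- b[ito] + fpumps$value[i]
    if (ifrom > 0) b[ifrom] <- b[ifrom] - fpumps$value[i]
  }
  # pressure pump: auxiliary flow unknown q (from -> to through the pump)
  # with constraint P(to) - P(from) = value
  for (i in seq_len(nrow(ppumps))) {
    qi <- length(unk_nodes) + i
    ifrom <- row_of(ppumps$node_from[i]); ito <- row_of(ppumps$node_to[i])
    if (ito > 0) { A[ito, qi] <- A[ito, qi] - 1; A[qi, ito] <- 1 }
    if (ifrom > 0) { A[ifrom, qi] <- A[ifrom, qi] + 1; A[qi, ifrom] <- -1 }
    b[qi] <- ppumps$value[i]
  }
  list(A = A, b = b,
       unknowns = c(paste0("p:", unk_nodes),
                    if (nrow(ppumps)) paste0("q:", ppumps$id)),
       node_index = nidx, ground = ground, ppump_ids = ppumps$id,
       resistances = R)
}

# Resolve base or droplet-modified channel resistances into a named vector
# ordered like network$channels.
effective_channel_resistances <- function(network, effective_resistances) {
  ch <- network$channels
  if (is.null(effective_resistances)) {
    return(stats::setNames(ch$resistance, ch$id))
  }
  miss <- setdiff(ch$id, names(effective_resistances))
  if (length(miss)) stop("effective_resistances missing channel(s): ",
                         paste(miss, collapse = ", "))
  stats::setNames(as.numeric(effective_resistances[ch$id]), ch$id)
}

#' Solve the instantaneous flow field
#'
#' Solves the hydraulic circuit by Modified Nodal Analysis: node pressures
#' (relative to the ground node at 0 Pa), signed channel flow rates
#' (`Q = (P_a - P_b)/R*`, positive from `node_a` to `node_b`) and pump flow
#' rates. The solve is direct (dense LU); networks in this abstraction are
#' small, so robustness is preferred over sparse machinery.
#'
#' @inheritParams assemble_system
#' @param time simulation time stamp attached to the returned state, s.
#' @return an object of class `mf_flow_state` with elements `time`,
#'   `node_pressures`, `channel_flows`, `pump_flows`,
#'   `effective_resistances`.
#' @examples
#' net <- make_parallel_pair()
#' solve_flow(net)
#' @export
solve_flow <- function(network, effective_resistances = NULL, time = 0) {
  nd <- network$nodes
  sys <- assemble_system(network, effective_resistances)
  x <- tryCatch(solve(sys$A, sys$b), error = function(e) {
    stop("singular hydraulic system (floating subnetwork or missing ",
         "reference); check validate_network(): ", conditionMessage(e),
         call. = FALSE)
  })
  p <- stats::setNames(rep(0, nrow(nd)), nd$id)
  if (length(sys$node_index)) {
    p[names(sys$node_index)] <- x[sys$node_index]
  }
  ch <- network$channels
  R <- pmax(sys$resistances, .min_resistance)
  qch <- stats::setNames((p[ch$node_a] - p[ch$node_b]) / R, ch$id)
  pp <- network$pumps
  qp <- stats::setNames(rep(NA_real_, nrow(pp)), pp$id)
  qp[pp$kind == "flow_rate"] <- pp$value[pp$kind == "flow_rate"]
  if (length(sys$ppump_ids)) {
    qp[sys$ppump_ids] <- x[length(sys$node_index) + seq_along(sys$ppump_ids)]
  }
  structure(list(time = time, node_pressures = p, channel_flows = qch,
                 pump_flows = qp, effective_resistances = sys$resistances),
            class = "mf_flow_state")
}

#' @export
print.mf_flow_state <- function(x, ...) {
  cat("<mf_flow_state> t =", x$time, "s\n")
  cat("  pressures [Pa]:\n")
  print(signif(x$node_pressures, 6))
  cat("  channel flows [m^3/s]:\n")
  print(signif(x$channel_flows, 6))
  invisible(x)
}

#' Mass-conservation residuals at the network nodes
#'
#' For every non-ground node, sums the signed channel and pump flows and
#' normalizes by the largest flow magnitude anywhere in the network (so
#' quiescent dead-end nodes, whose incident flows are pure rounding noise,
#' report a residual near zero rather than noise/noise). At a valid solution
#' the relative residuals are at rounding level (well below 1e-9).
#'
#' @param flow_state result of [solve_flow()].
#' @param network the network it was solved on.
#' @return named numeric vector of relative residuals per non-ground node.
#' @export
check_conservation <- function(flow_state, network) {
  nd <- network$nodes; ch <- network$channels; pp <- network$pumps
  scale <- max(abs(flow_state$channel_flows), abs(flow_state$pump_flows), 0)
  out <- stats::setNames(numeric(0), character(0))
  for (node in nd$id[!nd$is_ground]) {
    q <- c(-flow_state$channel_flows[ch$id[ch$node_a == node]],
           flow_state$channel_flows[ch$id[ch$node_b == node]],
           flow_state$pump_flows[pp$id[pp$node_to == node]],
           -flow_state$pump_flows[pp$id[pp$node_from == node]])
    out[node] <- if (scale == 0) 0 else abs(sum(q)) / scale
  }
  out
}

#' Two-terminal equivalent hydraulic resistance
#'
#' Resistance seen between two nodes of the channel network under a unit
#' probe flow: all pumps are removed, `port_b` is grounded, a unit flow is
#' driven from `port_b` to `port_a`, and the resulting pressure at `port_a`
#' equals the equivalent resistance.
#'
#' @param network an [mf_network()].
#' @param port_a,port_b node ids of the port.
#' @return equivalent resistance in Pa s/m^3.
#' @export
equivalent_resistance <- function(network, port_a, port_b) {
  nd <- network$nodes
  nd$is_ground <- nd$id == port_b
  probe <- network
  probe$nodes <- nd
  probe$pumps <- mf_pump("probe", port_b, port_a, "flow_rate", 1)
  fs <- tryCatch(solve_flow(probe), error = function(e) {
    stop("ports '", port_a, "' and '", port_b, "' are not connected ",
         "through the channel network", call. = FALSE)
  })
  unname(fs$node_pressures[port_a])
}
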