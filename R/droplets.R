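# Droplet module: droplet resistance coupling, branch selection and boundary
# events on top of the base flow solver.

#' Hydraulic resistance increment of a droplet
#'
#' A dispersed-phase plug of length `l_droplet` adds
#' \deqn{R_{Droplet} = b \, a \, \mu_c \, l_{Droplet} / (w h^3)}
#' to its channel's resistance, where `a` is the geometric prefactor of the
#' rectangular-channel resistance (so that with `b = 1` the droplet resists
#' exactly like an equal-length plug of continuous phase, and `b` expresses
#' the excess of the dispersed phase). The factor `b` depends on the
#' experimental system and usually lies between 2 and 5.
#'
#' @param l_droplet droplet length in m (must be shorter than the channel).
#' @param b dimensionless droplet resistance factor.
#' @param width,height channel cross-section in m.
#' @param viscosity continuous-phase viscosity in Pa s.
#' @return resistance increment in Pa s/m^3.
#' @export
droplet_resistance <- function(l_droplet, b, width, height, viscosity) {
  check_positive(l_droplet = l_droplet, b = b, width = width, height = height,
                 viscosity = viscosity)
  b * rect_prefactor(width, height) * viscosity * l_droplet /
    (width * height^3)
}

#' Per-channel effective resistances with resident droplets
#'
#' Each channel's effective resistance is its geometric resistance plus the
#' sum of the resistance increments of the droplets currently residing in it:
#' with n identical droplets, `R* = R + n R_Droplet`. A droplet is booked to
#' exactly one channel at a time (the one holding it), never split across a
#' junction.
#'
#' @param network an [mf_network()].
#' @param droplets droplet occupancy: a data frame with columns `channel`,
#'   `length`, `b` (one row per in-channel droplet), or a list of droplet
#'   state records with those fields. `NULL` or empty reproduces the base
#'   resistances exactly.
#' @return named vector of effective resistances R*, Pa s/m^3, ordered like
#'   the network's channels.
#' @export
effective_resistances <- function(network, droplets = NULL) {
  ch <- network$channels
  R <- stats::setNames(ch$resistance, ch$id)
  if (is.null(droplets)) return(R)
  if (is.list(droplets) && !is.data.frame(droplets)) {
    droplets <- droplets[vapply(droplets, function(d)
      identical(d$state, "in_channel"), logical(1))]
    if (!length(droplets)) return(R)
    droplets <- data.frame(
      channel = vapply(droplets, `[[`, character(1), "channel"),
      length = vapply(droplets, `[[`, numeric(1), "length"),
      b = vapply(droplets, `[[`, numeric(1), "b"),
      stringsAsFactors = FALSE)
  }
  if (!nrow(droplets)) return(R)
  m <- match(droplets$channel, ch$id)
  if (anyNA(m)) stop("droplet located in unknown channel")
  if (any(droplets$length >= ch$length[m])) {
    stop("droplet longer than its channel: droplets spanning junctions are ",
         "not supported")
  }
  inc <- droplet_resistance(droplets$length, droplets$b, ch$width[m],
                            ch$height[m], network$viscosity)
  add <- rowsum(inc, droplets$channel)
  R[rownames(add)] <- R[rownames(add)] + add[, 1]
  R
}

#' Branch selection at a junction
#'
#' When a droplet's leading edge reaches a junction it enters the outflow
#' channel carrying the highest instantaneous volumetric flow rate (the path
#' of least resistance). Ties are broken deterministically by channel id
#' order.
#'
#' @param node junction node id.
#' @param flow_state current [solve_flow()] result.
#' @param network the network.
#' @param exclude channel ids never selected (e.g. the channel the droplet
#'   arrives from).
#' @param q_eps flow magnitude below which a channel counts as quiescent.
#' @return the selected channel id.
#' @export
select_branch <- function(node, flow_state, network, exclude = NULL,
                          q_eps = 1e-18) {
  ch <- network$channels
  q <- flow_state$channel_flows
  out_a <- ch$id[ch$node_a == node & q[ch$id] > q_eps]
  out_b <- ch$id[ch$node_b == node & q[ch$id] < -q_eps]
  ids <- setdiff(c(out_a, out_b), exclude)
  if (!length(ids)) {
    stop("dead end: no outflow channel at node '", node, "'", call. = FALSE)
  }
  ids <- sort(ids)
  ids[which.max(abs(q[ids]))]
}

#' Upcoming droplet boundary events
#'
#' For every droplet travelling in a channel, the time until its leading edge
#' reaches the channel end at the current speed `Q/(w h)` (the droplet moves
#' with the channel flow in this model). Droplets in quiescent channels have
#' no pending event.
#'
#' @param droplets list of droplet state records (fields `id`, `state`,
#'   `channel`, `head`, `length`).
#' @param flow_state current flow solution.
#' @param network the network.
#' @param q_eps quiescence threshold on |Q|, m^3/s.
#' @return data frame with columns `time_to_event`, `droplet`, `channel`,
#'   sorted by `time_to_event`.
#' @export
droplet_events <- function(droplets, flow_state, network, q_eps = 1e-18) {
  ch <- network$channels
  rows <- list()
  for (d in droplets) {
    if (!identical(d$state, "in_channel")) next
    i <- match(d$channel, ch$id)
    Q <- flow_state$channel_flows[[d$channel]]
    if (abs(Q) <= q_eps) next
    lfrac <- d$length / ch$length[i]
    remaining <- if (Q > 0) 1 - d$head else d$head - lfrac
    remaining <- max(remaining, 0)
    rows[[length(rows) + 1L]] <- data.frame(
      time_to_event = remaining * ch$volume[i] / abs(Q),
      droplet = d$id, channel = d$channel, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(time_to_event = numeric(0), droplet = character(0),
                      channel = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$time_to_event, out$droplet), , drop = FALSE]
}

#' Droplet paths through the network
#'
#' Ordered list of channels each droplet visited over a finished run, with
#' adjacent duplicates removed.
#'
#' @param resultset an `mf_resultset` from [run_simulation()].
#' @return named list of character vectors (channel id sequences).
#' @export
extract_paths <- function(resultset) {
  lapply(resultset$droplets, function(d) {
    p <- d$path
    if (length(p) < 2) return(p)
    p[c(TRUE, p[-1] != p[-length(p)])]
  })
}

#' Droplet injection times from spacing distances
#'
#' Translates a sequence of droplet spacings into a timed injection schedule:
#' the first droplet is injected at `t = 0` and each subsequent injection
#' time is
#' \deqn{t_i = t_{i-1} + d_i \, w_{c1} h_{c1} / Q_{in},}
#' the time the injection channel flow needs to advance by the spacing
#' distance.
#'
#' @param distances spacings `d_i` between consecutive droplets, m (the first
#'   element is the gap between droplet 1 and droplet 2).
#' @param channel id of the injection channel.
#' @param network the network (supplies the injection channel cross-section).
#' @param Q_in volumetric flow rate of the feeding pump, m^3/s.
#' @param lengths droplet lengths in m (recycled to the number of droplets).
#' @param b droplet resistance factors (recycled).
#' @param ids droplet ids; default `d1`, `d2`, ...
#' @return data frame of droplet records usable as the network's `droplets`.
#' @export
droplet_schedule_from_distances <- function(distances, channel, network, Q_in,
                                            lengths, b = 3, ids = NULL) {
  i <- match(channel, network$channels$id)
  if (is.na(i)) stop("unknown channel '", channel, "'")
  wc <- network$channels$width[i]; hc <- network$channels$height[i]
  times <- c(0, cumsum(distances * wc * hc / Q_in))
  n <- length(times)
  lengths <- rep_len(lengths, n); b <- rep_len(b, n)
  if (is.null(ids)) ids <- paste0("d", seq_len(n))
  do.call(rbind, lapply(seq_len(n), function(k) {
    mf_droplet(ids[k], lengths[k], channel, t_inject = times[k], b = b[k])
  }))
}
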