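# Event-driven simulation engine. The loop alternates flow solves with
# discrete events (fixed steps, slug interfaces reaching channel ends,
# droplet boundary crossings, scheduled injections, termination); between
# events every interface advances by |Q| dt / V of its channel, which makes
# plug-flow advection exact.

#' Simulation settings
#'
#' @param max_time end of the simulated horizon, s.
#' @param fixed_step optional fixed time step, s: an event fires every
#'   `fixed_step` seconds in addition to the physical events (useful for
#'   regular output and for membrane exchange cadence).
#' @param max_events hard cap on the number of processed events (guards
#'   against runaway event loops).
#' @param q_eps flow magnitude in m^3/s below which a channel counts as
#'   quiescent and is excluded from transit-time minima.
#' @param time_tol events closer together than this (s) are merged and
#'   processed in deterministic order (injections, then droplet boundaries by
#'   droplet id, then transits).
#' @param merge_tol relative concentration tolerance for merging adjacent
#'   slugs.
#' @param record logical; record the full state at every event (default) or
#'   only first/last.
#' @return a list of class `mf_config`.
#' @export
sim_config <- function(max_time = 10, fixed_step = NULL, max_events = 1e6,
                       q_eps = 1e-18, time_tol = 1e-12, merge_tol = 1e-12,
                       record = TRUE) {
  if (max_time <= 0) stop("max_time must be positive")
  if (!is.null(fixed_step) && fixed_step <= 0) stop("fixed_step must be positive")
  structure(list(max_time = max_time, fixed_step = fixed_step,
                 max_events = max_events, q_eps = q_eps, time_tol = time_tol,
                 merge_tol = merge_tol, record = isTRUE(record)),
            class = "mf_config")
}

#' Shortest channel transit time
#'
#' The minimum over flowing channels of the full-channel residence time
#' `V/|Q|`; channels with `|Q| <= q_eps` are excluded. Returns `Inf` for a
#' quiescent network.
#'
#' @param flow_state a [solve_flow()] result.
#' @param network the network.
#' @param q_eps quiescence threshold, m^3/s.
#' @return duration in s.
#' @export
min_transit_time <- function(flow_state, network, q_eps = 1e-18) {
  q <- abs(flow_state$channel_flows[network$channels$id])
  keep <- q > q_eps
  if (!any(keep)) return(Inf)
  min(network$channels$volume[keep] / q[keep])
}

# Fresh simulation state: channels uniformly filled with the network's
# initial mixture, tanks pristine, droplets scheduled.
init_state <- function(network, config) {
  init <- network$initial_mixture
  slugs <- stats::setNames(
    lapply(seq_len(nrow(network$channels)), function(i) uniform_slug_set(init)),
    network$channels$id)
  sp <- network$species$id
  zero <- stats::setNames(rep(0, length(sp)), sp)
  tanks <- stats::setNames(
    lapply(seq_len(nrow(network$membranes)), function(i) uniform_slug_set(zero)),
    network$membranes$id)
  R_M <- stats::setNames(
    lapply(seq_len(nrow(network$membranes)), function(i)
      membrane_resistances_by_species(network$membranes[i, ], network$species)),
    network$membranes$id)
  droplets <- lapply(seq_len(nrow(network$droplets)), function(i) {
    d <- network$droplets[i, ]
    list(id = d$id, length = d$length, b = d$b, channel = d$channel,
         head = NA_real_, t_inject = d$t_inject, state = "scheduled",
         path = character(0), exit_time = NA_real_)
  })
  names(droplets) <- network$droplets$id
  incidence <- list(
    a = lapply(network$nodes$id, function(n)
      which(network$channels$node_a == n)),
    b = lapply(network$nodes$id, function(n)
      which(network$channels$node_b == n)))
  structure(list(time = 0, network = network, config = config, slugs = slugs,
                 incidence = incidence,
                 tanks = tanks, tank_R_M = R_M, droplets = droplets,
                 flow = NULL,
                 next_fixed = if (is.null(config$fixed_step)) Inf
                              else config$fixed_step,
                 event_count = 0L, log = list()),
            class = "mf_state")
}

rel_equal <- function(a, b, tol) {
  all(abs(a - b) <= tol * (abs(a) + abs(b)))
}

# Earliest slug-interface arrival at a channel outlet; includes the virtual
# interface created at the inlet whenever the inlet mixture differs from the
# slug currently adjacent to it.
nearest_transit_time <- function(state, flow_state, nm) {
  net <- state$network
  q_eps <- state$config$q_eps
  mtol <- state$config$merge_tol
  ch_a <- net$channels$node_a; ch_b <- net$channels$node_b
  ch_vol <- net$channels$volume
  qvec <- as.numeric(flow_state$channel_flows)
  best <- Inf
  for (i in seq_along(qvec)) {
    Q <- qvec[i]
    if (abs(Q) <= q_eps) next
    s <- state$slugs[[i]]
    b <- s$b
    k <- length(b)
    full <- ch_vol[i] / abs(Q)
    if (k > 2) {
      pos <- if (Q > 0) 1 - b[k - 1] else b[2]
      best <- min(best, pos * full)
    } else if (full < best && ncol(s$C) > 0) {
      inlet_node <- if (Q > 0) ch_a[i] else ch_b[i]
      if (!rel_equal(nm[inlet_node, ], s$C[1, ], mtol)) {
        best <- full
      }
    }
  }
  best
}

#' Determine the next simulation event
#'
#' Returns the earliest of: the configured fixed step, the nearest slug
#' interface reaching a channel end, the earliest droplet boundary crossing,
#' the next scheduled injection change (mixture windows and droplet
#' injections), and the simulation horizon. Events closer together than
#' `time_tol` are merged; the reported kind follows the deterministic
#' priority injections > droplet boundaries > transits > fixed step.
#'
#' @param state an `mf_state` (with a solved `flow` field, as maintained by
#'   [run_simulation()]).
#' @param config an [sim_config()].
#' @param nm precomputed node-mixture matrix for the current instant
#'   (internal optimization; recomputed when `NULL`).
#' @return list with `time` (absolute, s) and `kind`.
#' @export
next_event <- function(state, config = state$config, nm = NULL) {
  t <- state$time
  fs <- state$flow
  if (is.null(nm)) nm <- node_mixtures(state, fs)
  cand_t <- config$max_time
  cand_k <- "termination"
  prio <- c(injection = 1, droplet_boundary = 2, channel_transit = 3,
            fixed_step = 4, termination = 5)
  offer <- function(time, kind) {
    if (time < cand_t - config$time_tol ||
        (time <= cand_t + config$time_tol && prio[kind] < prio[cand_k])) {
      cand_t <<- min(time, cand_t)
      cand_k <<- kind
    }
  }
  for (inj in state$network$injections) {
    for (tb in c(inj$t_start, inj$t_end)) {
      if (is.finite(tb) && tb > t + config$time_tol) offer(tb, "injection")
    }
  }
  for (d in state$droplets) {
    if (identical(d$state, "scheduled") && d$t_inject > t - config$time_tol) {
      offer(max(d$t_inject, t), "injection")
    }
  }
  de <- droplet_events(state$droplets, fs, state$network, config$q_eps)
  if (nrow(de)) offer(t + de$time_to_event[1], "droplet_boundary")
  tt <- nearest_transit_time(state, fs, nm)
  if (is.finite(tt)) offer(t + tt, "channel_transit")
  if (is.finite(state$next_fixed)) offer(state$next_fixed, "fixed_step")
  list(time = max(cand_t, t), kind = cand_k)
}

#' Advance the simulation state by a time increment
#'
#' Moves every slug interface and droplet downstream by the fraction
#' `|Q| dt / V` of its channel, applies the mirror-and-recycle rotation and
#' the RK4 membrane exchange to membrane-coupled channels, and advances the
#' clock. `dt` must not exceed the time to the next event, so no interface
#' overshoots a channel end.
#'
#' @param state an `mf_state` with a solved `flow` field.
#' @param dt time increment, s.
#' @param nm precomputed node-mixture matrix (internal optimization).
#' @return the advanced state.
#' @export
advance <- function(state, dt, nm = NULL) {
  if (dt < 0) stop("dt must be non-negative")
  net <- state$network
  fs <- state$flow
  cfg <- state$config
  if (is.null(nm)) nm <- node_mixtures(state, fs)
  memb_of <- stats::setNames(net$membranes$id, net$membranes$channel)
  ch_id <- net$channels$id; ch_a <- net$channels$node_a
  ch_b <- net$channels$node_b; ch_vol <- net$channels$volume
  qvec <- as.numeric(fs$channel_flows)
  for (i in seq_along(ch_id)) {
    cid <- ch_id[i]
    Q <- qvec[i]
    quiescent <- abs(Q) <= cfg$q_eps
    s_frac <- if (quiescent) 0 else min(1, abs(Q) * dt / ch_vol[i])
    mid <- memb_of[cid]
    if (is.na(mid) && s_frac == 0) next
    sl <- state$slugs[[i]]
    inlet_node <- if (Q >= 0) ch_a[i] else ch_b[i]
    inlet_mix <- stats::setNames(nm[inlet_node, ], colnames(nm))
    if (is.na(mid) && nrow(sl$C) == 1 &&
        rel_equal(inlet_mix, sl$C[1, ], cfg$merge_tol)) {
      next                     # uniform channel refilled with the same mixture
    }
    flip <- !quiescent && Q < 0
    if (flip) sl <- flip_slugs(sl)
    if (s_frac > 0) {
      sl <- propagate_slugs(sl, s_frac, inlet_mix, cfg$merge_tol)$slugs
    }
    if (!is.na(mid)) {
      tk <- state$tanks[[mid]]
      if (flip) tk <- flip_slugs(tk)
      tk <- mirror_and_recycle(tk, s_frac)
      al <- align_slug_sets(sl, tk)
      m <- net$membranes[net$membranes$id == mid, ]
      ex <- exchange_step(al$x, al$y, state$tank_R_M[[mid]], dt,
                          net$channels$volume[i], m$tank_volume)
      jm <- merge_slug_set(ex$channel, cfg$merge_tol, partner = ex$tank)
      sl <- jm$x; tk <- jm$y
      if (flip) tk <- flip_slugs(tk)
      state$tanks[[mid]] <- tk
    }
    if (flip) sl <- flip_slugs(sl)
    state$slugs[[cid]] <- sl
  }
  for (j in seq_along(state$droplets)) {
    d <- state$droplets[[j]]
    if (!identical(d$state, "in_channel")) next
    i <- match(d$channel, net$channels$id)
    Q <- fs$channel_flows[[d$channel]]
    if (abs(Q) <= cfg$q_eps) next
    s_frac <- abs(Q) * dt / net$channels$volume[i]
    lfrac <- d$length / net$channels$length[i]
    head <- d$head + sign(Q) * s_frac
    state$droplets[[j]]$head <- min(max(head, lfrac), 1)
  }
  state$time <- state$time + dt
  state
}

# Process everything due at the current instant: place scheduled droplets,
# transfer or retire droplets whose leading edge sits at a channel end. Flows
# are re-solved after every resistance-changing action so later selections in
# a merged batch see the updated field.
apply_due_events <- function(state) {
  net <- state$network
  cfg <- state$config
  ptol <- 1e-9
  resolve <- function() {
    effR <- effective_resistances(net, state$droplets)
    state$flow <<- solve_flow(net, effR, time = state$time)
  }
  ord <- order(vapply(state$droplets, `[[`, character(1), "id"))
  for (j in ord) {
    d <- state$droplets[[j]]
    if (identical(d$state, "scheduled") &&
        d$t_inject <= state$time + cfg$time_tol) {
      i <- match(d$channel, net$channels$id)
      Q <- state$flow$channel_flows[[d$channel]]
      lfrac <- d$length / net$channels$length[i]
      state$droplets[[j]]$head <- if (Q >= 0) lfrac else 1
      state$droplets[[j]]$state <- "in_channel"
      state$droplets[[j]]$path <- d$channel
      state$log[[length(state$log) + 1L]] <-
        list(time = state$time, kind = "droplet_inject", id = d$id,
             detail = d$channel)
      resolve()
    }
  }
  for (j in ord) {
    d <- state$droplets[[j]]
    if (!identical(d$state, "in_channel")) next
    i <- match(d$channel, net$channels$id)
    Q <- state$flow$channel_flows[[d$channel]]
    if (abs(Q) <= cfg$q_eps) next
    lfrac <- d$length / net$channels$length[i]
    at_end <- (Q > 0 && d$head >= 1 - ptol) ||
              (Q < 0 && d$head - lfrac <= ptol)
    if (!at_end) next
    node <- if (Q > 0) net$channels$node_b[i] else net$channels$node_a[i]
    branch <- tryCatch(
      select_branch(node, state$flow, net, exclude = d$channel,
                    q_eps = cfg$q_eps),
      error = function(e) NULL)
    if (is.null(branch)) {
      state$droplets[[j]]$state <- "exited"
      state$droplets[[j]]$exit_time <- state$time
      state$log[[length(state$log) + 1L]] <-
        list(time = state$time, kind = "droplet_exit", id = d$id,
             detail = node)
    } else {
      bi <- match(branch, net$channels$id)
      if (d$length >= net$channels$length[bi]) {
        stop("droplet '", d$id, "' does not fit channel '", branch, "'")
      }
      Qb <- state$flow$channel_flows[[branch]]
      enters_at_a <- net$channels$node_a[bi] == node
      state$droplets[[j]]$channel <- branch
      state$droplets[[j]]$head <-
        if (enters_at_a) d$length / net$channels$length[bi] else 1
      state$droplets[[j]]$path <- c(d$path, branch)
      state$log[[length(state$log) + 1L]] <-
        list(time = state$time, kind = "droplet_transfer", id = d$id,
             detail = branch)
    }
    resolve()
  }
  while (state$next_fixed <= state$time + cfg$time_tol) {
    state$next_fixed <- state$next_fixed + cfg$fixed_step
  }
  state
}

# A state is steady when nothing can change any more: no droplets pending or
# travelling, no future injection-window boundaries, no membranes (their
# exchange evolves continuously), and every channel uniformly filled with
# its inlet mixture.
is_steady <- function(state, nm) {
  if (nrow(state$network$membranes)) return(FALSE)
  for (d in state$droplets) if (!identical(d$state, "exited")) return(FALSE)
  for (inj in state$network$injections) {
    for (tb in c(inj$t_start, inj$t_end)) {
      if (is.finite(tb) && tb > state$time + state$config$time_tol) return(FALSE)
    }
  }
  net <- state$network
  fs <- state$flow
  for (i in seq_len(nrow(net$channels))) {
    cid <- net$channels$id[i]
    s <- state$slugs[[cid]]
    if (nrow(s$C) > 1) return(FALSE)
    if (ncol(s$C) == 0) next
    Q <- fs$channel_flows[[cid]]
    if (abs(Q) <= state$config$q_eps) next
    inlet <- if (Q > 0) net$channels$node_a[i] else net$channels$node_b[i]
    if (!rel_equal(nm[inlet, ], s$C[1, ], 1e-12)) return(FALSE)
  }
  TRUE
}

record_entry <- function(rec, state, nm) {
  net <- state$network
  fs <- state$flow
  nsp <- nrow(net$species)
  ch_mix <- matrix(0, nrow(net$channels), nsp,
                   dimnames = list(net$channels$id, net$species$id))
  tank_mix <- matrix(0, length(state$tanks), nsp,
                     dimnames = list(names(state$tanks), net$species$id))
  if (nsp > 0) {
    if (length(state$slugs)) {
      ch_mix[] <- t(matrix(vapply(state$slugs, slug_mean_conc, numeric(nsp)),
                           nrow = nsp))
    }
    if (length(state$tanks)) {
      tank_mix[] <- t(matrix(vapply(state$tanks, slug_mean_conc, numeric(nsp)),
                             nrow = nsp))
    }
  }
  drops <- if (length(state$droplets)) data.frame(
    id = vapply(state$droplets, `[[`, character(1), "id"),
    state = vapply(state$droplets, `[[`, character(1), "state"),
    channel = vapply(state$droplets, `[[`, character(1), "channel"),
    head = vapply(state$droplets, `[[`, numeric(1), "head"),
    stringsAsFactors = FALSE, row.names = NULL
  ) else NULL
  entry <- list(time = state$time, node_pressures = fs$node_pressures,
                channel_flows = fs$channel_flows,
                pump_flows = fs$pump_flows, node_mix = nm,
                channel_mix = ch_mix, tank_mix = tank_mix, droplets = drops)
  n <- length(rec$entries)
  if (n > 0 && abs(rec$entries[[n]]$time - state$time) <= 1e-12) {
    rec$entries[[n]] <- entry          # same instant: keep the latest state
  } else {
    rec$entries[[n + 1L]] <- entry
  }
  invisible(NULL)
}

#' Run an event-driven simulation
#'
#' The main loop: solve the flow field (re-using the previous solution while
#' no resistance or pump changed), record the state, find the next event,
#' advance all material to it, and apply the event; repeated until the
#' horizon is reached or the state can provably no longer change (all
#' droplets have left, schedules are exhausted and every channel is flushed
#' to its steady mixture).
#'
#' @param network an [mf_network()]; must pass [validate_network()].
#' @param config an [sim_config()].
#' @return an object of class `mf_resultset`: recorded `entries`, the event
#'   log `events`, per-droplet records `droplets` (with `path`), the
#'   `final_state`, termination `status` (`"max_time"`, `"steady"`) and the
#'   processed `event_count`.
#' @examples
#' net <- make_y_junction()
#' rs <- run_simulation(net, sim_config(max_time = 60))
#' outlet_concentration_profile(rs, "sink")
#' @export
run_simulation <- function(network, config = sim_config()) {
  assert_valid_network(network)
  state <- init_state(network, config)
  rec <- new.env(parent = emptyenv())
  rec$entries <- list()
  last_R <- NULL
  status <- "max_time"
  repeat {
    state$event_count <- state$event_count + 1L
    if (state$event_count > config$max_events) {
      stop("event cap exceeded (", config$max_events,
           "); raise max_events if this run is expected to be this long")
    }
    effR <- if (length(state$droplets))
      effective_resistances(network, state$droplets)
    else stats::setNames(network$channels$resistance, network$channels$id)
    if (is.null(state$flow) || !identical(effR, last_R)) {
      state$flow <- solve_flow(network, effR, time = state$time)
      last_R <- effR
    } else {
      state$flow$time <- state$time
    }
    nm <- node_mixtures(state, state$flow)
    if (config$record || length(rec$entries) == 0) record_entry(rec, state, nm)
    if (is_steady(state, nm)) {
      status <- "steady"
      break
    }
    ev <- next_event(state, config, nm)
    dt <- ev$time - state$time
    if (dt > 0) state <- advance(state, dt, nm)
    if (ev$kind == "termination") break
    state <- apply_due_events(state)
  }
  record_entry(rec, state, node_mixtures(state, state$flow))
  ev_log <- if (length(state$log)) do.call(rbind, lapply(state$log, function(e)
    data.frame(time = e$time, kind = e$kind, id = e$id, detail = e$detail,
               stringsAsFactors = FALSE)))
  else data.frame(time = numeric(0), kind = character(0), id = character(0),
                  detail = character(0), stringsAsFactors = FALSE)
  structure(list(entries = rec$entries, events = ev_log,
                 droplets = state$droplets, final_state = state,
                 network = network, config = config, status = status,
                 event_count = state$event_count),
            class = "mf_resultset")
}

#' @export
print.mf_resultset <- function(x, ...) {
  cat("<mf_resultset> ", length(x$entries), " recorded states, ",
      x$event_count, " events, status '", x$status, "'\n", sep = "")
  if (length(x$droplets)) {
    exited <- sum(vapply(x$droplets, function(d)
      identical(d$state, "exited"), logical(1)))
    cat("  droplets: ", exited, "/", length(x$droplets), " exited\n", sep = "")
  }
  invisible(x)
}
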