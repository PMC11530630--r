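# Independent reference implementations used as oracles. These deliberately
# avoid the package's solver/event machinery: the nodal solve is a full
# (n x n) grounded system solved with qr.solve, the resistance formulas are
# retyped one-liners, and the droplet enumerator is a plain loop that
# re-solves the whole network after every candidate event.

# Dense grounded nodal solve: all node pressures as unknowns, conservation
# row per node, ground row replaced by an identity row; pressure pumps add
# one auxiliary flow unknown and constraint row each.
oracle_solve <- function(network, effective_resistances = NULL) {
  nd <- network$nodes; ch <- network$channels; pp <- network$pumps
  ids <- nd$id; n <- length(ids)
  R <- if (is.null(effective_resistances)) ch$resistance
       else as.numeric(effective_resistances[ch$id])
  np <- sum(pp$kind == "pressure")
  N <- n + np
  A <- matrix(0, N, N); rhs <- numeric(N)
  ix <- stats::setNames(seq_len(n), ids)
  for (k in seq_len(nrow(ch))) {
    i <- ix[[ch$node_a[k]]]; j <- ix[[ch$node_b[k]]]; g <- 1 / R[k]
    A[i, i] <- A[i, i] + g; A[j, j] <- A[j, j] + g
    A[i, j] <- A[i, j] - g; A[j, i] <- A[j, i] - g
  }
  qrow <- n
  for (k in seq_len(nrow(pp))) {
    f <- ix[[pp$node_from[k]]]; to <- ix[[pp$node_to[k]]]
    if (pp$kind[k] == "flow_rate") {
      rhs[to] <- rhs[to] + pp$value[k]
      rhs[f] <- rhs[f] - pp$value[k]
    } else {
      qrow <- qrow + 1
      A[to, qrow] <- A[to, qrow] - 1
      A[f, qrow] <- A[f, qrow] + 1
      A[qrow, to] <- 1; A[qrow, f] <- -1
      rhs[qrow] <- pp$value[k]
    }
  }
  gi <- ix[[ids[nd$is_ground]]]
  A[gi, ] <- 0; A[gi, gi] <- 1; rhs[gi] <- 0
  # equilibrate the conservation rows (conductances ~1e-10 vs unit
  # constraint rows would otherwise ruin the conditioning)
  R0 <- exp(mean(log(R)))
  kcl <- setdiff(seq_len(n), gi)
  A[kcl, ] <- A[kcl, ] * R0; rhs[kcl] <- rhs[kcl] * R0
  x <- qr.solve(A, rhs)
  p <- stats::setNames(x[1:n], ids)
  list(p = p, q = stats::setNames((p[ch$node_a] - p[ch$node_b]) / R, ch$id))
}

# Random connected resistor network with <= n_nodes nodes: spanning tree plus
# a few extra channels, one ground/sink, one or two pumps of random kind.
random_flow_network <- function(n_nodes, seed) {
  set.seed(seed)
  ids <- paste0("n", seq_len(n_nodes))
  edges <- lapply(2:n_nodes, function(i) c(sample(i - 1, 1), i))
  for (k in seq_len(sample(0:3, 1))) {
    edges[[length(edges) + 1]] <- sample(n_nodes, 2)
  }
  channels <- lapply(seq_along(edges), function(k) {
    w <- stats::runif(1, 50e-6, 300e-6)
    h <- w * stats::runif(1, 0.1, 0.8)
    mf_channel(paste0("c", k), ids[edges[[k]][1]], ids[edges[[k]][2]],
               w, h, stats::runif(1, 0.3e-3, 3e-3))
  })
  nodes <- lapply(seq_len(n_nodes), function(i)
    mf_node(ids[i], is_ground = i == n_nodes, is_sink = i == n_nodes))
  n_pump <- sample(1:2, 1)
  targets <- sample(n_nodes - 1, n_pump)   # distinct outlets keep MNA regular
  pumps <- lapply(seq_len(n_pump), function(k) {
    kind <- sample(c("flow_rate", "pressure"), 1)
    mf_pump(paste0("p", k), ids[n_nodes], ids[targets[k]], kind,
            if (kind == "flow_rate") stats::runif(1, 0.2, 2) * 1e-9
            else stats::runif(1, 100, 5000))
  })
  mf_network(nodes, channels, pumps)
}

# Brute-force droplet routing enumerator: at every candidate event the full
# network is re-solved from scratch; droplets move with the channel flow,
# pick the outflow branch with the highest flow at junctions (ties by id),
# and exit at dead ends. Returns the event log and per-droplet paths.
oracle_droplet_run <- function(network, droplets_df, max_events = 1000) {
  ch <- network$channels; mu <- network$viscosity
  pref <- function(w, h) 12 / (1 - 192 * h / (pi^5 * w) * tanh(pi * w / (2 * h)))
  Rbase <- pref(ch$width, ch$height) * mu * ch$length / (ch$width * ch$height^3)
  vol <- ch$width * ch$height * ch$length
  ds <- lapply(seq_len(nrow(droplets_df)), function(i) {
    d <- droplets_df[i, ]
    list(id = d$id, len = d$length, b = d$b, ch0 = d$channel, t0 = d$t_inject,
         state = "pending", chan = NA_character_, head = NA_real_,
         path = character(0))
  })
  names(ds) <- droplets_df$id
  flows <- function() {
    Reff <- Rbase
    for (d in ds) if (d$state == "in") {
      i <- match(d$chan, ch$id)
      Reff[i] <- Reff[i] + d$b * pref(ch$width[i], ch$height[i]) * mu *
        d$len / (ch$width[i] * ch$height[i]^3)
    }
    oracle_solve(network, stats::setNames(Reff, ch$id))$q
  }
  events <- list()
  t <- 0
  for (iter in seq_len(max_events)) {
    q <- flows()
    cand <- Inf
    for (d in ds) {
      if (d$state == "pending") cand <- min(cand, d$t0)
      if (d$state == "in") {
        i <- match(d$chan, ch$id); Q <- q[[d$chan]]
        if (abs(Q) <= 1e-18) next
        rem <- if (Q > 0) 1 - d$head else d$head - d$len / ch$length[i]
        cand <- min(cand, t + max(rem, 0) * vol[i] / abs(Q))
      }
    }
    if (!is.finite(cand)) break
    dt <- cand - t
    for (nm in names(ds)) {
      d <- ds[[nm]]
      if (d$state != "in") next
      i <- match(d$chan, ch$id); Q <- q[[d$chan]]
      if (abs(Q) <= 1e-18) next
      ds[[nm]]$head <- d$head + sign(Q) * abs(Q) * dt / vol[i]
    }
    t <- cand
    for (nm in sort(names(ds))) {          # injections first, in id order
      d <- ds[[nm]]
      if (d$state == "pending" && d$t0 <= t + 1e-12) {
        i <- match(d$ch0, ch$id)
        ds[[nm]]$state <- "in"; ds[[nm]]$chan <- d$ch0
        ds[[nm]]$head <- if (q[[d$ch0]] >= 0) d$len / ch$length[i] else 1
        ds[[nm]]$path <- d$ch0
        events[[length(events) + 1]] <-
          list(time = t, kind = "droplet_inject", id = nm, detail = d$ch0)
        q <- flows()
      }
    }
    for (nm in sort(names(ds))) {          # then boundary crossings by id
      d <- ds[[nm]]
      if (d$state != "in") next
      i <- match(d$chan, ch$id); Q <- q[[d$chan]]
      if (abs(Q) <= 1e-18) next
      lfrac <- d$len / ch$length[i]
      at_end <- (Q > 0 && d$head >= 1 - 1e-9) ||
                (Q < 0 && d$head - lfrac <= 1e-9)
      if (!at_end) next
      node <- if (Q > 0) ch$node_b[i] else ch$node_a[i]
      outs <- sort(setdiff(c(ch$id[ch$node_a == node & q[ch$id] > 1e-18],
                             ch$id[ch$node_b == node & q[ch$id] < -1e-18]),
                           d$chan))
      if (!length(outs)) {
        ds[[nm]]$state <- "out"
        events[[length(events) + 1]] <-
          list(time = t, kind = "droplet_exit", id = nm, detail = node)
      } else {
        sel <- outs[which.max(abs(q[outs]))]
        bi <- match(sel, ch$id)
        ds[[nm]]$chan <- sel
        ds[[nm]]$head <- if (ch$node_a[bi] == node)
          d$len / ch$length[bi] else 1
        ds[[nm]]$path <- c(d$path, sel)
        events[[length(events) + 1]] <-
          list(time = t, kind = "droplet_transfer", id = nm, detail = sel)
      }
      q <- flows()
    }
    if (all(vapply(ds, function(d) d$state == "out", logical(1)))) break
  }
  list(events = do.call(rbind, lapply(events, function(e)
         data.frame(time = e$time, kind = e$kind, id = e$id,
                    detail = e$detail, stringsAsFactors = FALSE))),
       paths = lapply(ds, `[[`, "path"))
}

# Random ring-network routing scenario for the droplet oracle comparison.
random_ring_scenario <- function(seed) {
  set.seed(seed)
  n_mod <- sample(1:2, 1)
  l_byp <- stats::runif(n_mod, 0.8e-3, 1.2e-3)
  net <- make_ring_network(n_mod, l_bypass = l_byp,
                           l_module = l_byp * stats::runif(n_mod, 1.1, 1.6))
  n_d <- sample(1:3, 1)
  gaps <- stats::runif(n_d - 1, 1e-3, 8e-3)
  t_inj <- c(0, cumsum(gaps))
  net$droplets <- do.call(rbind, lapply(seq_len(n_d), function(i)
    mf_droplet(paste0("d", i), stats::runif(1, 0.1e-3, 0.3e-3), "c_in",
               t_inject = t_inj[i], b = stats::runif(1, 2, 5))))
  net
}

# Weighted-mean mixing oracle (direct arithmetic).
oracle_mix <- function(flows, conc) sum(conc * flows) / sum(flows)

# Total moles per species in a channel+tank compartment pair.
slug_moles_pair <- function(ch, tk, V_c, V_t) {
  colSums(ch$C * diff(ch$b)) * V_c + colSums(tk$C * diff(tk$b)) * V_t
}
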