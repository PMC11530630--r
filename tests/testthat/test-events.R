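# Event engine: time stepping, advection, termination.

test_that("min transit time is the minimum V/|Q| over flowing channels", {
  net <- make_series_chain(2, Q = 1e-9, lengths = c(1e-3, 1.5e-3))
  fs <- solve_flow(net)
  expect_equal(min_transit_time(fs, net),
               min(net$channels$volume) / 1e-9)

  # one channel V = 5e-12 m^3, Q = 1e-9 m^3/s -> 5e-3 s
  net1 <- make_series_chain(1, Q = 1e-9, lengths = 1e-3)
  expect_equal(min_transit_time(solve_flow(net1), net1), 5e-3)
})

test_that("quiescent channels are excluded from the transit minimum", {
  # dead-end branch: no flow through it
  net <- mf_network(
    nodes = list(mf_node("in"), mf_node("stub"),
                 mf_node("out", is_ground = TRUE, is_sink = TRUE)),
    channels = list(mf_channel("c1", "in", "out", 1e-4, 5e-5, 1e-3),
                    mf_channel("dead", "in", "stub", 1e-4, 5e-5, 1e-6)),
    pumps = list(mf_pump("p1", "out", "in", "flow_rate", 1e-9)))
  fs <- solve_flow(net)
  expect_equal(abs(unname(fs$channel_flows[["dead"]])), 0)
  expect_equal(min_transit_time(fs, net), 5e-3)

  fs$channel_flows[] <- 0
  expect_identical(min_transit_time(fs, net), Inf)
})

test_that("the next event is the earliest candidate", {
  net <- make_series_chain(1, Q = 1e-9,
                           species = list(mf_species("A", 1e-9)),
                           injections = list(mf_injection("in", c(A = 1))))
  # transit = 5e-3 s; a smaller fixed step wins
  cfg <- sim_config(max_time = 10, fixed_step = 1e-3)
  st <- microflow:::init_state(net, cfg)
  st$flow <- solve_flow(net)
  ev <- next_event(st, cfg)
  expect_equal(ev$time, 1e-3)
  expect_equal(ev$kind, "fixed_step")

  # without the fixed step the interface arrival wins
  cfg2 <- sim_config(max_time = 10)
  st2 <- microflow:::init_state(net, cfg2)
  st2$flow <- solve_flow(net)
  ev2 <- next_event(st2, cfg2)
  expect_equal(ev2$time, 5e-3)
  expect_equal(ev2$kind, "channel_transit")

  # nothing pending before the horizon -> termination
  net0 <- make_series_chain(1, Q = 1e-9)
  cfg0 <- sim_config(max_time = 2)
  st0 <- microflow:::init_state(net0, cfg0)
  st0$flow <- solve_flow(net0)
  ev0 <- next_event(st0, cfg0)
  expect_equal(ev0$kind, "termination")
  expect_equal(ev0$time, 2)
})

test_that("advance moves interfaces by the flow fraction", {
  net <- make_series_chain(1, Q = 1e-9,
                           species = list(mf_species("A", 1e-9)),
                           injections = list(mf_injection("in", c(A = 1))))
  cfg <- sim_config(max_time = 10)
  st <- microflow:::init_state(net, cfg)
  st$flow <- solve_flow(net)
  st$slugs[["c1"]] <- slug_set(c(0, 0.25, 1), rbind(c(A = 1), c(A = 0)))
  transit <- 5e-3
  st2 <- advance(st, 0.5 * transit)   # shift by half the channel
  expect_true(any(abs(st2$slugs[["c1"]]$b - 0.75) < 1e-12))
  # exact remaining transit puts the front at the outlet (interface consumed)
  st3 <- advance(st2, 0.25 * transit)
  expect_equal(sum(diff(st3$slugs[["c1"]]$b)), 1, tolerance = 1e-12)
})

test_that("slug intervals always partition the channel exactly", {
  set.seed(31)
  gt <- make_gradient_tree(5, randomize = TRUE)
  rs <- run_simulation(gt$network, sim_config(max_time = 1e5, record = FALSE))
  for (s in rs$final_state$slugs) {
    expect_equal(s$b[1], 0)
    expect_equal(s$b[length(s$b)], 1)
    expect_true(all(diff(s$b) > 0))
  }
})

test_that("recorded times increase strictly", {
  net <- make_y_junction()
  rs <- run_simulation(net, sim_config(max_time = 60, fixed_step = 1e-3))
  times <- vapply(rs$entries, `[[`, numeric(1), "time")
  expect_true(all(diff(times) > 0))
})

test_that("pressures stay constant over time for a constant pump", {
  net <- make_y_junction()
  rs <- run_simulation(net, sim_config(max_time = 60))
  p <- t(vapply(rs$entries, `[[`, numeric(nrow(net$nodes)), "node_pressures"))
  expect_equal(max(apply(p, 2, function(x) diff(range(x)))), 0)
})

test_that("halving the fixed step leaves advection arrival times unchanged", {
  run_arrival <- function(dt) {
    net <- make_series_chain(3, Q = 1e-9, lengths = c(1e-3, 2e-3, 0.5e-3),
                             species = list(mf_species("A", 1e-9)),
                             injections = list(mf_injection("in", c(A = 1))))
    rs <- run_simulation(net, sim_config(max_time = 1, fixed_step = dt))
    op <- outlet_concentration_profile(rs, "out")
    opA <- op[op$species == "A", ]
    min(opA$time[opA$concentration > 0.5])
  }
  a1 <- run_arrival(1e-3)
  a2 <- run_arrival(5e-4)
  expect_equal(a1, a2, tolerance = 1e-12)   # interface tracking is exact
})

test_that("droplet runs terminate once all droplets have left", {
  net <- make_ring_network(1)
  net$droplets <- mf_droplet("d1", 2e-4, "c_in")
  rs <- run_simulation(net, sim_config(max_time = 1e4))
  expect_equal(rs$status, "steady")
  expect_true(all(vapply(rs$droplets, function(d) d$state == "exited",
                         logical(1))))
  expect_lt(rs$final_state$time, 1)
})

test_that("the event cap aborts runaway loops", {
  net <- make_y_junction()
  expect_error(run_simulation(net, sim_config(max_time = 60, fixed_step = 1e-4,
                                              max_events = 3)),
               "event cap")
})
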