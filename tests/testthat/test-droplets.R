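# Droplet module: resistance coupling, branch selection, routing.

test_that("a droplet with b = 1 resists like an equal-length carrier plug", {
  w <- 1e-4; h <- 5e-5; mu <- 1e-3; ld <- 1e-3
  expect_equal(droplet_resistance(ld, 1, w, h, mu),
               channel_resistance(w, h, ld, mu))
  expect_equal(droplet_resistance(ld, 3, w, h, mu),
               3 * channel_resistance(w, h, ld, mu))
})

test_that("droplet resistance matches an independent formula evaluation", {
  # frozen from a one-line evaluation with w=100 um, h=33 um, l=200 um, b=2.5
  expect_equal(droplet_resistance(200e-6, 2.5, 100e-6, 33e-6, 1e-3),
               2105448032519.0789, tolerance = 1e-12)
})

test_that("effective resistance sums the resident droplet increments", {
  net <- make_ring_network(1)
  base <- stats::setNames(net$channels$resistance, net$channels$id)
  expect_equal(effective_resistances(net, NULL), base)

  two <- data.frame(channel = c("byp1", "byp1"), length = 2e-4, b = 3)
  inc <- droplet_resistance(2e-4, 3, 1e-4, 5e-5, net$viscosity)
  got <- effective_resistances(net, two)
  expect_equal(unname(got[["byp1"]] - base[["byp1"]]), 2 * inc)

  mixed <- data.frame(channel = c("byp1", "mod1"), length = c(1e-4, 3e-4),
                      b = c(2, 4.5))
  incs <- droplet_resistance(c(1e-4, 3e-4), c(2, 4.5), 1e-4, 5e-5,
                             net$viscosity)
  got <- effective_resistances(net, mixed)
  expect_equal(unname(got[["byp1"]] - base[["byp1"]]), incs[1])
  expect_equal(unname(got[["mod1"]] - base[["mod1"]]), incs[2])
})

test_that("oversized droplets are rejected", {
  net <- make_ring_network(1)
  big <- data.frame(channel = "byp1", length = 2e-3, b = 3)
  expect_error(effective_resistances(net, big), "junction")
})

test_that("branch selection follows the highest flow with id tie-break", {
  net <- make_ring_network(1)           # byp1 shorter than mod1
  fs <- solve_flow(net)
  expect_equal(select_branch("j1", fs, net, exclude = "c_in"), "byp1")

  # equal-length branches tie; the lexicographically first id wins
  net2 <- make_ring_network(1, l_module = 1e-3)
  fs2 <- solve_flow(net2)
  expect_equal(select_branch("j1", fs2, net2, exclude = "c_in"), "byp1")

  expect_error(select_branch("out", fs, net, exclude = "c_out"), "dead end")
})

test_that("a resident droplet flips the branch selection", {
  net <- make_ring_network(1)
  fs0 <- solve_flow(net)
  expect_equal(select_branch("j1", fs0, net, exclude = "c_in"), "byp1")
  header <- data.frame(channel = "byp1", length = 2e-4, b = 3)
  fs1 <- solve_flow(net, effective_resistances(net, header))
  expect_equal(select_branch("j1", fs1, net, exclude = "c_in"), "mod1")
})

test_that("adding a droplet strictly lowers its branch's flow share", {
  net <- make_parallel_pair()
  fs0 <- solve_flow(net)
  share0 <- fs0$channel_flows[["c1"]] / sum(fs0$channel_flows)
  d <- data.frame(channel = "c1", length = 2e-4, b = 3)
  fs1 <- solve_flow(net, effective_resistances(net, d))
  share1 <- fs1$channel_flows[["c1"]] / sum(fs1$channel_flows)
  expect_lt(share1, share0)
})

test_that("removing all droplets reproduces the base solution exactly", {
  net <- make_ring_network(2)
  expect_identical(effective_resistances(net, list()),
                   stats::setNames(net$channels$resistance, net$channels$id))
})

test_that("droplet boundary events are proportional to remaining distance", {
  net <- make_series_chain(1, Q = 1e-9)    # transit V/Q = 5e-3 s
  fs <- solve_flow(net)
  mk <- function(head) list(list(id = "d1", state = "in_channel",
                                 channel = "c1", head = head, length = 1e-4))
  ev <- droplet_events(mk(0.5), fs, net)
  expect_equal(ev$time_to_event, 0.5 * 5e-3)
  # two droplets: the nearest boundary comes first
  ds <- c(mk(0.2), list(list(id = "d2", state = "in_channel", channel = "c1",
                             head = 0.9, length = 1e-4)))
  ev2 <- droplet_events(ds, fs, net)
  expect_equal(ev2$droplet[1], "d2")
})

test_that("droplet traversal time equals the channel residence time V/Q", {
  net <- make_series_chain(2, Q = 1e-9, lengths = c(1e-3, 2e-3))
  net$droplets <- mf_droplet("d1", 1e-4, "c1")
  rs <- run_simulation(net, sim_config(max_time = 10))
  ev <- rs$events
  t_in <- ev$time[ev$kind == "droplet_inject"]
  t_sw <- ev$time[ev$kind == "droplet_transfer"]
  t_out <- ev$time[ev$kind == "droplet_exit"]
  lfrac <- 1e-4 / 1e-3
  # effective resistances change the flow; use recorded flows for V/Q
  Q1 <- rs$entries[[1]]$channel_flows[["c1"]]
  expect_equal(t_sw - t_in, (1 - lfrac) * net$channels$volume[1] / Q1,
               tolerance = 1e-9)
})

test_that("routing is deterministic and matches the brute-force enumerator", {
  net <- random_ring_scenario(404)
  rs1 <- run_simulation(net, sim_config(max_time = 1e4))
  rs2 <- run_simulation(net, sim_config(max_time = 1e4))
  expect_identical(extract_paths(rs1), extract_paths(rs2))
  or <- oracle_droplet_run(net, net$droplets)
  expect_identical(extract_paths(rs1), or$paths[names(extract_paths(rs1))])
})

test_that("spacing distances convert to injection times through the inlet", {
  net <- make_ring_network(1)
  sched <- droplet_schedule_from_distances(c(1e-3, 2e-3), "c_in", net,
                                           Q_in = 1e-9, lengths = 2e-4)
  wh <- net$channels$width[1] * net$channels$height[1]
  expect_equal(sched$t_inject, c(0, 1e-3 * wh / 1e-9,
                                 (1e-3 + 2e-3) * wh / 1e-9))
  expect_true(all(diff(sched$t_inject) >= 0))
})
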