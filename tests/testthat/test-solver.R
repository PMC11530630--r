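# Modified Nodal Analysis solver.

test_that("system size follows the MNA bookkeeping", {
  # single channel + flow pump between ground and one node -> 1x1
  net <- mf_network(
    nodes = list(mf_node("a"), mf_node("g", is_ground = TRUE, is_sink = TRUE)),
    channels = list(mf_channel("c1", "a", "g", 1e-4, 5e-5, 1e-3)),
    pumps = list(mf_pump("p1", "g", "a", "flow_rate", 1e-9)))
  expect_equal(dim(assemble_system(net)$A), c(1, 1))

  # no pressure pumps: unknowns = nodes - 1
  net <- make_y_junction()
  expect_equal(length(assemble_system(net)$unknowns), nrow(net$nodes) - 1)

  # a pressure pump adds one flow unknown
  net <- make_series_chain(2, Q = 1000, kind = "pressure")
  expect_equal(length(assemble_system(net)$unknowns), nrow(net$nodes) - 1 + 1)
})

test_that("two identical parallel channels split a flow-rate pump evenly", {
  net <- make_parallel_pair(Q = 1e-9)
  fs <- solve_flow(net)
  expect_equal(unname(fs$channel_flows[["c1"]]), 0.5e-9)
  expect_equal(unname(fs$channel_flows[["c2"]]), 0.5e-9)
})

test_that("a pressure pump across a series chain is a voltage divider", {
  dP <- 2000
  net <- make_series_chain(2, Q = dP, kind = "pressure",
                           lengths = c(1e-3, 3e-3))
  fs <- solve_flow(net)
  R1 <- net$channels$resistance[1]; R2 <- net$channels$resistance[2]
  expect_equal(unname(fs$channel_flows[["c1"]]), dP / (R1 + R2))
  expect_equal(unname(fs$node_pressures[["n1"]]), dP * R2 / (R1 + R2))
  expect_equal(unname(fs$pump_flows[["p1"]]), dP / (R1 + R2))
})

test_that("random networks agree with the dense oracle solve", {
  for (seed in 1:25) {
    n <- sample(4:12, 1)
    net <- random_flow_network(n, seed)
    fs <- solve_flow(net)
    or <- oracle_solve(net)
    expect_equal(fs$node_pressures[names(or$p)], or$p, tolerance = 1e-9)
    expect_lt(max(check_conservation(fs, net)), 1e-9)
  }
})

test_that("solutions scale linearly with pump strength", {
  net <- random_flow_network(8, 99)
  fs1 <- solve_flow(net)
  net$pumps$value <- net$pumps$value * 3.5
  fs2 <- solve_flow(net)
  expect_equal(fs2$node_pressures, 3.5 * fs1$node_pressures)
  expect_equal(fs2$channel_flows, 3.5 * fs1$channel_flows)
})

test_that("relabeling nodes leaves the physics unchanged", {
  net <- random_flow_network(7, 123)
  relabel <- function(x) paste0("z_", x)
  net2 <- net
  net2$nodes$id <- relabel(net2$nodes$id)
  net2$channels$node_a <- relabel(net2$channels$node_a)
  net2$channels$node_b <- relabel(net2$channels$node_b)
  net2$pumps$node_from <- relabel(net2$pumps$node_from)
  net2$pumps$node_to <- relabel(net2$pumps$node_to)
  fs <- solve_flow(net); fs2 <- solve_flow(net2)
  expect_equal(unname(fs2$node_pressures[relabel(names(fs$node_pressures))]),
               unname(fs$node_pressures))
  expect_equal(fs2$channel_flows, fs$channel_flows)
})

test_that("disconnected networks raise a structured error", {
  net <- mf_network(
    nodes = list(mf_node("in"), mf_node("out", is_ground = TRUE,
                                        is_sink = TRUE),
                 mf_node("float1"), mf_node("float2")),
    channels = list(mf_channel("c1", "in", "out", 1e-4, 5e-5, 1e-3),
                    mf_channel("cf", "float1", "float2", 1e-4, 5e-5, 1e-3)),
    pumps = list(mf_pump("p1", "out", "in", "flow_rate", 1e-9)))
  expect_error(solve_flow(net), "singular|floating")
  expect_match(validate_network(net), "float", all = FALSE)
})

test_that("equivalent resistance reduces series and parallel pairs", {
  net <- make_series_chain(2, lengths = c(1e-3, 2.5e-3))
  R <- net$channels$resistance
  expect_equal(equivalent_resistance(net, "in", "out"), sum(R),
               tolerance = 1e-12)
  net <- make_parallel_pair()
  R <- net$channels$resistance
  expect_equal(equivalent_resistance(net, "in", "out"),
               prod(R) / sum(R), tolerance = 1e-12)
})

test_that("a Wheatstone-like bridge matches a delta-star hand reduction", {
  set.seed(5)
  l <- runif(5, 0.5e-3, 3e-3)
  nodes <- list(mf_node("t"), mf_node("u"), mf_node("v"),
                mf_node("g", is_ground = TRUE, is_sink = TRUE))
  channels <- list(mf_channel("e1", "t", "u", 1e-4, 5e-5, l[1]),
                   mf_channel("e2", "t", "v", 1e-4, 5e-5, l[2]),
                   mf_channel("e3", "u", "v", 1e-4, 5e-5, l[3]),
                   mf_channel("e4", "u", "g", 1e-4, 5e-5, l[4]),
                   mf_channel("e5", "v", "g", 1e-4, 5e-5, l[5]))
  net <- mf_network(nodes, channels,
                    pumps = list(mf_pump("p", "g", "t", "flow_rate", 1e-9)))
  R <- stats::setNames(net$channels$resistance, net$channels$id)
  # delta {t,u,v} -> star: Rt = R1 R2 / S, Ru = R1 R3 / S, Rv = R2 R3 / S
  S <- R[["e1"]] + R[["e2"]] + R[["e3"]]
  Rt <- R[["e1"]] * R[["e2"]] / S
  Ru <- R[["e1"]] * R[["e3"]] / S
  Rv <- R[["e2"]] * R[["e3"]] / S
  par <- function(a, b) a * b / (a + b)
  expected <- Rt + par(Ru + R[["e4"]], Rv + R[["e5"]])
  expect_equal(equivalent_resistance(net, "t", "g"), unname(expected),
               tolerance = 1e-12)
})
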