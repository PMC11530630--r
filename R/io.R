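# Network JSON reader/writer and result writers. The canonical on-disk
# format is a JSON object with the top-level keys nodes, channels, pumps,
# fluids, species, injections, droplets, membranes, settings; every physical
# value is either a bare number (SI) or {"value": x, "unit": "um"}. A formal
# JSON Schema of the dialect ships in inst/extdata/network-schema.json; the
# reader enforces the same rules with located error messages.

.key_spec <- list(
  nodes = c("id", "is_ground", "is_sink"),
  channels = c("id", "node_a", "node_b", "width", "height", "length"),
  pumps = c("id", "node_from", "node_to", "kind", "value"),
  fluids = c("id", "viscosity"),
  species = c("id", "diffusion_coefficient"),
  injections = c("node", "concentrations", "t_start", "t_end"),
  droplets = c("id", "length", "b", "channel", "t_inject"),
  membranes = c("id", "channel", "area", "pore_radius", "porosity",
                "thickness", "tank_volume"),
  settings = c("max_time", "fixed_step", "max_events", "record"))

check_keys <- function(obj, allowed, where) {
  extra <- setdiff(names(obj), allowed)
  if (length(extra)) {
    stop("unknown key '", extra[1], "' at ", where,
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
}

need <- function(obj, key, where) {
  if (is.null(obj[[key]])) stop("missing key '", key, "' at ", where,
                                call. = FALSE)
  obj[[key]]
}

#' Read a network description file
#'
#' Parses and validates the JSON network dialect, converting any
#' unit-annotated quantities to SI on load. Unknown keys are rejected with
#' the JSON location; the resulting network is checked with
#' [validate_network()].
#'
#' @param path path to a network JSON file.
#' @return list with the `network` ([mf_network()]) and the `config`
#'   ([sim_config()]) built from the optional `settings` block.
#' @seealso [write_network()]; the format description in
#'   `system.file("extdata", "network-schema.json", package = "microflow")`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_keys(doc, names(.key_spec), "/")
  at <- function(section, i) paste0("/", section, "/", i - 1)
  nodes <- lapply(seq_along(doc$nodes), function(i) {
    o <- doc$nodes[[i]]; w <- at("nodes", i)
    check_keys(o, .key_spec$nodes, w)
    mf_node(need(o, "id", w), isTRUE(o$is_ground), isTRUE(o$is_sink))
  })
  channels <- lapply(seq_along(doc$channels), function(i) {
    o <- doc$channels[[i]]; w <- at("channels", i)
    check_keys(o, .key_spec$channels, w)
    mf_channel(need(o, "id", w), need(o, "node_a", w), need(o, "node_b", w),
               parse_quantity(need(o, "width", w), "length", w),
               parse_quantity(need(o, "height", w), "length", w),
               parse_quantity(need(o, "length", w), "length", w))
  })
  pumps <- lapply(seq_along(doc$pumps), function(i) {
    o <- doc$pumps[[i]]; w <- at("pumps", i)
    check_keys(o, .key_spec$pumps, w)
    kind <- need(o, "kind", w)
    dim <- if (kind == "pressure") "pressure" else "flow_rate"
    mf_pump(need(o, "id", w), need(o, "node_from", w), need(o, "node_to", w),
            kind, parse_quantity(need(o, "value", w), dim, w))
  })
  fluids <- lapply(seq_along(doc$fluids), function(i) {
    o <- doc$fluids[[i]]; w <- at("fluids", i)
    check_keys(o, .key_spec$fluids, w)
    mf_fluid(need(o, "id", w),
             parse_quantity(need(o, "viscosity", w), "viscosity", w))
  })
  if (!length(fluids)) fluids <- list(mf_fluid("carrier", 1e-3))
  species <- lapply(seq_along(doc$species), function(i) {
    o <- doc$species[[i]]; w <- at("species", i)
    check_keys(o, .key_spec$species, w)
    mf_species(need(o, "id", w),
               parse_quantity(need(o, "diffusion_coefficient", w),
                              "diffusivity", w))
  })
  injections <- lapply(seq_along(doc$injections), function(i) {
    o <- doc$injections[[i]]; w <- at("injections", i)
    check_keys(o, .key_spec$injections, w)
    conc <- need(o, "concentrations", w)
    cv <- vapply(conc, parse_quantity, numeric(1),
                 dimension = "concentration", where = w)
    mf_injection(need(o, "node", w), cv,
                 t_start = if (is.null(o$t_start)) 0 else
                   parse_quantity(o$t_start, "time", w),
                 t_end = if (is.null(o$t_end)) Inf else
                   parse_quantity(o$t_end, "time", w))
  })
  droplets <- lapply(seq_along(doc$droplets), function(i) {
    o <- doc$droplets[[i]]; w <- at("droplets", i)
    check_keys(o, .key_spec$droplets, w)
    mf_droplet(need(o, "id", w),
               parse_quantity(need(o, "length", w), "length", w),
               need(o, "channel", w),
               t_inject = if (is.null(o$t_inject)) 0 else
                 parse_quantity(o$t_inject, "time", w),
               b = if (is.null(o$b)) 3 else
                 parse_quantity(o$b, "dimensionless", w))
  })
  membranes <- lapply(seq_along(doc$membranes), function(i) {
    o <- doc$membranes[[i]]; w <- at("membranes", i)
    check_keys(o, .key_spec$membranes, w)
    mf_membrane(need(o, "id", w), need(o, "channel", w),
                parse_quantity(need(o, "area", w), "area", w),
                parse_quantity(need(o, "pore_radius", w), "length", w),
                parse_quantity(need(o, "porosity", w), "dimensionless", w),
                parse_quantity(need(o, "thickness", w), "length", w),
                parse_quantity(need(o, "tank_volume", w), "volume", w))
  })
  network <- mf_network(nodes, channels, pumps, fluids, species,
                        injections, droplets, membranes)
  s <- doc$settings
  config <- sim_config(
    max_time = if (is.null(s$max_time)) 10 else
      parse_quantity(s$max_time, "time", "/settings"),
    fixed_step = if (is.null(s$fixed_step)) NULL else
      parse_quantity(s$fixed_step, "time", "/settings"),
    max_events = if (is.null(s$max_events)) 1e6 else s$max_events,
    record = if (is.null(s$record)) TRUE else isTRUE(s$record))
  list(network = network, config = config)
}

#' Write a network description file
#'
#' Serializes a network (and optionally its simulation settings) to the JSON
#' dialect, all values in SI. `read_network(write_network(net, path))`
#' reproduces the network.
#'
#' @param network an [mf_network()].
#' @param path output file path.
#' @param config optional [sim_config()] stored under `settings`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, config = NULL) {
  row_list <- function(df) lapply(seq_len(nrow(df)), function(i)
    as.list(df[i, , drop = FALSE]))
  doc <- list(
    nodes = row_list(network$nodes),
    channels = row_list(network$channels[, .key_spec$channels]),
    pumps = row_list(network$pumps),
    fluids = row_list(network$fluids),
    species = row_list(network$species),
    injections = lapply(network$injections, function(x) {
      rec <- list(node = x$node, concentrations = as.list(x$concentrations),
                  t_start = x$t_start)
      if (is.finite(x$t_end)) rec$t_end <- x$t_end
      rec
    }),
    droplets = row_list(network$droplets),
    membranes = row_list(network$membranes))
  if (!is.null(config)) {
    doc$settings <- list(max_time = config$max_time,
                         max_events = config$max_events,
                         record = config$record)
    if (!is.null(config$fixed_step)) doc$settings$fixed_step <- config$fixed_step
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Long-format time series of a result set: one row per
# (time, entity_type, id, variable).
resultset_timeseries <- function(resultset) {
  rows <- lapply(resultset$entries, function(e) {
    out <- list(
      data.frame(time = e$time, entity_type = "node",
                 id = names(e$node_pressures), variable = "pressure_Pa",
                 value = as.numeric(e$node_pressures),
                 stringsAsFactors = FALSE),
      data.frame(time = e$time, entity_type = "channel",
                 id = names(e$channel_flows), variable = "flow_m3_per_s",
                 value = as.numeric(e$channel_flows),
                 stringsAsFactors = FALSE))
    sp <- colnames(e$node_mix)
    for (s in sp) {
      out[[length(out) + 1L]] <- data.frame(
        time = e$time, entity_type = "node", id = rownames(e$node_mix),
        variable = paste0("concentration_", s),
        value = as.numeric(e$node_mix[, s]), stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        time = e$time, entity_type = "channel", id = rownames(e$channel_mix),
        variable = paste0("concentration_", s),
        value = as.numeric(e$channel_mix[, s]), stringsAsFactors = FALSE)
      if (nrow(e$tank_mix)) {
        out[[length(out) + 1L]] <- data.frame(
          time = e$time, entity_type = "tank", id = rownames(e$tank_mix),
          variable = paste0("concentration_", s),
          value = as.numeric(e$tank_mix[, s]), stringsAsFactors = FALSE)
      }
    }
    if (!is.null(e$droplets) && nrow(e$droplets)) {
      d <- e$droplets[e$droplets$state == "in_channel", , drop = FALSE]
      if (nrow(d)) {
        out[[length(out) + 1L]] <- data.frame(
          time = e$time, entity_type = "droplet", id = d$id,
          variable = "head_fraction", value = d$head,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}

#' Resample a recorded time series on a regular grid
#'
#' Event times cluster irregularly; for plotting and comparison the recorded
#' values can be linearly interpolated onto a fixed cadence.
#'
#' @param timeseries long-format data frame as produced by the result
#'   writers (columns `time`, `entity_type`, `id`, `variable`, `value`).
#' @param dt output cadence, s.
#' @return data frame with the same columns on the regular grid.
#' @export
resample_timeseries <- function(timeseries, dt) {
  grid <- seq(min(timeseries$time), max(timeseries$time), by = dt)
  keys <- unique(timeseries[, c("entity_type", "id", "variable")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- timeseries[timeseries$entity_type == k$entity_type &
                      timeseries$id == k$id &
                      timeseries$variable == k$variable, ]
    v <- stats::approx(sub$time, sub$value, xout = grid, rule = 2)$y
    data.frame(time = grid, entity_type = k$entity_type, id = k$id,
               variable = k$variable, value = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write simulation results to a directory
#'
#' Writes `timeseries.csv` (long format: time, entity_type, id, variable,
#' value), `summary.json` (status, final pressures/flows/concentrations,
#' event log), `droplet_paths.json` (when droplets were simulated) and
#' `manifest.json` (software version, event count, file list). Output is
#' deterministic: rerunning the same input yields byte-identical files.
#'
#' @param resultset an `mf_resultset`.
#' @param out_dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(resultset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  ts <- resultset_timeseries(resultset)
  f_ts <- file.path(out_dir, "timeseries.csv")
  utils::write.csv(ts, f_ts, row.names = FALSE, quote = FALSE)
  files <- c(files, f_ts)
  last <- resultset$entries[[length(resultset$entries)]]
  summary <- list(
    status = resultset$status,
    event_count = resultset$event_count,
    final_time = last$time,
    node_pressures_Pa = as.list(last$node_pressures),
    channel_flows_m3_per_s = as.list(last$channel_flows),
    events = resultset$events)
  f_sum <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, f_sum, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  files <- c(files, f_sum)
  has_droplets <- length(resultset$droplets) > 0
  if (has_droplets) {
    f_dp <- file.path(out_dir, "droplet_paths.json")
    jsonlite::write_json(extract_paths(resultset), f_dp, digits = NA,
                         pretty = TRUE)
    files <- c(files, f_dp)
  }
  manifest <- list(
    package = "microflow",
    version = as.character(utils::packageVersion("microflow")),
    status = resultset$status,
    event_count = resultset$event_count,
    max_time = resultset$config$max_time,
    droplet_paths_written = has_droplets,
    files = basename(c(files, file.path(out_dir, "manifest.json"))))
  f_mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f_mf)
  invisible(files)
}
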