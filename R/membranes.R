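# Membrane module: pore-discovery permeability model, diffusive flux between
# a channel and its attached tank, and RK4 integration of the coupled
# concentration pair per mirrored slug.

#' Membrane resistance from the pore-discovery model
#'
#' Lumps the membrane geometry into a single resistance to diffusive species
#' transport. Three contributions are combined: the pore-discovery resistance
#' of a single pore \eqn{R_d = 1/(4 r D_F)}, shared among
#' \eqn{N_p = (A_m/A_p)\,\phi} pores (with pore area \eqn{A_p = \pi r^2} and
#' porosity \eqn{\phi}), and the resistance of the effective thickness the
#' species must cross, \eqn{R_{th} = th/(A_m D_F)}:
#' \deqn{R_M = R_d / N_p + R_{th}.}
#' Because the area is folded into the resistance, the transmembrane molar
#' flow is simply \eqn{J = \Delta C / R_M} (see [membrane_flux()]).
#'
#' Zero porosity gives an impermeable membrane, reported as `Inf` with
#' attribute `impermeable = TRUE`.
#'
#' @param area membrane surface area \eqn{A_m}, m^2.
#' @param pore_radius pore radius r, m.
#' @param porosity open-area fraction in [0, 1).
#' @param thickness effective thickness th, m (geometric or
#'   tortuosity-corrected, at the user's discretion).
#' @param diffusion_coefficient species free diffusivity \eqn{D_F}, m^2/s.
#' @return membrane resistance \eqn{R_M} in s/m^3.
#' @export
membrane_resistance <- function(area, pore_radius, porosity, thickness,
                                diffusion_coefficient) {
  check_positive(area = area, pore_radius = pore_radius,
                 thickness = thickness,
                 diffusion_coefficient = diffusion_coefficient)
  if (porosity < 0 || porosity >= 1) stop("porosity must lie in [0, 1)")
  if (porosity == 0) {
    return(structure(Inf, impermeable = TRUE))
  }
  R_d <- 1 / (4 * pore_radius * diffusion_coefficient)
  A_p <- pi * pore_radius^2
  N_p <- (area / A_p) * porosity
  R_th <- thickness / (area * diffusion_coefficient)
  R_d / N_p + R_th
}

#' Transmembrane molar flow
#'
#' Linear flux law through the lumped membrane resistance:
#' `J = delta_c / R_M`, positive from channel to tank when the channel is
#' richer.
#'
#' @param delta_c concentration difference (channel minus tank), mol/m^3.
#' @param R_M membrane resistance, s/m^3 (`Inf` = impermeable, flux 0).
#' @return molar flow in mol/s.
#' @export
membrane_flux <- function(delta_c, R_M) {
  ifelse(is.infinite(R_M), 0, delta_c / R_M)
}

#' One classic fourth-order Runge-Kutta step
#'
#' Standard four-stage RK4 update for `dy/dt = f(t, y)`; global error is
#' O(dt^4) on smooth problems.
#'
#' @param f derivative function `f(t, y)` returning a vector like `y`.
#' @param y current state (numeric vector).
#' @param t current time.
#' @param dt step size.
#' @return the state at `t + dt`.
#' @export
rk4_step <- function(f, y, t, dt) {
  k1 <- f(t, y)
  k2 <- f(t + dt / 2, y + dt / 2 * k1)
  k3 <- f(t + dt / 2, y + dt / 2 * k2)
  k4 <- f(t + dt, y + dt * k3)
  out <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(out))) {
    stop("non-finite state in RK4 step (dt too large or derivative singular)")
  }
  out
}

#' Channel-tank exchange over one engine step
#'
#' Integrates the diffusive exchange between every aligned channel/tank slug
#' pair over `dt` with classic RK4. Each pair exchanges through the membrane
#' area share proportional to its length fraction, so the pair `(C_c, C_t)`
#' obeys the coupled linear system
#' \deqn{V_{t}\,dC_t/dt = \Delta C / R_{M},\qquad
#'       V_{c}\,dC_c/dt = -\Delta C / R_{M},}
#' written per unit length fraction; the length fraction cancels between the
#' area share and the compartment volumes, so every pair relaxes with the
#' same rate constant \eqn{\lambda = (1/V_c + 1/V_t)/R_M}. The step is
#' internally subdivided so that \eqn{\lambda h \le} `safety` for every
#' species, which keeps the RK4 error far below the linear-law time scale and
#' rules out overshoot. Total moles per species in each channel+tank pair are
#' conserved (a linear invariant, preserved by RK4 up to rounding).
#'
#' @param channel_slugs,tank_slugs aligned `mf_slugs` profiles (identical
#'   bounds; see [align_slug_sets()]).
#' @param R_M named vector of membrane resistances per species, s/m^3.
#' @param dt engine step, s.
#' @param channel_volume,tank_volume total compartment volumes, m^3.
#' @param safety dimensionless cap on `lambda * h` per RK4 substep.
#' @return list with updated `channel` and `tank` slug sets.
#' @export
exchange_step <- function(channel_slugs, tank_slugs, R_M, dt,
                          channel_volume, tank_volume, safety = 0.05) {
  b <- channel_slugs$b
  if (length(b) != length(tank_slugs$b) ||
      max(abs(b - tank_slugs$b)) > 1e-9) {
    stop("misaligned slugs: channel and tank profiles must share bounds")
  }
  sp <- colnames(channel_slugs$C)
  if (length(sp) == 0 || dt <= 0) {
    return(list(channel = channel_slugs, tank = tank_slugs))
  }
  kinv <- 1 / as.numeric(R_M[sp])          # 0 for impermeable species
  kinv[!is.finite(kinv)] <- 0
  lambda <- (1 / channel_volume + 1 / tank_volume) * kinv
  nsub <- max(1L, ceiling(dt * max(lambda) / safety))
  h <- dt / nsub
  k <- nrow(channel_slugs$C)
  y <- c(channel_slugs$C, tank_slugs$C)    # column-major: channel then tank
  n <- length(channel_slugs$C)
  kc <- matrix(rep(kinv, each = k), k)     # conductance per cell x species
  f <- function(t, y) {
    Cc <- matrix(y[1:n], k); Ct <- matrix(y[(n + 1):(2 * n)], k)
    d <- (Cc - Ct) * kc
    c(-d / channel_volume, d / tank_volume)
  }
  t <- 0
  for (i in seq_len(nsub)) {
    y <- rk4_step(f, y, t, h)
    t <- t + h
  }
  Cc <- matrix(y[1:n], k, dimnames = list(NULL, sp))
  Ct <- matrix(y[(n + 1):(2 * n)], k, dimnames = list(NULL, sp))
  list(channel = structure(list(b = b, C = Cc), class = "mf_slugs"),
       tank = structure(list(b = b, C = Ct), class = "mf_slugs"))
}

# Per-species membrane resistances for one membrane record.
membrane_resistances_by_species <- function(membrane, species) {
  vapply(seq_len(nrow(species)), function(i) {
    as.numeric(membrane_resistance(membrane$area, membrane$pore_radius,
                                   membrane$porosity, membrane$thickness,
                                   species$diffusion_coefficient[i]))
  }, numeric(1)) -> r
  stats::setNames(r, species$id)
}

#' Tank concentration time series
#'
#' Volume-weighted mean concentration of a membrane's tank over a run.
#'
#' @param resultset an `mf_resultset` from [run_simulation()].
#' @param membrane id of the membrane/tank.
#' @return data frame with columns `time`, `species`, `concentration`.
#' @export
tank_concentration_profile <- function(resultset, membrane) {
  net <- resultset$network
  if (!membrane %in% net$membranes$id) stop("unknown membrane '", membrane, "'")
  sp <- net$species$id
  rows <- lapply(resultset$entries, function(e) {
    data.frame(time = e$time, species = sp,
               concentration = as.numeric(e$tank_mix[membrane, sp]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
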