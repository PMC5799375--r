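## Mean-field (ODE) engine: integrates the same propensity functions as the
## stochastic engine, with gene ON-allele counts replaced by continuous
## occupancies. Used for deterministic protocol analysis and for computing
## the basal steady state.

ode_deriv_factory <- function(compiled) {
  ri <- compiled$ri; inh <- compiled$inh; alpha <- compiled$alpha
  S <- compiled$S
  function(t, x, parms) {
    xp <- c(1, pmax(x, 0))
    a <- parms * xp[ri[, 1L] + 1L] * xp[ri[, 2L] + 1L] * xp[ri[, 3L] + 1L]
    ia <- inh > 0L
    if (any(ia)) a[ia] <- a[ia] / (1 + alpha[ia] * xp[inh[ia] + 1L])
    list(as.vector(S %*% a))
  }
}

#' Mean-field simulation of a reaction network
#'
#' Integrates the deterministic rate equations sharing the stochastic
#' engine's propensity functions (telegraph gene states become continuous
#' ON-allele occupancies). Protocol events are handled as exact changepoints:
#' the integrator is restarted at each event time with the updated state and
#' rate constants. Deterministic for fixed inputs.
#'
#' @param network A \code{\link{build_network}} object.
#' @param init Initial state (defaults to the network's basal state template
#'   \code{network$x0}).
#' @param protocol Optional \code{\link{make_protocol}} object.
#' @param horizon Simulated time (s); defaults to the protocol horizon.
#' @param output_dt Output grid spacing (s).
#' @param rel_tol,abs_tol Solver tolerances (lsoda).
#' @param uptake Optional per-transfection bolus override (molecules).
#' @return Object of class \code{"trajectory"}: \code{time} (s),
#'   \code{counts} (time x species matrix), \code{mode = "ode"}.
#' @export
ode_run <- function(network, init = NULL, protocol = NULL, horizon = NULL,
                    output_dt = 60, rel_tol = 1e-6, abs_tol = 1e-3,
                    uptake = NULL) {
  if (is.null(init)) init <- network$x0
  if (is.null(horizon)) {
    if (is.null(protocol)) stop("need horizon or protocol", call. = FALSE)
    horizon <- protocol$horizon
  }
  if (horizon <= 0 || output_dt <= 0)
    stop("horizon and output_dt must be > 0", call. = FALSE)
  comp <- network$compiled
  sched <- if (is.null(protocol)) list(times = numeric(0)) else
    compile_schedule(network, protocol, uptake = uptake)
  deriv <- ode_deriv_factory(comp)

  grid <- seq(0, horizon, by = output_dt)
  cps <- sched$times[sched$times < horizon]
  bounds <- sort(unique(c(0, cps, horizon)))
  x <- as.numeric(init); names(x) <- network$species
  rates <- comp$rate
  out <- matrix(NA_real_, length(grid), length(x),
                dimnames = list(NULL, network$species))
  if (grid[1] == 0) out[1, ] <- x
  for (b in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[b]; t1 <- bounds[b + 1L]
    k <- match(t0, sched$times)
    if (!is.na(k)) {
      x <- x + sched$dx[, k]
      rates <- sched$rates[, k]
      gi <- which(grid == t0)
      if (length(gi)) out[gi, ] <- x   # value just after an event at a grid point
    }
    seg <- grid[grid > t0 & grid <= t1]
    tt <- unique(c(t0, seg, t1))
    if (length(tt) < 2L) tt <- c(t0, t1)
    sol <- deSolve::lsoda(y = x, times = tt, func = deriv, parms = rates,
                          rtol = rel_tol, atol = abs_tol)
    if (attr(sol, "istate")[1L] < 0)
      stop("ODE solver failed near t = ", utils::tail(sol[, 1], 1), " s",
           call. = FALSE)
    if (length(seg))
      out[match(seg, grid), ] <- sol[match(seg, sol[, 1]), -1, drop = FALSE]
    x <- sol[nrow(sol), -1]
  }
  structure(list(time = grid, counts = out, mode = "ode", seed = NA_integer_,
                 n_events = NA_real_, species = network$species),
            class = "trajectory")
}

#' Basal (unstimulated) deterministic steady state
#'
#' Integrates the unstimulated mean-field model long enough for all basal
#' pools to relax and returns the final state. Used as the deterministic
#' backbone for stochastic equilibration.
#'
#' @param network A \code{reaction_network}.
#' @param duration Relaxation time (s); the default spans many multiples of
#'   the slowest basal timescale (STAT protein turnover).
#' @return Named numeric state vector.
#' @export
basal_state <- function(network, duration = 2e6) {
  tr <- ode_run(network, horizon = duration, output_dt = duration / 4)
  x <- tr$counts[nrow(tr$counts), ]
  names(x) <- network$species
  x
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> mode:", x$mode, " points:", length(x$time),
      " span:", utils::tail(x$time, 1), "s",
      if (is.finite(x$n_events)) paste(" events:", x$n_events) else "", "\n")
  invisible(x)
}

#' Extract one species' profile from a trajectory
#' @param trajectory A \code{trajectory}.
#' @param species Species name.
#' @return Numeric vector along \code{trajectory$time}.
#' @export
species_profile <- function(trajectory, species) {
  if (!species %in% colnames(trajectory$counts))
    stop("unknown species: ", species, call. = FALSE)
  trajectory$counts[, species]
}

#' Write a trajectory as tidy CSV
#'
#' Long format: \code{time, species, value, cell_id, mode}.
#' @param trajectory A \code{trajectory}.
#' @param path Output CSV path.
#' @param cell_id Identifier written to the \code{cell_id} column.
#' @param species Optional subset of species to write.
#' @export
write_trajectory_csv <- function(trajectory, path, cell_id = 1L,
                                 species = NULL) {
  cols <- if (is.null(species)) colnames(trajectory$counts) else species
  df <- do.call(rbind, lapply(cols, function(s) {
    data.frame(time = trajectory$time, species = s,
               value = trajectory$counts[, s],
               cell_id = cell_id, mode = trajectory$mode)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
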