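## Stochastic engines: exact Gillespie SSA (default) and approximate
## tau-leaping, both consuming the compiled reaction table.

## Derive the (seed, stream) pair for the PCG32 generator. Cells get
## independent streams keyed by (master seed, cell index).
rng_key <- function(seed, cell = 0L) {
  c(as.integer(seed %% 2147483647), as.integer(cell %% 2147483647))
}

#' Exact stochastic simulation of a reaction network
#'
#' Samples a statistically exact path of the Markov jump process defined by
#' the network's propensities (Gillespie direct method; propensity updates
#' restricted to the reaction dependency graph). Protocol events are
#' propensity/state changepoints handled exactly: the pending unit-rate
#' exponential clock is rescaled across each discontinuity. Identical
#' (network, init, protocol, seed) give a bit-identical trajectory.
#'
#' @param network A \code{\link{build_network}} object.
#' @param init Initial state (integer counts; defaults to the rounded network
#'   template \code{network$x0}). Use \code{\link{equilibrate}} for a
#'   stationary prestimulation state.
#' @param protocol Optional \code{\link{make_protocol}} object.
#' @param horizon Simulated time (s), > 0; defaults to the protocol horizon.
#' @param seed Integer master seed.
#' @param output_dt Output grid spacing (s), > 0. Trajectory values are the
#'   piecewise-constant jump path sampled just before each grid time.
#' @param cell Stream index (used by \code{\link{run_ensemble}}).
#' @param uptake Optional per-transfection bolus override (molecules).
#' @param mode \code{"ssa"} (exact) or \code{"tau"} (tau-leaping,
#'   approximate, error parameter \code{eps}).
#' @param eps Tau-leaping error control parameter.
#' @param max_events Guard against runaway propensities.
#' @return A \code{"trajectory"} object (integer counts in ssa mode).
#' @export
ssa_run <- function(network, init = NULL, protocol = NULL, horizon = NULL,
                    seed = 1L, output_dt = 60, cell = 0L, uptake = NULL,
                    mode = c("ssa", "tau"), eps = 0.03, max_events = 5e9) {
  mode <- match.arg(mode)
  if (is.null(init)) init <- network$x0
  if (is.null(horizon)) {
    if (is.null(protocol)) stop("need horizon or protocol", call. = FALSE)
    horizon <- protocol$horizon
  }
  if (horizon <= 0 || output_dt <= 0)
    stop("horizon and output_dt must be > 0", call. = FALSE)
  comp <- network$compiled
  x0 <- round(as.numeric(init))
  if (any(x0 < 0)) stop("negative initial counts", call. = FALSE)
  sched <- if (is.null(protocol))
    list(times = numeric(0),
         dx = matrix(0, length(x0), 0), rates = matrix(0, length(comp$rate), 0))
  else compile_schedule(network, protocol, uptake = uptake)
  grid <- seq(0, horizon, by = output_dt)

  ## events at t = 0 are applied before the run starts
  rates <- comp$rate
  keep <- sched$times > 0
  if (any(!keep)) {
    for (k in which(!keep)) {
      x0 <- x0 + round(sched$dx[, k])
      rates <- sched$rates[, k]
    }
  }
  cpt <- sched$times[keep]
  cpdx <- sched$dx[, keep, drop = FALSE]
  cpr <- sched$rates[, keep, drop = FALSE]

  res <- if (mode == "ssa")
    .ssa_core(x0, rates, comp$ri, comp$inh, comp$alpha,
              comp$st_reac, comp$st_spec, comp$st_delta,
              cpt, cpdx, cpr, grid, 0, horizon,
              numeric(0), rng_key(seed, cell), -1, max_events)
  else
    .tau_core(x0, rates, comp$ri, comp$inh, comp$alpha,
              comp$st_reac, comp$st_spec, comp$st_delta,
              cpt, cpdx, cpr, grid, 0, horizon, rng_key(seed, cell), eps)
  counts <- res$counts
  dimnames(counts) <- list(NULL, network$species)
  structure(list(time = grid, counts = counts, mode = mode,
                 seed = as.integer(seed), n_events = res$n_events,
                 species = network$species,
                 final_state = stats::setNames(res$state, network$species)),
            class = "trajectory")
}

#' Equilibrate a cell to its unstimulated stationary state
#'
#' The prestimulation (quiescence) phase: transcriptional bursting of the
#' two-state loci generates the broad cell-to-cell distributions of RIG-I,
#' PKR and OAS1A that underlie population heterogeneity.
#'
#' \code{mode = "full"} runs the exact SSA with no stimulus for
#' \code{duration} seconds (the canonical configuration uses 3e6 s, about 35
#' days). \code{mode = "fast"} draws an equivalent state directly: allele
#' states from the telegraph stationary occupancy, mRNA counts from a
#' matched super-Poissonian (negative binomial) law, and burst-driven protein
#' counts from moment-matched laws with variances obtained by linear noise
#' propagation through the gene -> mRNA -> protein cascade (stationary
#' Lyapunov equation); all remaining pools sit at the deterministic basal
#' state.
#'
#' @param network A \code{reaction_network}.
#' @param duration Equilibration time (s) for full mode; \code{duration = 0}
#'   returns \code{init} unchanged.
#' @param seed Integer seed.
#' @param mode \code{"fast"} or \code{"full"}.
#' @param init Starting state for full mode (defaults to the deterministic
#'   basal state).
#' @param cell Stream index.
#' @param basal Optional precomputed \code{\link{basal_state}} (avoids
#'   recomputation across an ensemble).
#' @return Named state vector (integer counts) of an unstimulated cell.
#' @export
equilibrate <- function(network, duration = 3e6, seed = 1L,
                        mode = c("fast", "full"), init = NULL, cell = 0L,
                        basal = NULL) {
  mode <- match.arg(mode)
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  if (is.null(basal)) basal <- basal_state(network)
  if (mode == "full") {
    x0 <- if (is.null(init)) round(basal) else round(as.numeric(init))
    if (duration == 0)
      return(stats::setNames(x0, network$species))
    tr <- ssa_run(network, init = x0, horizon = duration, seed = seed,
                  output_dt = duration, cell = cell)
    return(tr$final_state)
  }
  ## fast mode: moment-matched sampling of the bursty components
  x <- round(basal)
  names(x) <- network$species
  gt <- gene_table(network$params)
  p <- as.list(network$params)
  tl <- list(ddx58 = c("RIGI", p$ktl_rigi, p$d_rigi),
             eif2ak2 = c("PKR", p$ktl_pkr, p$d_pkr),
             oas1a = c("OAS", p$ktl_oas, p$d_oas))
  set.seed(rng_key(seed, cell)[1] + 7919L * (cell %% 262143L))
  for (i in seq_len(nrow(gt))) {
    g <- gt$gene[i]
    st <- stationary_gene_stats(gt$k_on[i], gt$k_off[i], gt$k_tx[i],
                                gt$gamma_m[i], gt$copy_number[i])
    non <- stats::rbinom(1, gt$copy_number[i], st$p_on)
    x[paste0("G_", g, "_on")] <- non
    x[paste0("G_", g, "_off")] <- gt$copy_number[i] - non
    x[gt$mrna[i]] <- rnbinom_matched(1, st$mean, st$variance)
    if (g %in% names(tl)) {
      prot <- tl[[g]]
      mom <- cascade_protein_moments(
        gt$k_on[i], gt$k_off[i], gt$k_tx[i], gt$gamma_m[i],
        as.numeric(prot[2]), as.numeric(prot[3]), gt$copy_number[i])
      x[prot[1]] <- rnbinom_matched(1, mom$mean, mom$variance)
    }
  }
  x
}

## negative binomial matched to (mean, variance); Poisson if not
## super-Poissonian
rnbinom_matched <- function(n, mean, variance) {
  if (mean <= 0) return(rep(0L, n))
  if (variance <= mean * 1.0001) return(stats::rpois(n, mean))
  size <- mean^2 / (variance - mean)
  stats::rnbinom(n, size = size, mu = mean)
}

## Stationary mean and LNA variance of the protein in the
## gene -> mRNA -> protein cascade (telegraph source), via the 3x3
## stationary Lyapunov equation A Sigma + Sigma A' + D = 0.
cascade_protein_moments <- function(k_on, k_off, k_tx, gamma_m,
                                    k_tl, gamma_p, copy_number = 2L) {
  n <- copy_number
  p_on <- k_on / (k_on + k_off)
  gbar <- n * p_on
  mbar <- gbar * k_tx / gamma_m
  pbar <- mbar * k_tl / gamma_p
  A <- matrix(c(-(k_on + k_off), 0, 0,
                k_tx, -gamma_m, 0,
                0, k_tl, -gamma_p), 3, 3, byrow = TRUE)
  D <- diag(c(k_on * (n - gbar) + k_off * gbar,
              k_tx * gbar + gamma_m * mbar,
              k_tl * mbar + gamma_p * pbar))
  I3 <- diag(3)
  Sig <- matrix(solve(kronecker(I3, A) + kronecker(A, I3), -as.vector(D)), 3, 3)
  list(mean = pbar, variance = Sig[3, 3], mrna_variance = Sig[2, 2])
}
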