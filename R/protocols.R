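## Stimulation protocols: timed in-silico counterparts of the wet-lab
## treatments (LPS, transfected poly(I:C), IFN-beta priming, cycloheximide,
## the PKR inhibitor C16, and IFNAR-blocking antibody).

.protocol_actions <- c("add_LPS", "transfect_polyIC", "add_IFNb",
                       "add_CHX", "add_C16", "block_IFNAR", "release", "none")

#' Construct a validated stimulation protocol
#'
#' Events are (time, action, dose) triples applied to a running simulation as
#' propensity/state changepoints. Doses are in the experimental units:
#' ug/ml for LPS and poly(I:C), U/ml for IFN-beta; CHX, C16, IFNAR block and
#' release take no dose. Times are in seconds from simulation start (i.e.
#' from the end of the equilibration phase).
#'
#' @param events List of events, each a list/vector with elements
#'   \code{time}, \code{action} and optionally \code{dose}.
#' @param genotype Genotype flag or \code{\link{genotype}} object.
#' @param horizon Total simulated time (s); must exceed the last event time.
#' @return Object of class \code{"stim_protocol"}.
#' @examples
#' make_protocol(list(list(time = 0, action = "add_LPS", dose = 1)),
#'               horizon = 6 * 3600)
#' @export
make_protocol <- function(events, genotype = "wild_type", horizon = 86400) {
  if (is.character(genotype)) genotype <- innatesim::genotype(genotype)
  if (length(events) < 1L)
    stop("a protocol needs at least one event", call. = FALSE)
  ev <- lapply(events, function(e) {
    e <- as.list(e)
    if (is.null(e$time) || is.null(e$action))
      stop("each event needs 'time' and 'action'", call. = FALSE)
    if (!e$action %in% .protocol_actions)
      stop("unknown action: ", e$action, call. = FALSE)
    dose <- if (is.null(e$dose)) 0 else as.numeric(e$dose)
    if (is.na(dose) || dose < 0)
      stop("negative or missing dose in event '", e$action, "'", call. = FALSE)
    list(time = as.numeric(e$time), action = e$action, dose = dose)
  })
  times <- vapply(ev, `[[`, 0, "time")
  if (is.unsorted(times))
    stop("event times must be non-decreasing", call. = FALSE)
  if (any(times < 0)) stop("event times must be >= 0", call. = FALSE)
  if (horizon <= max(times))
    stop("horizon must exceed the last event time", call. = FALSE)
  structure(list(events = ev, genotype = genotype, horizon = horizon),
            class = "stim_protocol")
}

#' Named protocol presets
#'
#' Ready-made protocols for the stimulation designs used throughout the
#' study: single-dose LPS; poly(I:C) at 0.1/0.3/1/3 ug/ml; direct IFN-beta;
#' IFN-beta priming (24 h, 1000 U/ml) followed by poly(I:C); the
#' quiescence-offset variants \code{"fig6b"} (2 days quiescence, then 1 day
#' poly(I:C)) and \code{"fig6c"} (1 day quiescence, 1 day IFN-beta priming,
#' then 1 day poly(I:C)); cycloheximide added 1 h before LPS
#' (\code{"chx_lps"}); the PKR inhibitor C16 added 1 h before poly(I:C)
#' (\code{"c16_polyic"}); and IFNAR blocking re-dosed at 0, 3, 6 and 10 h
#' after poly(I:C) (\code{"aifnar_polyic"}).
#'
#' @param name Preset name (see Details).
#' @param dose Stimulus dose where applicable (ug/ml; default 1 for LPS and
#'   poly(I:C)).
#' @param genotype Genotype flag.
#' @param horizon Override the preset's default horizon (s).
#' @return A \code{\link{make_protocol}} object.
#' @export
protocol_preset <- function(name, dose = 1, genotype = "wild_type",
                            horizon = NULL) {
  h <- 3600
  ev <- switch(
    name,
    "unstimulated" = list(list(time = 0, action = "none")),
    "lps" = list(list(time = 0, action = "add_LPS", dose = dose)),
    "polyic" = list(list(time = 0, action = "transfect_polyIC", dose = dose)),
    "ifnb" = list(list(time = 0, action = "add_IFNb", dose = 1000)),
    "primed_polyic" = list(
      list(time = 0, action = "add_IFNb", dose = 1000),
      list(time = 24 * h, action = "transfect_polyIC", dose = dose)),
    "fig6b" = list(
      list(time = 0, action = "none"),
      list(time = 48 * h, action = "transfect_polyIC", dose = dose)),
    "fig6c" = list(
      list(time = 0, action = "none"),
      list(time = 24 * h, action = "add_IFNb", dose = 1000),
      list(time = 48 * h, action = "transfect_polyIC", dose = dose)),
    "chx_lps" = list(
      list(time = 0, action = "add_CHX"),
      list(time = 3600, action = "add_LPS", dose = dose)),
    "c16_polyic" = list(
      list(time = 0, action = "add_C16"),
      list(time = 3600, action = "transfect_polyIC", dose = dose)),
    "aifnar_polyic" = list(
      list(time = 0, action = "transfect_polyIC", dose = dose),
      list(time = 0, action = "block_IFNAR"),
      list(time = 3 * h, action = "block_IFNAR"),
      list(time = 6 * h, action = "block_IFNAR"),
      list(time = 10 * h, action = "block_IFNAR")),
    stop("unknown preset: ", name, call. = FALSE))
  def_h <- switch(name,
                  "lps" = 6 * h, "chx_lps" = 7 * h,
                  "fig6b" = 72 * h, "fig6c" = 72 * h,
                  "primed_polyic" = 34 * h,
                  24 * h)
  make_protocol(ev, genotype = genotype,
                horizon = if (is.null(horizon)) def_h else horizon)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol> genotype:", x$genotype$flag,
      " horizon:", x$horizon, "s\n")
  for (e in x$events)
    cat(sprintf("  t = %8.0f s  %-16s dose = %g\n", e$time, e$action, e$dose))
  invisible(x)
}

#' Per-cell poly(I:C) uptake sampler
#'
#' Lipofectamine delivery partitions poly(I:C) very unevenly between cells.
#' Per-cell bolus amounts are drawn i.i.d. from a log-normal whose mean is
#' proportional to the dose (\code{pic_molecules_per_ugml} molecules per
#' ug/ml) and whose coefficient of variation is \code{cv}.
#'
#' @param dose Poly(I:C) dose (ug/ml), >= 0.
#' @param n_cells Number of cells, >= 1.
#' @param cv Coefficient of variation of the uptake distribution (> 0).
#' @param seed Optional integer seed (local RNG scope).
#' @param params Parameter vector (for the dose-to-molecules scale).
#' @return Numeric vector of per-cell intracellular bolus amounts
#'   (molecules); all zeros when \code{dose = 0}.
#' @export
sample_polyic_uptake <- function(dose, n_cells, cv = NULL, seed = NULL,
                                 params = default_params()) {
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (is.null(cv)) cv <- unname(params["uptake_cv"])
  if (cv <= 0) stop("dispersion (cv) must be > 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (dose == 0) return(numeric(n_cells))
  mu_lin <- dose * unname(params["pic_molecules_per_ugml"])
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mu_lin) - sdlog^2 / 2
  stats::rlnorm(n_cells, meanlog, sdlog)
}

## Compile a protocol into engine changepoints for one cell.
##
## Returns list(times, dx (S x k matrix of state increments), rates (m x k
## matrix of effective rate constants after each changepoint)). Group
## multipliers: CHX zeroes "translation", C16 scales "pkr_activation" by
## c16_factor, block_IFNAR zeroes "ifnar_bind"; "release" restores all to 1.
## `uptake` overrides the mean-dose bolus for transfect_polyIC events (one
## value per transfection event, in molecules).
compile_schedule <- function(network, protocol, uptake = NULL) {
  p <- network$params
  comp <- network$compiled
  sp <- network$species
  m <- length(comp$rate)
  mult <- c(translation = 1, pkr_activation = 1, ifnar_bind = 1)
  times <- vapply(protocol$events, `[[`, 0, "time")
  ut <- unique(times)
  dx <- matrix(0, length(sp), length(ut), dimnames = list(sp, NULL))
  rates <- matrix(0, m, length(ut))
  n_tf <- 0L
  for (k in seq_along(ut)) {
    for (e in protocol$events[times == ut[k]]) {
      switch(e$action,
        add_LPS = {
          dx["LPS", k] <- dx["LPS", k] + e$dose * p[["lps_units_per_ugml"]]
        },
        transfect_polyIC = {
          n_tf <- n_tf + 1L
          bolus <- if (is.null(uptake)) e$dose * p[["pic_molecules_per_ugml"]]
                   else uptake[n_tf]
          dx["pIC_ext", k] <- dx["pIC_ext", k] + bolus
        },
        add_IFNb = {
          dx["IFNb_e", k] <- dx["IFNb_e", k] +
            e$dose * p[["ifnb_molecules_per_unit"]]
        },
        add_CHX = mult["translation"] <- 0,
        add_C16 = mult["pkr_activation"] <- p[["c16_factor"]],
        block_IFNAR = mult["ifnar_bind"] <- 0,
        release = mult[] <- 1,
        none = NULL)
    }
    r <- comp$rate
    for (g in names(mult)) {
      sel <- comp$group == g
      if (any(sel)) r[sel] <- r[sel] * mult[[g]]
    }
    rates[, k] <- r
  }
  list(times = ut, dx = dx, rates = rates)
}
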