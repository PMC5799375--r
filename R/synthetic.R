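## Synthetic-data generators: pseudo-experimental datasets with the
## statistical structure the analysis pipeline assumes (bimodal single-cell
## translocation scores, replicate-noisy delta-CT time profiles, broad
## per-cell uptake measurements). Every generator is seeded and returns the
## ground truth needed for recovery tests.

#' Specification for synthetic datasets
#'
#' @param seed Integer seed.
#' @param n_cells Number of cells / rows.
#' @param responder_fraction Fraction of jointly responding cells in [0,1].
#' @param mean_lo,mean_hi Component means of the (log-normal) score mixture
#'   on the natural scale.
#' @param cv_lo,cv_hi Component coefficients of variation (> 0).
#' @param label_correlation Probability that a responder cell responds with
#'   both factors jointly (the remainder responds with one factor chosen at
#'   random); high values reproduce the observation that most IRF3
#'   responders are also NF-kB responders.
#' @param ct_sd Replicate noise s.d. in CT units (default 0.8, the observed
#'   replicate variability of the GAPDH reference across 183 measurements).
#' @param n_replicates RT-PCR replicates per time point.
#' @param dose,uptake_cv,measurement_cv Uptake generator settings.
#' @return List of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(seed = 1L, n_cells = 1000L,
                           responder_fraction = 0.4,
                           mean_lo = 0.04, mean_hi = 0.45,
                           cv_lo = 0.35, cv_hi = 0.25,
                           label_correlation = 0.9,
                           ct_sd = 0.8, n_replicates = 3L,
                           dose = 1, uptake_cv = 0.8,
                           measurement_cv = 0.2) {
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("responder_fraction must be in [0,1]", call. = FALSE)
  if (cv_lo <= 0 || cv_hi <= 0 || uptake_cv <= 0 || measurement_cv <= 0)
    stop("spreads must be > 0", call. = FALSE)
  if (label_correlation < 0 || label_correlation > 1)
    stop("label_correlation must be in [0,1]", call. = FALSE)
  structure(as.list(environment()), class = "synthetic_spec")
}

rlnorm_mcv <- function(n, mean, cv) {
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - sdl^2 / 2, sdl)
}

#' Generate a synthetic per-cell translocation-score dataset
#'
#' Two-component joint mixture: non-responders draw both scores from the
#' low (basal) component; responders draw the corresponding factor's score
#' from the high component. Joint responder status is correlated via
#' \code{label_correlation}. Scores are log-normal (they are intensity
#' ratios, strictly positive). Ground-truth labels are returned for
#' recovery tests.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return data.frame with columns \code{cell}, \code{score_nfkb},
#'   \code{score_irf3}, \code{responder} (joint ground truth),
#'   \code{responder_nfkb}, \code{responder_irf3}.
#' @export
gen_translocation_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  frac <- spec$responder_fraction
  joint <- stats::runif(n) < frac
  ## single-factor responders dilute the joint correlation: each non-joint
  ## cell responds with exactly one factor with a probability tuned so the
  ## expected single-responder mass is (1 - correlation) x responder mass
  rn <- joint; ri <- joint
  p_single <- if (frac >= 1) 0 else
    min(1, (1 - spec$label_correlation) * frac / (1 - frac))
  single <- !joint & (stats::runif(n) < p_single)
  if (any(single)) {
    pick <- stats::runif(sum(single)) < 0.5
    rn[single] <- pick
    ri[single] <- !pick
  }
  draw <- function(resp) ifelse(
    resp,
    rlnorm_mcv(n, spec$mean_hi, spec$cv_hi),
    rlnorm_mcv(n, spec$mean_lo, spec$cv_lo))
  data.frame(cell = seq_len(n),
             score_nfkb = draw(rn),
             score_irf3 = draw(ri),
             responder = rn & ri,
             responder_nfkb = rn,
             responder_irf3 = ri)
}

#' Generate replicate delta-CT time profiles from mean mRNA trajectories
#'
#' Converts each mean copy-number profile to the RT-PCR scale via the
#' calibration table (\code{dCT = Q - log2(copies)}) and adds Gaussian
#' replicate noise in CT units. Round-tripping through
#' \code{\link{dct_to_copies}} and averaging replicates recovers the input
#' means up to the log-normal replicate bias.
#'
#' @param profiles data.frame or matrix of mean mRNA copies/cell, one
#'   column per gene, plus a \code{time} column (or separate \code{time}).
#' @param calibration A \code{\link{calibration_table}} covering the genes.
#' @param spec A \code{\link{synthetic_spec}} (uses \code{ct_sd},
#'   \code{n_replicates}, \code{seed}).
#' @param time Optional time vector if \code{profiles} has no time column.
#' @return Long data.frame: \code{gene, time, replicate, dct}.
#' @export
gen_rtpcr_dataset <- function(profiles, calibration, spec, time = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  profiles <- as.data.frame(profiles)
  if (is.null(time)) {
    if (!"time" %in% names(profiles))
      stop("profiles needs a time column (or pass time=)", call. = FALSE)
    time <- profiles$time
    profiles <- profiles[setdiff(names(profiles), "time")]
  }
  if (any(as.matrix(profiles) <= 0))
    stop("mean copies must be > 0 (delta-CT undefined)", call. = FALSE)
  set.seed(spec$seed)
  out <- list()
  for (g in names(profiles)) {
    Q <- get_Q(calibration, g)
    base_dct <- copies_to_dct(Q, profiles[[g]])
    for (r in seq_len(spec$n_replicates)) {
      noise <- if (spec$ct_sd > 0)
        stats::rnorm(length(base_dct), 0, spec$ct_sd) else 0
      out[[length(out) + 1L]] <- data.frame(
        gene = g, time = time, replicate = r, dct = base_dct + noise)
    }
  }
  do.call(rbind, out)
}

#' Generate per-cell fluorescence-like uptake measurements
#'
#' Per-cell poly(I:C) uptake draws with multiplicative log-normal
#' measurement noise on top: the output variance therefore always exceeds
#' the input uptake variance.
#'
#' @param spec A \code{\link{synthetic_spec}} (uses \code{dose},
#'   \code{n_cells}, \code{uptake_cv}, \code{measurement_cv}, \code{seed}).
#' @return data.frame with \code{cell}, \code{uptake} (ground truth) and
#'   \code{fluorescence} (noisy measurement).
#' @export
gen_uptake_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  up <- sample_polyic_uptake(spec$dose, spec$n_cells, cv = spec$uptake_cv,
                             seed = spec$seed)
  set.seed(spec$seed + 1L)
  noise <- rlnorm_mcv(spec$n_cells, 1, spec$measurement_cv)
  data.frame(cell = seq_len(spec$n_cells), uptake = up,
             fluorescence = up * noise)
}
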