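## Read-out layer: nuclear-translocation scoring of per-nucleus intensity
## records, responding/active-cell classification, and profile features.
## The same classifier serves immunostaining-style tables and simulated
## trajectories (via nuclear/total ratios).

#' Nuclear-translocation score of one stained nucleus
#'
#' Quantifies nuclear translocation from summed pixel intensities of a
#' nuclear contour in the primary (quantified) channel and an auxiliary
#' nuclear-staining channel. Three normalisation cases are supported:
#' \describe{
#'   \item{Case 1}{background-corrected nuclear ratio, normalised by the
#'     relative overall image intensity of the two channels (used for
#'     RelA/NF-kB and IRF3): \eqn{(\tilde I^Q_n/\tilde I^Q_*) /
#'     (\tilde I^N_n/\tilde I^N_*)} where \eqn{\tilde I = I - S
#'     \langle p_{bg}\rangle}.}
#'   \item{Case 2}{background-corrected nuclear ratio without overall-image
#'     normalisation (used for p-STAT1, whose cellular abundance changes
#'     during the experiment).}
#'   \item{Case 3}{raw nuclear ratio, no background or image correction
#'     (live-cell time-lapse, where only relative changes matter).}
#' }
#'
#' @param record List or one-row data.frame with fields \code{I_Q_nuc},
#'   \code{I_N_nuc}, \code{S_nuc}, \code{p_bg_Q}, \code{p_bg_N},
#'   \code{I_Q_img}, \code{I_N_img}, \code{S_img} (areas in pixels,
#'   intensities in a.u.; the image-level fields are only needed for Case 1).
#' @param case Normalisation case: 1, 2 or 3.
#' @return Dimensionless score (scalar).
#' @examples
#' r <- list(I_Q_nuc = 100, I_N_nuc = 50, S_nuc = 10, p_bg_Q = 2, p_bg_N = 1,
#'           I_Q_img = 1000, I_N_img = 400, S_img = 100)
#' translocation_score(r, case = 1)  # 0.75
#' translocation_score(r, case = 3)  # 2
#' @export
translocation_score <- function(record, case = 1) {
  r <- as.list(record)
  if (!case %in% 1:3) stop("case must be 1, 2 or 3", call. = FALSE)
  need <- c("I_Q_nuc", "I_N_nuc", "S_nuc")
  if (case == 1) need <- c(need, "p_bg_Q", "p_bg_N", "I_Q_img", "I_N_img",
                           "S_img")
  if (case == 2) need <- c(need, "p_bg_Q", "p_bg_N")
  miss <- setdiff(need, names(r))
  if (length(miss))
    stop("record lacks field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (r$S_nuc <= 0) stop("nuclear contour area must be > 0", call. = FALSE)
  if (r$I_Q_nuc < 0 || r$I_N_nuc < 0)
    stop("raw intensities must be >= 0", call. = FALSE)
  if (case == 3) {
    if (r$I_N_nuc <= 0)
      stop("degenerate record: zero auxiliary nuclear intensity",
           call. = FALSE)
    return(r$I_Q_nuc / r$I_N_nuc)
  }
  qn <- r$I_Q_nuc - r$S_nuc * r$p_bg_Q
  nn <- r$I_N_nuc - r$S_nuc * r$p_bg_N
  if (nn <= 0)
    stop("degenerate record: non-positive background-corrected nuclear ",
         "denominator", call. = FALSE)
  if (case == 2) return(qn / nn)
  if (r$S_img <= 0) stop("image area must be > 0", call. = FALSE)
  qi <- r$I_Q_img - r$S_img * r$p_bg_Q
  ni <- r$I_N_img - r$S_img * r$p_bg_N
  if (qi <= 0 || ni <= 0)
    stop("degenerate record: non-positive background-corrected image ",
         "intensity", call. = FALSE)
  (qn / qi) / (nn / ni)
}

#' Vectorised translocation scores for a quantification table
#'
#' @param records data.frame with the columns of
#'   \code{\link{translocation_score}}; degenerate rows (non-positive
#'   corrected denominators) are flagged and excluded rather than scored.
#' @param case Normalisation case.
#' @return data.frame with columns \code{score} and \code{excluded}.
#' @export
translocation_scores <- function(records, case = 1) {
  n <- nrow(records)
  score <- rep(NA_real_, n); excl <- logical(n)
  for (i in seq_len(n)) {
    s <- tryCatch(translocation_score(records[i, , drop = FALSE], case),
                  error = function(e) NA_real_)
    if (is.na(s)) excl[i] <- TRUE else score[i] <- s
  }
  data.frame(score = score, excluded = excl)
}

#' Responding threshold from non-treated control cells
#'
#' A cell is deemed responding when its nuclear translocation exceeds a
#' threshold derived from the score distribution of non-treated cells: the
#' empirical \code{quantile} (default 0.95) of the control scores.
#'
#' @param control_scores Numeric vector of scores of non-treated cells
#'   (>= 50 recommended; fewer raises a warning).
#' @param quantile Probability in (0,1).
#' @return Scalar threshold.
#' @export
responding_threshold <- function(control_scores, quantile = 0.95) {
  if (length(control_scores) == 0)
    stop("empty control set", call. = FALSE)
  if (quantile <= 0 || quantile >= 1)
    stop("quantile must be in (0,1)", call. = FALSE)
  if (length(control_scores) < 50)
    warning("fewer than 50 control scores; threshold estimate is unstable")
  unname(stats::quantile(control_scores, quantile, type = 7, na.rm = TRUE))
}

#' Classify responding and active cells
#'
#' A cell responds for a factor when its score exceeds that factor's
#' threshold; it is active when it responds with both NF-kB and IRF3
#' translocation. Scores must be aligned by cell id.
#'
#' @param scores data.frame with columns \code{cell}, \code{score_nfkb},
#'   \code{score_irf3} (or two named numeric vectors via \code{score_nfkb}
#'   and \code{score_irf3} arguments).
#' @param thresholds Named list/vector with elements \code{nfkb} and
#'   \code{irf3}.
#' @return List with the per-cell call table (\code{calls}) and the summary
#'   fractions \code{frac_responding_nfkb}, \code{frac_responding_irf3},
#'   \code{frac_active}.
#' @export
classify_active <- function(scores, thresholds) {
  if (!all(c("cell", "score_nfkb", "score_irf3") %in% names(scores)))
    stop("scores needs columns cell, score_nfkb, score_irf3", call. = FALSE)
  if (anyDuplicated(scores$cell))
    stop("duplicated cell ids", call. = FALSE)
  th <- as.list(thresholds)
  if (is.null(th$nfkb) || is.null(th$irf3))
    stop("thresholds needs elements nfkb and irf3", call. = FALSE)
  resp_n <- scores$score_nfkb > th$nfkb
  resp_i <- scores$score_irf3 > th$irf3
  calls <- data.frame(cell = scores$cell,
                      score_nfkb = scores$score_nfkb,
                      score_irf3 = scores$score_irf3,
                      responding_nfkb = resp_n,
                      responding_irf3 = resp_i,
                      active = resp_n & resp_i)
  list(calls = calls,
       frac_responding_nfkb = mean(resp_n),
       frac_responding_irf3 = mean(resp_i),
       frac_active = mean(resp_n & resp_i))
}

#' Nuclear-translocation proxy scores from simulated trajectories
#'
#' Maps a cell's state to the immunostaining score convention: the nuclear
#' count of a factor divided by its total cell count (NF-kB: free nuclear
#' plus nuclear complex over the conserved total; IRF3: nuclear
#' phospho-IRF3 over total IRF3). One classifier thus serves experimental
#' tables and simulations.
#'
#' @param counts State matrix or vector with the model's species columns.
#' @param factor \code{"nfkb"} or \code{"irf3"}.
#' @param params Parameter vector (for the conserved totals).
#' @return Numeric score(s) in [0, 1].
#' @export
simulated_translocation <- function(counts, factor = c("nfkb", "irf3"),
                                    params = default_params()) {
  factor <- match.arg(factor)
  if (is.null(dim(counts))) counts <- t(as.matrix(counts))
  if (factor == "nfkb")
    (counts[, "NFkBn"] + counts[, "NIn"]) / params[["nfkb_total"]]
  else
    counts[, "IRF3pn"] / params[["irf3_total"]]
}

#' Population mean profile of a species over an ensemble
#' @param ensemble An \code{\link{run_ensemble}} result.
#' @param species Species name.
#' @return Numeric vector on \code{ensemble$time} (arithmetic mean over
#'   member cells).
#' @export
mean_trajectory <- function(ensemble, species) {
  if (!species %in% dimnames(ensemble$counts)[[2]])
    stop("unknown species: ", species, call. = FALSE)
  rowMeans(ensemble$counts[, species, , drop = FALSE], dims = 2)[, 1]
}

#' Peak and termination features of a response profile
#'
#' \code{peak_time} is the first argmax of the profile. \code{termination
#' time} is the first time after the peak at which the profile falls to or
#' below \code{baseline + f * (peak - baseline)}, with the baseline taken as
#' the profile's initial value.
#'
#' @param profile Numeric vector on a uniform grid.
#' @param time Time grid (s), same length.
#' @param frac Fraction-of-peak defining termination (default 0.2).
#' @return List with \code{peak_time}, \code{peak_value},
#'   \code{termination_time} (NA while the profile has not yet terminated).
#'   A flat profile (zero range) has no defined peak and raises an error.
#' @export
profile_features <- function(profile, time, frac = 0.2) {
  if (length(profile) != length(time))
    stop("profile and time lengths differ", call. = FALSE)
  if (diff(range(profile)) == 0)
    stop("flat profile: peak undefined", call. = FALSE)
  ipk <- which.max(profile)  # earliest index on ties
  baseline <- profile[1]
  thr <- baseline + frac * (profile[ipk] - baseline)
  after <- which(seq_along(profile) > ipk & profile <= thr)
  list(peak_time = time[ipk], peak_value = profile[ipk],
       termination_time = if (length(after)) time[after[1]] else NA_real_)
}

#' Pearson correlation between two per-cell score vectors
#' @param x,y Paired numeric vectors (>= 3 points).
#' @return Sample Pearson correlation coefficient.
#' @export
pair_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need >= 3 paired points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(x, y)
}
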