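## Digital-PCR calibration: conversion between relative RT-PCR delta-CT
## values (normalised against GAPDH) and absolute mRNA copies per cell.
##
## For gene i with paired dPCR/RT-PCR measurements the normalisation
## coefficient is Q_i = < log2(mRNA)_i + dCT >, so that
## log2(mRNA) = Q_i - dCT; higher expression means lower dCT.

#' Normalisation coefficient from paired dPCR/RT-PCR measurements
#'
#' @param copies Absolute mRNA copies/cell from dPCR, one per lysate (> 0).
#' @param dct Paired RT-PCR delta-CT values (target CT minus GAPDH CT).
#' @return Q (log2 units): the mean of \code{log2(copies) + dct} over pairs.
#'   Fewer than 3 pairs raises a warning (the convention is n >= 3).
#' @examples
#' compute_Q(1, 12)          # 12
#' compute_Q(c(4, 16), c(10, 8))  # 12
#' @export
compute_Q <- function(copies, dct) {
  if (length(copies) != length(dct))
    stop("copies and dct must be paired", call. = FALSE)
  if (length(copies) < 1) stop("need at least one pair", call. = FALSE)
  if (any(!is.finite(copies)) || any(!is.finite(dct)))
    stop("non-finite measurement", call. = FALSE)
  if (any(copies <= 0))
    stop("mRNA copies must be > 0", call. = FALSE)
  if (length(copies) < 3)
    warning("fewer than 3 dPCR/RT-PCR pairs")
  mean(log2(copies) + dct)
}

#' Convert delta-CT to absolute copies per cell (and back)
#'
#' \code{dct_to_copies} applies \code{copies = 2^(Q - dCT)};
#' \code{copies_to_dct} is its exact inverse \code{dCT = Q - log2(copies)}
#' (used to convert simulated mRNA means onto the RT-PCR scale).
#'
#' @param Q Normalisation coefficient (log2 units).
#' @param dct Delta-CT value(s).
#' @param copies mRNA copies/cell (> 0 for the reverse direction).
#' @return Copies/cell, or delta-CT, respectively.
#' @examples
#' dct_to_copies(20, 10)   # 1024
#' copies_to_dct(20, 1024) # 10
#' @export
dct_to_copies <- function(Q, dct) {
  if (any(!is.finite(Q)) || any(!is.finite(dct)))
    stop("non-finite input", call. = FALSE)
  2^(Q - dct)
}

#' @rdname dct_to_copies
#' @export
copies_to_dct <- function(Q, copies) {
  if (any(!is.finite(Q)) || any(!is.finite(copies)))
    stop("non-finite input", call. = FALSE)
  if (any(copies <= 0)) stop("copies must be > 0", call. = FALSE)
  Q - log2(copies)
}

#' Build a calibration table from a paired-measurement data.frame
#'
#' @param pairs data.frame with columns \code{gene}, \code{lysate},
#'   \code{copies}, \code{dct}: one dPCR value paired with one RT-PCR
#'   delta-CT per lysate.
#' @param all_genes Optional character vector of genes the table should
#'   cover; genes without dPCR data receive the fallback Q equal to the mean
#'   of the available per-gene Q values.
#' @return Object of class \code{"calibration_table"}: data.frame with
#'   columns \code{gene}, \code{Q}, \code{n_pairs}, \code{fallback}.
#' @export
calibration_table <- function(pairs, all_genes = NULL) {
  need <- c("gene", "copies", "dct")
  if (!all(need %in% names(pairs)))
    stop("pairs needs columns gene, copies, dct", call. = FALSE)
  genes <- unique(pairs$gene)
  tab <- do.call(rbind, lapply(genes, function(g) {
    sel <- pairs$gene == g
    data.frame(gene = g,
               Q = suppressWarnings(compute_Q(pairs$copies[sel],
                                              pairs$dct[sel])),
               n_pairs = sum(sel), fallback = FALSE)
  }))
  if (!is.null(all_genes)) {
    rest <- setdiff(all_genes, genes)
    if (length(rest) > 0) {
      qbar <- mean(tab$Q)
      tab <- rbind(tab, data.frame(gene = rest, Q = qbar, n_pairs = 0L,
                                   fallback = TRUE))
    }
  }
  structure(tab, class = c("calibration_table", "data.frame"))
}

#' Look up a gene's Q in a calibration table
#' @param table A \code{\link{calibration_table}}.
#' @param gene Gene name.
#' @return Scalar Q.
#' @export
get_Q <- function(table, gene) {
  i <- match(gene, table$gene)
  if (is.na(i)) stop("gene not in calibration table: ", gene, call. = FALSE)
  table$Q[i]
}

#' Read/write calibration measurement tables as CSV
#' @param path CSV file with columns \code{gene, lysate, copies, dct}.
#' @return data.frame of pairs.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "lysate", "copies", "dct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("calibration CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}
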