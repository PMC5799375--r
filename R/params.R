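#' Default model parameterization
#'
#' Returns the canonical rate-constant set of the innate-immune network model.
#' All first-order constants are in 1/s, bimolecular constants in
#' 1/(molecule*s), transcription/translation rates in molecules/s per active
#' template. Copy-number scale follows the mammalian-cell convention: abundant
#' signalling proteins (NF-kB, IKK, IkBa, STATs) at 1e4--1e5 molecules/cell,
#' low-expressed interferon-stimulated genes at 1--10 mRNA/cell. The telegraph
#' (two-state) gene constants are chosen so that the basal stationary mRNA
#' means are 10 copies/cell for Ddx58 and Eif2ak2 and 1 copy/cell for Oas1a
#' and Ifnb1, and the NF-kB module constants so that the mean-field nuclear
#' NF-kB response to LPS peaks near 40 min and terminates near 1.5 h.
#'
#' Each value carries a provenance tag (attribute \code{provenance}), one of
#' \code{"spec_default"} or \code{"user"} once modified via
#' \code{\link{set_params}}.
#'
#' @return Named numeric vector of rate constants with a \code{provenance}
#'   attribute (character vector of the same length).
#' @seealso \code{\link{build_network}}, \code{\link{set_params}}
#' @export
default_params <- function() {
  p <- c(
    ## --- input signals -----------------------------------------------------
    d_lps         = 6e-4,   # LPS signal decay (receptor adaptation)
    k_ikk_lps     = 1.5e-7,   # IKK activation per LPS signal unit
    k_pic_entry   = 3e-4,   # poly(I:C) bolus -> cytoplasm (first order, ~4 h to complete)
    d_pic         = 1.2e-4,   # cytoplasmic poly(I:C) degradation
    ## --- RIG-I sensing -----------------------------------------------------
    k_rigi_act    = 8e-9,   # RIG-I activation per cytoplasmic poly(I:C) molecule
    d_rigia       = 3e-4,   # active RIG-I relaxation
    d_rigi        = 2e-5,   # RIG-I protein turnover (both forms)
    ktl_rigi      = 2e-4,   # RIG-I translation per Ddx58 mRNA
    k_ikk_rigi    = 7e-6,   # IKK activation per active RIG-I
    k_tbk_rigi    = 5e-6,   # TBK1 activation per active RIG-I
    ## --- kinases -----------------------------------------------------------
    k_ikk_i       = 1e-3,   # spontaneous IKK inactivation
    k_a20_ikk     = 3e-7,   # A20-catalysed IKK inactivation
    k_ikk_r       = 5e-4,   # inactive -> neutral IKK recycling
    d_tbk         = 8e-4,   # spontaneous TBK1 dephosphorylation
    k_a20_tbk     = 3e-7,   # A20-catalysed TBK1 inactivation
    ## --- NF-kB / IkBa core -------------------------------------------------
    ktl_ikba      = 1.2,    # IkBa translation per mRNA (PKR-inhibited)
    d_ikba_f      = 1.2e-3, # free IkBa degradation (cytoplasmic and nuclear)
    k_ikk_deg_f   = 2e-8,   # IKK-driven degradation of free IkBa
    k_ikk_deg_c   = 2e-8,   # IKK-driven degradation of complexed IkBa
    d_ikba_c      = 2e-5,   # constitutive turnover of complexed IkBa
    k_nfkb_in     = 5e-3,   # free NF-kB nuclear import
    k_nfkb_ikba   = 1e-5,   # NF-kB:IkBa association (cytoplasm and nucleus)
    k_ni_export   = 1e-2,   # nuclear complex export
    k_ikba_in     = 1e-3,   # free IkBa nuclear import
    k_ikba_out    = 1e-4,   # free IkBa nuclear export
    ktl_a20       = 0.5,    # A20 translation per mRNA (PKR-inhibited)
    d_a20         = 1e-4,   # A20 protein turnover
    ## --- IRF3 --------------------------------------------------------------
    k_irf3_phos   = 5e-7,   # IRF3 phosphorylation per active TBK1
    k_irf3_dephos = 1e-3,   # cytoplasmic p-IRF3 dephosphorylation
    k_irf3_in     = 5e-3,   # p-IRF3 nuclear import
    k_irf3n_off   = 8e-4,   # nuclear p-IRF3 dephosphorylation + export
    ## --- IFN-beta / IFNAR --------------------------------------------------
    ktl_ifnb      = 1e-2,   # IFN-beta translation per mRNA
    k_sec         = 1e-3,   # IFN-beta secretion
    d_ifnb_c      = 1e-4,   # intracellular IFN-beta decay
    d_ifnb_e      = 2e-4,   # extracellular IFN-beta decay
    k_ifnar_bind  = 1e-7,   # IFN-beta/IFNAR binding (ligand consumed)
    d_ifnara      = 2e-3,   # active receptor recycling (ligand degraded)
    k_socs_inh    = 3e-6,   # SOCS1 inhibition of active IFNAR
    d_ifnari      = 1e-4,   # inhibited receptor recovery
    ## --- JAK/STAT ----------------------------------------------------------
    k_stat_phos   = 8e-7,   # STAT1/2 phosphorylation per active IFNAR
    k_stat_dephos = 1e-3,   # p-STAT dephosphorylation
    k_dimer       = 1.5e-7, # p-STAT1:p-STAT2 dimerisation
    d_statd       = 3e-4,   # dimer dissociation (to unphosphorylated STATs)
    ktl_stat1     = 4e-3,   # STAT1 translation per mRNA
    ktl_stat2     = 4e-3,
    d_stat        = 4e-6,   # slow STAT protein turnover (~24 h half-life)
    ktl_socs1     = 1e-2,   # SOCS1 translation per mRNA
    d_socs1       = 2e-4,   # SOCS1 protein turnover
    ## --- PKR / OAS1A -------------------------------------------------------
    ktl_pkr       = 2e-4,   # PKR translation per Eif2ak2 mRNA
    d_pkr         = 2e-5,   # PKR protein turnover (both forms)
    k_pkr_act     = 3e-8,   # PKR activation per cytoplasmic poly(I:C) molecule
    d_pkra        = 1e-4,   # active PKR relaxation
    alpha_pkr     = 1.2e-2,   # translation inhibition: factor 1/(1 + alpha*PKRa)
    ktl_oas       = 2e-4,   # OAS1A translation per Oas1a mRNA
    d_oas         = 2e-5,   # OAS1A protein turnover (both forms)
    k_oas_act     = 3e-8,   # OAS1A activation per cytoplasmic poly(I:C) molecule
    d_oasa        = 1e-4,   # active OAS1A relaxation
    k_oas_deg     = 1e-4,   # OAS1A-enhanced degradation of Nfkbia/Tnfaip3 mRNA
    ## --- conserved totals --------------------------------------------------
    nfkb_total    = 1e5,
    ikk_total     = 1e5,
    tbk_total     = 1e4,
    irf3_total    = 1e4,
    ifnar_total   = 2e3,
    ## --- gene loci: telegraph switching + transcription --------------------
    ## NF-kB-responsive immediate-early inhibitors
    kon_nfkbia  = 2e-4, koff_nfkbia  = 2e-3, ktx_nfkbia  = 1.6e-2, gm_nfkbia  = 8e-4,
    kact_nfkbia = 2e-7,
    kon_tnfaip3 = 2e-5, koff_tnfaip3 = 2e-3, ktx_tnfaip3 = 1.6e-2, gm_tnfaip3 = 8e-4,
    kact_tnfaip3 = 2e-7,
    ## Ifnb1: AND gate (nuclear NF-kB x nuclear p-IRF3)
    kon_ifnb1 = 5e-6, koff_ifnb1 = 5e-3, ktx_ifnb1 = 2.5e-1, gm_ifnb1 = 5e-4,
    kact_ifnb1 = 1e-10,
    ## STAT-responsive interferon-stimulated genes
    kon_stat1   = 1e-5, koff_stat1   = 1e-4, ktx_stat1   = 5.5e-3, gm_stat1   = 1e-4,
    kact_stat1  = 1e-5,
    kon_stat2   = 1e-5, koff_stat2   = 1e-4, ktx_stat2   = 5.5e-3, gm_stat2   = 1e-4,
    kact_stat2  = 1e-5,
    kon_ddx58   = 1e-5, koff_ddx58   = 1e-4, ktx_ddx58   = 5.5e-3, gm_ddx58   = 1e-4,
    kact_ddx58  = 1e-5,
    kon_eif2ak2 = 1e-5, koff_eif2ak2 = 1e-4, ktx_eif2ak2 = 5.5e-3, gm_eif2ak2 = 1e-4,
    kact_eif2ak2 = 1e-5,
    kon_oas1a   = 1e-5, koff_oas1a   = 1e-4, ktx_oas1a   = 5.5e-4, gm_oas1a   = 1e-4,
    kact_oas1a  = 1e-5,
    kon_socs1   = 1e-5, koff_socs1   = 1e-4, ktx_socs1   = 5.5e-3, gm_socs1   = 3e-4,
    kact_socs1  = 1e-5,
    ## --- dose/unit conversions ---------------------------------------------
    lps_units_per_ugml      = 1e4,  # LPS signal units added per ug/ml
    pic_molecules_per_ugml  = 2e4,  # mean poly(I:C) bolus per ug/ml (per cell)
    ifnb_molecules_per_unit = 1e3,  # extracellular IFN-beta molecules per U/ml
                                    # (in the cell's 8 nl medium aliquot)
    uptake_cv               = 0.8,  # lognormal CV of per-cell poly(I:C) uptake
    c16_factor              = 0.2   # residual PKR activation under C16
  )
  attr(p, "provenance") <- rep("spec_default", length(p))
  names(attr(p, "provenance")) <- names(p)
  p
}

#' Override model parameters
#'
#' @param params Parameter vector from \code{\link{default_params}}.
#' @param ... Named scalar overrides, e.g. \code{set_params(p, d_a20 = 2e-4)}.
#' @return Updated parameter vector; overridden entries are tagged with
#'   provenance \code{"user"}.
#' @export
set_params <- function(params, ...) {
  upd <- c(...)
  if (length(upd) == 0L) return(params)
  bad <- setdiff(names(upd), names(params))
  if (length(bad) > 0L)
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(upd)) || any(upd < 0))
    stop("parameter values must be finite and >= 0", call. = FALSE)
  prov <- attr(params, "provenance")
  params[names(upd)] <- upd
  prov[names(upd)] <- "user"
  attr(params, "provenance") <- prov
  params
}

#' Validate a parameter vector against the canonical set
#' @param params Named numeric vector.
#' @return Invisibly \code{TRUE}; otherwise a configuration error naming the
#'   first missing or invalid constant.
#' @export
validate_params <- function(params) {
  ref <- names(default_params())
  missing <- setdiff(ref, names(params))
  if (length(missing) > 0L)
    stop("missing rate constant(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(params)))
    stop("non-finite rate constant: ",
         names(params)[which(!is.finite(params))[1L]], call. = FALSE)
  if (any(params < 0))
    stop("negative rate constant: ",
         names(params)[which(params < 0)[1L]], call. = FALSE)
  invisible(TRUE)
}

#' Gene locus table
#'
#' Assembles the two-state (telegraph) locus definitions from a parameter
#' vector: per-allele switch-on/off rates, transcription rate when ON, mRNA
#' degradation rate, activating transcription factor, and diploid copy number.
#' The \code{Ifnb1} locus is AND-gated: its activated switch-on propensity is
#' proportional to the product of nuclear NF-kB and nuclear p-IRF3 counts.
#'
#' @param params Parameter vector (default \code{\link{default_params}}).
#' @return data.frame with one row per locus.
#' @export
gene_table <- function(params = default_params()) {
  loci <- c("nfkbia", "tnfaip3", "ifnb1", "stat1", "stat2",
            "ddx58", "eif2ak2", "oas1a", "socs1")
  activator <- c(nfkbia = "NFkBn", tnfaip3 = "NFkBn", ifnb1 = "NFkBn*IRF3pn",
                 stat1 = "STATd", stat2 = "STATd", ddx58 = "STATd",
                 eif2ak2 = "STATd", oas1a = "STATd", socs1 = "STATd")
  mrna <- c(nfkbia = "IkBa_mRNA", tnfaip3 = "A20_mRNA", ifnb1 = "IFNb_mRNA",
            stat1 = "STAT1_mRNA", stat2 = "STAT2_mRNA", ddx58 = "RIGI_mRNA",
            eif2ak2 = "PKR_mRNA", oas1a = "OAS_mRNA", socs1 = "SOCS1_mRNA")
  data.frame(
    gene        = loci,
    copy_number = 2L,
    k_on        = unname(params[paste0("kon_", loci)]),
    k_off       = unname(params[paste0("koff_", loci)]),
    k_tx        = unname(params[paste0("ktx_", loci)]),
    k_act       = unname(params[paste0("kact_", loci)]),
    gamma_m     = unname(params[paste0("gm_", loci)]),
    activator   = unname(activator[loci]),
    mrna        = unname(mrna[loci]),
    stringsAsFactors = FALSE
  )
}

#' Stationary mean and variance of a telegraph-model locus
#'
#' Closed-form stationary moments of the mRNA count for a two-state gene
#' switching ON/OFF at basal rates, transcribing only when ON. Alleles switch
#' independently, so means and variances are additive over the copy number.
#' The per-allele Fano factor is
#' \code{1 + k_tx*k_off / ((k_on+k_off)*(k_on+k_off+gamma))}, i.e. the
#' distribution is super-Poissonian (bursty) whenever \code{k_off > 0}.
#'
#' @param k_on,k_off Per-allele switch rates (1/s), both > 0.
#' @param k_tx Transcription rate when ON (mRNA/s).
#' @param gamma_m mRNA degradation rate (1/s), > 0.
#' @param copy_number Number of independently switching alleles (default 2).
#' @return List with \code{mean}, \code{variance}, \code{p_on} and
#'   \code{fano}.
#' @examples
#' # symmetric switch, one allele: ON half the time
#' stationary_gene_stats(1e-4, 1e-4, 1e-2, 1e-3, copy_number = 1)$mean
#' @export
stationary_gene_stats <- function(k_on, k_off, k_tx, gamma_m, copy_number = 2L) {
  if (gamma_m <= 0)
    stop("mRNA degradation rate must be > 0 (stationary moments diverge)",
         call. = FALSE)
  if (any(c(k_on, k_off, k_tx) < 0) || k_on <= 0 || k_off < 0)
    stop("rates must be positive", call. = FALSE)
  p_on <- k_on / (k_on + k_off)
  m1 <- p_on * k_tx / gamma_m                 # per-allele mean
  fano <- 1 + k_tx * k_off /
    ((k_on + k_off) * (k_on + k_off + gamma_m))
  list(mean = copy_number * m1,
       variance = copy_number * m1 * fano,
       p_on = p_on,
       fano = fano)
}
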