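## Canonical reaction network of the coupled IRF3 / NF-kB / JAK-STAT model.
##
## The network is held as a flat reaction table (rate constant, up to three
## multiplicative species factors, optional 1/(1+alpha*X) translation-
## inhibition factor, sparse stoichiometry, scaling group) that both the
## stochastic (SSA/tau-leap) and the mean-field (ODE) engines consume
## unchanged. Gene loci appear as pairs of species (alleles OFF / alleles ON)
## whose switching, like everything else, is an ordinary reaction.

species_names <- function() {
  loci <- gene_table()$gene
  c("LPS", "pIC_ext", "pIC_cyt",
    "RIGI_mRNA", "RIGI", "RIGIa",
    "IKKn", "IKKa", "IKKi",
    "TBK0", "TBK1a",
    "IkBa_mRNA", "IkBa", "IkBan", "NIc", "NIn", "NFkB", "NFkBn",
    "A20_mRNA", "A20",
    "IRF3", "IRF3p", "IRF3pn",
    "IFNb_mRNA", "IFNb_c", "IFNb_e",
    "IFNAR", "IFNARa", "IFNARi",
    "STAT1_mRNA", "STAT1", "STAT1p",
    "STAT2_mRNA", "STAT2", "STAT2p",
    "STATd",
    "SOCS1_mRNA", "SOCS1",
    "PKR_mRNA", "PKR", "PKRa",
    "OAS_mRNA", "OAS", "OASa",
    paste0("G_", rep(loci, each = 2), c("_off", "_on")))
}

#' Construct a genotype descriptor
#'
#' @param flag One of \code{"wild_type"}, \code{"RelA_knockout"},
#'   \code{"Stat1_knockout"}.
#' @return Object of class \code{"genotype"}.
#' @export
genotype <- function(flag = c("wild_type", "RelA_knockout", "Stat1_knockout")) {
  flag <- match.arg(flag)
  structure(list(flag = flag), class = "genotype")
}

#' Build the canonical reaction network
#'
#' Expands the model's reaction rules into a flat reaction list: LPS-driven
#' transient IKK activation with adaptation; poly(I:C) entry and degradation;
#' RIG-I sensing activating IKK and TBK1; A20-catalysed inactivation of both
#' kinases; IKK-driven IkBa degradation releasing NF-kB; NF-kB-gated switching
#' of the Nfkbia/Tnfaip3 loci; IkBa resynthesis, nuclear entry, NF-kB binding
#' and re-export; TBK1-driven IRF3 phosphorylation and nuclear shuttling; the
#' AND-gated Ifnb1 locus (switch-on propensity proportional to nuclear NF-kB
#' times nuclear p-IRF3); IFN-beta translation, secretion, IFNAR binding and
#' SOCS1 receptor inhibition; STAT1/2 phosphorylation, heterodimerisation and
#' activation of the STAT-responsive loci (Stat1, Stat2, Ddx58, Eif2ak2,
#' Oas1a, Socs1); poly(I:C)-driven PKR/OAS1A activation, with active PKR
#' scaling down IkBa/A20 translation and active OAS1A adding to Nfkbia/Tnfaip3
#' mRNA degradation; and constitutive mRNA/protein turnover.
#'
#' Knockout genotypes zero the corresponding protein's synthesis and remove it
#' from the initial state: \code{RelA_knockout} removes all NF-kB (free,
#' nuclear and complexed), so NF-kB-gated loci can only switch on at their
#' basal rate; \code{Stat1_knockout} removes STAT1 protein and sets its
#' translation to zero, so no STAT1/2 heterodimer ever forms.
#'
#' Construction is deterministic: identical inputs give identical reaction
#' lists.
#'
#' @param genotype A \code{\link{genotype}} object (or flag string).
#' @param params Parameter vector; validated against the canonical constant
#'   set (a missing constant raises a configuration error naming it).
#' @param pkr_all_mrna If \code{TRUE}, active PKR inhibits translation of all
#'   mRNAs and active OAS1A degrades all mRNAs (global translational
#'   shutdown); default restricts both to the NF-kB-inducible inhibitors
#'   IkBa and A20.
#' @return Object of class \code{"reaction_network"}: species names, default
#'   initial state, reaction table, and engine-ready flat arrays.
#' @export
build_network <- function(genotype = "wild_type",
                          params = default_params(),
                          pkr_all_mrna = FALSE) {
  if (is.character(genotype)) genotype <- innatesim::genotype(genotype)
  if (!inherits(genotype, "genotype"))
    stop("genotype must be a genotype object or flag string", call. = FALSE)
  validate_params(params)
  p <- as.list(params)

  sp <- species_names()
  ix <- seq_along(sp); names(ix) <- sp
  reactions <- vector("list", 256L); nr <- 0L

  add <- function(name, rate, reactants = character(), stoich, group = "",
                  inhibitor = "", alpha = 0) {
    nr <<- nr + 1L
    reactions[[nr]] <<- list(name = name, rate = rate,
                             reactants = reactants, stoich = stoich,
                             group = group, inhibitor = inhibitor,
                             alpha = alpha)
  }

  ## -- gene loci: switching and transcription ------------------------------
  gt <- gene_table(params)
  for (i in seq_len(nrow(gt))) {
    g <- gt$gene[i]
    off <- paste0("G_", g, "_off"); on <- paste0("G_", g, "_on")
    m <- gt$mrna[i]
    add(paste0(g, "_on_basal"), gt$k_on[i], off,
        stats::setNames(c(-1, 1), c(off, on)))
    if (gt$k_act[i] > 0) {
      tf <- if (gt$activator[i] == "NFkBn*IRF3pn") c("NFkBn", "IRF3pn")
            else gt$activator[i]
      add(paste0(g, "_on_act"), gt$k_act[i], c(off, tf),
          stats::setNames(c(-1, 1), c(off, on)))
    }
    add(paste0(g, "_off"), gt$k_off[i], on,
        stats::setNames(c(-1, 1), c(on, off)))
    add(paste0(g, "_tx"), gt$k_tx[i], on, stats::setNames(1, m))
    add(paste0(m, "_deg"), gt$gamma_m[i], m, stats::setNames(-1, m))
    if (pkr_all_mrna || g %in% c("nfkbia", "tnfaip3"))
      add(paste0(m, "_deg_oas"), p$k_oas_deg, c(m, "OASa"),
          stats::setNames(-1, m))
  }

  ## -- input signals -------------------------------------------------------
  add("lps_decay", p$d_lps, "LPS", c(LPS = -1))
  add("ikk_act_lps", p$k_ikk_lps, c("IKKn", "LPS"), c(IKKn = -1, IKKa = 1))
  add("pic_entry", p$k_pic_entry, "pIC_ext", c(pIC_ext = -1, pIC_cyt = 1))
  add("pic_deg", p$d_pic, "pIC_cyt", c(pIC_cyt = -1))

  ## -- RIG-I ---------------------------------------------------------------
  add("rigi_act", p$k_rigi_act, c("RIGI", "pIC_cyt"), c(RIGI = -1, RIGIa = 1))
  add("rigia_relax", p$d_rigia, "RIGIa", c(RIGIa = -1, RIGI = 1))
  add("rigi_deg", p$d_rigi, "RIGI", c(RIGI = -1))
  add("rigia_deg", p$d_rigi, "RIGIa", c(RIGIa = -1))
  add("rigi_tl", p$ktl_rigi, "RIGI_mRNA", c(RIGI = 1), group = "translation")
  add("ikk_act_rigi", p$k_ikk_rigi, c("IKKn", "RIGIa"), c(IKKn = -1, IKKa = 1))
  add("tbk_act_rigi", p$k_tbk_rigi, c("TBK0", "RIGIa"), c(TBK0 = -1, TBK1a = 1))

  ## -- kinase inactivation / recycling -------------------------------------
  add("ikk_inact", p$k_ikk_i, "IKKa", c(IKKa = -1, IKKi = 1))
  add("ikk_inact_a20", p$k_a20_ikk, c("IKKa", "A20"), c(IKKa = -1, IKKi = 1))
  add("ikk_recycle", p$k_ikk_r, "IKKi", c(IKKi = -1, IKKn = 1))
  add("tbk_inact", p$d_tbk, "TBK1a", c(TBK1a = -1, TBK0 = 1))
  add("tbk_inact_a20", p$k_a20_tbk, c("TBK1a", "A20"), c(TBK1a = -1, TBK0 = 1))

  ## -- NF-kB / IkBa core ---------------------------------------------------
  add("ikba_tl", p$ktl_ikba, "IkBa_mRNA", c(IkBa = 1),
      group = "translation", inhibitor = "PKRa", alpha = p$alpha_pkr)
  add("ikba_deg_f", p$d_ikba_f, "IkBa", c(IkBa = -1))
  add("ikban_deg_f", p$d_ikba_f, "IkBan", c(IkBan = -1))
  add("ikba_deg_ikk", p$k_ikk_deg_f, c("IkBa", "IKKa"), c(IkBa = -1))
  add("nic_deg_ikk", p$k_ikk_deg_c, c("NIc", "IKKa"), c(NIc = -1, NFkB = 1))
  add("nic_turnover", p$d_ikba_c, "NIc", c(NIc = -1, NFkB = 1))
  add("nin_turnover", p$d_ikba_c, "NIn", c(NIn = -1, NFkBn = 1))
  add("nfkb_import", p$k_nfkb_in, "NFkB", c(NFkB = -1, NFkBn = 1))
  add("nfkb_bind", p$k_nfkb_ikba, c("NFkB", "IkBa"),
      c(NFkB = -1, IkBa = -1, NIc = 1))
  add("nfkbn_bind", p$k_nfkb_ikba, c("NFkBn", "IkBan"),
      c(NFkBn = -1, IkBan = -1, NIn = 1))
  add("nin_export", p$k_ni_export, "NIn", c(NIn = -1, NIc = 1))
  add("ikba_import", p$k_ikba_in, "IkBa", c(IkBa = -1, IkBan = 1))
  add("ikba_export", p$k_ikba_out, "IkBan", c(IkBan = -1, IkBa = 1))
  add("a20_tl", p$ktl_a20, "A20_mRNA", c(A20 = 1),
      group = "translation", inhibitor = "PKRa", alpha = p$alpha_pkr)
  add("a20_deg", p$d_a20, "A20", c(A20 = -1))

  ## -- IRF3 ----------------------------------------------------------------
  add("irf3_phos", p$k_irf3_phos, c("IRF3", "TBK1a"), c(IRF3 = -1, IRF3p = 1))
  add("irf3_dephos", p$k_irf3_dephos, "IRF3p", c(IRF3p = -1, IRF3 = 1))
  add("irf3_import", p$k_irf3_in, "IRF3p", c(IRF3p = -1, IRF3pn = 1))
  add("irf3n_off", p$k_irf3n_off, "IRF3pn", c(IRF3pn = -1, IRF3 = 1))

  ## -- IFN-beta / IFNAR ----------------------------------------------------
  add("ifnb_tl", p$ktl_ifnb, "IFNb_mRNA", c(IFNb_c = 1), group = "translation")
  add("ifnb_sec", p$k_sec, "IFNb_c", c(IFNb_c = -1, IFNb_e = 1))
  add("ifnbc_deg", p$d_ifnb_c, "IFNb_c", c(IFNb_c = -1))
  add("ifnbe_deg", p$d_ifnb_e, "IFNb_e", c(IFNb_e = -1))
  add("ifnar_bind", p$k_ifnar_bind, c("IFNb_e", "IFNAR"),
      c(IFNb_e = -1, IFNAR = -1, IFNARa = 1), group = "ifnar_bind")
  add("ifnar_recycle", p$d_ifnara, "IFNARa", c(IFNARa = -1, IFNAR = 1))
  add("ifnar_inhib", p$k_socs_inh, c("IFNARa", "SOCS1"),
      c(IFNARa = -1, IFNARi = 1))
  add("ifnar_recover", p$d_ifnari, "IFNARi", c(IFNARi = -1, IFNAR = 1))

  ## -- JAK/STAT ------------------------------------------------------------
  ktl1 <- if (genotype$flag == "Stat1_knockout") 0 else p$ktl_stat1
  add("stat1_phos", p$k_stat_phos, c("STAT1", "IFNARa"),
      c(STAT1 = -1, STAT1p = 1))
  add("stat2_phos", p$k_stat_phos, c("STAT2", "IFNARa"),
      c(STAT2 = -1, STAT2p = 1))
  add("stat1_dephos", p$k_stat_dephos, "STAT1p", c(STAT1p = -1, STAT1 = 1))
  add("stat2_dephos", p$k_stat_dephos, "STAT2p", c(STAT2p = -1, STAT2 = 1))
  add("stat_dimer", p$k_dimer, c("STAT1p", "STAT2p"),
      c(STAT1p = -1, STAT2p = -1, STATd = 1))
  add("statd_dissoc", p$d_statd, "STATd",
      c(STATd = -1, STAT1 = 1, STAT2 = 1))
  add("stat1_tl", ktl1, "STAT1_mRNA", c(STAT1 = 1), group = "translation")
  add("stat2_tl", p$ktl_stat2, "STAT2_mRNA", c(STAT2 = 1),
      group = "translation")
  add("stat1_deg", p$d_stat, "STAT1", c(STAT1 = -1))
  add("stat1p_deg", p$d_stat, "STAT1p", c(STAT1p = -1))
  add("stat2_deg", p$d_stat, "STAT2", c(STAT2 = -1))
  add("stat2p_deg", p$d_stat, "STAT2p", c(STAT2p = -1))
  add("statd_deg", p$d_stat, "STATd", c(STATd = -1))
  add("socs1_tl", p$ktl_socs1, "SOCS1_mRNA", c(SOCS1 = 1),
      group = "translation")
  add("socs1_deg", p$d_socs1, "SOCS1", c(SOCS1 = -1))

  ## -- PKR / OAS1A ---------------------------------------------------------
  add("pkr_tl", p$ktl_pkr, "PKR_mRNA", c(PKR = 1), group = "translation")
  add("pkr_deg", p$d_pkr, "PKR", c(PKR = -1))
  add("pkra_deg", p$d_pkr, "PKRa", c(PKRa = -1))
  add("pkr_act", p$k_pkr_act, c("PKR", "pIC_cyt"), c(PKR = -1, PKRa = 1),
      group = "pkr_activation")
  add("pkra_relax", p$d_pkra, "PKRa", c(PKRa = -1, PKR = 1))
  add("oas_tl", p$ktl_oas, "OAS_mRNA", c(OAS = 1), group = "translation")
  add("oas_deg", p$d_oas, "OAS", c(OAS = -1))
  add("oasa_deg", p$d_oas, "OASa", c(OASa = -1))
  add("oas_act", p$k_oas_act, c("OAS", "pIC_cyt"), c(OAS = -1, OASa = 1))
  add("oasa_relax", p$d_oasa, "OASa", c(OASa = -1, OAS = 1))

  reactions <- reactions[seq_len(nr)]

  ## -- default (pre-equilibration) initial state ---------------------------
  x0 <- stats::setNames(numeric(length(sp)), sp)
  x0["RIGI_mRNA"] <- 10; x0["RIGI"] <- round(10 * p$ktl_rigi / p$d_rigi)
  x0["IKKn"] <- p$ikk_total; x0["TBK0"] <- p$tbk_total
  x0["IkBa_mRNA"] <- 4; x0["IkBa"] <- 2000; x0["IkBan"] <- 2000
  x0["NIc"] <- p$nfkb_total
  x0["A20_mRNA"] <- 1; x0["A20"] <- round(1 * p$ktl_a20 / p$d_a20)
  x0["IRF3"] <- p$irf3_total
  x0["IFNAR"] <- p$ifnar_total
  x0["STAT1_mRNA"] <- 10; x0["STAT1"] <- round(10 * p$ktl_stat1 / p$d_stat)
  x0["STAT2_mRNA"] <- 10; x0["STAT2"] <- round(10 * p$ktl_stat2 / p$d_stat)
  x0["PKR_mRNA"] <- 10; x0["PKR"] <- round(10 * p$ktl_pkr / p$d_pkr)
  x0["OAS_mRNA"] <- 1; x0["OAS"] <- round(1 * p$ktl_oas / p$d_oas)
  x0[paste0("G_", gt$gene, "_off")] <- gt$copy_number

  if (genotype$flag == "RelA_knockout")
    x0[c("NFkB", "NFkBn", "NIc", "NIn")] <- 0
  if (genotype$flag == "Stat1_knockout")
    x0[c("STAT1", "STAT1p", "STATd")] <- 0

  net <- structure(
    list(species = sp, x0 = x0, reactions = reactions,
         genotype = genotype, params = params,
         pkr_all_mrna = pkr_all_mrna),
    class = "reaction_network")
  net$compiled <- compile_network(net)
  net
}

## Flatten the reaction list into engine-ready arrays:
##   rate:   base rate constants (length m)
##   ri:     m x 3 integer matrix of propensity factor species (0 = none)
##   inh:    inhibitor species index (0 = none), alpha: inhibition strength
##   stoich: dense species x reaction increment matrix (used by the ODE) and
##           a sparse triplet form (used by the C++ SSA core)
##   group:  protocol scaling group per reaction
compile_network <- function(net) {
  sp <- net$species
  ix <- seq_along(sp); names(ix) <- sp
  m <- length(net$reactions)
  rate <- numeric(m)
  ri <- matrix(0L, m, 3L)
  inh <- integer(m); alpha <- numeric(m)
  group <- character(m)
  S <- matrix(0, length(sp), m, dimnames = list(sp, NULL))
  for (j in seq_len(m)) {
    r <- net$reactions[[j]]
    rate[j] <- r$rate
    if (length(r$reactants) > 3L)
      stop("internal: >3 propensity factors in ", r$name)
    if (length(r$reactants) > 0L)
      ri[j, seq_along(r$reactants)] <- ix[r$reactants]
    if (nzchar(r$inhibitor)) { inh[j] <- ix[[r$inhibitor]]; alpha[j] <- r$alpha }
    group[j] <- r$group
    S[ix[names(r$stoich)], j] <- S[ix[names(r$stoich)], j] + r$stoich
  }
  ## sparse triplets for the SSA core
  nz <- which(S != 0, arr.ind = TRUE)
  ord <- order(nz[, "col"], nz[, "row"])
  nz <- nz[ord, , drop = FALSE]
  list(rate = rate, ri = ri, inh = inh, alpha = alpha, group = group,
       S = S,
       st_reac = as.integer(nz[, "col"]),
       st_spec = as.integer(nz[, "row"]),
       st_delta = as.integer(S[nz]),
       names = vapply(net$reactions, `[[`, "", "name"))
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      length(x$reactions), " reactions, genotype: ", x$genotype$flag,
      "\n", sep = "")
  invisible(x)
}

#' Number of reactions in a network
#' @param network A \code{reaction_network}.
#' @return Integer count.
#' @export
n_reactions <- function(network) length(network$reactions)

#' Species index lookup
#' @param network A \code{reaction_network}.
#' @param species Character vector of species names.
#' @return Integer indices; unknown names raise an error.
#' @export
species_index <- function(network, species) {
  i <- match(species, network$species)
  if (anyNA(i))
    stop("unknown species: ", paste(species[is.na(i)], collapse = ", "),
         call. = FALSE)
  i
}

#' Serialise a network configuration to YAML
#'
#' Writes genotype, options and the full parameter vector (with provenance
#' tags) to a plain-text YAML file; \code{read_network_config} rebuilds an
#' identical network from it.
#'
#' @param network A \code{reaction_network}.
#' @param path Output file path.
#' @export
write_network_config <- function(network, path) {
  cfg <- list(
    genotype = network$genotype$flag,
    pkr_all_mrna = network$pkr_all_mrna,
    params = as.list(network$params),
    provenance = as.list(attr(network$params, "provenance")))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_network_config
#' @param path Path to a YAML file written by \code{write_network_config}.
#' @return A rebuilt \code{reaction_network}.
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- unlist(cfg$params)
  prov <- unlist(cfg$provenance)
  attr(p, "provenance") <- stats::setNames(as.character(prov), names(p))
  build_network(genotype(cfg$genotype), params = p,
                pkr_all_mrna = isTRUE(cfg$pkr_all_mrna))
}

#' Build a custom reaction network
#'
#' Low-level constructor for arbitrary mass-action networks (used for
#' isolated-subsystem analyses: single telegraph loci, birth-death and decay
#' processes). Each reaction is a list with \code{name}, \code{rate},
#' \code{reactants} (0--3 species names whose counts multiply the
#' propensity), \code{stoich} (named vector of count increments) and
#' optionally \code{inhibitor}/\code{alpha} for a 1/(1+alpha*X) factor and a
#' \code{group} label.
#'
#' @param species Character vector of species names.
#' @param reactions List of reaction descriptors (see Details).
#' @param x0 Named or positional initial counts (default all zero).
#' @return A \code{reaction_network} usable with \code{\link{ssa_run}} and
#'   \code{\link{ode_run}}.
#' @examples
#' bd <- custom_network(
#'   "X",
#'   list(list(name = "birth", rate = 2, reactants = character(),
#'             stoich = c(X = 1)),
#'        list(name = "death", rate = 0.1, reactants = "X",
#'             stoich = c(X = -1))))
#' @export
custom_network <- function(species, reactions, x0 = NULL) {
  if (anyDuplicated(species)) stop("duplicated species", call. = FALSE)
  reactions <- lapply(reactions, function(r) {
    if (is.null(r$name) || is.null(r$rate) || is.null(r$stoich))
      stop("each reaction needs name, rate, stoich", call. = FALSE)
    if (r$rate < 0 || !is.finite(r$rate))
      stop("invalid rate in reaction ", r$name, call. = FALSE)
    r$reactants <- if (is.null(r$reactants)) character() else r$reactants
    bad <- setdiff(c(r$reactants, names(r$stoich),
                     if (!is.null(r$inhibitor) && nzchar(r$inhibitor))
                       r$inhibitor),
                   species)
    if (length(bad))
      stop("unknown species in reaction ", r$name, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (is.null(r$group)) r$group <- ""
    if (is.null(r$inhibitor)) r$inhibitor <- ""
    if (is.null(r$alpha)) r$alpha <- 0
    r
  })
  if (is.null(x0)) x0 <- stats::setNames(numeric(length(species)), species)
  else if (is.null(names(x0))) x0 <- stats::setNames(as.numeric(x0), species)
  else {
    full <- stats::setNames(numeric(length(species)), species)
    full[names(x0)] <- x0
    x0 <- full
  }
  net <- structure(
    list(species = species, x0 = x0, reactions = reactions,
         genotype = genotype("wild_type"), params = default_params(),
         pkr_all_mrna = FALSE),
    class = "reaction_network")
  net$compiled <- compile_network(net)
  net
}

#' Isolated two-state (telegraph) locus as a standalone network
#'
#' Gene switching, transcription and mRNA degradation only; used as the SSA
#' oracle for \code{\link{stationary_gene_stats}} and for fast/full
#' equilibration cross-checks.
#'
#' @param k_on,k_off,k_tx,gamma_m Telegraph rates (1/s).
#' @param copy_number Alleles (default 2).
#' @param k_tl,gamma_p Optional translation/protein-degradation rates; when
#'   both are given the network includes the protein stage.
#' @return A \code{reaction_network} with species \code{G_off, G_on, M}
#'   (and \code{P} if translated).
#' @export
telegraph_network <- function(k_on, k_off, k_tx, gamma_m, copy_number = 2L,
                              k_tl = NULL, gamma_p = NULL) {
  species <- c("G_off", "G_on", "M")
  rx <- list(
    list(name = "on", rate = k_on, reactants = "G_off",
         stoich = c(G_off = -1, G_on = 1)),
    list(name = "off", rate = k_off, reactants = "G_on",
         stoich = c(G_on = -1, G_off = 1)),
    list(name = "tx", rate = k_tx, reactants = "G_on", stoich = c(M = 1)),
    list(name = "deg", rate = gamma_m, reactants = "M", stoich = c(M = -1)))
  x0 <- c(G_off = copy_number, G_on = 0, M = 0)
  if (!is.null(k_tl) && !is.null(gamma_p)) {
    species <- c(species, "P")
    rx <- c(rx, list(
      list(name = "tl", rate = k_tl, reactants = "M", stoich = c(P = 1)),
      list(name = "pdeg", rate = gamma_p, reactants = "P",
           stoich = c(P = -1))))
    x0 <- c(x0, P = 0)
  }
  custom_network(species, rx, x0)
}
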