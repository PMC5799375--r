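test_that("network construction is deterministic and matches the rule expansion", {
  net1 <- build_network()
  net2 <- build_network()
  expect_identical(net1$compiled, net2$compiled)
  expect_identical(vapply(net1$reactions, `[[`, "", "name"),
                   vapply(net2$reactions, `[[`, "", "name"))

  ## independent enumeration of the rule expansion:
  ## each locus: basal on, activated on, off, transcription, mRNA decay;
  ## OAS1A-enhanced decay only for the NF-kB-inducible inhibitors
  gt <- gene_table()
  n_gene <- sum(5L + (gt$gene %in% c("nfkbia", "tnfaip3")))
  n_signal <- 4L   # LPS decay, LPS->IKK, polyIC entry, polyIC decay
  n_rigi <- 7L     # act, relax, 2x turnover, translation, ->IKK, ->TBK1
  n_kinase <- 5L   # IKK inact (2 routes), recycle, TBK1 inact (2 routes)
  n_nfkb <- 15L    # IkBa translation/degradation/shuttling/binding, A20
  n_irf3 <- 4L
  n_ifn <- 8L      # translation, secretion, decays, IFNAR binding/cycling
  n_stat <- 15L    # phos/dephos x2, dimer, dissoc, translation x2,
                   # degradation x5, SOCS1 translation + degradation
  n_pkroas <- 10L
  expect_equal(n_reactions(net1),
               n_gene + n_signal + n_rigi + n_kinase + n_nfkb + n_irf3 +
                 n_ifn + n_stat + n_pkroas)
})

test_that("Ifnb1 locus is AND-gated by nuclear NF-kB and nuclear p-IRF3", {
  net <- build_network()
  comp <- net$compiled
  j <- which(comp$names == "ifnb1_on_act")
  expect_length(j, 1)
  ri <- comp$ri[j, ]
  sp <- net$species[ri[ri > 0]]
  expect_setequal(sp, c("G_ifnb1_off", "NFkBn", "IRF3pn"))
  ## propensity is zero whenever nuclear NF-kB is zero, whatever p-IRF3 does
  x <- net$x0
  x["G_ifnb1_off"] <- 2; x["NFkBn"] <- 0; x["IRF3pn"] <- 5000
  vals <- x[ri[ri > 0]]
  expect_equal(comp$rate[j] * prod(vals), 0)
  x["NFkBn"] <- 100
  expect_gt(comp$rate[j] * prod(x[ri[ri > 0]]), 0)
})

test_that("RelA knockout removes NF-kB and leaves only basal locus switching", {
  net <- build_network("RelA_knockout")
  nfkb_pools <- c("NFkB", "NFkBn", "NIc", "NIn")
  expect_true(all(net$x0[nfkb_pools] == 0))
  ## no reaction creates NF-kB from outside the conserved pools, so the
  ## NF-kB-gated activation propensities are identically zero
  comp <- net$compiled
  i_pools <- match(nfkb_pools, net$species)
  creates <- comp$st_delta > 0 & comp$st_spec %in% i_pools
  sources <- unique(comp$st_reac[creates])
  for (j in sources) {
    cons <- comp$st_spec[comp$st_reac == j & comp$st_delta < 0]
    expect_true(any(cons %in% i_pools))  # only pool-to-pool moves
  }
  for (nm in c("nfkbia_on_act", "tnfaip3_on_act", "ifnb1_on_act")) {
    j <- which(comp$names == nm)
    ri <- comp$ri[j, ]
    expect_equal(prod(net$x0[ri[ri > 0]]), 0)
  }
})

test_that("Stat1 knockout zeroes STAT1 synthesis and initial protein", {
  net <- build_network("Stat1_knockout")
  expect_equal(unname(net$x0[c("STAT1", "STAT1p", "STATd")]), c(0, 0, 0))
  j <- which(net$compiled$names == "stat1_tl")
  expect_equal(net$compiled$rate[j], 0)
})

test_that("missing or invalid rate constants raise configuration errors", {
  p <- default_params()
  expect_error(build_network(params = p[-match("d_a20", names(p))]),
               "d_a20")
  expect_error(build_network("RelB_knockout"), "arg")
  p2 <- p; p2["d_lps"] <- -1
  expect_error(build_network(params = p2), "negative")
})

test_that("telegraph stationary moments: closed form matches trivial cases", {
  ## symmetric switch, single allele: ON half the time
  st <- stationary_gene_stats(1e-4, 1e-4, 1e-2, 1e-3, copy_number = 1)
  expect_equal(st$mean, 0.5 * 1e-2 / 1e-3)
  expect_equal(st$p_on, 0.5)
  ## super-Poissonian whenever k_off > 0
  expect_gt(st$fano, 1)
  expect_error(stationary_gene_stats(1e-4, 1e-4, 1e-2, 0), "diverge")
})

test_that("default locus parameters reproduce the basal expression anchors", {
  gt <- gene_table()
  means <- vapply(seq_len(nrow(gt)), function(i)
    stationary_gene_stats(gt$k_on[i], gt$k_off[i], gt$k_tx[i], gt$gamma_m[i],
                          gt$copy_number[i])$mean, 0)
  names(means) <- gt$gene
  expect_equal(unname(means["ddx58"]), 10, tolerance = 0.05)
  expect_equal(unname(means["eif2ak2"]), 10, tolerance = 0.05)
  expect_equal(unname(means["oas1a"]), 1, tolerance = 0.05)
  expect_equal(unname(means["ifnb1"]), 1, tolerance = 0.05)
})

test_that("telegraph stationary moments match a long SSA run of the isolated locus", {
  k_on <- 2e-3; k_off <- 8e-3; k_tx <- 2; gm <- 2e-2
  net <- telegraph_network(k_on, k_off, k_tx, gm, copy_number = 2)
  st <- stationary_gene_stats(k_on, k_off, k_tx, gm, copy_number = 2)
  ## ~1e7 events over the run (transcription/degradation flux ~1.6/s)
  tr <- ssa_run(net, horizon = 6e6, seed = 42, output_dt = 50)
  expect_gt(tr$n_events, 1e6)
  ## batch-means standard errors (self-calibrating against autocorrelation)
  m <- species_profile(tr, "M")
  m <- m[seq(length(m) %/% 2 + 1, length(m))]
  nb <- 25L
  batches <- split(m, cut(seq_along(m), nb, labels = FALSE))
  b_mean <- vapply(batches, mean, 0)
  b_var <- vapply(batches, stats::var, 0)
  expect_lt(abs(mean(m) - st$mean), 3 * stats::sd(b_mean) / sqrt(nb))
  expect_lt(abs(stats::var(m) - st$variance),
            3 * stats::sd(b_var) / sqrt(nb))
})

test_that("removing A20 synthesis prolongs nuclear NF-kB activity after LPS", {
  p <- default_params()
  net <- build_network(params = p)
  net_no_a20 <- build_network(params = set_params(p, ktl_a20 = 0))
  b <- basal_state(net)
  b2 <- basal_state(net_no_a20)
  pr <- protocol_preset("lps")
  dwell_above_half_peak <- function(net, b) {
    tr <- ode_run(net, init = b, protocol = pr, output_dt = 60)
    nn <- species_profile(tr, "NFkBn") + species_profile(tr, "NIn")
    sum(nn > max(nn) / 2) * 60
  }
  expect_gt(dwell_above_half_peak(net_no_a20, b2),
            dwell_above_half_peak(net, b))
})

test_that("without PKR and OAS1A activation the poly(I:C) response is pulse-like", {
  p <- set_params(default_params(), k_pkr_act = 0, k_oas_act = 0)
  net <- build_network(params = p)
  b <- basal_state(net)
  tr <- ode_run(net, init = b, protocol = protocol_preset("polyic", dose = 1),
                output_dt = 300)
  nn <- species_profile(tr, "NFkBn") + species_profile(tr, "NIn")
  ft <- profile_features(nn, tr$time)
  expect_false(is.na(ft$termination_time))
  expect_lt(ft$termination_time, 4 * 3600)
})

test_that("Stat1 knockout keeps Ddx58 transcription at basal level after stimulus", {
  net <- build_network("Stat1_knockout")
  b <- basal_state(net)
  tr <- ode_run(net, init = b, protocol = protocol_preset("polyic", dose = 1),
                output_dt = 600)
  post <- species_profile(tr, "RIGI_mRNA")[tr$time >= 6 * 3600]
  expect_lt(max(post), 2 * b[["RIGI_mRNA"]])
})

test_that("network configuration round-trips through YAML", {
  p <- set_params(default_params(), d_a20 = 3.3e-4)
  net <- build_network("Stat1_knockout", params = p)
  path <- tempfile(fileext = ".yaml")
  write_network_config(net, path)
  net2 <- read_network_config(path)
  expect_equal(net2$genotype$flag, "Stat1_knockout")
  expect_equal(unname(net2$params), unname(net$params))
  expect_identical(attr(net2$params, "provenance")[["d_a20"]], "user")
  expect_identical(net2$compiled$rate, net$compiled$rate)
  unlink(path)
})
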