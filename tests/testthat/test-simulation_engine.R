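test_that("a network with all propensities zero stays constant", {
  net <- custom_network(
    c("A", "B"),
    list(list(name = "conv", rate = 0, reactants = "A",
              stoich = c(A = -1, B = 1))),
    c(A = 7, B = 3))
  tr <- ssa_run(net, horizon = 1000, seed = 1, output_dt = 100)
  expect_true(all(tr$counts[, "A"] == 7))
  expect_true(all(tr$counts[, "B"] == 3))
  expect_equal(tr$n_events, 0)
})

test_that("SSA death process matches the closed-form decay mean", {
  gamma <- 0.05
  net <- decay_network(gamma = gamma, x0 = 10)
  n <- 1000
  t_check <- 20
  finals <- vapply(seq_len(n), function(i) {
    tr <- ssa_run(net, horizon = t_check, seed = 7, cell = i, output_dt = t_check)
    tr$counts[nrow(tr$counts), "X"]
  }, 0)
  expected <- 10 * exp(-gamma * t_check)        # ~3.68
  se <- sqrt(10 * exp(-gamma * t_check) * (1 - exp(-gamma * t_check)) / n)
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("birth-death stationary law is Poisson (chi-squared GOF)", {
  k <- 2; gamma <- 0.1                           # stationary mean 20
  net <- birth_death_network(k, gamma, x0 = 20)
  ## samples spaced 5 relaxation times apart are effectively independent
  dt <- 5 / gamma
  n <- 1e4
  tr <- ssa_run(net, horizon = n * dt, seed = 99, output_dt = dt)
  x <- tr$counts[-1, "X"]
  lambda <- k / gamma
  ## pool tails so expected counts stay >= 5
  breaks <- c(-Inf, seq(10, 30), Inf)
  obs <- table(cut(x, breaks))
  pr <- diff(ppois(c(-Inf, seq(10, 30), Inf), lambda))
  chi <- sum((as.numeric(obs) - n * pr)^2 / (n * pr))
  df <- length(pr) - 1
  expect_gt(pchisq(chi, df, lower.tail = FALSE), 0.01)
})

test_that("ODE birth-death matches the closed form and SSA converges to it", {
  k <- 2; gamma <- 0.1
  net <- birth_death_network(k, gamma, x0 = 0)
  tr <- ode_run(net, horizon = 60, output_dt = 1, abs_tol = 1e-8,
                rel_tol = 1e-8)
  expected <- (k / gamma) * (1 - exp(-gamma * tr$time))
  expect_equal(unname(tr$counts[, "X"]), expected, tolerance = 1e-5)

  ## law of large numbers: scaling counts x100 shrinks the relative
  ## deviation of a single SSA path from the mean field
  rel_dev <- function(scale) {
    neti <- birth_death_network(k * scale, gamma, x0 = 0)
    tri <- ssa_run(neti, horizon = 60, seed = 5, output_dt = 1)
    sol <- scale * expected[-1]
    mean(abs(tri$counts[-1, "X"] - sol) / pmax(sol, 1))
  }
  expect_lt(rel_dev(100), rel_dev(1))
})

test_that("fixed seeds reproduce paths; different seeds decorrelate them", {
  net <- birth_death_network(2, 0.1, x0 = 20)
  t1 <- ssa_run(net, horizon = 500, seed = 3, output_dt = 5)
  t2 <- ssa_run(net, horizon = 500, seed = 3, output_dt = 5)
  expect_identical(t1$counts, t2$counts)
  finals <- vapply(1:60, function(s)
    ssa_run(net, horizon = 50, seed = s, output_dt = 50)$counts[2, "X"], 0)
  ## summary statistic across seeds is uncorrelated with seed order
  expect_lt(abs(cor(finals[-1], finals[-length(finals)])), 0.35)
})

test_that("ensemble mean of a linear sub-network equals the ODE solution", {
  net <- telegraph_network(2e-3, 2e-3, 0.1, 1e-3, copy_number = 2)
  horizon <- 2000
  ode <- ode_run(net, horizon = horizon, output_dt = horizon,
                 abs_tol = 1e-8, rel_tol = 1e-8)
  m_ode <- ode$counts[nrow(ode$counts), "M"]
  n <- 300
  finals <- vapply(seq_len(n), function(i)
    ssa_run(net, horizon = horizon, seed = 11, cell = i,
            output_dt = horizon)$counts[2, "M"], 0)
  se <- sd(finals) / sqrt(n)
  expect_lt(abs(mean(finals) - m_ode), 3.5 * se)
})

test_that("no SSA trajectory records a negative count and NF-kB is conserved", {
  net <- build_network()
  x0 <- equilibrate(net, seed = 8, mode = "fast")
  tr <- ssa_run(net, init = x0, protocol = protocol_preset("polyic", dose = 1,
                                                           horizon = 4 * 3600),
                seed = 21, output_dt = 300)
  expect_true(all(tr$counts >= 0))
  tot <- rowSums(tr$counts[, c("NFkB", "NFkBn", "NIc", "NIn")])
  expect_true(all(tot == tot[1]))
})

test_that("equilibrate: duration 0 in full mode returns the initial state", {
  net <- build_network()
  b <- round(basal_state(net))
  out <- equilibrate(net, duration = 0, mode = "full", init = b)
  expect_equal(unname(out), unname(b))
})

test_that("fast equilibration matches full-SSA marginals (scaled run)", {
  net <- build_network()
  basal <- basal_state(net)
  n <- 80
  dur <- 1.2e5   # several autocorrelation times of the slowest sampled pool
  full <- t(vapply(seq_len(n), function(i)
    equilibrate(net, duration = dur, seed = 17, mode = "full", cell = i,
                basal = basal),
    numeric(length(net$species))))
  fast <- t(vapply(seq_len(n), function(i)
    equilibrate(net, seed = 18, mode = "fast", cell = i, basal = basal),
    numeric(length(net$species))))
  colnames(full) <- colnames(fast) <- net$species
  check <- c("RIGI_mRNA", "RIGI", "PKR_mRNA", "PKR", "OAS", "G_ddx58_on")
  alpha <- 0.01 / length(check)                 # Bonferroni over species
  for (s in check) {
    p <- suppressWarnings(stats::ks.test(full[, s], fast[, s]))$p.value
    expect_gt(p, alpha)
  }
})

test_that("tau-leaping approximates the exact dynamics and is flagged", {
  net <- birth_death_network(20, 0.1, x0 = 0)
  tr <- ssa_run(net, horizon = 200, seed = 4, output_dt = 10, mode = "tau")
  expect_identical(tr$mode, "tau")
  late <- tr$counts[tr$time > 100, "X"]
  expect_lt(abs(mean(late) - 200), 5 * sqrt(200))
  expect_true(all(tr$counts >= 0))
})
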