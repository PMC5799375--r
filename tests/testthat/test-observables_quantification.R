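ref_record <- list(I_Q_nuc = 100, I_N_nuc = 50, S_nuc = 10,
                   p_bg_Q = 2, p_bg_N = 1,
                   I_Q_img = 1000, I_N_img = 400, S_img = 100)

test_that("translocation score reproduces the hand-evaluated normalisations", {
  ## Case 1: ((100-20)/(1000-200)) / ((50-10)/(400-100)) = 0.1/0.1333 = 0.75
  expect_equal(translocation_score(ref_record, case = 1), 0.75)
  ## Case 3: raw ratio
  expect_equal(translocation_score(ref_record, case = 3), 2)
  ## Case 2: background-corrected ratio without image normalisation
  expect_equal(translocation_score(ref_record, case = 2), 80 / 40)
})

test_that("a homogeneous image scores 1 under Case 1", {
  r <- list(I_Q_nuc = 30, I_N_nuc = 60, S_nuc = 10, p_bg_Q = 0, p_bg_N = 0,
            I_Q_img = 300, I_N_img = 600, S_img = 100)
  expect_equal(translocation_score(r, case = 1), 1)
})

test_that("Case-1 score is invariant to a whole-channel gain change", {
  gain <- 7.3
  r2 <- ref_record
  r2$I_Q_nuc <- gain * r2$I_Q_nuc
  r2$I_Q_img <- gain * r2$I_Q_img
  r2$p_bg_Q <- gain * r2$p_bg_Q
  expect_equal(translocation_score(r2, case = 1),
               translocation_score(ref_record, case = 1))
})

test_that("degenerate records are rejected, and flagged in table scoring", {
  bad <- ref_record; bad$I_N_nuc <- 5     # corrected denominator < 0
  expect_error(translocation_score(bad, case = 1), "degenerate")
  tab <- rbind(as.data.frame(ref_record), as.data.frame(bad))
  out <- translocation_scores(tab, case = 1)
  expect_equal(out$excluded, c(FALSE, TRUE))
  expect_equal(out$score[1], 0.75)
})

test_that("responding threshold is the control quantile", {
  expect_equal(responding_threshold(rep(3.2, 60)), 3.2)
  set.seed(1)
  z <- rnorm(1000)
  expect_lt(abs(responding_threshold(z, 0.95) - qnorm(0.95)), 0.1)
  expect_error(responding_threshold(numeric(0)), "empty")
  expect_error(responding_threshold(z, 1.2), "quantile")
  expect_error(responding_threshold(z, 0), "quantile")
})

test_that("active-cell classification recovers a known mixture fraction", {
  sc <- data.frame(cell = 1:4, score_nfkb = c(1, 1, 1, 1) / 10,
                   score_irf3 = c(1, 1, 1, 1) / 10)
  out <- classify_active(sc, list(nfkb = 1, irf3 = 1))
  expect_equal(out$frac_active, 0)

  set.seed(7)
  n <- 2000; frac <- 0.30
  hot <- runif(n) < frac
  sc <- data.frame(
    cell = seq_len(n),
    score_nfkb = ifelse(hot, rlnorm(n, log(0.5), 0.2),
                        rlnorm(n, log(0.02), 0.3)),
    score_irf3 = ifelse(hot, rlnorm(n, log(0.4), 0.2),
                        rlnorm(n, log(0.015), 0.3)))
  out <- classify_active(sc, list(nfkb = 0.1, irf3 = 0.1))
  se <- sqrt(frac * (1 - frac) / n)
  expect_lt(abs(out$frac_active - frac), 3 * se)
  ## active implies responding for both factors
  expect_true(all(!out$calls$active |
                    (out$calls$responding_nfkb & out$calls$responding_irf3)))
  expect_error(classify_active(sc[, -1], list(nfkb = 1, irf3 = 1)), "cell")
})

test_that("active fraction is non-increasing in either threshold", {
  set.seed(11)
  sc <- data.frame(cell = 1:500, score_nfkb = rlnorm(500, -2, 1),
                   score_irf3 = rlnorm(500, -2, 1))
  ths <- c(0.02, 0.05, 0.15, 0.4)
  f_n <- vapply(ths, function(t)
    classify_active(sc, list(nfkb = t, irf3 = 0.05))$frac_active, 0)
  f_i <- vapply(ths, function(t)
    classify_active(sc, list(nfkb = 0.05, irf3 = t))$frac_active, 0)
  expect_true(all(diff(f_n) <= 0))
  expect_true(all(diff(f_i) <= 0))
})

test_that("profile features: peak, termination, ties and reversal", {
  t_min <- seq(0, 80) * 60
  prof <- sin(pi * seq(0, 80) / 80)
  ft <- profile_features(prof, t_min)
  expect_equal(ft$peak_time, 40 * 60)
  ## time-reversed unimodal profile maps peak to horizon - peak
  skew <- dgamma(seq(0, 80) / 10, shape = 2)
  ftf <- profile_features(skew, t_min)
  ftr <- profile_features(rev(skew), t_min)
  expect_equal(ftr$peak_time, max(t_min) - ftf$peak_time)
  ## earliest argmax on ties
  prof2 <- c(0, 1, 1, 0)
  expect_equal(profile_features(prof2, 0:3)$peak_time, 1)
  expect_error(profile_features(rep(2, 10), 1:10), "flat")
})

test_that("pair correlation handles the exact and degenerate cases", {
  x <- c(1, 2, 5, 7)
  expect_equal(pair_correlation(x, x), 1)
  expect_equal(pair_correlation(x, -x), -1)
  expect_error(pair_correlation(x, rep(1, 4)), "zero variance")
  expect_error(pair_correlation(1:2, 1:2), "3 paired")
})

test_that("simulated translocation proxy lies in [0,1] and tracks nuclear counts", {
  net <- build_network()
  x <- net$x0
  x["NFkBn"] <- 4e4; x["NIn"] <- 1e4
  s <- simulated_translocation(x, "nfkb", net$params)
  expect_equal(unname(s), 0.5)
  x["IRF3pn"] <- 2.5e3
  expect_equal(unname(simulated_translocation(x, "irf3", net$params)), 0.25)
})
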