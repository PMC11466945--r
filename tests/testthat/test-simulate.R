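test_that("herd design honors the pen/treatment/sex layout", {
  cfg <- sim_config(seed = 3)
  herd <- simulate_herd(cfg)
  expect_equal(nrow(herd$pigs), 96)
  expect_equal(length(unique(herd$pigs$pen_id)), 12)
  expect_equal(as.vector(table(herd$pigs$treatment)), rep(32L, 3))
  sex_tab <- table(herd$pigs$pen_id, herd$pigs$sex)
  expect_true(all(sex_tab == 4L))
  # weight trajectories strictly increasing per pig
  inc <- tapply(herd$weights$weight_kg,
                herd$weights$pig_id,
                function(w) all(diff(w) > 0))
  expect_true(all(inc))
  # preference matrices symmetric, zero diagonal
  for (W in herd$preference) {
    expect_equal(W, t(W))
    expect_equal(unname(diag(W)), rep(0, 8))
  }
})

test_that("zero concentration collapses hub and block to uniform", {
  base <- simulate_herd(sim_config(seed = 9))
  hub <- simulate_herd(sim_config(seed = 9, preference_structure = "hub",
                                  kappa = 0))
  blk <- simulate_herd(sim_config(seed = 9, preference_structure = "block",
                                  kappa = 0))
  expect_identical(base$preference, hub$preference)
  expect_identical(base$preference, blk$preference)
  # with kappa > 0 the structures differ as designed
  hub3 <- simulate_herd(sim_config(seed = 9, preference_structure = "hub",
                                   kappa = 3))
  W <- hub3$preference[[1]]
  expect_equal(unname(W[1, 2:8]), rep(4, 7))
  expect_equal(unname(W[2, 3]), 1)
})

test_that("the generator is deterministic and pen-stable", {
  cfg <- sim_config(n_pens = 3, seed = 77)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$scans, b$scans)
  expect_identical(a$bites, b$bites)
  expect_identical(a$scores, b$scores)
  # adding pens leaves the data of existing pens untouched
  big <- simulate_study(sim_config(n_pens = 5, seed = 77,
                                   treatments = c("LM", "LM", "HLM",
                                                  "NLM", "NLM")))
  keep <- function(df) df[df$pen_id %in% sprintf("pen%02d", 1:3), ]
  rownames_reset <- function(df) { rownames(df) <- NULL; df }
  expect_identical(rownames_reset(keep(a$scans)),
                   rownames_reset(keep(big$scans)))
  expect_identical(rownames_reset(keep(a$bites)),
                   rownames_reset(keep(big$bites)))
})

test_that("lying scans obey the structural contract", {
  cfg <- sim_config(n_pens = 2, seed = 5)
  herd <- simulate_herd(cfg)
  scans <- simulate_lying_scans(herd, cfg)
  # symmetry + partners-imply-lying, via the reader's validator
  expect_silent(tailnet:::validate_scans(scans))
  # at most two partners each
  npart <- lengths(strsplit(scans$partners, ";", fixed = TRUE))
  expect_true(all(npart <= 2))
  # p_lie = 0: nobody lying, no pairs
  none <- simulate_lying_scans(herd, sim_config(n_pens = 2, seed = 5,
                                                p_lie = 0))
  expect_true(all(none$lying == 0))
  expect_true(all(none$partners == ""))
})

test_that("a 2-pig pen with certain lying is always paired, HWI = 1", {
  cfg <- sim_config(n_pens = 1, pigs_per_pen = 2, treatments = "LM",
                    p_lie = 1, seed = 2)
  herd <- simulate_herd(cfg)
  scans <- simulate_lying_scans(herd, cfg)
  expect_true(all(scans$lying == 1))
  expect_true(all(scans$partners != ""))
  agg <- aggregate_scans(build_scan_matrices(scans, "pen01", 15))
  net <- build_association_network(agg)
  expect_equal(net$W[1, 2], 1)
})

test_that("uniform preference yields exchangeable dyads in mean HWI", {
  # Monte-Carlo: many replicate pen-periods, mean HWI per dyad ~ constant
  cfg <- sim_config(n_pens = 1, treatments = "LM", seed = 0,
                    periods = 15L, p_lie = 0.8)
  hw <- matrix(0, 8, 8)
  reps <- 60
  for (s in seq_len(reps)) {
    c2 <- sim_config(n_pens = 1, treatments = "LM", seed = s, periods = 15L)
    herd <- simulate_herd(c2)
    scans <- simulate_lying_scans(herd, c2)
    hw <- hw + build_association_network(
      aggregate_scans(build_scan_matrices(scans, "pen01", 15)))$W
  }
  hw <- hw / reps
  vals <- hw[upper.tri(hw)]
  # all 28 dyad means within Monte-Carlo error of the common mean
  expect_lt(max(abs(vals - mean(vals))), 4 * stats::sd(vals) / sqrt(1) + 0.05)
  expect_lt(stats::sd(vals) / mean(vals), 0.35)
})

test_that("bite counts follow the configured Poisson law", {
  cfg <- sim_config(n_pens = 2, seed = 4, bite_rate_base = 0)
  herd <- simulate_herd(cfg)
  expect_equal(nrow(simulate_bite_events(herd, cfg)), 0)
  # law of large numbers at sigma = 0: empirical mean -> lambda
  lam <- 0.7
  cfg2 <- sim_config(n_pens = 1, pigs_per_pen = 2, treatments = "LM",
                     periods = 15L, sigma_out = 0, sigma_in = 0,
                     bite_rate_base = lam, seed = 1)
  counts <- vapply(seq_len(2500), function(s) {
    c3 <- sim_config(n_pens = 1, pigs_per_pen = 2, treatments = "LM",
                     periods = 15L, sigma_out = 0, sigma_in = 0,
                     bite_rate_base = lam, seed = s)
    h <- simulate_herd(c3)
    ev <- simulate_bite_events(h, c3)
    sum(ev$biter == h$pigs$pig_id[1])
  }, numeric(1))
  # 2500 replicates of one directed dyad: mean within 4 SEs of lambda
  expect_lt(abs(mean(counts) - lam), 4 * sqrt(lam / 2500))
  # timestamps inside the 6-h window
  cfgt <- sim_config(n_pens = 1, treatments = "LM", seed = 8)
  ev <- simulate_bite_events(simulate_herd(cfgt), cfgt)
  expect_true(all(ev$timestamp_min >= 0 & ev$timestamp_min <= 360))
  expect_true(all(ev$biter != ev$recipient))
})

test_that("tail scores stay in range and respond to bites as configured", {
  cfg <- sim_config(n_pens = 2, seed = 6)
  herd <- simulate_herd(cfg)
  # no bites at all: every score 0
  empty <- simulate_bite_events(herd, sim_config(n_pens = 2, seed = 6,
                                                 bite_rate_base = 0))
  sc0 <- simulate_tail_scores(herd, empty, cfg)
  expect_true(all(sc0$score == 0))
  # certain escalation with bites in >= 4 windows reaches the cap of 4
  cfg4 <- sim_config(n_pens = 1, treatments = "LM", seed = 3,
                     periods = c(15L, 17L, 19L, 21L, 23L), injury_gain = 1,
                     heal_prob = 0, bite_rate_base = 2)
  herd4 <- simulate_herd(cfg4)
  ev4 <- simulate_bite_events(herd4, cfg4)
  hit <- names(which(table(factor(ev4$recipient,
                                  levels = herd4$pigs$pig_id),
                           ev4$period) > 0))
  all_windows <- names(which(rowSums(table(ev4$recipient, ev4$period) > 0)
                             == 5))
  sc4 <- simulate_tail_scores(herd4, ev4, cfg4)
  mts <- score_tails(sc4)
  expect_true(all(mts$mts[mts$pig_id %in% all_windows] == 4))
  # scores always in 0..4
  expect_true(all(sc4$score %in% 0:4))
})

test_that("mean MTS is monotone in the bite rate", {
  grid <- c(0, 0.5, 1, 2)
  mean_mts <- vapply(grid, function(br) {
    res <- vapply(1:4, function(s) {
      cfg <- sim_config(n_pens = 4, treatments = rep("LM", 4),
                        bite_rate_base = br, seed = s)
      herd <- simulate_herd(cfg)
      ev <- simulate_bite_events(herd, cfg)
      mean(score_tails(simulate_tail_scores(herd, ev, cfg))$mts)
    }, numeric(1))
    mean(res)
  }, numeric(1))
  expect_true(all(diff(mean_mts) >= 0))
  expect_gt(mean_mts[4], mean_mts[1])
})
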