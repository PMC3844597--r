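test_that("the score kernel reproduces the worked examples", {
  expect_equal(g2mFormula(1, 3, 5), 0)          # p = 1: -log2(1) = 0
  expect_equal(g2mFormula(0.25, 1, 2), 40)      # 10 * 2 * 1 * 2
  expect_equal(g2mFormula(0.01, 0, 7), 0)       # no change: log2(0 + 1) = 0
})

test_that("the score is monotone in significance and magnitude and symmetric
           in direction", {
  # increasing -log2(p)
  p_grid <- c(0.5, 0.2, 0.05, 0.001)
  s <- g2mFormula(p_grid, 1, 2)
  expect_true(all(diff(s) > 0))
  # increasing fold magnitude
  s2 <- g2mFormula(0.05, c(0.25, 0.5, 1, 2), 2)
  expect_true(all(diff(s2) > 0))
  # down-regulation: same |log2fc| gives the same magnitude term, and a
  # negative consistency ratio flips only the sign
  expect_equal(abs(g2mFormula(0.05, -1, -2)), g2mFormula(0.05, 1, 2),
               tolerance = 1e-12)
})

test_that("fold changes against vehicle match hand-computable cases", {
  # drug mean == vehicle mean at every time
  x_eq <- tinyExperiment(drug_vals = 5, veh_vals = 5)
  fct <- foldChanges(x_eq)
  tb <- fcTable(fct)
  expect_true(all(tb$log2fc == 0))
  expect_true(all(tb$fold == 1))
  expect_true(all(tb$t_p == 1))

  # planted +1 log2 shift, zero noise: fold ratio exactly 2
  x_up <- tinyExperiment(drug_vals = 6, veh_vals = 5)
  tb2 <- fcTable(foldChanges(x_up))
  expect_true(all(tb2$log2fc == 1))
  expect_true(all(tb2$fold == 2))
  expect_true(all(tb2$t_p == 0))
  sm <- fcSummary(foldChanges(x_up))
  expect_equal(sm$foldmean, 1)
  expect_equal(sm$foldsd, 0)
})

test_that("a 1.0 log2 shift at noise sd 0.2 with n = 3 is typically
           significant", {
  # vectorised across probes: one probe per simulated seed
  n_sim <- 400
  withr::with_seed(17, {
    drug_vals <- matrix(rnorm(n_sim * 12, mean = 1, sd = 0.2), n_sim, 12)
    veh_vals <- matrix(rnorm(n_sim * 12, mean = 0, sd = 0.2), n_sim, 12)
  })
  x <- tinyExperiment(drug_vals, veh_vals)
  tb <- fcTable(foldChanges(x))
  expect_lt(median(tb$t_p), 0.05)
})

test_that("zero cross-time variance yields an undefined score, a warning,
           and exclusion from ranking", {
  x <- tinyExperiment(drug_vals = 6, veh_vals = 5)  # constant +1 shift
  fct <- foldChanges(x)
  expect_warning(sc <- g2mScore(fct), "zero cross-time sd")
  expect_true(all(is.na(scoreTable(sc)$score)))
  expect_equal(nrow(globalScores(sc)), 0)
  expect_equal(nrow(sc@excluded), 1)
})

test_that("aggregation keeps the per-time score of maximal magnitude with its
           sign", {
  # probe responds at t=2 strongly down, weakly up elsewhere
  drug_vals <- matrix(rep(c(0.3, -2, 0.4, 0.1), each = 3), 1, 12, byrow = TRUE)
  x <- tinyExperiment(drug_vals = drug_vals[rep(1, 2), ], veh_vals = 0)
  # add tiny jitter so t-tests are defined and foldsd > 0
  m <- exprValues(x)
  withr::with_seed(3, m <- m + rnorm(length(m), sd = 0.05))
  x <- DrugExpressionSet(m, sampleSheet(x))
  sc <- g2mScore(foldChanges(x))
  ds <- drugScores(sc)
  tb <- scoreTable(sc)
  for (i in seq_len(nrow(ds))) {
    sub <- tb[tb$probe_id == ds$probe_id[i], ]
    expect_equal(ds$score[i], sub$score[which.max(abs(sub$score))])
  }
  # swapping drug and vehicle labels leaves |score| unchanged
  sheet_sw <- sampleSheet(x)
  sheet_sw$drug <- ifelse(sheet_sw$drug == "SAL", "COC", "SAL")
  sheet_sw$is_vehicle <- sheet_sw$drug == "SAL"
  sheet_sw$control <- ifelse(sheet_sw$is_vehicle, NA, "SAL")
  sheet_sw$role <- ifelse(sheet_sw$is_vehicle, "vehicle", "treatment")
  sc_sw <- g2mScore(foldChanges(DrugExpressionSet(m, sheet_sw)))
  expect_equal(abs(globalScores(sc_sw)$score), abs(globalScores(sc)$score),
               tolerance = 1e-12)
})

test_that("selection is deterministic and honours both modes", {
  gs <- data.frame(probe_id = c("c", "a", "b", "d"),
                   score = c(5, -5, 2, 0))
  sc <- new("G2MScoreTable", table = data.frame(), drugScores = data.frame(),
            globalScores = gs, excluded = data.frame())
  top2 <- selectTranscripts(sc, "top_k", 2)
  expect_equal(top2$probe_id, c("a", "c"))      # tie at |5| broken by id
  expect_equal(top2$rank, 1:2)
  thr <- selectTranscripts(sc, "threshold", 10)
  expect_equal(nrow(thr), 0)                    # nothing above 10
  expect_error(selectTranscripts(sc, "top_k", 5), "exceeds")
})

test_that("planted responsive probes are recovered by top-k selection", {
  # 50 planted responders among 1000 probes: a responsive fraction small
  # enough that quantile normalization's equal-distribution assumption holds
  cfg <- syntheticConfig(
    nProbes = 1000,
    networks = list(net_1 = list(size = 50, weights = c(DAT = 1, NET = 1))),
    amplitudeRange = c(2, 3),   # planted probes with unambiguously high scores
    seed = 23)
  sim <- generateExperiment(cfg)
  x <- suppressWarnings(normalizeExpression(sim$experiment))
  sc <- suppressWarnings(g2mScore(foldChanges(x)))
  top <- selectTranscripts(sc, "top_k", 50)
  truth <- trueMembership(sim$truth)
  expect_gte(sum(truth[top$probe_id] == "net_1"), 48)
})
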