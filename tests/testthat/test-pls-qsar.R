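test_that("noise-free linear data are fit exactly", {
  lib <- toy_library(n_peptides = 8, seed = 51)
  spec <- calpainqsar:::as_feature_spec("P2", "KYTJ820101")
  X <- calpainqsar:::featurize_spec(lib$windows, spec, lib$tables)
  y <- 150 + 42.5 * X[, 1]
  m <- fit_pls_qsar(NULL, y, spec, lib$tables, X = X)
  expect_equal(m$r2, 1, tolerance = 1e-9)
  expect_equal(unname(m$coefficients[1]), 42.5, tolerance = 1e-6)
  expect_equal(m$intercept, 150, tolerance = 1e-4)
})

test_that("full-component PLS equals the least-squares solution", {
  set.seed(61)
  for (rep in 1:5) {
    X <- matrix(rnorm(120), 30, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- rnorm(30)
    fit <- calpainqsar:::.pls_fit(X, y, ncomp = 4)
    ols <- stats::lm.fit(cbind(1, X), y)$coefficients
    expect_lt(max(abs(fit$coefficients - ols[-1])), 1e-8)
    expect_lt(abs(fit$intercept - ols[1]), 1e-8)
  }
})

test_that("planted coefficients are recovered from noisy libraries", {
  # coefficients with the heterogeneous magnitudes of real descriptor
  # models; each scale's spread is physical-unit sized, so the per-feature
  # effect ranges are comparable (as they are in fitted efficiency models)
  truth <- c(60, -11.7, 25, 1.04)
  tabs <- planted_pls_tables(truth)
  spec <- calpainqsar:::as_feature_spec(
    c("P2", "P1", "P3p", "P4p"),
    c("PLANT1", "PLANT2", "PLANT3", "PLANT4"))
  for (seed in 1:3) {
    peps <- generate_peptides(14, seed = 300 + seed)
    w <- enumerate_windows(peps, complete_range = 6)[1:119, ]
    X <- calpainqsar:::featurize_spec(w, spec, tabs)
    signal <- 400 + drop(X %*% truth)
    set.seed(400 + seed)
    y <- signal + rnorm(119, sd = 0.1 * sd(signal))
    m <- fit_pls_qsar(NULL, y, spec, tabs, X = X)
    rel <- abs(m$coefficients - truth) / abs(truth)
    expect_true(all(sign(m$coefficients) == sign(truth)))
    expect_true(all(rel <= 0.15))
  }
})

test_that("clean data yield no outliers and an unchanged refit", {
  lib <- toy_library(n_peptides = 8, seed = 63)
  spec <- calpainqsar:::as_feature_spec("P2", "KYTJ820101")
  X <- calpainqsar:::featurize_spec(lib$windows, spec, lib$tables)
  set.seed(5)
  y <- 100 + 20 * X[, 1] + rnorm(nrow(X), sd = 5)
  m <- fit_pls_qsar(NULL, y, spec, lib$tables, X = X)
  m2 <- exclude_outliers_and_refit(m)
  expect_identical(m2$excluded_outliers, character())
  expect_equal(m2$coefficients, m$coefficients)
})

test_that("a planted gross outlier is flagged exactly", {
  spec <- calpainqsar:::as_feature_spec("P2", "KYTJ820101")
  tabs <- example_descriptor_tables()
  peps <- generate_peptides(6, seed = 65)
  w <- enumerate_windows(peps, complete_range = 6)[1:50, ]
  X <- calpainqsar:::featurize_spec(w, spec, tabs)
  set.seed(9)
  y <- 100 + 20 * X[, 1] + rnorm(50, sd = 4)
  y[17] <- y[17] + 40 * 10  # ten-sigma displacement
  m <- fit_pls_qsar(NULL, y, spec, tabs, X = X)
  m2 <- exclude_outliers_and_refit(m)
  expect_equal(m2$excluded_outliers, "17")
  # refusal guard: a fit where most rows would be flagged
  y_wild <- c(rep(0, 25), rep(1000, 25))
  m3 <- fit_pls_qsar(NULL, y_wild, spec, tabs, X = X)
  expect_error(exclude_outliers_and_refit(m3, threshold = 0.1),
               "refusing")
})

test_that("predictions are linear and intercept-free in differences", {
  lib <- toy_library(n_peptides = 8, seed = 67)
  spec <- calpainqsar:::as_feature_spec(
    list("P2", c("P2", "P1")), c("KYTJ820101", "SYNTH001"))
  X <- calpainqsar:::featurize_spec(lib$windows, spec, lib$tables)
  set.seed(3)
  y <- 50 + drop(X %*% c(12, -4)) + rnorm(nrow(X))
  m <- fit_pls_qsar(NULL, y, spec, lib$tables, X = X)
  w1 <- lib$windows[1, ]
  w2 <- lib$windows[2, ]
  d <- predict(m, w1) - predict(m, w2)
  m_shift <- m
  m_shift$intercept <- m$intercept + 1000
  expect_equal(predict(m_shift, w1) - predict(m_shift, w2), d)
})

test_that("zero-coefficient models predict the intercept everywhere", {
  lib <- toy_library(n_peptides = 6, seed = 69)
  spec <- calpainqsar:::as_feature_spec("P2", "KYTJ820101")
  set.seed(1)
  m <- fit_pls_qsar(NULL, rnorm(30), spec, lib$tables,
                    X = calpainqsar:::featurize_spec(lib$windows[1:30, ],
                                                     spec, lib$tables))
  m$coefficients[] <- 0
  m$intercept <- 77
  expect_equal(predict(m, lib$windows[1:5, ]), rep(77, 5))
})

test_that("position contributions recompose the full prediction", {
  lib <- toy_library(n_peptides = 8, seed = 71)
  spec <- calpainqsar:::as_feature_spec(
    c("P2", "P1", "P3p"), c("KYTJ820101", "SYNTH001", "SYNTH002"))
  X <- calpainqsar:::featurize_spec(lib$windows, spec, lib$tables)
  set.seed(4)
  y <- 200 + drop(X %*% c(10, 5, -8)) + rnorm(nrow(X))
  m <- fit_pls_qsar(NULL, y, spec, lib$tables, X = X)
  w <- lib$windows[3, ]
  total <- m$intercept +
    sum(vapply(c("P2", "P1", "P3p"), function(p) {
      prof <- position_contribution(m, p)
      prof$delta[prof$residue == w[[p]]]
    }, 0.0))
  expect_equal(total, predict(m, w), tolerance = 1e-9)
  expect_error(position_contribution(m, "P9"), "not in model")
  # constant-scale feature gives a flat profile
  const <- descriptor_table("CONST",
                            stats::setNames(rep(1, 20), aa_alphabet()),
                            "molecular")
  m_const <- m
  m_const$feature_spec <- calpainqsar:::as_feature_spec("P2", "CONST")
  m_const$tables <- dplyr::bind_rows(lib$tables, const)
  m_const$coefficients <- c(P2_CONST = 5)
  prof <- position_contribution(m_const, "P2")
  expect_equal(attr(prof, "range"), 0)
})

test_that("paired-feature contributions average over partner residues", {
  tabs <- example_descriptor_tables()
  spec <- calpainqsar:::as_feature_spec(list(c("P3p", "P4p")), "SYNTH001")
  lib <- toy_library(n_peptides = 8, seed = 73)
  X <- calpainqsar:::featurize_spec(lib$windows, spec, tabs)
  set.seed(6)
  y <- 100 - 8.6 * X[, 1] + rnorm(nrow(X))
  m <- fit_pls_qsar(NULL, y, spec, tabs, X = X)
  prof <- position_contribution(m, "P3p")
  vals <- calpainqsar:::descriptor_values(tabs, "SYNTH001")
  coefficient <- unname(m$coefficients[1])
  # brute force: average the pair term over the 20 partner residues
  brute <- vapply(aa_alphabet(), function(a) {
    mean(vapply(aa_alphabet(), function(b) {
      coefficient * (vals[[a]] + vals[[b]])
    }, 0.0))
  }, 0.0)
  expect_equal(prof$delta, unname(brute), tolerance = 1e-9)
})

test_that("subsequence scores obey additivity", {
  tabs <- example_descriptor_tables()
  spec <- calpainqsar:::as_feature_spec(
    list("P2", "P1", c("P1", "P1p")),
    c("KYTJ820101", "SYNTH001", "SYNTH002"))
  lib <- toy_library(n_peptides = 8, seed = 75)
  X <- calpainqsar:::featurize_spec(lib$windows, spec, tabs)
  set.seed(8)
  y <- 300 + drop(X %*% c(30, -12, 7)) + rnorm(nrow(X))
  m <- fit_pls_qsar(NULL, y, spec, tabs, X = X)
  # exhaustive maximum over P2 x P1 dipeptides equals per-position argmax
  combos <- expand.grid(P2 = aa_alphabet(), P1 = aa_alphabet(),
                        stringsAsFactors = FALSE)
  scores <- vapply(seq_len(nrow(combos)), function(i) {
    score_subsequence(m, c(P2 = combos$P2[i], P1 = combos$P1[i]))
  }, 0.0)
  best_p2 <- aa_alphabet()[which.max(vapply(aa_alphabet(), function(a) {
    score_subsequence(m, c(P2 = a, P1 = "A"))
  }, 0.0))]
  best_p1 <- aa_alphabet()[which.max(vapply(aa_alphabet(), function(a) {
    score_subsequence(m, c(P2 = "A", P1 = a))
  }, 0.0))]
  expect_equal(max(scores),
               score_subsequence(m, c(P2 = best_p2, P1 = best_p1)))
  expect_error(score_subsequence(m, c(P9 = "A")), "excludes every")
})

test_that("regression evaluation matches hand computation and a LOO loop", {
  pred <- c(1.2, 2.1, 2.9, 4.3, 5.1)
  meas <- c(1.0, 2.0, 3.0, 4.0, 5.0)
  ev <- evaluate_regression(pred, meas)
  fit <- stats::lm(pred ~ meas)
  expect_equal(ev$r, stats::cor(pred, meas))
  expect_equal(ev$slope, unname(coef(fit)[2]))
  expect_equal(ev$intercept, unname(coef(fit)[1]))
  loo <- vapply(1:5, function(i) {
    f <- stats::lm(pred[-i] ~ meas[-i])
    unname(coef(f)[1] + coef(f)[2] * meas[i])
  }, 0.0)
  expect_equal(ev$xr, stats::cor(loo, pred), tolerance = 1e-12)
  ident <- evaluate_regression(meas, meas)
  expect_equal(ident$r, 1)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_error(evaluate_regression(rep(1, 5), meas), "zero variance")
})

test_that("PLS backward selection keeps a perfect predictor", {
  lib <- toy_library(n_peptides = 8, seed = 77)
  spec <- calpainqsar:::as_feature_spec("P2", "KYTJ820101")
  X <- calpainqsar:::featurize_spec(lib$windows, spec, lib$tables)
  y <- 10 + 3 * X[, 1]
  traj <- backward_select_pls(X, y, floor = 0.6)
  expect_equal(nrow(traj$steps), 1)
  expect_true(traj$floor_met)
})

test_that("PLS backward selection recovers planted signal features", {
  hits <- 0L
  for (seed in 1:3) {
    tabs <- example_descriptor_tables(n_synthetic = 7)
    peps <- generate_peptides(16, seed = 500 + seed)
    w <- enumerate_windows(peps, complete_range = 6)
    spec <- calpainqsar:::as_feature_spec(
      c("P2", "P1", "P3p", "P4", "P5", "P2p", "P6"),
      c("KYTJ820101", "SYNTH001", "SYNTH002", "SYNTH003", "SYNTH004",
        "SYNTH005", "SYNTH006"))
    X <- calpainqsar:::featurize_spec(w, spec, tabs)
    set.seed(600 + seed)
    # equal per-feature contributions: dropping any one planted feature
    # must push the cross-validated r^2 below the 0.6 floor
    Xs <- scale(X[, 1:3])
    signal <- drop(Xs %*% c(50, -50, 50))
    # noise sized so the three-feature fit cross-validates near 0.75 but
    # any two-feature subset falls near 0.5, below the floor
    y <- 300 + signal + rnorm(nrow(X), sd = 50)
    traj <- backward_select_pls(X, y, floor = 0.6)
    planted <- c("P2_KYTJ820101", "P1_SYNTH001", "P3p_SYNTH002")
    if (all(planted %in% traj$chosen_features)) hits <- hits + 1L
  }
  expect_gte(hits, 2)
})

test_that("PLS models survive a JSON round-trip", {
  lib <- toy_library(n_peptides = 8, seed = 79)
  spec <- calpainqsar:::as_feature_spec(
    list("P2", c("P2", "P1")), c("KYTJ820101", "SYNTH001"))
  X <- calpainqsar:::featurize_spec(lib$windows, spec, lib$tables)
  set.seed(2)
  y <- 100 + drop(X %*% c(8, -3)) + rnorm(nrow(X))
  m <- fit_pls_qsar(NULL, y, spec, lib$tables, X = X)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(predict(m2, lib$windows[1:8, ]),
               predict(m, lib$windows[1:8, ]), tolerance = 1e-9)
})
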