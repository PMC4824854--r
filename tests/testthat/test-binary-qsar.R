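bq_matrix <- function(n_pos, n_neg, pos_rate, neg_rate) {
  # deterministic one-binary-feature data with exact class-conditional rates
  x <- c(rep(1, round(n_pos * pos_rate)), rep(0, n_pos - round(n_pos * pos_rate)),
         rep(1, round(n_neg * neg_rate)), rep(0, n_neg - round(n_neg * neg_rate)))
  y <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  list(X = matrix(x, ncol = 1, dimnames = list(NULL, "f1")), y = y)
}

test_that("one binary feature reproduces the closed-form Bayes posterior", {
  # prior 0.4, P(x=1|cleaved)=0.9, P(x=1|uncleaved)=0.2 -> P(cleaved|x=1)=0.75
  d <- bq_matrix(400, 600, 0.9, 0.2)
  fit <- calpainqsar:::.bq_fit(d$X, d$y, n_components = 1, bins = 2,
                               smoothing = 0.5)
  post1 <- calpainqsar:::.bq_predict(fit, matrix(1, 1, 1))
  post0 <- calpainqsar:::.bq_predict(fit, matrix(0, 1, 1))
  closed1 <- 0.4 * 0.9 / (0.4 * 0.9 + 0.6 * 0.2)
  closed0 <- 0.4 * 0.1 / (0.4 * 0.1 + 0.6 * 0.8)
  expect_equal(post1, closed1, tolerance = 0.01)
  expect_equal(post0, closed0, tolerance = 0.01)
})

test_that("a perfectly separating feature trains and cross-validates to 1", {
  x <- c(seq(-2, -0.1, length.out = 25), seq(0.1, 2, length.out = 25))
  y <- x > 0
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "f1"))
  fit <- calpainqsar:::.bq_fit(X, y)
  pr <- calpainqsar:::.bq_predict(fit, X)
  expect_equal(mean((pr >= 0.5) == y), 1)
  expect_equal(loo_binary_accuracy(X, y)$accuracy, 1)
})

test_that("the leave-one-out routine equals a literal n-refit loop", {
  lib <- toy_library(n_peptides = 3, seed = 21)
  w <- lib$windows[1:12, ]
  spec <- calpainqsar:::as_feature_spec(c("P2", "P1"),
                                        c("KYTJ820101", "SYNTH001"))
  X <- calpainqsar:::featurize_spec(w, spec, lib$tables)
  y <- w$label
  got <- loo_binary_accuracy(X, y)
  manual <- vapply(seq_along(y), function(i) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) return(mean(ytr))
    m <- fit_binary_qsar(NULL, ytr, spec, lib$tables,
                         X = X[-i, , drop = FALSE])
    predict(m, X = X[i, , drop = FALSE])
  }, 0.0)
  expect_equal(got$probabilities, manual, tolerance = 1e-12)
  expect_equal(got$accuracy, mean((manual >= 0.5) == y))
})

test_that("label-shuffled data cross-validates near the majority rate", {
  lib <- toy_library(n_peptides = 56, seed = 23)
  w <- lib$windows[1:500, ]
  spec <- calpainqsar:::as_feature_spec(c("P2", "P1"),
                                        c("KYTJ820101", "SYNTH001"))
  X <- calpainqsar:::featurize_spec(w, spec, lib$tables)
  set.seed(77)
  y_shuffled <- sample(w$label)
  xa <- loo_binary_accuracy(X, y_shuffled)$accuracy
  majority <- max(mean(y_shuffled), 1 - mean(y_shuffled))
  expect_lt(abs(xa - majority), 0.03 + 1e-9)
})

test_that("single-class training input is rejected", {
  X <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "f1"))
  expect_error(calpainqsar:::.bq_fit(X, rep(TRUE, 20)), "both classes")
  expect_error(calpainqsar:::.bq_fit(X[1:3, , drop = FALSE],
                                     c(TRUE, FALSE, TRUE),
                                     n_components = 5),
               "fewer rows")
})

test_that("confusion-matrix metrics follow their definitions", {
  # TP=3, FP=1, TN=2, FN=2 by construction
  probs <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.1, 0.3, 0.4)
  labs <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  ev <- evaluate_classification(probs, labs, threshold = 0.5)
  expect_equal(ev$TP, 3); expect_equal(ev$FP, 1)
  expect_equal(ev$TN, 2); expect_equal(ev$FN, 2)
  expect_equal(ev$sensitivity, 0.6)
  expect_equal(ev$specificity, 2 / 3)
  expect_equal(ev$ppv, 0.75)
  expect_equal(ev$accuracy, 0.625)
  expect_error(evaluate_classification(numeric(), logical()), "empty")
})

test_that("metric identities hold over random confusion compositions", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(4:60, 1)
    labs <- sample(c(TRUE, FALSE), n, replace = TRUE)
    probs <- runif(n)
    th <- runif(1)
    ev <- evaluate_classification(probs, labs, th)
    expect_equal(ev$TP + ev$FN, sum(labs))
    expect_equal(ev$TN + ev$FP, sum(!labs))
    expect_equal(ev$accuracy, (ev$TP + ev$TN) / n)
    if (!is.na(ev$sensitivity))
      expect_equal(ev$sensitivity, ev$TP / (ev$TP + ev$FN))
    if (!is.na(ev$ppv))
      expect_equal(ev$ppv, ev$TP / (ev$TP + ev$FP))
    if (!is.na(ev$npv))
      expect_equal(ev$npv, ev$TN / (ev$TN + ev$FN))
  }
})

test_that("probabilities stay inside (0,1) and ignore affine rescaling", {
  lib <- toy_library(n_peptides = 12, seed = 29)
  w <- lib$windows
  spec <- calpainqsar:::as_feature_spec("P2", "KYTJ820101")
  m1 <- fit_binary_qsar(w, w$label, spec, lib$tables)
  p1 <- predict(m1, w)
  expect_true(all(p1 > 0 & p1 < 1))
  # affine rescale of the descriptor table: z-scoring absorbs it exactly
  tabs2 <- lib$tables
  tabs2[aa_alphabet()] <- 5 * tabs2[aa_alphabet()] + 3
  m2 <- fit_binary_qsar(w, w$label, spec, tabs2)
  expect_equal(predict(m2, w), p1, tolerance = 1e-10)
})

test_that("backward selection discards planted noise features", {
  hits <- 0L
  for (seed in 1:3) {
    lib <- generate_synthetic_library(n_peptides = 45, seed = 100 + seed)
    w <- lib$windows[1:400, ]
    spec <- calpainqsar:::as_feature_spec(
      c("P2", "P1", "P4", "P3p", "P5p"),
      c("KYTJ820101", "KYTJ820101", "SYNTH001", "SYNTH002", "SYNTH003"))
    X <- calpainqsar:::featurize_spec(w, spec, lib$tables)
    traj <- backward_select_binary(X, w$label, floor = 0.7)
    chosen <- traj$chosen_features
    informative <- c("P2_KYTJ820101", "P1_KYTJ820101")
    expect_lte(length(chosen), 3)
    expect_lte(length(setdiff(chosen, informative)), 1)
    if ("P2_KYTJ820101" %in% chosen) hits <- hits + 1L
    expect_true(all(diff(traj$steps$n_features) == -1))
  }
  expect_gte(hits, 2)
})

test_that("a single feature above the floor gives a one-step trajectory", {
  x <- c(seq(-2, -0.1, length.out = 25), seq(0.1, 2, length.out = 25))
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "f1"))
  traj <- backward_select_binary(X, x > 0, floor = 0.7)
  expect_equal(nrow(traj$steps), 1)
  expect_true(traj$floor_met)
  expect_equal(traj$chosen_features, "f1")
})

test_that("an unreachable floor is reported, not silently passed", {
  set.seed(55)
  X <- matrix(rnorm(120), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(TRUE, FALSE), 30)
  traj <- backward_select_binary(X, y, floor = 0.99)
  expect_false(traj$floor_met)
  expect_equal(traj$chosen_step, which.max(traj$steps$criterion))
})

test_that("protein scanning reports a track with unscorable termini", {
  lib <- toy_library(n_peptides = 12, seed = 33)
  spec <- calpainqsar:::as_feature_spec(c("P2", "P1p"),
                                        c("KYTJ820101", "KYTJ820101"))
  m <- fit_binary_qsar(lib$windows, lib$windows$label, spec, lib$tables)
  prot <- generate_peptides(1, length = 60, seed = 8)$sequence
  track <- scan_protein(m, prot, threshold = 0.95)
  expect_equal(nrow(track), 59)  # L - 1 bonds
  # needs P2 (residue bond-1) and P1p (residue bond+1): only bond 1 lacks P2
  expect_true(is.na(track$probability[1]))
  expect_false(anyNA(track$probability[2:59]))
  expect_equal(sum(!is.na(track$probability)), 59 - 1)
  expect_true(all(track$called[which(track$probability >= 0.95)]))
  # homopolymer: constant track wherever scorable
  mono <- scan_protein(m, strrep("A", 30))
  expect_equal(length(unique(stats::na.omit(mono$probability))), 1)
})

test_that("cooperativity counts match brute-force pair counting", {
  lib <- toy_library(n_peptides = 15, seed = 41)
  w <- lib$windows
  tab <- cooperativity_table(w, w$label, residues_a = c("L", "A", "F"),
                             residues_b = c("G", "Q"))
  for (i in seq_len(nrow(tab))) {
    sel <- !is.na(w$P2) & !is.na(w$P1) &
      w$P2 == tab$P2[i] & w$P1 == tab$P1[i]
    expect_equal(tab$n_total[i], sum(sel))
    expect_equal(tab$n_cleaved[i], sum(w$label[sel]))
  }
  empty <- cooperativity_table(w[0, ], logical(0))
  expect_true(all(empty$n_total == 0))
})

test_that("binary models survive a JSON round-trip", {
  lib <- toy_library(n_peptides = 10, seed = 47)
  spec <- calpainqsar:::as_feature_spec(c("P2", "P1"),
                                        c("KYTJ820101", "SYNTH001"))
  m <- fit_binary_qsar(lib$windows, lib$windows$label, spec, lib$tables)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(predict(m2, lib$windows), predict(m, lib$windows),
               tolerance = 1e-9)
})
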