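# Internal Bayes binary-QSAR fit on a plain numeric matrix. The published
# scheme: z-score the features, rotate onto principal components, keep the
# components explaining var_explained of the variance, histogram each
# retained component per class with Laplace-smoothed bin probabilities, and
# combine by naive Bayes with the class prior.
.bq_fit <- function(X, y, n_components = "auto", bins = 10, smoothing = 0.5,
                    var_explained = 0.98) {
  X <- as.matrix(X)
  y <- as.logical(y)
  n <- nrow(X)
  if (length(unique(y)) < 2L) stop("both classes must be present",
                                   call. = FALSE)
  if (anyNA(X)) stop("missing feature values; restrict the window range",
                     call. = FALSE)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  eg <- eigen(crossprod(Xs) / (n - 1), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  keep <- if (identical(n_components, "auto")) {
    max(1L, which(cumsum(ev) / sum(ev) >= var_explained)[1])
  } else {
    k <- as.integer(n_components)
    if (k > n) stop("fewer rows than components", call. = FALSE)
    min(k, ncol(X))
  }
  rot <- eg$vectors[, seq_len(keep), drop = FALSE]
  scores <- Xs %*% rot
  comps <- lapply(seq_len(keep), function(j) {
    s <- scores[, j]
    edges <- seq(min(s), max(s), length.out = bins + 1L)
    if (edges[1] == edges[bins + 1L]) edges <- edges[1] + c(-0.5, 0.5)
    bin <- findInterval(s, edges, all.inside = TRUE)
    nb <- length(edges) - 1L
    cnt_pos <- tabulate(bin[y], nbins = nb)
    cnt_neg <- tabulate(bin[!y], nbins = nb)
    list(edges = edges,
         p_pos = (cnt_pos + smoothing) / (sum(y) + smoothing * nb),
         p_neg = (cnt_neg + smoothing) / (sum(!y) + smoothing * nb))
  })
  list(center = center, scale = scale_, rotation = rot, components = comps,
       prior = mean(y), bins = bins, smoothing = smoothing,
       n_components = keep)
}

.bq_predict <- function(fit, X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("incomplete window: missing feature values",
                     call. = FALSE)
  Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  scores <- Xs %*% fit$rotation
  log_pos <- log(fit$prior)
  log_neg <- log(1 - fit$prior)
  lp <- rep(log_pos, nrow(X))
  ln <- rep(log_neg, nrow(X))
  for (j in seq_along(fit$components)) {
    comp <- fit$components[[j]]
    bin <- findInterval(scores[, j], comp$edges, all.inside = TRUE)
    lp <- lp + log(comp$p_pos[bin])
    ln <- ln + log(comp$p_neg[bin])
  }
  1 / (1 + exp(ln - lp))
}

#' Fit a Bayes binary-QSAR cleavability classifier
#'
#' The classifier z-scores the per-position descriptor features, rotates
#' them onto principal components, retains the leading components (by
#' cumulative explained variance), estimates binned class-conditional
#' densities per component with Laplace smoothing, and combines them by
#' Bayes' rule with the training prevalence as prior. It emits the posterior
#' probability that a window is cleaved. Training labels follow the
#' cut-off convention of the source data: cleaved sequences are coded 1,
#' uncleaved 0, and the 0.5 cut on that coding defines the positive class.
#'
#' @param windows Window tibble (or \code{NULL} when \code{X} is supplied).
#' @param labels Logical (or 0/1) vector: cleaved or not.
#' @param feature_spec Feature specification ([as_feature_spec()]).
#' @param tables Descriptor tibble.
#' @param n_components \code{"auto"} (retain components up to
#'   \code{var_explained} cumulative variance) or an integer.
#' @param bins Histogram bins per component (default 10).
#' @param smoothing Pseudo-count per bin (default 0.5).
#' @param var_explained Cumulative variance retained under \code{"auto"}
#'   (default 0.98).
#' @param X Optional precomputed feature matrix.
#' @param ss Optional secondary-structure sidecar ([featurize()]).
#' @return A \code{binary_qsar} object.
#' @export
fit_binary_qsar <- function(windows, labels, feature_spec, tables,
                            n_components = "auto", bins = 10,
                            smoothing = 0.5, var_explained = 0.98,
                            X = NULL, ss = NULL) {
  if (is.null(X)) X <- featurize_spec(windows, feature_spec, tables, ss = ss)
  labels <- as.logical(labels)
  fit <- .bq_fit(X, labels, n_components, bins, smoothing, var_explained)
  structure(c(fit, list(feature_spec = feature_spec,
                        feature_names = colnames(X), tables = tables,
                        threshold = 0.5)),
            class = "binary_qsar")
}

#' Predict cleavage probability
#'
#' @param object A \code{binary_qsar} model.
#' @param windows Window tibble; every model position must be present and
#'   non-missing (an incomplete window is an error).
#' @param X Optional precomputed feature matrix.
#' @param ss Optional secondary-structure sidecar.
#' @param ... Unused.
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
predict.binary_qsar <- function(object, windows = NULL, X = NULL, ss = NULL,
                                ...) {
  if (is.null(X)) {
    X <- featurize_spec(windows, object$feature_spec, object$tables,
                        ss = ss)
  }
  .bq_predict(object, X)
}

#' Leave-one-out cross-validated classification accuracy (XA)
#'
#' Refits the classifier on n - 1 rows and classifies the held-out row at
#' threshold 0.5, for every row in turn. If a fold's training set collapses
#' to a single class, the held-out row is predicted from the training
#' prior. Deterministic given the inputs.
#'
#' @param X Feature matrix.
#' @param labels Logical (or 0/1) vector.
#' @param ... Fit configuration passed to the classifier
#'   (\code{n_components}, \code{bins}, \code{smoothing},
#'   \code{var_explained}).
#' @param threshold Classification threshold (default 0.5).
#' @return List: \code{accuracy} (XA), \code{sensitivity},
#'   \code{specificity}, and the per-fold \code{probabilities}.
#' @export
loo_binary_accuracy <- function(X, labels, ..., threshold = 0.5) {
  X <- as.matrix(X)
  y <- as.logical(labels)
  n <- length(y)
  stopifnot(n >= 10L, nrow(X) == n)
  prob <- vapply(seq_len(n), function(i) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) return(mean(ytr))
    fit <- .bq_fit(X[-i, , drop = FALSE], ytr, ...)
    .bq_predict(fit, X[i, , drop = FALSE])
  }, 0.0)
  called <- prob >= threshold
  list(accuracy = mean(called == y),
       sensitivity = if (any(y)) mean(called[y]) else NA_real_,
       specificity = if (any(!y)) mean(!called[!y]) else NA_real_,
       probabilities = prob)
}

#' Classification performance at a threshold
#'
#' Confusion counts and the five derived proportions: sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), positive predictive value TP/(TP+FP),
#' negative predictive value TN/(TN+FN), accuracy (TP+TN)/total.
#'
#' @param probabilities Predicted probabilities.
#' @param labels True labels (logical or 0/1).
#' @param threshold Probability at or above which a site is called cleaved.
#' @return One-row tibble of counts and proportions.
#' @export
evaluate_classification <- function(probabilities, labels, threshold = 0.5) {
  stopifnot(length(probabilities) == length(labels))
  if (!length(labels)) stop("empty input", call. = FALSE)
  y <- as.logical(labels)
  called <- probabilities >= threshold
  tp <- sum(called & y)
  fp <- sum(called & !y)
  tn <- sum(!called & !y)
  fn <- sum(!called & y)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble::tibble(threshold = threshold, TP = tp, FP = fp, TN = tn, FN = fn,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp),
                 npv = ratio(tn, tn + fn),
                 accuracy = (tp + tn) / length(y))
}

#' Performance as a function of classification threshold
#'
#' @inheritParams evaluate_classification
#' @param thresholds Thresholds to sweep.
#' @return A \code{performance_curve} tibble, one row per threshold.
#' @export
performance_curve <- function(probabilities, labels,
                              thresholds = seq(0, 1, by = 0.01)) {
  out <- purrr::map_dfr(thresholds,
                        function(th) evaluate_classification(probabilities,
                                                             labels, th))
  class(out) <- c("performance_curve", class(out))
  out
}

#' Scan a protein for predicted cleavage sites
#'
#' Slides the model across every peptide bond of a protein: bonds whose
#' window covers all model positions get a cleavage probability, bonds too
#' close to a terminus are reported unscorable. Sites at or above the
#' (deliberately strict) threshold are called cleavable.
#'
#' @param model A \code{binary_qsar} model.
#' @param sequence Protein sequence (single string) or a one-row tibble from
#'   [read_fasta()].
#' @param threshold Call threshold (default 0.95, the high-confidence mode).
#' @param ss Optional secondary-structure sidecar for the protein.
#' @param id Protein identifier for the output.
#' @return A \code{scan_track} tibble: \code{bond_after}, \code{p1}
#'   (residue N-terminal to the bond), \code{probability} (NA when
#'   unscorable), \code{called}.
#' @export
scan_protein <- function(model, sequence, threshold = 0.95, ss = NULL,
                         id = "protein") {
  if (is.data.frame(sequence)) {
    id <- sequence$peptide_id[1] %||% id
    sequence <- sequence$sequence[1]
  }
  check_sequence(sequence)
  L <- nchar(sequence)
  needed <- unique(unlist(model$feature_spec$positions))
  flank <- max(as.integer(sub("^P(\\d+)p?$", "\\1", needed)))
  prot <- tibble::tibble(peptide_id = id, sequence = sequence)
  windows <- enumerate_windows(prot, flank = max(flank, 1))
  complete <- !Reduce(`|`, lapply(needed, function(p) is.na(windows[[p]])))
  prob <- rep(NA_real_, nrow(windows))
  if (any(complete)) {
    prob[complete] <- predict(model, windows[complete, , drop = FALSE],
                              ss = ss)
  }
  out <- tibble::tibble(bond_after = windows$bond_after,
                        p1 = windows$P1,
                        probability = prob,
                        called = !is.na(prob) & prob >= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "id") <- id
  class(out) <- c("scan_track", class(out))
  out
}

#' Cleaved/total counts for pairs of residues at two positions
#'
#' Tallies, for each combination of residues at two window positions
#' (classically P2 and P1), how many library windows carry that pair and how
#' many of them were cleaved — the direct, model-free readout of
#' between-position cooperativity.
#'
#' @param windows Window tibble.
#' @param labels Logical cleaved/uncleaved labels, one per window.
#' @param position_a,position_b The two positions (defaults P2, P1).
#' @param residues_a,residues_b Residue subsets to tabulate (default: all
#'   20).
#' @return Tibble: residue pair, \code{n_cleaved}, \code{n_total}.
#' @export
cooperativity_table <- function(windows, labels, position_a = "P2",
                                position_b = "P1",
                                residues_a = aa_alphabet(),
                                residues_b = aa_alphabet()) {
  stopifnot(length(labels) == nrow(windows))
  y <- as.logical(labels)
  grid <- tidyr::expand_grid(!!position_a := residues_a,
                             !!position_b := residues_b)
  a <- windows[[position_a]]
  b <- windows[[position_b]]
  purrr::pmap_dfr(grid, function(...) {
    pair <- list(...)
    sel <- !is.na(a) & !is.na(b) & a == pair[[1]] & b == pair[[2]]
    tibble::tibble(!!position_a := pair[[1]], !!position_b := pair[[2]],
                   n_cleaved = sum(y[sel]), n_total = sum(sel))
  })
}
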