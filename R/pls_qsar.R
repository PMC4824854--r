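# NIPALS partial least squares on centered data. Returns coefficients on
# the original predictor scale plus an intercept. With ncomp equal to the
# rank of X the fit coincides with ordinary least squares.
.pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncomp >= 1)
  xm <- colMeans(X)
  ym <- mean(y)
  E <- sweep(X, 2, xm)
  f <- y - ym
  p <- ncol(X)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  actual <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- drop(crossprod(E, t_)) / tt
    q_ <- sum(t_ * f) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q_ * t_
    W[, a] <- w
    P[, a] <- p_
    Q[a] <- q_
    Tm[, a] <- t_
    actual <- a
  }
  if (actual == 0L) stop("no usable latent component (zero-variance input)",
                         call. = FALSE)
  W <- W[, seq_len(actual), drop = FALSE]
  P <- P[, seq_len(actual), drop = FALSE]
  Q <- Q[seq_len(actual)]
  # beta = W (P'W)^-1 q
  beta <- drop(W %*% solve(crossprod(P, W), Q))
  list(coefficients = beta, intercept = ym - sum(xm * beta),
       n_components = actual, x_means = xm, y_mean = ym)
}

.pls_predict <- function(fit, X) {
  drop(as.matrix(X) %*% fit$coefficients) + fit$intercept
}

# Leave-one-out cross-validated r^2 (1 - PRESS/SS) for a given component
# count; refits per fold.
.pls_loo_xr2 <- function(X, y, ncomp) {
  n <- length(y)
  pred <- vapply(seq_len(n), function(i) {
    fit <- .pls_fit(X[-i, , drop = FALSE], y[-i], ncomp)
    .pls_predict(fit, X[i, , drop = FALSE])
  }, 0.0)
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Fit a partial-least-squares model of catalytic efficiency
#'
#' Regresses kcat/Km (M^-1 s^-1, raw scale) on per-position descriptor
#' features by NIPALS partial least squares. The number of latent components
#' is chosen, when \code{n_components = "auto"}, by maximizing the
#' leave-one-out cross-validated r^2 (Xr^2) up to \code{min(8, rank)};
#' at full rank the coefficients equal the ordinary-least-squares solution.
#' Features may sit at a single position (e.g. P10) or a paired position
#' (e.g. P2-P1), in which case the feature value is the sum of the
#' descriptor at the two member positions.
#'
#' @param windows Window tibble, or \code{NULL} if \code{X} is given.
#' @param response Numeric kcat/Km values, one per row.
#' @param feature_spec Tibble with list-column \code{positions} (1 or 2
#'   labels per feature) and \code{descriptor_id}; see [as_feature_spec()].
#' @param tables Descriptor tibble resolving every feature.
#' @param n_components \code{"auto"} or an integer.
#' @param X Optional precomputed feature matrix (then \code{windows},
#'   \code{feature_spec}, \code{tables} describe it but are not evaluated).
#' @param ss Optional secondary-structure sidecar, see [featurize()].
#' @return A \code{pls_qsar} object: coefficients per feature, intercept,
#'   component count, training diagnostics (\code{r2}, \code{xr2}), and the
#'   tables needed to predict from windows.
#' @export
fit_pls_qsar <- function(windows, response, feature_spec, tables,
                         n_components = "auto", X = NULL, ss = NULL) {
  if (is.null(X)) {
    X <- featurize_spec(windows, feature_spec, tables, ss = ss)
  }
  X <- as.matrix(X)
  y <- as.numeric(response)
  stopifnot(nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) stop("missing values in features or response",
                                 call. = FALSE)
  if (nrow(X) < ncol(X) + 2L) stop("need at least p + 2 rows", call. = FALSE)
  rank <- qr(sweep(X, 2, colMeans(X)))$rank
  if (rank < 1L) stop("zero usable components: all features constant",
                      call. = FALSE)
  cap <- min(8L, rank)
  if (identical(n_components, "auto")) {
    xr2 <- vapply(seq_len(cap), function(a) .pls_loo_xr2(X, y, a), 0.0)
    ncomp <- which.max(xr2)
  } else {
    ncomp <- min(as.integer(n_components), cap)
  }
  fit <- .pls_fit(X, y, ncomp)
  fitted <- .pls_predict(fit, X)
  structure(list(
    feature_spec = feature_spec,
    feature_names = colnames(X),
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    intercept = fit$intercept,
    n_components = fit$n_components,
    tables = tables,
    excluded_outliers = character(),
    fitted = fitted, response = y,
    r2 = stats::cor(fitted, y)^2,
    xr2 = .pls_loo_xr2(X, y, fit$n_components),
    X = X
  ), class = "pls_qsar")
}

#' Flag outliers, exclude them and refit once
#'
#' Rows whose standardized residual exceeds 2.5 in absolute value are
#' flagged, removed, and the model refit once on the remainder. If more
#' than \code{max_fraction} of rows are flagged the refit is refused.
#'
#' @param model A \code{pls_qsar} object.
#' @param threshold Standardized-residual threshold (default 2.5).
#' @param max_fraction Refuse if more rows than this fraction are flagged
#'   (default 0.2).
#' @return A refit \code{pls_qsar} with \code{excluded_outliers} recorded;
#'   if nothing is flagged the model is returned unchanged.
#' @export
exclude_outliers_and_refit <- function(model, threshold = 2.5,
                                       max_fraction = 0.2) {
  stopifnot(inherits(model, "pls_qsar"))
  resid <- model$response - model$fitted
  std <- resid / stats::sd(resid)
  flagged <- which(abs(std) > threshold)
  if (!length(flagged)) return(model)
  if (length(flagged) > max_fraction * length(resid)) {
    stop(length(flagged), " of ", length(resid),
         " rows flagged as outliers; refusing to refit", call. = FALSE)
  }
  keep <- setdiff(seq_along(resid), flagged)
  refit <- fit_pls_qsar(NULL, model$response[keep], model$feature_spec,
                        model$tables, n_components = model$n_components,
                        X = model$X[keep, , drop = FALSE])
  refit$excluded_outliers <- rownames(model$X)[flagged] %||%
    as.character(flagged)
  refit
}

#' Predict kcat/Km for cleavage-site windows
#'
#' \code{intercept + sum(coefficient * feature value)}; units M^-1 s^-1.
#' A missing residue at a single-position feature is an error; a missing
#' member of a paired feature is marginalized by the uniform 20-residue
#' average of the descriptor at that position.
#'
#' @param object A \code{pls_qsar} model.
#' @param windows Window tibble (or a feature matrix via \code{X}).
#' @param X Optional precomputed feature matrix.
#' @param ss Optional secondary-structure sidecar.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_qsar <- function(object, windows = NULL, X = NULL, ss = NULL,
                             ...) {
  if (is.null(X)) {
    spec <- object$feature_spec
    cols <- lapply(seq_len(nrow(spec)), function(i) {
      posns <- spec$positions[[i]]
      id <- spec$descriptor_id[i]
      vals <- descriptor_values(object$tables, id)
      part <- lapply(posns, function(p) {
        res <- windows[[p]]
        if (is.null(res)) stop("windows lack position ", p, call. = FALSE)
        v <- vals[res]
        if (length(posns) == 1L && anyNA(v)) {
          stop("incomplete window: missing residue at ", p, call. = FALSE)
        }
        v[is.na(v)] <- mean(vals)  # paired-feature marginalization
        unname(v)
      })
      Reduce(`+`, part)
    })
    X <- do.call(cbind, cols)
    colnames(X) <- object$feature_names
  }
  drop(as.matrix(X) %*% object$coefficients) + object$intercept
}

#' Per-residue contribution of one position to predicted kcat/Km
#'
#' Evaluates, for each of the 20 residues placed at \code{position}, the
#' summed contribution of every model feature involving that position;
#' paired-position partners are averaged uniformly over the 20 residues.
#' The profile is intercept-free (differences between residues are exactly
#' differences of full-window predictions).
#'
#' @param model A \code{pls_qsar} model.
#' @param position Position label appearing in at least one model feature.
#' @return A \code{contribution_profile} tibble: \code{residue},
#'   \code{delta}; attribute \code{range} = max - min.
#' @export
position_contribution <- function(model, position) {
  spec <- model$feature_spec
  involved <- vapply(spec$positions, function(p) position %in% p, TRUE)
  if (!any(involved)) stop("position ", position, " not in model",
                           call. = FALSE)
  delta <- stats::setNames(numeric(20), aa_alphabet())
  for (i in which(involved)) {
    vals <- descriptor_values(model$tables, spec$descriptor_id[i])
    coeff <- model$coefficients[i]
    partners <- setdiff(spec$positions[[i]], position)
    partner_term <- length(partners) * mean(vals)
    delta <- delta + coeff * (vals[aa_alphabet()] + partner_term)
  }
  out <- tibble::tibble(residue = aa_alphabet(), delta = unname(delta))
  attr(out, "range") <- max(out$delta) - min(out$delta)
  class(out) <- c("contribution_profile", class(out))
  out
}

#' Score a partial cleavage-site sequence
#'
#' Sums the contributions of all model features over a restricted position
#' range (e.g. score the hexapeptide P3-P3'): features wholly inside the
#' range use the specified residues; out-of-range members of paired
#' features, and out-of-range single-position features, are replaced by the
#' uniform 20-residue average of their descriptor, so scores are comparable
#' across subsequences of the same range. The intercept is included so the
#' score is on the kcat/Km scale.
#'
#' @param model A \code{pls_qsar} model.
#' @param residues Named character vector, e.g.
#'   \code{c(P3 = "P", P2 = "L", P1 = "F", P1p = "A", P2p = "E", P3p = "R")};
#'   every in-range position used by the model must be present.
#' @param include_intercept Include the model intercept (default TRUE).
#' @return Scalar score in M^-1 s^-1.
#' @export
score_subsequence <- function(model, residues, include_intercept = TRUE) {
  spec <- model$feature_spec
  in_range <- names(residues)
  any_used <- FALSE
  total <- if (include_intercept) model$intercept else 0
  for (i in seq_len(nrow(spec))) {
    vals <- descriptor_values(model$tables, spec$descriptor_id[i])
    term <- 0
    touches <- FALSE
    for (p in spec$positions[[i]]) {
      if (p %in% in_range) {
        res <- residues[[p]]
        if (!res %in% aa_alphabet()) {
          stop("invalid residue '", res, "' at ", p, call. = FALSE)
        }
        term <- term + vals[[res]]
        touches <- TRUE
      } else {
        term <- term + mean(vals)
      }
    }
    any_used <- any_used || touches
    total <- total + model$coefficients[i] * term
  }
  if (!any_used) stop("range excludes every model feature", call. = FALSE)
  unname(total)
}

#' Agreement between predicted and measured values
#'
#' Pearson r, its leave-one-out analogue Xr (the correlation between the
#' measurements and the leave-one-out predictions of the simple linear
#' calibration of predicted on measured), and the least-squares line of
#' predicted on measured.
#'
#' @param predictions,measurements Paired numeric vectors, n >= 3.
#' @return Tibble: \code{r}, \code{xr}, \code{slope}, \code{intercept},
#'   \code{n}.
#' @export
evaluate_regression <- function(predictions, measurements) {
  n <- length(predictions)
  stopifnot(n >= 3L, length(measurements) == n)
  if (stats::sd(predictions) == 0 || stats::sd(measurements) == 0) {
    stop("zero variance", call. = FALSE)
  }
  fit <- stats::lm(predictions ~ measurements)
  # leave-one-out prediction of the calibration line via the hat matrix
  h <- stats::lm.influence(fit)$hat
  loo_pred <- stats::fitted(fit) - h * stats::residuals(fit) / (1 - h)
  tibble::tibble(
    r = stats::cor(predictions, measurements),
    xr = stats::cor(loo_pred, predictions),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = n
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
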