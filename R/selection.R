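# Greedy backward elimination over a feature matrix: at each step the
# feature whose removal maximizes the criterion is dropped (ties broken by
# column order). Returns the full trajectory; the chosen step is the
# smallest feature set whose criterion exceeds the floor, or the
# best-criterion step flagged `floor_met = FALSE` when none does.
.backward_select <- function(X, y, criterion, floor) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 1L)
  current <- colnames(X)
  steps <- tibble::tibble(
    step = 1L,
    features = list(current),
    n_features = length(current),
    criterion = criterion(X[, current, drop = FALSE], y)
  )
  while (length(current) > 1L) {
    scores <- vapply(seq_along(current), function(j) {
      criterion(X[, current[-j], drop = FALSE], y)
    }, 0.0)
    drop_j <- which.max(scores)  # first maximum: deterministic tie-break
    current <- current[-drop_j]
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      step = nrow(steps) + 1L,
      features = list(current),
      n_features = length(current),
      criterion = scores[drop_j]
    ))
  }
  above <- which(steps$criterion > floor)
  if (length(above)) {
    chosen <- above[which.max(steps$step[above])]  # smallest feature set
    floor_met <- TRUE
  } else {
    chosen <- which.max(steps$criterion)
    floor_met <- FALSE
  }
  structure(list(steps = steps, chosen_step = chosen, floor = floor,
                 floor_met = floor_met,
                 chosen_features = steps$features[[chosen]]),
            class = "selection_trajectory")
}

#' Backward feature elimination for the binary-QSAR classifier
#'
#' Greedy backward elimination with leave-one-out cross-validated accuracy
#' (XA) as the criterion: the chosen model is the smallest feature set with
#' XA above the floor (default 0.7) and, among candidate removals at one
#' step, the one giving the higher criterion (deterministic ordering breaks
#' exact ties). If no step clears the floor the best step is returned
#' flagged \code{floor_met = FALSE}.
#'
#' @param X Feature matrix with named columns.
#' @param labels Logical cleaved/uncleaved labels.
#' @param floor Minimum acceptable XA (default 0.7).
#' @param ... Fit configuration forwarded to the classifier.
#' @return A \code{selection_trajectory}.
#' @export
backward_select_binary <- function(X, labels, floor = 0.7, ...) {
  crit <- function(Xs, y) loo_binary_accuracy(Xs, y, ...)$accuracy
  .backward_select(X, as.logical(labels), crit, floor)
}

#' Backward feature elimination for the PLS efficiency model
#'
#' As [backward_select_binary()] but the criterion is the leave-one-out
#' cross-validated r^2 (Xr^2) of the partial-least-squares fit, with floor
#' 0.6.
#'
#' @param X Feature matrix with named columns.
#' @param response Numeric kcat/Km values.
#' @param floor Minimum acceptable Xr^2 (default 0.6).
#' @param n_components Component count per fit (\code{"auto"} uses the
#'   matrix rank capped at 8; an integer fixes it).
#' @return A \code{selection_trajectory}.
#' @export
backward_select_pls <- function(X, response, floor = 0.6,
                                n_components = "auto") {
  crit <- function(Xs, y) {
    rank <- qr(sweep(as.matrix(Xs), 2, colMeans(as.matrix(Xs))))$rank
    if (rank < 1L) return(-Inf)
    ncomp <- if (identical(n_components, "auto")) min(8L, rank) else
      min(as.integer(n_components), rank)
    .pls_loo_xr2(as.matrix(Xs), y, ncomp)
  }
  .backward_select(X, response, crit, floor)
}

#' @export
print.selection_trajectory <- function(x, ...) {
  cat("Backward selection trajectory (", nrow(x$steps), " steps)\n",
      sep = "")
  cat("Chosen step ", x$chosen_step, ": ",
      length(x$chosen_features), " feature(s), criterion ",
      signif(x$steps$criterion[x$chosen_step], 4),
      if (x$floor_met) "" else "  [floor not met]", "\n", sep = "")
  cat("Features: ", paste(x$chosen_features, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
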