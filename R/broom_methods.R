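#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted binary-QSAR model
#'
#' One row per feature with its permutation-style relevance: the drop in
#' training accuracy when that feature column is shuffled (averaged over
#' \code{n_perm} deterministic shuffles). This is an importance analogue,
#' not a reproduction of any proprietary importance statistic.
#'
#' @param x A \code{binary_qsar} object.
#' @param labels Training labels; needed for the relevance column (omit to
#'   skip it).
#' @param X Training feature matrix matching \code{labels}.
#' @param n_perm Shuffles per feature (default 10).
#' @param ... Unused.
#' @return Tibble: \code{position}, \code{descriptor_id}, and optionally
#'   \code{importance}.
#' @export
tidy.binary_qsar <- function(x, labels = NULL, X = NULL, n_perm = 10, ...) {
  out <- tibble::tibble(
    position = vapply(x$feature_spec$positions, paste, "", collapse = "."),
    descriptor_id = x$feature_spec$descriptor_id
  )
  if (!is.null(labels) && !is.null(X)) {
    X <- as.matrix(X)
    y <- as.logical(labels)
    base_acc <- mean((.bq_predict(x, X) >= x$threshold) == y)
    rng <- local_rng(7L)
    out$importance <- vapply(seq_len(ncol(X)), function(j) {
      drops <- vapply(seq_len(n_perm), function(b) {
        Xp <- X
        Xp[, j] <- Xp[rng$sample_int(nrow(X)), j]
        base_acc - mean((.bq_predict(x, Xp) >= x$threshold) == y)
      }, 0.0)
      mean(drops)
    }, 0.0)
  }
  out
}

#' @rdname tidy.binary_qsar
#' @export
glance.binary_qsar <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$feature_spec),
                 n_components = x$n_components,
                 bins = x$bins, smoothing = x$smoothing,
                 prior = x$prior, threshold = x$threshold)
}

#' Tidy a fitted PLS efficiency model
#'
#' One row per feature: its coefficient (on the raw descriptor scale) and
#' the per-feature effect range \code{delta_kcat_km}, the spread of the
#' feature's contribution over the 20 residues (paired positions summed),
#' i.e. how much that term can move the predicted efficiency.
#'
#' @param x A \code{pls_qsar} object.
#' @param ... Unused.
#' @return Tibble: \code{position}, \code{descriptor_id},
#'   \code{coefficient}, \code{delta_kcat_km}.
#' @export
tidy.pls_qsar <- function(x, ...) {
  delta <- vapply(seq_len(nrow(x$feature_spec)), function(i) {
    vals <- descriptor_values(x$tables, x$feature_spec$descriptor_id[i])
    k <- length(x$feature_spec$positions[[i]])
    contrib <- x$coefficients[i] * vals * k
    max(contrib) - min(contrib)
  }, 0.0)
  tibble::tibble(
    position = vapply(x$feature_spec$positions, paste, "", collapse = "."),
    descriptor_id = x$feature_spec$descriptor_id,
    coefficient = unname(x$coefficients),
    delta_kcat_km = delta
  )
}

#' @rdname tidy.pls_qsar
#' @export
glance.pls_qsar <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$feature_spec),
                 n_components = x$n_components,
                 r2 = x$r2, xr2 = x$xr2,
                 n = length(x$response),
                 n_outliers_excluded = length(x$excluded_outliers),
                 intercept = x$intercept)
}

#' @rdname backward_select_binary
#' @param x A \code{selection_trajectory}.
#' @param ... Unused.
#' @export
tidy.selection_trajectory <- function(x, ...) {
  x$steps |>
    dplyr::mutate(features = vapply(.data$features, paste, "",
                                    collapse = ", "),
                  chosen = .data$step == x$chosen_step)
}
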