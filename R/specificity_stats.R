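#' Standard amino-acid composition (Swiss-Prot release 2012_9)
#'
#' Background residue frequencies used to standardize position-specific
#' frequencies into enrichment log-ratios.
#'
#' @return Tibble with columns \code{residue} and \code{proportion}
#'   (fractions summing to 1).
#' @export
standard_aa_composition <- function() {
  pct <- c(A = 8.67, C = 1.26, D = 5.32, E = 6.17, F = 4.01, G = 7.10,
           H = 2.21, I = 5.96, K = 5.25, L = 9.92, M = 2.46, N = 4.09,
           P = 4.71, Q = 3.95, R = 5.46, S = 6.66, T = 5.57, V = 6.77,
           W = 1.30, Y = 3.03)
  tibble::tibble(residue = names(pct), proportion = unname(pct) / 100)
}

#' Position-specific residue frequencies and enrichment log-ratios
#'
#' Tallies the residues occupying each window position and standardizes the
#' observed proportions by a background composition:
#' \code{log_ratio = log10(observed proportion / background proportion)}.
#' A residue that never occurs at a position gets \code{-Inf} as a sentinel
#' (such cells are drawn "not to scale" in logos and excluded pairwise from
#' profile correlations). Missing window positions are excluded from that
#' position's denominator.
#'
#' @param windows Window tibble.
#' @param composition Background composition tibble
#'   (default [standard_aa_composition()]).
#' @param positions Position labels to profile (default: all).
#' @return A \code{frequency_profile} tibble: \code{position},
#'   \code{residue}, \code{count}, \code{n}, \code{proportion},
#'   \code{log_ratio}.
#' @export
frequency_profile <- function(windows, composition = standard_aa_composition(),
                              positions = NULL) {
  if (!nrow(windows)) stop("empty window set", call. = FALSE)
  if (is.null(positions)) {
    positions <- intersect(position_labels(window_flank(windows)),
                           names(windows))
  }
  positions <- order_positions(positions)
  bg <- stats::setNames(composition$proportion, composition$residue)
  prof <- purrr::map_dfr(positions, function(pos) {
    res <- windows[[pos]]
    res <- res[!is.na(res)]
    counts <- table(factor(res, levels = aa_alphabet()))
    tibble::tibble(position = pos, residue = aa_alphabet(),
                   count = as.integer(counts), n = length(res))
  })
  prof <- prof |>
    dplyr::mutate(proportion = ifelse(.data$n > 0, .data$count / .data$n,
                                      NA_real_),
                  log_ratio = log10(.data$proportion /
                                      unname(bg[.data$residue])))
  class(prof) <- c("frequency_profile", class(prof))
  prof
}

#' Correlate two frequency profiles
#'
#' Pearson correlation over the matched (position, residue) cells of two
#' enrichment profiles, with the significance of r assessed by the t-test for
#' a correlation coefficient, \code{t = r * sqrt((n - 2) / (1 - r^2))} on
#' \code{n - 2} degrees of freedom. Cells that are non-finite in either
#' profile (residues absent at a position) are excluded pairwise and counted.
#'
#' @param profile_a,profile_b \code{frequency_profile} objects over the same
#'   positions.
#' @param on Column to correlate: \code{"log_ratio"} (default) or
#'   \code{"proportion"}.
#' @return Tibble: \code{r}, \code{t}, \code{df}, \code{p}, \code{n_used},
#'   \code{n_dropped}.
#' @export
profile_correlation <- function(profile_a, profile_b, on = "log_ratio") {
  joined <- dplyr::inner_join(
    profile_a[c("position", "residue", on)],
    profile_b[c("position", "residue", on)],
    by = c("position", "residue"), suffix = c("_a", "_b")
  )
  a <- joined[[paste0(on, "_a")]]
  b <- joined[[paste0(on, "_b")]]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stop("fewer than 3 shared finite cells", call. = FALSE)
  correlation_t_test(a[ok], b[ok]) |>
    dplyr::mutate(n_dropped = sum(!ok))
}

#' t-test for a Pearson correlation coefficient
#'
#' @param x,y Paired numeric vectors.
#' @return Tibble: \code{r}, \code{t}, \code{df}, \code{p}, \code{n_used}.
#' @export
correlation_t_test <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n)
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  tibble::tibble(r = r, t = tstat, df = n - 2,
                 p = 2 * stats::pt(-abs(tstat), df = n - 2), n_used = n)
}

#' Z-test for the equality of two proportions
#'
#' Pooled-variance two-sample Z test on counts, two-sided normal p-value,
#' without continuity correction: used to compare per-position residue
#' frequencies between the two calpain isoforms.
#'
#' @param x1,n1 Successes and trials in sample 1.
#' @param x2,n2 Successes and trials in sample 2.
#' @return Tibble: \code{p1}, \code{p2}, \code{z}, \code{p}.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble::tibble(p1 = p1, p2 = p2, z = z,
                 p = if (z == 0) 1 else 2 * stats::pnorm(-abs(z)))
}

#' Z-test for one proportion
#'
#' \code{Z = (x/n - p0) / sqrt(p0 (1 - p0) / n)}, two-sided: used to test
#' whether the cleavage frequency at one bond position departs from the
#' uniform-cleavage expectation.
#'
#' @param x,n Successes and trials.
#' @param p0 Null proportion, in (0, 1).
#' @return Tibble: \code{estimate}, \code{z}, \code{p}.
#' @export
one_proportion_z <- function(x, n, p0) {
  stopifnot(n > 0, p0 > 0, p0 < 1, x >= 0, x <= n)
  z <- (x / n - p0) / sqrt(p0 * (1 - p0) / n)
  tibble::tibble(estimate = x / n, z = z,
                 p = ifelse(z == 0, 1, 2 * stats::pnorm(-abs(z))))
}

#' Binomial probability that a residue is entirely absent
#'
#' Probability of observing zero occurrences of a residue with background
#' frequency \code{expected_p} across \code{n_sites} independent sites:
#' \code{(1 - expected_p)^n_sites}. Used to decide whether a residue's
#' absence from a position is itself significant.
#'
#' @param n_sites Number of sites observed.
#' @param expected_p Background frequency of the residue, in (0, 1).
#' @return Probability in (0, 1].
#' @export
absent_residue_binomial <- function(n_sites, expected_p) {
  stopifnot(expected_p > 0, expected_p < 1, n_sites >= 0)
  (1 - expected_p)^n_sites
}

#' Welch's t-test for two means with unequal variances
#'
#' Thin wrapper around [stats::t.test()] (Welch statistic with Satterthwaite
#' degrees of freedom, two-sided), returned tidily.
#'
#' @param sample_a,sample_b Numeric vectors, each of length at least 2.
#' @return Tibble: \code{t}, \code{df}, \code{p}, \code{mean_a},
#'   \code{mean_b}.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2L, length(sample_b) >= 2L)
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    stop("zero variance in both samples", call. = FALSE)
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_a = mean(sample_a),
                 mean_b = mean(sample_b))
}

#' Correlation of catalytic efficiencies between the two calpains
#'
#' Pearson correlation of per-site kcat/Km measured for calpain-1 and
#' calpain-2 on the same cleavage sites.
#'
#' @param estimates A data frame with columns \code{site_id}, \code{enzyme}
#'   and \code{kcat_km} (long form), or a data frame already paired with
#'   columns \code{kcat_km_c1} and \code{kcat_km_c2}.
#' @return List with \code{r} and the paired tibble \code{pairs}.
#' @export
kcat_correlation <- function(estimates) {
  if (all(c("kcat_km_c1", "kcat_km_c2") %in% names(estimates))) {
    pairs <- tibble::as_tibble(estimates)
  } else {
    stopifnot(all(c("site_id", "enzyme", "kcat_km") %in% names(estimates)))
    pairs <- estimates |>
      dplyr::mutate(enzyme = tolower(.data$enzyme)) |>
      tidyr::pivot_wider(id_cols = "site_id", names_from = "enzyme",
                         values_from = "kcat_km", names_prefix = "kcat_km_")
  }
  pairs <- pairs[stats::complete.cases(pairs[c("kcat_km_c1", "kcat_km_c2")]), ]
  if (nrow(pairs) < 3L) stop("fewer than 3 paired sites", call. = FALSE)
  list(r = stats::cor(pairs$kcat_km_c1, pairs$kcat_km_c2), pairs = pairs)
}

#' Cleavage-position bias across an oligopeptide library
#'
#' Counts how often cleavage falls after each residue position in the library
#' peptides and tests each bond against the uniform-cleavage expectation
#' (1 / (L - 1) per bond of a length-L peptide, aggregated over the library;
#' about 5\% per bond for 20-mers) with the one-proportion Z-test.
#'
#' @param sites Data frame with columns \code{peptide_id} and
#'   \code{bond_after} (one row per detected cleavage site).
#' @param peptide_lengths Data frame with columns \code{peptide_id} and
#'   \code{length} for the whole library (cleaved or not).
#' @return Tibble, one row per bond position: \code{bond_after},
#'   \code{count}, \code{observed}, \code{expected}, \code{z}, \code{p}.
#' @export
cleavage_position_bias <- function(sites, peptide_lengths) {
  stopifnot(all(c("peptide_id", "bond_after") %in% names(sites)),
            all(c("peptide_id", "length") %in% names(peptide_lengths)))
  n_sites <- nrow(sites)
  if (!n_sites) stop("empty site set", call. = FALSE)
  max_bond <- max(peptide_lengths$length) - 1L
  # expected share of bond b under uniform within-peptide cleavage,
  # library-weighted: mean over peptides of 1/(L-1) * [b <= L-1]
  expected <- vapply(seq_len(max_bond), function(b) {
    mean(ifelse(peptide_lengths$length - 1L >= b,
                1 / (peptide_lengths$length - 1L), 0))
  }, 0.0)
  expected <- expected / sum(expected)
  counts <- tabulate(sites$bond_after, nbins = max_bond)
  purrr::map_dfr(seq_len(max_bond), function(b) {
    zt <- one_proportion_z(counts[b], n_sites, expected[b])
    tibble::tibble(bond_after = b, count = counts[b],
                   observed = zt$estimate, expected = expected[b],
                   z = zt$z, p = zt$p)
  })
}
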