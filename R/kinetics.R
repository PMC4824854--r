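#' The 8-plex channel design of the multiplexed kinetics assay
#'
#' One digestion per isobaric-label channel, each at a different initial
#' substrate concentration. Channels 114-119 contain enzyme; channel 113 is
#' the no-enzyme full-length reference (10 uM substrate) and channel 121
#' carries the synthetic fragment standards at 5 uM with no substrate.
#'
#' @param enzyme_total Total enzyme concentration \code{[E]_t} in M
#'   (default 2.5e-6).
#' @param reaction_time Reaction time in seconds (default 900).
#' @param standard_conc Fragment-standard concentration in channel 121, M
#'   (default 5e-6).
#' @return A \code{channel_design} list: tibble \code{channels} with columns
#'   \code{channel}, \code{S0} (initial substrate, M), \code{enzyme}
#'   (logical), plus the scalar settings.
#' @export
channel_design <- function(enzyme_total = 2.5e-6, reaction_time = 900,
                           standard_conc = 5e-6) {
  channels <- tibble::tibble(
    channel = c("113", "114", "115", "116", "117", "118", "119", "121"),
    S0 = c(1.0e-5, 2.0e-5, 1.0e-5, 6.7e-6, 5.0e-6, 4.0e-6, 3.3e-6, 0),
    enzyme = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  structure(list(channels = channels, enzyme_total = enzyme_total,
                 reaction_time = reaction_time,
                 standard_conc = standard_conc,
                 reference_channel = "113", standard_channel = "121"),
            class = "channel_design")
}

#' Initial velocity from full-length peptide decay
#'
#' \code{v0 = ([S]0(n) - I_n / I_113 * [S]0(113)) / t}: the amount of
#' full-length (both-termini-capped) peptide consumed in channel n, judged
#' against the no-enzyme reference channel, divided by the reaction time.
#' Under noise the result can be negative; it is returned as-is and the
#' regression step drops (and counts) non-positive velocities.
#'
#' @param i_n Standardized full-length intensity in channel n.
#' @param i_113 Standardized full-length intensity in the no-enzyme
#'   reference channel (must be positive).
#' @param s0_n,s0_113 Initial substrate concentrations (M) of channel n and
#'   the reference channel.
#' @param time Reaction time in seconds (default 900).
#' @return Initial velocity in M/s.
#' @export
v0_full_length <- function(i_n, i_113, s0_n, s0_113, time = 900) {
  if (any(i_113 <= 0)) stop("reference intensity I_113 must be > 0",
                            call. = FALSE)
  (s0_n - i_n / i_113 * s0_113) / time
}

#' Initial velocity from cleaved-fragment formation
#'
#' \code{v0 = I_n / I_121 * standard_conc / t}: fragment formed in channel n
#' quantified against the 5 uM fragment standard in channel 121.
#'
#' @param i_n Standardized fragment intensity in channel n.
#' @param i_121 Standardized fragment-standard intensity (must be positive).
#' @param standard_conc Standard concentration in M (default 5e-6).
#' @inheritParams v0_full_length
#' @return Initial velocity in M/s (non-negative for non-negative input).
#' @export
v0_fragment <- function(i_n, i_121, standard_conc = 5e-6, time = 900) {
  if (any(i_121 <= 0)) stop("standard intensity I_121 must be > 0",
                            call. = FALSE)
  i_n / i_121 * standard_conc / time
}

#' Estimate kcat/Km by Lineweaver-Burk regression
#'
#' Regresses \code{1/v0} on \code{1/[S]0} and converts the slope b to the
#' specificity constant \code{kcat/Km = 1/(b * [E]_t)} (under
#' \code{[S] << Km} the slope is \code{Km / Vmax} so this is exact for
#' Michaelis-Menten data). Points with \code{v0 <= 0} are dropped and
#' counted; fewer than three usable points gives a not-estimable result
#' (\code{NA} value). The standard error is propagated from the slope
#' standard error by the delta method.
#'
#' Two refinements are off by default and used by the recovery pipeline
#' [estimate_kcat_km()]: \code{weighting = "reciprocal"} applies weights
#' \code{v0^2} (the correct variance weighting when intensity noise is
#' multiplicative, under which \code{var(1/v0)} scales with \code{(1/v0)^2});
#' \code{correct_depletion = TRUE} inverts the first-order depletion of an
#' endpoint assay, \code{k = -log(1 - k_app [E]_t t) / ([E]_t t)}, which
#' makes recovery exact on noise-free first-order data even when a large
#' fraction of substrate is consumed.
#'
#' @param s0 Initial substrate concentrations (M).
#' @param v0 Initial velocities (M/s).
#' @param enzyme_total Enzyme concentration \code{[E]_t} (M).
#' @param weighting \code{"none"} (ordinary least squares, default) or
#'   \code{"reciprocal"}.
#' @param correct_depletion Apply the first-order endpoint correction.
#' @param time Reaction time (s); needed only for the depletion correction.
#' @return One-row tibble: \code{value} (M^-1 s^-1), \code{se},
#'   \code{slope}, \code{slope_se}, \code{n_points}, \code{n_dropped},
#'   \code{method}.
#' @export
lineweaver_burk <- function(s0, v0, enzyme_total = 2.5e-6,
                            weighting = c("none", "reciprocal"),
                            correct_depletion = FALSE, time = 900) {
  weighting <- match.arg(weighting)
  stopifnot(length(s0) == length(v0), enzyme_total > 0)
  ok <- is.finite(v0) & v0 > 0 & is.finite(s0) & s0 > 0
  n_dropped <- sum(!ok)
  not_estimable <- tibble::tibble(
    value = NA_real_, se = NA_real_, slope = NA_real_, slope_se = NA_real_,
    n_points = sum(ok), n_dropped = n_dropped, method = "lineweaver_burk")
  if (sum(ok) < 3L) return(not_estimable)
  x <- 1 / s0[ok]
  y <- 1 / v0[ok]
  w <- if (weighting == "reciprocal") 1 / y^2 else rep(1, length(y))
  fit <- stats::lm(y ~ x, weights = w)
  b <- unname(stats::coef(fit)[2])
  b_se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  if (!is.finite(b) || b <= 0) return(not_estimable)
  value <- 1 / (b * enzyme_total)
  se <- b_se / (b^2 * enzyme_total)
  if (correct_depletion) {
    f <- value * enzyme_total * time   # apparent fraction consumed
    if (!is.finite(f) || f <= 0 || f >= 1) return(not_estimable)
    se <- se / (1 - f)
    value <- -log(1 - f) / (enzyme_total * time)
  }
  tibble::tibble(value = value, se = se, slope = b, slope_se = b_se,
                 n_points = sum(ok), n_dropped = n_dropped,
                 method = "lineweaver_burk")
}

#' Estimate kcat/Km by Eadie-Hofstee regression
#'
#' Regresses \code{v0} on \code{v0/[S]0}; the slope is \code{-Km} and the
#' intercept \code{Vmax}, so \code{kcat/Km = -(intercept/slope)/[E]_t}.
#' Provided for comparison with [lineweaver_burk()]; note that strictly
#' first-order data (\code{v0} proportional to \code{[S]0}) make the
#' abscissa constant and the fit degenerate, in which case the result is
#' not estimable.
#'
#' @inheritParams lineweaver_burk
#' @return One-row tibble as in [lineweaver_burk()].
#' @export
eadie_hofstee <- function(s0, v0, enzyme_total = 2.5e-6) {
  stopifnot(length(s0) == length(v0), enzyme_total > 0)
  ok <- is.finite(v0) & v0 > 0 & is.finite(s0) & s0 > 0
  not_estimable <- tibble::tibble(
    value = NA_real_, se = NA_real_, slope = NA_real_, slope_se = NA_real_,
    n_points = sum(ok), n_dropped = sum(!ok), method = "eadie_hofstee")
  if (sum(ok) < 3L) return(not_estimable)
  x <- v0[ok] / s0[ok]
  y <- v0[ok]
  # degenerate shapes: strictly first-order data (constant v0/S0) or a
  # saturated plateau (constant v0) leave the regression uninformative
  if (stats::sd(x) < 1e-12 * mean(x) ||
      stats::sd(y) < 1e-12 * mean(y)) {
    return(not_estimable)
  }
  fit <- stats::lm(y ~ x)
  km <- -unname(stats::coef(fit)[2])
  vmax <- unname(stats::coef(fit)[1])
  if (!is.finite(km) || km <= 0 || vmax <= 0) return(not_estimable)
  # delta-method SE for vmax/km from the coefficient covariance
  vc <- suppressWarnings(stats::vcov(fit))
  grad <- c(1 / km, vmax / km^2)  # d(vmax/km)/d(intercept, slope=-km)
  se_ratio <- sqrt(drop(t(grad) %*% vc %*% grad))
  tibble::tibble(value = vmax / km / enzyme_total,
                 se = se_ratio / enzyme_total,
                 slope = unname(stats::coef(fit)[2]),
                 slope_se = suppressWarnings(summary(fit)$coefficients[2, 2]),
                 n_points = sum(ok), n_dropped = sum(!ok),
                 method = "eadie_hofstee")
}

#' Simulate a multiplexed first-order digestion
#'
#' Generates reporter intensities for one peptide with a single cleavage
#' site of known specificity constant under the channel design: full-length
#' decay \code{S(t) = S0 exp(-k [E] t)} in enzyme channels, the two
#' complementary cleavage fragments accumulating as \code{S0 - S(t)}, the
#' no-enzyme reference and the 5 uM fragment standards, all multiplied by
#' independent log-normal noise of coefficient of variation \code{noise_cv}.
#' Intensities are reported on an arbitrary instrument scale proportional to
#' concentration (already control-standardized).
#'
#' @param true_kcat_km Specificity constant in M^-1 s^-1.
#' @param design A [channel_design()].
#' @param noise_cv Log-normal coefficient of variation (>= 0).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param peptide_id Identifier written into the output.
#' @return Tidy intensity tibble: \code{peptide_id}, \code{species}
#'   (\code{full_length}, \code{fragment_n}, \code{fragment_c}),
#'   \code{channel}, \code{intensity}.
#' @export
simulate_digestion <- function(true_kcat_km, design = channel_design(),
                               noise_cv = 0, seed = 1,
                               peptide_id = "sim") {
  stopifnot(noise_cv >= 0, true_kcat_km >= 0)
  ch <- design$channels
  scale <- 1e8  # arbitrary instrument response per M
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    expr
  }
  withr_seed({
    lnoise <- function(n) {
      if (noise_cv == 0) return(rep(1, n))
      sdl <- sqrt(log(1 + noise_cv^2))
      exp(stats::rnorm(n, -sdl^2 / 2, sdl))
    }
    kE <- true_kcat_km * design$enzyme_total
    remaining <- ifelse(ch$enzyme,
                        ch$S0 * exp(-kE * design$reaction_time), ch$S0)
    cleaved <- ch$S0 - remaining
    rows <- list(
      tibble::tibble(species = "full_length", channel = ch$channel,
                     conc = remaining),
      tibble::tibble(species = "fragment_n", channel = ch$channel,
                     conc = cleaved +
                       ifelse(ch$channel == design$standard_channel,
                              design$standard_conc, 0)),
      tibble::tibble(species = "fragment_c", channel = ch$channel,
                     conc = cleaved +
                       ifelse(ch$channel == design$standard_channel,
                              design$standard_conc, 0))
    )
    out <- dplyr::bind_rows(rows)
    out$intensity <- out$conc * scale * lnoise(nrow(out))
    out$intensity[out$conc == 0] <- 0
    tibble::tibble(peptide_id = peptide_id, species = out$species,
                   channel = out$channel, intensity = out$intensity)
  })
}

#' Estimate kcat/Km from multiplexed intensity data
#'
#' The full recovery pipeline: per peptide, initial velocities are computed
#' from every available route - each cleaved fragment against its channel-121
#' standard ([v0_fragment()]) and the full-length decay against the
#' no-enzyme reference ([v0_full_length()]) - each route is fitted by
#' variance-weighted Lineweaver-Burk regression with the first-order
#' depletion correction, and the per-route estimates are combined by
#' inverse-variance weighting. Routes with negative slope or fewer than
#' three positive velocities are skipped.
#'
#' @param intensities Tidy intensity tibble as produced by
#'   [simulate_digestion()] or [read_intensity_table()].
#' @param design A [channel_design()].
#' @param method \code{"combined"} (default), \code{"fragment"} or
#'   \code{"full_length"}.
#' @param correct_depletion,weighting Passed to [lineweaver_burk()]
#'   (defaults: corrected, reciprocal-variance weighted).
#' @return Tibble, one row per peptide: \code{peptide_id}, \code{value}
#'   (M^-1 s^-1), \code{se}, \code{n_routes}, \code{n_points}.
#' @export
estimate_kcat_km <- function(intensities, design = channel_design(),
                             method = c("combined", "fragment",
                                        "full_length"),
                             correct_depletion = TRUE,
                             weighting = "reciprocal") {
  method <- match.arg(method)
  ch <- design$channels
  enz <- ch[ch$enzyme, ]
  purrr::map_dfr(split(intensities, intensities$peptide_id), function(df) {
    routes <- list()
    if (method %in% c("combined", "fragment")) {
      frags <- setdiff(unique(df$species), "full_length")
      for (sp in frags) {
        sub <- df[df$species == sp, ]
        i121 <- sub$intensity[sub$channel == design$standard_channel]
        i_n <- sub$intensity[match(enz$channel, sub$channel)]
        if (length(i121) == 1 && isTRUE(i121 > 0) && !all(is.na(i_n))) {
          v0 <- v0_fragment(i_n, i121, design$standard_conc,
                            design$reaction_time)
          routes[[length(routes) + 1L]] <-
            lineweaver_burk(enz$S0, v0, design$enzyme_total,
                            weighting = weighting,
                            correct_depletion = correct_depletion,
                            time = design$reaction_time)
        }
      }
    }
    if (method %in% c("combined", "full_length")) {
      sub <- df[df$species == "full_length", ]
      iref <- sub$intensity[sub$channel == design$reference_channel]
      s0ref <- ch$S0[ch$channel == design$reference_channel]
      i_n <- sub$intensity[match(enz$channel, sub$channel)]
      if (length(iref) == 1 && isTRUE(iref > 0) && !all(is.na(i_n))) {
        v0 <- v0_full_length(i_n, iref, enz$S0, s0ref,
                             design$reaction_time)
        routes[[length(routes) + 1L]] <-
          lineweaver_burk(enz$S0, v0, design$enzyme_total,
                          weighting = weighting,
                          correct_depletion = correct_depletion,
                          time = design$reaction_time)
      }
    }
    ests <- dplyr::bind_rows(routes)
    ests <- ests[is.finite(ests$value) & is.finite(ests$se) &
                   ests$se >= 0, ]
    if (!nrow(ests)) {
      return(tibble::tibble(peptide_id = df$peptide_id[1], value = NA_real_,
                            se = NA_real_, n_routes = 0L, n_points = 0L))
    }
    # an exactly-fitting route (se 0, noise-free data) dominates the others
    tol <- 1e-9 * max(abs(ests$value))
    if (any(ests$se <= tol)) {
      exact <- ests[ests$se <= tol, ]
      return(tibble::tibble(peptide_id = df$peptide_id[1],
                            value = mean(exact$value), se = 0,
                            n_routes = nrow(exact),
                            n_points = sum(exact$n_points)))
    }
    w <- 1 / ests$se^2
    tibble::tibble(peptide_id = df$peptide_id[1],
                   value = sum(w * ests$value) / sum(w),
                   se = sqrt(1 / sum(w)), n_routes = nrow(ests),
                   n_points = sum(ests$n_points))
  })
}

#' Apply per-channel control-peptide standardization
#'
#' Divides raw intensities by a per-channel factor computed as the geometric
#' mean of the control peptides' intensities in that channel.
#'
#' @param intensities Tidy intensity tibble including control-peptide rows.
#' @param control_ids Peptide ids of the control peptides.
#' @return The tibble with controls removed and \code{intensity} rescaled.
#' @export
standardize_intensities <- function(intensities, control_ids) {
  ctrl <- intensities[intensities$peptide_id %in% control_ids, ]
  if (!nrow(ctrl)) stop("no control-peptide rows found", call. = FALSE)
  factors <- ctrl |>
    dplyr::summarise(factor = exp(mean(log(.data$intensity))),
                     .by = "channel")
  if (any(!is.finite(factors$factor) | factors$factor <= 0)) {
    stop("control intensities must be positive in every channel",
         call. = FALSE)
  }
  out <- intensities[!intensities$peptide_id %in% control_ids, ]
  out$intensity <- out$intensity /
    factors$factor[match(out$channel, factors$channel)]
  out
}
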