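#' Bundled example descriptor tables
#'
#' The Kyte-Doolittle hydropathy scale (AAindex accession KYTJ820101), read
#' from the AAindex-format fixture shipped with the package, plus
#' \code{n_synthetic} reproducible synthetic scales (labelled as such) drawn
#' once from a standard normal per residue. Synthetic scales stand in for
#' the large descriptor libraries used in real analyses; they are generated,
#' not published values.
#'
#' @param n_synthetic Number of synthetic scales to append (default 5).
#' @param seed Seed for the synthetic scales.
#' @return A descriptor tibble.
#' @export
example_descriptor_tables <- function(n_synthetic = 5, seed = 20) {
  path <- system.file("extdata", "aaindex_kytj820101.txt",
                      package = "calpainqsar")
  tabs <- read_aaindex(path)
  if (n_synthetic > 0) {
    rng <- local_rng(seed)
    synth <- purrr::map_dfr(seq_len(n_synthetic), function(i) {
      vals <- stats::setNames(round(rng$rnorm(20), 3), aa_alphabet())
      descriptor_table(sprintf("SYNTH%03d", i), vals, kind = "molecular",
                       description = "synthetic random scale")
    })
    tabs <- dplyr::bind_rows(tabs, synth)
  }
  tabs
}

# Seeded RNG scoped to this object; leaves the global RNG stream intact.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else {
    NULL
  }
  set.seed(seed)
  env$state <- get(".Random.seed", .GlobalEnv)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  with_state <- function(f) {
    function(...) {
      prev <- if (exists(".Random.seed", .GlobalEnv)) {
        get(".Random.seed", .GlobalEnv)
      } else {
        NULL
      }
      assign(".Random.seed", env$state, .GlobalEnv)
      on.exit({
        env$state <- get(".Random.seed", .GlobalEnv)
        if (!is.null(prev)) assign(".Random.seed", prev, .GlobalEnv)
      })
      f(...)
    }
  }
  list(rnorm = with_state(stats::rnorm),
       runif = with_state(stats::runif),
       sample = with_state(sample),
       sample_int = with_state(sample.int))
}

#' Scramble a peptide sequence
#'
#' Uniform seeded permutation of the residues (Fisher-Yates via
#' [sample()]), the construction used for control peptides: composition is
#' preserved, order randomized.
#'
#' @param sequence Residue string, length >= 2.
#' @param seed Integer seed.
#' @return The scrambled sequence.
#' @export
scramble_peptide <- function(sequence, seed = 1) {
  stopifnot(nchar(sequence) >= 2L)
  check_sequence(sequence)
  rng <- local_rng(seed)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  paste(rng$sample(chars, length(chars)), collapse = "")
}

#' Generate random peptides from a background composition
#'
#' @param n Number of peptides.
#' @param length Peptide length (default 20, the oligopeptide-library
#'   design).
#' @param composition Residue composition tibble
#'   (default [standard_aa_composition()]).
#' @param seed Integer seed.
#' @param prefix Identifier prefix.
#' @return Tibble with \code{peptide_id} and \code{sequence}.
#' @export
generate_peptides <- function(n, length = 20,
                              composition = standard_aa_composition(),
                              seed = 1, prefix = "SYN") {
  rng <- local_rng(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(rng$sample(composition$residue, length, replace = TRUE,
                     prob = composition$proportion), collapse = "")
  }, "")
  tibble::tibble(peptide_id = sprintf("%s%04d", prefix, seq_len(n)),
                 sequence = seqs)
}

#' Generate a synthetic cleavage-site library
#'
#' Emulates the oligopeptide-digestion study end to end: 20-mer peptides
#' drawn from the standard background composition; every internal bond
#' enumerated as a window; a planted linear model on per-position descriptor
#' values assigns each window a true kcat/Km (M^-1 s^-1) multiplied by
#' log-normal noise; windows are labelled cleaved when the noisy efficiency
#' exceeds the cleavage threshold. With \code{threshold = "auto"} the
#' threshold is the empirical quantile of the generated efficiencies giving
#' the target positive prevalence (default 0.39, matching the 314/806
#' complete-window prevalence of the study design).
#' Optionally, multiplexed intensity records are simulated for a subset of
#' windows.
#'
#' @param n_peptides Number of 20-mer peptides (default 87).
#' @param peptide_length Residues per peptide (default 20).
#' @param planted Feature spec tibble with \code{positions},
#'   \code{descriptor_id} and \code{coefficient} columns (default: a single
#'   P2 hydropathy term, coefficient 40 M^-1 s^-1 per scale unit).
#' @param intercept Baseline efficiency (default 200 M^-1 s^-1).
#' @param noise_cv Log-normal coefficient of variation on the efficiency
#'   (default 0.5).
#' @param threshold \code{"auto"} or a numeric cleavage threshold
#'   (M^-1 s^-1).
#' @param prevalence Target positive fraction under \code{"auto"}.
#' @param tables Descriptor tibble (default
#'   [example_descriptor_tables()]).
#' @param complete_range Restrict windows to those complete over
#'   Pk-Pk' (default 6, the range used for model fitting).
#' @param seed Integer seed; output is fully deterministic given it.
#' @return List with \code{peptides}, \code{windows} (with \code{label} and
#'   \code{kcat_km} columns), \code{threshold}, \code{planted},
#'   \code{tables}.
#' @export
generate_synthetic_library <- function(n_peptides = 87, peptide_length = 20,
                                       planted = NULL, intercept = 200,
                                       noise_cv = 0.5, threshold = "auto",
                                       prevalence = 0.39, tables = NULL,
                                       complete_range = 6, seed = 1) {
  if (is.null(tables)) tables <- example_descriptor_tables()
  if (is.null(planted)) {
    planted <- as_feature_spec("P2", "KYTJ820101")
    planted$coefficient <- 40
  }
  stopifnot(all(c("positions", "descriptor_id", "coefficient") %in%
                  names(planted)))
  peptides <- generate_peptides(n_peptides, peptide_length, seed = seed)
  windows <- enumerate_windows(peptides, flank = 10,
                               complete_range = complete_range)
  Xp <- featurize_spec(windows, planted, tables)
  signal <- intercept + drop(Xp %*% planted$coefficient)
  rng <- local_rng(seed + 1L)
  noise <- if (noise_cv > 0) {
    sdl <- sqrt(log(1 + noise_cv^2))
    exp(rng$rnorm(length(signal), -sdl^2 / 2, sdl))
  } else {
    rep(1, length(signal))
  }
  kcat <- pmax(signal, 0) * noise
  if (identical(threshold, "auto")) {
    threshold <- unname(stats::quantile(kcat, 1 - prevalence, type = 1))
  }
  windows$kcat_km <- kcat
  windows$label <- kcat > threshold
  list(peptides = peptides, windows = windows, threshold = threshold,
       planted = planted, tables = tables)
}

#' Construct a filtered decoy sequence database
#'
#' The staged construction used to pad a small target database for
#' false-discovery-rate estimation: (1) take the C-terminal
#' \code{tail_len} residues of every proteome entry of at least that
#' length; (2) eliminate tails whose reversed sequence shares any
#' contiguous \code{block}-residue substring with any core (target)
#' sequence, giving the large decoy set; (3) further eliminate tails whose
#' forward sequence shares such a block; (4) sample \code{sample_n}
#' survivors uniformly without replacement, giving the small decoy set.
#' All stage counts are reported.
#'
#' @param proteome Tibble with \code{peptide_id} and \code{sequence}.
#' @param core Tibble with \code{peptide_id} and \code{sequence} (the
#'   target database).
#' @param tail_len C-terminal tail length (default 20).
#' @param block Shared-substring length triggering elimination (default 4).
#' @param sample_n Size of the sampled small set (default
#'   \code{min(4000, survivors)}; an explicit larger value is an error).
#' @param seed Seed for the sampling stage.
#' @return List: \code{hs_large}, \code{hs_small} (tibbles),
#'   \code{counts} (named integer vector of stage sizes).
#' @export
build_decoy_db <- function(proteome, core, tail_len = 20, block = 4,
                           sample_n = NULL, seed = 1) {
  stopifnot(block >= 1, nrow(proteome) > 0)
  check_sequence(proteome$sequence, "proteome")
  if (nrow(core)) check_sequence(core$sequence, "core")
  long_enough <- nchar(proteome$sequence) >= tail_len
  tails <- proteome[long_enough, ]
  tails$sequence <- substring(tails$sequence,
                              nchar(tails$sequence) - tail_len + 1L)
  core_blocks <- unique(unlist(lapply(core$sequence, substr_blocks, block)))
  reverse_chr <- function(x) {
    vapply(strsplit(x, "", fixed = TRUE),
           function(ch) paste(rev(ch), collapse = ""), "")
  }
  hits <- function(seqs) {
    vapply(seqs, function(s) any(substr_blocks(s, block) %in% core_blocks),
           TRUE, USE.NAMES = FALSE)
  }
  rev_hit <- if (length(core_blocks)) hits(reverse_chr(tails$sequence)) else
    rep(FALSE, nrow(tails))
  hs_large <- tails[!rev_hit, ]
  fwd_hit <- if (length(core_blocks)) hits(hs_large$sequence) else
    rep(FALSE, nrow(hs_large))
  survivors <- hs_large[!fwd_hit, ]
  if (is.null(sample_n)) sample_n <- min(4000L, nrow(survivors))
  if (sample_n > nrow(survivors)) {
    stop("sample_n = ", sample_n, " exceeds surviving entries (",
         nrow(survivors), "); stage counts: tails ", nrow(tails),
         ", after reverse filter ", nrow(hs_large),
         ", after forward filter ", nrow(survivors), call. = FALSE)
  }
  rng <- local_rng(seed)
  hs_small <- survivors[sort(rng$sample_int(nrow(survivors), sample_n)), ]
  list(hs_large = hs_large, hs_small = hs_small,
       counts = c(entries = nrow(proteome), tails = nrow(tails),
                  after_reverse_filter = nrow(hs_large),
                  after_forward_filter = nrow(survivors),
                  sampled = nrow(hs_small)))
}

# All contiguous substrings of length `block`.
substr_blocks <- function(s, block) {
  L <- nchar(s)
  if (L < block) return(character())
  starts <- seq_len(L - block + 1L)
  substring(s, starts, starts + block - 1L)
}
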