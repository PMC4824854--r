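# Shared in-code fixtures: tiny descriptor tables with hand-enterable
# values, and small window sets built from explicit sequences.

toy_tables <- function() {
  ind_leu <- stats::setNames(rep(0, 20), aa_alphabet())
  ind_leu[["L"]] <- 1
  ramp <- stats::setNames(seq(-1, 1, length.out = 20), aa_alphabet())
  dplyr::bind_rows(
    descriptor_table("IND_LEU", ind_leu, kind = "molecular",
                     description = "leucine indicator"),
    descriptor_table("RAMP", ramp, kind = "molecular",
                     description = "alphabetical ramp")
  )
}

kd_table <- function() {
  read_aaindex(system.file("extdata", "aaindex_kytj820101.txt",
                           package = "calpainqsar"))
}

# Windows from explicit (sequence, bond) pairs.
toy_windows <- function(seqs, bonds, flank = 10) {
  build_window(tibble::tibble(peptide_id = paste0("t", seq_along(seqs)),
                              sequence = seqs),
               bonds, flank = flank)
}

# Synthetic descriptor scales sized so each planted coefficient contributes
# a comparable share of the response spread (scale sd ~ 120 / |coefficient|),
# the way descriptor units and coefficients co-vary in fitted models.
planted_pls_tables <- function(coefficients, seed = 99) {
  rng_seq <- stats::setNames(seq(-1.6, 1.6, length.out = 20), aa_alphabet())
  purrr::map_dfr(seq_along(coefficients), function(i) {
    set.seed(seed + i)
    vals <- sample(rng_seq) * 120 / abs(coefficients[i])
    names(vals) <- aa_alphabet()
    descriptor_table(sprintf("PLANT%d", i), vals, kind = "molecular",
                     description = "synthetic planted scale")
  })
}

# A moderately sized labelled library shared across classifier tests.
toy_library <- function(n_peptides = 40, seed = 11, noise_cv = 0.5) {
  generate_synthetic_library(n_peptides = n_peptides, seed = seed,
                             noise_cv = noise_cv)
}
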