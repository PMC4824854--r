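#' The 20 canonical amino-acid one-letter codes
#'
#' Returned in alphabetical order, the order used for residue columns in
#' descriptor tables and frequency profiles.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# AAindex1 flat files list residues in pair order A/L R/K N/M D/F C/P Q/S E/T
# G/W H/Y I/V: row 1 = first member of each pair, row 2 = second.
aaindex_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Position labels for a cleavage-site window
#'
#' Labels run N- to C-terminal: \code{P<flank>} ... \code{P1} on the
#' non-prime side of the scissile bond, then \code{P1p} ... \code{P<flank>p}
#' (the prime side, "p" = prime) C-terminal to it. These strings are used as
#' column names in window tibbles and in feature names, so they round-trip
#' through file headers unambiguously.
#'
#' @param flank Number of positions on each side of the bond (default 10).
#' @return Character vector of length \code{2 * flank}.
#' @export
position_labels <- function(flank = 10) {
  stopifnot(is.numeric(flank), flank >= 1)
  c(paste0("P", rev(seq_len(flank))), paste0("P", seq_len(flank), "p"))
}

# Signed offset of a position label relative to the scissile bond:
# P1 -> 0, P2 -> -1, ..., P1p -> +1, P2p -> +2 (residue index = bond_after +
# offset for non-prime, bond_after + k for Pk').
position_offset <- function(labels) {
  prime <- grepl("p$", labels)
  k <- as.integer(sub("^P(\\d+)p?$", "\\1", labels))
  if (anyNA(k)) {
    stop("malformed position label(s): ",
         paste(labels[is.na(k)], collapse = ", "), call. = FALSE)
  }
  ifelse(prime, k, 1L - k)
}

# Order position labels N- to C-terminal.
order_positions <- function(labels) {
  labels[order(position_offset(labels))]
}

check_sequence <- function(sequence, what = "sequence") {
  bad <- !grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$"),
                sequence)
  if (any(bad)) {
    stop(what, " contains non-canonical residue codes: ",
         paste(utils::head(sequence[bad], 3), collapse = ", "), call. = FALSE)
  }
  invisible(sequence)
}
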