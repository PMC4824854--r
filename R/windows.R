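#' Build cleavage-site windows around given scissile bonds
#'
#' A window aligns the residues flanking one peptide bond on the P10...P1 /
#' P1'...P10' grid: P1 is the residue immediately N-terminal to the bond
#' (residue \code{bond_after}), Pk the residue \code{k - 1} positions further
#' N-terminal, and Pk' the residue \code{k} positions C-terminal. Positions
#' falling outside the peptide are \code{NA} (missing). Terminal chemistry
#' (acetylation, diketopiperazine) is carried as metadata only and never
#' featurized.
#'
#' @param peptides Data frame with columns \code{peptide_id} and
#'   \code{sequence}; optional columns \code{enzyme} and \code{status} are
#'   carried through.
#' @param bond_after 1-based index of the residue N-terminal to the scissile
#'   bond. Either length 1 (recycled) or one per peptide. Must be at least 1
#'   and strictly less than the sequence length (cleavage C-terminal to the
#'   last residue is no bond).
#' @param flank Number of positions per side (default 10, the P10-P10' grid).
#' @return A tibble with one row per window: \code{peptide_id},
#'   \code{bond_after}, any carried metadata, and one character column per
#'   position label (N- to C-terminal order).
#' @examples
#' build_window(tibble::tibble(peptide_id = "pep1", sequence = "ACDEF"),
#'              bond_after = 2)
#' @export
build_window <- function(peptides, bond_after, flank = 10) {
  stopifnot(is.data.frame(peptides),
            all(c("peptide_id", "sequence") %in% names(peptides)))
  check_sequence(peptides$sequence)
  n <- nrow(peptides)
  bond_after <- vctrs::vec_recycle(as.integer(bond_after), n)
  len <- nchar(peptides$sequence)
  if (any(bond_after < 1L | bond_after >= len)) {
    stop("no scissile bond: `bond_after` must lie in [1, length - 1]",
         call. = FALSE)
  }
  labels <- position_labels(flank)
  offsets <- position_offset(labels)
  res <- matrix(NA_character_, n, length(labels),
                dimnames = list(NULL, labels))
  chars <- strsplit(peptides$sequence, "", fixed = TRUE)
  for (j in seq_along(labels)) {
    idx <- bond_after + offsets[j]
    ok <- idx >= 1L & idx <= len
    res[ok, j] <- vapply(which(ok), function(i) chars[[i]][idx[i]], "")
  }
  meta <- peptides[intersect(c("peptide_id", "enzyme", "status"),
                             names(peptides))]
  dplyr::bind_cols(tibble::as_tibble(meta),
                   tibble::tibble(bond_after = bond_after),
                   tibble::as_tibble(res))
}

#' Enumerate every cleavage-site window of each peptide
#'
#' One window per internal peptide bond: a 20-mer yields 19 windows.
#' Optionally restricts to windows with no missing residues over a symmetric
#' range, e.g. \code{complete_range = 6} keeps only windows whose P6-P6'
#' positions are all inside the peptide (bonds 6..14 of a 20-mer).
#'
#' @inheritParams build_window
#' @param complete_range If not \code{NULL}, an integer k: keep only windows
#'   complete over Pk-Pk'.
#' @return A tibble of windows as in [build_window()].
#' @export
enumerate_windows <- function(peptides, flank = 10, complete_range = NULL) {
  stopifnot(is.data.frame(peptides))
  check_sequence(peptides$sequence)
  expanded <- peptides |>
    dplyr::mutate(.len = nchar(.data$sequence)) |>
    dplyr::reframe(bond_after = seq_len(.data$.len - 1L),
                   dplyr::across(dplyr::everything()),
                   .by = "peptide_id") |>
    dplyr::select(-".len")
  out <- build_window(expanded, expanded$bond_after, flank = flank)
  if (!is.null(complete_range)) {
    stopifnot(complete_range >= 1, complete_range <= flank)
    keep_cols <- position_labels(complete_range)
    complete <- !Reduce(`|`, lapply(keep_cols, function(cl) is.na(out[[cl]])))
    out <- out[complete, , drop = FALSE]
  }
  out
}

#' Reverse windows for use as negative controls
#'
#' Reverses the residue order of each window about the scissile bond, the
#' construction used to turn known cleaved sequences into matched
#' negative-control sequences: position Pk swaps with Pk'. A palindromic
#' window is unchanged and double reversal is the identity.
#'
#' @param windows A window tibble from [build_window()].
#' @return The windows with prime/non-prime residues exchanged.
#' @export
reverse_windows <- function(windows) {
  pos <- intersect(position_labels(window_flank(windows)), names(windows))
  prime <- grepl("p$", pos)
  partner <- ifelse(prime, sub("p$", "", pos), paste0(pos, "p"))
  missing_partner <- setdiff(partner, names(windows))
  if (length(missing_partner)) {
    stop("windows lack partner position column(s): ",
         paste(missing_partner, collapse = ", "), call. = FALSE)
  }
  out <- windows
  out[pos] <- windows[partner]
  out
}

# Infer the flank of a window tibble from its position columns.
window_flank <- function(windows) {
  pos <- grep("^P\\d+p?$", names(windows), value = TRUE)
  if (!length(pos)) stop("no position columns found", call. = FALSE)
  max(abs(position_offset(pos)))
}

# Unique window key used as row identifier in feature matrices.
window_id <- function(windows) {
  paste(windows$peptide_id, windows$bond_after, sep = "@")
}
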