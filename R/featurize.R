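#' Convert windows into a per-position feature matrix
#'
#' Crosses the requested window positions with every descriptor scale: each
#' feature column holds the descriptor value of the residue occupying that
#' position (or, for secondary-structure descriptors, the per-residue
#' probability supplied in \code{ss}). A missing window position yields a
#' missing cell for every residue-keyed descriptor. Column order is
#' deterministic: positions N- to C-terminal (outer), descriptor ids
#' lexicographic (inner); names are \code{"<position>_<descriptor_id>"}.
#'
#' @param windows Window tibble from [build_window()] /
#'   [enumerate_windows()].
#' @param tables Descriptor tibble ([descriptor_table()],
#'   [read_aaindex()], ...). Rows with kind \code{"secondary_structure"}
#'   are looked up in \code{ss} instead of by residue identity.
#' @param positions Position labels to featurize (default: all window
#'   positions).
#' @param ss Optional per-residue secondary-structure sidecar: a data frame
#'   with columns \code{peptide_id}, \code{residue_index}, and one numeric
#'   column per secondary-structure descriptor id (probabilities in [0, 1]).
#' @return Tibble with \code{window_id}, any \code{label} / \code{kcat_km}
#'   columns carried from \code{windows}, then the feature columns.
#' @export
featurize <- function(windows, tables, positions = NULL, ss = NULL) {
  stopifnot(is.data.frame(windows), is.data.frame(tables))
  if (is.null(positions)) {
    positions <- intersect(position_labels(window_flank(windows)),
                           names(windows))
  }
  positions <- order_positions(positions)
  missing_pos <- setdiff(positions, names(windows))
  if (length(missing_pos)) {
    stop("windows lack position column(s): ",
         paste(missing_pos, collapse = ", "), call. = FALSE)
  }
  ss_ids <- sort(tables$descriptor_id[tables$kind == "secondary_structure"])
  res_ids <- sort(setdiff(tables$descriptor_id, ss_ids))
  if (length(ss_ids) && is.null(ss)) {
    stop("secondary-structure descriptors requested but no `ss` sidecar ",
         "supplied: ", paste(ss_ids, collapse = ", "), call. = FALSE)
  }
  ids <- c(res_ids, ss_ids)
  out <- tibble::tibble(window_id = window_id(windows))
  for (extra in intersect(c("label", "kcat_km"), names(windows))) {
    out[[extra]] <- windows[[extra]]
  }
  offsets <- position_offset(positions)
  for (pi in seq_along(positions)) {
    pos <- positions[pi]
    residues <- windows[[pos]]
    known <- is.na(residues) | residues %in% aa_alphabet()
    if (!all(known)) {
      bad <- which(!known)[1]
      stop("unknown residue code '", residues[bad], "' at ", pos,
           " of window ", out$window_id[bad], call. = FALSE)
    }
    for (id in sort(ids)) {
      if (id %in% res_ids) {
        vals <- descriptor_values(tables, id)[residues]
      } else {
        idx <- windows$bond_after + offsets[pi]
        key <- paste(windows$peptide_id, idx, sep = "\r")
        ss_key <- paste(ss$peptide_id, ss$residue_index, sep = "\r")
        if (!id %in% names(ss)) {
          stop("ss sidecar lacks column '", id, "'", call. = FALSE)
        }
        vals <- ss[[id]][match(key, ss_key)]
      }
      out[[paste(pos, id, sep = "_")]] <- unname(vals)
    }
  }
  # re-order: position outer in N->C order, descriptor lexicographic inner
  feat <- as.vector(t(outer(positions, sort(ids), paste, sep = "_")))
  out[c(setdiff(names(out), feat), feat)]
}

#' Evaluate an explicit feature specification
#'
#' Computes the feature matrix for a list of (position, descriptor)
#' features, the representation fitted models use. A paired-position
#' feature (two labels in one \code{positions} entry) is the sum of the
#' descriptor value at the member positions.
#'
#' @param windows Window tibble.
#' @param spec Feature tibble from [as_feature_spec()].
#' @param tables Descriptor tibble.
#' @param ss Optional secondary-structure sidecar, see [featurize()].
#' @return Numeric matrix, one named column per feature
#'   (\code{"<positions>_<descriptor_id>"}).
#' @export
featurize_spec <- function(windows, spec, tables, ss = NULL) {
  stopifnot(is.data.frame(spec),
            all(c("positions", "descriptor_id") %in% names(spec)))
  cols <- lapply(seq_len(nrow(spec)), function(i) {
    posns <- spec$positions[[i]]
    id <- spec$descriptor_id[i]
    part <- lapply(posns, function(p) {
      fm <- featurize(windows, tables[tables$descriptor_id == id, ],
                      positions = p, ss = ss)
      fm[[paste(p, id, sep = "_")]]
    })
    Reduce(`+`, part)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- feature_names(spec)
  m
}

feature_names <- function(spec) {
  paste(vapply(spec$positions, paste, "", collapse = "."),
        spec$descriptor_id, sep = "_")
}

#' Construct a feature specification
#'
#' A feature is one descriptor evaluated at one position, or at a pair of
#' positions (given as a length-2 element of a list). Recycling follows
#' tibble rules.
#'
#' @param positions Character vector of position labels, or a list whose
#'   elements are single labels or pairs (e.g.
#'   \code{list("P10", c("P2", "P1"))}).
#' @param descriptor_id Descriptor id per feature.
#' @return A feature tibble with list-column \code{positions} and
#'   \code{descriptor_id}.
#' @export
as_feature_spec <- function(positions, descriptor_id) {
  if (!is.list(positions)) positions <- as.list(positions)
  tibble::tibble(positions = positions, descriptor_id = descriptor_id)
}

#' Select, per position, the descriptor most correlated with activity
#'
#' For every (position, residue-keyed descriptor) pair, computes the squared
#' Pearson correlation between the descriptor values taken by the residues at
#' that position and the measured catalytic efficiencies, and keeps the
#' best-scoring descriptor per position. This is the pre-selection step that
#' reduces a large descriptor library to one scale per position before model
#' fitting. Zero-variance descriptor columns are excluded with a warning;
#' ties break lexicographically on descriptor id.
#'
#' @inheritParams featurize
#' @param response Numeric vector of catalytic efficiencies (one per window);
#'   pairs with a missing feature or response are dropped, and at least three
#'   complete pairs are required for a candidate to be scored.
#' @return Tibble with one row per position: \code{position},
#'   \code{descriptor_id}, \code{r_squared}.
#' @export
select_best_descriptor_per_position <- function(windows, tables, positions,
                                                response, ss = NULL) {
  stopifnot(length(response) == nrow(windows))
  fm <- featurize(windows, tables, positions = positions, ss = ss)
  feat_cols <- setdiff(names(fm), c("window_id", "label", "kcat_km"))
  scores <- purrr::map_dfr(feat_cols, function(cl) {
    x <- fm[[cl]]
    ok <- !is.na(x) & !is.na(response)
    pos_id <- strsplit(cl, "_", fixed = TRUE)[[1]]
    pos <- pos_id[1]
    id <- paste(pos_id[-1], collapse = "_")
    if (sum(ok) < 3L) {
      return(tibble::tibble(position = pos, descriptor_id = id,
                            r_squared = NA_real_))
    }
    if (stats::sd(x[ok]) == 0) {
      warning("zero-variance feature excluded: ", cl, call. = FALSE)
      return(tibble::tibble(position = pos, descriptor_id = id,
                            r_squared = NA_real_))
    }
    tibble::tibble(position = pos, descriptor_id = id,
                   r_squared = stats::cor(x[ok], response[ok])^2)
  })
  scores |>
    dplyr::filter(!is.na(.data$r_squared)) |>
    dplyr::arrange(position_offset(.data$position),
                   dplyr::desc(.data$r_squared), .data$descriptor_id) |>
    dplyr::distinct(.data$position, .keep_all = TRUE)
}

#' Rank descriptor scales against a per-residue activity profile
#'
#' Given one value per residue (for example the modelled contribution of each
#' amino acid at one position), correlates every descriptor scale with the
#' profile by Pearson's r and Spearman's rho, ranks the scales independently
#' on each (by absolute correlation, since the sign of a scale is an
#' arbitrary convention), and orders them by the sum of the two ranks.
#' Spearman's rho complements r because some scales have outlier-heavy
#' distributions. Constant scales get the worst rank.
#'
#' @param scores Named numeric vector: one value per canonical residue.
#' @param tables Descriptor tibble of residue-keyed scales.
#' @return Tibble sorted best-first: \code{descriptor_id}, \code{r},
#'   \code{rho}, \code{rank_r}, \code{rank_rho}, \code{rank_sum}.
#' @export
rank_descriptors <- function(scores, tables) {
  stopifnot(length(scores) == 20L, setequal(names(scores), aa_alphabet()))
  scores <- scores[aa_alphabet()]
  tabs <- tables[tables$kind != "secondary_structure", , drop = FALSE]
  cors <- purrr::map_dfr(seq_len(nrow(tabs)), function(i) {
    v <- unlist(tabs[i, aa_alphabet()])
    if (stats::sd(v) == 0) {
      return(tibble::tibble(descriptor_id = tabs$descriptor_id[i],
                            r = NA_real_, rho = NA_real_))
    }
    tibble::tibble(
      descriptor_id = tabs$descriptor_id[i],
      r = stats::cor(v, scores),
      rho = stats::cor(v, scores, method = "spearman")
    )
  })
  worst <- nrow(cors)
  rank_abs <- function(x) {
    r <- rank(-abs(x), ties.method = "min", na.last = "keep")
    r[is.na(r)] <- worst
    r
  }
  cors |>
    dplyr::mutate(rank_r = rank_abs(.data$r),
                  rank_rho = rank_abs(.data$rho),
                  rank_sum = .data$rank_r + .data$rank_rho) |>
    dplyr::arrange(.data$rank_sum, .data$descriptor_id)
}
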