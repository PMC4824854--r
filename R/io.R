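#' Read or write a cleavage-site table
#'
#' Tab-separated, one row per cleavage site: \code{peptide_id},
#' \code{sequence}, \code{bond_after} (1-based residue index N-terminal to
#' the scissile bond), optional \code{enzyme} (C1/C2/both), \code{status}
#' (Rp/Nv/Lit/uncleaved), \code{kcat_km} and \code{kcat_km_se}
#' (M^-1 s^-1). Malformed rows are reported with their line number.
#'
#' @param path File path.
#' @return A tibble of validated sites.
#' @export
read_site_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("peptide_id", "sequence", "bond_after")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop("site table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lineno <- seq_len(nrow(tbl)) + 1L  # header is line 1
  bad_seq <- !grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$"),
                    tbl$sequence)
  if (any(bad_seq)) {
    stop("invalid sequence at line ", lineno[bad_seq][1], call. = FALSE)
  }
  bond <- suppressWarnings(as.integer(tbl$bond_after))
  bad_bond <- is.na(bond) | bond < 1L | bond >= nchar(tbl$sequence)
  if (any(bad_bond)) {
    stop("invalid bond_after at line ", lineno[bad_bond][1],
         " (must be in [1, length - 1])", call. = FALSE)
  }
  tbl$bond_after <- bond
  tibble::as_tibble(tbl)
}

#' @rdname read_site_table
#' @param sites Site tibble.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write protein sequences in FASTA format
#'
#' @param path File path.
#' @return [read_fasta()] returns a tibble with \code{peptide_id} and
#'   \code{sequence}.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("the Biostrings package is required to read FASTA", call. = FALSE)
  }
  xs <- Biostrings::readAAStringSet(path)
  tibble::tibble(peptide_id = sub("\\s.*$", "", names(xs)),
                 sequence = as.character(xs))
}

#' @rdname read_fasta
#' @param seqs Tibble with \code{peptide_id} and \code{sequence}.
#' @export
write_fasta <- function(seqs, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("the Biostrings package is required to write FASTA", call. = FALSE)
  }
  xs <- Biostrings::AAStringSet(stats::setNames(seqs$sequence,
                                                seqs$peptide_id))
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read or write a tidy reporter-intensity table
#'
#' Tab-separated with columns \code{peptide_id}, \code{species}
#' (\code{full_length}, \code{fragment_n}, \code{fragment_c}),
#' \code{channel}, \code{intensity}.
#'
#' @param path File path.
#' @return A tibble of intensities.
#' @export
read_intensity_table <- function(path) {
  tbl <- utils::read.delim(path, colClasses = c(channel = "character"),
                           stringsAsFactors = FALSE)
  required <- c("peptide_id", "species", "channel", "intensity")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop("intensity table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  neg <- which(tbl$intensity < 0)
  if (length(neg)) {
    stop("negative intensity at line ", neg[1] + 1L, call. = FALSE)
  }
  tibble::as_tibble(tbl)
}

#' @rdname read_intensity_table
#' @param intensities Intensity tibble.
#' @export
write_intensity_table <- function(intensities, path) {
  utils::write.table(intensities, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model to a versioned JSON document
#'
#' Both model classes round-trip: features, preprocessing, densities or
#' coefficients, prior/intercept and thresholds are stored; the descriptor
#' tables the model was fit with are embedded so a written model predicts
#' on its own.
#'
#' @param model A \code{binary_qsar} or \code{pls_qsar} object.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  cls <- class(model)[1]
  stopifnot(cls %in% c("binary_qsar", "pls_qsar"))
  payload <- unclass(model)
  if (cls == "binary_qsar") {
    payload$rotation <- apply(model$rotation, 2, identity, simplify = FALSE)
  } else {
    payload$X <- NULL
    payload$fitted <- NULL
    payload$response <- NULL
  }
  payload$feature_spec <- list(
    positions = lapply(model$feature_spec$positions, as.character),
    descriptor_id = model$feature_spec$descriptor_id
  )
  doc <- list(format = "calpainqsar-model", version = 1L, class = cls,
              model = payload)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_model_json
#' @return [read_model_json()] returns the restored model object.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$format, "calpainqsar-model")) {
    stop("not a model document: ", path, call. = FALSE)
  }
  m <- doc$model
  m$feature_spec <- tibble::tibble(
    positions = lapply(m$feature_spec$positions, as.character),
    descriptor_id = m$feature_spec$descriptor_id
  )
  m$tables <- tibble::as_tibble(m$tables)
  if (doc$class == "binary_qsar") {
    m$center <- stats::setNames(as.numeric(m$center), m$feature_names)
    m$scale <- stats::setNames(as.numeric(m$scale), m$feature_names)
    m$rotation <- do.call(cbind, lapply(m$rotation, as.numeric))
    m$components <- lapply(m$components, function(comp) {
      list(edges = as.numeric(comp$edges),
           p_pos = as.numeric(comp$p_pos),
           p_neg = as.numeric(comp$p_neg))
    })
  } else {
    m$coefficients <- stats::setNames(as.numeric(m$coefficients),
                                      m$feature_names)
    m$X <- NULL
  }
  structure(m, class = doc$class)
}
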