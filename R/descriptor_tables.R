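#' Construct a descriptor table
#'
#' A descriptor table is one named amino-acid scale: a value per canonical
#' residue (e.g. an AAindex hydropathy scale, or a molecular surface-area
#' scale). Tables are stored wide, one row per descriptor, with one column
#' per residue in alphabetical order.
#'
#' @param descriptor_id Scale identifier (e.g. AAindex accession
#'   \code{"KYTJ820101"} or a local id such as \code{"ASA+"}).
#' @param values Named numeric vector with exactly the 20 canonical residues
#'   as names.
#' @param kind One of \code{"aaindex"}, \code{"molecular"},
#'   \code{"secondary_structure"}.
#' @param description Free-text description of the scale.
#' @return A one-row descriptor tibble; row-bind several to form a table set.
#' @export
descriptor_table <- function(descriptor_id, values,
                             kind = c("aaindex", "molecular",
                                      "secondary_structure"),
                             description = "") {
  kind <- match.arg(kind)
  if (kind != "secondary_structure") {
    stopifnot(length(values) == 20L,
              setequal(names(values), aa_alphabet()))
    values <- values[aa_alphabet()]
  }
  dplyr::bind_cols(
    tibble::tibble(descriptor_id = descriptor_id, kind = kind,
                   description = description),
    tibble::as_tibble(as.list(values))
  )
}

#' Read an AAindex1 flat file
#'
#' Parses records of the AAindex1 format: accession on the \code{H} line,
#' description on the \code{D} line, and 20 values after the \code{I} line in
#' the canonical pair order A/L, R/K, N/M, D/F, C/P, Q/S, E/T, G/W, H/Y, I/V
#' (first row the first member of each pair, second row the second).
#'
#' @param path Path to an AAindex1 flat file.
#' @return A descriptor tibble, one row per record, residues as columns.
#' @export
read_aaindex <- function(path) {
  lines <- readLines(path)
  rec_start <- grep("^H ", lines)
  if (!length(rec_start)) stop("no AAindex records ('H ' lines) in ", path,
                               call. = FALSE)
  rec_end <- c(rec_start[-1] - 1L, length(lines))
  recs <- purrr::map2(rec_start, rec_end, function(s, e) {
    block <- lines[s:e]
    acc <- trimws(sub("^H ", "", block[1]))
    d_line <- grep("^D ", block, value = TRUE)
    descr <- if (length(d_line)) trimws(sub("^D ", "", d_line[1])) else ""
    i_at <- grep("^I ", block)
    if (!length(i_at) || i_at + 2L > length(block)) {
      stop("record ", acc, ": missing or truncated 'I' value block",
           call. = FALSE)
    }
    vals <- suppressWarnings(
      as.numeric(unlist(strsplit(trimws(block[i_at + (1:2)]), "\\s+")))
    )
    if (length(vals) != 20L || anyNA(vals)) {
      stop("record ", acc, ": expected 20 numeric values", call. = FALSE)
    }
    names(vals) <- aaindex_order()
    descriptor_table(acc, vals, kind = "aaindex", description = descr)
  })
  dplyr::bind_rows(recs)
}

#' Read or write a generic descriptor TSV
#'
#' Tab-separated with a \code{descriptor_id} column followed by the 20
#' residue columns (alphabetical); optional \code{kind} and
#' \code{description} columns.
#'
#' @param path File path.
#' @return [read_descriptor_tsv()] returns a descriptor tibble.
#' @export
read_descriptor_tsv <- function(path) {
  tbl <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing <- setdiff(c("descriptor_id", aa_alphabet()), names(tbl))
  if (length(missing)) {
    stop("descriptor TSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"kind" %in% names(tbl)) tbl$kind <- "molecular"
  if (!"description" %in% names(tbl)) tbl$description <- ""
  tibble::as_tibble(tbl)[c("descriptor_id", "kind", "description",
                           aa_alphabet())]
}

#' @rdname read_descriptor_tsv
#' @param tables Descriptor tibble.
#' @export
write_descriptor_tsv <- function(tables, path) {
  utils::write.table(tables, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Standardize descriptor scales across the 20 residues
#'
#' Replaces each scale by its z-score over the 20 residue values. Model
#' fitting is invariant to affine rescaling of any input scale, but
#' standardization keeps principal-component and latent-variable steps
#' numerically comparable across scales; raw values are retained for
#' reporting physical effect sizes.
#'
#' @param tables Descriptor tibble.
#' @return Descriptor tibble with standardized values.
#' @export
standardize_descriptors <- function(tables) {
  res <- aa_alphabet()
  vals <- as.matrix(tables[res])
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, stats::sd)
  if (any(sdv == 0)) {
    warning("constant descriptor(s) left unscaled: ",
            paste(tables$descriptor_id[sdv == 0], collapse = ", "))
    sdv[sdv == 0] <- 1
  }
  tables[res] <- (vals - mu) / sdv
  tables
}

# Named lookup vector for one descriptor row.
descriptor_values <- function(tables, id) {
  row <- tables[tables$descriptor_id == id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("descriptor '", id, "' not found (or duplicated) in tables",
         call. = FALSE)
  }
  unlist(row[aa_alphabet()])
}
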