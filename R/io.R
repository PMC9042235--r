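#' Read C-alpha coordinates from a PDB file
#'
#' Reads a PDB file (wwPDB v3.3 fixed-width columns, via bio3d), keeps one
#' C-alpha per ordered residue, resolves alternate locations to the highest
#' occupancy, preserves author residue numbering and warns about ordered
#' residues lacking a CA atom. Insertion codes and multi-model files are
#' rejected.
#'
#' @param path Path to a PDB file.
#' @return A [ca_model()] whose coordinate tibble carries `chain`, `resno`,
#'   `aa` (one-letter code), `x`, `y`, `z`. The topology treats every chain
#'   as its own single-copy entity.
#' @export
read_ca_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      stop("unparseable PDB file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  at <- tibble::as_tibble(pdb$atom)
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported (file '", path, "')",
         call. = FALSE)
  }
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("no CA atoms in '", path, "'", call. = FALSE)
  # altloc: keep highest occupancy (ties: first record)
  ca$o[is.na(ca$o)] <- 1
  ca <- ca |>
    dplyr::group_by(.data$chain, .data$resno) |>
    dplyr::slice_max(.data$o, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  missing_ca <- dplyr::anti_join(
    dplyr::distinct(at, .data$chain, .data$resno),
    dplyr::distinct(ca, .data$chain, .data$resno),
    by = c("chain", "resno")
  )
  if (nrow(missing_ca) > 0) {
    warning(nrow(missing_ca), " ordered residue(s) without a CA atom were skipped",
            call. = FALSE)
  }
  co <- ca |>
    dplyr::transmute(chain = .data$chain, resno = as.integer(.data$resno),
                     aa = bio3d::aa321(.data$resid),
                     x = .data$x, y = .data$y, z = .data$z) |>
    dplyr::arrange(.data$chain, .data$resno)
  chains <- co |>
    dplyr::group_by(chain_id = .data$chain) |>
    dplyr::summarise(residues = list(.data$resno), .groups = "drop") |>
    dplyr::mutate(entity = .data$chain_id, copy = 1L)
  ca_model(co, topology = complex_topology(chains))
}

#' Write a C-alpha model as a PDB file
#'
#' One CA ATOM record per residue (chain ids and author residue numbers
#' preserved); zinc sites, when present, are written as HETATM ZN records.
#' Coordinates are written at PDB precision (3 decimals).
#'
#' @param model A [ca_model()]; coordinates must be finite.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(model, path) {
  co <- model$coords
  xyz <- as.matrix(co[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    stop("non-finite coordinates cannot be written", call. = FALSE)
  }
  aa <- if ("aa" %in% names(co)) bio3d::aa123(co$aa) else rep("ALA", nrow(co))
  type <- rep("ATOM", nrow(co))
  chain <- co$chain
  resno <- co$resno
  elety <- rep("CA", nrow(co))
  elesy <- rep("C", nrow(co))
  if (!is.null(model$zn) && nrow(model$zn) > 0) {
    zn <- model$zn
    if (!all(is.finite(as.matrix(zn[, c("x", "y", "z")])))) {
      stop("non-finite zinc coordinates", call. = FALSE)
    }
    xyz <- rbind(xyz, as.matrix(zn[, c("x", "y", "z")]))
    type <- c(type, rep("HETATM", nrow(zn)))
    chain <- c(chain, zn$chain)
    resno <- c(resno, 9000L + seq_len(nrow(zn)))
    aa <- c(aa, rep("ZN", nrow(zn)))
    elety <- c(elety, rep("ZN", nrow(zn)))
    elesy <- c(elesy, rep("ZN", nrow(zn)))
  }
  n_at <- length(type)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)), type = type,
                   resno = resno, resid = aa, chain = chain, elety = elety,
                   elesy = elesy, o = rep(1, n_at), b = rep(0, n_at))
  invisible(path)
}

#' Read / write restraint tables (TSV)
#'
#' Tab-separated with header
#' `chain_a res_a chain_b res_b class probability upper_bound`; empty
#' probability/upper_bound fields are allowed (and required on cross-link
#' rows for probability). See [restraint_table()] for the invariants.
#'
#' @param path File path.
#' @return `read_restraints()` returns a [restraint_table()];
#'   `write_restraints()` returns `path` invisibly.
#' @export
read_restraints <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chain_a = readr::col_character(), res_a = readr::col_integer(),
    chain_b = readr::col_character(), res_b = readr::col_integer(),
    class = readr::col_character(), probability = readr::col_double(),
    upper_bound = readr::col_double()
  ))
  restraint_table(x)
}

#' @rdname read_restraints
#' @param table A [restraint_table()] (or coercible data frame).
#' @export
write_restraints <- function(table, path) {
  table <- restraint_table(table)
  readr::write_tsv(as.data.frame(table)[, c("chain_a", "res_a", "chain_b",
                                            "res_b", "class", "probability",
                                            "upper_bound")], path)
  invisible(path)
}

#' Read / write contact maps (TSV)
#'
#' Tab-separated with header `i j probability`: residue-pair contact
#' probabilities indexed on a single sequence (or on a hybrid paired
#' alignment; see [mask_linker()]).
#'
#' @param path File path.
#' @return `read_contact_map()` returns a `contact_map` tibble.
#' @export
read_contact_map <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    i = readr::col_integer(), j = readr::col_integer(),
    probability = readr::col_double()
  ))
  contact_map(x)
}

#' @rdname read_contact_map
#' @param cm A contact map tibble with columns `i`, `j`, `probability`.
#' @export
write_contact_map <- function(cm, path) {
  readr::write_tsv(as.data.frame(cm)[, c("i", "j", "probability")], path)
  invisible(path)
}

#' Validate a contact map
#'
#' @param x Data frame with columns `i`, `j`, `probability` (positions
#'   1-based on the underlying sequence) and optionally chain columns.
#' @return The tibble, classed `contact_map`.
#' @export
contact_map <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("i", "j", "probability") %in% names(x)))
  if (any(x$probability < 0 | x$probability > 1)) {
    stop("contact probabilities must be in [0, 1]", call. = FALSE)
  }
  if (any(x$i == x$j)) stop("self-contacts are not allowed", call. = FALSE)
  class(x) <- unique(c("contact_map", class(x)))
  x
}

#' Read / write aligned FASTA multiple sequence alignments
#'
#' Rows must be equal width. The organism tag used for pairing sequences
#' across alignments is parsed from the FASTA header as the text after the
#' first `|` (the header grammar used throughout: `id|organism`). The first
#' row is taken as the reference (query) row unless `reference` says
#' otherwise.
#'
#' @param path File path.
#' @param reference Index of the reference row (default 1).
#' @return `read_msa()` returns an [msa()] object.
#' @export
read_msa <- function(path, reference = 1) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0) stop("empty alignment in '", path, "'", call. = FALSE)
  headers <- names(ss)
  ids <- sub("\\|.*$", "", headers)
  orgs <- ifelse(grepl("\\|", headers), sub("^[^|]*\\|", "", headers), NA_character_)
  msa(seq_id = ids, organism = orgs,
      sequence = unname(as.character(ss)), reference = reference)
}

#' @rdname read_msa
#' @param aln An [msa()] object.
#' @export
write_msa <- function(aln, path) {
  ss <- Biostrings::AAStringSet(aln$rows$sequence)
  names(ss) <- ifelse(is.na(aln$rows$organism), aln$rows$seq_id,
                      paste(aln$rows$seq_id, aln$rows$organism, sep = "|"))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
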