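#' Multiple sequence alignment container
#'
#' Rows of equal-width aligned sequences with a sequence id and an organism
#' tag (used to pair sequences across alignments of interacting proteins).
#' One row is the reference (query) row; its ungapped positions define the
#' residue numbering that conservation calls and contact maps are reported
#' on.
#'
#' @param seq_id Character vector of row ids.
#' @param organism Character vector of organism/strain tags (may be `NA`).
#' @param sequence Character vector of aligned sequences (gaps as `-`),
#'   equal widths.
#' @param reference Index of the reference row.
#' @return An `msa` object.
#' @export
msa <- function(seq_id, organism, sequence, reference = 1) {
  rows <- tibble::tibble(seq_id = seq_id, organism = organism,
                         sequence = toupper(sequence))
  if (nrow(rows) == 0) stop("empty alignment", call. = FALSE)
  w <- unique(nchar(rows$sequence))
  if (length(w) != 1) stop("alignment rows have unequal widths", call. = FALSE)
  if (reference < 1 || reference > nrow(rows)) {
    stop("reference row out of range", call. = FALSE)
  }
  structure(list(rows = rows, width = w, reference = as.integer(reference)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", nrow(x$rows), " rows x ", x$width, " columns (reference: ",
      x$rows$seq_id[x$reference], ")\n", sep = "")
  invisible(x)
}

## internal: alignment as a character matrix (rows x columns)
msa_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows$sequence, "", fixed = TRUE))
}

## internal: map alignment columns to 1-based ungapped reference positions
## (NA where the reference row is gapped)
reference_positions <- function(aln) {
  ref <- strsplit(aln$rows$sequence[aln$reference], "", fixed = TRUE)[[1]]
  pos <- cumsum(ref != "-")
  pos[ref == "-"] <- NA_integer_
  as.integer(pos)
}

#' Call conserved alignment columns
#'
#' For each column the identity fraction is the count of rows carrying the
#' modal non-gap residue divided by the total number of rows (gaps never
#' count toward identity but stay in the denominator -- the strict reading
#' of the "identical in at least 70% of the sequences" rule). A column is
#' conserved when the fraction is at least `threshold`.
#'
#' @param aln An [msa()] with at least 2 rows.
#' @param threshold Conservation threshold (default 0.70).
#' @return A tibble (class `conservation_call`) with one row per column:
#'   `column`, `modal_residue`, `identity_fraction`, `conserved`,
#'   `reference_position` (NA where the reference row is gapped).
#' @examples
#' aln <- msa(seq_id = c("ref", "h1", "h2"),
#'            organism = c("B_subtilis", "org_2", "org_3"),
#'            sequence = c("MKWL", "MKAL", "MKWV"))
#' call_conservation(aln, threshold = 0.70)
#' @export
call_conservation <- function(aln, threshold = 0.70) {
  stopifnot(inherits(aln, "msa"))
  if (nrow(aln$rows) < 2) stop("alignment needs >= 2 rows", call. = FALSE)
  m <- msa_matrix(aln)
  n <- nrow(m)
  refpos <- reference_positions(aln)
  out <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col != "-"]
    if (length(res) == 0) {
      return(tibble::tibble(column = j, modal_residue = NA_character_,
                            identity_fraction = 0))
    }
    tab <- sort(table(res), decreasing = TRUE)
    # deterministic tie-break: among equally frequent residues, the
    # alphabetically first
    top <- max(tab)
    modal <- sort(names(tab)[tab == top])[1]
    tibble::tibble(column = j, modal_residue = modal,
                   identity_fraction = top / n)
  })
  out$conserved <- out$identity_fraction >= threshold
  out$reference_position <- refpos
  attr(out, "threshold") <- threshold
  class(out) <- c("conservation_call", class(out))
  out
}

#' Build a hybrid (paired) alignment of two interacting proteins
#'
#' Concatenates the two alignments row-wise, pairing non-reference rows by
#' organism tag; sequences present in only one alignment are dropped (and
#' listed in the drop log). The reference row becomes
#' `refA + 20 glycines + refB`; in all other rows the linker region is
#' filled with gaps so that the homologs stay aligned to the reference
#' proteins. Contact predictions computed on the hybrid can be cleaned up
#' with [mask_linker()], which discards predictions touching the inserted
#' linker.
#'
#' @param msa_a,msa_b [msa()] objects whose reference rows are the two
#'   interacting reference proteins (same organism tag).
#' @param linker_length Number of inserted glycines (default 20).
#' @return A `hybrid_msa` (an [msa()] with extras): attributes
#'   `linker_columns` (integer vector of linker column indices, 1-based),
#'   `width_a`, `width_b`, `pair_manifest` (tibble of paired row ids) and
#'   `dropped` (tibble of unpaired rows with the alignment they came from).
#' @export
build_hybrid_msa <- function(msa_a, msa_b,
                             linker_length = default_config()$linker_length) {
  stopifnot(inherits(msa_a, "msa"), inherits(msa_b, "msa"))
  ref_org <- msa_a$rows$organism[msa_a$reference]
  if (is.na(ref_org) || !identical(ref_org, msa_b$rows$organism[msa_b$reference])) {
    stop("reference organism missing from one of the alignments",
         call. = FALSE)
  }
  a <- msa_a$rows; b <- msa_b$rows
  a$.side_row <- seq_len(nrow(a)); b$.side_row <- seq_len(nrow(b))
  # collision rule: first occurrence of an organism tag wins, with a warning
  dedup <- function(x, label) {
    dup <- duplicated(x$organism) & !is.na(x$organism)
    if (any(dup)) {
      warning("duplicated organism tag(s) in ", label, ": keeping first occurrence",
              call. = FALSE)
    }
    x[!dup, , drop = FALSE]
  }
  a1 <- dedup(a, "first alignment"); b1 <- dedup(b, "second alignment")
  paired <- dplyr::inner_join(a1, b1, by = "organism",
                              suffix = c("_a", "_b"))
  # reference pair first
  ref_at <- which(paired$organism == ref_org)
  paired <- dplyr::bind_rows(paired[ref_at, ], paired[-ref_at, ])
  dropped <- dplyr::bind_rows(
    dplyr::anti_join(a1, b1, by = "organism") |>
      dplyr::transmute(seq_id = .data$seq_id, organism = .data$organism,
                       alignment = "a"),
    dplyr::anti_join(b1, a1, by = "organism") |>
      dplyr::transmute(seq_id = .data$seq_id, organism = .data$organism,
                       alignment = "b")
  )
  linker <- strrep("G", linker_length)
  gaps <- strrep("-", linker_length)
  mid <- c(linker, rep(gaps, nrow(paired) - 1))
  hyb <- msa(
    seq_id = paste(paired$seq_id_a, paired$seq_id_b, sep = "+"),
    organism = paired$organism,
    sequence = paste0(paired$sequence_a, mid, paired$sequence_b),
    reference = 1
  )
  refrow_a <- paired$sequence_a[1]
  if (grepl("-", refrow_a, fixed = TRUE) ||
      grepl("-", paired$sequence_b[1], fixed = TRUE)) {
    warning("reference row contains gaps; hybrid positions follow alignment columns",
            call. = FALSE)
  }
  attr(hyb, "linker_columns") <- msa_a$width + seq_len(linker_length)
  attr(hyb, "width_a") <- msa_a$width
  attr(hyb, "width_b") <- msa_b$width
  attr(hyb, "pair_manifest") <- tibble::tibble(
    row_a = paired$seq_id_a, row_b = paired$seq_id_b,
    organism = paired$organism
  )
  attr(hyb, "dropped") <- dropped
  class(hyb) <- c("hybrid_msa", class(hyb))
  hyb
}

#' Remove linker-region predictions from a hybrid contact map
#'
#' Contact predictions for the inserted glycine linker are artefacts of the
#' pasting and are discarded. Remaining records are re-indexed from hybrid
#' columns to per-protein positions: `scope` becomes `intra_a`, `intra_b`
#' or `inter`, with `pos_a`/`pos_b` 1-based on each protein.
#'
#' @param cm A [contact_map()] indexed on hybrid columns (1-based).
#' @param hybrid A hybrid alignment from [build_hybrid_msa()].
#' @return A tibble with columns `scope`, `pos_a`, `pos_b`, `probability`
#'   (classed `contact_map` via the `i`,`j` columns retained for `intra_*`
#'   scopes is dropped; this is the per-protein indexed form).
#' @export
mask_linker <- function(cm, hybrid) {
  stopifnot(inherits(hybrid, "hybrid_msa"))
  lk <- attr(hybrid, "linker_columns")
  wa <- attr(hybrid, "width_a"); wb <- attr(hybrid, "width_b")
  total <- wa + length(lk) + wb
  if (nrow(cm) > 0 && (max(cm$i, cm$j) > total || min(cm$i, cm$j) < 1)) {
    stop("contact position outside hybrid width (", total, ")", call. = FALSE)
  }
  keep <- !(cm$i %in% lk | cm$j %in% lk)
  cm <- cm[keep, , drop = FALSE]
  lo <- pmin(cm$i, cm$j); hi <- pmax(cm$i, cm$j)
  off <- wa + length(lk)
  side <- function(p) ifelse(p <= wa, "a", "b")
  reindex <- function(p) ifelse(p <= wa, p, p - off)
  tibble::tibble(
    scope = dplyr::case_when(
      side(lo) == "a" & side(hi) == "a" ~ "intra_a",
      side(lo) == "b" & side(hi) == "b" ~ "intra_b",
      TRUE ~ "inter"
    ),
    pos_a = as.integer(reindex(lo)),
    pos_b = as.integer(reindex(hi)),
    probability = cm$probability
  )
}

#' Curate a contact map into contact restraints
#'
#' Applies, in order: (1) the probability filter -- keep records with
#' probability strictly greater than `p_threshold` (0.15); (2) if a model
#' is supplied, the violation filter -- drop records whose per-contact
#' restraint score on that model (class weight times flat-bottom energy on
#' the ambiguous minimum distance, the same term used in [total_score()])
#' exceeds `violation_threshold` (10 score-units); (3) a manual exclusion
#' list, mirroring the editing of predicted contacts that were incompatible
#' with the cross-linking data.
#'
#' @param cm Data frame with columns `chain_a`, `res_a`, `chain_b`, `res_b`,
#'   `probability` (e.g. a re-indexed [mask_linker()] output joined to
#'   chains, or a [simulate_contact_map()] draw).
#' @param model Optional [ca_model()] used for the violation filter.
#' @param p_threshold Probability cutoff, strict (default 0.15).
#' @param violation_threshold Per-contact score cutoff in score-units
#'   (default 10).
#' @param weights A [score_weights()].
#' @param contact_bound Contact upper bound, Angstrom.
#' @param exclude Optional data frame of pairs to drop
#'   (`chain_a,res_a,chain_b,res_b`), applied last, order-insensitive.
#' @return A [restraint_table()] of `contact_intra` / `contact_inter` rows
#'   (intra: same chain; inter: different chains), with `upper_bound`
#'   filled.
#' @export
curate_contacts <- function(cm, model = NULL,
                            p_threshold = default_config()$contact_p_threshold,
                            violation_threshold = default_config()$contact_violation_threshold,
                            weights = score_weights(),
                            contact_bound = default_config()$contact_bound,
                            exclude = NULL) {
  cm <- tibble::as_tibble(cm)
  need <- c("chain_a", "res_a", "chain_b", "res_b", "probability")
  stopifnot(all(need %in% names(cm)))
  kept <- cm[cm$probability > p_threshold, , drop = FALSE]
  kept$class <- ifelse(kept$chain_a == kept$chain_b,
                       "contact_intra", "contact_inter")
  kept$upper_bound <- contact_bound
  if (!is.null(model) && nrow(kept) > 0) {
    topo <- model$topology
    score1 <- vapply(seq_len(nrow(kept)), function(k) {
      row <- kept[k, ]
      ca <- if (is.null(topo)) row$chain_a else copy_group(topo, row$chain_a)
      cb <- if (is.null(topo)) row$chain_b else copy_group(topo, row$chain_b)
      r <- contact_restraint(ca, row$res_a, cb, row$res_b,
                             probability = row$probability,
                             kind = sub("contact_", "", row$class),
                             upper_bound = contact_bound)
      w <- unlist(weights)[[row$class]]
      w * restraint_energy(model, r)
    }, 0)
    kept <- kept[score1 <= violation_threshold, , drop = FALSE]
  }
  if (!is.null(exclude) && nrow(kept) > 0) {
    key <- function(ca, ra, cb, rb) {
      k1 <- paste(ca, ra, cb, rb); k2 <- paste(cb, rb, ca, ra)
      pmin(k1, k2)
    }
    drop_keys <- key(exclude$chain_a, exclude$res_a,
                     exclude$chain_b, exclude$res_b)
    kept <- kept[!key(kept$chain_a, kept$res_a, kept$chain_b, kept$res_b)
                 %in% drop_keys, , drop = FALSE]
  }
  restraint_table(kept[, c("chain_a", "res_a", "chain_b", "res_b", "class",
                           "probability", "upper_bound")])
}
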