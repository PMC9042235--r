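#' Scoring weights for the restraint classes
#'
#' Relative weights applied when summing restraint energies into the total
#' score. The cross-link / inter-protein contact / intra-protein contact
#' weights default to 25, 0.25 and 0.1 -- the weighting used for the
#' inhibition-complex models. The remaining classes (rigid groups, anchors,
#' membrane slab, sterics, chain bonds) carry the package's own defaults.
#'
#' @param crosslink,contact_inter,contact_intra,rigid,anchor,slab,sterics,bond
#'   Non-negative class weights.
#' @return A named list of class `score_weights`.
#' @export
score_weights <- function(crosslink = 25, contact_inter = 0.25,
                          contact_intra = 0.1, rigid = 1, anchor = 1,
                          slab = 1, sterics = 1, bond = 1) {
  w <- list(crosslink = crosslink, contact_inter = contact_inter,
            contact_intra = contact_intra, rigid = rigid, anchor = anchor,
            slab = slab, sterics = sterics, bond = bond)
  if (any(unlist(w) < 0)) stop("weights must be >= 0", call. = FALSE)
  structure(w, class = "score_weights")
}

#' Flat-bottom harmonic distance energy
#'
#' Zero inside the upper bound, `(d - upper_bound)^2` beyond it (unit
#' internal force constant; the class weight is applied at aggregation).
#'
#' @param d Distance(s), Angstrom, non-negative.
#' @param upper_bound Upper bound(s), Angstrom, positive.
#' @return Energy, same length as `d`.
#' @export
distance_energy <- function(d, upper_bound) {
  if (any(d < 0)) stop("distance must be >= 0", call. = FALSE)
  if (any(upper_bound <= 0)) stop("upper_bound must be > 0", call. = FALSE)
  pmax(0, d - upper_bound)^2
}

## ---- restraint constructors -------------------------------------------

new_restraint <- function(subclass, ...) {
  structure(list(...), class = c(subclass, "restraint"))
}

#' Cross-link distance restraint
#'
#' An upper bound on the C-alpha distance between two engineered-cysteine
#' sites. Each side carries an equivalence set of chain copies; the
#' restraint acts on the minimum distance over all copy combinations
#' (contact predictions and cross-links cannot distinguish chemically
#' equivalent oligomer subunits). Negative cross-links record pairs that
#' failed to cross-link: they contribute no energy and are used only for
#' violation diagnostics and contact curation.
#'
#' @param chains_a,chains_b Character vectors: equivalent chain copies for
#'   each site.
#' @param res_a,res_b Author residue numbers (scalars).
#' @param upper_bound Upper bound, Angstrom (default 12 for
#'   disulfide-competent C-alpha pairs).
#' @param polarity `"positive"` or `"negative"`.
#' @return A `crosslink_restraint`.
#' @export
crosslink_restraint <- function(chains_a, res_a, chains_b, res_b,
                                upper_bound = 12, polarity = "positive") {
  polarity <- match.arg(polarity, c("positive", "negative"))
  if (length(chains_a) == 0 || length(chains_b) == 0) {
    stop("empty equivalence set", call. = FALSE)
  }
  if (upper_bound <= 0) stop("upper_bound must be > 0", call. = FALSE)
  new_restraint("crosslink_restraint",
                chains_a = chains_a, res_a = as.integer(res_a),
                chains_b = chains_b, res_b = as.integer(res_b),
                upper_bound = upper_bound, polarity = polarity)
}

#' Predicted-contact distance restraint
#'
#' Same geometry as [crosslink_restraint()] but derived from a predicted
#' residue contact, carrying its probability and an intra/inter kind that
#' selects the class weight.
#'
#' @inheritParams crosslink_restraint
#' @param probability Contact probability in (0, 1].
#' @param kind `"inter"` or `"intra"`.
#' @param upper_bound Upper bound, Angstrom (default 10 for a C-alpha
#'   contact).
#' @return A `contact_restraint`.
#' @export
contact_restraint <- function(chains_a, res_a, chains_b, res_b,
                              probability, kind = c("inter", "intra"),
                              upper_bound = 10) {
  kind <- match.arg(kind)
  if (length(chains_a) == 0 || length(chains_b) == 0) {
    stop("empty equivalence set", call. = FALSE)
  }
  if (probability <= 0 || probability > 1) {
    stop("probability must be in (0, 1]", call. = FALSE)
  }
  new_restraint("contact_restraint",
                chains_a = chains_a, res_a = as.integer(res_a),
                chains_b = chains_b, res_b = as.integer(res_b),
                upper_bound = upper_bound, probability = probability,
                kind = kind)
}

#' Rigid-group restraint
#'
#' Restrains the internal pairwise distances of a residue group (a helix or
#' domain) to reference values, so the group keeps its shape while moving
#' freely as a body.
#'
#' @param chain Chain id.
#' @param residues Integer vector of member residues (>= 3).
#' @param ref_dist Symmetric matrix of reference distances, or a
#'   [ca_model()] from which they are measured.
#' @param force_constant Internal force constant (score-units per
#'   Angstrom^2).
#' @return A `rigid_group_restraint`.
#' @export
rigid_group_restraint <- function(chain, residues, ref_dist,
                                  force_constant = 1) {
  residues <- as.integer(residues)
  if (length(residues) < 3) stop("rigid group needs >= 3 members", call. = FALSE)
  if (inherits(ref_dist, "ca_model")) {
    idx <- residue_index(ref_dist, rep(chain, length(residues)), residues)
    ref_dist <- as.matrix(stats::dist(coords_matrix(ref_dist)[idx, , drop = FALSE]))
  }
  stopifnot(is.matrix(ref_dist),
            nrow(ref_dist) == length(residues),
            isTRUE(all.equal(ref_dist, t(ref_dist))))
  new_restraint("rigid_group_restraint",
                chain = chain, residues = residues, ref_dist = ref_dist,
                force_constant = force_constant)
}

#' Positional anchor restraint
#'
#' Harmonic tether of every listed residue to a reference coordinate,
#' `k * sum(|x - x_ref|^2)`. The default force constant is 0.1
#' score-units per Angstrom^2, the value used to keep refined models close
#' to the assembled C-alpha model.
#'
#' @param ref Data frame with columns `chain`, `resno`, `x`, `y`, `z`, or a
#'   [ca_model()] (anchors every residue at its current position).
#' @param k Force constant, >= 0.
#' @return An `anchor_restraint`.
#' @export
anchor_restraint <- function(ref, k = 0.1) {
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (inherits(ref, "ca_model")) ref <- ref$coords
  ref <- tibble::as_tibble(ref)[, c("chain", "resno", "x", "y", "z")]
  new_restraint("anchor_restraint", ref = ref, k = k)
}

#' Membrane slab restraint
#'
#' Keeps membrane-embedded residues inside a slab of half-width `half_width`
#' centred on z = 0: quadratic penalty on `|z| - half_width` outside it.
#'
#' @param chain,residues Chain id(s) and residue numbers of the
#'   membrane-embedded residues (recycled against each other).
#' @param half_width Slab half-width, Angstrom (> 0, default 15).
#' @return A `membrane_slab_restraint`.
#' @export
membrane_slab_restraint <- function(chain, residues, half_width = 15) {
  if (half_width <= 0) stop("half_width must be > 0", call. = FALSE)
  members <- tibble::tibble(chain = chain, resno = as.integer(residues))
  new_restraint("membrane_slab_restraint",
                members = members, half_width = half_width)
}

#' Soft-core steric repulsion
#'
#' Quadratic penalty on any non-bonded bead pair closer than `d_min`
#' (default 4.0 Angstrom C-alpha to C-alpha). Consecutive residues of a
#' chain are exempt; they are handled by [chain_bond_restraint()].
#'
#' @param d_min Minimum allowed non-bonded distance, Angstrom.
#' @return A `steric_restraint`.
#' @export
steric_restraint <- function(d_min = 4) {
  new_restraint("steric_restraint", d_min = d_min)
}

#' Chain-connectivity springs
#'
#' Harmonic springs at the ideal C-alpha virtual bond length (3.8 Angstrom)
#' between consecutive residues (author numbers differing by one) of each
#' chain.
#'
#' @param bond_length Rest length, Angstrom.
#' @return A `chain_bond_restraint`.
#' @export
chain_bond_restraint <- function(bond_length = 3.8) {
  new_restraint("chain_bond_restraint", bond_length = bond_length)
}

#' Bundle restraints into a set
#'
#' @param ... Restraint objects or lists of them.
#' @return A `restraint_set` (a flat list of restraints).
#' @export
restraint_set <- function(...) {
  items <- list(...)
  flat <- list()
  for (it in items) {
    if (inherits(it, "restraint")) flat <- c(flat, list(it))
    else if (is.list(it)) {
      stopifnot(all(vapply(it, inherits, TRUE, "restraint")))
      flat <- c(flat, it)
    } else stop("not a restraint", call. = FALSE)
  }
  structure(flat, class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("<restraint_set> ", length(x), " restraints\n", sep = "")
  cls <- table(vapply(x, restraint_class, ""))
  for (nm in names(cls)) cat("  ", nm, ": ", cls[[nm]], "\n", sep = "")
  invisible(x)
}

#' @export
c.restraint_set <- function(...) restraint_set(...)

## score class label of a restraint (keys into score_weights)
restraint_class <- function(r) {
  if (inherits(r, "crosslink_restraint")) return("crosslink")
  if (inherits(r, "contact_restraint")) {
    return(if (r$kind == "inter") "contact_inter" else "contact_intra")
  }
  if (inherits(r, "rigid_group_restraint")) return("rigid")
  if (inherits(r, "anchor_restraint")) return("anchor")
  if (inherits(r, "membrane_slab_restraint")) return("slab")
  if (inherits(r, "steric_restraint")) return("sterics")
  if (inherits(r, "chain_bond_restraint")) return("bond")
  stop("unknown restraint type", call. = FALSE)
}

#' @rdname restraint_set
#' @param x A `restraint_set`.
#' @export
tidy.restraint_set <- function(x, ...) {
  purrr::map_dfr(x, function(r) {
    tibble::tibble(
      class = restraint_class(r),
      chain_a = if (!is.null(r$chains_a)) paste(r$chains_a, collapse = ",") else NA_character_,
      res_a = if (!is.null(r$res_a)) r$res_a else NA_integer_,
      chain_b = if (!is.null(r$chains_b)) paste(r$chains_b, collapse = ",") else NA_character_,
      res_b = if (!is.null(r$res_b)) r$res_b else NA_integer_,
      upper_bound = if (!is.null(r$upper_bound)) r$upper_bound else NA_real_,
      probability = if (!is.null(r$probability)) r$probability else NA_real_,
      polarity = if (!is.null(r$polarity)) r$polarity else NA_character_
    )
  })
}

## ---- energies ----------------------------------------------------------

#' Ambiguous minimum distance of a paired restraint
#'
#' Minimum C-alpha distance over the Cartesian product of the equivalence
#' sets on both sides of a cross-link or contact restraint -- the "closest
#' copy" reading of restraints on oligomers.
#'
#' @param model A [ca_model()].
#' @param r A [crosslink_restraint()] or [contact_restraint()].
#' @return Distance in Angstrom.
#' @export
ambiguous_min_distance <- function(model, r) {
  if (length(r$chains_a) == 0 || length(r$chains_b) == 0) {
    stop("empty equivalence set", call. = FALSE)
  }
  m <- coords_matrix(model)
  ia <- residue_index(model, r$chains_a, rep(r$res_a, length(r$chains_a)))
  ib <- residue_index(model, r$chains_b, rep(r$res_b, length(r$chains_b)))
  best <- Inf
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((m[i, ] - m[j, ])^2))
    if (d < best) best <- d
  }
  best
}

#' Energy of a single restraint on a model
#'
#' Dispatches over the restraint types: flat-bottom harmonic on the
#' ambiguous minimum distance for cross-links (positive polarity only) and
#' contacts; sum of squared internal-distance deviations for rigid groups;
#' harmonic tethers for anchors; quadratic slab penalty on `|z|`; soft-core
#' repulsion for sterics; bond springs for chain connectivity. All energies
#' are >= 0 and zero iff the restraint is satisfied. Class weights are not
#' applied here; see [total_score()].
#'
#' @param model A [ca_model()].
#' @param r A restraint.
#' @return Non-negative energy in score-units.
#' @export
restraint_energy <- function(model, r) UseMethod("restraint_energy", r)

#' @export
restraint_energy.crosslink_restraint <- function(model, r) {
  if (r$polarity == "negative") return(0)
  distance_energy(ambiguous_min_distance(model, r), r$upper_bound)
}

#' @export
restraint_energy.contact_restraint <- function(model, r) {
  distance_energy(ambiguous_min_distance(model, r), r$upper_bound)
}

#' @export
restraint_energy.rigid_group_restraint <- function(model, r) {
  idx <- residue_index(model, rep(r$chain, length(r$residues)), r$residues)
  d <- as.matrix(stats::dist(coords_matrix(model)[idx, , drop = FALSE]))
  dev <- (d - r$ref_dist)[upper.tri(d)]
  r$force_constant * sum(dev^2)
}

#' @export
restraint_energy.anchor_restraint <- function(model, r) {
  idx <- residue_index(model, r$ref$chain, r$ref$resno)
  m <- coords_matrix(model)[idx, , drop = FALSE]
  r$k * sum((m - as.matrix(r$ref[, c("x", "y", "z")]))^2)
}

#' @export
restraint_energy.membrane_slab_restraint <- function(model, r) {
  idx <- residue_index(model, r$members$chain, r$members$resno)
  z <- coords_matrix(model)[idx, 3]
  sum(pmax(0, abs(z) - r$half_width)^2)
}

#' @export
restraint_energy.steric_restraint <- function(model, r) {
  m <- coords_matrix(model)
  d <- as.matrix(stats::dist(m))
  pen <- pmax(r$d_min - d, 0)^2  # first arg keeps the matrix dims
  bp <- bond_pairs(model)
  pen[bp] <- 0; pen[bp[, 2:1, drop = FALSE]] <- 0
  sum(pen[upper.tri(pen)])
}

#' @export
restraint_energy.chain_bond_restraint <- function(model, r) {
  bp <- bond_pairs(model)
  if (nrow(bp) == 0) return(0)
  m <- coords_matrix(model)
  d <- sqrt(rowSums((m[bp[, 1], , drop = FALSE] - m[bp[, 2], , drop = FALSE])^2))
  sum((d - r$bond_length)^2)
}

#' Weighted total score of a model under a restraint set
#'
#' Sum over restraints of class weight times restraint energy. The return
#' value is the scalar score; per-class subtotals are attached as the
#' `"breakdown"` attribute and can be retrieved with [score_breakdown()].
#'
#' @param model A [ca_model()].
#' @param restraints A [restraint_set()].
#' @param weights A [score_weights()].
#' @return Scalar score (score-units) with a `breakdown` attribute.
#' @export
total_score <- function(model, restraints, weights = score_weights()) {
  cls <- vapply(restraints, restraint_class, "")
  en <- vapply(restraints, function(r) restraint_energy(model, r), 0)
  w <- unlist(weights)[cls]
  br <- tibble::tibble(class = cls, energy = en, weight = unname(w),
                       weighted = en * unname(w)) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(), energy = sum(.data$energy),
                     weighted = sum(.data$weighted), .groups = "drop")
  structure(sum(en * w), breakdown = br)
}

#' @rdname total_score
#' @param score A value returned by [total_score()].
#' @export
score_breakdown <- function(score) attr(score, "breakdown")

#' Count restraint violations
#'
#' A positive cross-link or contact is violated when its ambiguous minimum
#' distance exceeds `upper_bound + tol`; a negative cross-link is violated
#' when the distance falls below `upper_bound - tol` (proximity where none
#' was observed experimentally). Only distance-type restraints are counted.
#'
#' @param model A [ca_model()].
#' @param restraints A [restraint_set()].
#' @param tol Tolerance in Angstrom (default 0).
#' @return Tibble with one row per class (`crosslink_positive`,
#'   `crosslink_negative`, `contact_inter`, `contact_intra`) plus a `total`
#'   row: columns `class`, `n`, `violations`.
#' @export
count_violations <- function(model, restraints, tol = 0) {
  rows <- purrr::map_dfr(restraints, function(r) {
    cls <- if (inherits(r, "crosslink_restraint")) {
      paste0("crosslink_", r$polarity)
    } else if (inherits(r, "contact_restraint")) {
      paste0("contact_", r$kind)
    } else return(NULL)
    d <- ambiguous_min_distance(model, r)
    viol <- if (identical(cls, "crosslink_negative")) {
      d < r$upper_bound - tol
    } else {
      d > r$upper_bound + tol
    }
    tibble::tibble(class = cls, violated = viol)
  })
  lev <- c("crosslink_positive", "crosslink_negative",
           "contact_inter", "contact_intra")
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(class = character(), violated = logical())
  }
  out <- rows |>
    dplyr::mutate(class = factor(.data$class, levels = lev)) |>
    dplyr::group_by(.data$class, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     violations = sum(.data$violated), .groups = "drop") |>
    dplyr::mutate(class = as.character(.data$class))
  dplyr::bind_rows(out, tibble::tibble(class = "total", n = sum(out$n),
                                       violations = sum(out$violations)))
}

#' Cross-link violation count of a model
#'
#' Convenience accessor for the selection key used in ensemble ranking:
#' the number of violated positive cross-links.
#'
#' @inheritParams count_violations
#' @return Integer count.
#' @export
crosslink_violations <- function(model, restraints, tol = 0) {
  v <- count_violations(model, restraints, tol)
  as.integer(v$violations[v$class == "crosslink_positive"])
}
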