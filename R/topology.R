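#' Define the chain layout of a complex
#'
#' A complex topology records which chains make up the system, which chains
#' are chemically equivalent copies of the same entity (e.g. the four
#' subunits of a protease tetramer), which residue stretches move as rigid
#' groups (helices, domains), and which residues are membrane-embedded.
#' All residue numbering is author (1-based) numbering; residues are keyed
#' by `(chain, resno)` throughout the package.
#'
#' @param chains Data frame with columns `chain_id`, `entity`, `copy` and a
#'   list-column `residues` of integer vectors (author numbering, strictly
#'   increasing).
#' @param rigid_groups Optional data frame with columns `group_id`,
#'   `chain_id` and list-column `residues`; each group needs at least three
#'   members.
#' @param membrane Optional data frame with columns `chain_id` and
#'   list-column `residues` flagging membrane-embedded residues.
#'
#' @return A `complex_topology` object.
#' @export
complex_topology <- function(chains, rigid_groups = NULL, membrane = NULL) {
  chains <- tibble::as_tibble(chains)
  stopifnot(all(c("chain_id", "entity", "copy", "residues") %in% names(chains)))
  if (anyDuplicated(chains$chain_id)) {
    stop("duplicated chain_id in topology", call. = FALSE)
  }
  for (r in chains$residues) {
    if (length(r) == 0 || is.unsorted(r, strictly = TRUE)) {
      stop("chain residues must be non-empty and strictly increasing", call. = FALSE)
    }
  }
  if (!is.null(rigid_groups)) {
    rigid_groups <- tibble::as_tibble(rigid_groups)
    stopifnot(all(c("group_id", "chain_id", "residues") %in% names(rigid_groups)))
    if (any(lengths(rigid_groups$residues) < 3)) {
      stop("rigid groups need at least 3 member residues", call. = FALSE)
    }
  }
  if (!is.null(membrane)) {
    membrane <- tibble::as_tibble(membrane)
    stopifnot(all(c("chain_id", "residues") %in% names(membrane)))
  }
  structure(
    list(chains = chains, rigid_groups = rigid_groups, membrane = membrane),
    class = "complex_topology"
  )
}

#' @export
print.complex_topology <- function(x, ...) {
  cat("<complex_topology> ", nrow(x$chains), " chains, ",
      sum(lengths(x$chains$residues)), " residues\n", sep = "")
  ent <- dplyr::count(x$chains, .data$entity, name = "copies")
  for (i in seq_len(nrow(ent))) {
    cat("  ", ent$entity[i], " x", ent$copies[i], "\n", sep = "")
  }
  invisible(x)
}

#' Chains equivalent to a given chain
#'
#' Returns the chain ids belonging to the same entity (oligomer copies).
#' Used to expand ambiguous restraints over chemically equivalent subunits.
#'
#' @param topology A [complex_topology()].
#' @param chain_id A chain id present in the topology.
#' @return Character vector of equivalent chain ids (includes `chain_id`).
#' @export
copy_group <- function(topology, chain_id) {
  ch <- topology$chains
  ent <- ch$entity[match(chain_id, ch$chain_id)]
  if (is.na(ent)) stop("unknown chain '", chain_id, "'", call. = FALSE)
  ch$chain_id[ch$entity == ent]
}

#' Coarse-grained C-alpha model of a complex
#'
#' One bead (3-D coordinate, Angstrom) per residue per chain. Coordinates
#' live in a tibble with columns `chain`, `resno`, `x`, `y`, `z` (additional
#' columns such as `aa` are carried along untouched). Zinc pseudo-atoms
#' added by [place_zinc()] are stored separately and written as HETATM
#' records by [write_ca_pdb()].
#'
#' @param coords Data frame with columns `chain`, `resno`, `x`, `y`, `z`.
#' @param topology Optional [complex_topology()] consistent with `coords`.
#' @param zn Optional data frame of zinc sites (`chain`, `x`, `y`, `z`).
#' @return A `ca_model` object.
#' @export
ca_model <- function(coords, topology = NULL, zn = NULL) {
  coords <- tibble::as_tibble(coords)
  stopifnot(all(c("chain", "resno", "x", "y", "z") %in% names(coords)))
  if (anyDuplicated(coords[, c("chain", "resno")])) {
    stop("duplicated (chain, resno) in coordinates", call. = FALSE)
  }
  structure(list(coords = coords, topology = topology, zn = zn),
            class = "ca_model")
}

#' @export
print.ca_model <- function(x, ...) {
  cat("<ca_model> ", nrow(x$coords), " residues in ",
      dplyr::n_distinct(x$coords$chain), " chains",
      if (!is.null(x$zn)) paste0(", ", nrow(x$zn), " Zn"), "\n", sep = "")
  invisible(x)
}

#' @rdname ca_model
#' @param x A `ca_model`.
#' @param ... Unused.
#' @export
tidy.ca_model <- function(x, ...) x$coords

#' @rdname ca_model
#' @export
glance.ca_model <- function(x, ...) {
  tibble::tibble(
    n_residues = nrow(x$coords),
    n_chains = dplyr::n_distinct(x$coords$chain),
    n_zn = if (is.null(x$zn)) 0L else nrow(x$zn)
  )
}

## internal: coordinates as plain matrix plus (chain, resno) -> row lookup
coords_matrix <- function(model) {
  m <- as.matrix(model$coords[, c("x", "y", "z")])
  rownames(m) <- residue_key(model$coords$chain, model$coords$resno)
  m
}

residue_key <- function(chain, resno) paste(chain, resno, sep = ":")

residue_index <- function(model, chain, resno, strict = TRUE) {
  idx <- match(residue_key(chain, resno),
               residue_key(model$coords$chain, model$coords$resno))
  if (strict && anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("residue ", chain[miss], ":", resno[miss], " not in model",
         call. = FALSE)
  }
  idx
}

#' Distance between two residues of a model
#'
#' @param model A [ca_model()].
#' @param chain_a,res_a,chain_b,res_b Residue identifiers.
#' @return Euclidean C-alpha distance in Angstrom.
#' @export
residue_distance <- function(model, chain_a, res_a, chain_b, res_b) {
  m <- coords_matrix(model)
  i <- residue_index(model, chain_a, res_a)
  j <- residue_index(model, chain_b, res_b)
  sqrt(sum((m[i, ] - m[j, ])^2))
}

## internal: consecutive-residue bonds (author numbers differing by 1
## within a chain); returns integer matrix of row index pairs
bond_pairs <- function(model) {
  co <- model$coords
  ord <- order(co$chain, co$resno)
  ch <- co$chain[ord]
  rn <- co$resno[ord]
  take <- which(ch[-length(ch)] == ch[-1] & rn[-1] - rn[-length(rn)] == 1L)
  cbind(ord[take], ord[take + 1L])
}

#' Superpose one model onto another and report the RMSD
#'
#' Least-squares (Kabsch) superposition over residues shared by the two
#' models, matched by `(chain, resno)`.
#'
#' @param model,reference [ca_model()] objects sharing residue keys.
#' @return A list with `rmsd` (Angstrom) and `model` (the transformed copy).
#' @export
superpose <- function(model, reference) {
  ka <- residue_key(model$coords$chain, model$coords$resno)
  kb <- residue_key(reference$coords$chain, reference$coords$resno)
  common <- intersect(ka, kb)
  if (length(common) < 3) stop("fewer than 3 shared residues", call. = FALSE)
  P <- coords_matrix(model)[match(common, ka), , drop = FALSE]
  Q <- coords_matrix(reference)[match(common, kb), , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  full <- sweep(coords_matrix(model), 2, pc) %*% R
  full <- sweep(full, 2, qc, `+`)
  out <- model
  out$coords$x <- full[, 1]; out$coords$y <- full[, 2]; out$coords$z <- full[, 3]
  fitted <- sweep(P0 %*% R, 2, qc, `+`)
  list(rmsd = sqrt(mean(rowSums((fitted - Q)^2))), model = out)
}
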