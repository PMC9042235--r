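#' Synthetic benchmark specification
#'
#' The generator settings used throughout testing. Defaults describe the
#' standard recovery benchmark: a 2-chain, 3-helices-per-chain membrane
#' bundle of ~90 residues, 12 planted cross-links with no false positives,
#' and a contact map with true-positive rate 0.8 and false-positive rate
#' 0.05.
#'
#' @param seed Integer seed.
#' @param n_chains Number of chains.
#' @param helices_per_chain Helices per chain.
#' @param helix_length Residues per helix.
#' @param membrane_half_width Membrane slab half-width, Angstrom.
#' @param crosslinks List: `n_tp`, `n_tn`, `n_fp`, `bound` (Angstrom),
#'   `margin` (Angstrom separating true negatives / decoys from the bound).
#' @param contacts List: `cutoff` (Angstrom), `tp_rate`, `fp_rate`,
#'   `min_seq_sep` (minimum intra-chain sequence separation).
#' @param msa List: `n_rows`, `targets` (per-column conservation targets).
#' @return A `synth_spec` list.
#' @examples
#' spec <- synth_spec(seed = 1)
#' ref <- make_reference_complex(spec)
#' xl <- simulate_crosslinks(ref, spec)
#' count_violations(ref, as_restraint_set(xl, ref$topology))
#' @export
synth_spec <- function(seed = 1, n_chains = 2, helices_per_chain = 3,
                       helix_length = 15, membrane_half_width = 15,
                       crosslinks = list(n_tp = 12, n_tn = 4, n_fp = 0,
                                         bound = 12, margin = 8),
                       contacts = list(cutoff = 10, tp_rate = 0.8,
                                       fp_rate = 0.05, min_seq_sep = 4),
                       msa = list(n_rows = 20,
                                  targets = c(0.5, 0.69, 0.70, 0.71, 1.0))) {
  rates <- c(contacts$tp_rate, contacts$fp_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]", call. = FALSE)
  if (any(c(crosslinks$n_tp, crosslinks$n_tn, crosslinks$n_fp) < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  structure(list(seed = seed, n_chains = n_chains,
                 helices_per_chain = helices_per_chain,
                 helix_length = helix_length,
                 membrane_half_width = membrane_half_width,
                 crosslinks = crosslinks, contacts = contacts, msa = msa),
            class = "synth_spec")
}

## ideal alpha-helix C-alpha trace: rise 1.5 A/residue, 100 deg/residue,
## radius 2.3 A (consecutive C-alpha ~ 3.8 A), axis along z through `origin`
ideal_helix <- function(n, origin, up = TRUE, phase = 0) {
  t <- seq_len(n) - 1
  ang <- phase + t * 100 * pi / 180
  z <- (t - (n - 1) / 2) * 1.5
  if (!up) z <- -z
  cbind(x = origin[1] + 2.3 * cos(ang),
        y = origin[2] + 2.3 * sin(ang),
        z = z)
}

#' Generate a synthetic reference membrane complex
#'
#' Ideal alpha-helix C-alpha traces (1.5 Angstrom rise, 100 degrees per
#' residue, consecutive C-alpha ~ 3.8 Angstrom) packed clash-free on a
#' hexagonal lattice of helix axes (10 Angstrom spacing, antiparallel
#' alternation), with consecutive helices of a chain on adjacent lattice
#' sites. Helices of one chain are separate rigid segments with a gap in
#' residue numbering (as across a chain break), so consecutive-numbered
#' residues are always at virtual-bond distance. All residues are annotated
#' membrane-embedded (the bundle spans the slab). A tiny seeded jitter
#' (0.02 Angstrom) breaks exact degeneracies; deterministic given
#' `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return A [ca_model()] whose topology carries per-helix rigid groups and
#'   membrane annotations.
#' @export
make_reference_complex <- function(spec = synth_spec()) {
  set.seed(spec$seed)
  h <- spec$helices_per_chain
  len <- spec$helix_length
  total <- spec$n_chains * h
  # hexagonal lattice sites, row-major; consecutive sites 10 A apart
  per_row <- max(h, ceiling(sqrt(total)))
  sites <- list()
  r <- 0
  while (length(sites) < total) {
    for (cc in 0:(per_row - 1)) {
      sites[[length(sites) + 1]] <- c(cc * 10 + (r %% 2) * 5, r * 8.6603)
    }
    r <- r + 1
  }
  coords <- list(); rigid <- list(); membrane <- list()
  chain_rows <- list()
  for (ci in seq_len(spec$n_chains)) {
    chain_id <- LETTERS[ci]
    blocks <- list()
    for (hi in seq_len(h)) {
      site <- sites[[(ci - 1) * h + hi]]
      res0 <- (hi - 1) * (len + 5)
      m <- ideal_helix(len, site, up = (hi %% 2 == 1),
                       phase = (ci + hi) * 0.7)
      blocks[[hi]] <- tibble::tibble(chain = chain_id,
                                     resno = res0 + seq_len(len),
                                     x = m[, 1], y = m[, 2], z = m[, 3])
      rigid[[length(rigid) + 1]] <- tibble::tibble(
        group_id = paste0(chain_id, "_h", hi), chain_id = chain_id,
        residues = list(res0 + seq_len(len))
      )
    }
    blk <- dplyr::bind_rows(blocks)
    coords[[ci]] <- blk
    membrane[[ci]] <- tibble::tibble(chain_id = chain_id,
                                     residues = list(blk$resno))
    chain_rows[[ci]] <- tibble::tibble(chain_id = chain_id,
                                       entity = chain_id, copy = 1L,
                                       residues = list(blk$resno))
  }
  co <- dplyr::bind_rows(coords)
  co[, c("x", "y", "z")] <- co[, c("x", "y", "z")] +
    matrix(stats::rnorm(3 * nrow(co), sd = 0.02), ncol = 3)
  topo <- complex_topology(dplyr::bind_rows(chain_rows),
                           rigid_groups = dplyr::bind_rows(rigid),
                           membrane = dplyr::bind_rows(membrane))
  model <- ca_model(co, topology = topo)
  # packing sanity: bounded retry contract -- the lattice construction is
  # clash-free by design, so a violation means an unsatisfiable spec
  m <- coords_matrix(model)
  d <- as.matrix(stats::dist(m))
  bp <- bond_pairs(model)
  d[bp] <- Inf; d[bp[, 2:1, drop = FALSE]] <- Inf
  diag(d) <- Inf
  if (min(d) < 4) stop("unsatisfiable packing for this spec", call. = FALSE)
  model
}

## all residue pairs with distances; scope: "inter" or "any"
all_pairs <- function(model, scope = "any", min_seq_sep = 0) {
  co <- model$coords
  m <- coords_matrix(model)
  idx <- utils::combn(nrow(co), 2)
  i <- idx[1, ]; j <- idx[2, ]
  d <- sqrt(rowSums((m[i, , drop = FALSE] - m[j, , drop = FALSE])^2))
  tb <- tibble::tibble(chain_a = co$chain[i], res_a = co$resno[i],
                       chain_b = co$chain[j], res_b = co$resno[j],
                       distance = d)
  if (scope == "inter") tb <- tb[tb$chain_a != tb$chain_b, , drop = FALSE]
  if (min_seq_sep > 0) {
    tb <- tb[tb$chain_a != tb$chain_b |
               abs(tb$res_a - tb$res_b) >= min_seq_sep, , drop = FALSE]
  }
  tb
}

#' Simulate a cross-linking experiment on a reference complex
#'
#' True positives are drawn uniformly from inter-chain residue pairs within
#' the cross-link bound; true negatives (observed non-cross-linking pairs)
#' from pairs beyond `bound + margin`; false positives, if requested, are
#' distant pairs mislabelled positive. The ground-truth label of every row
#' is kept in the `"truth"` attribute for test oracles.
#'
#' @param reference A [ca_model()].
#' @param spec A [synth_spec()] (its `crosslinks` and `seed` are used).
#' @return A [restraint_table()] of `crosslink_positive` /
#'   `crosslink_negative` rows with `upper_bound` set to the simulated
#'   bound; attribute `truth` is a character vector (`"tp"`, `"fp"`,
#'   `"tn"`) aligned with the rows.
#' @export
simulate_crosslinks <- function(reference, spec = synth_spec()) {
  cl <- spec$crosslinks
  set.seed(spec$seed + 1L)
  pairs <- all_pairs(reference, scope = "inter")
  near <- pairs[pairs$distance <= cl$bound, , drop = FALSE]
  far <- pairs[pairs$distance > cl$bound + cl$margin, , drop = FALSE]
  if (nrow(near) < cl$n_tp || nrow(far) < cl$n_tn + cl$n_fp) {
    stop("not enough eligible pairs for the requested cross-link counts",
         call. = FALSE)
  }
  tp <- near[sample.int(nrow(near), cl$n_tp), , drop = FALSE]
  fa <- far[sample.int(nrow(far), cl$n_tn + cl$n_fp), , drop = FALSE]
  tn <- fa[seq_len(cl$n_tn), , drop = FALSE]
  fp <- fa[cl$n_tn + seq_len(cl$n_fp), , drop = FALSE]
  tab <- dplyr::bind_rows(
    dplyr::mutate(tp, class = "crosslink_positive"),
    dplyr::mutate(fp, class = "crosslink_positive"),
    dplyr::mutate(tn, class = "crosslink_negative")
  )
  out <- restraint_table(tibble::tibble(
    chain_a = tab$chain_a, res_a = tab$res_a,
    chain_b = tab$chain_b, res_b = tab$res_b, class = tab$class,
    probability = NA_real_, upper_bound = cl$bound
  ))
  attr(out, "truth") <- c(rep("tp", nrow(tp)), rep("fp", nrow(fp)),
                          rep("tn", nrow(tn)))
  out
}

## scaled Beta draws for contact probabilities: true contacts above the
## curation threshold, false contacts straddling it
r_true_prob <- function(n) 0.15 + 0.85 * stats::rbeta(n, 5, 2)
r_false_prob <- function(n) pmin(0.3, pmax(1e-6, 0.3 * stats::rbeta(n, 2, 5)))

#' Simulate a predicted contact map on a reference complex
#'
#' Emulates co-evolution-derived contact predictions: every true contact
#' (pair within the cutoff) is emitted with probability `tp_rate` and a
#' probability value drawn from Beta(5, 2) scaled to (0.15, 1]; false
#' contacts (pairs beyond the cutoff) are emitted at `fp_rate` with values
#' from Beta(2, 5) scaled to (0, 0.3], straddling the 0.15 curation
#' threshold. Ground truth is kept in the `truth` column.
#'
#' @inheritParams simulate_crosslinks
#' @return A tibble (class `contact_map`) with columns `chain_a`, `res_a`,
#'   `chain_b`, `res_b`, `probability`, `truth` (`"tp"`/`"fp"`) and the
#'   reference `distance`.
#' @export
simulate_contact_map <- function(reference, spec = synth_spec()) {
  ct <- spec$contacts
  set.seed(spec$seed + 2L)
  pairs <- all_pairs(reference, scope = "any", min_seq_sep = ct$min_seq_sep)
  true_p <- pairs[pairs$distance <= ct$cutoff, , drop = FALSE]
  false_p <- pairs[pairs$distance > ct$cutoff, , drop = FALSE]
  tp <- true_p[stats::runif(nrow(true_p)) < ct$tp_rate, , drop = FALSE]
  fp <- false_p[stats::runif(nrow(false_p)) < ct$fp_rate, , drop = FALSE]
  out <- dplyr::bind_rows(
    dplyr::mutate(tp, probability = r_true_prob(nrow(tp)), truth = "tp"),
    dplyr::mutate(fp, probability = r_false_prob(nrow(fp)), truth = "fp")
  )
  class(out) <- c("contact_map", class(out))
  out
}

#' Simulate a multiple sequence alignment with controlled conservation
#'
#' Per column, the modal residue is planted in `floor(target * n_rows)`
#' rows and the remaining rows draw uniformly from the other 19 amino
#' acids, so the realized identity fraction is `floor(target * n) / n` and
#' the conservation caller recovers exactly the columns whose target
#' reaches the threshold. Organism tags are `tag_prefix` followed by the
#' row number, with the reference row tagged `ref_organism`.
#'
#' @param spec A [synth_spec()] (its `msa` and `seed` are used).
#' @param ref_organism Organism tag of the reference (first) row.
#' @param tag_prefix Prefix for the homolog organism tags.
#' @return An [msa()].
#' @export
simulate_msa <- function(spec = synth_spec(), ref_organism = "B_subtilis",
                         tag_prefix = "org") {
  ms <- spec$msa
  set.seed(spec$seed + 3L)
  n <- ms$n_rows
  targets <- ms$targets
  if (any(targets < 1 / n | targets > 1)) {
    stop("conservation targets must be in [1/n_rows, 1]", call. = FALSE)
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cols <- lapply(targets, function(tg) {
    modal <- sample(aa, 1)
    k <- floor(tg * n + 1e-9)  # guard the exact-multiple boundary
    col <- character(n)
    keep <- sample.int(n, k)
    col[keep] <- modal
    col[-keep] <- sample(setdiff(aa, modal), n - k, replace = TRUE)
    col
  })
  m <- do.call(cbind, cols)
  msa(seq_id = c("ref", paste0("row", seq_len(n - 1) + 1)),
      organism = c(ref_organism, paste0(tag_prefix, "_", seq_len(n - 1) + 1)),
      sequence = apply(m, 1, paste, collapse = ""),
      reference = 1)
}

#' Simulate a pair of alignments sharing organism tags
#'
#' Two alignments of "interacting proteins" whose rows share organism tags
#' (apart from `n_unpaired` rows private to each), for exercising
#' [build_hybrid_msa()].
#'
#' @param spec A [synth_spec()].
#' @param n_unpaired Rows present in only one of the two alignments.
#' @inheritParams simulate_msa
#' @return List with elements `a` and `b` ([msa()] objects).
#' @export
simulate_msa_pair <- function(spec = synth_spec(), n_unpaired = 1,
                              ref_organism = "B_subtilis") {
  a <- simulate_msa(spec, ref_organism = ref_organism, tag_prefix = "org")
  spec_b <- spec
  spec_b$seed <- spec$seed + 1000L
  spec_b$msa$targets <- rev(spec$msa$targets)
  b <- simulate_msa(spec_b, ref_organism = ref_organism, tag_prefix = "org")
  if (n_unpaired > 0) {
    extra <- function(aln, label, k) {
      set.seed(spec$seed + 4L)
      aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
      seqs <- vapply(seq_len(k), function(i) {
        paste(sample(aa, aln$width, replace = TRUE), collapse = "")
      }, "")
      msa(seq_id = c(aln$rows$seq_id, paste0(label, seq_len(k))),
          organism = c(aln$rows$organism, paste0(label, "_only_", seq_len(k))),
          sequence = c(aln$rows$sequence, seqs), reference = aln$reference)
    }
    a <- extra(a, "a", n_unpaired)
    b <- extra(b, "b", n_unpaired)
  }
  list(a = a, b = b)
}

#' Scramble a model by rigid per-chain transforms
#'
#' Applies a seeded random rigid-body transform to every chain: a uniform
#' random rotation about the chain centroid and a translation of length up
#' to `magnitude` Angstrom in a uniform random direction. Internal chain
#' geometry is untouched.
#'
#' @param model A [ca_model()].
#' @param seed Integer seed.
#' @param magnitude Maximum translation, Angstrom (0 is the identity).
#' @return The scrambled [ca_model()].
#' @export
scramble <- function(model, seed = 1, magnitude = 30) {
  set.seed(seed)
  co <- model$coords
  for (ch in unique(co$chain)) {
    rows <- which(co$chain == ch)
    m <- as.matrix(co[rows, c("x", "y", "z")])
    ctr <- colMeans(m)
    if (magnitude > 0) {
      R <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      shift <- u * stats::runif(1, 0, magnitude)
      m <- sweep(sweep(m, 2, ctr) %*% R, 2, ctr + shift, `+`)
    }
    co[rows, c("x", "y", "z")] <- tibble::as_tibble(m, .name_repair = ~c("x", "y", "z"))
  }
  model$coords <- co
  model
}
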