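RESTRAINT_CLASSES <- c("crosslink_positive", "crosslink_negative",
                       "contact_inter", "contact_intra")

#' Validate a tabular restraint table
#'
#' A restraint table is the TSV-facing tabular form of paired restraints:
#' columns `chain_a`, `res_a`, `chain_b`, `res_b`, `class`, `probability`,
#' `upper_bound`. `class` is one of `crosslink_positive`,
#' `crosslink_negative`, `contact_inter`, `contact_intra`. Probability must
#' be present exactly for contact classes; self-pairs (same chain and
#' residue) are rejected.
#'
#' @param x A data frame.
#' @return The validated tibble, classed `restraint_table`.
#' @export
restraint_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("chain_a", "res_a", "chain_b", "res_b", "class")
  if (!all(need %in% names(x))) {
    stop("restraint table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"probability" %in% names(x)) x$probability <- NA_real_
  if (!"upper_bound" %in% names(x)) x$upper_bound <- NA_real_
  bad <- setdiff(unique(x$class), RESTRAINT_CLASSES)
  if (length(bad) > 0) {
    stop("unknown restraint class ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(RESTRAINT_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$chain_a == x$chain_b & x$res_a == x$res_b)) {
    stop("self-pairs (same chain and residue) are not allowed", call. = FALSE)
  }
  is_contact <- grepl("^contact", x$class)
  if (any(is_contact & is.na(x$probability))) {
    stop("contact rows must carry a probability", call. = FALSE)
  }
  if (any(!is_contact & !is.na(x$probability))) {
    stop("probability is only allowed on contact classes", call. = FALSE)
  }
  if (any(!is.na(x$probability) & (x$probability < 0 | x$probability > 1))) {
    stop("probability must be in [0, 1]", call. = FALSE)
  }
  if (any(!is.na(x$upper_bound) & x$upper_bound <= 0)) {
    stop("upper_bound must be > 0", call. = FALSE)
  }
  x$res_a <- as.integer(x$res_a)
  x$res_b <- as.integer(x$res_b)
  class(x) <- c("restraint_table", class(x))
  x
}

#' Expand a restraint table into restraint objects
#'
#' Each row becomes a [crosslink_restraint()] or [contact_restraint()]. When
#' a topology is given, each side's chain is expanded to the full set of
#' chemically equivalent copies of its entity (ambiguity defaults to all
#' copies), and rows are restricted to chains known to the topology. Rows
#' without an explicit `upper_bound` fall back to the class default.
#'
#' @param table A [restraint_table()].
#' @param topology Optional [complex_topology()] used to expand copy
#'   equivalence.
#' @param crosslink_bound,contact_bound Default upper bounds (Angstrom) for
#'   rows lacking one.
#' @return A [restraint_set()].
#' @export
as_restraint_set <- function(table, topology = NULL,
                             crosslink_bound = default_config()$crosslink_bound,
                             contact_bound = default_config()$contact_bound) {
  table <- restraint_table(table)
  expand <- function(ch) {
    if (is.null(topology)) ch else copy_group(topology, ch)
  }
  rs <- purrr::pmap(table, function(chain_a, res_a, chain_b, res_b, class,
                                    probability, upper_bound, ...) {
    if (startsWith(class, "crosslink")) {
      crosslink_restraint(expand(chain_a), res_a, expand(chain_b), res_b,
                          upper_bound = ifelse(is.na(upper_bound),
                                               crosslink_bound, upper_bound),
                          polarity = sub("crosslink_", "", class))
    } else {
      contact_restraint(expand(chain_a), res_a, expand(chain_b), res_b,
                        probability = probability,
                        kind = sub("contact_", "", class),
                        upper_bound = ifelse(is.na(upper_bound),
                                             contact_bound, upper_bound))
    }
  })
  restraint_set(rs)
}

#' Baseline structural restraints for a model
#'
#' Assembles the non-experimental restraint layer every assembly run uses:
#' one [rigid_group_restraint()] per rigid group of the topology (reference
#' distances measured on `model`), [chain_bond_restraint()] springs,
#' [steric_restraint()] soft-core repulsion, and a
#' [membrane_slab_restraint()] over the topology's membrane-annotated
#' residues (if any).
#'
#' @param model A [ca_model()] carrying a topology with rigid groups.
#' @param half_width Membrane slab half-width, Angstrom.
#' @param d_min Steric minimum distance, Angstrom.
#' @param bond_length Chain bond rest length, Angstrom.
#' @return A [restraint_set()].
#' @export
base_restraints <- function(model,
                            half_width = default_config()$slab_half_width,
                            d_min = default_config()$steric_d_min,
                            bond_length = default_config()$bond_length) {
  topo <- model$topology
  if (is.null(topo)) stop("model has no topology", call. = FALSE)
  rs <- list(steric_restraint(d_min = d_min),
             chain_bond_restraint(bond_length = bond_length))
  if (!is.null(topo$rigid_groups)) {
    for (i in seq_len(nrow(topo$rigid_groups))) {
      g <- topo$rigid_groups[i, ]
      rs <- c(rs, list(rigid_group_restraint(g$chain_id, g$residues[[1]], model)))
    }
  }
  if (!is.null(topo$membrane) && nrow(topo$membrane) > 0) {
    mem <- tidyr::unnest(topo$membrane, "residues")
    rs <- c(rs, list(membrane_slab_restraint(mem$chain_id, mem$residues,
                                             half_width = half_width)))
  }
  restraint_set(rs)
}

#' Protocol constants
#'
#' One place holding every tunable default of the modeling protocol, in the
#' units noted. The cross-link/contact weighting (25 / 0.25 / 0.1), the
#' anchor force constant (0.1 per Angstrom^2), the strict 0.15 contact
#' probability cutoff, the 10 score-unit contact violation cutoff, the
#' 100-step minimization, the ensemble of 8 selected by fewest cross-link
#' violations, the 20-glycine hybrid-MSA linker and the 70% conservation
#' rule are the literature protocol constants; the remainder are this
#' package's own documented choices.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    weights = score_weights(),
    anchor_k = 0.1,              # score-units / A^2
    contact_p_threshold = 0.15,  # strict: keep probability > 0.15
    contact_violation_threshold = 10,  # score-units
    minimize_steps = 100,
    n_models = 8,
    selection = "fewest crosslink violations, then total score, then index",
    linker_length = 20,          # glycines between paired sequences
    conservation_threshold = 0.70,
    crosslink_bound = 12,        # A, Calpha-Calpha for disulfide pairs
    contact_bound = 10,          # A, Calpha-Calpha contact definition
    slab_half_width = 15,        # A
    steric_d_min = 4,            # A
    bond_length = 3.8,           # A
    anneal_cycles = 5,
    anneal_kT = c(5, 3, 2, 1, 0.5),
    anneal_steps_per_cycle = 500,
    zn_ligands = c(43, 47, 137),
    sigk_truncation = 1:37
  )
}
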