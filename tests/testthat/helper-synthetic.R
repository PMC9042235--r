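# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; no binary data.

# a tiny two-chain model with explicitly known coordinates
toy_two_chain <- function() {
  chains <- tibble::tibble(
    chain_id = c("A", "B"), entity = c("A", "B"), copy = 1L,
    residues = list(1:4, 1:4)
  )
  coords <- tibble::tibble(
    chain = rep(c("A", "B"), each = 4),
    resno = rep(1:4, 2),
    x = c(0, 3.8, 7.6, 11.4, 0, 3.8, 7.6, 11.4),
    y = c(rep(0, 4), rep(8, 4)),
    z = 0
  )
  ca_model(coords, complex_topology(chains))
}

# a toy tetramer: four copies of entity "FB" plus one partner chain "S"
toy_tetramer <- function() {
  chains <- tibble::tibble(
    chain_id = c("A", "B", "C", "D", "S"),
    entity = c(rep("FB", 4), "S"), copy = c(1:4, 1L),
    residues = c(rep(list(1:3), 4), list(1:3))
  )
  blocks <- purrr::imap(
    list(A = c(0, 0), B = c(20, 0), C = c(0, 20), D = c(20, 20),
         S = c(10, 10)),
    function(org, ch) {
      tibble::tibble(chain = ch, resno = 1:3,
                     x = org[1] + c(0, 3.8, 7.6), y = org[2], z = 0)
    }
  )
  ca_model(dplyr::bind_rows(blocks), complex_topology(chains))
}

# random model: k chains, n residues each, coordinates in a box
random_model <- function(n_chains = 2, n_res = 6, scale = 20) {
  chains <- tibble::tibble(
    chain_id = LETTERS[seq_len(n_chains)],
    entity = LETTERS[seq_len(n_chains)], copy = 1L,
    residues = rep(list(seq_len(n_res)), n_chains)
  )
  coords <- tibble::tibble(
    chain = rep(LETTERS[seq_len(n_chains)], each = n_res),
    resno = rep(seq_len(n_res), n_chains),
    x = stats::runif(n_chains * n_res, 0, scale),
    y = stats::runif(n_chains * n_res, 0, scale),
    z = stats::runif(n_chains * n_res, -scale / 2, scale / 2)
  )
  ca_model(coords, complex_topology(chains))
}

# random mixed restraint set on a model (used by the oracle-equivalence
# tests); returns only distance-free classes when `paired_only = FALSE`
random_restraints <- function(model, n_paired = 10) {
  co <- model$coords
  pick <- function() co[sample.int(nrow(co), 1), ]
  paired <- lapply(seq_len(n_paired), function(i) {
    a <- pick(); b <- pick()
    while (a$chain == b$chain && a$resno == b$resno) b <- pick()
    u <- stats::runif(1, 2, 15)
    kind <- sample(c("crosslink", "inter", "intra"), 1)
    if (kind == "crosslink") {
      crosslink_restraint(a$chain, a$resno, b$chain, b$resno, upper_bound = u,
                          polarity = sample(c("positive", "negative"), 1,
                                            prob = c(0.8, 0.2)))
    } else {
      contact_restraint(a$chain, a$resno, b$chain, b$resno,
                        probability = stats::runif(1, 0.16, 1), kind = kind,
                        upper_bound = u)
    }
  })
  ch <- co$chain[1]
  res <- sort(co$resno[co$chain == ch])[1:3]
  ref_shift <- model
  ref_shift$coords$x <- ref_shift$coords$x + stats::rnorm(nrow(co), sd = 1)
  restraint_set(
    paired,
    rigid_group_restraint(ch, res, ref_shift),
    anchor_restraint(ref_shift, k = 0.1),
    membrane_slab_restraint(co$chain, co$resno, half_width = 8),
    steric_restraint(),
    chain_bond_restraint()
  )
}

# independent brute-force total score: recomputes every term from the
# primitive formulas, without calling restraint_energy()
brute_force_score <- function(model, restraints, weights = score_weights()) {
  co <- model$coords
  xyz <- as.matrix(co[, c("x", "y", "z")])
  at <- function(chain, resno) {
    xyz[which(co$chain == chain & co$resno == resno)[1], ]
  }
  w <- unlist(weights)
  total <- 0
  for (r in restraints) {
    cls <- xlassemble:::restraint_class(r)
    e <- if (cls %in% c("crosslink", "contact_inter", "contact_intra")) {
      if (!is.null(r$polarity) && r$polarity == "negative") 0 else {
        dmin <- Inf
        for (ca in r$chains_a) for (cb in r$chains_b) {
          d <- sqrt(sum((at(ca, r$res_a) - at(cb, r$res_b))^2))
          if (d < dmin) dmin <- d
        }
        max(0, dmin - r$upper_bound)^2
      }
    } else if (cls == "rigid") {
      s <- 0
      for (i in seq_along(r$residues)) for (j in seq_along(r$residues)) {
        if (i < j) {
          d <- sqrt(sum((at(r$chain, r$residues[i]) -
                           at(r$chain, r$residues[j]))^2))
          s <- s + (d - r$ref_dist[i, j])^2
        }
      }
      r$force_constant * s
    } else if (cls == "anchor") {
      s <- 0
      for (i in seq_len(nrow(r$ref))) {
        s <- s + sum((at(r$ref$chain[i], r$ref$resno[i]) -
                        c(r$ref$x[i], r$ref$y[i], r$ref$z[i]))^2)
      }
      r$k * s
    } else if (cls == "slab") {
      s <- 0
      for (i in seq_len(nrow(r$members))) {
        z <- at(r$members$chain[i], r$members$resno[i])[3]
        s <- s + max(0, abs(z) - r$half_width)^2
      }
      s
    } else if (cls == "sterics") {
      s <- 0
      n <- nrow(co)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        bonded <- co$chain[i] == co$chain[j] &&
          abs(co$resno[i] - co$resno[j]) == 1
        if (!bonded) {
          d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
          s <- s + max(0, r$d_min - d)^2
        }
      }
      s
    } else if (cls == "bond") {
      s <- 0
      n <- nrow(co)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (co$chain[i] == co$chain[j] &&
            abs(co$resno[i] - co$resno[j]) == 1) {
          d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
          s <- s + (d - r$bond_length)^2
        }
      }
      s
    } else stop("unhandled class in oracle")
    total <- total + w[[cls]] * e
  }
  total
}

# independent brute-force violation counts (naive double loop)
brute_force_violations <- function(model, restraints, tol = 0) {
  co <- model$coords
  xyz <- as.matrix(co[, c("x", "y", "z")])
  at <- function(chain, resno) {
    xyz[which(co$chain == chain & co$resno == resno)[1], ]
  }
  counts <- c(crosslink_positive = 0L, crosslink_negative = 0L,
              contact_inter = 0L, contact_intra = 0L)
  for (r in restraints) {
    lab <- if (inherits(r, "crosslink_restraint")) {
      paste0("crosslink_", r$polarity)
    } else if (inherits(r, "contact_restraint")) {
      paste0("contact_", r$kind)
    } else next
    dmin <- Inf
    for (ca in r$chains_a) for (cb in r$chains_b) {
      d <- sqrt(sum((at(ca, r$res_a) - at(cb, r$res_b))^2))
      if (d < dmin) dmin <- d
    }
    viol <- if (lab == "crosslink_negative") dmin < r$upper_bound - tol
            else dmin > r$upper_bound + tol
    if (viol) counts[lab] <- counts[lab] + 1L
  }
  counts
}
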