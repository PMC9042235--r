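test_that("flat-bottom distance energy has the stated closed form", {
  expect_equal(distance_energy(5, 8), 0)
  expect_equal(distance_energy(10, 8), 4)
  expect_equal(distance_energy(8, 8), 0)  # boundary inside
  expect_error(distance_energy(-1, 8), ">= 0")
  expect_error(distance_energy(1, 0), "> 0")
})

test_that("ambiguous minimum distance reduces, enumerates and is rigid-invariant", {
  model <- toy_tetramer()
  # single-copy x single-copy: the plain pair distance
  r1 <- crosslink_restraint("A", 1, "S", 1)
  expect_equal(ambiguous_min_distance(model, r1),
               residue_distance(model, "A", 1, "S", 1))
  # 1 x 4 copies equals a brute-force min over the four distances
  r4 <- crosslink_restraint("S", 2, c("A", "B", "C", "D"), 3)
  d4 <- vapply(c("A", "B", "C", "D"), function(ch) {
    residue_distance(model, "S", 2, ch, 3)
  }, 0)
  expect_equal(ambiguous_min_distance(model, r4), min(d4))
  # symmetric in site order
  r4s <- crosslink_restraint(c("A", "B", "C", "D"), 3, "S", 2)
  expect_equal(ambiguous_min_distance(model, r4s),
               ambiguous_min_distance(model, r4))
  # invariant under a global rigid translation
  shifted <- model
  shifted$coords$x <- shifted$coords$x + 100
  shifted$coords$z <- shifted$coords$z - 42
  expect_equal(ambiguous_min_distance(shifted, r4),
               ambiguous_min_distance(model, r4), tolerance = 1e-12)
})

test_that("restraint energies match their stated closed forms", {
  model <- toy_two_chain()
  # anchor at own reference is zero
  anc0 <- anchor_restraint(model, k = 0.1)
  expect_equal(restraint_energy(model, anc0), 0)
  # one residue displaced 2 A with k = 0.1 gives 0.1 * 2^2 = 0.4
  disp <- model
  disp$coords$z[3] <- disp$coords$z[3] + 2
  expect_equal(restraint_energy(disp, anc0), 0.4)
  # slab: a bead at |z| = 18 with half-width 15 contributes 9
  slab <- membrane_slab_restraint(model$coords$chain, model$coords$resno,
                                  half_width = 15)
  deep <- model
  deep$coords$z[1] <- -18
  expect_equal(restraint_energy(deep, slab), 9)
  # chain bonds at ideal 3.8 geometry are zero
  expect_equal(restraint_energy(model, chain_bond_restraint()), 0)
  # sterics: the two chains sit 8 A apart, no penalty; squeeze them to 2 A
  expect_equal(restraint_energy(model, steric_restraint()), 0)
  clash <- model
  clash$coords$y[clash$coords$chain == "B"] <- 2
  expect_gt(restraint_energy(clash, steric_restraint()), 0)
})

test_that("rigid-group energy is invariant under rigid rotation of the group", {
  model <- toy_two_chain()
  rg <- rigid_group_restraint("A", 1:4, model)
  expect_equal(restraint_energy(model, rg), 0)
  rot <- model
  idx <- rot$coords$chain == "A"
  m <- as.matrix(rot$coords[idx, c("x", "y", "z")])
  R <- xlassemble:::rotation_matrix(c(1, 2, 3), 0.7)
  m2 <- sweep(sweep(m, 2, colMeans(m)) %*% R, 2, colMeans(m) + c(5, -2, 1), `+`)
  rot$coords[idx, c("x", "y", "z")] <- tibble::as_tibble(m2, .name_repair = ~c("x", "y", "z"))
  expect_equal(restraint_energy(rot, rg), 0, tolerance = 1e-9)
  # squashing the group is penalized
  sq <- model
  sq$coords$x[idx] <- sq$coords$x[idx] * 0.5
  expect_gt(restraint_energy(sq, rg), 0)
})

test_that("negative cross-links carry no energy, only diagnostics", {
  model <- toy_two_chain()
  rneg <- crosslink_restraint("A", 1, "B", 4, upper_bound = 50,
                              polarity = "negative")
  expect_equal(restraint_energy(model, rneg), 0)
  v <- count_violations(model, restraint_set(rneg))
  # the pair is closer than 50 A although no cross-link was observed
  expect_equal(v$violations[v$class == "crosslink_negative"], 1)
})

test_that("total score weights classes as 25 / 0.25 / 0.1 and reports subtotals", {
  model <- toy_two_chain()
  expect_equal(as.numeric(total_score(model, restraint_set())), 0)
  # one violated cross-link with distance energy 4 scores 100 under weight 25
  d <- residue_distance(model, "A", 1, "B", 4)
  r <- crosslink_restraint("A", 1, "B", 4, upper_bound = d - 2)
  ts <- total_score(model, restraint_set(r))
  expect_equal(as.numeric(ts), 25 * 4, tolerance = 1e-9)
  br <- score_breakdown(ts)
  expect_equal(br$weighted[br$class == "crosslink"], 100, tolerance = 1e-9)
})

test_that("adding a satisfied restraint leaves the score unchanged", {
  set.seed(33)
  model <- random_model()
  rset <- random_restraints(model, n_paired = 5)
  base <- as.numeric(total_score(model, rset))
  d <- residue_distance(model, "A", 1, "B", 2)
  satisfied <- crosslink_restraint("A", 1, "B", 2, upper_bound = d + 5)
  expect_equal(as.numeric(total_score(model, c(rset, restraint_set(satisfied)))),
               base, tolerance = 1e-12)
})

test_that("score is rigid-invariant without anchors or slab terms", {
  set.seed(34)
  model <- random_model()
  rset <- restraint_set(
    crosslink_restraint("A", 1, "B", 3, upper_bound = 5),
    contact_restraint("A", 2, "B", 2, probability = 0.5, kind = "inter",
                      upper_bound = 4),
    rigid_group_restraint("A", 1:4, model),
    steric_restraint(), chain_bond_restraint()
  )
  s0 <- as.numeric(total_score(model, rset))
  moved <- model
  m <- xlassemble:::coords_matrix(model)
  R <- xlassemble:::rotation_matrix(c(0.3, -1, 2), 1.1)
  m2 <- sweep(m %*% R, 2, c(30, -12, 7), `+`)
  moved$coords[, c("x", "y", "z")] <- tibble::as_tibble(m2, .name_repair = ~c("x", "y", "z"))
  expect_equal(as.numeric(total_score(moved, rset)), s0, tolerance = 1e-8)
})

test_that("violation counting is exact on a constructed model and monotone in tol", {
  # place B residues at known distances from A residues
  chains <- tibble::tibble(chain_id = c("A", "B"), entity = c("A", "B"),
                           copy = 1L, residues = list(1:4, 1:4))
  co <- tibble::tibble(
    chain = rep(c("A", "B"), each = 4), resno = rep(1:4, 2),
    x = c(0, 10, 20, 30, 0, 10, 20, 30),
    y = c(rep(0, 4), 13, 15, 11, 9), z = 0
  )
  model <- ca_model(co, complex_topology(chains))
  rset <- restraint_set(lapply(1:4, function(i) {
    crosslink_restraint("A", i, "B", i, upper_bound = 12)
  }))
  # distances 13, 15, 11, 9 against bound 12: exactly two exceed it
  v <- count_violations(model, rset)
  expect_equal(v$violations[v$class == "crosslink_positive"], 2)
  # raise the third pair to 14 A so exactly three bounds are exceeded
  co$y[5:8] <- c(13, 15, 14, 9)
  model3 <- ca_model(co, complex_topology(chains))
  v3 <- count_violations(model3, rset)
  expect_equal(v3$violations[v3$class == "crosslink_positive"], 3)
  # counts are non-increasing in the tolerance
  tols <- c(0, 1, 2, 3, 5)
  counts <- vapply(tols, function(t) {
    v <- count_violations(model3, rset, tol = t)
    v$violations[v$class == "total"]
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("the compiled score and gradient agree with the plain-R reference", {
  for (s in 1:20) {
    set.seed(400 + s)
    model <- random_model(n_chains = 2, n_res = 5)
    rset <- random_restraints(model, n_paired = 6)
    w <- score_weights()
    sys <- xlassemble:::compile_system(model, rset, w)
    m <- xlassemble:::coords_matrix(model)
    expect_equal(xlassemble:::sys_score(m, sys),
                 as.numeric(total_score(model, rset, w)),
                 tolerance = 1e-9)
    # gradient against central finite differences on a few coordinates
    if (s <= 3) {
      g <- xlassemble:::sys_grad(m, sys)
      h <- 1e-6
      for (probe in list(c(1, 1), c(3, 2), c(8, 3))) {
        i <- probe[1]; c0 <- probe[2]
        mp <- m; mp[i, c0] <- mp[i, c0] + h
        mm <- m; mm[i, c0] <- mm[i, c0] - h
        num <- (xlassemble:::sys_score(mp, sys) -
                  xlassemble:::sys_score(mm, sys)) / (2 * h)
        expect_equal(g[i, c0], num, tolerance = 1e-4)
      }
    }
  }
})
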