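test_that("minimization is a fixed point at score zero and fills a quadratic bowl", {
  model <- toy_two_chain()
  anc <- restraint_set(anchor_restraint(model, k = 0.1))
  out <- minimize(model, anc)
  expect_equal(xlassemble:::coords_matrix(out),
               xlassemble:::coords_matrix(model), tolerance = 1e-9)
  # a single displaced bead converges back to its anchor
  disp <- model
  disp$coords$x[1] <- disp$coords$x[1] + 6
  disp$coords$z[1] <- disp$coords$z[1] - 4
  rec <- minimize(disp, restraint_set(anchor_restraint(model, k = 0.1)),
                  steps = 500)
  expect_equal(as.numeric(rec$coords[1, c("x", "y", "z")]),
               as.numeric(model$coords[1, c("x", "y", "z")]),
               tolerance = 1e-2)
})

test_that("minimization closes a violated cross-link and never raises the score", {
  chains <- tibble::tibble(chain_id = c("A", "B"), entity = c("A", "B"),
                           copy = 1L, residues = list(1L, 1L))
  model <- ca_model(tibble::tibble(chain = c("A", "B"), resno = 1L,
                                   x = c(0, 20), y = 0, z = 0),
                    complex_topology(chains))
  rset <- restraint_set(crosslink_restraint("A", 1, "B", 1, upper_bound = 10))
  out <- minimize(model, rset, steps = 200)
  expect_lte(residue_distance(out, "A", 1, "B", 1), 10 + 1e-3)
  tr <- attr(out, "trace")
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("minimization rejects non-finite input", {
  model <- toy_two_chain()
  model$coords$x[1] <- Inf
  expect_error(minimize(model, restraint_set(chain_bond_restraint())),
               "non-finite")
})

test_that("a null schedule is the identity and equal seeds give identical trajectories", {
  model <- toy_two_chain()
  rset <- restraint_set(chain_bond_restraint(), steric_restraint())
  null_sched <- anneal_schedule(cycles = 1, steps_per_cycle = 0, kT = 1,
                                minimize_steps = 0, seed = 1)
  out <- anneal(model, rset, schedule = null_sched)
  expect_identical(xlassemble:::coords_matrix(out),
                   xlassemble:::coords_matrix(model))
  sched <- anneal_schedule(cycles = 2, steps_per_cycle = 50, kT = c(2, 1),
                           minimize_steps = 10, seed = 99)
  a1 <- anneal(model, rset, schedule = sched)
  a2 <- anneal(model, rset, schedule = sched)
  expect_identical(xlassemble:::coords_matrix(a1),
                   xlassemble:::coords_matrix(a2))
})

test_that("the cycle-boundary score trace is non-increasing", {
  spec <- synth_spec(seed = 3)
  ref <- make_reference_complex(spec)
  xl <- simulate_crosslinks(ref, spec)
  rset <- c(as_restraint_set(xl, ref$topology), base_restraints(ref))
  start <- scramble(ref, seed = 8, magnitude = 20)
  out <- anneal(start, rset,
                schedule = anneal_schedule(cycles = 4, steps_per_cycle = 100,
                                           kT = c(5, 3, 1, 0.5),
                                           minimize_steps = 30, seed = 12))
  tr <- attr(out, "trace")
  expect_equal(nrow(tr), 4)
  expect_true(all(diff(tr$score) <= 1e-9))
})

test_that("schedule validation enforces the temperature ladder", {
  expect_error(anneal_schedule(cycles = 0), ">= 1")
  expect_error(anneal_schedule(cycles = 2, kT = c(1, 2)), "non-increasing")
  expect_error(anneal_schedule(cycles = 2, kT = c(1, -1)), "non-increasing|positive")
})

test_that("a single-stage plan reduces to annealing the placed system", {
  model <- toy_two_chain()
  rset <- restraint_set(
    crosslink_restraint("A", 1, "B", 1, upper_bound = 6),
    chain_bond_restraint(), steric_restraint()
  )
  sched <- anneal_schedule(cycles = 1, steps_per_cycle = 30, kT = 1,
                           minimize_steps = 20)
  plan <- stage_plan(stage("all", add = "A"))
  one_chain <- ca_model(model$coords[model$coords$chain == "A", ],
                        model$topology)
  res <- run_stage_plan(plan, one_chain, restraint_set(chain_bond_restraint()),
                        schedule = sched, seed = 5)
  set.seed(5)
  direct <- anneal(one_chain, restraint_set(chain_bond_restraint()),
                   schedule = sched)
  expect_equal(xlassemble:::coords_matrix(res$model),
               xlassemble:::coords_matrix(direct), tolerance = 1e-12)
})

test_that("removal stages delete residues and the restraints touching them", {
  model <- toy_two_chain()
  rset <- restraint_set(
    crosslink_restraint("A", 1, "B", 1, upper_bound = 20),
    crosslink_restraint("A", 4, "B", 4, upper_bound = 20),
    chain_bond_restraint(), steric_restraint()
  )
  sched <- anneal_schedule(cycles = 1, steps_per_cycle = 0, kT = 1,
                           minimize_steps = 0)
  plan <- stage_plan(
    stage("both", add = c("A", "B")),
    stage("trim", remove = list(chain = "B", residues = 1:2))
  )
  res <- run_stage_plan(plan, model, rset, schedule = sched, seed = 2)
  final <- res$model$coords
  expect_equal(sort(final$resno[final$chain == "B"]), 3:4)
  # the cross-link to the removed residue is no longer active
  active <- purrr::compact(lapply(rset, xlassemble:::restrict_restraint,
                                  res$model))
  expect_equal(sum(vapply(active, inherits, TRUE, "crosslink_restraint")), 1)
})

test_that("explicitly activating a restraint on an absent entity names the stage", {
  model <- toy_two_chain()
  rset <- restraint_set(
    crosslink_restraint("A", 1, "B", 1, upper_bound = 20),
    chain_bond_restraint()
  )
  sched <- anneal_schedule(cycles = 1, steps_per_cycle = 0, kT = 1,
                           minimize_steps = 0)
  plan <- stage_plan(
    stage("lonely", add = "A", restraints = 1L),
    stage("partner", add = "B")
  )
  expect_error(run_stage_plan(plan, model, rset, schedule = sched, seed = 1),
               "lonely")
  expect_error(stage_plan(stage("s1", add = "A"), stage("s2", add = "A")),
               "more than once")
})

test_that("the staged inhibition-complex plan emits seven snapshots", {
  fx <- load_paper_fixture()
  topo <- fx$topology
  topo$chains$residues[[which(topo$chains$chain_id == "S")]] <- 1:114
  helix <- function(ch, residues, ox) {
    t <- seq_along(residues) - 1
    ang <- t * 100 * pi / 180
    tibble::tibble(chain = ch, resno = residues,
                   x = ox + 2.3 * cos(ang), y = 2.3 * sin(ang),
                   z = (t - (length(residues) - 1) / 2) * 1.5)
  }
  co <- dplyr::bind_rows(purrr::imap(
    stats::setNames(seq_len(7) * 12, topo$chains$chain_id),
    function(ox, ch) {
      helix(ch, topo$chains$residues[[which(topo$chains$chain_id == ch)]], ox)
    }
  ))
  model <- ca_model(co, topo)
  rset <- c(as_restraint_set(fx$restraints, topo), base_restraints(model))
  sched <- anneal_schedule(cycles = 1, steps_per_cycle = 10, kT = 1,
                           minimize_steps = 5)
  res <- run_stage_plan(fixture_stage_plan(), model, rset,
                        schedule = sched, seed = 7)
  expect_length(res$snapshots, 7)
  expect_equal(res$log$stage[5], "truncate_proregion")
  final <- res$model$coords
  # the Proregion (sigmaK 1-37) is gone from the final model
  expect_equal(min(final$resno[final$chain == "S"]), 38)
  # tetramer ambiguity: fixture cross-links span all four protease copies
  active <- purrr::compact(lapply(rset, xlassemble:::restrict_restraint,
                                  res$model))
  xls <- active[vapply(active, inherits, TRUE, "crosslink_restraint")]
  expect_true(all(vapply(xls, function(r) {
    length(r$chains_a) == 4 || length(r$chains_b) == 4
  }, TRUE)))
  # one zinc per protease subunit at the ligand centroid
  zn <- suppressWarnings(place_zinc(res$model))
  expect_equal(nrow(zn$zn), 4)
})

test_that("ensemble selection ranks by violations, then score, then index", {
  expect_equal(xlassemble:::select_model_index(c(2, 0, 1), c(1, 9, 1)), 2)
  expect_equal(xlassemble:::select_model_index(c(1, 1, 1), c(5, 2, 9)), 2)
  expect_equal(xlassemble:::select_model_index(c(1, 1), c(3, 3)), 1)
})

test_that("an ensemble of one selects that model; results serialize deterministically", {
  model <- toy_two_chain()
  rset <- restraint_set(
    crosslink_restraint("A", 1, "B", 1, upper_bound = 10),
    chain_bond_restraint(), steric_restraint()
  )
  sched <- anneal_schedule(cycles = 1, steps_per_cycle = 20, kT = 1,
                           minimize_steps = 10)
  plan <- stage_plan(stage("all", add = c("A", "B")))
  res1 <- build_ensemble(plan, model, rset, schedule = sched, n_models = 1,
                         base_seed = 4)
  expect_equal(res1$selected, 1)
  expect_equal(nrow(tidy(res1)), 1)
  res2 <- build_ensemble(plan, model, rset, schedule = sched, n_models = 3,
                         base_seed = 4)
  res3 <- build_ensemble(plan, model, rset, schedule = sched, n_models = 3,
                         base_seed = 4)
  expect_identical(serialize_assembly(res2), serialize_assembly(res3))
  expect_equal(glance(res2)$n_models, 3)
})

test_that("zinc placement uses the ligand C-alpha centroid", {
  chains <- tibble::tibble(chain_id = "A", entity = "FB", copy = 1L,
                           residues = list(c(43L, 47L, 137L)))
  model <- ca_model(tibble::tibble(chain = "A", resno = c(43L, 47L, 137L),
                                   x = c(0, 3, 0), y = c(0, 0, 3), z = 0),
                    complex_topology(chains))
  out <- suppressWarnings(place_zinc(model, ligand_residues = c(43, 47, 137)))
  expect_equal(as.numeric(out$zn[1, c("x", "y", "z")]), c(1, 1, 0))
  # a close-by zinc warns about the clash
  expect_warning(place_zinc(model, ligand_residues = c(43, 47, 137)),
                 "zinc site")
  # missing ligand residues are hard errors
  expect_error(place_zinc(model, ligand_residues = c(43, 47, 200)),
               "not in model")
})
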