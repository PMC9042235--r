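#' Annealing schedule
#'
#' Parameters of the stochastic refinement protocol: per cycle, Metropolis
#' Monte-Carlo sampling at the cycle's temperature (rigid chain moves plus
#' single-bead jitter), followed by gradient minimization. Defaults are the
#' package's desk-scale protocol: 5 cycles at kT = 5, 3, 2, 1, 0.5
#' score-units, 500 sampling steps per cycle, 100 minimization steps.
#'
#' @param cycles Number of cycles (>= 1).
#' @param steps_per_cycle Monte-Carlo proposals per cycle.
#' @param kT Temperature ladder, score-units, positive and non-increasing;
#'   recycled to `cycles` if scalar.
#' @param trans_max Max rigid-body translation per move, Angstrom.
#' @param rot_max Max rigid-body rotation per move, radians.
#' @param jitter_sd Single-bead jitter standard deviation, Angstrom.
#' @param jitter_prob Probability that a proposal is a bead jitter rather
#'   than a rigid chain move.
#' @param minimize_steps Gradient-descent steps per cycle.
#' @param seed Optional integer seed (see [anneal()]).
#' @return An `anneal_schedule` list.
#' @export
anneal_schedule <- function(cycles = default_config()$anneal_cycles,
                            steps_per_cycle = default_config()$anneal_steps_per_cycle,
                            kT = default_config()$anneal_kT,
                            trans_max = 3, rot_max = 0.3,
                            jitter_sd = 0.5, jitter_prob = 0.2,
                            minimize_steps = default_config()$minimize_steps,
                            seed = NULL) {
  if (cycles < 1) stop("cycles must be >= 1", call. = FALSE)
  if (length(kT) == 1) kT <- rep(kT, cycles)
  if (length(kT) != cycles) stop("kT ladder must match cycles", call. = FALSE)
  if (any(kT <= 0) || is.unsorted(rev(kT))) {
    stop("temperatures must be positive and non-increasing", call. = FALSE)
  }
  structure(list(cycles = as.integer(cycles),
                 steps_per_cycle = as.integer(steps_per_cycle), kT = kT,
                 trans_max = trans_max, rot_max = rot_max,
                 jitter_sd = jitter_sd, jitter_prob = jitter_prob,
                 minimize_steps = as.integer(minimize_steps), seed = seed),
            class = "anneal_schedule")
}

## Rodrigues rotation matrix about a unit axis
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## internal gradient descent with Armijo backtracking on a compiled system
min_sys <- function(x, sys, steps, tol = 1e-6) {
  f <- sys_score(x, sys)
  if (!is.finite(f)) stop("non-finite score at start of minimization",
                          call. = FALSE)
  trace <- numeric(0)
  t_prev <- NA_real_
  for (k in seq_len(steps)) {
    g <- sys_grad(x, sys)
    gn2 <- sum(g^2)
    if (sqrt(gn2) < tol) break
    gmax <- max(abs(g))
    t <- if (is.na(t_prev)) 1 / max(1, gmax) else min(t_prev * 2, 2 / gmax)
    repeat {
      xn <- x - t * g
      fn <- sys_score(xn, sys)
      if (!is.finite(fn)) {
        stop("non-finite score during minimization (step ", k, ", score ",
             f, ")", call. = FALSE)
      }
      if (fn <= f - 1e-4 * t * gn2) break
      t <- t / 2
      if (t < 1e-14) break
    }
    if (fn >= f) break  # no descent direction progress left
    x <- xn; f <- fn; t_prev <- t
    trace <- c(trace, f)
  }
  list(x = x, f = f, trace = trace)
}

#' Minimize a model against its restraints
#'
#' Gradient descent with backtracking line search on the weighted total
#' score (everywhere differentiable: the flat-bottom terms are C1). The
#' score is non-increasing from step to step; the run stops after `steps`
#' iterations, at gradient norm below `tol`, or when no further descent is
#' possible.
#'
#' @param model A [ca_model()] with finite coordinates.
#' @param restraints A [restraint_set()].
#' @param weights A [score_weights()].
#' @param steps Maximum iterations (default 100, the protocol's
#'   minimization length).
#' @param tol Gradient-norm convergence tolerance.
#' @return The minimized [ca_model()], with the per-step score trace in
#'   attribute `"trace"` and the final score in attribute `"score"`.
#' @export
minimize <- function(model, restraints, weights = score_weights(),
                     steps = default_config()$minimize_steps, tol = 1e-6) {
  x <- coords_matrix(model)
  if (!all(is.finite(x))) stop("non-finite coordinates", call. = FALSE)
  sys <- compile_system(model, restraints, weights)
  res <- min_sys(x, sys, steps, tol)
  out <- set_coords(model, res$x)
  attr(out, "trace") <- res$trace
  attr(out, "score") <- res$f
  out
}

set_coords <- function(model, m) {
  model$coords$x <- m[, 1]; model$coords$y <- m[, 2]; model$coords$z <- m[, 3]
  model
}

#' Simulated annealing of a model against its restraints
#'
#' Cycles of Metropolis Monte-Carlo sampling at decreasing temperature
#' (rigid-body moves of whole chains plus single-bead jitter) each followed
#' by gradient minimization -- the coarse-grained stand-in for cycles of
#' elevated-temperature dynamics and minimization. Deterministic given
#' `schedule$seed`.
#'
#' @inheritParams minimize
#' @param schedule An [anneal_schedule()].
#' @param frozen Chain ids excluded from Monte-Carlo moves.
#' @return The annealed [ca_model()]; attribute `"trace"` holds a tibble
#'   with one row per cycle (`cycle`, `kT`, `accept_rate`, `score` after
#'   minimization).
#' @export
anneal <- function(model, restraints, weights = score_weights(),
                   schedule = anneal_schedule(), frozen = character()) {
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  co <- model$coords
  x <- coords_matrix(model)
  sys <- compile_system(model, restraints, weights)
  chain_rows <- split(seq_len(nrow(co)), co$chain)
  movable <- setdiff(names(chain_rows), frozen)
  movable_rows <- unlist(chain_rows[movable], use.names = FALSE)
  f <- sys_score(x, sys)
  trace <- vector("list", schedule$cycles)
  for (cyc in seq_len(schedule$cycles)) {
    kT <- schedule$kT[cyc]
    acc <- 0L
    if (length(movable_rows) > 0) {
      for (s in seq_len(schedule$steps_per_cycle)) {
        xn <- x
        if (stats::runif(1) < schedule$jitter_prob || length(movable) == 0) {
          i <- movable_rows[sample.int(length(movable_rows), 1)]
          xn[i, ] <- xn[i, ] + stats::rnorm(3, sd = schedule$jitter_sd)
        } else {
          ch <- movable[sample.int(length(movable), 1)]
          rows <- chain_rows[[ch]]
          ctr <- colMeans(x[rows, , drop = FALSE])
          R <- rotation_matrix(stats::rnorm(3),
                               stats::runif(1, -schedule$rot_max,
                                            schedule$rot_max))
          shift <- stats::runif(3, -schedule$trans_max, schedule$trans_max)
          xn[rows, ] <- sweep(sweep(x[rows, , drop = FALSE], 2, ctr) %*% R,
                              2, ctr + shift, `+`)
        }
        fn <- sys_score(xn, sys)
        if (fn <= f || stats::runif(1) < exp(-(fn - f) / kT)) {
          x <- xn; f <- fn; acc <- acc + 1L
        }
      }
    }
    if (schedule$minimize_steps > 0) {
      res <- min_sys(x, sys, schedule$minimize_steps)
      x <- res$x; f <- res$f
    }
    # greedy restart: never carry a cycle that ended worse than the best
    # post-minimization state, so the cycle-boundary score trace is
    # non-increasing
    if (cyc > 1 && f > f_best) {
      x <- x_best; f <- f_best
    } else {
      x_best <- x; f_best <- f
    }
    trace[[cyc]] <- tibble::tibble(
      cycle = cyc, kT = kT,
      accept_rate = if (schedule$steps_per_cycle > 0)
        acc / schedule$steps_per_cycle else NA_real_,
      score = f
    )
  }
  out <- set_coords(model, x)
  attr(out, "trace") <- dplyr::bind_rows(trace)
  attr(out, "score") <- f
  out
}

## ---- staged assembly ---------------------------------------------------

#' Define one stage of a staged assembly plan
#'
#' @param name Stage label.
#' @param add Chain ids introduced at this stage (placed at a seeded random
#'   pose outside the current complex's bounding sphere).
#' @param remove Optional list `list(chain =, residues =)` of residues
#'   deleted at this stage (e.g. truncating a proregion); restraints
#'   touching them are dropped.
#' @param frozen Chain ids held fixed during this stage's annealing.
#' @param restraints Optional integer indices into the full restraint set
#'   to activate explicitly; the default (`NULL`) activates every restraint
#'   whose residues are all present. An explicit index referencing an
#'   entity not yet present is an error naming the stage.
#' @return A `stage` list.
#' @export
stage <- function(name, add = character(), remove = NULL,
                  frozen = character(), restraints = NULL) {
  structure(list(name = name, add = add, remove = remove, frozen = frozen,
                 restraints = restraints), class = "stage")
}

#' Ordered staged-assembly plan
#'
#' Validates that every chain is introduced exactly once.
#'
#' @param ... `stage()` objects.
#' @return A `stage_plan` list.
#' @export
stage_plan <- function(...) {
  stages <- list(...)
  stopifnot(all(vapply(stages, inherits, TRUE, "stage")))
  added <- unlist(lapply(stages, `[[`, "add"))
  if (anyDuplicated(added)) {
    stop("chain(s) introduced more than once: ",
         paste(unique(added[duplicated(added)]), collapse = ", "),
         call. = FALSE)
  }
  structure(stages, class = "stage_plan")
}

## restrict a restraint to residues present in `model`; NULL if inactive
restrict_restraint <- function(r, model) {
  key <- residue_key(model$coords$chain, model$coords$resno)
  has <- function(chain, resno) residue_key(chain, resno) %in% key
  if (inherits(r, "crosslink_restraint") || inherits(r, "contact_restraint")) {
    ka <- r$chains_a[has(r$chains_a, r$res_a)]
    kb <- r$chains_b[has(r$chains_b, r$res_b)]
    if (length(ka) == 0 || length(kb) == 0) return(NULL)
    r$chains_a <- ka; r$chains_b <- kb
    return(r)
  }
  if (inherits(r, "rigid_group_restraint")) {
    keep <- has(rep(r$chain, length(r$residues)), r$residues)
    if (sum(keep) < 3) return(NULL)
    r$residues <- r$residues[keep]
    r$ref_dist <- r$ref_dist[keep, keep, drop = FALSE]
    return(r)
  }
  if (inherits(r, "anchor_restraint")) {
    keep <- has(r$ref$chain, r$ref$resno)
    if (!any(keep)) return(NULL)
    r$ref <- r$ref[keep, , drop = FALSE]
    return(r)
  }
  if (inherits(r, "membrane_slab_restraint")) {
    keep <- has(r$members$chain, r$members$resno)
    if (!any(keep)) return(NULL)
    r$members <- r$members[keep, , drop = FALSE]
    return(r)
  }
  r  # sterics / bonds always apply to whatever is present
}

subset_topology <- function(topo, coords) {
  if (is.null(topo)) return(NULL)
  present <- unique(coords$chain)
  ch <- topo$chains[topo$chains$chain_id %in% present, , drop = FALSE]
  ch$residues <- lapply(ch$chain_id, function(c0) {
    sort(coords$resno[coords$chain == c0])
  })
  rg <- topo$rigid_groups
  if (!is.null(rg)) {
    rg <- rg[rg$chain_id %in% present, , drop = FALSE]
    if (nrow(rg) == 0) rg <- NULL
  }
  mem <- topo$membrane
  if (!is.null(mem)) {
    mem <- mem[mem$chain_id %in% present, , drop = FALSE]
    if (nrow(mem) == 0) mem <- NULL
  }
  complex_topology(ch, rg, mem)
}

#' Run a staged assembly plan
#'
#' Executes the stages in order: newly added chains take their internal
#' geometry from `model` (the per-chain starting coordinates, e.g. template
#' or synthetic geometry) and are placed with a random orientation 10
#' Angstrom outside the bounding sphere of the current complex; removed
#' residues are deleted together with every restraint touching them; then
#' the current complex is annealed with only the restraints whose residues
#' are all present (ambiguous sides restricted to present copies). All
#' randomness derives from `seed`.
#'
#' @param plan A [stage_plan()].
#' @param model A [ca_model()] covering every chain the plan introduces.
#' @param restraints A [restraint_set()] over the full system.
#' @param schedule An [anneal_schedule()] (applied per stage).
#' @param weights A [score_weights()].
#' @param seed Integer seed.
#' @return A `stage_result`: list with the final `model`, `snapshots` (one
#'   [ca_model()] per stage) and a per-stage `log` tibble.
#' @export
run_stage_plan <- function(plan, model, restraints,
                           schedule = anneal_schedule(),
                           weights = score_weights(), seed = 1) {
  stopifnot(inherits(plan, "stage_plan"))
  set.seed(seed)
  ref <- model$coords
  cur <- ref[0, , drop = FALSE]
  snapshots <- vector("list", length(plan))
  log <- vector("list", length(plan))
  sched <- schedule; sched$seed <- NULL  # single seeded stream for the run
  for (si in seq_along(plan)) {
    st <- plan[[si]]
    for (ch in st$add) {
      block <- ref[ref$chain == ch, , drop = FALSE]
      if (nrow(block) == 0) {
        stop("stage '", st$name, "' adds unknown chain '", ch, "'",
             call. = FALSE)
      }
      m <- as.matrix(block[, c("x", "y", "z")])
      ctr <- colMeans(m)
      m0 <- sweep(m, 2, ctr)
      if (nrow(cur) == 0) {
        block[, c("x", "y", "z")] <- sweep(m0, 2, ctr, `+`)
      } else {
        cm <- as.matrix(cur[, c("x", "y", "z")])
        ccen <- colMeans(cm)
        rad <- sqrt(max(rowSums(sweep(cm, 2, ccen)^2)))
        own <- sqrt(max(rowSums(m0^2)))
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        R <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
        pos <- ccen + u * (rad + own + 10)
        block[, c("x", "y", "z")] <- sweep(m0 %*% R, 2, pos, `+`)
      }
      cur <- dplyr::bind_rows(cur, block)
    }
    if (!is.null(st$remove)) {
      drop <- cur$chain == st$remove$chain & cur$resno %in% st$remove$residues
      cur <- cur[!drop, , drop = FALSE]
    }
    cur_model <- ca_model(cur, topology = subset_topology(model$topology, cur))
    active <- purrr::compact(lapply(restraints, restrict_restraint, cur_model))
    if (!is.null(st$restraints)) {
      explicit <- lapply(restraints[st$restraints], restrict_restraint,
                         cur_model)
      if (any(vapply(explicit, is.null, TRUE))) {
        stop("stage '", st$name,
             "' activates a restraint referencing an entity not yet present",
             call. = FALSE)
      }
      active <- explicit
    }
    active <- restraint_set(active)
    cur_model <- anneal(cur_model, active, weights, sched,
                        frozen = st$frozen)
    cur <- cur_model$coords
    snapshots[[si]] <- cur_model
    log[[si]] <- tibble::tibble(
      stage = st$name, n_residues = nrow(cur),
      score = attr(cur_model, "score"),
      crosslink_violations = crosslink_violations(cur_model, active)
    )
  }
  structure(list(model = snapshots[[length(plan)]], snapshots = snapshots,
                 log = dplyr::bind_rows(log), seed = seed),
            class = "stage_result")
}

#' Build an ensemble of models and select the best
#'
#' Runs the stage plan `n_models` times with seeds `base_seed + 0 ...
#' base_seed + n_models - 1` and selects the model with the fewest
#' cross-link violations (ties broken by lowest total score, then lowest
#' index). The default ensemble size is 8.
#'
#' @inheritParams run_stage_plan
#' @param n_models Ensemble size (>= 1, default 8).
#' @param base_seed First seed.
#' @return An `assembly_result`: `models` (list of [ca_model()]),
#'   `summary` tibble (per model: seed, cross-link violations, total
#'   score), `selected` (index), and the configuration snapshot.
#' @export
build_ensemble <- function(plan, model, restraints,
                           schedule = anneal_schedule(),
                           weights = score_weights(),
                           n_models = default_config()$n_models,
                           base_seed = 1) {
  stopifnot(n_models >= 1)
  runs <- vector("list", n_models)
  rows <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    seed_i <- base_seed + i - 1L
    res <- run_stage_plan(plan, model, restraints, schedule, weights,
                          seed = seed_i)
    final <- res$model
    active <- restraint_set(
      purrr::compact(lapply(restraints, restrict_restraint, final))
    )
    sc <- as.numeric(total_score(final, active, weights))
    xl <- crosslink_violations(final, active)
    runs[[i]] <- final
    rows[[i]] <- tibble::tibble(model = i, seed = seed_i,
                                crosslink_violations = xl, total_score = sc)
  }
  summary <- dplyr::bind_rows(rows)
  sel <- select_model_index(summary$crosslink_violations, summary$total_score)
  structure(list(models = runs, summary = summary, selected = sel,
                 config = list(n_models = n_models, base_seed = base_seed,
                               schedule = unclass(schedule),
                               weights = unclass(weights))),
            class = "assembly_result")
}

## selection rule: fewest cross-link violations, then lowest total score,
## then lowest index
select_model_index <- function(crosslink_violations, total_score) {
  order(crosslink_violations, total_score, seq_along(crosslink_violations))[1]
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("<assembly_result> ", length(x$models), " models; selected model ",
      x$selected, " (", x$summary$crosslink_violations[x$selected],
      " cross-link violations)\n", sep = "")
  invisible(x)
}

#' @rdname build_ensemble
#' @param x An `assembly_result`.
#' @param ... Unused.
#' @export
tidy.assembly_result <- function(x, ...) {
  dplyr::mutate(x$summary, selected = .data$model == x$selected)
}

#' @rdname build_ensemble
#' @export
glance.assembly_result <- function(x, ...) {
  s <- x$summary[x$selected, ]
  tibble::tibble(n_models = length(x$models), selected = x$selected,
                 crosslink_violations = s$crosslink_violations,
                 total_score = s$total_score)
}

#' Selected model of an assembly result
#'
#' @param result An `assembly_result`.
#' @return The selected [ca_model()].
#' @export
selected_model <- function(result) result$models[[result$selected]]

#' Serialize an assembly result deterministically
#'
#' Canonical JSON (fixed 8-digit coordinate precision) for provenance and
#' the byte-identity determinism contract: two runs with identical
#' configuration and seeds serialize to identical bytes.
#'
#' @param result An `assembly_result`.
#' @param path Optional output path.
#' @return The JSON string, invisibly if `path` is given.
#' @export
serialize_assembly <- function(result, path = NULL) {
  payload <- list(
    selected = result$selected,
    summary = result$summary,
    config = result$config,
    models = lapply(result$models, function(m) {
      dplyr::mutate(m$coords[, c("chain", "resno", "x", "y", "z")],
                    dplyr::across(c("x", "y", "z"), ~ round(.x, 6)))
    })
  )
  js <- jsonlite::toJSON(payload, digits = I(8), auto_unbox = TRUE,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Place catalytic zinc ions
#'
#' Adds one zinc pseudo-atom per copy of the protease chain, at the
#' centroid of the C-alpha positions of the three ligand residues (default
#' D137, H43, H47 -- given as residue numbers). A zinc closer than 2
#' Angstrom to any bead raises a clash warning.
#'
#' @param model A [ca_model()] with a topology.
#' @param entity Entity whose copies receive a zinc (default: the first
#'   multi-copy entity, else the first entity).
#' @param ligand_residues Three residue numbers coordinating the ion.
#' @param min_sep Clash-check distance, Angstrom.
#' @return The model with a `zn` table (one row per copy); written as
#'   HETATM ZN records by [write_ca_pdb()].
#' @export
place_zinc <- function(model, entity = NULL,
                       ligand_residues = default_config()$zn_ligands,
                       min_sep = 2) {
  topo <- model$topology
  if (is.null(topo)) stop("model has no topology", call. = FALSE)
  if (is.null(entity)) {
    counts <- table(topo$chains$entity)
    entity <- if (any(counts > 1)) names(counts)[counts > 1][1] else
      topo$chains$entity[1]
  }
  chains <- topo$chains$chain_id[topo$chains$entity == entity]
  if (length(chains) == 0) stop("no chains of entity '", entity, "'",
                                call. = FALSE)
  m <- coords_matrix(model)
  zn <- purrr::map_dfr(chains, function(ch) {
    idx <- residue_index(model, rep(ch, length(ligand_residues)),
                         ligand_residues)
    ctr <- colMeans(m[idx, , drop = FALSE])
    tibble::tibble(chain = ch, x = ctr[1], y = ctr[2], z = ctr[3])
  })
  dmin <- apply(zn, 1, function(row) {
    p <- as.numeric(row[c("x", "y", "z")])
    min(sqrt(rowSums(sweep(m, 2, p)^2)))
  })
  if (any(dmin < min_sep)) {
    warning(sum(dmin < min_sep), " zinc site(s) within ", min_sep,
            " Angstrom of a bead", call. = FALSE)
  }
  model$zn <- zn
  model
}
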