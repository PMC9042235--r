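## Flattening of a restraint set into the numeric structures consumed by
## the compiled score/gradient (src/energy.cpp). Residues are indexed by
## row position in the model's coordinate tibble; class weights are baked
## into per-term weights here. The plain-R dispatch in R/restraints.R is
## the reference semantics; tests assert the two routes agree.

compile_system <- function(model, restraints, weights = score_weights()) {
  co <- model$coords
  n <- nrow(co)
  key <- residue_key(co$chain, co$resno)
  idx_of <- function(chain, resno) {
    i <- match(residue_key(chain, resno), key)
    if (anyNA(i)) stop("restraint references residue absent from model",
                       call. = FALSE)
    i
  }
  w <- unlist(weights)

  fb_pairs <- list(); fb_bound <- c(); fb_weight <- c(); fb_class <- c()
  rig_pairs <- list()
  anc_idx <- integer(); anc_ref <- list(); anc_w <- c()
  slab_idx <- integer(); slab_hw <- c(); slab_w <- c()
  w_ster <- 0; d_min <- 4
  bond_len <- 3.8; w_bond <- 0

  for (r in restraints) {
    if (inherits(r, "crosslink_restraint") || inherits(r, "contact_restraint")) {
      ia <- idx_of(r$chains_a, rep(r$res_a, length(r$chains_a)))
      ib <- idx_of(r$chains_b, rep(r$res_b, length(r$chains_b)))
      grid <- expand.grid(i = ia, j = ib)
      fb_pairs[[length(fb_pairs) + 1]] <- as.matrix(grid)
      fb_bound <- c(fb_bound, r$upper_bound)
      neg <- inherits(r, "crosslink_restraint") && r$polarity == "negative"
      cls <- restraint_class(r)
      fb_weight <- c(fb_weight, if (neg) 0 else w[[cls]])
      fb_class <- c(fb_class, switch(cls, crosslink = 1L,
                                     contact_inter = 2L, contact_intra = 3L))
    } else if (inherits(r, "rigid_group_restraint")) {
      idx <- idx_of(rep(r$chain, length(r$residues)), r$residues)
      pr <- which(upper.tri(r$ref_dist), arr.ind = TRUE)
      rig_pairs[[length(rig_pairs) + 1]] <- cbind(
        idx[pr[, 1]], idx[pr[, 2]], r$ref_dist[pr],
        r$force_constant * w[["rigid"]]
      )
    } else if (inherits(r, "anchor_restraint")) {
      ai <- idx_of(r$ref$chain, r$ref$resno)
      anc_idx <- c(anc_idx, ai)
      anc_ref[[length(anc_ref) + 1]] <- as.matrix(r$ref[, c("x", "y", "z")])
      anc_w <- c(anc_w, rep(r$k * w[["anchor"]], length(ai)))
    } else if (inherits(r, "membrane_slab_restraint")) {
      si <- idx_of(r$members$chain, r$members$resno)
      slab_idx <- c(slab_idx, si)
      slab_hw <- c(slab_hw, rep(r$half_width, length(si)))
      slab_w <- c(slab_w, rep(w[["slab"]], length(si)))
    } else if (inherits(r, "steric_restraint")) {
      w_ster <- w_ster + w[["sterics"]]
      d_min <- r$d_min
    } else if (inherits(r, "chain_bond_restraint")) {
      w_bond <- w_bond + w[["bond"]]
      bond_len <- r$bond_length
    }
  }

  fbm <- if (length(fb_pairs)) do.call(rbind, fb_pairs) else matrix(0L, 0, 2)
  storage.mode(fbm) <- "integer"
  fb_offset <- as.integer(cumsum(c(0, vapply(fb_pairs, nrow, 0))))
  rigm <- if (length(rig_pairs)) do.call(rbind, rig_pairs) else matrix(0, 0, 4)
  ancm <- if (length(anc_ref)) do.call(rbind, anc_ref) else matrix(0, 0, 3)
  bp <- bond_pairs(model)
  storage.mode(bp) <- "integer"

  list(n = n, key = key,
       fb_pairs = fbm, fb_offset = fb_offset, fb_bound = as.numeric(fb_bound),
       fb_weight = as.numeric(fb_weight), fb_class = as.integer(fb_class),
       rig_pairs = rigm,
       anc_idx = as.integer(anc_idx), anc_ref = ancm, anc_w = as.numeric(anc_w),
       slab_idx = as.integer(slab_idx), slab_hw = as.numeric(slab_hw),
       slab_w = as.numeric(slab_w),
       bond_pairs = bp, bond_len = bond_len, w_bond = w_bond,
       w_ster = w_ster, d_min = d_min)
}

## compiled total score (scalar) / per-class vector / gradient on a plain
## coordinate matrix ordered as model$coords
sys_score <- function(coords, sys) .xl_score(coords, sys)[["total"]]
sys_score_classes <- function(coords, sys) .xl_score(coords, sys)
sys_grad <- function(coords, sys) .xl_grad(coords, sys)
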