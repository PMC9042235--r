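make_aln <- function(seqs, orgs = NULL) {
  n <- length(seqs)
  if (is.null(orgs)) orgs <- c("B_subtilis", paste0("org_", seq_len(n - 1) + 1))
  msa(seq_id = paste0("s", seq_len(n)), organism = orgs, sequence = seqs)
}

test_that("identical rows are fully conserved; the 70% rule is >=", {
  aln <- make_aln(rep("MKWLV", 10))
  cc <- call_conservation(aln)
  expect_true(all(cc$conserved))
  expect_true(all(cc$identity_fraction == 1))

  # 7 of 10 rows share the modal residue at column 1
  seqs <- c(rep("A", 7), "C", "D", "E")
  aln2 <- make_aln(paste0(seqs, "A"))
  cc2 <- call_conservation(aln2, threshold = 0.70)
  expect_equal(cc2$identity_fraction[1], 0.7)
  expect_true(cc2$conserved[1])  # at least 70%: boundary included
})

test_that("per-column fractions match an independent brute-force tally", {
  set.seed(21)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY-", "")[[1]]
  rows <- vapply(1:20, function(i) {
    paste(sample(aa, 12, replace = TRUE), collapse = "")
  }, "")
  aln <- make_aln(rows)
  cc <- call_conservation(aln)
  m <- do.call(rbind, strsplit(rows, ""))
  for (j in 1:12) {
    col <- m[, j][m[, j] != "-"]
    expected <- if (length(col) == 0) 0 else max(table(col)) / 20
    expect_equal(cc$identity_fraction[j], expected)
  }
})

test_that("conservation is invariant to row order and full duplication", {
  set.seed(22)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rows <- vapply(1:8, function(i) {
    paste(sample(aa, 10, replace = TRUE), collapse = "")
  }, "")
  aln <- make_aln(rows)
  cc <- call_conservation(aln)
  shuffled <- make_aln(rows[c(1, sample(2:8))])  # keep reference row first
  expect_equal(call_conservation(shuffled)$identity_fraction,
               cc$identity_fraction)
  doubled <- make_aln(rep(rows, 2), orgs = paste0("o", 1:16))
  expect_equal(call_conservation(doubled)$identity_fraction,
               cc$identity_fraction)
})

test_that("gaps never count toward identity but stay in the denominator", {
  aln <- make_aln(c("A", "A", "-", "-"), orgs = paste0("o", 1:4))
  cc <- call_conservation(aln)
  expect_equal(cc$identity_fraction, 0.5)
})

test_that("conservation maps columns to ungapped reference positions", {
  aln <- make_aln(c("M-KL", "MAKL", "MAKL"))
  cc <- call_conservation(aln)
  expect_equal(cc$reference_position, c(1L, NA_integer_, 2L, 3L))
  expect_error(call_conservation(msa("s1", "B_subtilis", "MK")), ">= 2 rows")
})

test_that("hybrid reference row is refA + 20 glycines + refB", {
  set.seed(23)
  a <- make_aln(c(strrep("A", 50), strrep("C", 50)))
  b <- make_aln(c(strrep("D", 30), strrep("E", 30)))
  hyb <- build_hybrid_msa(a, b)
  expect_equal(hyb$width, 100)
  ref <- hyb$rows$sequence[1]
  expect_equal(substr(ref, 51, 70), strrep("G", 20))
  expect_equal(attr(hyb, "linker_columns"), 51:70)
  # homolog rows carry gaps in the linker region
  expect_equal(substr(hyb$rows$sequence[2], 51, 70), strrep("-", 20))
})

test_that("pairing is by organism; unpaired homologs are dropped and logged", {
  a <- msa(seq_id = c("a0", "a1", "a2"),
           organism = c("B_subtilis", "shared", "a_only"),
           sequence = c("MK", "MR", "ML"))
  b <- msa(seq_id = c("b0", "b1", "b2"),
           organism = c("B_subtilis", "shared", "b_only"),
           sequence = c("VW", "VY", "VF"))
  hyb <- build_hybrid_msa(a, b)
  expect_equal(nrow(hyb$rows), 2)
  man <- attr(hyb, "pair_manifest")
  expect_equal(man$organism, c("B_subtilis", "shared"))
  drops <- attr(hyb, "dropped")
  expect_setequal(drops$organism, c("a_only", "b_only"))
  # two single-row alignments: manifest of length 1
  hyb1 <- build_hybrid_msa(
    msa("a0", "B_subtilis", "MK"), msa("b0", "B_subtilis", "VW")
  )
  expect_equal(nrow(attr(hyb1, "pair_manifest")), 1)
})

test_that("a missing reference organism is a hard error", {
  a <- msa("a0", "B_subtilis", "MK")
  b <- msa("b0", "other_strain", "VW")
  expect_error(build_hybrid_msa(a, b), "reference organism")
})

test_that("linker predictions are masked and positions re-indexed per protein", {
  a <- make_aln(c(strrep("A", 50), strrep("C", 50)))
  b <- make_aln(c(strrep("D", 30), strrep("E", 30)))
  hyb <- build_hybrid_msa(a, b)
  cm <- contact_map(tibble::tibble(
    i = c(55L, 11L, 3L, 72L), j = c(80L, 86L, 20L, 95L),
    probability = c(0.9, 0.8, 0.7, 0.6)
  ))
  out <- mask_linker(cm, hyb)
  # (55, 80): i inside linker [51, 70] -> removed
  expect_equal(nrow(out), 3)
  # (11, 86): kept, re-indexed to (A:11, B:16) in 1-based protein numbering
  expect_equal(out[out$probability == 0.8, ]$scope, "inter")
  expect_equal(out[out$probability == 0.8, ]$pos_a, 11L)
  expect_equal(out[out$probability == 0.8, ]$pos_b, 16L)
  # (3, 20): intra first protein, unchanged
  expect_equal(out[out$probability == 0.7, ]$scope, "intra_a")
  expect_equal(out[out$probability == 0.7, ]$pos_b, 20L)
  # (72, 95): intra second protein, shifted by width_a + 20
  expect_equal(out[out$probability == 0.6, ]$scope, "intra_b")
  expect_equal(out[out$probability == 0.6, ]$pos_a, 2L)
  # empty map stays empty; out-of-range positions are hard errors
  empty <- contact_map(tibble::tibble(i = integer(), j = integer(),
                                      probability = double()))
  expect_equal(nrow(mask_linker(empty, hyb)), 0)
  expect_error(
    mask_linker(contact_map(tibble::tibble(i = 1L, j = 101L,
                                           probability = 0.5)), hyb),
    "outside hybrid width"
  )
})

test_that("probability filtering is strictly greater than the cutoff", {
  cm <- tibble::tibble(chain_a = "A", res_a = 1:3, chain_b = "B", res_b = 4:6,
                       probability = c(0.14, 0.15, 0.16))
  out <- curate_contacts(cm)
  expect_equal(out$probability, 0.16)  # 0.15 itself is excluded
  expect_equal(out$class, "contact_inter")
})

test_that("curation keeps intra/inter classification and applies exclusions last", {
  cm <- tibble::tibble(
    chain_a = c("A", "A", "A"), res_a = c(1L, 1L, 2L),
    chain_b = c("A", "B", "B"), res_b = c(5L, 3L, 4L),
    probability = c(0.9, 0.9, 0.9)
  )
  out <- curate_contacts(cm)
  expect_equal(out$class, c("contact_intra", "contact_inter", "contact_inter"))
  # exclusion is order-insensitive in the pair
  out2 <- curate_contacts(cm, exclude = tibble::tibble(
    chain_a = "B", res_a = 3L, chain_b = "A", res_b = 1L
  ))
  expect_equal(nrow(out2), 2)
})

test_that("curation with a model equals the brute-force record filter", {
  spec <- synth_spec(seed = 5)
  ref <- make_reference_complex(spec)
  cm <- simulate_contact_map(ref, spec)
  cm <- cm[sample.int(nrow(cm), 50), ]
  cfg <- default_config()
  out <- curate_contacts(cm, model = ref)
  w <- unlist(score_weights())
  keep <- vapply(seq_len(nrow(cm)), function(k) {
    row <- cm[k, ]
    if (row$probability <= cfg$contact_p_threshold) return(FALSE)
    d <- residue_distance(ref, row$chain_a, row$res_a, row$chain_b, row$res_b)
    cls <- if (row$chain_a == row$chain_b) "contact_intra" else "contact_inter"
    sc <- w[[cls]] * max(0, d - cfg$contact_bound)^2
    sc <= cfg$contact_violation_threshold
  }, TRUE)
  expected <- cm[keep, ]
  expect_equal(nrow(out), nrow(expected))
  expect_setequal(
    paste(out$chain_a, out$res_a, out$chain_b, out$res_b),
    paste(expected$chain_a, expected$res_a, expected$chain_b, expected$res_b)
  )
})

test_that("retained contacts never increase with the probability cutoff", {
  spec <- synth_spec(seed = 6)
  ref <- make_reference_complex(spec)
  cm <- simulate_contact_map(ref, spec)
  counts <- vapply(seq(0, 0.9, by = 0.1), function(p) {
    nrow(curate_contacts(cm, p_threshold = p))
  }, 0)
  expect_true(all(diff(counts) <= 0))
  # p_threshold 0 and no model keeps every record
  expect_equal(nrow(curate_contacts(cm, p_threshold = 0)), nrow(cm))
})

test_that("masking then filtering equals filtering then masking", {
  a <- make_aln(c(strrep("A", 12), strrep("C", 12)))
  b <- make_aln(c(strrep("D", 8), strrep("E", 8)))
  hyb <- build_hybrid_msa(a, b)
  set.seed(31)
  cm <- contact_map(tibble::tibble(
    i = sample(1:39, 30, replace = TRUE)
  ) |>
    dplyr::mutate(j = .data$i + sample(1:(40 - max(.data$i)), 30,
                                       replace = TRUE),
                  probability = stats::runif(30)) |>
    dplyr::distinct(.data$i, .data$j, .keep_all = TRUE))
  p <- 0.15
  mask_first <- mask_linker(cm, hyb)
  mask_first <- mask_first[mask_first$probability > p, ]
  filter_first <- mask_linker(cm[cm$probability > p, ], hyb)
  expect_equal(dplyr::arrange(mask_first, .data$pos_a, .data$pos_b),
               dplyr::arrange(filter_first, .data$pos_a, .data$pos_b))
})
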