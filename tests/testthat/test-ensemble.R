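test_that("confidence filtering is inclusive at both thresholds and truncates", {
  rows <- data.frame(
    design_id = sprintf("d%02d", 1:4),
    mean_plddt = c(85, 79.9, 80.0, 90),
    ipae = c(10, 10, 15.0, 15.1), stringsAsFactors = FALSE)
  kept <- filter_designs(rows)
  expect_setequal(kept$design_id, c("d01", "d03"))   # boundary row retained
  expect_equal(filter_designs(kept), kept)           # idempotent
  expect_true(all(kept$design_id %in% rows$design_id))

  many <- make_mock_metrics(300, fraction_passing = 0.75, seed = 2)
  kept100 <- filter_designs(many)
  expect_equal(nrow(kept100), 100)
  expect_true(all(diff(kept100$ipae) >= 0))          # ranked by ascending iPAE
  expect_equal(nrow(filter_designs(many, keep = 1e6)), 225)
})

test_that("confidence scatter is a lossless projection", {
  rows <- make_mock_metrics(10, 0.5, seed = 3)
  sc <- confidence_scatter(rows)
  expect_equal(nrow(sc), 10)
  expect_equal(sc$ipae, rows$ipae)
  expect_equal(sc$mean_plddt, rows$mean_plddt)
  expect_equal(nrow(confidence_scatter(rows[0, ])), 0)
})

test_that("design metrics tables validate on read", {
  rows <- make_mock_metrics(8, 0.5, seed = 4)
  p <- tempfile(fileext = ".csv")
  write_design_metrics(rows, p)
  back <- read_design_metrics(p)
  expect_equal(back$design_id, rows$design_id)
  bad <- rows
  bad$mean_plddt[1] <- 104
  write_design_metrics(bad, p)
  expect_error(read_design_metrics(p), "\\[0, 100\\]")
  bad2 <- rows
  bad2$length[1] <- 7
  write_design_metrics(bad2, p)
  expect_error(read_design_metrics(p), "disagrees")
})

test_that("backbone RMSD is zero for identical and rigidly moved models", {
  ref <- make_helix_dimer(helix_dimer_spec(seed = 31))
  same <- per_residue_rmsd(ref, ref)
  expect_equal(max(same$rmsd), 0, tolerance = 1e-9)
  expect_equal(global_rmsd(same), 0, tolerance = 1e-9)
  set.seed(77)
  moved <- apply_rigid(ref, random_rotation(), runif(3, -20, 20))
  pr <- per_residue_rmsd(moved, ref)
  expect_equal(global_rmsd(pr), 0, tolerance = 1e-6)
  expect_equal(max(pr$rmsd), 0, tolerance = 1e-6)
})

test_that("a single displaced residue dominates its RMSD profile", {
  ref <- make_helix_dimer(helix_dimer_spec(seed = 32))
  moved <- ref
  hit <- moved$atoms$chain_id == "A" & moved$atoms$res_seq == 5 &
    moved$atoms$name %in% c("N", "CA", "C", "O")
  moved$atoms$x[hit] <- moved$atoms$x[hit] + 2
  pr <- per_residue_rmsd(moved, ref)
  worst <- pr$model_residue[which.max(pr$rmsd)]
  expect_equal(worst, "A:ALA:5")
  expect_gt(max(pr$rmsd), 1.5)             # ~2 A, shrunk by re-superposition
  expect_lt(sort(pr$rmsd, decreasing = TRUE)[2], 0.5)
})

test_that("RMSD needs at least 3 complete mapped residues", {
  ref <- make_helix_dimer(helix_dimer_spec(n_residues = 4, seed = 33))
  corr <- data.frame(model_residue = c("A:ALA:1", "A:ALA:2"),
                     ref_residue = c("A:ALA:1", "A:ALA:2"))
  expect_error(per_residue_rmsd(ref, ref, corr), "at least 3")
})

test_that("energy-distance regression recovers exact linear relations", {
  rp <- function(d, e) {
    structure(data.frame(residue_i = canonical_key("A", "ALA", seq_along(d)),
                         residue_j = canonical_key("B", "ALA", seq_along(d)),
                         min_distance = d, mean_distance = d, sum_e_total = e,
                         n_atom_pairs = 1L),
              class = c("residue_pair_table", "data.frame"))
  }
  d <- c(2, 3, 4.5, 6, 8)
  up <- energy_distance_correlation(rp(d, 2 * d - 10))
  expect_equal(up$pearson_r, 1.0, tolerance = 1e-12)
  expect_equal(up$slope, 2, tolerance = 1e-9)
  expect_equal(up$intercept, -10, tolerance = 1e-9)
  down <- energy_distance_correlation(rp(d, -2 * d + 1))
  expect_equal(down$pearson_r, -1.0, tolerance = 1e-12)
  flat <- energy_distance_correlation(rp(d, rep(-3, 5)))
  expect_false(flat$defined)
  expect_true(is.na(flat$pearson_r))
  expect_null(flat$slope)
  expect_error(energy_distance_correlation(rp(c(1, 2), c(1, 2))), "at least 3")
})

test_that("global alignment handles identity, gaps, and symmetry", {
  same <- global_align("ACDE", "ACDE")
  expect_equal(same$identity, 1.0)
  expect_equal(same$aligned_a, "ACDE")
  gap <- global_align("ACDE", "ACE")
  expect_equal(gap$length, 4)
  expect_equal(gap$aligned_a, "ACDE")
  expect_true(gap$aligned_b %in% c("AC-E", "A-CE"))
  pairs <- list(c("MKV", "MQV"), c("ACDEFG", "ACFG"), c("W", "WW"))
  for (p in pairs)
    expect_equal(global_align(p[1], p[2])$score,
                 global_align(p[2], p[1])$score)
  expect_error(global_align("", "ACD"), "empty")
  expect_error(global_align("ACD", "AC1"), "non-amino-acid")
})

test_that("alignment scores match Biostrings and the exhaustive oracle", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(101)
  alpha <- c("A", "R", "N", "D", "C")
  seqs <- vapply(1:8, function(i)
    paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = ""),
    character(1))
  for (i in 1:4) for (j in 5:8) {
    mine <- global_align(seqs[i], seqs[j])$score
    expect_equal(mine, exhaustive_align_score(seqs[i], seqs[j], BLOSUM62),
                 label = paste(seqs[i], seqs[j], "vs exhaustive"))
    bs <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[i]), Biostrings::AAString(seqs[j]),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(mine, bs, label = paste(seqs[i], seqs[j], "vs Biostrings"))
  }
})

test_that("diversity metrics satisfy their closed forms", {
  dr <- diversity_report(c(a = "ACDE", b = "ACDE"))
  expect_equal(dr$hamming_distribution, 0)
  expect_equal(unname(dr$identity_matrix[1, 2]), 1)
  all_diff <- diversity_report(c(a = "AAAA", b = "CCCC"))
  expect_equal(all_diff$hamming_distribution, 1)

  half <- diversity_report(c(a = "AC", b = "AD"))
  expect_equal(unname(half$entropy_bits), c(0, 1))   # conserved, 50/50

  uniform <- diversity_report(setNames(paste0(AA <- strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]], "A"), paste0("s", 1:20)))
  expect_equal(unname(uniform$entropy_bits[1]), log2(20), tolerance = 1e-9)

  expect_true(isSymmetric(dr$identity_matrix))
  expect_equal(unname(diag(dr$identity_matrix)), c(1, 1))
  expect_error(diversity_report("ACDE"), "at least 2")
  expect_error(diversity_report(c("ACDE", "ACD")), "equal-length")
})

test_that("align-mode diversity counts gap columns as mismatches", {
  dr <- diversity_report(c(a = "ACDEF", b = "ACF"), mode = "align")
  al <- global_align("ACDEF", "ACF")
  expect_equal(unname(dr$hamming_matrix[1, 2]), 1 - al$identity)
  expect_equal(length(dr$entropy_bits), 5)   # columns of the first sequence
})

test_that("entropy is zero exactly on single-valued columns", {
  mat <- rbind(c("A", "C", "G"), c("A", "C", "T"), c("A", "D", "T"))
  h <- column_entropy(mat)
  expect_equal(h[1], 0)
  expect_true(all(h[2:3] > 0))
  expect_true(all(h >= 0 & h <= log2(20)))
})
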