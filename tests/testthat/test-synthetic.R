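test_that("dimer generation is bit-reproducible under a fixed seed", {
  s <- helix_dimer_spec(seed = 51, salt_bridges = list(c(3, 3)))
  m1 <- make_helix_dimer(s)
  m2 <- make_helix_dimer(s)
  expect_identical(m1$atoms, m2$atoms)
  m3 <- make_helix_dimer(helix_dimer_spec(seed = 52,
                                          salt_bridges = list(c(3, 3))))
  expect_false(identical(m1$atoms$x, m3$atoms$x))
})

test_that("dimer geometry respects the construction parameters", {
  sep <- 10
  m <- make_helix_dimer(helix_dimer_spec(n_residues = 12, separation = sep,
                                         seed = 53))
  expect_equal(length(unique(m$atoms$chain_id)), 2)
  expect_equal(nrow(model_residues(m)), 24)
  ca_a <- as.matrix(m$atoms[m$atoms$chain_id == "A" & m$atoms$name == "CA",
                            c("x", "y", "z")])
  ca_b <- as.matrix(m$atoms[m$atoms$chain_id == "B" & m$atoms$name == "CA",
                            c("x", "y", "z")])
  d <- sqrt(outer(rowSums(ca_a^2), rowSums(ca_b^2), "+") -
              2 * tcrossprod(ca_a, ca_b))
  # closest approach of two ideal helices (2.3 A Calpha radius) on axes
  # `sep` apart lies between sep - 2*2.3 and sep
  expect_gt(min(d), sep - 2 * 2.3 - 0.5)
  expect_lt(min(d), sep + 0.5)
  # consecutive Calphas ~3.8 A apart as in a real helix
  steps <- sqrt(rowSums((ca_a[-1, ] - ca_a[-nrow(ca_a), ])^2))
  expect_true(all(abs(steps - 3.8) < 0.2))
  expect_error(make_helix_dimer(helix_dimer_spec(sequence_a = strrep("Z", 12),
                                                 seed = 1)),
               "invalid residue")
})

test_that("engineered bridges form a close carboxylate-ammonium contact", {
  m <- make_helix_dimer(helix_dimer_spec(seed = 54,
                                         salt_bridges = list(c(6, 6))))
  a <- m$atoms
  oe <- as.matrix(a[a$chain_id == "A" & a$res_seq == 6 &
                      a$name %in% c("OE1", "OE2"), c("x", "y", "z")])
  nz <- as.matrix(a[a$chain_id == "B" & a$res_seq == 6 & a$name == "NZ",
                    c("x", "y", "z")])
  d <- sqrt(rowSums((oe - nz[rep(1, 2), ])^2))
  expect_true(any(d > 2.4 & d < 3.6))
})

test_that("mock contact tables recover the plan exactly at zero noise", {
  plan <- setNames(c(5, 2.5), canonical_key("A", "GLU", c(1, 2)))
  tab <- make_mock_contact_table(plan, noise_sd = 0, seed = 1)
  hs <- aggregate_hotspots(tab, hotspot_criteria("residue_pair"))
  got <- setNames(hs$receptor$strength, hs$receptor$residue_id)
  expect_equal(got[names(plan)], plan)
  expect_equal(nrow(make_mock_contact_table(setNames(numeric(0),
                                                     character(0)))), 0)
  expect_error(make_mock_contact_table(setNames(-1, "A:ALA:1")), ">= 0")
})

test_that("sequence ensembles honor rate, conservation, and the seed", {
  zero <- make_sequence_ensemble("ACDEFGHIKL", 20, 0, seed = 7)
  expect_equal(length(unique(zero)), 1)
  dr0 <- diversity_report(zero)
  expect_true(all(dr0$entropy_bits == 0))
  expect_true(all(dr0$hamming_distribution == 0))

  ens <- make_sequence_ensemble(strrep("A", 40), 60, 0.4,
                                conserved = c(1, 2, 40), seed = 8)
  mat <- do.call(rbind, strsplit(ens, ""))
  expect_true(all(mat[, c(1, 2, 40)] == "A"))
  expect_identical(ens, make_sequence_ensemble(strrep("A", 40), 60, 0.4,
                                               conserved = c(1, 2, 40),
                                               seed = 8))
  expect_error(make_sequence_ensemble("ACD", 5, 1.2), "\\[0, 1\\]")
  expect_error(make_sequence_ensemble("ACD", 5, 0.1, conserved = 9), "bounds")
})

test_that("pairwise Hamming distance matches its analytic expectation", {
  r <- 0.3
  L <- 60
  ens <- make_sequence_ensemble(strrep("A", L), 200, r, seed = 9)
  dr <- diversity_report(ens)
  # two independent designs differ at a site w.p. 2r(1-r) + r^2 * 18/19;
  # the ensemble mean fluctuates with the realized mutation rate, whose
  # standard error sqrt(r(1-r)/(200 L)) propagates to ~0.006 on the mean
  # Hamming distance, so a 3-sigma band of 0.02 is allowed
  expected <- 2 * r * (1 - r) + r^2 * 18 / 19
  expect_lt(abs(mean(dr$hamming_distribution) - expected), 0.02)
})

test_that("mock metrics tables hit the planned pass fraction exactly", {
  rows <- make_mock_metrics(200, 0.5, seed = 10)
  pass <- rows$mean_plddt >= 80 & rows$ipae <= 15
  expect_equal(sum(pass), 100)
  expect_equal(nrow(filter_designs(rows)), 100)
  none <- make_mock_metrics(40, 0, seed = 11)
  expect_equal(nrow(filter_designs(none)), 0)
  expect_identical(make_mock_metrics(50, 0.3, seed = 12),
                   make_mock_metrics(50, 0.3, seed = 12))
})

test_that("generated dimers re-parse losslessly through the PDB writer", {
  m <- make_helix_dimer(helix_dimer_spec(seed = 55,
                                         salt_bridges = list(c(2, 9))))
  p <- tempfile(fileext = ".pdb")
  write_structure(m, p)
  back <- load_structure(p)
  expect_equal(back$atoms$name, m$atoms$name)
  expect_equal(as.matrix(back$atoms[c("x", "y", "z")]),
               as.matrix(m$atoms[c("x", "y", "z")]), ignore_attr = TRUE)
})
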