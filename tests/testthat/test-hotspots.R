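# minimal hand-built contact table
manual_contacts <- function(e_totals, distances,
                            res_i = "A:GLU:1", res_j = "B:LYS:1") {
  n <- length(e_totals)
  structure(data.frame(
    atom_i = seq_len(n), atom_j = seq_len(n),
    name_i = rep_len("CX", n), name_j = rep_len("CX", n),
    residue_i = rep_len(res_i, n), residue_j = rep_len(res_j, n),
    het_i = rep_len(FALSE, n), het_j = rep_len(FALSE, n),
    distance = distances, e_lj = rep_len(0, n),
    e_coul = e_totals, e_total = e_totals, stringsAsFactors = FALSE),
    class = c("contact_table", "data.frame"))
}

test_that("favorable atom pairs accumulate into per-residue strength", {
  hs <- aggregate_hotspots(manual_contacts(c(-1.5, -2.0, 0.3), c(3, 3, 3)))
  expect_equal(hs$receptor$strength, 3.5)
  expect_equal(hs$receptor$n_favorable, 2)
  expect_equal(hs$ligand$strength, 3.5)
  empty <- aggregate_hotspots(manual_contacts(numeric(0), numeric(0)))
  expect_equal(nrow(empty$receptor), 0)
  expect_equal(nrow(empty$ligand), 0)
})

test_that("threshold semantics: -1.0 inclusive for residue pairs, strict negativity for atom pairs", {
  crit_rp <- hotspot_criteria("residue_pair")
  at_09 <- aggregate_hotspots(manual_contacts(-0.9, 3.0), crit_rp)
  expect_equal(nrow(at_09$receptor), 0)
  at_10 <- aggregate_hotspots(manual_contacts(-1.0, 3.0), crit_rp)
  expect_equal(at_10$receptor$strength, 1.0)
  too_far <- aggregate_hotspots(manual_contacts(-5, 3.6), crit_rp)
  expect_equal(nrow(too_far$receptor), 0)

  crit_ap <- hotspot_criteria("atom_pair")
  at_eps <- aggregate_hotspots(manual_contacts(c(-1e-6, 0), c(4.5, 3)),
                               crit_ap)
  expect_equal(at_eps$receptor$strength, 1e-6)  # zero-energy pair excluded
  at_451 <- aggregate_hotspots(manual_contacts(-2, 4.51), crit_ap)
  expect_equal(nrow(at_451$receptor), 0)
})

test_that("strength is conserved between the two sides", {
  for (seed in c(1, 4)) {
    m <- prepared_dimer(seed = seed)
    iface <- select_interface(m, "A", "B")
    ct <- enumerate_contacts(iface$receptor, iface$ligand, 4.5)
    hs <- aggregate_hotspots(ct)
    expect_equal(sum(hs$receptor$strength), sum(hs$ligand$strength),
                 tolerance = 1e-9)
    qual <- ct$e_total[ct$e_total < 0 & ct$distance <= 4.5]
    expect_equal(sum(hs$receptor$strength), sum(abs(qual)),
                 tolerance = 1e-9)
  }
})

test_that("an engineered salt bridge ranks first on both sides", {
  m <- prepared_dimer(seed = 42, salt_bridges = list(c(6, 6)))
  iface <- select_interface(m, "A", "B")
  ct <- enumerate_contacts(iface$receptor, iface$ligand, 4.5)
  hs <- aggregate_hotspots(ct)
  expect_equal(hs$receptor$residue_id[hs$receptor$rank == 1], "A:GLU:6")
  expect_equal(hs$ligand$residue_id[hs$ligand$rank == 1], "B:LYS:6")
  # brute-force strength oracle for the top receptor residue
  bf <- brute_force_contacts(iface$receptor, iface$ligand, 4.5,
                             dielectric_model())
  uid <- with(iface$receptor$atoms,
              canonical_key(chain_id, res_name, res_seq, icode))
  glu_rows <- bf[uid[bf$atom_i] == "A:GLU:6" & bf$e_total < 0, ]
  expect_equal(hs$receptor$strength[hs$receptor$rank == 1],
               sum(abs(glu_rows$e_total)), tolerance = 1e-9)
})

test_that("ranking is invariant to positive rescaling and thresholds are monotone", {
  m <- prepared_dimer(seed = 6)
  iface <- select_interface(m, "A", "B")
  ct <- enumerate_contacts(iface$receptor, iface$ligand, 4.5)
  hs <- aggregate_hotspots(ct)
  scaled <- ct
  scaled$e_total <- scaled$e_total * 3.7
  hs_scaled <- aggregate_hotspots(scaled)
  expect_equal(hs_scaled$receptor$residue_id, hs$receptor$residue_id)
  expect_equal(hs_scaled$receptor$rank, hs$receptor$rank)

  tight <- aggregate_hotspots(ct, hotspot_criteria("atom_pair",
                                                   distance_threshold = 3.5))
  loose <- aggregate_hotspots(ct, hotspot_criteria("atom_pair",
                                                   distance_threshold = 4.5))
  shared <- intersect(tight$receptor$residue_id, loose$receptor$residue_id)
  expect_true(all(
    loose$receptor$strength[match(shared, loose$receptor$residue_id)] >=
      tight$receptor$strength[match(shared, tight$receptor$residue_id)]))
  expect_true(all(tight$receptor$residue_id %in% loose$receptor$residue_id))
})

test_that("top_n truncates, nests, and breaks ties deterministically", {
  tab <- hotspot_table_from(setNames(c(5, 3, 2), canonical_key("A", "ALA", 1:3)))
  expect_equal(length(top_n(tab, 5)), 3)
  expect_equal(top_n(tab, 1), "A:ALA:1")
  expect_error(top_n(tab, 0), ">= 1")
  for (k in 1:2) expect_true(all(top_n(tab, k) %in% top_n(tab, k + 1)))
  tied <- hotspot_table_from(setNames(c(2, 2), c("A:ALA:9", "A:ALA:2")))
  expect_equal(top_n(tied, 1), "A:ALA:2")   # equal strength: lower resno wins
})

test_that("energy-weighted histogram reorders strengths by sequence position", {
  tab <- hotspot_table_from(setNames(c(1.5, 9, 4),
                                     c("A:ALA:30", "A:ALA:10", "A:ALA:20")))
  h <- energy_weighted_histogram(tab)
  expect_equal(h$residue_id, c("A:ALA:10", "A:ALA:20", "A:ALA:30"))
  expect_equal(h$strength, c(9, 4, 1.5))
  expect_equal(sum(h$strength), sum(tab$strength))
  expect_equal(nrow(energy_weighted_histogram(
    aggregate_hotspots(manual_contacts(numeric(0), numeric(0)))$receptor)), 0)
})

test_that("water and HETATM residues are excluded from aggregation", {
  ct <- manual_contacts(c(-2, -3), c(3, 3),
                        res_i = c("A:GLU:1", "A:HOH:99"),
                        res_j = c("B:LYS:1", "B:LYS:1"))
  hs <- aggregate_hotspots(ct)
  expect_equal(hs$receptor$residue_id, "A:GLU:1")
  expect_equal(hs$ligand$strength, 2)
  ct2 <- manual_contacts(-2, 3, res_i = "A:GTP:5")
  ct2$het_i <- TRUE
  expect_equal(nrow(aggregate_hotspots(ct2)$receptor), 0)
  expect_equal(nrow(aggregate_hotspots(ct2, include_hetero = TRUE)$receptor), 1)
})

test_that("hotspot engagement counts residues within the contact cutoff", {
  m <- prepared_dimer(seed = 8)
  expect_equal(hotspot_engagement(m, "B", "A:GLU:6", 4.5), 1)
  near_far <- hotspot_engagement(m, "B", c("A:GLU:6", "A:ALA:1"), 4.5)
  expect_equal(near_far, 1)
  far <- m
  far$atoms$x[far$atoms$chain_id == "B"] <-
    far$atoms$x[far$atoms$chain_id == "B"] + 100
  expect_equal(hotspot_engagement(far, "B", c("A:GLU:6", "A:ALA:1"), 4.5), 0)
  counts <- vapply(c(2, 4.5, 8, 20), function(cutoff)
    hotspot_engagement(m, "B", model_residues(m)$residue_id[1:12], cutoff),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(hotspot_engagement(m, "B", "A:TRP:99"), "absent")
})

test_that("hotspot tables round-trip through the CSV-with-header format", {
  m <- prepared_dimer(seed = 13)
  iface <- select_interface(m, "A", "B")
  hs <- aggregate_hotspots(enumerate_contacts(iface$receptor, iface$ligand))
  p <- tempfile(fileext = ".csv")
  write_hotspot_table(hs$receptor, p, dielectric = dielectric_model())
  back <- read_hotspot_table(p)
  expect_equal(back$residue_id, hs$receptor$residue_id)
  expect_equal(back$strength, hs$receptor$strength, tolerance = 1e-9)
  expect_equal(back$rank, hs$receptor$rank)
  expect_equal(attr(back, "side"), "receptor")
  expect_equal(attr(back, "criteria")$aggregation, "atom_pair")
})
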