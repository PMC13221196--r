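# Shared fixtures and independent oracles for the test suite.

# -- handwritten PDB fixtures -------------------------------------------------

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          record = "ATOM", icode = "", element = NULL) {
  if (is.null(element)) element <- substr(name, 1, 1)
  name_field <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %s %3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_field, resn, chain, resno,
          if (nzchar(icode)) icode else " ", x, y, z, 1, 0, element)
}

write_tiny_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

two_residue_pdb <- function() {
  write_tiny_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3, 0, 0)))
}

# a parameterized single-atom-per-position toy model built directly in code
toy_model <- function(df) {
  n <- nrow(df)
  defaults <- data.frame(
    serial = seq_len(n), name = "CA", element = "C", chain_id = "A",
    res_name = "ALA", res_seq = seq_len(n), icode = "", x = 0, y = 0, z = 0,
    is_hydrogen = FALSE, is_water = FALSE, is_hetatm = FALSE,
    charge = 0, sigma = 3.4, epsilon = 0.1, stringsAsFactors = FALSE)
  for (col in names(df)) defaults[[col]] <- df[[col]]
  structure_model(defaults, source = "toy")
}

# parameterized + folded heavy-atom dimer, the workhorse complex fixture
prepared_dimer <- function(seed = 1, separation = 10,
                           salt_bridges = list(c(6, 6)), n_residues = 12) {
  m <- make_helix_dimer(helix_dimer_spec(
    n_residues = n_residues, separation = separation,
    salt_bridges = salt_bridges, seed = seed))
  fold_hydrogen_charges(assign_parameters(m))
}

# -- independent energetics oracle (naive double loop, formulas inline) -------

brute_force_contacts <- function(receptor, ligand, cutoff, dielectric) {
  ra <- receptor$atoms
  la <- ligand$atoms
  rows <- list()
  k <- 0
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      r <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                  (ra$z[i] - la$z[j])^2)
      if (r <= cutoff) {
        sig <- (ra$sigma[i] + la$sigma[j]) / 2
        eps <- sqrt(ra$epsilon[i] * la$epsilon[j])
        e_lj <- 4 * eps * ((sig / r)^12 - (sig / r)^6)
        e_coul <- if (dielectric$mode == "vacuum") {
          332.0636 * ra$charge[i] * la$charge[j] / r
        } else {
          332.0636 * ra$charge[i] * la$charge[j] /
            (dielectric$screening_factor * r^2)
        }
        k <- k + 1
        rows[[k]] <- data.frame(atom_i = i, atom_j = j, distance = r,
                                e_lj = e_lj, e_coul = e_coul,
                                e_total = e_lj + e_coul)
      }
    }
  }
  if (!k) return(data.frame(atom_i = integer(), atom_j = integer(),
                            distance = numeric(), e_lj = numeric(),
                            e_coul = numeric(), e_total = numeric()))
  do.call(rbind, rows)
}

# -- exhaustive global-alignment oracle (recursive path enumeration) ----------

exhaustive_align_score <- function(seq_a, seq_b, sub, gap_open = 11,
                                   gap_extend = 1) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  n <- length(a)
  m <- length(b)
  rec <- function(i, j, state) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, sub[a[i], b[j]] + rec(i + 1, j + 1, "M"))
    if (i <= n) {
      cost <- if (state == "X") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j <= m) {
      cost <- if (state == "Y") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "start")
}

# -- rigid-body transforms ----------------------------------------------------

random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_out)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

# a strength-ranked hotspot table built directly from a named strength vector
hotspot_table_from <- function(strengths,
                               criteria = hotspot_criteria("residue_pair")) {
  plan <- setNames(as.vector(strengths), names(strengths))
  aggregate_hotspots(make_mock_contact_table(plan, seed = 1),
                     criteria)$receptor
}
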