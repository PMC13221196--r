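# Seeded generators for self-contained test inputs: toy two-chain helical
# complexes with engineered salt bridges, mock external contact tables, mock
# design-metrics tables, and mutated sequence ensembles.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# side-chain heavy-atom templates: distance of each atom from CA along the
# side-chain direction, plus a perpendicular split for branched tips (A).
SIDE_CHAIN_TEMPLATES <- list(
  ALA = data.frame(name = "CB", along = 1.53, perp = 0),
  SER = data.frame(name = c("CB", "OG"), along = c(1.53, 2.9), perp = 0),
  CYS = data.frame(name = c("CB", "SG"), along = c(1.53, 3.2), perp = 0),
  VAL = data.frame(name = c("CB", "CG1", "CG2"), along = c(1.53, 2.9, 2.9),
                   perp = c(0, 1.2, -1.2)),
  LEU = data.frame(name = c("CB", "CG", "CD1", "CD2"),
                   along = c(1.53, 2.9, 4.2, 4.2), perp = c(0, 0, 1.2, -1.2)),
  THR = data.frame(name = c("CB", "OG1", "CG2"), along = c(1.53, 2.9, 2.9),
                   perp = c(0, 1.2, -1.2)),
  ASP = data.frame(name = c("CB", "CG", "OD1", "OD2"),
                   along = c(1.53, 2.9, 4.0, 4.0), perp = c(0, 0, 1.1, -1.1)),
  ASN = data.frame(name = c("CB", "CG", "OD1", "ND2"),
                   along = c(1.53, 2.9, 4.0, 4.0), perp = c(0, 0, 1.1, -1.1)),
  GLU = data.frame(name = c("CB", "CG", "CD", "OE1", "OE2"),
                   along = c(1.53, 2.9, 4.3, 5.4, 5.4),
                   perp = c(0, 0, 0, 1.1, -1.1)),
  GLN = data.frame(name = c("CB", "CG", "CD", "OE1", "NE2"),
                   along = c(1.53, 2.9, 4.3, 5.4, 5.4),
                   perp = c(0, 0, 0, 1.1, -1.1)),
  LYS = data.frame(name = c("CB", "CG", "CD", "CE", "NZ"),
                   along = c(1.53, 2.9, 4.2, 5.4, 6.4), perp = 0),
  ARG = data.frame(name = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
                   along = c(1.53, 2.9, 4.2, 5.4, 6.6, 7.6, 7.6),
                   perp = c(0, 0, 0, 0, 0, 1.1, -1.1)),
  MET = data.frame(name = c("CB", "CG", "SD", "CE"),
                   along = c(1.53, 2.9, 4.5, 6.0), perp = 0),
  GLY = data.frame(name = character(), along = numeric(), perp = numeric()))

#' Specification for a synthetic two-helix dimer
#'
#' Defines a toy two-chain complex: two ideal alpha-helices (rise 1.5 A and
#' 100 degrees of twist per residue, 2.3 A Calpha radius) on parallel axes at
#' the requested separation, with idealized heavy-atom side chains and
#' optional engineered salt bridges whose side chains are oriented toward the
#' partner chain. Gaussian coordinate jitter (`jitter_sd`) emulates
#' coordinate noise; the seed makes the fixture bit-reproducible.
#'
#' @param n_residues residues per chain (default 12).
#' @param separation inter-axis separation, Angstrom (default 10).
#' @param sequence_a,sequence_b one-letter sequences; default poly-alanine of
#'   `n_residues`.
#' @param salt_bridges list of `c(pos_a, pos_b)` residue positions to mutate
#'   to an engineered GLU (chain A) / LYS (chain B) bridge.
#' @param seed mandatory RNG seed.
#' @param jitter_sd coordinate jitter standard deviation, Angstrom.
#' @return a `helix_dimer_spec` list.
#' @export
helix_dimer_spec <- function(n_residues = 12, separation = 10,
                             sequence_a = NULL, sequence_b = NULL,
                             salt_bridges = list(), seed = 1,
                             jitter_sd = 0.02) {
  if (separation <= 0) stop("separation must be > 0")
  if (is.null(sequence_a)) sequence_a <- strrep("A", n_residues)
  if (is.null(sequence_b)) sequence_b <- strrep("A", n_residues)
  if (nchar(sequence_a) != n_residues || nchar(sequence_b) != n_residues)
    stop("sequences must have n_residues letters")
  for (sb in salt_bridges)
    if (sb[1] < 1 || sb[1] > n_residues || sb[2] < 1 || sb[2] > n_residues)
      stop("salt bridge position out of bounds")
  structure(list(n_residues = n_residues, separation = separation,
                 sequence_a = sequence_a, sequence_b = sequence_b,
                 salt_bridges = salt_bridges, seed = seed,
                 jitter_sd = jitter_sd),
            class = "helix_dimer_spec")
}

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

# one ideal helix chain; returns an atom-table fragment
build_helix_chain <- function(seq3, chain_id, axis_y, phase0, toward,
                              bridge_pos) {
  rise <- 1.5
  twist <- 100 * pi / 180
  r_ca <- 2.3
  rows <- list()
  for (i in seq_along(seq3)) {
    th <- phase0 + (i - 1) * twist
    z <- (i - 1) * rise
    radial <- c(cos(th), sin(th), 0)
    ca <- c(0, axis_y, z) + r_ca * radial
    # plausible ideal-helix backbone placement around CA
    th_n <- th - 27 * pi / 180
    th_c <- th + 27 * pi / 180
    npos <- c(0, axis_y, z - 0.57) + 1.56 * c(cos(th_n), sin(th_n), 0)
    cpos <- c(0, axis_y, z + 0.57) + 2.00 * c(cos(th_c), sin(th_c), 0)
    opos <- cpos + c(0.40 * cos(th_c), 0.40 * sin(th_c), 1.15)
    res <- seq3[i]
    atoms <- rbind(N = npos, CA = ca, C = cpos, O = opos)
    tmpl <- SIDE_CHAIN_TEMPLATES[[res]]
    if (is.null(tmpl))
      stop("no side-chain template for residue ", res)
    if (nrow(tmpl)) {
      dir <- if (i %in% bridge_pos) c(0, toward, 0) else radial
      perp <- c(0, 0, 1)
      sc <- t(vapply(seq_len(nrow(tmpl)), function(k) {
        ca + tmpl$along[k] * dir + tmpl$perp[k] * perp
      }, numeric(3)))
      rownames(sc) <- tmpl$name
      atoms <- rbind(atoms, sc)
    }
    rows[[i]] <- data.frame(name = rownames(atoms), res_name = res,
                            res_seq = i, x = atoms[, 1], y = atoms[, 2],
                            z = atoms[, 3], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$chain_id <- chain_id
  out
}

#' Generate a synthetic two-helix dimer
#'
#' Builds the complex described by a [helix_dimer_spec()]: chain A on the
#' first axis, chain B on a parallel axis `separation` Angstrom away.
#' Engineered salt-bridge positions are mutated to GLU (chain A) and LYS
#' (chain B), their helices phased so the bridge Calphas face away from the
#' partner, and their side chains extended along the inter-chain direction,
#' which yields a well-formed (~2.5-3.5 A) carboxylate-ammonium contact at
#' the default separation. Deterministic for a fixed seed.
#'
#' @param spec a [helix_dimer_spec()].
#' @param path optional PDB output path.
#' @return a `structure_model` (written to `path` as PDB when given).
#' @export
make_helix_dimer <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "helix_dimer_spec"))
  to3 <- function(s, bridge, res3) {
    v <- AA1TO3[strsplit(s, "")[[1]]]
    if (anyNA(v)) stop("invalid residue code in sequence")
    v[bridge] <- res3
    unname(v)
  }
  pos_a <- vapply(spec$salt_bridges, `[`, 1, 1)
  pos_b <- vapply(spec$salt_bridges, `[`, 1, 2)
  seq_a3 <- to3(spec$sequence_a, pos_a, "GLU")
  seq_b3 <- to3(spec$sequence_b, pos_b, "LYS")
  twist <- 100 * pi / 180
  # phase the helices so the first bridge CA points away from the partner
  phase_a <- if (length(pos_a)) (-pi / 2) - (pos_a[1] - 1) * twist else 0
  phase_b <- if (length(pos_b)) (pi / 2) - (pos_b[1] - 1) * twist else pi
  ca <- build_helix_chain(seq_a3, "A", 0, phase_a, toward = 1,
                          bridge_pos = pos_a)
  cb <- build_helix_chain(seq_b3, "B", spec$separation, phase_b, toward = -1,
                          bridge_pos = pos_b)
  at <- rbind(ca, cb)
  at <- with_seed(spec$seed, {
    at$x <- at$x + rnorm(nrow(at), 0, spec$jitter_sd)
    at$y <- at$y + rnorm(nrow(at), 0, spec$jitter_sd)
    at$z <- at$z + rnorm(nrow(at), 0, spec$jitter_sd)
    at
  })
  # PDB-precision coordinates so written and in-memory fixtures agree
  at$x <- round(at$x, 3); at$y <- round(at$y, 3); at$z <- round(at$z, 3)
  atoms <- data.frame(
    serial = seq_len(nrow(at)), name = at$name,
    element = substr(at$name, 1, 1), chain_id = at$chain_id,
    res_name = at$res_name, res_seq = at$res_seq, icode = "",
    x = at$x, y = at$y, z = at$z, is_hydrogen = FALSE, is_water = FALSE,
    is_hetatm = FALSE, stringsAsFactors = FALSE)
  model <- structure_model(atoms, source = "synthetic helix dimer")
  if (!is.null(path)) write_structure(model, path)
  model
}

#' Generate a mock external contact table
#'
#' Emits residue-pair rows whose per-residue favorable-energy sums recover a
#' planned hotspot-strength profile (exactly at zero noise), emulating an
#' external contact/energy export for benchmarking round-trips. Each planned
#' residue contacts a distinct partner residue on the opposite chain at 3.0 A
#' with energy `-(strength) + noise`, so the default residue-pair criteria
#' qualify every row (plan strengths should be >= 1).
#'
#' @param plan named numeric vector: canonical residue id -> target strength
#'   (kcal/mol, >= 0).
#' @param noise_sd Gaussian energy noise, kcal/mol.
#' @param seed RNG seed.
#' @param partner_chain chain label for the generated partner residues.
#' @return a `residue_pair_table`.
#' @export
make_mock_contact_table <- function(plan, noise_sd = 0, seed = 1,
                                    partner_chain = "B") {
  if (!length(plan)) {
    return(structure(
      data.frame(residue_i = character(), residue_j = character(),
                 min_distance = numeric(), mean_distance = numeric(),
                 sum_e_total = numeric(), n_atom_pairs = integer(),
                 het_i = logical(), het_j = logical(),
                 stringsAsFactors = FALSE),
      class = c("residue_pair_table", "data.frame")))
  }
  if (any(plan < 0)) stop("plan strengths must be >= 0")
  noise <- with_seed(seed, rnorm(length(plan), 0, noise_sd))
  out <- data.frame(
    residue_i = names(plan),
    residue_j = canonical_key(partner_chain, "LYS", seq_along(plan)),
    min_distance = 3.0, mean_distance = 3.0,
    sum_e_total = -as.vector(plan) + noise,
    n_atom_pairs = 1L, het_i = FALSE, het_j = FALSE,
    stringsAsFactors = FALSE)
  structure(out, class = c("residue_pair_table", "data.frame"))
}

#' Generate a mutated design-sequence ensemble
#'
#' Starting from a consensus, each non-conserved position of each design is
#' mutated with probability `mutation_rate` to a uniformly chosen different
#' residue; conserved positions are never touched (entropy exactly zero by
#' construction, emulating the minimal variability of interface positions in
#' design ensembles).
#'
#' @param consensus consensus amino-acid sequence.
#' @param n_designs number of sequences.
#' @param mutation_rate per-site mutation probability in `[0, 1]`.
#' @param conserved integer positions never mutated.
#' @param seed RNG seed.
#' @param path optional FASTA output path.
#' @return named character vector of sequences (`design_001`, ...).
#' @export
make_sequence_ensemble <- function(consensus, n_designs, mutation_rate,
                                   conserved = integer(0), seed = 1,
                                   path = NULL) {
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  L <- nchar(consensus)
  if (length(conserved) && (min(conserved) < 1 || max(conserved) > L))
    stop("conserved positions out of bounds")
  cons <- strsplit(consensus, "")[[1]]
  free <- setdiff(seq_len(L), conserved)
  seqs <- with_seed(seed, {
    vapply(seq_len(n_designs), function(i) {
      s <- cons
      if (length(free) && mutation_rate > 0) {
        hit <- free[runif(length(free)) < mutation_rate]
        for (p in hit) s[p] <- sample(setdiff(AA20, s[p]), 1)
      }
      paste(s, collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("design_%03d", seq_len(n_designs))
  if (!is.null(path)) write_fasta(seqs, path)
  seqs
}

#' Generate a mock design-metrics table
#'
#' Builds `n_rows` design metrics rows of which exactly
#' `round(n_rows * fraction_passing)` satisfy the confidence thresholds
#' (mean pLDDT >= 80 AND iPAE <= 15); one passing row sits exactly on both
#' boundaries so inclusive threshold semantics are exercised. Rows are
#' shuffled deterministically under the seed.
#'
#' @param n_rows number of designs.
#' @param fraction_passing fraction in `[0, 1]` meeting the thresholds.
#' @param seed RNG seed.
#' @return design metrics data.frame (see [read_design_metrics()]).
#' @export
make_mock_metrics <- function(n_rows, fraction_passing, seed = 1) {
  if (fraction_passing < 0 || fraction_passing > 1)
    stop("fraction_passing must be in [0, 1]")
  n_pass <- round(n_rows * fraction_passing)
  with_seed(seed, {
    plddt <- c(runif(n_pass, 80.5, 97), runif(n_rows - n_pass, 40, 79.9))
    ipae <- c(runif(n_pass, 1, 14.5), runif(n_rows - n_pass, 15.2, 40))
    if (n_pass >= 1) { plddt[1] <- 80; ipae[1] <- 15 }
    # some failing rows fail on one criterion only
    n_fail <- n_rows - n_pass
    if (n_fail >= 2) {
      plddt[n_pass + 1] <- runif(1, 80, 95)   # fails on ipae only
      ipae[n_pass + 2] <- runif(1, 1, 15)     # fails on plddt only
    }
    L <- 60L
    seqs <- vapply(seq_len(n_rows), function(i)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
    df <- data.frame(
      design_id = sprintf("design_%03d", seq_len(n_rows)), length = L,
      sequence = seqs, mean_plddt = plddt, ipae = ipae,
      binder_rmsd = runif(n_rows, 0.5, 25),
      n_interface_residues = sample(5:30, n_rows, replace = TRUE),
      hotspot_engagement = sample(0:10, n_rows, replace = TRUE),
      helicity = runif(n_rows), mpnn_score = runif(n_rows, -3, 0),
      stringsAsFactors = FALSE)
    df <- df[sample(n_rows), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}
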