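#' @importFrom stats cor lm coef rnorm runif setNames aggregate sd
#' @importFrom utils read.csv write.csv head data
NULL

WATER_NAMES <- c("HOH", "WAT")

#' Atomic structure model
#'
#' A light container for one model of a protein complex: an atom table in file
#' order plus provenance. Coordinates are in Angstrom; residue numbering is
#' taken verbatim from the source (no renumbering), so literature residue
#' labels such as Glu957 are preserved. Nonbonded parameter columns
#' (`charge`, `sigma`, `epsilon`) are `NA` until [assign_parameters()] runs.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `chain_id`, `res_name`, `res_seq`, `icode`, `x`, `y`, `z`,
#'   `is_hydrogen`, `is_water`, `is_hetatm`, `charge`, `sigma`, `epsilon`.
#' @param source free-text provenance (file path or identifier).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, source = "") {
  needed <- c("serial", "name", "element", "chain_id", "res_name", "res_seq",
              "icode", "x", "y", "z", "is_hydrogen", "is_water", "is_hetatm")
  missing <- setdiff(needed, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  for (col in c("charge", "sigma", "epsilon"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (nrow(atoms) && !all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure_model: %d atoms, %d residues, chains [%s]%s\n",
              nrow(a), length(unique(residue_uid(a))),
              paste(unique(a$chain_id), collapse = ","),
              if (nzchar(x$source)) paste0(" (", x$source, ")") else ""))
  invisible(x)
}

#' Number of atoms in a structure model
#' @param model a `structure_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

# internal: unique residue id per atom, in file order
residue_uid <- function(atoms) {
  canonical_key(atoms$chain_id, atoms$res_name, atoms$res_seq, atoms$icode)
}

#' Canonical residue keys
#'
#' Formats residue identity as the canonical string `"chain:resname:resseq"`
#' (with a trailing insertion code when present, e.g. `"B:HIS:260A"`), the
#' label used in all CSV exports and cross-method comparisons.
#'
#' @param chain_id,res_name,res_seq,icode vectors of residue fields; `icode`
#'   may be `""`/`NA` for none.
#' @return character vector of canonical keys.
#' @seealso [parse_residue_key()] for the inverse.
#' @export
canonical_key <- function(chain_id, res_name, res_seq, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  sprintf("%s:%s:%d%s", chain_id, res_name, as.integer(res_seq), icode)
}

#' Parse canonical residue keys
#'
#' Inverse of [canonical_key()]; round-trips exactly.
#'
#' @param keys character vector of canonical keys.
#' @return data.frame with columns `chain_id`, `res_name`, `res_seq`, `icode`.
#' @export
parse_residue_key <- function(keys) {
  m <- regmatches(keys, regexec("^([^:]+):([^:]+):(-?[0-9]+)([A-Za-z]?)$", keys))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop("unparseable residue key: ", paste(keys[bad], collapse = ", "))
  data.frame(chain_id = vapply(m, `[`, "", 2L),
             res_name = vapply(m, `[`, "", 3L),
             res_seq = as.integer(vapply(m, `[`, "", 4L)),
             icode = vapply(m, `[`, "", 5L),
             stringsAsFactors = FALSE)
}

# internal: element from a PDB atom name when the element column is blank
infer_element <- function(name) {
  stripped <- sub("^[0-9']+", "", name)
  first <- substr(stripped, 1, 1)
  two <- substr(stripped, 1, 2)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA") &
           nchar(name) == 2 & !grepl("[0-9]", name), two, first)
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records of one MODEL block into a [structure_model()].
#' Alternate locations are resolved by keeping altloc `''`/`'A'` only.
#' Waters (`HOH`/`WAT`) are retained but flagged so downstream aggregation can
#' exclude them.
#'
#' @param path PDB file path.
#' @param model_index 1-based MODEL block to read (default first).
#' @return a `structure_model`.
#' @export
load_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = model_index > 1L,
                                     verbose = FALSE)),
    error = function(e) stop("no ATOM/HETATM records parsed from ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("no ATOM/HETATM records parsed from ", path)
  xyz <- if (model_index > 1L) {
    if (nrow(pdb$xyz) < model_index)
      stop("model_index ", model_index, " exceeds the ", nrow(pdb$xyz),
           " MODEL blocks in ", path)
    matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  } else {
    cbind(at$x, at$y, at$z)
  }
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                infer_element(at$elety), at$elesy)))
  chain <- ifelse(is.na(at$chain) | at$chain == "", " ", at$chain)
  icode <- ifelse(is.na(at$insert), "", at$insert)
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = elem, chain_id = chain,
    res_name = at$resid, res_seq = at$resno, icode = icode,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_hydrogen = elem == "H",
    is_water = at$resid %in% WATER_NAMES,
    is_hetatm = at$type == "HETATM",
    stringsAsFactors = FALSE)
  structure_model(atoms, source = path)
}

#' Write a structure model to PDB
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  if (!nrow(a)) stop("refusing to write an empty structure")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[c("x", "y", "z")]))),
                   type = ifelse(a$is_hetatm, "HETATM", "ATOM"),
                   resno = a$res_seq, resid = a$res_name, eleno = a$serial,
                   elety = a$name, chain = a$chain_id,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Remove water residues
#'
#' Drops all `HOH`/`WAT` residues, preserving the order of everything else.
#' Idempotent. Warns (and returns an empty model) if only waters were present.
#'
#' @param model a `structure_model`.
#' @return a `structure_model` without waters.
#' @export
strip_waters <- function(model) {
  keep <- !model$atoms$is_water
  if (!any(keep) && nrow(model$atoms))
    warning("structure contained only water residues; returning empty model")
  structure_model(model$atoms[keep, , drop = FALSE], source = model$source)
}

#' Split a complex into receptor and ligand atom sets
#'
#' Partitions the model by chain label; atoms on chains in neither set are
#' excluded. The two chain sets must be non-empty and disjoint.
#'
#' @param model a `structure_model`.
#' @param receptor_chains,ligand_chains character vectors of chain labels.
#' @return list with `structure_model` elements `receptor` and `ligand`.
#' @export
select_interface <- function(model, receptor_chains, ligand_chains) {
  if (!length(receptor_chains) || !length(ligand_chains))
    stop("receptor and ligand chain sets must be non-empty")
  if (length(intersect(receptor_chains, ligand_chains)))
    stop("receptor and ligand chain sets overlap: ",
         paste(intersect(receptor_chains, ligand_chains), collapse = ","))
  have <- unique(model$atoms$chain_id)
  unknown <- setdiff(c(receptor_chains, ligand_chains), have)
  if (length(unknown))
    stop("chain(s) ", paste(unknown, collapse = ","),
         " not in model; available chains: ", paste(have, collapse = ","))
  pick <- function(chains)
    structure_model(model$atoms[model$atoms$chain_id %in% chains, ,
                                drop = FALSE], source = model$source)
  list(receptor = pick(receptor_chains), ligand = pick(ligand_chains))
}

#' Residues of a structure model
#'
#' @param model a `structure_model`.
#' @return data.frame (one row per residue, file order) with the residue
#'   fields, canonical `residue_id`, and `is_water`/`is_hetatm` flags.
#' @export
model_residues <- function(model) {
  a <- model$atoms
  uid <- residue_uid(a)
  first <- !duplicated(uid)
  data.frame(residue_id = uid[first], chain_id = a$chain_id[first],
             res_name = a$res_name[first], res_seq = a$res_seq[first],
             icode = a$icode[first], is_water = a$is_water[first],
             is_hetatm = a$is_hetatm[first], stringsAsFactors = FALSE)
}
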