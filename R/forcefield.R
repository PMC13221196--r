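# Embedded nonbonded parameter subset and assignment onto structure models.
#
# The shipped table carries the Amber ff94/ff99 partial charges retained by
# ff14SB for the 20 canonical residues (histidine as the HIE/HID/HIP
# tautomers, HIE the pH-7 default) together with Amber Lennard-Jones well
# parameters, expressed as sigma (A) / epsilon (kcal/mol). Combination rule is
# Lorentz-Berthelot throughout. Terminal-variant charge sets are not shipped;
# chain-terminal residues fall back to the internal template with a warning.

.hf_env <- new.env(parent = emptyenv())

#' Load a nonbonded parameter set
#'
#' Reads a parameter table (columns `res_name`, `atom_name`, `charge_e`,
#' `sigma_A`, `epsilon_kcal_mol`, `bonded_heavy_atom`) into a `parameter_set`.
#' With `path = NULL` the embedded ff14SB-derived subset is returned (cached).
#'
#' @param path CSV path, or `NULL` for the shipped table.
#' @return A `parameter_set`: list with `table`, `name`, `combination_rule`.
#' @export
read_parameter_set <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.hf_env$default_params)) return(.hf_env$default_params)
    path <- system.file("extdata", "ff14sb_subset.csv", package = "hotforge")
    cache <- TRUE
  } else cache <- FALSE
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$bonded_heavy_atom[is.na(tab$bonded_heavy_atom)] <- ""
  if (any(tab$sigma_A <= 0) || any(tab$epsilon_kcal_mol < 0))
    stop("invalid LJ parameters in ", path)
  ps <- structure(list(table = tab, name = "ff14SB-subset",
                       combination_rule = "lorentz_berthelot"),
                  class = "parameter_set")
  if (cache) .hf_env$default_params <- ps
  ps
}

#' @rdname read_parameter_set
#' @export
default_parameter_set <- function() read_parameter_set(NULL)

#' Residue templates known to a parameter set
#' @param params a `parameter_set`.
#' @return character vector of template residue names.
#' @export
template_residues <- function(params) unique(params$table$res_name)

# internal: template residue name for a structure residue name (HIS -> HIE)
template_for <- function(res_name) ifelse(res_name == "HIS", "HIE", res_name)

#' Assign per-atom nonbonded parameters
#'
#' Looks up partial charge, LJ sigma and epsilon for every atom by
#' (residue template, atom name). Histidine (`HIS`) uses the neutral HIE
#' tautomer template. Atoms absent from the table (nonstandard residues,
#' terminal `OXT`/`H1`-`H3`, waters left in the model) are handled per
#' `on_missing`: `"error"` aborts naming the atom, `"zero_and_warn"` assigns
#' inert parameters (charge 0, epsilon 0) with one summary warning.
#'
#' @param model a `structure_model`.
#' @param params a `parameter_set` (default: the shipped subset).
#' @param on_missing `"error"` or `"zero_and_warn"`.
#' @return the model with `charge`, `sigma`, `epsilon` populated.
#' @export
assign_parameters <- function(model, params = default_parameter_set(),
                              on_missing = c("error", "zero_and_warn")) {
  on_missing <- match.arg(on_missing)
  a <- model$atoms
  tab <- params$table
  key <- paste(template_for(a$res_name), a$name, sep = "|")
  tkey <- paste(tab$res_name, tab$atom_name, sep = "|")
  idx <- match(key, tkey)
  miss <- is.na(idx)
  if (any(miss)) {
    labels <- unique(paste0(a$res_name[miss], "/", a$name[miss]))
    if (on_missing == "error")
      stop("no nonbonded parameters for atom(s): ",
           paste(labels, collapse = ", "))
    warning("assigned zero charge/epsilon to ", sum(miss),
            " atom(s) without parameters: ", paste(labels, collapse = ", "))
  }
  if (any(a$name == "OXT"))
    warning("terminal OXT present; terminal charge variants are not shipped, ",
            "internal residue templates were used")
  a$charge <- ifelse(miss, 0, tab$charge_e[idx])
  a$sigma <- ifelse(miss, 1, tab$sigma_A[idx])
  a$epsilon <- ifelse(miss, 0, tab$epsilon_kcal_mol[idx])
  structure_model(a, source = model$source)
}

#' Fold hydrogen charges onto bonded heavy atoms
#'
#' For heavy-atom-only structures: every hydrogen listed in a residue's
#' parameter template but absent from the coordinates has its partial charge
#' added to its canonical bonded heavy atom (bonding defined by the template),
#' so per-residue net charge is unchanged while hydrogen LJ terms drop out.
#' Hydrogens that *are* present keep their own charges and are left in place
#' unless `strip_existing = TRUE`, in which case their assigned charges are
#' folded the same way and the atoms removed. Either way every residue ends
#' at its full-template net charge, so the total system charge equals the sum
#' of residue formal charges; folding an already-folded model is a no-op.
#'
#' @param model a parameterized `structure_model` (see [assign_parameters()]).
#' @param params the `parameter_set` used for assignment.
#' @param strip_existing also fold and remove hydrogens present in the
#'   coordinates (default `FALSE`).
#' @return a `structure_model` whose heavy atoms carry the folded charges.
#' @export
fold_hydrogen_charges <- function(model, params = default_parameter_set(),
                                  strip_existing = FALSE) {
  if (isTRUE(model$hydrogens_folded)) return(model)   # idempotent
  a <- model$atoms
  if (anyNA(a$charge)) stop("assign_parameters() must run before folding")
  tab <- params$table
  htab <- tab[tab$bonded_heavy_atom != "", ]
  uid <- residue_uid(a)
  for (res in unique(uid)) {
    rows <- which(uid == res)
    tmpl <- template_for(a$res_name[rows[1]])
    hrows <- htab[htab$res_name == tmpl, ]
    if (!nrow(hrows)) next
    absent <- !(hrows$atom_name %in% a$name[rows])
    for (k in which(absent)) {
      tgt <- rows[a$name[rows] == hrows$bonded_heavy_atom[k]]
      if (length(tgt) == 1)
        a$charge[tgt] <- a$charge[tgt] + hrows$charge_e[k]
    }
    if (strip_existing) {
      present <- rows[a$is_hydrogen[rows]]
      for (p in present) {
        bh <- hrows$bonded_heavy_atom[match(a$name[p], hrows$atom_name)]
        tgt <- rows[a$name[rows] == bh]
        if (!is.na(bh) && length(tgt) == 1)
          a$charge[tgt] <- a$charge[tgt] + a$charge[p]
      }
    }
  }
  if (strip_existing) a <- a[!a$is_hydrogen, , drop = FALSE]
  out <- structure_model(a, source = model$source)
  out$hydrogens_folded <- TRUE
  out
}
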