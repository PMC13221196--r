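# Residue-level hotspot aggregation, ranking, Top-N selection and
# hotspot-engagement counting.

#' Hotspot qualification criteria
#'
#' Two favorable-contact definitions are first-class:
#' * `atom_pair` (default): an atom pair qualifies iff its total nonbonded
#'   energy is strictly below `energy_threshold` (default 0, i.e. any
#'   favorable pair) at a separation `<= distance_threshold` (default 4.5 A).
#' * `residue_pair`: a residue pair qualifies iff its summed energy is
#'   `<= energy_threshold` (default -1.0 kcal/mol, inclusive) with at least
#'   one interatomic distance `<= distance_threshold` (default 3.5 A).
#'
#' @param aggregation `"atom_pair"` or `"residue_pair"`.
#' @param energy_threshold kcal/mol; `NULL` for the mode default.
#' @param distance_threshold Angstrom; `NULL` for the mode default.
#' @return a `hotspot_criteria` list.
#' @export
hotspot_criteria <- function(aggregation = c("atom_pair", "residue_pair"),
                             energy_threshold = NULL,
                             distance_threshold = NULL) {
  aggregation <- match.arg(aggregation)
  if (is.null(energy_threshold))
    energy_threshold <- if (aggregation == "atom_pair") 0 else -1.0
  if (is.null(distance_threshold))
    distance_threshold <- if (aggregation == "atom_pair") 4.5 else 3.5
  if (distance_threshold <= 0) stop("distance_threshold must be > 0")
  structure(list(aggregation = aggregation,
                 energy_threshold = energy_threshold,
                 distance_threshold = distance_threshold),
            class = "hotspot_criteria")
}

# internal: rank with the documented tie-break
rank_hotspots <- function(df) {
  if (!nrow(df)) { df$rank <- integer(); return(df) }
  k <- parse_residue_key(df$residue_id)
  ord <- order(-df$strength, k$chain_id, k$res_seq, k$icode)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

hotspot_table <- function(df, side, criteria) {
  structure(rank_hotspots(df), class = c("hotspot_table", "data.frame"),
            side = side, criteria = criteria)
}

#' Aggregate contacts into per-residue hotspot strengths
#'
#' Each qualifying contribution (see [hotspot_criteria()]) adds the magnitude
#' of its (negative) energy to one receptor residue and one ligand residue, so
#' total strength on the two sides is identical. Strength is the cumulative
#' magnitude of favorable interaction energies; residues are ranked by
#' descending strength (ties: chain, then residue number). Water residues are
#' always excluded; other HETATM residues are excluded unless
#' `include_hetero = TRUE`.
#'
#' @param x a `contact_table` (either mode) or `residue_pair_table`
#'   (residue_pair mode only).
#' @param criteria a [hotspot_criteria()].
#' @param include_hetero also aggregate non-water HETATM residues.
#' @return list of two `hotspot_table`s (`receptor`, `ligand`), columns
#'   `residue_id`, `strength`, `n_favorable`, `rank`.
#' @export
aggregate_hotspots <- function(x, criteria = hotspot_criteria(),
                               include_hetero = FALSE) {
  is_contacts <- "e_total" %in% names(x) && "distance" %in% names(x)
  if (criteria$aggregation == "atom_pair") {
    if (!is_contacts)
      stop("atom_pair aggregation needs an atom-level contact_table")
    qual <- x[x$e_total < criteria$energy_threshold &
                x$distance <= criteria$distance_threshold, , drop = FALSE]
    energy <- qual$e_total
  } else {
    rp <- if (is_contacts) residue_pair_table(x) else x
    qual <- rp[rp$sum_e_total <= criteria$energy_threshold &
                 rp$min_distance <= criteria$distance_threshold, ,
               drop = FALSE]
    energy <- qual$sum_e_total
  }
  drop_res <- function(ids, het) {
    rn <- parse_residue_key(ids)$res_name
    rn %in% WATER_NAMES | (!include_hetero & het)
  }
  if (nrow(qual)) {
    het_i <- if (is.null(qual$het_i)) rep(FALSE, nrow(qual)) else qual$het_i
    het_j <- if (is.null(qual$het_j)) rep(FALSE, nrow(qual)) else qual$het_j
    keep <- !drop_res(qual$residue_i, het_i) & !drop_res(qual$residue_j, het_j)
    qual <- qual[keep, , drop = FALSE]
    energy <- energy[keep]
  }
  one_side <- function(ids) {
    if (!length(ids))
      return(data.frame(residue_id = character(), strength = numeric(),
                        n_favorable = integer(), stringsAsFactors = FALSE))
    s <- tapply(abs(energy), ids, sum)
    n <- tapply(energy, ids, length)
    data.frame(residue_id = names(s), strength = as.vector(s),
               n_favorable = as.vector(n), stringsAsFactors = FALSE)
  }
  list(receptor = hotspot_table(one_side(qual$residue_i), "receptor", criteria),
       ligand = hotspot_table(one_side(qual$residue_j), "ligand", criteria))
}

#' Top-N hotspot residues
#'
#' @param table a `hotspot_table`.
#' @param n number of residues (>= 1); fewer are returned if the table is
#'   shorter. Deterministic under ties via the table's total rank order.
#' @return character vector of canonical residue ids, strongest first.
#' @export
top_n <- function(table, n) {
  if (n < 1) stop("n must be >= 1")
  head(table$residue_id[order(table$rank)], n)
}

#' Energy-weighted hotspot bar series
#'
#' Per-residue bars of cumulative favorable-energy magnitude (Sum |E_neg|),
#' ordered by chain and residue sequence position for plotting.
#'
#' @param table a `hotspot_table`.
#' @return data.frame with `residue_id` and `strength`.
#' @export
energy_weighted_histogram <- function(table) {
  if (!nrow(table))
    return(data.frame(residue_id = character(), strength = numeric()))
  k <- parse_residue_key(table$residue_id)
  ord <- order(k$chain_id, k$res_seq, k$icode)
  data.frame(residue_id = table$residue_id[ord],
             strength = table$strength[ord], stringsAsFactors = FALSE)
}

#' Count hotspot residues engaged by a binder
#'
#' A listed target hotspot residue counts as engaged when at least one of its
#' heavy atoms lies within `contact_cutoff` of any heavy atom on the binder
#' chains.
#'
#' @param model a `structure_model` holding binder and target chains.
#' @param binder_chains chain labels of the candidate binder.
#' @param hotspot_residues canonical residue ids on the target.
#' @param contact_cutoff Angstrom (default 4.5).
#' @return integer count in `[0, length(hotspot_residues)]`.
#' @export
hotspot_engagement <- function(model, binder_chains, hotspot_residues,
                               contact_cutoff = 4.5) {
  a <- model$atoms
  uid <- residue_uid(a)
  missing <- setdiff(hotspot_residues, uid)
  if (length(missing))
    stop("hotspot residue(s) absent from model: ",
         paste(missing, collapse = ", "))
  bx <- as.matrix(a[a$chain_id %in% binder_chains & !a$is_hydrogen,
                    c("x", "y", "z"), drop = FALSE])
  if (!nrow(bx)) stop("no binder heavy atoms on chains ",
                      paste(binder_chains, collapse = ","))
  engaged <- vapply(hotspot_residues, function(res) {
    tx <- as.matrix(a[uid == res & !a$is_hydrogen, c("x", "y", "z"),
                      drop = FALSE])
    d2 <- outer(rowSums(tx^2), rowSums(bx^2), "+") - 2 * tcrossprod(tx, bx)
    min(sqrt(pmax(d2, 0))) <= contact_cutoff
  }, logical(1))
  sum(engaged)
}

#' Write a hotspot table (CSV with a JSON provenance header)
#'
#' The header block records the qualification criteria and side as `#`-prefixed
#' JSON lines; [read_hotspot_table()] restores them.
#'
#' @param table a `hotspot_table`.
#' @param path output path.
#' @param dielectric optional [dielectric_model()] to record.
#' @return `path`, invisibly.
#' @export
write_hotspot_table <- function(table, path, dielectric = NULL) {
  crit <- attr(table, "criteria")
  hdr <- list(side = attr(table, "side"),
              aggregation = crit$aggregation,
              energy_threshold = crit$energy_threshold,
              distance_threshold = crit$distance_threshold)
  if (!is.null(dielectric))
    hdr$dielectric <- list(mode = dielectric$mode,
                           screening_factor = dielectric$screening_factor)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(hdr, auto_unbox = TRUE)), con)
  out <- data.frame(residue_id = table$residue_id,
                    side = attr(table, "side"),
                    strength_kcal_mol = table$strength,
                    n_favorable = table$n_favorable, rank = table$rank)
  write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read a hotspot table written by [write_hotspot_table()]
#'
#' @param path file path.
#' @return a `hotspot_table`.
#' @export
read_hotspot_table <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines)
  hdr <- jsonlite::fromJSON(sub("^#\\s*", "", lines[hdr_lines[1]]))
  df <- read.csv(text = lines[-hdr_lines], stringsAsFactors = FALSE)
  crit <- hotspot_criteria(hdr$aggregation, hdr$energy_threshold,
                           hdr$distance_threshold)
  hotspot_table(data.frame(residue_id = df$residue_id,
                           strength = df$strength_kcal_mol,
                           n_favorable = df$n_favorable,
                           stringsAsFactors = FALSE),
                side = hdr$side, criteria = crit)
}
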