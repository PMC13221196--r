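# Chain-aware Calpha contact cartography: distance matrices,
# reciprocal-distance (100/d) maps and binary (<= cutoff) contact matrices.

#' Build chain-aware Calpha contact maps
#'
#' Collects the Calpha atoms of the named chains (in the given chain order,
#' file order within a chain), then computes the Calpha-Calpha distance
#' matrix, the reciprocal-distance map `100/d` (diagonal and any d < 1e-6 A
#' masked as `NA` to keep exports finite) and the binary contact matrix
#' `d <= cutoff` (inclusive). Residues without a Calpha (e.g. HETATM ligands)
#' are dropped with a warning.
#'
#' @param model a `structure_model`.
#' @param chains ordered chain labels to include.
#' @param cutoff binary-contact threshold, Angstrom (default 8).
#' @return a `contact_map_set`: list with `labels` (canonical residue ids),
#'   `chain_id`, `distance`, `reciprocal`, `binary`, `cutoff` and
#'   `chain_boundaries` (first/last matrix index per chain).
#' @export
build_contact_maps <- function(model, chains, cutoff = 8) {
  a <- model$atoms
  unknown <- setdiff(chains, unique(a$chain_id))
  if (length(unknown))
    stop("chain(s) not in model: ", paste(unknown, collapse = ","))
  keep <- list()
  for (ch in chains) {
    sub <- a[a$chain_id == ch, , drop = FALSE]
    uid <- residue_uid(sub)
    res_order <- unique(uid)
    ca <- sub[sub$name == "CA" & !sub$is_hydrogen, , drop = FALSE]
    ca <- ca[match(intersect(res_order, residue_uid(ca)), residue_uid(ca)), ,
             drop = FALSE]
    skipped <- setdiff(res_order, residue_uid(ca))
    if (length(skipped))
      warning("chain ", ch, ": ", length(skipped),
              " residue(s) without a Calpha skipped: ",
              paste(skipped, collapse = ", "))
    keep[[ch]] <- ca
  }
  ca <- do.call(rbind, keep)
  if (is.null(ca) || !nrow(ca)) stop("no Calpha atoms found in chains ",
                                     paste(chains, collapse = ","))
  labels <- residue_uid(ca)
  d <- as.matrix(stats::dist(as.matrix(ca[c("x", "y", "z")])))
  dimnames(d) <- list(labels, labels)
  recip <- 100 / d
  recip[d < 1e-6] <- NA
  diag(recip) <- NA
  binary <- (d <= cutoff) * 1L
  dimnames(recip) <- dimnames(binary) <- dimnames(d)
  n_per <- vapply(keep, nrow, 1L)
  ends <- cumsum(n_per)
  boundaries <- data.frame(chain_id = names(keep),
                           first = c(1L, head(ends, -1) + 1L), last = ends,
                           stringsAsFactors = FALSE)
  structure(list(labels = labels, chain_id = ca$chain_id, distance = d,
                 reciprocal = recip, binary = binary, cutoff = cutoff,
                 chain_boundaries = boundaries),
            class = "contact_map_set")
}

#' @export
print.contact_map_set <- function(x, ...) {
  cat(sprintf("contact_map_set: %d residues, chains [%s], cutoff %.1f A\n",
              length(x$labels),
              paste(x$chain_boundaries$chain_id, collapse = ","), x$cutoff))
  invisible(x)
}

#' Inter-chain block of a contact map set
#'
#' Rectangular submatrices restricted to `chain_a` rows by `chain_b` columns
#' of each map, for slicing the inter-chain interface out of a complex.
#'
#' @param maps a `contact_map_set`.
#' @param chain_a,chain_b chain labels present in the maps.
#' @return list with `distance`, `reciprocal`, `binary` blocks.
#' @export
interchain_block <- function(maps, chain_a, chain_b) {
  for (ch in c(chain_a, chain_b))
    if (!ch %in% maps$chain_id)
      stop("chain ", ch, " not present in contact maps")
  i <- maps$chain_id == chain_a
  j <- maps$chain_id == chain_b
  list(distance = maps$distance[i, j, drop = FALSE],
       reciprocal = maps$reciprocal[i, j, drop = FALSE],
       binary = maps$binary[i, j, drop = FALSE])
}

#' Export contact maps as dense CSV matrices
#'
#' Writes `<prefix>distance.csv`, `<prefix>reciprocal.csv` and
#' `<prefix>binary.csv`, each with residue-id header row and column.
#'
#' @param maps a `contact_map_set`.
#' @param prefix output path prefix.
#' @return the three paths, invisibly.
#' @export
write_contact_maps <- function(maps, prefix) {
  paths <- paste0(prefix, c("distance", "reciprocal", "binary"), ".csv")
  write.csv(maps$distance, paths[1])
  write.csv(maps$reciprocal, paths[2])
  write.csv(maps$binary, paths[3])
  invisible(paths)
}

#' Quick image rendering of one contact map
#'
#' Minimal base-graphics heatmap helper (publication styling is out of scope).
#'
#' @param maps a `contact_map_set`.
#' @param which `"distance"`, `"reciprocal"` or `"binary"`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot_contact_map <- function(maps, which = c("distance", "reciprocal",
                                             "binary"), ...) {
  which <- match.arg(which)
  m <- maps[[which]]
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  xlab = "residue index", ylab = "residue index",
                  main = paste("Calpha", which, "map"), ...)
  invisible(m)
}
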