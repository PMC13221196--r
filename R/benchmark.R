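# Concordance benchmarking of two per-residue hotspot rankings, plus
# ingestion of external residue-pair contact/energy tables (MOE-style
# Protein Contacts exports).

#' External contact-table dialect
#'
#' Column mapping and residue-label syntax for an external residue-pair
#' export. The shipped default emulates a MOE Protein Contacts table with
#' columns `residue_1`, `residue_2`, `distance_A`, `energy_kcal_mol` and
#' labels of the form `"GLU 957 (A)"` (name, number, optional insertion code,
#' chain in parentheses). Export headers vary between program versions, so
#' every element is overridable, or a whole dialect can be loaded from JSON.
#'
#' @param columns named character vector mapping the roles `residue_i`,
#'   `residue_j`, `distance`, `energy` to column names.
#' @param label_pattern regex with four capture groups: residue name, residue
#'   number, insertion code (may match empty) and chain.
#' @return a `contact_dialect` list.
#' @export
moe_dialect <- function(columns = c(residue_i = "residue_1",
                                    residue_j = "residue_2",
                                    distance = "distance_A",
                                    energy = "energy_kcal_mol"),
                        label_pattern = paste0(
                          "^\\s*([A-Z0-9]{1,3})\\s+(-?[0-9]+)",
                          "([A-Za-z]?)\\s*\\(([^)]+)\\)\\s*$")) {
  structure(list(columns = columns, label_pattern = label_pattern),
            class = "contact_dialect")
}

#' Read a dialect description from JSON
#' @param path JSON file with `columns` and `label_pattern`.
#' @return a `contact_dialect`.
#' @export
read_dialect <- function(path) {
  d <- jsonlite::fromJSON(path)
  moe_dialect(columns = unlist(d$columns), label_pattern = d$label_pattern)
}

# internal: raw external label -> canonical key
canonicalize_label <- function(labels, dialect) {
  m <- regmatches(labels, regexec(dialect$label_pattern, labels))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop("unmappable residue label in external table: \"",
         labels[which(bad)[1]], "\"")
  canonical_key(chain_id = vapply(m, `[`, "", 5L),
                res_name = vapply(m, `[`, "", 2L),
                res_seq = as.integer(vapply(m, `[`, "", 3L)),
                icode = vapply(m, `[`, "", 4L))
}

#' Ingest an external residue-pair contact table
#'
#' Reads a CSV export, canonicalizes residue labels, removes rows involving
#' water residues, and aggregates duplicate residue pairs, yielding a
#' `residue_pair_table` ready for [aggregate_hotspots()] in `residue_pair`
#' mode.
#'
#' @param path CSV path.
#' @param dialect a [moe_dialect()] describing the export format.
#' @return a `residue_pair_table`.
#' @export
ingest_external_table <- function(path, dialect = moe_dialect()) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- dialect$columns
  missing <- setdiff(unname(need), names(raw))
  if (length(missing))
    stop("external table lacks column(s): ", paste(missing, collapse = ", "))
  ri <- canonicalize_label(raw[[need[["residue_i"]]]], dialect)
  rj <- canonicalize_label(raw[[need[["residue_j"]]]], dialect)
  dist <- as.numeric(raw[[need[["distance"]]]])
  en <- as.numeric(raw[[need[["energy"]]]])
  water <- parse_residue_key(ri)$res_name %in% WATER_NAMES |
    parse_residue_key(rj)$res_name %in% WATER_NAMES
  ri <- ri[!water]; rj <- rj[!water]
  dist <- dist[!water]; en <- en[!water]
  key <- paste(ri, rj, sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  out <- data.frame(
    residue_i = ri[first], residue_j = rj[first],
    min_distance = as.vector(tapply(dist, grp, min)),
    mean_distance = as.vector(tapply(dist, grp, mean)),
    sum_e_total = as.vector(tapply(en, grp, sum)),
    n_atom_pairs = as.vector(tapply(en, grp, length)),
    het_i = FALSE, het_j = FALSE, stringsAsFactors = FALSE)
  structure(out, class = c("residue_pair_table", "data.frame"))
}

#' Write a residue-pair table in the MOE-like external dialect
#'
#' Round-trips through [ingest_external_table()] with the same dialect.
#'
#' @param rp a `residue_pair_table`.
#' @param path output CSV path.
#' @param dialect a [moe_dialect()].
#' @return `path`, invisibly.
#' @export
write_external_table <- function(rp, path, dialect = moe_dialect()) {
  fmt <- function(ids) {
    k <- parse_residue_key(ids)
    sprintf("%s %d%s (%s)", k$res_name, k$res_seq, k$icode, k$chain_id)
  }
  out <- data.frame(fmt(rp$residue_i), fmt(rp$residue_j),
                    rp$min_distance, rp$sum_e_total, check.names = FALSE)
  names(out) <- unname(dialect$columns[c("residue_i", "residue_j",
                                         "distance", "energy")])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Concordance of two hotspot rankings
#'
#' Compares two `hotspot_table`s for the same side of the same complex:
#' Spearman rank correlation (average-rank ties) and Pearson correlation of
#' strength magnitudes over residues present in both tables, plus Top-N
#' overlap statistics (intersection size, Jaccard index, and recall) at each
#' N in `n_set`. `recall_a` is `|TopN_a intersect TopN_b| / N` — the fraction
#' of A's Top-N recovered among B's Top-N at the same N — and symmetrically
#' for `recall_b` (here the two coincide; both are reported for format
#' stability). With fewer than 3 shared residues the correlations are
#' reported as `NA` and flagged undefined; overlap statistics are still
#' computed.
#'
#' @param table_a,table_b `hotspot_table`s.
#' @param n_set Top-N thresholds (default 5, 10, 20, 30, 50).
#' @return a `benchmark_report`: list with `n_shared`, `spearman_rho`,
#'   `pearson_r`, `correlations_defined`, `per_n` (data.frame), `only_a`,
#'   `only_b` (diagnostic residue lists).
#' @export
concordance <- function(table_a, table_b, n_set = c(5, 10, 20, 30, 50)) {
  shared <- intersect(table_a$residue_id, table_b$residue_id)
  ia <- match(shared, table_a$residue_id)
  ib <- match(shared, table_b$residue_id)
  defined <- length(shared) >= 3
  rho <- r <- NA_real_
  if (defined) {
    rho <- suppressWarnings(cor(table_a$strength[ia], table_b$strength[ib],
                                method = "spearman"))
    r <- suppressWarnings(cor(table_a$strength[ia], table_b$strength[ib],
                              method = "pearson"))
  }
  per_n <- do.call(rbind, lapply(n_set, function(n) {
    ta <- top_n(table_a, n)
    tb <- top_n(table_b, n)
    inter <- length(intersect(ta, tb))
    uni <- length(union(ta, tb))
    data.frame(N = n, intersection_size = inter,
               jaccard = if (uni) inter / uni else 1,
               recall_a = inter / n, recall_b = inter / n)
  }))
  structure(list(n_shared = length(shared), spearman_rho = rho,
                 pearson_r = r, correlations_defined = defined,
                 per_n = per_n,
                 only_a = setdiff(table_a$residue_id, shared),
                 only_b = setdiff(table_b$residue_id, shared)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report: %d shared residues, rho = %s, r = %s\n",
              x$n_shared,
              formatC(x$spearman_rho, digits = 3, format = "f"),
              formatC(x$pearson_r, digits = 3, format = "f")))
  print(x$per_n, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report (JSON) and its per-N table (CSV)
#'
#' @param report a `benchmark_report`.
#' @param json_path output JSON path.
#' @param csv_path optional per-N CSV path.
#' @return `json_path`, invisibly.
#' @export
write_benchmark_report <- function(report, json_path, csv_path = NULL) {
  out <- list(
    n_shared = report$n_shared, spearman_rho = report$spearman_rho,
    pearson_r = report$pearson_r,
    correlations_defined = report$correlations_defined,
    recall_definition = "recall_a = |TopN_a intersect TopN_b| / N (and symmetrically recall_b)",
    per_n = report$per_n, only_a = report$only_a, only_b = report$only_b)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path)) write.csv(report$per_n, csv_path, row.names = FALSE)
  invisible(json_path)
}
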