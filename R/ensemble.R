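# Design-ensemble triage and diagnostics: confidence filtering, per-residue
# backbone RMSD against a native interface, energy-distance regression,
# Needleman-Wunsch alignment, and sequence-diversity statistics.

DESIGN_METRIC_COLS <- c("design_id", "length", "sequence", "mean_plddt",
                        "ipae", "binder_rmsd", "n_interface_residues",
                        "hotspot_engagement", "helicity", "mpnn_score")

#' Read a unified design metrics table
#'
#' One row per candidate design, consolidating structural-confidence metrics
#' (mean pLDDT on the 0-100 scale, interface predicted aligned error,
#' binder RMSD), interface-contact descriptors and sequence-level statistics.
#' `helicity` and `mpnn_score` are pass-through values computed upstream by
#' the generative stack. iPAE is treated as an engine-reported scalar;
#' thresholds are applied verbatim with no unit conversion.
#'
#' @param path CSV with the documented header (see `DESIGN_METRIC_COLS`).
#' @return data.frame of design metrics rows.
#' @export
read_design_metrics <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("design_id", "mean_plddt", "ipae"), names(df))
  if (length(missing))
    stop("design metrics table lacks column(s): ",
         paste(missing, collapse = ", "))
  validate_design_metrics(df)
}

validate_design_metrics <- function(df) {
  if (any(df$mean_plddt < 0 | df$mean_plddt > 100))
    stop("mean_plddt outside [0, 100]")
  if (any(df$ipae < 0)) stop("negative ipae")
  if (!is.null(df$sequence) && !is.null(df$length)) {
    both <- !is.na(df$sequence) & !is.na(df$length)
    if (any(df$length[both] != nchar(df$sequence[both])))
      stop("length column disagrees with sequence length")
  }
  df
}

#' Write a design metrics table
#' @param rows design metrics data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design_metrics <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Confidence-filter and triage a design ensemble
#'
#' Retains rows with `mean_plddt >= plddt_min` AND `ipae <= ipae_max` (both
#' inclusive), ranks them by ascending iPAE, then descending mean pLDDT, then
#' `design_id` (a deterministic total order), and truncates to the `keep`
#' highest-confidence designs. Idempotent; an empty result is allowed.
#'
#' @param rows design metrics data.frame.
#' @param plddt_min minimum mean pLDDT (default 80).
#' @param ipae_max maximum iPAE (default 15).
#' @param keep maximum number of designs retained (default 100).
#' @return the retained, ranked subset.
#' @export
filter_designs <- function(rows, plddt_min = 80, ipae_max = 15, keep = 100) {
  ok <- rows$mean_plddt >= plddt_min & rows$ipae <= ipae_max
  out <- rows[ok, , drop = FALSE]
  out <- out[order(out$ipae, -out$mean_plddt, out$design_id), , drop = FALSE]
  out <- head(out, keep)
  rownames(out) <- NULL
  out
}

#' iPAE-versus-pLDDT projection for confidence scatterplots
#'
#' @param rows design metrics data.frame.
#' @return data.frame with `design_id`, `ipae`, `mean_plddt`, values passed
#'   through unmodified.
#' @export
confidence_scatter <- function(rows) {
  data.frame(design_id = rows$design_id, ipae = rows$ipae,
             mean_plddt = rows$mean_plddt, stringsAsFactors = FALSE)
}

# internal: per-residue backbone coordinate block for mapped residues
backbone_block <- function(model, residues, atom_names) {
  a <- model$atoms
  uid <- residue_uid(a)
  lapply(residues, function(res) {
    sub <- a[uid == res & a$name %in% atom_names, , drop = FALSE]
    sub <- sub[match(atom_names, sub$name), , drop = FALSE]
    if (anyNA(sub$name)) return(NULL)
    as.matrix(sub[c("x", "y", "z")])
  })
}

#' Per-residue backbone RMSD after Kabsch superposition
#'
#' Performs one optimal rigid-body least-squares superposition of the model
#' onto the reference over all mapped backbone atoms (N, Calpha, C, O by
#' default), then reports the RMSD of each residue's backbone atoms and the
#' global RMSD over all superposed atoms. Residue correspondence defaults to
#' file order (i-th mapped residue of the model to i-th of the reference);
#' pass an explicit two-column mapping when numbering differs. Mapped
#' residues missing any backbone atom on either side are skipped with a
#' warning.
#'
#' @param model,reference `structure_model`s (waters/HETATM ignored).
#' @param correspondence optional data.frame with columns `model_residue`,
#'   `ref_residue` (canonical keys).
#' @param atom_names backbone atom names (default `c("N","CA","C","O")`).
#' @return an `rmsd_profile`: data.frame with `index`, `model_residue`,
#'   `ref_residue`, `rmsd`, plus attributes `global_rmsd` and `n_atoms`.
#' @export
per_residue_rmsd <- function(model, reference, correspondence = NULL,
                             atom_names = c("N", "CA", "C", "O")) {
  res_of <- function(m) {
    r <- model_residues(m)
    r$residue_id[!r$is_water & !r$is_hetatm]
  }
  if (is.null(correspondence)) {
    mr <- res_of(model)
    rr <- res_of(reference)
    n <- min(length(mr), length(rr))
    if (length(mr) != length(rr))
      warning("model and reference residue counts differ (", length(mr),
              " vs ", length(rr), "); pairing the first ", n, " in order")
    correspondence <- data.frame(model_residue = mr[seq_len(n)],
                                 ref_residue = rr[seq_len(n)],
                                 stringsAsFactors = FALSE)
  }
  mb <- backbone_block(model, correspondence$model_residue, atom_names)
  rb <- backbone_block(reference, correspondence$ref_residue, atom_names)
  ok <- !vapply(mb, is.null, logical(1)) & !vapply(rb, is.null, logical(1))
  if (any(!ok))
    warning(sum(!ok), " mapped residue(s) missing backbone atoms skipped")
  if (sum(ok) < 3)
    stop("superposition needs at least 3 mapped residues with complete ",
         "backbones (have ", sum(ok), ")")
  correspondence <- correspondence[ok, , drop = FALSE]
  mxyz <- do.call(rbind, mb[ok])
  rxyz <- do.call(rbind, rb[ok])
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(rxyz)),
                           mobile = as.vector(t(mxyz)),
                           fixed.inds = seq_len(3 * nrow(rxyz)),
                           mobile.inds = seq_len(3 * nrow(mxyz)))
  fxyz <- matrix(fitted, ncol = 3, byrow = TRUE)
  dev2 <- rowSums((fxyz - rxyz)^2)
  k <- length(atom_names)
  res_idx <- rep(seq_len(nrow(correspondence)), each = k)
  per_res <- sqrt(as.vector(tapply(dev2, res_idx, mean)))
  out <- data.frame(index = seq_len(nrow(correspondence)),
                    model_residue = correspondence$model_residue,
                    ref_residue = correspondence$ref_residue,
                    rmsd = per_res, stringsAsFactors = FALSE)
  structure(out, class = c("rmsd_profile", "data.frame"),
            global_rmsd = sqrt(mean(dev2)), n_atoms = nrow(rxyz))
}

#' Global RMSD of an `rmsd_profile`
#' @param profile an `rmsd_profile` from [per_residue_rmsd()].
#' @return numeric global backbone RMSD, Angstrom.
#' @export
global_rmsd <- function(profile) attr(profile, "global_rmsd")

#' Energy-versus-distance regression over residue pairs
#'
#' Least-squares line of summed interaction energy against mean interatomic
#' distance over the residue pairs of a contact interface, with the Pearson
#' correlation coefficient; a well-packed interface shows the expected
#' inverse relationship (closer pairs, more favorable energies). With zero
#' variance in either variable the correlation is undefined and flagged, and
#' the slope/intercept are omitted.
#'
#' @param rp a `residue_pair_table` (needs >= 3 rows).
#' @return list with `pearson_r`, `slope`, `intercept`, `n`, `defined`.
#' @export
energy_distance_correlation <- function(rp) {
  if (nrow(rp) < 3) stop("need at least 3 residue pairs")
  x <- rp$mean_distance
  y <- rp$sum_e_total
  if (sd(x) == 0 || sd(y) == 0)
    return(list(pearson_r = NA_real_, slope = NULL, intercept = NULL,
                n = nrow(rp), defined = FALSE))
  fit <- lm(y ~ x)
  list(pearson_r = cor(x, y), slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), n = nrow(rp), defined = TRUE)
}

# internal: cached BLOSUM62 from Biostrings
blosum62 <- function() {
  if (is.null(.hf_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .hf_env$blosum62 <- e$BLOSUM62
  }
  .hf_env$blosum62
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_sequence <- function(s, who) {
  if (!nzchar(s)) stop(who, " sequence is empty")
  bad <- setdiff(strsplit(s, "")[[1]], c(AA20, "X"))
  if (length(bad))
    stop(who, " sequence has non-amino-acid letter(s): ",
         paste(unique(bad), collapse = ", "))
}

#' Needleman-Wunsch global alignment (affine gaps)
#'
#' Optimal global alignment under a substitution matrix with affine gap
#' penalties (Gotoh three-state recursion). A gap of length L costs
#' `gap_open + L * gap_extend`. Defaults are BLOSUM62 with gap open 11 /
#' extend 1, the standard global-alignment setting. Traceback ties are broken
#' deterministically: match/mismatch over a gap in the second sequence over a
#' gap in the first (diagonal > up > left), so alignments are reproducible.
#'
#' @param seq_a,seq_b amino-acid strings (20-letter alphabet plus X).
#' @param substitution substitution matrix (default: BLOSUM62 from
#'   Biostrings), or its name `"BLOSUM62"`.
#' @param gap_open,gap_extend positive gap penalties.
#' @return list with `aligned_a`, `aligned_b` (gapped strings), `score`,
#'   `identity` (matches / alignment length), `length`.
#' @export
global_align <- function(seq_a, seq_b, substitution = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  check_sequence(seq_a, "first")
  check_sequence(seq_b, "second")
  sub <- if (is.character(substitution) && length(substitution) == 1) {
    if (substitution != "BLOSUM62") stop("unknown substitution scheme")
    blosum62()
  } else substitution
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  n <- length(a); m <- length(b)
  go <- gap_open; ge <- gap_extend
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n) X[2:(n + 1), 1] <- -(go + ge * seq_len(n))
  if (m) Y[1, 2:(m + 1)] <- -(go + ge * seq_len(m))
  for (i in seq_len(n)) {
    s_row <- sub[a[i], b]
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- s_row[j] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                             Y[i, j + 1] - go - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
                             Y[i + 1, j] - ge)
    }
  }
  # traceback, tie preference M (diag) > X (up) > Y (left)
  pick <- function(scores) which.max(scores + c(2e-9, 1e-9, 0))
  state <- c("M", "X", "Y")[pick(c(M[n + 1, m + 1], X[n + 1, m + 1],
                                   Y[n + 1, m + 1]))]
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  i <- n; j <- m
  al_a <- character(0); al_b <- character(0)
  while (i > 0 || j > 0) {
    if (state == "M") {
      al_a <- c(a[i], al_a); al_b <- c(b[j], al_b)
      prev <- pick(c(M[i, j], X[i, j], Y[i, j]))
      i <- i - 1; j <- j - 1
      state <- c("M", "X", "Y")[prev]
    } else if (state == "X") {
      al_a <- c(a[i], al_a); al_b <- c("-", al_b)
      prev <- pick(c(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                     Y[i, j + 1] - go - ge))
      i <- i - 1
      state <- c("M", "X", "Y")[prev]
    } else {
      al_a <- c("-", al_a); al_b <- c(b[j], al_b)
      prev <- pick(c(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
                     Y[i + 1, j] - ge))
      j <- j - 1
      state <- c("M", "X", "Y")[prev]
    }
  }
  len <- length(al_a)
  matches <- sum(al_a == al_b & al_a != "-")
  list(aligned_a = paste(al_a, collapse = ""),
       aligned_b = paste(al_b, collapse = ""),
       score = score, identity = matches / len, length = len)
}

# internal: character matrix (sequences x columns) from equal-length strings
seq_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, ""))
}

#' Shannon entropy per alignment column
#'
#' `Hs = -sum_i p_i log2 p_i` over observed residue frequencies at each
#' column, in bits; 0 for a fully conserved column, log2(20) for a uniform
#' 20-way column. Gap characters are excluded from the frequencies.
#'
#' @param mat character matrix, sequences in rows, columns as positions.
#' @return numeric vector of per-column entropies (bits).
#' @export
column_entropy <- function(mat) {
  apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(NA_real_)
    p <- table(col) / length(col)
    -sum(p * log2(p))
  })
}

#' Sequence-diversity report for a design ensemble
#'
#' Computes the pairwise identity matrix, normalized Hamming distances
#' (mismatches / alignment length, in `[0, 1]`; identity is 1 minus the same
#' pair's Hamming distance) and per-column Shannon entropy in bits. In
#' `equal_length` mode (the design-ensemble norm: one consensus length)
#' positions are compared directly; in `align` mode every pair is globally
#' aligned first and gap columns count as mismatches, while the entropy
#' profile is computed over the columns of the first sequence via its
#' pairwise alignments (other sequences' unaligned insertions are ignored).
#'
#' @param sequences named character vector of amino-acid sequences (>= 2), or
#'   a `Biostrings::AAStringSet`.
#' @param mode `"equal_length"` or `"align"`.
#' @return a `diversity_report`: list with `identity_matrix`,
#'   `hamming_matrix`, `hamming_distribution` (upper-triangle values),
#'   `entropy_bits`, `mode`.
#' @export
diversity_report <- function(sequences, mode = c("equal_length", "align")) {
  mode <- match.arg(mode)
  if (methods::is(sequences, "AAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (length(sequences) < 2) stop("need at least 2 sequences")
  ids <- if (is.null(names(sequences))) {
    paste0("seq", seq_along(sequences))
  } else names(sequences)
  n <- length(sequences)
  ham <- matrix(0, n, n, dimnames = list(ids, ids))
  if (mode == "equal_length") {
    if (length(unique(nchar(sequences))) != 1)
      stop("equal_length mode requires equal-length sequences; use align mode")
    mat <- seq_matrix(sequences)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      h <- mean(mat[i, ] != mat[j, ])
      ham[i, j] <- ham[j, i] <- h
    }
    entropy <- column_entropy(mat)
  } else {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      al <- global_align(sequences[[i]], sequences[[j]])
      ham[i, j] <- ham[j, i] <- 1 - al$identity
    }
    # stack onto the first sequence's columns
    master <- strsplit(sequences[[1]], "")[[1]]
    stack <- matrix("-", n, length(master))
    stack[1, ] <- master
    for (i in 2:n) {
      al <- global_align(sequences[[1]], sequences[[i]])
      ca <- strsplit(al$aligned_a, "")[[1]]
      cb <- strsplit(al$aligned_b, "")[[1]]
      stack[i, ] <- cb[ca != "-"]
    }
    entropy <- column_entropy(stack)
  }
  structure(list(identity_matrix = 1 - ham, hamming_matrix = ham,
                 hamming_distribution = ham[upper.tri(ham)],
                 entropy_bits = entropy, mode = mode),
            class = "diversity_report")
}

#' Read amino-acid sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write amino-acid sequences to FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
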