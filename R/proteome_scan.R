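#' Score one 9-mer window against a normalized specificity matrix
#'
#' The window score is the additive position-specific scoring matrix
#' (PSSM) score: the sum over the nine positions of the normalized score
#' of the residue found there. Masked cells already carry their sentinel
#' normalized value, so their contribution follows the mask policy chosen
#' at normalization time. Windows containing a non-standard residue (X, U,
#' B, Z, ...) are unscorable and return NA.
#'
#' @param window 9-residue string (P5..P4').
#' @param matrix A normalized [specificity_matrix()], or a bare 9 x 20
#'   numeric matrix on the same layout.
#' @return Numeric score, or NA for an unscorable window.
#' @export
score_window <- function(window, matrix) {
  m <- normalized_layer(matrix)
  stopifnot(is.character(window), length(window) == 1L)
  if (nchar(window) != 9L)
    stop("window must be exactly 9 residues", call. = FALSE)
  idx <- match(strsplit(window, "")[[1]], AA_RESIDUES)
  if (anyNA(idx)) return(NA_real_)
  sum(m[cbind(seq_len(9L), idx)])
}

normalized_layer <- function(matrix) {
  if (inherits(matrix, "specificity_matrix")) {
    if (is.null(matrix$normalized))
      stop("specificity matrix has not been normalized; ",
           "call normalize_matrix() first", call. = FALSE)
    matrix$normalized
  } else {
    stopifnot(is.matrix(matrix), nrow(matrix) == 9L,
              identical(colnames(matrix), AA_RESIDUES))
    matrix
  }
}

#' Scan a protein for candidate cleavage sites
#'
#' Slides the 9-position matrix along the sequence and scores every
#' complete window. The scissile bond sits between P1 and P1', so a
#' protein of length L has max(0, L - 8) scorable bonds, with P1 index
#' running from 5 to L - 4; terminal bonds lacking a full recognition
#' window are not scored (no padding). Windows containing non-standard
#' residues are skipped.
#'
#' @param sequence Protein sequence string.
#' @param matrix Normalized specificity matrix.
#' @param protein_id Identifier carried into the output.
#' @param name Optional human-readable protein name.
#' @param threshold Minimum score retained (default 10).
#' @return data.frame with columns `protein_id`, `name`, `p1_index`
#'   (1-based residue index of P1), `site_label` ("i-(i+1)" for the bond),
#'   `window` (the 9-mer), `score`; sorted by descending score, ties
#'   broken by (protein_id, p1_index).
#' @export
scan_protein <- function(sequence, matrix, protein_id = "protein",
                         name = protein_id, threshold = 10) {
  m <- normalized_layer(matrix)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  empty <- data.frame(protein_id = character(), name = character(),
                      p1_index = integer(), site_label = character(),
                      window = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (L < 9L) {
    message("protein '", protein_id, "' shorter than 9 residues; no ",
            "scorable window")
    return(empty)
  }
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, AA_RESIDUES)
  starts <- seq_len(L - 8L)          # window start = P5 index
  p1 <- starts + (P1_OFFSET - 1L)
  # 9 stacked lookups; windows touching a non-standard residue become NA
  scores <- numeric(length(starts))
  for (k in 0:8) scores <- scores + m[cbind(k + 1L, idx[starts + k])]
  keep <- !is.na(scores) & scores >= threshold
  if (sum(is.na(scores)) > 0)
    message(sum(is.na(scores)), " window(s) in '", protein_id,
            "' skipped (non-standard residues)")
  if (!any(keep)) return(empty)
  out <- data.frame(
    protein_id = rep(protein_id, sum(keep)),
    name = rep(name, sum(keep)),
    p1_index = p1[keep],
    site_label = paste0(p1[keep], "-", p1[keep] + 1L),
    window = substring(sequence, starts[keep], starts[keep] + 8L),
    score = scores[keep],
    stringsAsFactors = FALSE)
  out[order(-out$score, out$protein_id, out$p1_index), , drop = FALSE]
}

#' Scan a set of proteins and rank all candidate sites
#'
#' Applies [scan_protein()] to every sequence, pools the hits, ranks them
#' globally by descending score (ties broken by protein id then P1 index,
#' so output is deterministic) and truncates to the best `top_n`.
#'
#' @param proteins Named character vector of sequences, a named
#'   `Biostrings::AAStringSet`, or a path to a FASTA file.
#' @param matrix Normalized specificity matrix.
#' @param threshold Minimum retained score (default 10).
#' @param top_n Keep this many best hits (default 500).
#' @param names Optional named character vector mapping protein ids to
#'   display names.
#' @return data.frame as in [scan_protein()] plus a `rank` column.
#' @export
scan_proteome <- function(proteins, matrix, threshold = 10, top_n = 500,
                          names = NULL) {
  seqs <- as_protein_set(proteins)
  if (anyDuplicated(base::names(seqs)))
    stop("duplicate protein id(s): ",
         paste(unique(base::names(seqs)[duplicated(base::names(seqs))]),
               collapse = ", "), call. = FALSE)
  stopifnot(top_n >= 1)
  hits <- lapply(base::names(seqs), function(id) {
    nm <- if (!is.null(names) && id %in% base::names(names)) names[[id]] else id
    scan_protein(seqs[[id]], matrix, protein_id = id, name = nm,
                 threshold = threshold)
  })
  out <- do.call(rbind, hits)
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(protein_id = character(), name = character(),
                      p1_index = integer(), site_label = character(),
                      window = character(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  out <- out[order(-out$score, out$protein_id, out$p1_index), , drop = FALSE]
  out <- head(out, top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

as_protein_set <- function(proteins) {
  if (inherits(proteins, "AAStringSet") || inherits(proteins, "BStringSet")) {
    seqs <- as.character(proteins)
  } else if (is.character(proteins) && length(proteins) == 1L &&
             file.exists(proteins) && is.null(names(proteins))) {
    fa <- Biostrings::readAAStringSet(proteins)
    seqs <- as.character(fa)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(proteins)) {
    seqs <- proteins
  } else {
    stop("'proteins' must be named sequences, an AAStringSet or a FASTA path",
         call. = FALSE)
  }
  if (length(seqs) == 0L) stop("no proteins to scan", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every protein needs an id (FASTA header / vector name)",
         call. = FALSE)
  seqs
}

#' Render a window with the scissile-bond marker
#'
#' Display helper: inserts a down-arrow after P1, e.g. `"VVHVK|SLET"`
#' becomes `"VVHVK↓SLET"`.
#'
#' @param window 9-mer window(s).
#' @return Character vector with the arrow inserted after position 5.
#' @export
format_cleavage_window <- function(window) {
  stopifnot(all(nchar(window) == 9L))
  paste0(substr(window, 1L, 5L), "↓", substr(window, 6L, 9L))
}
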