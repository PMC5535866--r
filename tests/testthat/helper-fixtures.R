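# shared fixtures: designs are cheap to rebuild, matrices are tiny

design_x <- build_library_design("X4-X-X4")
design_rk <- build_library_design("X4-R/K-X4")
design_yf <- build_library_design("X4-Y/F-X4")

# a matrix with a single scoring cell: +5 for Arg at P1, 0 elsewhere
single_cell_matrix <- function() {
  m <- matrix(0, 9, 20, dimnames = list(POSITION_LABELS, AA_RESIDUES))
  m["P1", "R"] <- 5
  m
}

# independent per-residue NNK codon counts (standard genetic code,
# tallied by hand over the 32 NNK codons; TAG is the single stop)
NNK_CODON_COUNTS <- c(A = 2, C = 1, D = 1, E = 1, F = 1, G = 2, H = 1,
                      I = 1, K = 1, L = 3, M = 1, N = 1, P = 2, Q = 1,
                      R = 3, S = 3, T = 2, V = 2, W = 1, Y = 1)

# brute-force PSSM scan oracle: enumerate every window with plain string
# ops and per-position lookups, then sort like the scanner does
brute_force_scan <- function(sequence, m, protein_id, threshold) {
  L <- nchar(sequence)
  rows <- list()
  if (L >= 9) {
    for (start in 1:(L - 8)) {
      w <- substr(sequence, start, start + 8)
      s <- 0
      ok <- TRUE
      for (k in 1:9) {
        aa <- substr(w, k, k)
        if (!aa %in% AA_RESIDUES) { ok <- FALSE; break }
        s <- s + m[k, aa]
      }
      if (ok && s >= threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = protein_id, p1_index = start + 4L, window = w,
          score = s, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(protein_id = character(), p1_index = integer(),
                      window = character(), score = numeric()))
  out <- do.call(rbind, rows)
  out[order(-out$score, out$protein_id, out$p1_index), , drop = FALSE]
}

# reference annotations built from the bundled predicted-sites table
hdm_annotations <- function(sites = hdm_predicted_sites()) {
  load_topology(data.frame(protein_id = sites$protein_id,
                           start = sites$ecd_start, end = sites$ecd_end))
}
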