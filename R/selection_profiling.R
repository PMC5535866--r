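#' Tally residues per subsite position
#'
#' Counts residue occurrences at each of the nine positions of an aligned
#' pool of selected 9-mers. Column sums at every position equal the pool
#' size n.
#'
#' @param peptides Character vector of 9-mer peptides (P5..P4').
#' @return Object of class `count_matrix`: an integer 9 x 20 matrix (rows
#'   [POSITION_LABELS], columns [AA_RESIDUES]) with attribute `n`.
#' @examples
#' cm <- count_residues(c("AAAAKAAAA", "AAAARAAAA"))
#' cm["P1", c("K", "R")]  # 1 1
#' @export
count_residues <- function(peptides) {
  if (length(peptides) == 0L)
    stop("empty selection dataset: no peptides to count", call. = FALSE)
  bad_len <- which(nchar(peptides) != 9L)
  if (length(bad_len))
    stop("peptide(s) of wrong length at index: ",
         paste(head(bad_len, 5L), collapse = ", "), call. = FALSE)
  chars <- matrix(unlist(strsplit(peptides, ""), use.names = FALSE),
                  nrow = length(peptides), ncol = 9L, byrow = TRUE)
  bad_aa <- !chars %in% AA_RESIDUES
  if (any(bad_aa))
    stop("non-standard residue(s) at peptide index: ",
         paste(head(unique(which(bad_aa, arr.ind = TRUE)[, 1]), 5L),
               collapse = ", "), call. = FALSE)
  counts <- vapply(seq_len(9L), function(i)
    table(factor(chars[, i], levels = AA_RESIDUES)),
    integer(length(AA_RESIDUES)))
  counts <- t(counts)
  dimnames(counts) <- list(POSITION_LABELS, AA_RESIDUES)
  structure(counts, n = length(peptides), class = c("count_matrix", "matrix"))
}

#' Binomial enrichment z-score for a residue at a position
#'
#' The specificity score of residue x at a position is the deviation of
#' its observed count from the library expectation, in standard-deviation
#' units of the binomial null:
#' \deqn{\Delta\sigma = \frac{Obs(x) - n P(x)}{\sqrt{n P(x) (1 - P(x))}}}
#' where Obs(x) is the count of x among the n selected sequences and P(x)
#' its probability in the naive library. Positive scores mark positively
#' selected residues, negative scores depletion.
#'
#' @param obs Observed count(s).
#' @param n Total sequences analysed.
#' @param p Library background probability (strictly inside (0, 1)).
#' @return Numeric z-score(s).
#' @examples
#' delta_sigma(15, 75, 0.05)  # ~5.96
#' @export
delta_sigma <- function(obs, n, p) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(p <= 0 | p >= 1))
    stop("undefined variance: background probability must lie strictly ",
         "between 0 and 1", call. = FALSE)
  (obs - n * p) / sqrt(n * p * (1 - p))
}

#' Specificity matrix from selection counts
#'
#' Applies [delta_sigma()] cellwise, with P(x) taken from the library
#' design background. Cells the library cannot produce (residues excluded
#' at a fixed position, e.g. the 18 non-Arg/Lys residues at P1 of an
#' X4-R/K-X4 library) are masked, not scored: no null distribution exists
#' for them.
#'
#' @param counts A [count_residues()] matrix.
#' @param design A [build_library_design()].
#' @return Object of class `specificity_matrix` with elements `scores`
#'   (9 x 20, NA in masked cells), `mask` (logical 9 x 20, TRUE =
#'   unsamplable), `n`, `design_name`, and `normalized` (NULL until
#'   [normalize_matrix()] is applied).
#' @export
specificity_matrix <- function(counts, design) {
  stopifnot(inherits(counts, "count_matrix"), inherits(design, "library_design"))
  n <- attr(counts, "n")
  bg <- design$background
  mask <- bg == 0
  if (any(counts[mask] > 0))
    stop("counts inconsistent with design: residues observed at a fixed ",
         "position that excludes them", call. = FALSE)
  scores <- matrix(NA_real_, 9L, length(AA_RESIDUES),
                   dimnames = dimnames(bg))
  scores[!mask] <- delta_sigma(counts[!mask], n, bg[!mask])
  structure(list(scores = scores, mask = mask, n = n,
                 design_name = design$name, normalized = NULL),
            class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("<specificity_matrix: n = ", x$n, ", design = ", x$design_name,
      if (!is.null(x$normalized)) ", normalized" else "", ">\n", sep = "")
  print(round(x$scores, 2))
  invisible(x)
}

#' Normalize a specificity matrix to the -5..+5 scoring scale
#'
#' Rescales all unmasked z-scores by one global linear factor
#' 5 / max|score| so the largest magnitude becomes 5, zero stays zero and
#' sign and ranking are preserved; this keeps scores comparable across
#' positions, as additive window scoring assumes. A per-position variant
#' (each row scaled to its own max) is available via `scope`.
#' Masked (library-unsamplable) cells receive a sentinel normalized value:
#' 0 under `mask_policy = "neutral_zero"` (a residue the library never
#' showed the protease is no evidence either way), or -5 under
#' `"hard_exclude"`.
#'
#' @param matrix A [specificity_matrix()].
#' @param scope `"global"` (default) or `"per_position"`.
#' @param mask_policy `"neutral_zero"` (default) or `"hard_exclude"`.
#' @return The matrix with its `normalized` field populated (9 x 20
#'   numeric, every value in \[-5, 5\]).
#' @export
normalize_matrix <- function(matrix, scope = c("global", "per_position"),
                             mask_policy = c("neutral_zero", "hard_exclude")) {
  stopifnot(inherits(matrix, "specificity_matrix"))
  scope <- match.arg(scope)
  mask_policy <- match.arg(mask_policy)
  s <- matrix$scores
  norm <- s
  if (scope == "global") {
    m <- max(abs(s), na.rm = TRUE)
    if (m == 0) {
      warning("all specificity scores are zero; matrix left unscaled",
              call. = FALSE)
    } else {
      norm <- 5 * s / m
    }
  } else {
    for (i in seq_len(nrow(s))) {
      m <- suppressWarnings(max(abs(s[i, ]), na.rm = TRUE))
      if (is.finite(m) && m > 0) norm[i, ] <- 5 * s[i, ] / m
    }
  }
  norm[matrix$mask] <- if (mask_policy == "neutral_zero") 0 else -5
  matrix$normalized <- norm
  matrix$mask_policy <- mask_policy
  matrix
}

#' Selection-round enrichment rate
#'
#' Ratio of infectious phages eluted by protease treatment to phages
#' released in the no-protease control of the same round. Values above 1
#' indicate productive, cleavage-driven elution.
#'
#' @param eluted_with_protease,eluted_control Phage counts (control > 0).
#' @return The ratio.
#' @examples
#' enrichment_rate(8e5, 1e5)  # 8
#' @export
enrichment_rate <- function(eluted_with_protease, eluted_control) {
  stopifnot(eluted_with_protease >= 0, eluted_control >= 0)
  if (any(eluted_control == 0))
    stop("undefined enrichment rate: control elution count is zero",
         call. = FALSE)
  eluted_with_protease / eluted_control
}

# fixed decimal text used by the TSV round-trip; enough digits that
# read-back values reformat identically
MATRIX_TSV_FMT <- "%.10g"

#' Write / read a specificity matrix as TSV
#'
#' The on-disk format is a 9-row table, rows labelled P5..P4p, one column
#' per residue (20 one-letter codes, alphabetical). Masked cells are
#' written as `NA`. Values are written as fixed decimal text so that a
#' write-read-write cycle is byte-identical.
#'
#' @param matrix A `specificity_matrix`, or for `write_matrix_tsv` any
#'   9 x 20 numeric matrix.
#' @param path Output / input file path.
#' @param which Which layer to write: `"scores"` (raw z-scores) or
#'   `"normalized"`.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns a 9 x 20 numeric matrix (NA where masked).
#' @export
write_matrix_tsv <- function(matrix, path, which = c("scores", "normalized")) {
  which <- match.arg(which)
  m <- if (inherits(matrix, "specificity_matrix")) matrix[[which]] else matrix
  if (is.null(m)) stop("matrix has no '", which, "' layer", call. = FALSE)
  stopifnot(is.matrix(m), nrow(m) == 9L)
  txt <- apply(m, c(1, 2), function(v)
    if (is.na(v)) "NA" else sprintf(MATRIX_TSV_FMT, v))
  lines <- c(paste(c("position", colnames(m)), collapse = "\t"),
             vapply(seq_len(9L), function(i)
               paste(c(rownames(m)[i], txt[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df)[1], "position") ||
      !identical(df$position, POSITION_LABELS))
    stop("not a specificity-matrix TSV: expected rows ",
         paste(POSITION_LABELS, collapse = ","), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$position
  storage.mode(m) <- "double"
  m
}
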