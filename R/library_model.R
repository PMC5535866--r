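#' Degenerate codon schemes
#'
#' A degenerate codon scheme describes one codon position of a randomized
#' library cassette: a nucleotide alphabet for each of the three codon
#' positions, plus a policy for stop codons that the scheme can emit. The
#' classic NNK scheme (any base, any base, G/T) encodes all 20 amino acids
#' in 32 codons, one of which (TAG, amber) is a stop.
#'
#' @param name Scheme label, or an IUPAC-style triplet such as `"NNK"`,
#'   `"ARG"`, `"TWT"` from which the three alphabets are derived.
#' @param alphabets Optional list of three character vectors of nucleotides
#'   overriding the IUPAC expansion of `name`.
#' @param stop_policy How stop codons contribute to the amino-acid
#'   background: `"exclude_renormalize"` drops them and renormalizes over
#'   the coding mass (the conservative choice for displayed, functional
#'   clones), `"amber_as_gln"` reads TAG as Gln, as in amber-suppressor
#'   hosts such as E. coli TG1.
#' @return An object of class `codon_scheme`.
#' @examples
#' codon_scheme("NNK")
#' codon_scheme("ARG")  # fixed-P1 Arg/Lys cassette
#' @export
codon_scheme <- function(name, alphabets = NULL,
                         stop_policy = c("exclude_renormalize", "amber_as_gln")) {
  stop_policy <- match.arg(stop_policy)
  if (is.null(alphabets)) {
    if (!is.character(name) || length(name) != 1L || nchar(name) != 3L)
      stop("'name' must be a 3-letter degenerate codon (e.g. \"NNK\") ",
           "when 'alphabets' is not given", call. = FALSE)
    alphabets <- lapply(strsplit(toupper(name), "")[[1]], iupac_expand)
  }
  if (!is.list(alphabets) || length(alphabets) != 3L)
    stop("'alphabets' must be a list of three nucleotide sets", call. = FALSE)
  alphabets <- lapply(alphabets, function(a) sort(unique(toupper(a))))
  for (a in alphabets) {
    if (length(a) == 0L || !all(a %in% c("A", "C", "G", "T")))
      stop("invalid scheme: each alphabet must be a nonempty subset of ",
           "{A, C, G, T}", call. = FALSE)
  }
  structure(list(name = name, alphabets = alphabets,
                 stop_policy = stop_policy),
            class = "codon_scheme")
}

iupac_expand <- function(code) {
  map <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  out <- map[[code]]
  if (is.null(out))
    stop("unknown IUPAC nucleotide code: ", code, call. = FALSE)
  out
}

#' @export
print.codon_scheme <- function(x, ...) {
  cat("<codon_scheme ", x$name, ": ",
      paste(vapply(x$alphabets, paste, "", collapse = "/"), collapse = " | "),
      "; stops: ", x$stop_policy, ">\n", sep = "")
  invisible(x)
}

#' Enumerate the codons of a degenerate scheme
#'
#' Expands the three position alphabets into the full codon set. Every
#' codon synthesized from an equimolar degenerate oligonucleotide is
#' equiprobable, so probabilities are uniform.
#'
#' @param scheme A [codon_scheme()].
#' @return A data.frame with columns `codon` and `probability`
#'   (probabilities sum to 1).
#' @examples
#' nrow(enumerate_degenerate_codons(codon_scheme("NNK")))  # 32
#' @export
enumerate_degenerate_codons <- function(scheme) {
  stopifnot(inherits(scheme, "codon_scheme"))
  grid <- expand.grid(b3 = scheme$alphabets[[3]],
                      b2 = scheme$alphabets[[2]],
                      b1 = scheme$alphabets[[1]],
                      stringsAsFactors = FALSE)
  codons <- sort(paste0(grid$b1, grid$b2, grid$b3))
  data.frame(codon = codons,
             probability = rep(1 / length(codons), length(codons)),
             stringsAsFactors = FALSE)
}

#' Amino-acid background of a degenerate codon scheme
#'
#' Translates every codon of the scheme with the standard genetic code and
#' aggregates codon probabilities per residue. This is the per-position
#' null distribution P(x) against which selection enrichment is measured.
#' Under `exclude_renormalize`, stop codons are removed and the remaining
#' mass renormalized (NNK: P(Trp) = 1/31, P(Leu) = 3/31, ...); under
#' `amber_as_gln`, TAG contributes to Gln (NNK: P(Gln) = 2/32).
#'
#' @param scheme A [codon_scheme()].
#' @return Named numeric vector of length 20 over [AA_RESIDUES]
#'   (alphabetical), summing to 1.
#' @examples
#' amino_acid_background(codon_scheme("NNK"))["W"]  # 1/31
#' @export
amino_acid_background <- function(scheme) {
  stopifnot(inherits(scheme, "codon_scheme"))
  codons <- enumerate_degenerate_codons(scheme)
  aa <- unname(Biostrings::GENETIC_CODE[codons$codon])
  pr <- codons$probability
  if (scheme$stop_policy == "amber_as_gln")
    aa[aa == "*" & codons$codon == "TAG"] <- "Q"
  keep <- aa != "*"
  if (!any(keep))
    stop("scheme encodes only stop codons", call. = FALSE)
  aa <- aa[keep]
  pr <- pr[keep]
  pr <- pr / sum(pr)
  bg <- setNames(numeric(length(AA_RESIDUES)), AA_RESIDUES)
  tab <- tapply(pr, aa, sum)
  bg[names(tab)] <- tab
  bg
}

#' Build a nonamer display library design
#'
#' A library design holds, for each of the nine subsite positions P5..P4',
#' the amino-acid background probabilities implied by its degenerate codon
#' cassette. The three standard designs are:
#' \describe{
#'   \item{`"X4-X-X4"`}{all nine positions fully randomized (NNK).}
#'   \item{`"X4-R/K-X4"`}{P1 fixed to Arg/Lys in equal ratio (ARG codon),
#'     the trypsin-like constraint.}
#'   \item{`"X4-Y/F-X4"`}{P1 fixed to Tyr/Phe in equal ratio (TWT codon),
#'     the chymotrypsin-like constraint. The alias `"X4-W/F-X4"` is
#'     accepted for this design (a naming variant seen in library
#'     construction records; the TWT cassette encodes Tyr/Phe).}
#' }
#'
#' @param spec Design name (one of the above, case/punctuation tolerant),
#'   or a list of 9 [codon_scheme()] objects for a custom design.
#' @param stop_policy Stop-codon policy forwarded to [codon_scheme()].
#' @return An object of class `library_design` with elements `name`,
#'   `background` (9 x 20 matrix, rows [POSITION_LABELS], columns
#'   [AA_RESIDUES], rows summing to 1) and `fixed_positions` (named list of
#'   allowed residue sets for constrained positions).
#' @examples
#' d <- build_library_design("X4-R/K-X4")
#' d$background["P1", c("R", "K")]  # 0.5 0.5
#' @export
build_library_design <- function(spec, stop_policy = "exclude_renormalize") {
  if (is.list(spec) && all(vapply(spec, inherits, TRUE, "codon_scheme"))) {
    if (length(spec) != 9L)
      stop("a custom design needs exactly 9 codon schemes", call. = FALSE)
    schemes <- spec
    name <- "custom"
  } else if (is.character(spec) && length(spec) == 1L) {
    key <- gsub("[^A-Z]", "", toupper(spec))
    nnk <- codon_scheme("NNK", stop_policy = stop_policy)
    p1 <- switch(key,
                 XXX = nnk,
                 XRKX = codon_scheme("ARG", stop_policy = stop_policy),
                 XYFX = ,
                 XWFX = codon_scheme("TWT", stop_policy = stop_policy),
                 stop("unknown library design: '", spec, "' (expected ",
                      "\"X4-X-X4\", \"X4-R/K-X4\" or \"X4-Y/F-X4\")",
                      call. = FALSE))
    schemes <- c(rep(list(nnk), 4), list(p1), rep(list(nnk), 4))
    name <- if (key == "XXX") "X4-X-X4"
            else if (key == "XRKX") "X4-R/K-X4"
            else "X4-Y/F-X4"
  } else {
    stop("'spec' must be a design name or a list of 9 codon schemes",
         call. = FALSE)
  }
  bg <- t(vapply(schemes, amino_acid_background, numeric(length(AA_RESIDUES))))
  dimnames(bg) <- list(POSITION_LABELS, AA_RESIDUES)
  stopifnot(all(abs(rowSums(bg) - 1) < 1e-9))
  fixed <- list()
  for (i in seq_len(9L)) {
    allowed <- AA_RESIDUES[bg[i, ] > 0]
    if (length(allowed) < length(AA_RESIDUES))
      fixed[[POSITION_LABELS[i]]] <- allowed
  }
  structure(list(name = name, background = bg, fixed_positions = fixed,
                 schemes = schemes),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design ", x$name, ">\n", sep = "")
  if (length(x$fixed_positions)) {
    for (p in names(x$fixed_positions))
      cat("  ", p, " restricted to {",
          paste(x$fixed_positions[[p]], collapse = ", "), "}\n", sep = "")
  } else cat("  all positions fully randomized\n")
  invisible(x)
}

#' Parse a displayed insert down to its aligned 9-mer core
#'
#' Displayed substrate cassettes carry the randomized nonamer between GPGG
#' spacers (His6-GPGG-core-GGPG-pIII). This parser accepts a bare 9-mer, a
#' flanked peptide, or DNA encoding either, and returns the core aligned
#' P5..P4'. DNA is detected by alphabet (A/C/G/T only, length a multiple
#' of 3) and translated with the standard genetic code.
#'
#' @param sequence Peptide or DNA string.
#' @param design Optional [build_library_design()]; when given, cores that
#'   violate a fixed-position constraint are flagged in `design_ok`.
#' @return List with `core9` (9-mer), `flank_ok` (were both GPGG/GGPG
#'   spacers found), and `design_ok` (TRUE, or FALSE when a fixed position
#'   holds a residue the library cannot produce; NA when no design given).
#' @examples
#' parse_displayed_insert("GPGGVVHVKSLETGGPG")$core9  # "VVHVKSLET"
#' @export
parse_displayed_insert <- function(sequence, design = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seqs <- toupper(gsub("\\s", "", sequence))
  if (nchar(seqs) == 0L) stop("empty sequence", call. = FALSE)
  chars <- strsplit(seqs, "")[[1]]
  if (all(chars %in% c("A", "C", "G", "T")) && nchar(seqs) %% 3L == 0L &&
      nchar(seqs) > 9L) {
    # DNA; peptides 9 long over {A,C,G,T} alone are ambiguous -> peptide
    pep <- as.character(Biostrings::translate(Biostrings::DNAString(seqs)))
    if (grepl("\\*", sub("\\*$", "", pep)))
      stop("internal stop codon in insert DNA", call. = FALSE)
    seqs <- sub("\\*$", "", pep)
    chars <- strsplit(seqs, "")[[1]]
  }
  if (!all(chars %in% AA_RESIDUES))
    stop("non-standard residue(s) in insert: ",
         paste(unique(chars[!chars %in% AA_RESIDUES]), collapse = ", "),
         call. = FALSE)
  flank_ok <- FALSE
  core <- seqs
  m <- regmatches(seqs, regexec("GPGG(.{9})GGPG", seqs))[[1]]
  if (length(m) == 2L) {
    core <- m[2]
    flank_ok <- TRUE
  }
  if (nchar(core) != 9L)
    stop("insert core is ", nchar(core), " residues, expected 9",
         call. = FALSE)
  design_ok <- NA
  if (!is.null(design)) {
    stopifnot(inherits(design, "library_design"))
    cc <- strsplit(core, "")[[1]]
    design_ok <- all(vapply(seq_len(9L), function(i)
      design$background[i, cc[i]] > 0, TRUE))
  }
  list(core9 = core, flank_ok = flank_ok, design_ok = design_ok)
}

#' Read selected clone peptides from FASTA or plain text
#'
#' Accepts a multi-FASTA file or a one-sequence-per-line text file of
#' selected clones (peptide or DNA, flanked or bare) and returns the
#' aligned 9-mer cores.
#'
#' @param path File path.
#' @param design Optional library design used to flag constraint
#'   violations (violating clones are dropped with a warning).
#' @return Character vector of 9-mer peptides.
#' @export
read_selected_clones <- function(path, design = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no sequences in ", path, call. = FALSE)
  if (startsWith(lines[[1]], ">")) {
    fa <- Biostrings::readBStringSet(path)
    seqs <- as.character(fa)
  } else {
    seqs <- trimws(lines)
  }
  parsed <- lapply(seqs, parse_displayed_insert, design = design)
  ok <- vapply(parsed, function(p) !isFALSE(p$design_ok), TRUE)
  if (!all(ok))
    warning(sum(!ok), " clone(s) violate the library's fixed-position ",
            "constraint and were dropped", call. = FALSE)
  unname(vapply(parsed[ok], `[[`, "", "core9"))
}
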