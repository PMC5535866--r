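# Seeded generators for every input the pipeline consumes. The selection
# model is deliberately minimal: per-phage elution is Bernoulli with
# probability logistic(b0 + b1 * PSSM score of the displayed 9-mer), the
# simplest monotone map from matrix score to per-round cleavage
# probability; between rounds the eluate is re-amplified to constant pool
# size by resampling with replacement.

#' Simulate a naive phage substrate library
#'
#' Draws i.i.d. 9-mer peptides, each position sampled independently from
#' the library design's amino-acid background (NNK statistics at random
#' positions, the fixed-residue pair at a constrained P1).
#'
#' @param design A [build_library_design()].
#' @param n Number of clones.
#' @param seed Integer seed (required: all generators are reproducible).
#' @return Character vector of n 9-mers.
#' @export
simulate_library <- function(design, n, seed) {
  stopifnot(inherits(design, "library_design"), n >= 1)
  set.seed(seed)
  cols <- vapply(seq_len(9L), function(i)
    sample(AA_RESIDUES, n, replace = TRUE, prob = design$background[i, ]),
    character(n))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  apply(cols, 1L, paste0, collapse = "")
}

#' Random ground-truth specificity matrix
#'
#' Generates a plausible protease specificity landscape for simulation:
#' most cells mildly positive or negative, with one or two strongly
#' preferred residues per position, normalized to the -5..+5 scale.
#' Masked cells (fixed positions of the design) are set to 0.
#'
#' @param design A [build_library_design()] giving the mask.
#' @param seed Integer seed.
#' @param n_strong Number of strongly preferred residues per position.
#' @return 9 x 20 normalized score matrix (rows [POSITION_LABELS]).
#' @export
random_truth_matrix <- function(design, seed, n_strong = 2L) {
  set.seed(seed)
  m <- matrix(rnorm(9L * 20L, 0, 1.2), 9L, 20L,
              dimnames = list(POSITION_LABELS, AA_RESIDUES))
  for (i in seq_len(9L)) {
    open <- which(design$background[i, ] > 0)
    pick <- sample(open, min(n_strong, length(open)))
    m[i, pick] <- m[i, pick] + runif(length(pick), 3, 5)
  }
  m[design$background == 0] <- 0
  5 * m / max(abs(m))
}

#' Simulate multi-round protease selection of a phage pool
#'
#' Each round, every phage in the pool is eluted (cleaved off its
#' support) with probability `plogis(b0 + b1 * s)`, where s is its 9-mer's
#' score under the ground-truth matrix. A no-protease control arm uses
#' score 0 for every phage, giving the per-round enrichment rate
#' (protease eluate / control eluate). The eluate is re-amplified back to
#' the pool size by resampling with replacement before the next round.
#' Optional increasing stringency lowers b0 by `stringency_step` each
#' round. After the last round, `clones_sequenced` survivors are sampled
#' for sequencing.
#'
#' @param pool Character vector of 9-mers (the naive library).
#' @param truth_matrix Normalized 9 x 20 ground-truth matrix.
#' @param rounds Number of selection rounds (default 3).
#' @param b0 Elution intercept on the logit scale (default -4): baseline
#'   per-round elution probability of a score-0 phage, plogis(-4) ~ 1.8%.
#' @param b1 Elution slope per score unit (default 0.5).
#' @param clones_sequenced Survivors sampled after the final round
#'   (default 75).
#' @param stringency_step Per-round decrement of b0 (default 0).
#' @param seed Integer seed.
#' @return List: `sequenced` (character vector), `rounds` (data.frame
#'   `round`, `eluted_with_protease`, `eluted_control`, `rate`,
#'   `mean_truth_score`), `final_pool`.
#' @export
simulate_selection <- function(pool, truth_matrix, rounds = 3L, b0 = -4,
                               b1 = 0.5, clones_sequenced = 75L,
                               stringency_step = 0, seed = 1L) {
  stopifnot(length(pool) > 0, rounds >= 1, clones_sequenced >= 1)
  set.seed(seed)
  n_pool <- length(pool)
  score_of <- function(peps) {
    chars <- matrix(unlist(strsplit(peps, ""), use.names = FALSE),
                    nrow = length(peps), ncol = 9L, byrow = TRUE)
    s <- numeric(length(peps))
    for (k in seq_len(9L))
      s <- s + truth_matrix[cbind(k, match(chars[, k], AA_RESIDUES))]
    s
  }
  current <- pool
  recs <- vector("list", rounds)
  eluate <- NULL
  for (r in seq_len(rounds)) {
    b0_r <- b0 - stringency_step * (r - 1L)
    s <- score_of(current)
    p_elute <- plogis(b0_r + b1 * s)
    eluted <- rbinom(length(current), 1L, p_elute) == 1L
    control <- sum(rbinom(length(current), 1L, plogis(b0_r)))
    if (!any(eluted))
      stop("selection extinct at round ", r, ": no phage eluted; use a ",
           "larger pool or weaker stringency", call. = FALSE)
    if (control == 0L) control <- 1L  # floor so the rate stays defined
    eluate <- current[eluted]
    recs[[r]] <- data.frame(round = r,
                            eluted_with_protease = sum(eluted),
                            eluted_control = control,
                            rate = enrichment_rate(sum(eluted), control),
                            mean_truth_score = mean(score_of(eluate)))
    current <- sample(eluate, n_pool, replace = TRUE)  # re-amplification
  }
  sequenced <- sample(eluate, min(clones_sequenced, length(eluate)),
                      replace = clones_sequenced > length(eluate))
  list(sequenced = sequenced, rounds = do.call(rbind, recs),
       final_pool = current)
}

#' Simulate a proteome with planted cleavage sites
#'
#' Generates random protein sequences (residues drawn uniformly, or from
#' `background_freqs`), embeds high-scoring 9-mer windows drawn from the
#' truth matrix at known P1 coordinates, and assigns each protein an
#' extracellular interval so the topology filter can be exercised. The
#' truth table records every planted site.
#'
#' @param truth_matrix Normalized 9 x 20 ground-truth matrix from which
#'   planted windows take each position's best residue.
#' @param n_proteins Number of proteins.
#' @param n_planted Number of proteins that receive one planted site.
#' @param length_range Protein length range (uniform integer draw).
#' @param ecd_fraction Fraction of each protein annotated extracellular,
#'   anchored at the N terminus (membrane-proximal tail intracellular).
#' @param plant_outside_ecd Indices (within the planted set) whose site is
#'   deliberately placed outside the ectodomain, for negative controls.
#' @param background_freqs Optional named residue frequency vector.
#' @param seed Integer seed.
#' @return List: `proteins` (named character vector), `topology`
#'   (data.frame `protein_id`, `start`, `end`), `truth` (data.frame
#'   `protein_id`, `p1_index`, `window`, `in_ecd`).
#' @export
simulate_proteome <- function(truth_matrix, n_proteins = 200L,
                              n_planted = 20L, length_range = c(120L, 600L),
                              ecd_fraction = 0.7,
                              plant_outside_ecd = integer(),
                              background_freqs = NULL, seed = 1L) {
  stopifnot(n_planted <= n_proteins, length_range[1] >= 30L)
  set.seed(seed)
  if (is.null(background_freqs))
    background_freqs <- setNames(rep(1 / 20, 20), AA_RESIDUES)
  # the consensus (per-position argmax) window of the truth matrix
  best_window <- paste0(AA_RESIDUES[apply(truth_matrix, 1L, which.max)],
                        collapse = "")
  ids <- sprintf("SYNP%04d", seq_len(n_proteins))
  lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                 replace = TRUE)
  proteins <- vapply(lens, function(L)
    paste0(sample(AA_RESIDUES, L, replace = TRUE, prob = background_freqs),
           collapse = ""), "")
  names(proteins) <- ids
  ecd_end <- pmax(20L, as.integer(floor(lens * ecd_fraction)))
  topology <- data.frame(protein_id = ids, start = 1L, end = ecd_end)
  planted_idx <- if (n_planted > 0) sample(n_proteins, n_planted)
                 else integer()
  truth <- data.frame(protein_id = character(), p1_index = integer(),
                      window = character(), in_ecd = logical())
  for (j in seq_along(planted_idx)) {
    i <- planted_idx[j]
    L <- lens[i]
    inside <- !(j %in% plant_outside_ecd)
    # choose P1 so the whole window fits; bond inside/outside the ECD
    lo <- 5L
    hi <- L - 4L
    if (inside) hi <- min(hi, ecd_end[i] - 1L)
    else lo <- max(lo, ecd_end[i] + 1L)
    if (lo > hi) stop("planted site does not fit protein ", ids[i],
                      call. = FALSE)
    p1 <- sample(seq(lo, hi), 1L)
    start <- p1 - 4L
    proteins[i] <- paste0(substr(proteins[i], 1L, start - 1L), best_window,
                          substr(proteins[i], start + 9L, L))
    truth <- rbind(truth, data.frame(protein_id = ids[i], p1_index = p1,
                                     window = best_window, in_ecd = inside))
  }
  list(proteins = proteins, topology = topology,
       truth = truth[order(truth$protein_id), , drop = FALSE])
}

#' Simulate phage-ELISA replicate readings for one site
#'
#' Untreated wells read around 1.0 absorbance unit; treated wells lose
#' the cleaved fraction. Gaussian well-to-well noise is added to both
#' arms and readings are floored just above zero.
#'
#' @param true_efficiency True percent cleavage (0-100).
#' @param noise_sd Well-to-well noise SD, in percent of the nominal
#'   untreated signal (default 2, i.e. 0.02 absorbance units).
#' @param replicates Replicates per arm (default 4: two independent
#'   experiments in duplicate).
#' @param seed Integer seed.
#' @param site_id,protease Labels carried into the output.
#' @return data.frame in [elisa_summary()] input layout (`site_id`,
#'   `protease`, `arm`, `replicate`, `a450`).
#' @export
simulate_elisa <- function(true_efficiency, noise_sd = 2,
                           replicates = 4L, seed = 1L,
                           site_id = "site", protease = "protease") {
  stopifnot(true_efficiency >= 0, true_efficiency <= 100, replicates >= 1)
  set.seed(seed)
  sd_abs <- noise_sd / 100
  untreated <- pmax(1e-6, 1.0 + rnorm(replicates, 0, sd_abs))
  treated <- pmax(0, untreated * (1 - true_efficiency / 100) +
                    rnorm(replicates, 0, sd_abs))
  data.frame(
    site_id = site_id, protease = protease,
    arm = rep(c("untreated", "treated"), each = replicates),
    replicate = rep(seq_len(replicates), 2L),
    a450 = c(untreated, treated),
    stringsAsFactors = FALSE)
}
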