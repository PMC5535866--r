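#' Rebuild a specificity matrix from sequenced clones
#'
#' Convenience wrapper for the profiling step: tally residues, score
#' against the design background, normalize.
#'
#' @param peptides Character vector of sequenced 9-mers.
#' @param design A [build_library_design()].
#' @param ... Passed to [normalize_matrix()] (`scope`, `mask_policy`).
#' @return A normalized [specificity_matrix()].
#' @export
profile_selection <- function(peptides, design, ...) {
  normalize_matrix(specificity_matrix(count_residues(peptides), design), ...)
}

#' Compare a recovered specificity matrix to the simulation truth
#'
#' Measures how well profiling recovered a known ground-truth matrix:
#' Spearman rank correlation over all unmasked cells, plus per-position
#' top-residue agreement restricted to strongly selected positions (those
#' whose best truth score reaches `strong_cutoff`).
#'
#' @param recovered Normalized [specificity_matrix()] (or bare 9 x 20
#'   matrix) rebuilt from sequenced clones.
#' @param truth 9 x 20 ground-truth normalized matrix.
#' @param mask Logical 9 x 20 matrix of unsamplable cells to drop; taken
#'   from `recovered` when it is a `specificity_matrix`.
#' @param strong_cutoff Truth score defining a strongly selected position
#'   (default 3).
#' @return List: `spearman`, `top1_agreement` (fraction, NA if no strong
#'   position), `n_strong_positions`, `n_cells`.
#' @export
recovery_stats <- function(recovered, truth, mask = NULL, strong_cutoff = 3) {
  if (inherits(recovered, "specificity_matrix")) {
    if (is.null(mask)) mask <- recovered$mask
    recovered <- recovered$normalized
  }
  if (is.null(mask)) mask <- matrix(FALSE, 9L, 20L)
  keep <- !mask
  rho <- cor(recovered[keep], truth[keep], method = "spearman")
  strong <- which(apply(truth, 1L, max) >= strong_cutoff)
  agree <- NA_real_
  if (length(strong)) {
    hits <- vapply(strong, function(i) {
      open <- which(!mask[i, ])
      open[which.max(truth[i, open])] == open[which.max(recovered[i, open])]
    }, TRUE)
    agree <- mean(hits)
  }
  list(spearman = rho, top1_agreement = agree,
       n_strong_positions = length(strong), n_cells = sum(keep))
}

#' Run the full pipeline on a simulated bundle
#'
#' End-to-end orchestration with a single seed: simulate a library and a
#' ground-truth protease, run the multi-round selection, profile the
#' sequenced clones into a normalized specificity matrix, simulate a
#' proteome with planted sites, scan it, filter hits to extracellular
#' bonds, simulate ELISA validation of the shortlisted sites, and write
#' every table plus a machine-readable run manifest. Identical config and
#' seed give byte-identical outputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param design_name Library design (default `"X4-X-X4"`).
#' @param pool_size Naive library size (default 10000).
#' @param rounds Selection rounds (default 3).
#' @param clones_sequenced Clones sequenced after the last round
#'   (default 75).
#' @param n_proteins,n_planted Proteome size and planted-site count.
#' @param threshold,top_n Scan threshold and truncation (defaults 10, 500).
#' @return Invisible list with the in-memory results (`matrix`,
#'   `rounds`, `predictions`, `shortlist`, `elisa`, `recovery`,
#'   `manifest_path`).
#' @export
run_pipeline <- function(out_dir, seed, design_name = "X4-X-X4",
                         pool_size = 10000L, rounds = 3L,
                         clones_sequenced = 75L, n_proteins = 100L,
                         n_planted = 10L, threshold = 10, top_n = 500L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 5L)
  design <- build_library_design(design_name)
  truth <- random_truth_matrix(design, seed = seeds[1])
  pool <- simulate_library(design, pool_size, seed = seeds[2])
  sel <- simulate_selection(pool, truth, rounds = rounds,
                            clones_sequenced = clones_sequenced,
                            seed = seeds[3])
  mat <- profile_selection(sel$sequenced, design)
  rec <- recovery_stats(mat, truth)

  prot <- simulate_proteome(truth, n_proteins = n_proteins,
                            n_planted = n_planted, seed = seeds[4])
  preds <- scan_proteome(prot$proteins, mat, threshold = threshold,
                         top_n = top_n)
  ann <- load_topology(prot$topology)
  sl <- shortlist(preds, ann, protease = "simulated")

  # ELISA: shortlisted planted sites cleave strongly, others weakly
  planted_key <- paste(prot$truth$protein_id, prot$truth$p1_index)
  elisa <- NULL
  if (nrow(sl$entries) > 0) {
    es <- derive_seeds(seeds[5], nrow(sl$entries) + 1L)
    for (i in seq_len(nrow(sl$entries))) {
      e <- sl$entries[i, ]
      true_eff <- if (paste(e$protein_id, e$p1_index) %in% planted_key)
        80 else 3
      elisa <- rbind(elisa, simulate_elisa(
        true_eff, seed = es[i],
        site_id = paste0(e$protein_id, ":", e$site_label),
        protease = "simulated"))
    }
    elisa <- rbind(elisa, simulate_elisa(
      2, seed = es[length(es)], site_id = "ctrl_neg", protease = "simulated"))
  }

  # artifacts
  paths <- c(
    clones = file.path(out_dir, "clones.txt"),
    rounds = file.path(out_dir, "rounds.tsv"),
    matrix_raw = file.path(out_dir, "matrix_raw.tsv"),
    matrix_norm = file.path(out_dir, "matrix_normalized.tsv"),
    proteome = file.path(out_dir, "proteome.fa"),
    topology = file.path(out_dir, "topology.tsv"),
    truth_sites = file.path(out_dir, "truth_sites.tsv"),
    predictions = file.path(out_dir, "predictions.tsv"),
    shortlist = file.path(out_dir, "shortlist.tsv"),
    elisa = file.path(out_dir, "elisa.csv"),
    validation = file.path(out_dir, "validation.tsv"))
  writeLines(sel$sequenced, paths["clones"])
  write_tsv <- function(df, p) utils::write.table(
    df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(fmt_num(sel$rounds), paths["rounds"])
  write_matrix_tsv(mat, paths["matrix_raw"], "scores")
  write_matrix_tsv(mat, paths["matrix_norm"], "normalized")
  writeLines(paste0(">", names(prot$proteins), "\n", prot$proteins),
             paths["proteome"])
  write_tsv(prot$topology, paths["topology"])
  write_tsv(prot$truth, paths["truth_sites"])
  write_tsv(fmt_num(preds), paths["predictions"])
  write_tsv(sl$entries, paths["shortlist"])
  validation <- NULL
  if (!is.null(elisa)) {
    utils::write.table(fmt_num(elisa), paths["elisa"], sep = ",",
                       quote = FALSE, row.names = FALSE)
    validation <- elisa_summary(elisa, control_site_id = "ctrl_neg")
    write_tsv(fmt_num(validation), paths["validation"])
  } else {
    paths <- paths[!names(paths) %in% c("elisa", "validation")]
  }

  manifest <- list(
    package = "phageprof",
    version = as.character(utils::packageVersion("phageprof")),
    seed = seed,
    parameters = list(design = design_name, pool_size = pool_size,
                      rounds = rounds, clones_sequenced = clones_sequenced,
                      n_proteins = n_proteins, n_planted = n_planted,
                      threshold = threshold, top_n = top_n),
    recovery = rec[c("spearman", "top1_agreement")],
    outputs = as.list(setNames(unname(tools::md5sum(paths)),
                               basename(paths))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(matrix = mat, truth = truth, rounds = sel$rounds,
                 predictions = preds, shortlist = sl, elisa = elisa,
                 validation = validation, recovery = rec,
                 manifest_path = manifest_path))
}

# fixed decimal text for numeric columns so rewritten tables are
# byte-stable across platforms
fmt_num <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.10g", df[[j]])
  df
}

# spawn reproducible per-stage seeds from one master seed (kept < 2^31)
derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}
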