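#' Phage-ELISA cleavage efficiency
#'
#' Fraction of immobilizable phage signal lost after protease treatment,
#' as a percentage: 100 * (A_untreated - A_treated) / A_untreated, where A
#' is the anti-phage ELISA absorbance at 450 nm. A fully cleaved display
#' gives ~100, an uncleaved one ~0; values are scale-invariant in the
#' absorbance units.
#'
#' @param a_untreated,a_treated Absorbance readings (untreated must be
#'   positive). Vectorized over replicate pairs.
#' @return Percent cleavage efficiency (Delta A / A).
#' @examples
#' cleavage_efficiency(1.0, 0.091)  # 90.9
#' @export
cleavage_efficiency <- function(a_untreated, a_treated) {
  if (any(a_untreated <= 0))
    stop("invalid measurement: untreated absorbance must be positive",
         call. = FALSE)
  100 * (a_untreated - a_treated) / a_untreated
}

#' Classify a site as efficiently cleaved
#'
#' A displayed site counts as efficiently cleaved when its mean Delta A/A
#' across replicates exceeds the threshold (strictly greater; a mean of
#' exactly 10 is not called cleaved).
#'
#' @param efficiencies Replicate Delta A/A percentages.
#' @param threshold Percent cutoff (default 10).
#' @return TRUE/FALSE.
#' @export
classify_cleaved <- function(efficiencies, threshold = 10) {
  stopifnot(length(efficiencies) >= 1L)
  mean(efficiencies) > threshold
}

#' Compare a site's cleavage to the negative control
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the site's
#' replicate efficiencies against the negative-control replicates, exact
#' for the small replicate numbers typical of phage ELISA.
#'
#' @param site_efficiencies,control_efficiencies Replicate Delta A/A
#'   values, at least 2 per group.
#' @return The two-sided p-value, or NA with a warning when either group
#'   has fewer than 2 replicates (not testable).
#' @examples
#' compare_to_control(c(60, 62, 65, 61), c(1, 2, 3, 2.5))  # 2/70
#' @export
compare_to_control <- function(site_efficiencies, control_efficiencies) {
  if (length(site_efficiencies) < 2L || length(control_efficiencies) < 2L) {
    warning("fewer than 2 replicates in a group; rank test not defined",
            call. = FALSE)
    return(NA_real_)
  }
  suppressWarnings(
    wilcox.test(site_efficiencies, control_efficiencies,
                alternative = "two.sided", exact = TRUE)$p.value)
}

#' Summarize an ELISA validation table
#'
#' Computes per-site mean Delta A/A, SEM (sd over sqrt of replicate
#' count), the efficiently-cleaved flag, and (when a control is present)
#' the Mann-Whitney p-value against it.
#'
#' @param records data.frame with columns `site_id`, `protease`, `arm`
#'   (`"treated"`/`"untreated"`), `replicate`, `a450` — or a path to such
#'   a CSV. Replicates are paired by the `replicate` column within each
#'   (site, protease).
#' @param control_site_id `site_id` of the negative control (e.g. a
#'   GGSGGSGGS display); NULL to skip significance testing.
#' @param threshold Percent cutoff for the cleaved flag (default 10).
#' @return data.frame: `site_id`, `protease`, `n_replicates`,
#'   `mean_da_over_a`, `sem`, `cleaved` (mean > threshold), `p_value`,
#'   `significant` (p < 0.05).
#' @export
elisa_summary <- function(records, control_site_id = NULL, threshold = 10) {
  df <- if (is.character(records)) {
    read.csv(records, stringsAsFactors = FALSE)
  } else as.data.frame(records)
  need <- c("site_id", "protease", "arm", "replicate", "a450")
  if (!all(need %in% names(df)))
    stop("ELISA records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  eff_by <- function(d) {
    u <- d[d$arm == "untreated", ]
    t <- d[d$arm == "treated", ]
    u <- u[order(u$replicate), ]
    t <- t[order(t$replicate), ]
    if (nrow(u) == 0L || nrow(t) == 0L || !identical(u$replicate, t$replicate))
      stop("unpaired treated/untreated replicates for site ",
           d$site_id[1], " / ", d$protease[1], call. = FALSE)
    cleavage_efficiency(u$a450, t$a450)
  }
  groups <- split(df, paste(df$site_id, df$protease, sep = "\r"))
  effs <- lapply(groups, eff_by)
  meta <- do.call(rbind, lapply(groups, function(d)
    d[1, c("site_id", "protease")]))
  ctrl <- NULL
  if (!is.null(control_site_id)) {
    ctrl_idx <- meta$site_id == control_site_id
    if (!any(ctrl_idx))
      stop("control site '", control_site_id, "' not in records",
           call. = FALSE)
    ctrl <- split(effs[ctrl_idx], meta$protease[ctrl_idx])
  }
  out <- data.frame(
    site_id = meta$site_id,
    protease = meta$protease,
    n_replicates = vapply(effs, length, 1L),
    mean_da_over_a = vapply(effs, mean, 1),
    sem = vapply(effs, function(e) sd(e) / sqrt(length(e)), 1),
    stringsAsFactors = FALSE)
  out$cleaved <- out$mean_da_over_a > threshold
  out$p_value <- NA_real_
  if (!is.null(ctrl)) {
    for (i in seq_len(nrow(out))) {
      if (out$site_id[i] == control_site_id) next
      ce <- ctrl[[out$protease[i]]]
      if (is.null(ce)) next
      out$p_value[i] <- compare_to_control(effs[[i]], ce[[1]])
    }
  }
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out <- out[order(out$protease, -out$mean_da_over_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-protease confirmation accounting
#'
#' Crosses a cleavage-efficiency table with the per-protease predicted
#' shortlist: for each protease, how many sites were predicted, how many
#' of those were efficiently cleaved (mean Delta A/A above threshold),
#' the confirmed fraction, and which cleaved sites were *not* predicted
#' for that protease (cross-protease "shared" cleavages).
#'
#' @param efficiency Data.frame with columns `site_id`, `protease`,
#'   `mean_da_over_a` (e.g. from [elisa_summary()], or a transcribed
#'   results table).
#' @param predicted Data.frame with columns `site_id`, `protease` listing
#'   which sites were predicted for which protease.
#' @param threshold Percent cutoff (default 10).
#' @param control_site_ids Site ids excluded from accounting (controls).
#' @return data.frame per protease: `protease`, `n_predicted`,
#'   `n_tested`, `n_cleaved` (predicted & cleaved), `fraction_confirmed`,
#'   `n_shared` (cleaved but not predicted for this protease), plus a
#'   `shared_sites` comma-joined column.
#' @export
confirmation_summary <- function(efficiency, predicted, threshold = 10,
                                 control_site_ids = character()) {
  eff <- as.data.frame(efficiency)
  prd <- as.data.frame(predicted)
  stopifnot(all(c("site_id", "protease", "mean_da_over_a") %in% names(eff)),
            all(c("site_id", "protease") %in% names(prd)))
  eff <- eff[!eff$site_id %in% control_site_ids, , drop = FALSE]
  proteases <- sort(unique(c(eff$protease, prd$protease)))
  rows <- lapply(proteases, function(pz) {
    pred_sites <- unique(prd$site_id[prd$protease == pz])
    tested <- eff[eff$protease == pz, , drop = FALSE]
    cleaved_sites <- tested$site_id[tested$mean_da_over_a > threshold]
    n_cleaved <- length(intersect(cleaved_sites, pred_sites))
    shared <- setdiff(cleaved_sites, pred_sites)
    data.frame(
      protease = pz,
      n_predicted = length(pred_sites),
      n_tested = nrow(tested),
      n_cleaved = n_cleaved,
      fraction_confirmed = if (length(pred_sites)) n_cleaved /
        length(pred_sites) else NA_real_,
      n_shared = length(shared),
      shared_sites = paste(sort(shared), collapse = ", "),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
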