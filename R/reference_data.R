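#' Curated HDM protease reference tables
#'
#' Bundled transcriptions of the published shortlist of predicted
#' cleavage sites for the house dust mite (HDM) protease allergens
#' Der p 1, Der p 3 and Der p 6 within the human cell surface proteome,
#' and of the phage-ELISA cleavage-efficiency summary for those sites.
#' They serve as worked inputs for the topology-filter and validation
#' accounting stages.
#'
#' `hdm_predicted_sites()` returns one row per (site, protease) pair:
#' `site_id`, `target` (protein name), `protein_id` (UniProt accession),
#' `protease`, `window` (9-mer P5..P4'), `p1_index`, `ecd_start`,
#' `ecd_end`. One site with a published cleavage-position *range* rather
#' than a single bond is transcribed with P1 at the nonamer's P1
#' position within that range.
#'
#' `hdm_elisa_efficiency()` returns `site_id`, `protease`, `window`,
#' `mean_da_over_a` (percent), `sem`, `predicted` (was the site predicted
#' for that protease, or only tested against it).
#'
#' @return A data.frame (see above).
#' @export
hdm_predicted_sites <- function() {
  path <- system.file("extdata", "hdm_predicted_sites.tsv",
                      package = "phageprof", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  # expand "Der p 1;Der p 3" rows to one row per protease
  idx <- rep(seq_len(nrow(df)),
             lengths(strsplit(df$proteases, ";", fixed = TRUE)))
  out <- df[idx, ]
  out$protease <- unlist(strsplit(df$proteases, ";", fixed = TRUE))
  out$proteases <- NULL
  out$name <- out$target  # display name picked up by shortlist()
  rownames(out) <- NULL
  out
}

#' @rdname hdm_predicted_sites
#' @export
hdm_elisa_efficiency <- function() {
  path <- system.file("extdata", "hdm_elisa_efficiency.tsv",
                      package = "phageprof", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$predicted <- df$predicted == "yes"
  df
}
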