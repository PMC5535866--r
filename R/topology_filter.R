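#' Load extracellular-domain annotations
#'
#' Reads a TSV with columns `protein_id`, `start`, `end` giving 1-based
#' inclusive extracellular intervals (ectodomains) per protein, e.g. from
#' curated topology records. Overlapping or adjacent intervals of the
#' same protein are merged; inverted intervals are an error reporting the
#' offending row.
#'
#' @param table Path to the TSV, or an equivalent data.frame.
#' @return Named list (by protein_id) of data.frames with columns `start`,
#'   `end` (merged, sorted, non-overlapping).
#' @examples
#' ann <- load_topology(data.frame(protein_id = "Q9NNX6",
#'                                 start = 59, end = 404))
#' @export
load_topology <- function(table) {
  df <- if (is.character(table)) {
    read.delim(table, stringsAsFactors = FALSE)
  } else as.data.frame(table)
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(df)))
    stop("topology table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(df$start > df$end | df$start < 1)
  if (length(bad))
    stop("invalid extracellular interval(s) at row(s): ",
         paste(bad, collapse = ", "), " (start > end or start < 1)",
         call. = FALSE)
  out <- lapply(split(df, df$protein_id), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start, end = d$end))
    data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
  })
  out[order(names(out))]
}

#' Is a predicted scissile bond extracellular?
#'
#' A predicted site passes the topology filter when the scissile bond is
#' solvent-exposed: both the P1 and the P1' residue must fall inside one
#' extracellular interval. The flanking recognition window may extend
#' beyond the ectodomain; only the cleaved bond itself must be inside.
#'
#' @param p1_index 1-based residue index of P1 (P1' is `p1_index + 1`).
#' @param intervals data.frame of `start`/`end` extracellular intervals
#'   for the protein (one element of [load_topology()]'s result), or NULL
#'   when the protein has no annotated ectodomain.
#' @return TRUE/FALSE.
#' @examples
#' ecd <- data.frame(start = 1, end = 46)
#' site_within_ecd(43, ecd)  # TRUE: bond 43-44 inside 1-46
#' site_within_ecd(46, ecd)  # FALSE: P1' = 47 outside
#' @export
site_within_ecd <- function(p1_index, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(FALSE)
  any(intervals$start <= p1_index & (p1_index + 1L) <= intervals$end)
}

#' Shortlist extracellular predictions and account for them
#'
#' Filters a ranked prediction table down to sites whose scissile bond is
#' extracellular, merges identical sites predicted for several proteases
#' into one entry carrying all labels, and reports the accounting a
#' screening campaign needs: how many sites survive, how many distinct
#' proteins they live on, and how many sites each protease contributes.
#'
#' Manual curation steps (privileging immune-related proteins, dropping
#' hypothetical/predicted entries) are not automated: `exclude_ids`
#' accepts an explicit drop list and the output carries an empty
#' `curation_note` column for the analyst.
#'
#' @param predictions data.frame with columns `protein_id`, `p1_index`,
#'   `window`, and either a `protease` column or a single `protease`
#'   argument; optional `name`, `score`.
#' @param annotations Result of [load_topology()]. Proteins absent from it
#'   are treated as having no ectodomain and are filtered out.
#' @param protease Protease label applied to all rows lacking one.
#' @param exclude_ids Protein ids to drop before filtering.
#' @return List with `entries` (one row per distinct site: `protein_id`,
#'   `name`, `proteases` (comma-joined), `p1_index`, `site_label`,
#'   `window`, `ecd_start`, `ecd_end`, `curation_note`) and `summary`
#'   (list: `n_sites`, `n_proteins`, `per_protease` named count vector).
#' @export
shortlist <- function(predictions, annotations, protease = NULL,
                      exclude_ids = character()) {
  pr <- as.data.frame(predictions)
  need <- c("protein_id", "p1_index", "window")
  if (!all(need %in% names(pr)))
    stop("predictions need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"protease" %in% names(pr)) {
    if (is.null(protease))
      stop("no 'protease' column and no 'protease' argument", call. = FALSE)
    pr$protease <- protease
  }
  if (!"name" %in% names(pr)) pr$name <- pr$protein_id
  pr <- pr[!pr$protein_id %in% exclude_ids, , drop = FALSE]

  keep <- vapply(seq_len(nrow(pr)), function(i)
    site_within_ecd(pr$p1_index[i], annotations[[pr$protein_id[i]]]), TRUE)
  pr <- pr[keep, , drop = FALSE]

  if (nrow(pr) == 0L) {
    entries <- data.frame(protein_id = character(), name = character(),
                          proteases = character(), p1_index = integer(),
                          site_label = character(), window = character(),
                          ecd_start = integer(), ecd_end = integer(),
                          curation_note = character(),
                          stringsAsFactors = FALSE)
    return(list(entries = entries,
                summary = list(n_sites = 0L, n_proteins = 0L,
                               per_protease = integer(0))))
  }

  key <- paste(pr$protein_id, pr$p1_index, sep = "@")
  entries <- do.call(rbind, lapply(split(pr, key), function(d) {
    iv <- annotations[[d$protein_id[1]]]
    hit <- iv[iv$start <= d$p1_index[1] & d$p1_index[1] + 1L <= iv$end, ][1, ]
    data.frame(protein_id = d$protein_id[1], name = d$name[1],
               proteases = paste(sort(unique(d$protease)), collapse = ", "),
               p1_index = d$p1_index[1],
               site_label = paste0(d$p1_index[1], "-", d$p1_index[1] + 1L),
               window = d$window[1],
               ecd_start = hit$start, ecd_end = hit$end,
               curation_note = "", stringsAsFactors = FALSE)
  }))
  entries <- entries[order(entries$protein_id, entries$p1_index), ,
                     drop = FALSE]
  rownames(entries) <- NULL

  per_protease <- sort(table(unique(pr[c("protein_id", "p1_index",
                                         "protease")])$protease),
                       decreasing = TRUE)
  list(entries = entries,
       summary = list(n_sites = nrow(entries),
                      n_proteins = length(unique(entries$protein_id)),
                      per_protease = c(per_protease)))
}
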