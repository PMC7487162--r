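#' Screen a proteome for candidate SLC transporters
#'
#' Stage 1 of the pipeline. A protein becomes a candidate when at least
#' one family profile-HMM hit reaches the significance threshold (default
#' E-value 0.01, applied across the pooled family profiles). The
#' best-scoring profile's family is recorded for diagnostics only: the
#' final family label always comes from the reciprocal-BLAST stage.
#'
#' @param hmm_hits data.frame as returned by [read_hmmer_tbl()]
#'   (`target_id`, `profile_family`, `evalue`, `score`).
#' @param proteome named character vector `gene_id -> sequence` (one
#'   longest isoform per gene).
#' @param threshold maximum full-sequence E-value (default 0.01).
#' @return data.frame with one row per candidate: `gene_id`,
#'   `best_profile_family`, `best_evalue`, `length`, sorted by gene id.
#' @export
screen_candidates <- function(hmm_hits, proteome, threshold = 0.01) {
  stopifnot(is.character(proteome), !is.null(names(proteome)))
  absent <- setdiff(unique(hmm_hits$target_id), names(proteome))
  if (length(absent) > 0L) {
    stop(sprintf("HMM hit target(s) absent from proteome: %s",
                 paste(utils::head(absent, 10L), collapse = ", ")),
         call. = FALSE)
  }
  keep <- hmm_hits$evalue <= threshold
  hits <- hmm_hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(gene_id = character(0),
                      best_profile_family = character(0),
                      best_evalue = numeric(0), length = integer(0)))
  }
  # Best hit per target: minimum E-value; ties broken by the
  # lexicographically smallest family code.
  ord <- order(hits$target_id, hits$evalue, hits$profile_family,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$target_id), , drop = FALSE]
  out <- data.frame(gene_id = best$target_id,
                    best_profile_family = best$profile_family,
                    best_evalue = best$evalue,
                    length = unname(nchar(proteome[best$target_id])),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
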