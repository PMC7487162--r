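#' Run the full SLC identification pipeline on one target species
#'
#' Chains the three stages for a single search against one model-species
#' reference: profile-HMM candidate screening, reciprocal-BLAST family
#' assignment, and the structural length/TM filters. Candidates without
#' any BLAST hit are dropped as non-SLC (and counted in the summary);
#' candidates failing the BLAST criteria are kept as "Unsorted" but never
#' enter family counts; family-assigned candidates failing a structural
#' filter are recorded in the verdict table and excluded from counts.
#'
#' @param proteome named character vector `gene_id -> sequence` for the
#'   target species (one longest isoform per gene).
#' @param hmm_hits data.frame from [read_hmmer_tbl()].
#' @param blast_hits ranked data.frame from [read_blast_tabular()] (the
#'   candidates BLASTed back against the model proteome).
#' @param subject_families named character vector `model gene -> family`.
#' @param stats `slc_family_stats` table from [family_profile_stats()].
#' @param tm_counts optional named vector of external TM predictions for
#'   the target proteome; the hydropathy fallback is used where absent.
#' @param screen_threshold HMM E-value cutoff (default 0.01).
#' @param species label for the target species.
#' @return object of class `slc_result`: list with `species`,
#'   `candidates`, `assignments` (post-filter labels; rejected genes
#'   dropped), `verdicts`, `family_counts` (named integer vector),
#'   `n_unsorted`, `n_rejected`, `n_no_hit`, `total_slc`.
#' @export
slc_identify <- function(proteome, hmm_hits, blast_hits, subject_families,
                         stats, tm_counts = NULL, screen_threshold = 0.01,
                         species = "target") {
  candidates <- screen_candidates(hmm_hits, proteome, screen_threshold)
  with_hits <- candidates$gene_id %in% blast_hits$query_id
  if (any(!with_hits)) {
    message(sprintf("%d candidate(s) without reciprocal BLAST hits dropped as non-SLC",
                    sum(!with_hits)))
  }
  hits <- blast_hits[blast_hits$query_id %in% candidates$gene_id, ,
                     drop = FALSE]
  fam_sizes <- table(subject_families)
  fam_sizes <- stats::setNames(as.integer(fam_sizes), names(fam_sizes))
  if (nrow(hits) > 0L) {
    assignments <- classify_candidates(hits, subject_families, fam_sizes)
  } else {
    assignments <- data.frame(gene_id = character(0), label = character(0),
                              rule = character(0), top_identity = numeric(0),
                              top_evalue = numeric(0),
                              top5_families = character(0))
  }
  verdicts <- structural_filter(assignments, stats, proteome, tm_counts)
  rejected <- verdicts$gene_id[!verdicts$final_pass]
  final <- assignments[!(assignments$gene_id %in% rejected), , drop = FALSE]
  sorted <- final[final$label != "Unsorted", , drop = FALSE]
  counts <- table(factor(sorted$label, levels = order_families(
    unique(c(stats$family, sorted$label)))))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(species = species,
                 candidates = candidates,
                 assignments = final,
                 verdicts = verdicts,
                 family_counts = counts,
                 n_unsorted = sum(final$label == "Unsorted"),
                 n_rejected = length(rejected),
                 n_no_hit = sum(!with_hits),
                 total_slc = nrow(sorted)),
            class = "slc_result")
}

#' @export
print.slc_result <- function(x, ...) {
  cat(sprintf("SLC identification for '%s'\n", x$species))
  cat(sprintf("  candidates screened: %d\n", nrow(x$candidates)))
  cat(sprintf("  sorted into families: %d (%d families)\n",
              x$total_slc, sum(x$family_counts > 0)))
  cat(sprintf("  Unsorted: %d; rejected by structural filters: %d; no BLAST hit: %d\n",
              x$n_unsorted, x$n_rejected, x$n_no_hit))
  invisible(x)
}

#' @export
summary.slc_result <- function(object, ...) {
  cnt <- object$family_counts
  data.frame(family = names(cnt), count = unname(cnt),
             stringsAsFactors = FALSE)
}
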