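#' Assign candidates to SLC families by reciprocal BLAST
#'
#' Stage 2 of the pipeline. Each candidate was BLASTed back against the
#' model-species proteome; the ranked hits decide its family. With F the
#' family of the top-ranked hit, a candidate is assigned to F when all of
#' the following hold ("all criteria"):
#'
#' 1. the top hit is a member of F (true by construction);
#' 2. at least four of the top five hits belong to F — or, when F has
#'    fewer than five curated members in total, every member of F appears
#'    among the top five ("small family"); when fewer than five hits
#'    exist at all, all of them must belong to F;
#' 3. the top hit's percent identity exceeds 20, the conventional floor
#'    for SLC family membership.
#'
#' Failing that, the candidate is still assigned to F when the top hit is
#' overwhelmingly more significant than the runner-up: the ratio of the
#' second E-value to the first exceeds 1e30 (a top E-value of exactly 0
#' with a nonzero runner-up counts as infinite fold change). A candidate
#' with a single hit fires the override when its identity exceeds 20%.
#' Everything else is labelled "Unsorted".
#'
#' @param ranked_hits data.frame of BLAST hits with a `rank` column, as
#'   returned by [read_blast_tabular()] or [rank_blast_hits()]; may cover
#'   many queries.
#' @param subject_families named character vector `subject_id -> family
#'   code` for the model-species proteins; every subject that appears in
#'   the hits must be mapped.
#' @param family_sizes named integer vector `family -> total curated
#'   members` (used by the small-family clause). Families absent from it
#'   are treated as having >= 5 members.
#' @param identity_min criterion-3 floor on top-hit percent identity
#'   (default 20; the top hit must exceed it strictly).
#' @param fold_change override threshold on the runner-up/top E-value
#'   ratio (default 1e30).
#' @return data.frame with one row per query: `gene_id`, `label` (family
#'   code or "Unsorted"), `rule` (one of `ALL_CRITERIA`, `SMALL_FAMILY`,
#'   `OVERWHELMING`, `UNSORTED`), `top_identity`, `top_evalue`,
#'   `top5_families` (comma-joined evidence).
#' @export
classify_candidates <- function(ranked_hits, subject_families,
                                family_sizes = integer(0),
                                identity_min = 20, fold_change = 1e30) {
  if (nrow(ranked_hits) == 0L) {
    stop("empty hit table: candidates without BLAST hits are dropped by the caller",
         call. = FALSE)
  }
  unmapped <- setdiff(unique(ranked_hits$subject_id), names(subject_families))
  if (length(unmapped) > 0L) {
    stop(sprintf("subject id(s) not mapped to a family: %s",
                 paste(utils::head(unmapped, 10L), collapse = ", ")),
         call. = FALSE)
  }
  queries <- unique(ranked_hits$query_id)
  per_query <- split(ranked_hits, factor(ranked_hits$query_id,
                                         levels = queries))
  rows <- lapply(queries, function(q) {
    h <- per_query[[q]]
    h <- h[order(h$rank), , drop = FALSE]
    classify_one(q, h, subject_families, family_sizes, identity_min,
                 fold_change)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Decision logic for a single query's ranked hits.
classify_one <- function(query, h, subject_families, family_sizes,
                         identity_min, fold_change) {
  fams <- unname(subject_families[h$subject_id])
  top5 <- utils::head(fams, 5L)
  fam_top <- fams[1L]
  n <- nrow(h)
  identity_ok <- h$percent_identity[1L] > identity_min

  fam_size <- if (fam_top %in% names(family_sizes)) {
    family_sizes[[fam_top]]
  } else {
    Inf
  }

  rule <- NA_character_
  if (is.finite(fam_size) && fam_size < 5) {
    # Small-family clause: every curated member of F must show up in the
    # top five subjects.
    members_seen <- length(unique(h$subject_id[utils::head(seq_len(n), 5L)][
      top5 == fam_top]))
    if (members_seen >= fam_size && identity_ok) rule <- "SMALL_FAMILY"
  } else if (n >= 5L) {
    if (sum(top5 == fam_top) >= 4L && identity_ok) rule <- "ALL_CRITERIA"
  } else {
    # Fewer than five hits exist: all of them must belong to F.
    if (all(fams == fam_top) && identity_ok) rule <- "ALL_CRITERIA"
  }

  if (is.na(rule)) {
    e1 <- h$evalue[1L]
    if (n == 1L) {
      if (identity_ok) rule <- "OVERWHELMING"
    } else {
      e2 <- h$evalue[2L]
      fires <- if (e1 == 0) e2 > 0 else (e2 / e1) > fold_change
      if (fires) rule <- "OVERWHELMING"
    }
  }

  label <- if (is.na(rule)) "Unsorted" else fam_top
  if (is.na(rule)) rule <- "UNSORTED"
  data.frame(gene_id = query, label = label, rule = rule,
             top_identity = h$percent_identity[1L], top_evalue = h$evalue[1L],
             top5_families = paste(top5, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Write an assignments table
#'
#' @param assignments data.frame from [classify_candidates()].
#' @param path file path (TSV with header).
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
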