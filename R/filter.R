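#' Structural plausibility filters
#'
#' Stage 3 of the pipeline. A family-assigned candidate is kept only if
#' its polypeptide length falls inside the family's acceptance window
#' (between two thirds of the curated minimum and four thirds of the
#' curated maximum, boundaries inclusive) and it has at least the
#' family's minimum number of transmembrane segments (half the lowest
#' count observed among curated members, rounded down). A TM threshold of
#' 0 makes that filter inert.
#'
#' @param length polypeptide length(s) in residues.
#' @param stats either a single-family row of a `slc_family_stats` table
#'   or the whole table plus a `family` argument.
#' @param family family code(s) used to look rows up in `stats`.
#' @return logical vector.
#' @examples
#' st <- data.frame(family = "SLC2", accept_lo = 200L, accept_hi = 800L,
#'                  tm_threshold = 5L)
#' length_filter(c(199, 200, 800, 801), st, "SLC2")
#' tm_filter(c(4, 5), st, "SLC2")
#' @export
length_filter <- function(length, stats, family = stats$family) {
  idx <- match(family, stats$family)
  if (anyNA(idx)) {
    stop(sprintf("family without statistics: %s",
                 paste(unique(family[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  length >= stats$accept_lo[idx] & length <= stats$accept_hi[idx]
}

#' @rdname length_filter
#' @param tm_count predicted transmembrane-segment count(s).
#' @export
tm_filter <- function(tm_count, stats, family = stats$family) {
  idx <- match(family, stats$family)
  if (anyNA(idx)) {
    stop(sprintf("family without statistics: %s",
                 paste(unique(family[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  tm_count >= stats$tm_threshold[idx]
}

# Kyte-Doolittle hydropathy values.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

#' Hydropathy-based transmembrane segment count
#'
#' A deterministic stand-in for an external transmembrane predictor, for
#' use when predictor output is not supplied: Kyte-Doolittle hydropathy
#' averaged over a sliding window of 19 residues; a TM segment is a
#' maximal run of window centers whose mean hydropathy is at least 1.6;
#' runs separated by fewer than 5 residues are merged. Sequences shorter
#' than the window have no complete window and count 0.
#'
#' @param sequence amino-acid string (20-letter alphabet plus X; X scores
#'   0).
#' @param window sliding-window width in residues (default 19, the
#'   canonical helix-spanning width).
#' @param cutoff mean-hydropathy threshold for a window center (default
#'   1.6).
#' @param merge_gap runs of qualifying centers separated by fewer than
#'   this many residues are merged (default 5).
#' @return non-negative integer segment count.
#' @examples
#' fallback_tm_count(strrep("G", 200))  # hydrophilic, 0 segments
#' @export
fallback_tm_count <- function(sequence, window = 19L, cutoff = 1.6,
                              merge_gap = 5L) {
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(aa)
  if (n < window) return(0L)
  vals <- KD_SCALE[aa]
  vals[is.na(vals)] <- 0
  win_means <- (stats::filter(vals, rep(1, window), sides = 2L)) / window
  centers <- which(!is.na(win_means) & win_means >= cutoff)
  if (length(centers) == 0L) return(0L)
  # Split qualifying centers into runs; adjacent runs with fewer than
  # merge_gap intervening residues count as one segment.
  gaps <- diff(centers) - 1L
  sum(gaps >= merge_gap) + 1L
}

#' Apply the structural filters to an assignments table
#'
#' Rejected genes keep their family label in the audit trail (the verdict
#' table) but are excluded from downstream family counts. TM counts are
#' taken from `tm_counts` when provided and otherwise computed with
#' [fallback_tm_count()] from `proteome`; the provenance of each count is
#' recorded.
#'
#' @param assignments data.frame from [classify_candidates()]; only rows
#'   with a family label (not "Unsorted") are filtered.
#' @param stats `slc_family_stats` table.
#' @param proteome named character vector `gene_id -> sequence`.
#' @param tm_counts optional named integer vector `gene_id -> count` from
#'   an external predictor.
#' @return data.frame with columns `gene_id`, `family`, `length`,
#'   `length_pass`, `tm_count_used`, `tm_source`, `tm_pass`, `final_pass`.
#' @export
structural_filter <- function(assignments, stats, proteome,
                              tm_counts = NULL) {
  fam_rows <- assignments[assignments$label != "Unsorted", , drop = FALSE]
  if (nrow(fam_rows) == 0L) {
    return(data.frame(gene_id = character(0), family = character(0),
                      length = integer(0), length_pass = logical(0),
                      tm_count_used = integer(0), tm_source = character(0),
                      tm_pass = logical(0), final_pass = logical(0)))
  }
  absent <- setdiff(fam_rows$gene_id, names(proteome))
  if (length(absent) > 0L) {
    stop(sprintf("assigned gene(s) absent from proteome: %s",
                 paste(utils::head(absent, 10L), collapse = ", ")),
         call. = FALSE)
  }
  len <- unname(nchar(proteome[fam_rows$gene_id]))
  have_ext <- !is.null(tm_counts) & fam_rows$gene_id %in% names(tm_counts)
  tm_used <- integer(nrow(fam_rows))
  tm_used[have_ext] <- as.integer(tm_counts[fam_rows$gene_id[have_ext]])
  if (any(!have_ext)) {
    tm_used[!have_ext] <- vapply(proteome[fam_rows$gene_id[!have_ext]],
                                 fallback_tm_count, integer(1))
  }
  lp <- length_filter(len, stats, fam_rows$label)
  tp <- tm_filter(tm_used, stats, fam_rows$label)
  data.frame(gene_id = fam_rows$gene_id, family = fam_rows$label,
             length = len, length_pass = lp, tm_count_used = tm_used,
             tm_source = ifelse(have_ext, "external", "hydropathy"),
             tm_pass = tp, final_pass = lp & tp,
             stringsAsFactors = FALSE, row.names = NULL)
}
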