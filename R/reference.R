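#' Load a family-labelled SLC reference set
#'
#' Builds the curated model-species reference used throughout the pipeline:
#' every protein carries an SLC family label, and the per-family length and
#' transmembrane statistics derived from it drive the structural filters.
#' Families known to cross-react with non-transporter enzymes can be
#' excluded up front; by default the SLC3 family is dropped because it is
#' closely homologous to a group of insect alpha-glucosidases.
#'
#' @param fasta path to a multi-FASTA of curated protein sequences, or a
#'   named character vector of sequences (names are gene ids).
#' @param family_map a data.frame with columns `gene_id` and `family`
#'   (codes like "SLC2"), or a named character vector `gene_id -> family`.
#' @param excluded character vector of family codes to drop (default
#'   `"SLC3"`). Use `character(0)` to keep everything.
#' @param species free-text label for the model species.
#'
#' @return An object of class `slc_reference`: a list with `species`,
#'   `entries` (data.frame `gene_id`, `family`, `length`), `sequences`
#'   (named character vector) and `excluded`.
#'
#' @examples
#' seqs <- c(g1 = "MKTLLVA", g2 = "MKWAAAG", g3 = "MAVLLPR")
#' fam <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                   family = c("SLC2", "SLC2", "SLC7"))
#' ref <- slc_reference(seqs, fam, excluded = character(0))
#' ref
#' @export
slc_reference <- function(fasta, family_map, excluded = "SLC3",
                          species = "model") {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    read_fasta(fasta)
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    fasta
  } else {
    stop("'fasta' must be a FASTA file path or a named character vector",
         call. = FALSE)
  }
  if (is.data.frame(family_map)) {
    stopifnot(all(c("gene_id", "family") %in% names(family_map)))
    fmap <- stats::setNames(as.character(family_map$family),
                            as.character(family_map$gene_id))
  } else {
    fmap <- family_map
  }
  assert_family_codes(fmap)
  if (length(excluded) > 0L) assert_family_codes(excluded, "excluded family")

  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene id(s) in reference: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(ids, names(fmap))
  if (length(missing) > 0L) {
    stop(sprintf("reference id(s) missing from family map: %s",
                 paste(utils::head(missing, 10L), collapse = ", ")),
         call. = FALSE)
  }
  assert_aa_sequences(seqs, ids)

  fam <- unname(fmap[ids])
  keep <- !(fam %in% excluded)
  entries <- data.frame(gene_id = ids[keep], family = fam[keep],
                        length = nchar(seqs[keep]),
                        stringsAsFactors = FALSE, row.names = NULL)
  obj <- structure(list(species = species,
                        entries = entries,
                        sequences = seqs[keep],
                        excluded = excluded),
                   class = "slc_reference")
  message(sprintf("reference '%s': %d entries in %d families (%d excluded by family filter)",
                  species, nrow(entries), length(unique(entries$family)),
                  sum(!keep)))
  obj
}

#' @export
print.slc_reference <- function(x, ...) {
  cat(sprintf("SLC reference set '%s': %d proteins, %d families\n",
              x$species, nrow(x$entries), length(unique(x$entries$family))))
  if (length(x$excluded) > 0L)
    cat("  excluded families:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Per-family length bounds and acceptance windows
#'
#' Computes, for each family over the union of one or two reference sets,
#' the minimum and maximum curated protein length and the acceptance
#' window used by the length filter: proteins shorter than the family
#' minimum by more than one third, or longer than the maximum by more than
#' one third, are rejected. The window is
#' `[floor((2/3) * min_len), ceiling((4/3) * max_len)]`, boundaries
#' inclusive, so curated sequences always pass their own family's filter.
#'
#' @param ref an [slc_reference()] object.
#' @param extra optional second `slc_reference` (e.g. the second model
#'   species); bounds are taken over the union. A family present in only
#'   one set uses that set's statistics alone.
#' @return data.frame with columns `family`, `n_seqs`, `min_len`,
#'   `max_len`, `accept_lo`, `accept_hi`, ordered by family index.
#' @examples
#' seqs <- c(a = strrep("M", 400), b = strrep("M", 600))
#' ref <- slc_reference(seqs, c(a = "SLC2", b = "SLC2"),
#'                      excluded = character(0))
#' compute_length_bounds(ref)  # window [266, 800]
#' @export
compute_length_bounds <- function(ref, extra = NULL) {
  stopifnot(inherits(ref, "slc_reference"))
  entries <- ref$entries
  if (!is.null(extra)) {
    stopifnot(inherits(extra, "slc_reference"))
    entries <- rbind(entries, extra$entries)
    only <- setdiff(union(ref$entries$family, extra$entries$family),
                    intersect(ref$entries$family, extra$entries$family))
    if (length(only) > 0L)
      message(sprintf("%d family(ies) present in one reference set only: %s",
                      length(only), paste(order_families(only), collapse = ", ")))
  }
  if (nrow(entries) == 0L)
    return(data.frame(family = character(0), n_seqs = integer(0),
                      min_len = integer(0), max_len = integer(0),
                      accept_lo = integer(0), accept_hi = integer(0)))
  sp <- split(entries$length, entries$family)
  fams <- order_families(names(sp))
  mn <- vapply(sp[fams], min, integer(1))
  mx <- vapply(sp[fams], max, integer(1))
  data.frame(family = fams,
             n_seqs = vapply(sp[fams], length, integer(1)),
             min_len = unname(mn), max_len = unname(mx),
             accept_lo = as.integer(floor(2 / 3 * mn)),
             accept_hi = as.integer(ceiling(4 / 3 * mx)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-family transmembrane-domain thresholds
#'
#' The structural TM filter requires a candidate to have at least half as
#' many predicted transmembrane segments as the least TM-rich curated
#' member of its family: `tm_threshold = floor(min(observed) / 2)`. A
#' threshold of 0 makes the filter inert for that family.
#'
#' @param ref an [slc_reference()] object (or the union via `extra`).
#' @param tm_counts named integer vector `gene_id -> TM count` covering the
#'   reference genes; genes absent from it are skipped with a message.
#' @param extra optional second `slc_reference`.
#' @return data.frame with columns `family`, `tm_min_observed`,
#'   `tm_threshold`.
#' @examples
#' seqs <- c(a = "MKT", b = "MKW", c = "MAV")
#' ref <- slc_reference(seqs, c(a = "SLC2", b = "SLC2", c = "SLC2"),
#'                      excluded = character(0))
#' compute_tm_thresholds(ref, c(a = 12, b = 12, c = 10))  # threshold 5
#' @export
compute_tm_thresholds <- function(ref, tm_counts, extra = NULL) {
  stopifnot(inherits(ref, "slc_reference"))
  entries <- ref$entries
  if (!is.null(extra)) entries <- rbind(entries, extra$entries)
  if (any(tm_counts < 0)) stop("negative TM count", call. = FALSE)
  covered <- entries$gene_id %in% names(tm_counts)
  if (any(!covered))
    message(sprintf("%d reference gene(s) without TM counts skipped",
                    sum(!covered)))
  fams <- order_families(unique(entries$family))
  ent <- entries[covered, , drop = FALSE]
  out <- data.frame(family = fams, tm_min_observed = NA_integer_,
                    tm_threshold = 0L, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (i in seq_along(fams)) {
    cnt <- tm_counts[ent$gene_id[ent$family == fams[i]]]
    if (length(cnt) == 0L) {
      warning(sprintf("family %s has no TM-covered genes; threshold set to 0",
                      fams[i]), call. = FALSE)
    } else {
      out$tm_min_observed[i] <- as.integer(min(cnt))
      out$tm_threshold[i] <- as.integer(floor(min(cnt) / 2))
    }
  }
  out
}

#' Combined per-family acceptance statistics
#'
#' Convenience wrapper joining [compute_length_bounds()] and
#' [compute_tm_thresholds()] into the single per-family statistics table
#' consumed by the structural filters.
#'
#' @inheritParams compute_tm_thresholds
#' @return data.frame of class `slc_family_stats` with columns `family`,
#'   `n_seqs`, `min_len`, `max_len`, `accept_lo`, `accept_hi`,
#'   `tm_min_observed`, `tm_threshold`.
#' @export
family_profile_stats <- function(ref, tm_counts, extra = NULL) {
  len <- compute_length_bounds(ref, extra)
  tm <- compute_tm_thresholds(ref, tm_counts, extra)
  out <- merge(len, tm, by = "family", sort = FALSE)
  out <- out[order(family_index(out$family)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("slc_family_stats", "data.frame")
  out
}

#' Write / read the per-family statistics table
#'
#' Serialized as a plain TSV with a header row so that the same statistics
#' can be reused across target species without recomputation.
#'
#' @param stats a `slc_family_stats` data.frame.
#' @param path file path.
#' @return `read_family_stats` returns the `slc_family_stats` data.frame.
#' @export
write_family_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_family_stats
#' @export
read_family_stats <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_family_codes(out$family)
  class(out) <- c("slc_family_stats", "data.frame")
  out
}
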