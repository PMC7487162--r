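#' Merge assignments from the two model-species searches
#'
#' A gene found in either the human-reference or the fly-reference search
#' is a candidate SLC for that species, so the merge takes the union of
#' gene ids. When both searches assign a family and they agree, that
#' family stands; when they disagree, the assignment whose top hit has
#' the smaller E-value wins (exact ties go to the first argument, by
#' convention the human reference, on curation-quality grounds) and the
#' conflict is flagged. A family label always beats "Unsorted".
#'
#' @param a,b assignment data.frames from [classify_candidates()] (the
#'   convention is `a` = human-reference search, `b` = fly-reference).
#' @return merged assignments data.frame with an extra `provenance`
#'   column (`"a"`, `"b"`, `"both"`) and logical `conflict`.
#' @export
merge_assignments <- function(a, b) {
  if (nrow(a) == 0L && nrow(b) == 0L) {
    out <- data.frame(gene_id = character(0), label = character(0),
                      rule = character(0), top_identity = numeric(0),
                      top_evalue = numeric(0), top5_families = character(0))
    out$provenance <- character(0)
    out$conflict <- logical(0)
    return(out)
  }
  ids <- sort(union(a$gene_id, b$gene_id))
  ia <- match(ids, a$gene_id)
  ib <- match(ids, b$gene_id)
  rows <- lapply(seq_along(ids), function(i) {
    ra <- if (!is.na(ia[i])) a[ia[i], , drop = FALSE] else NULL
    rb <- if (!is.na(ib[i])) b[ib[i], , drop = FALSE] else NULL
    if (is.null(rb)) {
      out <- ra; out$provenance <- "a"; out$conflict <- FALSE
    } else if (is.null(ra)) {
      out <- rb; out$provenance <- "b"; out$conflict <- FALSE
    } else {
      conflict <- FALSE
      if (ra$label == rb$label) {
        out <- if (ra$top_evalue <= rb$top_evalue) ra else rb
      } else if (rb$label == "Unsorted") {
        out <- ra
      } else if (ra$label == "Unsorted") {
        out <- rb
      } else {
        conflict <- TRUE
        out <- if (rb$top_evalue < ra$top_evalue) rb else ra
      }
      out$provenance <- "both"; out$conflict <- conflict
    }
    out
  })
  out <- do.call(rbind, rows)
  nconf <- sum(out$conflict)
  if (nconf > 0L)
    message(sprintf("%d dual-search family conflict(s) resolved by top-hit E-value",
                    nconf))
  rownames(out) <- NULL
  out
}

#' Drop species with low proteome completeness
#'
#' Fragmented gene sets bias family counts in both directions, so species
#' whose BUSCO completeness score falls below the cutoff (strictly less
#' than; default 75%) are removed before any comparative analysis.
#'
#' @param species_results named list of per-species result objects (any
#'   list-like value), named by species id.
#' @param busco_scores named numeric vector `species -> completeness %`.
#' @param cutoff completeness percentage (default 75).
#' @return the filtered list; removed species are reported by message.
#' @export
busco_gate <- function(species_results, busco_scores, cutoff = 75) {
  ids <- names(species_results)
  missing <- setdiff(ids, names(busco_scores))
  if (length(missing) > 0L) {
    stop(sprintf("species without BUSCO score: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  drop <- ids[busco_scores[ids] < cutoff]
  if (length(drop) > 0L)
    message(sprintf("removed %d species with completeness < %g%%: %s",
                    length(drop), cutoff, paste(drop, collapse = ", ")))
  species_results[setdiff(ids, drop)]
}

#' Cross-species family-size matrix
#'
#' Tabulates the number of sorted, filter-passing SLC genes per family in
#' each species. Absent families get 0; columns are all families of the
#' supplied universe in numeric order (e.g. SLC1...SLC66 minus exclusions).
#' Unsorted genes are never counted here.
#'
#' @param species_counts named list: species id -> named integer vector
#'   `family -> count` (or an assignments/verdict-derived vector).
#' @param families character vector of family codes defining the columns;
#'   defaults to the union observed, in numeric order.
#' @return integer matrix, species rows by family columns.
#' @export
build_family_matrix <- function(species_counts, families = NULL) {
  if (length(species_counts) == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = length(families %||% character(0)),
                  dimnames = list(character(0), families %||% character(0))))
  }
  if (is.null(families)) {
    families <- order_families(unique(unlist(lapply(species_counts, names))))
  } else {
    families <- order_families(families)
  }
  mat <- matrix(0L, nrow = length(species_counts), ncol = length(families),
                dimnames = list(names(species_counts), families))
  for (sp in names(species_counts)) {
    cnt <- species_counts[[sp]]
    cnt <- cnt[names(cnt) %in% families]
    mat[sp, names(cnt)] <- as.integer(cnt)
  }
  mat
}

#' Compare an assignment set against an external gene list
#'
#' Set-algebra overlap report used for validation against precompiled
#' transporter lists (e.g. a curated fly gene group or another transporter
#' database).
#'
#' @param ours character vector of gene ids identified here.
#' @param theirs character vector of gene ids from the external list.
#' @return list with `shared`, `only_ours`, `only_theirs` (sorted
#'   character vectors) and a `summary` integer vector of their sizes.
#' @export
compare_gene_sets <- function(ours, theirs) {
  ours <- unique(ours); theirs <- unique(theirs)
  shared <- sort(intersect(ours, theirs))
  only_ours <- sort(setdiff(ours, theirs))
  only_theirs <- sort(setdiff(theirs, ours))
  list(shared = shared, only_ours = only_ours, only_theirs = only_theirs,
       summary = c(shared = length(shared), only_ours = length(only_ours),
                   only_theirs = length(only_theirs)))
}
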