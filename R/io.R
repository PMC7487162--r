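#' Read and write protein FASTA
#'
#' Thin wrappers around Biostrings. Record ids are the first
#' whitespace-delimited token of the header line; empty sequences are a
#' hard error naming the record.
#'
#' @param path file path.
#' @return `read_fasta` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  names(seqs) <- ids
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty sequence for record(s): %s",
                 paste(ids[!nzchar(seqs)], collapse = ", ")), call. = FALSE)
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Parse 12-column BLAST tabular output
#'
#' Reads the standard tabular report (`-outfmt 6`: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore) and
#' ranks the hits of each query by the documented sort key: E-value
#' ascending, bit score descending, subject id ascending. The ranking is
#' therefore deterministic and independent of input line order.
#'
#' @param path file path (tab-separated, no header, >= 12 columns).
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `evalue`, `bitscore`, `rank`.
#' @export
read_blast_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0), rank = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 12L)) {
    stop(sprintf("line %d: expected >= 12 tab-separated columns, got %d",
                 which(ncols < 12L)[1L], min(ncols)), call. = FALSE)
  }
  pick <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      stop(sprintf("line %d: non-numeric %s '%s'",
                   which(is.na(v))[1L], what, x[which(is.na(v))[1L]]),
           call. = FALSE)
    }
    v
  }
  hits <- data.frame(query_id = pick(1L), subject_id = pick(2L),
                     percent_identity = num(pick(3L), "percent identity"),
                     evalue = num(pick(11L), "evalue"),
                     bitscore = num(pick(12L), "bitscore"),
                     stringsAsFactors = FALSE)
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    stop("percent identity outside [0, 100]", call. = FALSE)
  }
  if (any(hits$evalue < 0)) stop("negative E-value", call. = FALSE)
  rank_blast_hits(hits)
}

#' Rank BLAST hits per query
#'
#' Sort key: E-value ascending, bit score descending, subject id
#' ascending; `rank` is 1-based within each query. Ties are fully
#' resolved so the ranking is deterministic.
#'
#' @param hits data.frame with at least `query_id`, `subject_id`,
#'   `evalue`, `bitscore`.
#' @return the same data.frame sorted, with a `rank` column.
#' @export
rank_blast_hits <- function(hits) {
  ord <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                          FUN = seq_along)
  rownames(hits) <- NULL
  hits
}

#' Parse HMMER per-target tabular output
#'
#' Reads the whitespace-delimited `--tblout` dialect ('#'-prefixed lines
#' are comments): target name in column 1, query (profile) name in column
#' 3, full-sequence E-value in column 5, full-sequence bit score in column
#' 6. Profile names are translated to family codes through `profile_map`;
#' an unknown profile is a hard error.
#'
#' @param path file path.
#' @param profile_map named character vector `profile name -> family
#'   code`. Profiles named directly by a family code need no entry.
#' @return data.frame with columns `target_id`, `profile_family`,
#'   `evalue`, `score`.
#' @export
read_hmmer_tbl <- function(path, profile_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(data.frame(target_id = character(0), profile_family = character(0),
                      evalue = numeric(0), score = numeric(0)))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  ncols <- lengths(fields)
  if (any(ncols < 6L)) {
    stop(sprintf("line %d: expected >= 6 whitespace-delimited columns",
                 which(ncols < 6L)[1L]), call. = FALSE)
  }
  target <- vapply(fields, `[[`, character(1), 1L)
  profile <- vapply(fields, `[[`, character(1), 3L)
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 6L)))
  if (anyNA(evalue) || anyNA(score)) {
    stop(sprintf("line %d: non-numeric E-value or score",
                 which(is.na(evalue) | is.na(score))[1L]), call. = FALSE)
  }
  fam <- profile
  if (!is.null(profile_map)) {
    mapped <- profile %in% names(profile_map)
    fam[mapped] <- unname(profile_map[profile[mapped]])
  }
  unknown <- unique(fam[!is_family_code(fam)])
  if (length(unknown) > 0L) {
    stop(sprintf("unknown profile name(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (any(evalue <= 0)) stop("HMM E-values must be positive", call. = FALSE)
  data.frame(target_id = target, profile_family = fam, evalue = evalue,
             score = score, stringsAsFactors = FALSE)
}

#' Parse transmembrane-prediction output
#'
#' Accepts either the predictor summary-line dialect
#' (`# <id> Number of predicted TMHs:  <n>`) or a plain two-column TSV
#' (`gene_id <TAB> tm_count`). Negative counts are an error.
#'
#' @param path file path.
#' @return named integer vector `gene_id -> tm_count`.
#' @export
read_tm_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  summary_re <- "Number of predicted TMHs:"
  is_summary <- grepl(summary_re, lines, fixed = TRUE)
  if (any(is_summary)) {
    sl <- lines[is_summary]
    sl <- sub("^#\\s*", "", sl)
    ids <- sub("\\s.*$", "", sl)
    cnt <- suppressWarnings(as.integer(sub(".*Number of predicted TMHs:\\s*",
                                           "", sl)))
  } else {
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) == 0L) return(stats::setNames(integer(0), character(0)))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 2L)) {
      stop(sprintf("line %d: expected two tab-separated columns",
                   which(lengths(fields) < 2L)[1L]), call. = FALSE)
    }
    ids <- vapply(fields, `[[`, character(1), 1L)
    cnt <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  }
  if (anyNA(cnt)) {
    stop(sprintf("non-integer TM count for '%s'", ids[which(is.na(cnt))[1L]]),
         call. = FALSE)
  }
  if (any(cnt < 0)) {
    stop(sprintf("negative TM count for '%s'", ids[which(cnt < 0)[1L]]),
         call. = FALSE)
  }
  stats::setNames(cnt, ids)
}

#' @rdname read_tm_table
#' @param tm_counts named integer vector `gene_id -> tm_count`.
#' @export
write_tm_table <- function(tm_counts, path) {
  utils::write.table(data.frame(gene_id = names(tm_counts),
                                tm_count = as.integer(tm_counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read BUSCO completeness scores
#'
#' Two-column TSV: species id and completeness percentage.
#'
#' @param path file path.
#' @return named numeric vector `species -> completeness %`.
#' @export
read_busco_scores <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expected two columns: species, completeness",
                           call. = FALSE)
  scores <- as.numeric(tab[[2L]])
  if (anyNA(scores) || any(scores < 0 | scores > 100)) {
    stop("completeness scores must be percentages in [0, 100]", call. = FALSE)
  }
  stats::setNames(scores, as.character(tab[[1L]]))
}

#' Run an external search tool, if available
#'
#' Optional adapters for the profile-HMM build/search, protein BLAST and
#' transmembrane prediction steps. Each adapter checks that the binary is
#' on the PATH and fails loudly with a "tool unavailable" error otherwise;
#' the pipeline itself is fully driven by the tabular files these tools
#' produce, so precomputed outputs can always be substituted.
#'
#' @param tool one of "hmmbuild", "hmmsearch", "blastp", "makeblastdb".
#' @param args character vector of command-line arguments.
#' @param stdout,stderr passed to [system2()].
#' @return the exit status invisibly; output files are wherever `args`
#'   directed them.
#' @export
run_external <- function(tool = c("hmmbuild", "hmmsearch", "blastp",
                                  "makeblastdb"),
                         args = character(), stdout = "", stderr = "") {
  tool <- match.arg(tool)
  if (!nzchar(Sys.which(tool))) {
    stop(sprintf("tool unavailable: '%s' not found on PATH", tool),
         call. = FALSE)
  }
  status <- system2(tool, args, stdout = stdout, stderr = stderr)
  if (is.character(status)) return(invisible(status))
  if (status != 0L) {
    stop(sprintf("'%s' exited with status %d", tool, status), call. = FALSE)
  }
  invisible(status)
}
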