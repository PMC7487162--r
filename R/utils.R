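# Internal helpers shared across modules.

# Family codes are "SLC" followed by a positive integer (SLC1..SLC66 in the
# human nomenclature, but any positive index is syntactically valid).
is_family_code <- function(x) {
  grepl("^SLC[1-9][0-9]*$", x)
}

family_index <- function(x) {
  as.integer(sub("^SLC", "", x))
}

# Order family codes numerically (SLC2 before SLC10).
order_families <- function(x) {
  x[order(family_index(x))]
}

assert_family_codes <- function(x, what = "family code") {
  bad <- unique(x[!is_family_code(x)])
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s(s): %s", what,
                 paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

AA_ALPHABET20X <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

assert_aa_sequences <- function(seqs, ids = names(seqs)) {
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty sequence for record(s): %s",
                 paste(utils::head(ids[!nzchar(seqs)], 5L), collapse = ", ")),
         call. = FALSE)
  }
  ok <- grepl(sprintf("^[%s]+$", paste(AA_ALPHABET20X, collapse = "")),
              toupper(seqs))
  if (any(!ok)) {
    stop(sprintf("non amino-acid characters in record(s): %s",
                 paste(utils::head(ids[!ok], 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
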