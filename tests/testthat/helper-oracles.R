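# Independent oracle implementations used to cross-check the package.
# These are deliberately literal, unoptimized transcriptions of the
# decision rules and textbook formulas; they never share code with the
# implementation under test.

# Literal rule-by-rule family-assignment oracle for one query's hits,
# already sorted by rank.
oracle_classify <- function(h, subject_families, family_sizes,
                            identity_min = 20, fold_change = 1e30) {
  fams <- unname(subject_families[h$subject_id])
  F <- fams[1L]
  n <- nrow(h)
  top5 <- fams[seq_len(min(5L, n))]

  crit3 <- h$percent_identity[1L] > identity_min

  size_known <- F %in% names(family_sizes)
  small <- size_known && family_sizes[[F]] < 5
  if (small) {
    seen <- unique(h$subject_id[seq_len(min(5L, n))][top5 == F])
    crit2 <- length(seen) >= family_sizes[[F]]
    rule_if_pass <- "SMALL_FAMILY"
  } else if (n >= 5L) {
    crit2 <- sum(top5 == F) >= 4L
    rule_if_pass <- "ALL_CRITERIA"
  } else {
    crit2 <- all(fams == F)
    rule_if_pass <- "ALL_CRITERIA"
  }

  if (crit2 && crit3) return(list(label = F, rule = rule_if_pass))

  if (n == 1L) {
    if (crit3) return(list(label = F, rule = "OVERWHELMING"))
  } else {
    e1 <- h$evalue[1L]; e2 <- h$evalue[2L]
    fires <- if (e1 == 0) e2 > 0 else (e2 / e1) > fold_change
    if (fires) return(list(label = F, rule = "OVERWHELMING"))
  }
  list(label = "Unsorted", rule = "UNSORTED")
}

# Random ranked hit table for one query over a fixed subject universe.
# Exercises ties, zero E-values, small families, identities around the
# 20% boundary, and short hit lists.
random_hit_table <- function(query, universe) {
  n <- sample(1:8, 1L)
  subjects <- sample(universe$subject_id, n)
  evalue <- 10^stats::runif(n, -90, 0)
  if (stats::runif(1) < 0.15) evalue[sample(n, 1L)] <- 0
  if (n >= 2L && stats::runif(1) < 0.2) evalue[2L] <- evalue[1L]  # ties
  h <- data.frame(query_id = query, subject_id = subjects,
                  percent_identity = round(stats::runif(n, 0, 60), 1),
                  evalue = evalue,
                  bitscore = round(stats::runif(n, 50, 500), 1),
                  stringsAsFactors = FALSE)
  rank_blast_hits(h)
}

# Subject universe with a mix of family sizes, including small families.
make_universe <- function(n_big = 4L, n_small = 3L) {
  fams <- c(paste0("SLC", 1:n_big), paste0("SLC", 50 + seq_len(n_small)))
  sizes <- c(sample(5:8, n_big, replace = TRUE),
             sample(1:4, n_small, replace = TRUE))
  subject_id <- unlist(lapply(seq_along(fams), function(i) {
    sprintf("%s_m%d", fams[i], seq_len(sizes[i]))
  }))
  families <- rep(fams, sizes)
  list(subject_id = subject_id,
       map = stats::setNames(families, subject_id),
       sizes = stats::setNames(as.integer(sizes), fams))
}

# From-scratch one-way ANOVA via explicit sums of squares.
oracle_anova <- function(y, g) {
  g <- as.character(g)
  groups <- unique(g)
  k <- length(groups)
  N <- length(y)
  grand <- mean(y)
  ssb <- sum(vapply(groups, function(gr) {
    yi <- y[g == gr]
    length(yi) * (mean(yi) - grand)^2
  }, numeric(1)))
  ssw <- sum(vapply(groups, function(gr) {
    yi <- y[g == gr]
    sum((yi - mean(yi))^2)
  }, numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  list(f = f, p = p)
}

# Naive agglomerative clustering oracle: repeatedly merge the pair of
# clusters with the smallest complete-linkage distance; returns the
# sequence of merge heights.
oracle_complete_linkage_heights <- function(mat) {
  d <- as.matrix(stats::dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        dij <- max(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) { best_d <- dij; best <- c(j, i) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# Small reference fixture shared by several unit tests.
tiny_reference <- function() {
  seqs <- c(a1 = strrep("M", 400), a2 = strrep("M", 500),
            a3 = strrep("M", 600), b1 = strrep("M", 300))
  suppressMessages(slc_reference(
    seqs, c(a1 = "SLC2", a2 = "SLC2", a3 = "SLC2", b1 = "SLC7"),
    excluded = character(0)))
}
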