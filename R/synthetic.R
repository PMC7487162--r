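# Synthetic fixtures with known ground truth. Sequences are built from
# per-family residue signatures: transmembrane segments are 19-mers of a
# strongly hydrophobic residue, linkers and padding use a strongly
# hydrophilic residue, so the hydropathy fallback recovers the planted
# TM count exactly and family composition signatures stay distinct.

HPHOB_POOL <- c("I", "L", "V", "F", "M", "A", "C")
HPHIL_POOL <- c("R", "K", "D", "E", "N", "Q", "H")

family_signature <- function(i) {
  h <- HPHOB_POOL[(i - 1L) %% length(HPHOB_POOL) + 1L]
  p <- HPHIL_POOL[((i - 1L) %/% length(HPHOB_POOL)) %% length(HPHIL_POOL) + 1L]
  c(hydrophobic = h, hydrophilic = p)
}

# A sequence of `n_tm` hydrophobic 19-mers separated by 10-residue
# hydrophilic linkers, padded with hydrophilic residues to `length`.
build_tm_sequence <- function(length, n_tm, sig) {
  seg <- strrep(sig[["hydrophobic"]], 19L)
  linker <- strrep(sig[["hydrophilic"]], 10L)
  core <- if (n_tm > 0L) {
    paste(rep(seg, n_tm), collapse = linker)
  } else {
    ""
  }
  core_len <- nchar(core)
  if (core_len > length) {
    stop(sprintf("length %d too short for %d TM segments", length, n_tm),
         call. = FALSE)
  }
  pad <- length - core_len
  lead <- pad %/% 2L
  paste0(strrep(sig[["hydrophilic"]], lead), core,
         strrep(sig[["hydrophilic"]], pad - lead))
}

#' Generate a synthetic family-labelled reference set
#'
#' Builds a curated-reference stand-in with planted truth: each family
#' has a fixed TM-segment count and a length range, and member lengths
#' are drawn uniformly from that range (subject to fitting the TM
#' architecture). The hydropathy fallback recovers each planted TM count
#' exactly by construction.
#'
#' @param n_families number of families (codes `SLC1`, `SLC2`, ...).
#' @param members_per_family curated members per family (recycled).
#' @param length_range two-column matrix (or length-2 vector, recycled)
#'   of per-family min/max lengths. Default 400-600 residues.
#' @param tm_count per-family TM-segment count (recycled; default 6).
#' @param seed integer seed; the same seed reproduces identical output.
#' @return list with `ref` (an [slc_reference()]), `tm_counts` (named
#'   vector of planted counts), `truth` (data.frame `gene_id`, `family`,
#'   `length`, `tm_count`), and `params`.
#' @export
fixture_reference <- function(n_families = 5L, members_per_family = 5L,
                              length_range = c(400L, 600L),
                              tm_count = 6L, seed = 1L) {
  set.seed(seed)
  if (n_families == 0L) {
    ref <- structure(list(species = "synthetic_model",
                          entries = data.frame(gene_id = character(0),
                                               family = character(0),
                                               length = integer(0)),
                          sequences = stats::setNames(character(0),
                                                      character(0)),
                          excluded = character(0)),
                     class = "slc_reference")
    return(list(ref = ref, tm_counts = stats::setNames(integer(0),
                                                       character(0)),
                truth = data.frame(gene_id = character(0),
                                   family = character(0),
                                   length = integer(0),
                                   tm_count = integer(0)),
                params = list(seed = seed)))
  }
  if (is.null(dim(length_range))) {
    length_range <- matrix(rep(length_range, length.out = 2L * n_families),
                           ncol = 2L, byrow = TRUE)
  }
  members <- rep_len(members_per_family, n_families)
  tms <- rep_len(as.integer(tm_count), n_families)
  fams <- paste0("SLC", seq_len(n_families))
  rows <- list(); seqs <- character(0)
  for (i in seq_len(n_families)) {
    sig <- family_signature(i)
    min_needed <- if (tms[i] > 0L) 19L * tms[i] + 10L * (tms[i] - 1L) else 1L
    lo <- max(length_range[i, 1L], min_needed)
    hi <- max(length_range[i, 2L], lo)
    for (j in seq_len(members[i])) {
      len <- sample(lo:hi, 1L)
      gid <- sprintf("%s_ref%02d", fams[i], j)
      seqs[gid] <- build_tm_sequence(len, tms[i], sig)
      rows[[length(rows) + 1L]] <- data.frame(gene_id = gid,
                                              family = fams[i],
                                              length = len,
                                              tm_count = tms[i],
                                              stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  ref <- suppressMessages(
    slc_reference(seqs, stats::setNames(truth$family, truth$gene_id),
                  excluded = character(0), species = "synthetic_model"))
  list(ref = ref,
       tm_counts = stats::setNames(truth$tm_count, truth$gene_id),
       truth = truth,
       params = list(seed = seed, length_range = length_range, tm = tms))
}

#' Generate a synthetic target proteome with planted decoys
#'
#' Emits a proteome in which every sequence has a known fate: true
#' family members (within the family length window, full TM
#' architecture), "fragment" decoys (length below two thirds of the
#' family minimum, to be caught by the length filter), "soluble" decoys
#' (in-window length but zero TM segments, to be caught by the TM
#' filter), and "non_slc" sequences with no family signature (never
#' screened in).
#'
#' @param reference a [fixture_reference()] result; family architecture
#'   (signatures, length ranges, TM counts) is reused from it.
#' @param members_per_family true members planted per family (recycled).
#' @param n_fragments,n_soluble,n_non_slc decoy counts.
#' @param seed integer seed.
#' @return list with `proteome` (named character vector) and `truth`
#'   (data.frame `gene_id`, `class` in
#'   `{"member","fragment","soluble","non_slc"}`, `family` (NA for
#'   non_slc), `length`, `tm_count`).
#' @export
fixture_target_proteome <- function(reference, members_per_family = 10L,
                                    n_fragments = 10L, n_soluble = 10L,
                                    n_non_slc = 10L, seed = 1L) {
  set.seed(seed + 1L)
  rt <- reference$truth
  fams <- order_families(unique(rt$family))
  if (length(fams) == 0L) stop("reference has no families", call. = FALSE)
  members <- rep_len(members_per_family, length(fams))
  fam_min <- vapply(fams, function(f) min(rt$length[rt$family == f]),
                    integer(1))
  fam_max <- vapply(fams, function(f) max(rt$length[rt$family == f]),
                    integer(1))
  fam_tm <- vapply(fams, function(f) min(rt$tm_count[rt$family == f]),
                   integer(1))
  rows <- list(); seqs <- character(0)
  add <- function(gid, sq, cls, fam, tmc) {
    seqs[[gid]] <<- sq
    rows[[length(rows) + 1L]] <<- data.frame(gene_id = gid, class = cls,
                                             family = fam,
                                             length = nchar(sq),
                                             tm_count = tmc,
                                             stringsAsFactors = FALSE)
  }
  for (i in seq_along(fams)) {
    sig <- family_signature(family_index(fams[i]))
    tmc <- fam_tm[i]
    min_needed <- if (tmc > 0L) 19L * tmc + 10L * (tmc - 1L) else 1L
    lo <- max(fam_min[i], min_needed)
    hi <- max(fam_max[i], lo)
    for (j in seq_len(members[i])) {
      len <- sample(lo:hi, 1L)
      add(sprintf("tgt_%s_m%02d", fams[i], j),
          build_tm_sequence(len, tmc, sig), "member", fams[i], tmc)
    }
  }
  # Fragments: below the family's acceptance floor, but still carrying
  # enough TM segments to pass the TM filter, so only the length filter
  # catches them.
  for (k in seq_len(n_fragments)) {
    i <- sample(seq_along(fams), 1L)
    sig <- family_signature(family_index(fams[i]))
    thr <- fam_tm[i] %/% 2L
    min_needed <- if (thr > 0L) 19L * thr + 10L * (thr - 1L) else 19L
    ceiling_len <- as.integer(floor(2 / 3 * fam_min[i])) - 1L
    if (ceiling_len < min_needed) {
      stop("fixture family too short to host a TM-bearing fragment decoy",
           call. = FALSE)
    }
    len <- sample(min_needed:ceiling_len, 1L)
    add(sprintf("tgt_frag%02d", k), build_tm_sequence(len, thr, sig),
        "fragment", fams[i], thr)
  }
  # Soluble homologs: in-window length, zero TM segments.
  for (k in seq_len(n_soluble)) {
    i <- sample(seq_along(fams), 1L)
    sig <- family_signature(family_index(fams[i]))
    len <- sample(fam_min[i]:max(fam_max[i], fam_min[i]), 1L)
    add(sprintf("tgt_sol%02d", k), build_tm_sequence(len, 0L, sig),
        "soluble", fams[i], 0L)
  }
  # Non-SLC background: alternating weakly polar residues, no family
  # signature, no planted search hits.
  for (k in seq_len(n_non_slc)) {
    len <- sample(150:800, 1L)
    aa <- sample(c("G", "S", "T", "P", "Y", "W"), len, replace = TRUE)
    add(sprintf("tgt_bg%02d", k), paste(aa, collapse = ""), "non_slc",
        NA_character_, 0L)
  }
  truth <- do.call(rbind, rows)
  list(proteome = seqs, truth = truth)
}

#' Generate HMM and BLAST hit tables consistent with planted truth
#'
#' Constructs the search artifacts the pipeline consumes, encoding the
#' planted truth in the hit ordering: every member/fragment/soluble gene
#' gets a significant profile hit for its true family, and its
#' reciprocal-BLAST top five are members of that family on a fixed
#' E-value ladder. Noise degrades the tables: `rank_swap_prob` replaces
#' each top-five subject with a random other-family subject with that
#' probability, and `identity_jitter_sd` adds Gaussian noise to percent
#' identities. Non-SLC genes get either no profile hit or one far above
#' the screening threshold.
#'
#' @param target a [fixture_target_proteome()] result.
#' @param reference the [fixture_reference()] used to build it.
#' @param rank_swap_prob per-position probability of corrupting a
#'   top-five subject (default 0).
#' @param identity_jitter_sd standard deviation of identity noise
#'   (default 0).
#' @param seed integer seed.
#' @return list with `hmm_hits` and `blast_hits` data.frames in the
#'   shapes produced by [read_hmmer_tbl()] and [read_blast_tabular()].
#' @export
fixture_hit_tables <- function(target, reference, rank_swap_prob = 0,
                               identity_jitter_sd = 0, seed = 1L) {
  set.seed(seed + 2L)
  rt <- reference$truth
  truth <- target$truth
  hmm <- list(); blast <- list()
  for (r in seq_len(nrow(truth))) {
    gid <- truth$gene_id[r]
    cls <- truth$class[r]
    if (cls == "non_slc") {
      # Half get a hopeless hit, half none at all.
      if (stats::runif(1) < 0.5) {
        hmm[[length(hmm) + 1L]] <- data.frame(
          target_id = gid, profile_family = sample(unique(rt$family), 1L),
          evalue = stats::runif(1, 0.5, 5), score = stats::runif(1, 1, 10),
          stringsAsFactors = FALSE)
      }
      next
    }
    fam <- truth$family[r]
    hmm[[length(hmm) + 1L]] <- data.frame(
      target_id = gid, profile_family = fam,
      evalue = 10^stats::runif(1, -60, -20),
      score = stats::runif(1, 100, 400), stringsAsFactors = FALSE)
    members <- rt$gene_id[rt$family == fam]
    others <- rt$gene_id[rt$family != fam]
    top <- utils::head(rep_len(sample(members), 5L), 5L)
    if (length(members) < 5L && length(others) > 0L) {
      top <- c(sample(members), sample(others,
                                       min(5L - length(members),
                                           length(others))))
    }
    if (rank_swap_prob > 0 && length(others) > 0L) {
      swap <- stats::runif(length(top)) < rank_swap_prob
      top[swap] <- sample(others, sum(swap), replace = TRUE)
    }
    n_extra <- min(3L, length(others))
    subjects <- c(top, if (n_extra > 0L) sample(others, n_extra))
    e0 <- 10^stats::runif(1, -70, -50)
    evalues <- e0 * 10^(8 * (seq_along(subjects) - 1L))
    identity <- c(45, 40, 38, 35, 33, 28, 26, 24)[seq_along(subjects)] +
      stats::rnorm(length(subjects), 0, identity_jitter_sd)
    identity <- pmin(100, pmax(0, identity))
    blast[[length(blast) + 1L]] <- data.frame(
      query_id = gid, subject_id = subjects,
      percent_identity = round(identity, 1),
      evalue = evalues,
      bitscore = round(500 - 40 * (seq_along(subjects) - 1L), 1),
      stringsAsFactors = FALSE)
  }
  hmm_hits <- if (length(hmm) > 0L) do.call(rbind, hmm) else
    data.frame(target_id = character(0), profile_family = character(0),
               evalue = numeric(0), score = numeric(0))
  blast_hits <- if (length(blast) > 0L) do.call(rbind, blast) else
    data.frame(query_id = character(0), subject_id = character(0),
               percent_identity = numeric(0), evalue = numeric(0),
               bitscore = numeric(0))
  list(hmm_hits = hmm_hits, blast_hits = rank_blast_hits(blast_hits))
}

#' Generate a synthetic species cohort for the statistics layer
#'
#' Plants per-group family-size templates and draws species counts as
#' rounded Gaussians truncated at zero, alongside a trait table, an
#' ultrametric coalescent tree over the species, and BUSCO completeness
#' scores with a configurable fraction of low-quality species to
#' exercise the completeness gate.
#'
#' @param groups named list: group name -> list(n = species count,
#'   template = named numeric vector family -> mean size).
#' @param noise_sd within-group standard deviation of counts (default 1,
#'   in genes).
#' @param busco_low_frac fraction of species given completeness < 75
#'   (default 0).
#' @param seed integer seed.
#' @return list with `matrix` (species x family counts), `traits`
#'   (data.frame `species`, `taxonomic_group`, `phagy`, `vory`), `tree`
#'   (ultrametric `phylo`), `busco` (named vector), `truth` (the planted
#'   templates).
#' @export
fixture_cohort <- function(groups, noise_sd = 1, busco_low_frac = 0,
                           seed = 1L) {
  set.seed(seed + 3L)
  fam_all <- order_families(unique(unlist(lapply(groups,
                                                 function(g) names(g$template)))))
  rows <- list(); traits <- list()
  phagy_levels <- c("monophagous", "oligophagous", "polyphagous")
  vory_levels <- c("herbivore", "carnivore", "omnivore")
  for (gname in names(groups)) {
    g <- groups[[gname]]
    tmpl <- stats::setNames(rep(0, length(fam_all)), fam_all)
    tmpl[names(g$template)] <- g$template
    for (s in seq_len(g$n)) {
      sp <- sprintf("%s_sp%02d", gname, s)
      cnt <- pmax(0, round(stats::rnorm(length(fam_all), tmpl, noise_sd)))
      rows[[sp]] <- stats::setNames(as.integer(cnt), fam_all)
      traits[[length(traits) + 1L]] <- data.frame(
        species = sp, taxonomic_group = gname,
        phagy = sample(phagy_levels, 1L), vory = sample(vory_levels, 1L),
        stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- fam_all
  traits <- do.call(rbind, traits)
  n_sp <- nrow(mat)
  tree <- if (n_sp >= 2L) {
    tr <- ape::rcoal(n_sp, tip.label = rownames(mat))
    # Scale tree depth to a nominal 500 units so exports look like
    # time-calibrated trees.
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 500
    tr
  } else {
    NULL
  }
  busco <- stats::setNames(stats::runif(n_sp, 80, 99), rownames(mat))
  if (busco_low_frac > 0 && n_sp > 0L) {
    n_low <- max(1L, round(busco_low_frac * n_sp))
    low <- sample(rownames(mat), n_low)
    busco[low] <- stats::runif(n_low, 40, 74.9)
  }
  list(matrix = mat, traits = traits, tree = tree, busco = busco,
       truth = lapply(groups, `[[`, "template"))
}

#' Write a self-contained fixture directory
#'
#' Emits every artifact the pipeline consumes — reference FASTA and
#' family map, target proteome FASTA, HMM and BLAST tabular hit files,
#' TM-count TSV, BUSCO scores, trait table, family-size matrix,
#' ultrametric Newick tree — plus a MANIFEST TSV of per-gene truth.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed driving all generators.
#' @param n_families,members_per_family,n_decoys fixture dimensions.
#' @return the directory path, invisibly.
#' @export
fixture_write_all <- function(dir, seed = 1L, n_families = 5L,
                              members_per_family = 10L, n_decoys = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fr <- fixture_reference(n_families = n_families, seed = seed)
  tgt <- fixture_target_proteome(fr, members_per_family = members_per_family,
                                 n_fragments = n_decoys,
                                 n_soluble = n_decoys, n_non_slc = n_decoys,
                                 seed = seed)
  hits <- fixture_hit_tables(tgt, fr, seed = seed)
  write_fasta(fr$ref$sequences, file.path(dir, "reference.faa"))
  utils::write.table(fr$truth[, c("gene_id", "family")],
                     file.path(dir, "reference_families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tm_table(fr$tm_counts, file.path(dir, "reference_tm.tsv"))
  write_fasta(tgt$proteome, file.path(dir, "target.faa"))
  hh <- hits$hmm_hits
  writeLines(sprintf("%s -          %s -          %.3g %.1f 0.0 1",
                     hh$target_id, hh$profile_family, hh$evalue, hh$score),
             file.path(dir, "target_hmm.tbl"))
  bh <- hits$blast_hits
  writeLines(sprintf("%s\t%s\t%.1f\t0\t0\t0\t0\t0\t0\t0\t%.3g\t%.1f",
                     bh$query_id, bh$subject_id, bh$percent_identity,
                     bh$evalue, bh$bitscore),
             file.path(dir, "target_blast.tsv"))
  cohort <- fixture_cohort(
    groups = list(insecta = list(n = 10L,
                                 template = stats::setNames(
                                   rep(10, n_families),
                                   paste0("SLC", seq_len(n_families)))),
                  arachnida = list(n = 10L,
                                   template = stats::setNames(
                                     rep(5, n_families),
                                     paste0("SLC", seq_len(n_families))))),
    seed = seed, busco_low_frac = 0.1)
  utils::write.table(data.frame(species = names(cohort$busco),
                                busco = round(cohort$busco, 1)),
                     file.path(dir, "busco.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cohort$traits, file.path(dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(species = rownames(cohort$matrix),
                                cohort$matrix, check.names = FALSE),
                     file.path(dir, "family_sizes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(cohort$tree, file.path(dir, "species_tree.nwk"))
  utils::write.table(tgt$truth, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
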