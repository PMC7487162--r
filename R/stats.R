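#' Per-family one-way ANOVA across trait groups
#'
#' For every family column of the family-size matrix, fits a one-way
#' ANOVA of count against one categorical species trait (taxonomic
#' group, dietary breadth "phagy", or dietary type "vory"). Trait
#' categories represented by fewer than `min_group` species (default 8)
#' are excluded from that comparison; a family/trait combination with
#' fewer than two eligible categories is marked not testable. P-values
#' are Bonferroni-corrected over the number of tests actually performed
#' (all families x all requested traits, after eligibility filtering).
#' A comparison is called significant when its raw p-value is below
#' `p_cutoff` (default 1e-5) and its maximum effect — the largest
#' absolute difference between two group mean counts, in genes — exceeds
#' `effect_cutoff` (default 3).
#'
#' Degenerate inputs follow fixed conventions: groups with identical
#' counts and equal means give F = 0 and p = 1; zero within-group
#' variance with unequal means gives F = Inf and p = 0.
#'
#' @param mat family-size matrix (species rows, family columns), as from
#'   [build_family_matrix()].
#' @param traits data.frame with rownames (or a `species` column)
#'   matching the matrix rows and one column per categorical trait.
#' @param covariables trait columns to test (default all).
#' @param min_group minimum species per eligible category (default 8).
#' @param p_cutoff,effect_cutoff significance gate (defaults 1e-5 and 3
#'   genes).
#' @return data.frame of class `slc_anova`, one row per family x trait:
#'   `family`, `covariable`, `n_groups`, `f_value`, `p_value`,
#'   `bonferroni_p`, `max_effect`, `significant`, `testable`; the number
#'   of tests used for the correction is in `attr(, "m")`.
#' @export
family_anova <- function(mat, traits, covariables = NULL, min_group = 8L,
                         p_cutoff = 1e-5, effect_cutoff = 3) {
  if (!is.null(traits$species)) {
    rownames(traits) <- traits$species
    traits$species <- NULL
  }
  if (is.null(covariables)) covariables <- colnames(traits)
  missing <- setdiff(rownames(mat), rownames(traits))
  if (length(missing) > 0L) {
    stop(sprintf("species without trait data: %s",
                 paste(utils::head(missing, 10L), collapse = ", ")),
         call. = FALSE)
  }
  rows <- list()
  for (cv in covariables) {
    grp <- as.character(traits[rownames(mat), cv])
    tab <- table(grp[!is.na(grp)])
    eligible <- names(tab)[tab >= min_group]
    keep <- !is.na(grp) & grp %in% eligible
    for (fam in colnames(mat)) {
      if (sum(keep) == 0L || length(eligible) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, covariable = cv, n_groups = length(eligible),
          f_value = NA_real_, p_value = NA_real_, bonferroni_p = NA_real_,
          max_effect = NA_real_, significant = FALSE, testable = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      res <- oneway_anova(mat[keep, fam], factor(grp[keep]))
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, covariable = cv, n_groups = length(eligible),
        f_value = res$f, p_value = res$p, bonferroni_p = NA_real_,
        max_effect = res$max_effect, significant = FALSE, testable = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- sum(out$testable)
  if (m > 0L)
    out$bonferroni_p[out$testable] <- bonferroni(out$p_value[out$testable], m)
  out$significant <- out$testable & !is.na(out$p_value) &
    out$p_value < p_cutoff & out$max_effect > effect_cutoff
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "p_cutoff") <- p_cutoff
  attr(out, "effect_cutoff") <- effect_cutoff
  class(out) <- c("slc_anova", "data.frame")
  out
}

# One-way ANOVA of y on a factor g via the standard linear-model fit,
# with the degenerate-variance conventions documented in family_anova().
oneway_anova <- function(y, g) {
  g <- droplevels(g)
  means <- tapply(y, g, mean)
  max_effect <- max(stats::dist(means))
  if (stats::var(y) == 0) {
    return(list(f = 0, p = 1, max_effect = 0))
  }
  within_ss <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (within_ss == 0) {
    return(list(f = Inf, p = 0, max_effect = max_effect))
  }
  fit <- stats::anova(stats::lm(y ~ g))
  list(f = fit[["F value"]][1L], p = fit[["Pr(>F)"]][1L],
       max_effect = max_effect)
}

#' @export
print.slc_anova <- function(x, ...) {
  cat(sprintf("Family-size one-way ANOVA: %d comparisons (%d testable), Bonferroni m = %d\n",
              nrow(x), sum(x$testable), attr(x, "m")))
  sig <- x[x$significant, , drop = FALSE]
  cat(sprintf("%d significant at p < %g with max effect > %g genes\n",
              nrow(sig), attr(x, "p_cutoff"), attr(x, "effect_cutoff")))
  if (nrow(sig) > 0L) {
    sig <- sig[order(sig$p_value), c("family", "covariable", "p_value",
                                     "bonferroni_p", "max_effect")]
    print.data.frame(utils::head(sig, 20L), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.slc_anova <- function(object, ...) {
  out <- object[order(object$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Bonferroni correction
#'
#' `min(1, p * m)` with `m` the number of tests performed.
#'
#' @param p raw p-value(s).
#' @param m number of tests.
#' @return corrected p-value(s), capped at 1.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Coefficient of variation per family
#'
#' Sample standard deviation divided by mean, per column of the
#' family-size matrix; a measure of how stable a family's size is across
#' species. Families with mean 0 are undefined and reported as `NA`.
#'
#' @param mat family-size matrix (species rows, family columns).
#' @return named numeric vector, one value per family.
#' @export
family_cv <- function(mat) {
  means <- colMeans(mat)
  sds <- apply(mat, 2L, stats::sd)
  out <- ifelse(means == 0, NA_real_, sds / means)
  stats::setNames(out, colnames(mat))
}

#' Hierarchically cluster species by family-size profile
#'
#' Agglomerative clustering of species on their family-size rows
#' (Euclidean distance, complete linkage by default; both recorded in
#' the output so the run is reproducible). The dendrogram is also
#' emitted as a Newick string, and the matrix is returned re-ordered by
#' the dendrogram for heatmap display.
#'
#' @param mat family-size matrix with at least one species row.
#' @param distance method for [stats::dist()] (default "euclidean").
#' @param linkage method for [stats::hclust()] (default "complete").
#' @return list with `hclust` (`NULL` for a single species), `newick`,
#'   `ordered` (the reordered matrix), `distance`, `linkage`.
#' @export
cluster_species <- function(mat, distance = "euclidean",
                            linkage = "complete") {
  if (nrow(mat) == 0L) stop("no species to cluster", call. = FALSE)
  if (nrow(mat) == 1L) {
    return(list(hclust = NULL,
                newick = sprintf("%s;", rownames(mat)),
                ordered = mat, distance = distance, linkage = linkage))
  }
  hc <- stats::hclust(stats::dist(mat, method = distance), method = linkage)
  phy <- ape::as.phylo(hc)
  list(hclust = hc,
       newick = ape::write.tree(phy),
       ordered = mat[hc$order, , drop = FALSE],
       distance = distance, linkage = linkage)
}

#' Export family counts and a pruned ultrametric tree for CAFE
#'
#' Writes the tab-separated gene-family count file expected by
#' birth-death family-evolution software (columns: Desc, Family ID, one
#' column per species; one row per family) and prunes the supplied
#' ultrametric tree to the requested species subset, preserving branch
#' lengths. The tree must be ultrametric within `tol`: the spread of
#' root-to-tip path lengths may not exceed it.
#'
#' @param mat family-size matrix.
#' @param tree an ultrametric `phylo` object or path to a Newick file.
#' @param species subset of species to export (default: all matrix rows).
#' @param counts_file,tree_file output paths.
#' @param tol ultrametricity tolerance on the root-to-tip depth spread
#'   (default 1e-6, in branch-length units).
#' @return invisibly, a list with the pruned `phylo` and the exported
#'   count data.frame.
#' @export
cafe_export <- function(mat, tree, species = rownames(mat),
                        counts_file, tree_file, tol = 1e-6) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  miss_mat <- setdiff(species, rownames(mat))
  miss_tree <- setdiff(species, tree$tip.label)
  if (length(miss_mat) > 0L || length(miss_tree) > 0L) {
    stop(sprintf("species missing from %s: %s",
                 if (length(miss_mat) > 0L) "matrix" else "tree",
                 paste(c(miss_mat, miss_tree), collapse = ", ")),
         call. = FALSE)
  }
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  spread <- max(depths) - min(depths)
  if (spread > tol) {
    stop(sprintf("tree is not ultrametric: root-to-tip depth spread %.3g exceeds tolerance %g",
                 spread, tol), call. = FALSE)
  }
  pruned <- if (length(species) < length(tree$tip.label)) {
    ape::keep.tip(tree, species)
  } else {
    tree
  }
  counts <- data.frame(Desc = "(null)", `Family ID` = colnames(mat),
                       check.names = FALSE, stringsAsFactors = FALSE)
  for (sp in species) counts[[sp]] <- unname(mat[sp, ])
  utils::write.table(counts, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ape::write.tree(pruned, tree_file)
  invisible(list(tree = pruned, counts = counts))
}

#' Read a CAFE-format count file back into a matrix
#'
#' Inverse of the count-file side of [cafe_export()], used for
#' round-trip validation.
#'
#' @param path count file path.
#' @return integer matrix, species rows by family columns.
#' @export
read_cafe_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  fam <- tab[["Family ID"]]
  sp <- setdiff(colnames(tab), c("Desc", "Family ID"))
  mat <- t(as.matrix(tab[, sp, drop = FALSE]))
  colnames(mat) <- fam
  storage.mode(mat) <- "integer"
  mat
}
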