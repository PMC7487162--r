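mk_cohort_mat <- function(groups) {
  # groups: named list group -> matrix/vector of counts per species
  mat <- do.call(rbind, unname(groups))
  traits <- data.frame(
    species = rownames(mat),
    taxonomic_group = rep(names(groups), vapply(groups, nrow, integer(1))),
    stringsAsFactors = FALSE)
  list(mat = mat, traits = traits)
}

grp_mat <- function(name, counts) {
  m <- matrix(counts, ncol = 1, dimnames = list(
    sprintf("%s_sp%02d", name, seq_along(counts)), "SLC2"))
  m
}

test_that("identical groups give F = 0, p = 1 and zero effect", {
  g <- mk_cohort_mat(list(A = grp_mat("A", rep(c(4, 5, 6), 3)),
                          B = grp_mat("B", rep(c(4, 5, 6), 3))))
  res <- family_anova(g$mat, g$traits, min_group = 8L)
  expect_true(res$testable)
  expect_equal(res$f_value, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$max_effect, 0)
  expect_false(res$significant)
})

test_that("perfectly separated groups are maximally significant", {
  g <- mk_cohort_mat(list(A = grp_mat("A", rep(10, 8)),
                          B = grp_mat("B", rep(2, 8))))
  res <- family_anova(g$mat, g$traits, min_group = 8L)
  expect_equal(res$max_effect, 8)
  expect_equal(res$p_value, 0)
  expect_true(res$significant)
})

test_that("ANOVA agrees with the sum-of-squares oracle to 1e-10 relative", {
  set.seed(161)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    sizes <- sample(8:15, k, replace = TRUE)
    y <- unlist(lapply(seq_len(k), function(j) {
      rnorm(sizes[j], mean = sample(3:12, 1), sd = runif(1, 0.5, 3))
    }))
    g <- rep(paste0("G", seq_len(k)), sizes)
    groups <- split(seq_along(y), g)
    mat <- matrix(y, ncol = 1,
                  dimnames = list(sprintf("sp%03d", seq_along(y)), "SLC9"))
    traits <- data.frame(species = rownames(mat), taxonomic_group = g)
    res <- family_anova(mat, traits, min_group = 8L)
    orc <- oracle_anova(y, g)
    expect_equal(res$f_value, orc$f, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
  }
})

test_that("p-values are invariant to shifting all counts by a constant", {
  set.seed(171)
  y <- rnorm(24, 10, 2)
  g <- rep(c("A", "B", "C"), each = 8)
  mat1 <- matrix(y, ncol = 1, dimnames = list(sprintf("s%02d", 1:24), "SLC1"))
  mat2 <- mat1 + 7
  traits <- data.frame(species = rownames(mat1), taxonomic_group = g)
  r1 <- family_anova(mat1, traits, min_group = 8L)
  r2 <- family_anova(mat2, traits, min_group = 8L)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-8)
  expect_equal(r1$max_effect, r2$max_effect, tolerance = 1e-8)
})

test_that("groups below eight members are excluded, small designs untestable", {
  counts <- c(rep(5, 8), rep(9, 8), rep(20, 4))  # third group ineligible
  g <- rep(c("A", "B", "C"), c(8, 8, 4))
  mat <- matrix(counts, ncol = 1,
                dimnames = list(sprintf("s%02d", seq_along(counts)), "SLC3"))
  traits <- data.frame(species = rownames(mat), taxonomic_group = g)
  res <- family_anova(mat, traits, min_group = 8L)
  expect_equal(res$n_groups, 2L)  # C dropped
  expect_equal(res$max_effect, 4)  # |5 - 9|, group C's 20 never seen

  # Only one eligible group: not testable.
  traits2 <- traits; traits2$taxonomic_group <- rep(c("A", "B"), c(16, 4))
  res2 <- family_anova(mat, traits2, min_group = 8L)
  expect_false(res2$testable)
  expect_false(res2$significant)
})

test_that("Bonferroni multiplies and caps at one", {
  expect_equal(bonferroni(0.001, 198), 0.198)
  expect_equal(bonferroni(0.9, 198), 1)
  expect_equal(bonferroni(0.37, 1), 0.37)
  # m equals the number of testable comparisons actually performed.
  g <- mk_cohort_mat(list(A = grp_mat("A", rnorm(8, 5)),
                          B = grp_mat("B", rnorm(8, 6))))
  res <- family_anova(g$mat, g$traits, min_group = 8L)
  expect_equal(attr(res, "m"), 1L)
  expect_equal(res$bonferroni_p, min(1, res$p_value * 1))
})

test_that("the significance gate needs both a tiny p and a large effect", {
  set.seed(181)
  # Big effect but modest p: not significant.
  a <- rnorm(8, 10, 6); b <- rnorm(8, 14, 6)
  mat <- matrix(c(a, b), ncol = 1,
                dimnames = list(sprintf("s%02d", 1:16), "SLC5"))
  traits <- data.frame(species = rownames(mat),
                       taxonomic_group = rep(c("A", "B"), each = 8))
  res <- family_anova(mat, traits, min_group = 8L)
  if (res$p_value >= 1e-5) expect_false(res$significant)

  # Tiny p but effect below three genes: not significant.
  a2 <- rep(c(5, 5.1), 8); b2 <- rep(c(7, 7.1), 8)
  mat2 <- matrix(c(a2, b2), ncol = 1,
                 dimnames = list(sprintf("t%02d", 1:32), "SLC5"))
  traits2 <- data.frame(species = rownames(mat2),
                        taxonomic_group = rep(c("A", "B"), each = 16))
  res2 <- family_anova(mat2, traits2, min_group = 8L)
  expect_lt(res2$p_value, 1e-5)
  expect_lt(res2$max_effect, 3)
  expect_false(res2$significant)
})

test_that("coefficients of variation match the closed form and scale-cancel", {
  mat <- cbind(SLC1 = c(2, 2, 2), SLC2 = c(1, 3, 0), SLC3 = c(0, 0, 0))
  rownames(mat) <- c("s1", "s2", "s3")
  cv <- family_cv(mat)
  expect_equal(unname(cv["SLC1"]), 0)
  expect_true(is.na(cv["SLC3"]))
  expect_equal(unname(family_cv(mat[, "SLC2", drop = FALSE][1:2, ,
                                                            drop = FALSE])),
               sqrt(2) / 2, tolerance = 1e-6)

  set.seed(191)
  for (i in 1:50) {
    x <- matrix(runif(30, 1, 20), ncol = 3,
                dimnames = list(sprintf("s%d", 1:10), paste0("SLC", 1:3)))
    c_scale <- runif(1, 0.1, 50)
    expect_equal(family_cv(x), family_cv(x * c_scale), tolerance = 1e-10)
    expect_equal(unname(family_cv(x)),
                 apply(x, 2, sd) / colMeans(x), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("species clustering is deterministic and matches a naive oracle", {
  mat <- rbind(s1 = c(5, 5, 5), s2 = c(5, 5, 5), s3 = c(20, 1, 9))
  colnames(mat) <- paste0("SLC", 1:3)
  cl <- cluster_species(mat)
  expect_equal(cl$hclust$height[1], 0)  # identical rows merge first at 0
  expect_true(grepl("s1", cl$newick) && grepl("s3", cl$newick))

  single <- cluster_species(mat[1, , drop = FALSE])
  expect_null(single$hclust)
  expect_equal(single$newick, "s1;")

  set.seed(201)
  rmat <- matrix(runif(20 * 6, 0, 30), nrow = 20,
                 dimnames = list(sprintf("sp%02d", 1:20), paste0("SLC", 1:6)))
  cl2 <- cluster_species(rmat)
  expect_equal(cl2$hclust$height, oracle_complete_linkage_heights(rmat),
               tolerance = 1e-10)
  expect_equal(rownames(cl2$ordered), rownames(rmat)[cl2$hclust$order])
})

test_that("CAFE export validates ultrametricity and round-trips counts", {
  set.seed(211)
  mat <- matrix(sample(0:15, 4 * 3, replace = TRUE), nrow = 4,
                dimnames = list(paste0("sp", 1:4), paste0("SLC", c(1, 2, 7))))
  tree <- ape::rcoal(4, tip.label = paste0("sp", 1:4))
  cf <- withr::local_tempfile(fileext = ".tsv")
  tf <- withr::local_tempfile(fileext = ".nwk")
  out <- cafe_export(mat, tree, counts_file = cf, tree_file = tf)
  expect_identical(read_cafe_counts(cf), mat)

  # Pruning preserves tip depths (the pruned tree stays ultrametric).
  out2 <- cafe_export(mat, tree, species = paste0("sp", 1:2),
                      counts_file = cf, tree_file = tf)
  d <- ape::node.depth.edgelength(out2$tree)[1:2]
  expect_lt(max(d) - min(d), 1e-8)
  expect_identical(read_cafe_counts(cf), mat[1:2, , drop = FALSE])

  # Non-ultrametric trees are rejected with the measured spread.
  bad <- tree; bad$edge.length[1] <- bad$edge.length[1] + 1
  expect_error(cafe_export(mat, bad, counts_file = cf, tree_file = tf),
               "ultrametric")
  expect_error(cafe_export(mat, tree, species = c("sp1", "ghost"),
                           counts_file = cf, tree_file = tf), "ghost")

  # Random matrices: emit -> parse is identity.
  for (i in 1:10) {
    m <- matrix(sample(0:30, 12, replace = TRUE), nrow = 3,
                dimnames = list(paste0("x", 1:3), paste0("SLC", 1:4)))
    tr <- ape::rcoal(3, tip.label = paste0("x", 1:3))
    cafe_export(m, tr, counts_file = cf, tree_file = tf)
    expect_identical(read_cafe_counts(cf), m)
  }
})

test_that("Newick emitted by clustering parses back to the same topology", {
  set.seed(221)
  mat <- matrix(runif(8 * 4, 0, 20), nrow = 8,
                dimnames = list(sprintf("sp%d", 1:8), paste0("SLC", 1:4)))
  cl <- cluster_species(mat)
  phy <- ape::read.tree(text = cl$newick)
  expect_setequal(phy$tip.label, rownames(mat))
  expect_equal(ape::Ntip(phy), 8)
})
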