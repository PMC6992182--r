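fixture_matrix <- function(scale = TRUE) {
  index_matrix(nutritional_indices(load_study_fixture()), scale = scale)
}

test_that("z-scoring gives each index column mean 0 and sample SD 1", {
  m <- fixture_matrix()
  expect_equal(unname(colMeans(m)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(m, 2, sd)), rep(1, 5), tolerance = 1e-9)
})

test_that("unscaled matrices carry the input values through", {
  ind <- nutritional_indices(load_study_fixture())
  m <- index_matrix(ind, scale = FALSE)
  expect_equal(unname(m[, "ia"]), ind$ia)
  expect_equal(rownames(m), ind$species)
})

test_that("two-species z-scores are the closed-form +/- 1/sqrt(2) pair", {
  ind <- data.frame(species = c("a", "b"), ia = c(0.5, 1.0), hh = c(2, 1))
  m <- index_matrix(ind, scale = TRUE)
  expect_equal(sort(unname(m[, "ia"])), c(-1, 1) / sqrt(2))
  expect_equal(sort(unname(m[, "hh"])), c(-1, 1) / sqrt(2))
})

test_that("zero-variance columns cannot be z-scored", {
  ind <- data.frame(species = c("a", "b", "c"), ia = c(1, 1, 1),
                    hh = c(1, 2, 3))
  expect_error(index_matrix(ind, scale = TRUE), "zero-variance")
  expect_silent(index_matrix(ind, scale = FALSE))
})

test_that("identical species merge at height zero", {
  ind <- data.frame(species = c("a", "b", "c"),
                    ia = c(1, 1, 3), hh = c(2, 2, 5))
  m <- index_matrix(ind, scale = FALSE)
  cl <- cluster_species(m, k = 2)
  expect_equal(min(cl$hclust$height), 0)
  expect_equal(cl$groups[["a"]], cl$groups[["b"]])
})

test_that("complete linkage merges the closest collinear pair first", {
  # points at 0, 1 and 4 on a line: brute force over merge orders says the
  # (0,1) pair (distance 1) merges before anything else
  ind <- data.frame(species = c("p0", "p1", "p4"), v = c(0, 1, 4),
                    w = c(0, 0, 0) + 1)
  m <- index_matrix(ind[, c("species", "v")], scale = FALSE)
  cl <- cluster_species(m, linkage = "complete", k = 2)
  expect_equal(cl$groups[["p0"]], cl$groups[["p1"]])
  expect_false(cl$groups[["p4"]] == cl$groups[["p0"]])
  expect_equal(cl$hclust$height, c(1, 4))
})

test_that("the four-group cut yields four non-empty groups on the survey", {
  for (linkage in c("complete", "average", "ward")) {
    cl <- cluster_species(fixture_matrix(), linkage = linkage, k = 4)
    expect_equal(sort(unique(cl$groups)), 1:4, label = linkage)
    expect_true(all(table(cl$groups) >= 1))
    expect_equal(sort(names(cl$groups)), sort(cl$leaf_order))
  }
})

test_that("group ids increase with composite nutritional quality", {
  cl <- cluster_species(fixture_matrix(), k = 4)
  m <- fixture_matrix()
  score <- rowMeans(m[, c("hh", "ps")]) - rowMeans(m[, c("ia", "it", "n6_n3")])
  group_means <- tapply(score, cl$groups[rownames(m)], mean)
  expect_true(all(diff(group_means) > 0))
})

test_that("the nutritionally best survey group holds the published five species", {
  best <- c("Collichthys lucidus", "Ilisha elongata", "Trypauchen vagina",
            "Odontamblyopus rubicundus", "Sillago sihama")
  hit <- FALSE
  for (linkage in c("complete", "average", "ward")) {
    cl <- cluster_species(fixture_matrix(), linkage = linkage, k = 4)
    top <- names(cl$groups)[cl$groups == 4]
    if (setequal(top, best)) hit <- TRUE
  }
  expect_true(hit)
})

test_that("clustering is invariant to the order of input rows", {
  ind <- nutritional_indices(load_study_fixture())
  cl1 <- cluster_species(index_matrix(ind), k = 4)
  set.seed(3)
  for (i in 1:3) {
    perm <- sample(nrow(ind))
    cl2 <- cluster_species(index_matrix(ind[perm, ]), k = 4)
    expect_equal(cl2$groups[names(cl1$groups)], cl1$groups)
  }
})

test_that("the heatmap TSV is the reordered matrix and round-trips", {
  m <- fixture_matrix()
  cl <- cluster_species(m, k = 4)
  path <- tempfile(fileext = ".tsv")
  export_heatmap(m, cl, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(back), 22)
  expect_equal(back$species, cl$leaf_order)
  expect_equal(as.matrix(back[, -1]),
               unclass(m)[cl$leaf_order, ], tolerance = 1e-6,
               ignore_attr = TRUE)
  # scale-off export equals the indices table up to row permutation
  ind <- nutritional_indices(load_study_fixture())
  m0 <- index_matrix(ind, scale = FALSE)
  cl0 <- cluster_species(m0, k = 4)
  path0 <- tempfile(fileext = ".tsv")
  export_heatmap(m0, cl0, path0)
  back0 <- read.delim(path0, check.names = FALSE)
  back0 <- back0[match(ind$species, back0$species), ]
  expect_equal(back0$ia, ind$ia, tolerance = 1e-6)
})

test_that("degenerate clustering inputs raise errors", {
  ind <- data.frame(species = c("a", "b"), ia = c(1, 2), hh = c(1, 2))
  m <- index_matrix(ind, scale = FALSE)
  expect_error(cluster_species(m, k = 5), "between 1")
  expect_error(index_matrix(ind[1, , drop = FALSE]), "nrow")
})
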