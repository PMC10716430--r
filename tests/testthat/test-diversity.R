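cherry_tree <- function() parse_newick("((A:1{0},B:1{1}):1{2},(C:1{3},D:1{4}):1{5});")

pl_tbl <- function(edges, lwr, names = paste0("r", seq_along(edges))) {
  tibble::tibble(name = names, multiplicity = 1, edge = as.integer(edges),
                 like_weight_ratio = lwr, likelihood = NA_real_)
}

test_that("bwpd matches hand-evaluated cases", {
  tr <- cherry_tree()
  # all mass on one tip: every edge one-sided, diversity 0
  expect_equal(bwpd(tr, tibble::tibble(edge = 0L, mass = 1), theta = 1), 0)

  # two-tip cherry with equal mass and unit pendant edges
  tr2 <- parse_newick("(A:1{0},B:1{1});")
  prof2 <- tibble::tibble(edge = c(0L, 1L), mass = c(0.5, 0.5))
  expect_equal(bwpd(tr2, prof2, theta = 1), 2)

  # theta = 0 gives the branch length of the mass-spanning edges
  # edges 0, 2, 3, 5 (unit length each) carry mass on both sides
  prof <- tibble::tibble(edge = c(0L, 3L), mass = c(0.5, 0.5))
  expect_equal(bwpd(tr, prof, theta = 0), 4)
  expect_error(bwpd(tr, tibble::tibble(edge = 0L, mass = 0.5)), "normalized")
})

test_that("bwpd is non-negative, scale-invariant and non-increasing in theta", {
  set.seed(11)
  for (i in 1:25) {
    tr <- random_tree(sample(4:30, 1))
    edges <- sample(tr$edge_num[-tr$root], sample(2:5, 1))
    w <- rgamma(length(edges), 1)
    prof <- tibble::tibble(edge = edges, mass = w / sum(w))
    thetas <- c(0, 0.25, 0.5, 1)
    vals <- vapply(thetas, function(th) bwpd(tr, prof, theta = th), numeric(1))
    expect_true(all(vals >= 0))
    expect_true(all(diff(vals) <= 1e-12)) # non-increasing in theta
    # normalization of a scaled profile changes nothing
    prof10 <- dplyr::mutate(prof, mass = mass * 10)
    expect_equal(bwpd(tr, dplyr::mutate(prof10, mass = mass / sum(mass))),
                 vals[4])
  }
})

test_that("edge_mass_profiles normalizes per sample and tracks counts", {
  tr <- cherry_tree()
  s1 <- pl_tbl(c(0, 1), c(0.7, 0.7))
  profs <- edge_mass_profiles(list(a = s1), tr)
  expect_equal(sum(profs$mass), 1)
  expect_equal(unname(attr(profs, "n_placements")["a"]), 2)
})

test_that("edge PCA separates opposite cherries along the separating path", {
  tr <- cherry_tree()
  samples <- list(
    s1 = pl_tbl(c(0, 1), c(0.5, 0.5)),
    s2 = pl_tbl(c(3, 4), c(0.5, 0.5))
  )
  profs <- edge_mass_profiles(samples, tr)
  pc <- edge_pca(profs, tr, min_placements = 1)
  # projections symmetric about zero on PC1
  expect_equal(sum(pc$projections$PC1), 0, tolerance = 1e-9)
  expect_gt(abs(pc$projections$PC1[1]), 0.5)
  # internal-edge loadings: only the two cherry edges (the separating path)
  expect_setequal(pc$loadings$edge, c(2L, 5L))
  expect_true(all(abs(pc$loadings$PC1) > 0.1))
  # orthonormal rotation
  rot <- as.matrix(pc$loadings[, -1])
  expect_equal(crossprod(rot), diag(ncol(rot)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("identical samples yield zero eigenvalues and filters apply", {
  tr <- cherry_tree()
  one <- pl_tbl(c(0, 3), c(0.6, 0.4))
  profs <- edge_mass_profiles(list(a = one, b = one, c = one), tr)
  pc <- edge_pca(profs, tr, min_placements = 1)
  expect_equal(max(pc$eigenvalues), 0, tolerance = 1e-12)

  # a sample below the placement floor is excluded
  few <- pl_tbl(0, 1)
  many <- pl_tbl(rep(c(0, 1, 3, 4), 5), rep(0.25, 20),
                 names = paste0("r", 1:20))
  many2 <- pl_tbl(rep(c(0, 4), 10), rep(0.5, 20), names = paste0("q", 1:20))
  profs2 <- edge_mass_profiles(list(small = few, big = many, big2 = many2), tr)
  pc2 <- edge_pca(profs2, tr, min_placements = 20)
  expect_setequal(pc2$retained, c("big", "big2"))
  expect_equal(pc2$dropped, "small")
  expect_error(edge_pca(profs2, tr, min_placements = 21), "fewer than 2")
})

test_that("permuting samples permutes projections identically", {
  set.seed(12)
  tr <- random_tree(12)
  mk <- function() {
    edges <- sample(tr$edge_num[-tr$root], 4)
    pl_tbl(edges, rep(0.25, 4))
  }
  samples <- list(a = mk(), b = mk(), c = mk(), d = mk())
  p1 <- edge_pca(edge_mass_profiles(samples, tr), tr, min_placements = 1)
  p2 <- edge_pca(edge_mass_profiles(samples[c("c", "a", "d", "b")], tr), tr,
                 min_placements = 1)
  m1 <- p1$projections[match(c("c", "a", "d", "b"), p1$projections$sample), ]
  # components are defined up to sign
  for (pc in c("PC1", "PC2")) {
    expect_true(isTRUE(all.equal(m1[[pc]], p2$projections[[pc]], tolerance = 1e-8)) ||
                isTRUE(all.equal(m1[[pc]], -p2$projections[[pc]], tolerance = 1e-8)))
  }
})
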