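read_tbl <- function(edges, lwr, name = "r1", mult = 1) {
  tibble::tibble(name = name, multiplicity = mult, edge = as.integer(edges),
                 like_weight_ratio = lwr, likelihood = NA_real_)
}

test_that("accumulate_read matches hand-worked cases", {
  tr <- parse_newick("((A:1{0},B:1{1}):1{2},(C:1{3},D:1{4}):1{5});")

  # all mass on a tip edge stays there
  expect_equal(accumulate_read(tr, read_tbl(0, 1.0), 0.95), 0L)

  # cherry split 0.6/0.4 accumulates to the subtending edge
  expect_equal(accumulate_read(tr, read_tbl(c(0, 1), c(0.6, 0.4)), 0.95), 2L)

  # 0.96 on one tip beats 0.04 in a distant clade
  expect_equal(accumulate_read(tr, read_tbl(c(0, 3), c(0.96, 0.04)), 0.95), 0L)

  # threshold is relative to realized mass: 0.88/0.90 > 0.95
  expect_equal(accumulate_read(tr, read_tbl(c(0, 3), c(0.88, 0.02)), 0.95), 0L)
  # ... but absolute thresholding pushes the same read to the root sentinel
  expect_true(is.na(accumulate_read(tr, read_tbl(c(0, 3), c(0.88, 0.02)), 0.95,
                                    relative = FALSE)))

  expect_error(accumulate_read(tr, read_tbl(integer(0), numeric(0)), 0.95),
               "no placements")
  expect_error(accumulate_read(tr, read_tbl(0, 1), 0.5), "threshold")
})

test_that("accumulate_read equals the exhaustive most-distal-edge oracle", {
  set.seed(101)
  for (i in 1:200) {
    tr <- random_tree(sample(4:64, 1))
    rd <- random_read(tr)
    th <- runif(1, 0.55, 1)
    expect_identical(accumulate_read(tr, rd, th), oracle_accumulate(tr, rd, th))
  }
})

test_that("raising the threshold never moves the accumulated edge tipward", {
  set.seed(202)
  for (i in 1:100) {
    tr <- random_tree(sample(4:40, 1))
    rd <- random_read(tr)
    th <- sort(runif(2, 0.55, 1))
    d_low <- edge_depth(tr, accumulate_read(tr, rd, th[1]))
    d_high <- edge_depth(tr, accumulate_read(tr, rd, th[2]))
    expect_lte(d_high, d_low)
  }
})

test_that("assign_gene routes edges to genes and applies the dual discard", {
  rp <- simulate_refpkg(c(nrfA = 4, onr = 3, outgroup = 2), seed = 5)
  tr <- rp$tree; rg <- rp$regions

  nrfa_edge <- rg$edges$nrfA[1]
  expect_equal(assign_gene(tr, rg, nrfa_edge,
                           c(nrfA = 1, onr = 0), 1, 0.95), "nrfA")

  # above the split with mass in both genes: discarded
  expect_equal(assign_gene(tr, rg, NA_integer_,
                           c(nrfA = 0.55, onr = 0.40), 0.95, 0.95),
               "dual_discarded")

  # outgroup mass only: unassigned
  out_edge <- rg$edges$outgroup[1]
  expect_equal(assign_gene(tr, rg, out_edge,
                           c(nrfA = 0.02, onr = 0.01), 1, 0.95), "unassigned")
})

test_that("count_genes conserves reads and books dual/unassigned separately", {
  rp <- simulate_refpkg(c(nrfA = 4, onr = 3, outgroup = 3), seed = 6)
  tr <- rp$tree; rg <- rp$regions
  e_nrfa <- rg$edges$nrfA[1]
  e_onr <- rg$edges$onr[1]
  e_out <- rg$edges$outgroup[1]
  pls <- dplyr::bind_rows(
    read_tbl(e_nrfa, 1, "r1"), read_tbl(e_nrfa, 1, "r2"), read_tbl(e_nrfa, 1, "r3"),
    read_tbl(c(e_nrfa, e_onr), c(0.55, 0.45), "r4"), # dual
    read_tbl(e_out, 1, "r5")                         # outgroup
  )
  counts <- count_genes(pls, tr, rg, threshold = 0.95)
  expect_equal(counts$count[counts$label == "nrfA"], 3)
  expect_equal(counts$count[counts$label == "dual_discarded"], 1)
  expect_equal(counts$count[counts$label == "unassigned"], 1)
  expect_equal(sum(counts$count), 5)

  # multiplicity contributes to the tally
  pls_m <- read_tbl(e_nrfa, 1, "rm", mult = 4)
  cm <- count_genes(pls_m, tr, rg)
  expect_equal(cm$count[cm$label == "nrfA"], 4)

  # empty sample: all zeros
  c0 <- count_genes(pls[0, ], tr, rg)
  expect_true(all(c0$count == 0))
})

test_that("classification is order-invariant and exact at zero noise", {
  rp <- simulate_refpkg(c(nrfA = 6, onr = 4, nirK = 4, nirS = 4, outgroup = 3),
                        seed = 8)
  sim <- simulate_placements(rp, c(nrfA = 30, onr = 10, nirK = 20, nirS = 15),
                             spread = 0, cross_region_rate = 0, seed = 9)
  counts <- count_genes(sim$placements, rp$tree, rp$regions)
  expect_equal(counts$count[match(c("nrfA", "onr", "nirK", "nirS"), counts$label)],
               c(30, 10, 20, 15))
  expect_equal(counts$count[counts$label == "dual_discarded"], 0)

  shuf <- sim$placements[sample.int(nrow(sim$placements)), ]
  calls1 <- dplyr::arrange(classify_reads(sim$placements, rp$tree, rp$regions), name)
  calls2 <- dplyr::arrange(classify_reads(shuf, rp$tree, rp$regions), name)
  expect_equal(as.data.frame(calls1), as.data.frame(calls2))
})
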