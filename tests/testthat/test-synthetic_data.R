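test_that("simulate_refpkg builds labeled monophyletic regions deterministically", {
  rp <- simulate_refpkg(c(nrfA = 8, onr = 4, outgroup = 4), seed = 1)
  expect_equal(rp$tree$n_tip, 16L)
  expect_equal(nrow(rp$regions$genes), 3L)
  expect_equal(unname(rp$regions$roles["outgroup"]), "outgroup")
  # target regions pairwise disjoint
  expect_length(intersect(rp$regions$edges$nrfA, rp$regions$edges$onr), 0)

  rp2 <- simulate_refpkg(c(nrfA = 8, onr = 4, outgroup = 4), seed = 1)
  expect_identical(write_newick(rp$tree), write_newick(rp2$tree))
  expect_identical(rp$sequences, rp2$sequences)

  # planted reference peptides classify to their region's class
  calls <- classify_sequences(rp$sequences)
  calls <- dplyr::left_join(calls, rp$classes, by = "id")
  expect_true(all(calls$class.x == calls$class.y))

  expect_error(simulate_refpkg(c(nrfA = 1, onr = 4)), "tips")
})

test_that("simulated placements are valid jplace and recover composition", {
  rp <- simulate_refpkg(c(nrfA = 6, onr = 4, nirK = 4, nirS = 4, outgroup = 3),
                        seed = 2)
  comp <- c(nrfA = 50, onr = 10, nirK = 100, nirS = 50)
  sim <- simulate_placements(rp, comp, spread = 0, cross_region_rate = 0,
                             gbp = 2, seed = 3)
  expect_equal(sim$delta_true, (50 - 150) / 2)

  # round trip through the jplace writer/reader without loss
  path <- file.path(withr::local_tempdir(), "s.jplace")
  write_jplace(rp$tree, sim$placements, path)
  back <- read_jplace(path)
  expect_equal(sort(unique(back$placements$name)),
               sort(unique(sim$placements$name)))
  counts <- count_genes(back$placements, back$tree, rp$regions)
  expect_equal(counts$count[match(names(comp), counts$label)], unname(comp))

  # determinism under the seed
  sim2 <- simulate_placements(rp, comp, spread = 0, cross_region_rate = 0,
                              gbp = 2, seed = 3)
  expect_identical(as.data.frame(sim$placements), as.data.frame(sim2$placements))
  expect_error(simulate_placements(rp, c(nrfA = -1)), ">= 0")
  expect_error(simulate_placements(rp, c(nosZ = 5)), "not target")
})

test_that("placement spread stays inside the true region", {
  rp <- simulate_refpkg(c(nrfA = 8, onr = 5, outgroup = 3), seed = 4)
  sim <- simulate_placements(rp, c(nrfA = 80, onr = 40), spread = 0.5, seed = 5)
  calls <- classify_reads(sim$placements, rp$tree, rp$regions)
  truth <- sim$truth$gene[match(calls$name, sim$truth$name)]
  expect_true(all(calls$label == truth))
  # reads carry at most seven placements
  expect_lte(max(table(sim$placements$name)), 7L)
})

test_that("cross-region leaks trigger the dual discard at the planted rate", {
  rp <- simulate_refpkg(c(nrfA = 6, onr = 5, outgroup = 3), seed = 6)
  sim <- simulate_placements(rp, c(nrfA = 500), spread = 0,
                             cross_region_rate = 0.1, seed = 7)
  counts <- count_genes(sim$placements, rp$tree, rp$regions)
  dual <- counts$count[counts$label == "dual_discarded"]
  expect_equal(dual, sum(sim$truth$leaked))
  ci <- stats::binom.test(dual, 500, p = 0.1)$conf.int
  expect_true(0.1 >= ci[1] && 0.1 <= ci[2])
})

test_that("simulated metadata honors ranges, biomes and planted effects", {
  md <- simulate_metadata(n = 120, seed = 8)
  d <- md$data
  expect_true(all(d$ph >= 4.0 & d$ph <= 9.6))
  expect_true(all(d$nitrate >= 1.0 & d$nitrate <= 59.0))
  expect_true(all(d$organic_carbon >= 0.1 & d$organic_carbon <= 5.9))
  expect_setequal(levels(d$biome), c("Cropland", "Desert", "Forest", "Grassland"))
  # response decomposes into recorded expectation plus noise
  resid <- d$delta_nrfa_nir - md$truth$expected$expected
  expect_lt(abs(mean(resid)), 5)
  expect_lt(abs(sd(resid) - md$truth$noise_sd), 4)

  expect_identical(simulate_metadata(n = 120, seed = 8)$data, d)
  expect_error(simulate_metadata(n = 10), "at least 30")
  expect_error(simulate_metadata(n = 50, biomes = numeric(0)), "biome")
})

test_that("end-to-end: simulate, classify, quantify recovers the true delta", {
  rp <- simulate_refpkg(c(nrfA = 6, onr = 3, nirK = 5, nirS = 4, outgroup = 3),
                        seed = 9)
  sim <- simulate_placements(rp, c(nrfA = 120, onr = 10, nirK = 90, nirS = 60),
                             spread = 0.3, cross_region_rate = 0, gbp = 1.5,
                             seed = 10)
  counts <- count_genes(sim$placements, rp$tree, rp$regions)
  get <- function(g) counts$count[counts$label == g]
  d_hat <- delta_nrfa_nir(get("nrfA"), get("nirK"), get("nirS"), sim$gbp)
  expect_equal(d_hat, sim$delta_true)
})
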