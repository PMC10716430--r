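test_that("collinearity_filter keeps the priority variable of each cluster", {
  set.seed(41)
  a <- runif(60)
  X <- data.frame(a = a, b = a) # rho = 1
  expect_equal(collinearity_filter(X, c("a", "b")), "a")

  # |rho| below the 0.7 boundary keeps both
  repeat {
    x <- rnorm(80); y <- 0.6 * x + rnorm(80)
    if (abs(cor(x, y, method = "spearman")) < 0.69) break
  }
  expect_setequal(collinearity_filter(data.frame(a = x, b = y), c("a", "b")),
                  c("a", "b"))

  # transitive chain a~b~c collapses into one component
  n <- 200
  b <- rnorm(n)
  chain <- data.frame(a = b + rnorm(n, sd = 0.3), b = b,
                      c = b + rnorm(n, sd = 0.3),
                      d = rnorm(n))
  stopifnot(abs(cor(chain$a, chain$b, method = "spearman")) >= 0.7,
            abs(cor(chain$b, chain$c, method = "spearman")) >= 0.7)
  kept <- collinearity_filter(chain, c("b", "a", "c", "d"))
  expect_setequal(kept, c("b", "d"))

  # input column order is irrelevant given the same priority list
  kept2 <- collinearity_filter(chain[, c("d", "c", "b", "a")],
                               c("b", "a", "c", "d"))
  expect_equal(kept, kept2)

  expect_error(collinearity_filter(chain, c("a", "b")), "priority")
})

test_that("tune_rf minimizes OOB RMSE deterministically", {
  md <- simulate_metadata(n = 120, noise_sd = 5, seed = 51)$data
  preds <- c("organic_carbon", "nitrate", "ph", "calcium")
  grid1 <- data.frame(num_trees = 100, mtry = 2, max_depth = 5)
  fit1 <- tune_rf(md, "delta_nrfa_nir", preds, grid1, seed = 1)
  expect_equal(fit1$params$num_trees, 100)

  grid <- expand.grid(num_trees = c(100, 200), mtry = c(1, 2), max_depth = c(3, 9))
  fitA <- tune_rf(md, "delta_nrfa_nir", preds, grid, seed = 2)
  fitB <- tune_rf(md, "delta_nrfa_nir", preds, grid, seed = 2)
  expect_equal(fitA$params, fitB$params)
  expect_equal(fitA$results$oob_rmse, fitB$results$oob_rmse)
  expect_equal(min(fitA$results$oob_rmse), fitA$params$oob_rmse)

  expect_error(tune_rf(md, "delta_nrfa_nir", preds,
                       data.frame(num_trees = 50, mtry = 10, max_depth = 0)),
               "mtry")
})

test_that("a pure-noise response has no out-of-bag signal", {
  set.seed(61)
  r2 <- replicate(3, {
    d <- data.frame(y = rnorm(150), a = rnorm(150), b = rnorm(150), c = rnorm(150))
    fit <- tune_rf(d, "y", c("a", "b", "c"),
                   expand.grid(num_trees = 200, mtry = 1:2, max_depth = c(0, 5)),
                   seed = sample.int(1e6, 1))
    fit$model$r.squared
  })
  expect_true(all(r2 <= 0.1))
})

test_that("ALE recovers closed forms for linear and additive predictors", {
  set.seed(71)
  X <- data.frame(x1 = runif(600), x2 = runif(600, -1, 1))

  # linear predictor: slope 2, interval-weighted mean exactly zero
  a1 <- ale(function(d) 2 * d$x1, X, "x1", grid_size = 30)
  expect_equal(sum(a1$n * a1$effect) / sum(a1$n), 0, tolerance = 1e-9)
  slopes <- diff(a1$effect) / diff(a1$x)
  expect_equal(unname(slopes), rep(2, length(slopes)), tolerance = 1e-9)

  # constant predictor: flat zero
  a0 <- ale(function(d) rep(3, nrow(d)), X, "x1")
  expect_true(all(abs(a0$effect) < 1e-12))

  # additive predictor: ALE of x2 matches x2^2 - E[x2^2] up to grid error
  f <- function(d) d$x1 + d$x2^2
  a2 <- ale(f, X, "x2", grid_size = 30)
  expected <- a2$x^2 - mean(X$x2^2)
  expect_lt(max(abs(a2$effect - expected)), 0.02)

  # invariance to adding a constant to the predictor
  a3 <- ale(function(d) 2 * d$x1 + 100, X, "x1", grid_size = 30)
  expect_equal(a3$effect, a1$effect, tolerance = 1e-9)

  expect_error(ale(f, transform(X, x1 = 1), "x1"), "constant")
})

test_that("categorical ALE centers per-level effects", {
  set.seed(72)
  X <- data.frame(x = runif(300),
                  biome = factor(sample(c("Cropland", "Forest", "Grassland"),
                                        300, TRUE)))
  f <- function(d) ifelse(d$biome == "Cropland", -40, 10) + d$x
  a <- ale(f, X, "biome")
  expect_equal(sum(a$n * a$effect) / sum(a$n), 0, tolerance = 1e-9)
  expect_lt(a$effect[a$x == "Cropland"], -20)
  expect_gt(a$effect[a$x == "Forest"], 0)
})

test_that("a planted monotone soil effect is recovered by the fitted model", {
  # plant a saturating monotone pH effect and check the fitted ALE is
  # monotone with a matching effect range, averaged over 10 simulations
  f_true <- function(d) 20 * tanh(2 * (d$ph - 6.8))
  trend <- numeric(10); rng_ratio <- numeric(10)
  for (s in 1:10) {
    md <- simulate_metadata(n = 250, effects = list(ph_eff = f_true),
                            noise_sd = 8, seed = 100 + s)$data
    fit <- tune_rf(md, "delta_nrfa_nir",
                   c("organic_carbon", "nitrate", "ph", "calcium", "copper", "biome"),
                   data.frame(num_trees = 300, mtry = 2, max_depth = 9),
                   seed = s)
    a <- ale(fit, md, "ph", grid_size = 20)
    trend[s] <- cor(a$x, a$effect, method = "spearman")
    rng_true <- diff(range(f_true(data.frame(ph = a$x))))
    rng_ratio[s] <- diff(range(a$effect)) / rng_true
  }
  expect_gt(mean(trend), 0.9)
  expect_lt(abs(mean(rng_ratio) - 1), 0.25)
})

test_that("select_predictors drops pure-noise variables", {
  md <- simulate_metadata(n = 200, noise_sd = 5, seed = 81)$data
  md$junk <- rnorm(200)
  sel <- select_predictors(md, "delta_nrfa_nir",
                           c("organic_carbon", "nitrate", "junk"),
                           n_repeats = 3, num_trees = 300, seed = 7)
  expect_true(all(c("organic_carbon", "nitrate") %in% sel$selected))
  expect_false("junk" %in% sel$selected)
})
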