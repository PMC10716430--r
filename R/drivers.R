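#' Prune collinear predictors by Spearman correlation
#'
#' Builds a graph joining variable pairs with `|rho| >= r_threshold`
#' (Spearman) and keeps the highest-priority variable of each connected
#' component. Deterministic, and independent of column order given the same
#' priority list.
#'
#' @param X data frame of numeric predictors (>= 2 columns).
#' @param priority character vector ordering ALL columns of `X` from most to
#'   least relevant for the process under study.
#' @param r_threshold absolute Spearman correlation at or above which two
#'   variables are considered collinear.
#' @return character vector of retained variable names (in priority order).
#' @export
collinearity_filter <- function(X, priority, r_threshold = 0.7) {
  stopifnot(ncol(X) >= 2L)
  if (!setequal(priority, names(X)) || anyDuplicated(priority)) {
    stop("priority must list every predictor exactly once", call. = FALSE)
  }
  rho <- stats::cor(as.data.frame(X), method = "spearman")
  adj <- abs(rho) >= r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  keep <- vapply(split(names(comp), comp), function(vars) {
    vars[which.min(match(vars, priority))]
  }, character(1))
  priority[priority %in% keep]
}

#' Permutation-importance variable elimination
#'
#' A simple stand-in for forest-based variable selection: fits a random
#' forest, measures permutation importance over `n_repeats` refits, and
#' drops variables whose importance is not positive in every repeat.
#'
#' @param data data frame containing response and predictors.
#' @param response response column name.
#' @param predictors predictor column names.
#' @param n_repeats number of refits.
#' @param num_trees trees per forest.
#' @param seed integer seed.
#' @return list with `selected` (character) and `importance` (tibble
#'   `variable`, `repeat`, `importance`).
#' @export
select_predictors <- function(data, response, predictors, n_repeats = 5,
                              num_trees = 500, seed = 1L) {
  imp <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    fit <- ranger::ranger(
      stats::reformulate(predictors, response), data = data,
      num.trees = num_trees, importance = "permutation",
      seed = as.integer(seed) + r,
      respect.unordered.factors = "order"
    )
    tibble::tibble(variable = names(fit$variable.importance),
                   rep = r, importance = unname(fit$variable.importance))
  })
  keep <- imp |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(always_positive = all(.data$importance > 0), .groups = "drop") |>
    dplyr::filter(.data$always_positive)
  list(selected = predictors[predictors %in% keep$variable], importance = imp)
}

#' Tune a random forest by out-of-bag RMSE over a parameter grid
#'
#' Fits one forest per grid row and keeps the combination with the lowest
#' out-of-bag root-mean-square error; ties are broken towards a smaller
#' maximum depth, then fewer features per split. Deterministic under a seed
#' (the same seed is used for every candidate).
#'
#' @param data data frame containing response and predictors.
#' @param response response column name.
#' @param predictors predictor column names.
#' @param grid data frame with columns `num_trees`, `mtry`, `max_depth`
#'   (`max_depth = 0` means unlimited).
#' @param seed integer seed.
#' @return object of class `nitro_rf_tune`: list with `model` (the winning
#'   `ranger` fit), `params` (one-row tibble), `results` (grid with
#'   `oob_rmse`), `response`, `predictors`. [generics::tidy()] returns the
#'   grid results, [generics::glance()] the winner.
#' @export
tune_rf <- function(data, response, predictors, grid, seed = 1L) {
  stopifnot(nrow(grid) >= 1L,
            all(c("num_trees", "mtry", "max_depth") %in% names(grid)))
  if (any(grid$mtry > length(predictors))) {
    stop("grid mtry exceeds the number of predictors", call. = FALSE)
  }
  form <- stats::reformulate(predictors, response)
  results <- grid |>
    tibble::as_tibble() |>
    dplyr::mutate(oob_rmse = purrr::pmap_dbl(
      list(.data$num_trees, .data$mtry, .data$max_depth),
      function(nt, mt, md) {
        fit <- ranger::ranger(form, data = data, num.trees = nt, mtry = mt,
                              max.depth = md, seed = as.integer(seed),
                              respect.unordered.factors = "order")
        sqrt(fit$prediction.error)
      }
    ))
  best <- results |>
    dplyr::arrange(.data$oob_rmse, .data$max_depth, .data$mtry) |>
    dplyr::slice(1)
  model <- ranger::ranger(form, data = data, num.trees = best$num_trees,
                          mtry = best$mtry, max.depth = best$max_depth,
                          seed = as.integer(seed),
                          respect.unordered.factors = "order")
  structure(
    list(model = model, params = best, results = results,
         response = response, predictors = predictors, seed = seed),
    class = "nitro_rf_tune"
  )
}

#' @export
print.nitro_rf_tune <- function(x, ...) {
  cat("<nitro_rf_tune> best: ", x$params$num_trees, " trees, mtry ",
      x$params$mtry, ", max depth ", x$params$max_depth,
      ", OOB RMSE ", format(x$params$oob_rmse, digits = 5), "\n", sep = "")
  invisible(x)
}

#' @method tidy nitro_rf_tune
#' @export
tidy.nitro_rf_tune <- function(x, ...) x$results

#' @method glance nitro_rf_tune
#' @export
glance.nitro_rf_tune <- function(x, ...) {
  dplyr::mutate(x$params, oob_r_squared = x$model$r.squared)
}

#' @export
predict.nitro_rf_tune <- function(object, newdata, ...) {
  stats::predict(object$model, data = newdata)$predictions
}

#' Accumulated local effects of one predictor
#'
#' First-order ALE: the feature range is cut at `grid_size` quantile
#' breakpoints; within each interval the mean prediction difference between
#' the interval's endpoints (holding all other features at their observed
#' values) is accumulated, and the resulting curve is centered so that its
#' interval-mass-weighted mean is zero. Positive values mean predictions
#' above the average, negative below. Unlike partial dependence, ALE only
#' evaluates the model near observed data, so it is robust to correlated
#' predictors.
#'
#' Categorical features get one centered effect per level (mean prediction
#' with the feature set to that level, centered by level frequencies).
#'
#' @param predict_fn function taking a data frame and returning numeric
#'   predictions (e.g. `function(d) predict(fit, d)`), or a
#'   `nitro_rf_tune` object.
#' @param X data frame of observed predictor values.
#' @param feature feature name.
#' @param grid_size number of intervals for numeric features.
#' @return object of class `nitro_ale`: tibble `feature`, `x` (right
#'   breakpoint or level), `effect`, `n` (points per interval), plus
#'   attribute `breaks`. [generics::tidy()] returns the tibble.
#' @export
ale <- function(predict_fn, X, feature, grid_size = 30) {
  if (inherits(predict_fn, "nitro_rf_tune")) {
    fit <- predict_fn
    predict_fn <- function(d) stats::predict(fit, d)
  }
  stopifnot(is.function(predict_fn), feature %in% names(X))
  x <- X[[feature]]
  if (is.numeric(x)) {
    if (length(unique(x)) < 2L) stop("constant feature: ALE undefined", call. = FALSE)
    breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = grid_size + 1),
                                     type = 7, names = FALSE))
    K <- length(breaks) - 1L
    if (K < 1L) stop("feature has too few distinct values", call. = FALSE)
    interval <- findInterval(x, breaks, all.inside = TRUE) # 1..K
    delta <- numeric(K); n_k <- integer(K)
    for (k in seq_len(K)) {
      idx <- which(interval == k)
      n_k[k] <- length(idx)
      if (n_k[k] == 0L) next
      hi <- X[idx, , drop = FALSE]; hi[[feature]] <- breaks[k + 1L]
      lo <- X[idx, , drop = FALSE]; lo[[feature]] <- breaks[k]
      delta[k] <- mean(predict_fn(hi) - predict_fn(lo))
    }
    g <- cumsum(delta) # effect at right breakpoint of each interval
    center <- sum(n_k * g) / sum(n_k)
    out <- tibble::tibble(feature = feature, x = breaks[-1L],
                          effect = g - center, n = n_k)
    attr(out, "breaks") <- breaks
  } else {
    lev <- if (is.factor(x)) levels(droplevels(factor(x))) else sort(unique(as.character(x)))
    if (length(lev) < 2L) stop("constant feature: ALE undefined", call. = FALSE)
    eff <- vapply(lev, function(l) {
      Z <- X
      Z[[feature]] <- factor(l, levels = lev)
      mean(predict_fn(Z))
    }, numeric(1))
    n_k <- as.integer(table(factor(as.character(x), levels = lev)))
    center <- sum(n_k * eff) / sum(n_k)
    out <- tibble::tibble(feature = feature, x = lev,
                          effect = unname(eff) - center, n = n_k)
  }
  structure(out, class = c("nitro_ale", class(out)))
}

#' @method tidy nitro_ale
#' @export
tidy.nitro_ale <- function(x, ...) tibble::as_tibble(x)
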