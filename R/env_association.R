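# Genotype-environment association: VIF pruning, environmental PCA,
# Kruskal-Wallis, GLMs, logistic regression, dbRDA, Mantel tests.

#' Iterative VIF pruning of environmental variables
#'
#' Repeatedly drops the variable with the largest variance inflation
#' factor (`VIF_j = 1/(1 - R2_j)` from regressing variable j on the
#' others) until all remaining VIF values fall below the threshold.
#' Exact collinearity yields an infinite VIF and is dropped first;
#' ties break by column order.
#'
#' @param env data frame of numeric variables (rows > variables).
#' @param threshold VIF threshold (default 10).
#' @param variables optional subset of column names to consider.
#' @return list: `retained` (character), `log` (tibble of steps with
#'   the VIF of each dropped variable), `vif` (final VIFs).
#' @export
vif_prune <- function(env, threshold = 10, variables = NULL) {
  vars <- variables %||% names(env)[vapply(env, is.numeric, logical(1))]
  if (length(vars) < 2) stop("need >= 2 numeric variables", call. = FALSE)
  if (nrow(env) <= length(vars))
    stop("need more rows than variables", call. = FALSE)
  vif_of <- function(active) {
    vapply(active, function(v) {
      r2 <- suppressWarnings(summary(stats::lm(
        stats::reformulate(active[active != v], v), data = env)))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  log <- tibble::tibble(step = integer(), dropped = character(),
                        vif = numeric())
  active <- vars
  step <- 0L
  repeat {
    v <- vif_of(active)
    if (max(v) < threshold || length(active) == 2) break
    step <- step + 1L
    worst <- names(v)[which.max(v)]
    log <- dplyr::add_row(log, step = step, dropped = worst,
                          vif = unname(v[worst]))
    active <- setdiff(active, worst)
  }
  list(retained = active, log = log, vif = vif_of(active))
}

#' PCA of environmental variables
#'
#' PCA on the correlation matrix (variables standardized); percent
#' variance per component sums to 100.
#'
#' @param env data frame.
#' @param variables numeric columns to use (default: all numeric).
#' @return `ssr_pca`: `scores` tibble (PC columns plus any non-numeric
#'   input columns), `loadings`, `percent`.
#' @export
pca_env <- function(env, variables = NULL) {
  vars <- variables %||% names(env)[vapply(env, is.numeric, logical(1))]
  X <- as.matrix(env[, vars])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column: ", paste(vars[sds == 0], collapse = ", "),
         call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(as.data.frame(pc$x))
  extra <- env[, setdiff(names(env), vars), drop = FALSE]
  structure(list(scores = dplyr::bind_cols(tibble::as_tibble(extra), scores),
                 loadings = pc$rotation, percent = pct, variables = vars),
            class = "ssr_pca")
}

#' Kruskal-Wallis test of group differences per axis
#'
#' Rank-based Kruskal-Wallis chi-squared (with tie correction) of each
#' score column against the group labels.
#'
#' @param scores data frame of axis scores (e.g. `$scores` of
#'   [pca_env()] or a subset of PC columns).
#' @param groups group label vector (>= 2 groups, >= 2 obs each), or
#'   the name of a column in `scores`.
#' @param axes columns to test (default: all numeric columns).
#' @return tibble: axis, chisq, df, p.
#' @export
kw_species_test <- function(scores, groups, axes = NULL) {
  if (is.character(groups) && length(groups) == 1) {
    gcol <- groups
    groups <- scores[[gcol]]
    scores <- scores[, setdiff(names(scores), gcol)]
  }
  axes <- axes %||% names(scores)[vapply(scores, is.numeric, logical(1))]
  g <- factor(groups)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  purrr::map_dfr(axes, function(a) {
    x <- scores[[a]]
    if (length(unique(x)) == 1) {
      warning("all values tied on ", a, "; p = 1", call. = FALSE)
      return(tibble::tibble(axis = a, chisq = 0, df = nlevels(g) - 1L,
                            p = 1))
    }
    kt <- stats::kruskal.test(x, g)
    tibble::tibble(axis = a, chisq = unname(kt$statistic),
                   df = unname(kt$parameter), p = kt$p.value)
  })
}

#' Regress environmental variables on two ordination axes
#'
#' Per variable: the two-predictor linear model
#' `variable ~ axis1 + axis2`, reported as per-axis slope, SE, t and p
#' plus the model's adjusted R-squared, overall F and p.
#'
#' @param env data frame of environmental variables.
#' @param axes data frame/matrix with exactly two numeric axis columns.
#' @param variables variables to fit (default: all numeric in `env`).
#' @return tibble, one row per variable x axis, with model-level
#'   columns repeated (`adj_r2`, `f`, `model_p`).
#' @export
glm_on_axis <- function(env, axes, variables = NULL) {
  axes <- as.data.frame(axes)
  if (ncol(axes) != 2) stop("need exactly two axes", call. = FALSE)
  if (any(vapply(axes, stats::sd, numeric(1)) == 0))
    stop("zero-variance axis", call. = FALSE)
  if (nrow(axes) < 3) stop("need n >= 3", call. = FALSE)
  names(axes) <- c("axis1", "axis2")
  vars <- variables %||% names(env)[vapply(env, is.numeric, logical(1))]
  purrr::map_dfr(vars, function(v) {
    d <- cbind(y = env[[v]], axes)
    fit <- stats::lm(y ~ axis1 + axis2, data = d)
    sm <- summary(fit)
    co <- sm$coefficients
    fstat <- sm$fstatistic
    tibble::tibble(
      variable = v, axis = c("axis1", "axis2"),
      estimate = co[2:3, 1], se = co[2:3, 2],
      t = co[2:3, 3], p = co[2:3, 4],
      adj_r2 = sm$adj.r.squared,
      f = unname(fstat[1]),
      model_p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  })
}

#' Multivariate logistic regression of species on predictors
#'
#' Maximum-likelihood logistic fit (IRLS) of a binary species label on
#' all predictors jointly; Wald `Z = coef / SE`. Perfect separation is
#' detected (diverging coefficients / vanishing residual deviance) and
#' flagged in the `separation` attribute rather than silently
#' returned.
#'
#' @param data data frame holding predictors.
#' @param species binary label vector (or name of a column in `data`).
#' @param predictors predictor column names (default: all numeric).
#' @return tibble: term, estimate, se, z, p. Attribute `separation`.
#' @export
logistic_species <- function(data, species, predictors = NULL) {
  if (is.character(species) && length(species) == 1) {
    sp <- data[[species]]
    data <- data[, setdiff(names(data), species), drop = FALSE]
  } else sp <- species
  y <- as.integer(factor(sp)) - 1L
  if (length(unique(y)) != 2) stop("species label must be binary",
                                   call. = FALSE)
  preds <- predictors %||% names(data)[vapply(data, is.numeric, logical(1))]
  if (length(y) <= length(preds))
    stop("need n > number of predictors", call. = FALSE)
  X <- as.data.frame(data[, preds, drop = FALSE])
  qx <- qr(scale(as.matrix(X), scale = FALSE))
  if (qx$rank < ncol(X))
    stop("rank-deficient predictors (duplicated column?)", call. = FALSE)
  d <- cbind(y = y, X)
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sep <- fit$deviance < 1e-6 * max(fit$null.deviance, 1) || !fit$converged
  if (sep) warning("perfect separation detected; coefficients diverge",
                   call. = FALSE)
  co <- summary(fit)$coefficients
  out <- tibble::tibble(term = rownames(co), estimate = co[, 1],
                        se = co[, 2], z = co[, 3], p = co[, 4])
  attr(out, "separation") <- sep
  out
}

#' Leading principal components of the genotype matrix
#'
#' PCA of the centered one-hot allele-count matrix; the genetic
#' response used by the constrained ordination.
#'
#' @param ds [microsat_data()] object.
#' @param n_pcs components to return.
#' @return tibble: individual, population, species, PC columns.
#' @export
genetic_pcs <- function(ds, n_pcs = 2) {
  assert_ssr_geno(ds)
  X <- allele_count_matrix(ds)
  X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  dplyr::bind_cols(ds$individuals,
                   tibble::as_tibble(as.data.frame(
                     pc$x[, seq_len(n_pcs), drop = FALSE])))
}

#' Distance-based redundancy analysis with marginal permutation tests
#'
#' Euclidean distances on the genetic response are decomposed into
#' principal coordinates and constrained on the standardized
#' predictors (for Euclidean distance this equals an RDA on the
#' response matrix). Per-variable significance is the type II
#' (marginal) permutation F of each variable given all others;
#' adjusted R-squared follows Ezekiel's formula.
#'
#' @param response numeric matrix/data frame (e.g. [genetic_pcs()]
#'   PC columns), rows aligned with `env`.
#' @param env data frame of predictors.
#' @param predictors predictor column names (default: all numeric in
#'   `env`).
#' @param n_perm permutations for the marginal tests.
#' @param seed optional RNG seed.
#' @return `ssr_dbrda`: inertia partition, adjusted R2, per-variable
#'   F/p tibble, site scores, and the underlying vegan model.
#' @export
dbrda_env <- function(response, env, predictors = NULL, n_perm = 9999,
                      seed = NULL) {
  preds <- predictors %||% names(env)[vapply(env, is.numeric, logical(1))]
  rdf <- as.data.frame(response)
  Y <- as.matrix(rdf[, vapply(rdf, is.numeric, logical(1)), drop = FALSE])
  if (nrow(Y) != nrow(env)) stop("response and env rows not aligned",
                                 call. = FALSE)
  if (length(preds) > nrow(Y) - 1)
    stop("more predictors than rows - 1", call. = FALSE)
  X <- as.data.frame(scale(as.matrix(env[, preds])))
  if (!is.null(seed)) set.seed(seed)
  d <- stats::dist(Y)
  mod <- vegan::dbrda(d ~ ., data = X)
  aov <- stats::anova(mod, by = "margin", permutations = n_perm)
  r2 <- vegan::RsquareAdj(mod)
  tot <- mod$tot.chi
  con <- mod$CCA$tot.chi
  unc <- if (is.null(mod$CA)) 0 else mod$CA$tot.chi
  scores <- tryCatch(
    vegan::scores(mod, display = "sites",
                  choices = seq_len(min(2, mod$CCA$rank))),
    error = function(e) NULL)
  tests <- tibble::tibble(
    variable = rownames(aov)[seq_along(preds)],
    df = aov$Df[seq_along(preds)],
    f = aov$F[seq_along(preds)],
    p = aov$`Pr(>F)`[seq_along(preds)])
  structure(list(
    total_inertia = tot, constrained_inertia = con,
    unconstrained_inertia = unc,
    constrained_prop = con / tot,
    adj_r2 = r2$adj.r.squared, r2 = r2$r.squared,
    eigenvalues = mod$CCA$eig,
    residual_eigenvalues = if (is.null(mod$CA)) numeric(0) else mod$CA$eig,
    site_scores = if (is.null(scores)) NULL else
      tibble::as_tibble(as.data.frame(scores)),
    biplot_scores = mod$CCA$biplot,
    tests = tests, n_perm = n_perm, model = mod),
    class = "ssr_dbrda")
}

#' @export
print.ssr_dbrda <- function(x, ...) {
  cat(sprintf(
    "dbRDA: %.2f%% of inertia constrained (adj R2 = %.3f)\n",
    100 * x$constrained_prop, x$adj_r2))
  print(x$tests)
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of off-diagonal entries; p-value from
#' simultaneous row/column permutation of one matrix.
#'
#' @param a,b symmetric zero-diagonal distance matrices (or `dist`).
#' @param n_perm permutations.
#' @param seed optional RNG seed.
#' @return tibble: r, p, n_perm.
#' @export
mantel_test <- function(a, b, n_perm = 999, seed = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!isTRUE(all.equal(dim(a), dim(b))))
    stop("matrices differ in size", call. = FALSE)
  off <- function(m) m[lower.tri(m)]
  if (stats::sd(off(a)) == 0 || stats::sd(off(b)) == 0)
    stop("constant distance matrix", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(a), stats::as.dist(b),
                      permutations = n_perm)
  tibble::tibble(r = unname(mt$statistic), p = mt$signif, n_perm = n_perm)
}

#' Attach population-level environmental values to individuals
#'
#' The study measures environment per site; individuals inherit their
#' population's values by a join on the population label.
#'
#' @param ds [microsat_data()] object.
#' @param env data frame with a `population` column.
#' @return tibble: one row per individual with environment columns.
#' @export
join_env <- function(ds, env) {
  assert_ssr_geno(ds)
  if (!"population" %in% names(env))
    stop("`env` needs a population column", call. = FALSE)
  miss <- setdiff(unique(ds$individuals$population), env$population)
  if (length(miss) > 0)
    stop("populations missing from env: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dplyr::left_join(ds$individuals, tibble::as_tibble(env),
                   by = "population")
}
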