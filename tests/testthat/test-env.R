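test_that("VIF pruning matches the correlation-matrix oracle", {
  set.seed(51)
  # orthogonalized columns: nothing dropped, all VIF ~ 1
  X <- qr.Q(qr(scale(matrix(rnorm(200 * 4), 200, 4),
                     scale = FALSE)))
  env <- as.data.frame(X); names(env) <- paste0("v", 1:4)
  pr <- vif_prune(env)
  expect_equal(pr$retained, names(env))
  expect_true(all(abs(pr$vif - 1) < 1e-8))

  # a duplicated column: exactly one of the pair goes first
  env2 <- env; env2$v1_copy <- env2$v1
  pr2 <- vif_prune(env2)
  expect_equal(nrow(pr2$log), 1)
  expect_true(pr2$log$dropped %in% c("v1", "v1_copy"))
  expect_equal(sum(c("v1", "v1_copy") %in% pr2$retained), 1)
  expect_true(is.infinite(pr2$log$vif))

  # correlated Gaussians: VIFs equal diag(solve(cor(X)))
  S <- matrix(0.6, 5, 5); diag(S) <- 1
  Y <- MASS::mvrnorm(300, rep(0, 5), S)
  env3 <- as.data.frame(Y); names(env3) <- paste0("w", 1:5)
  v_imp <- vif_prune(env3, threshold = Inf)$vif
  v_oracle <- diag(solve(cor(Y)))
  expect_equal(unname(v_imp), unname(v_oracle), tolerance = 1e-8)

  # termination: final set always satisfies the threshold
  pr3 <- vif_prune(env3, threshold = 1.5)
  expect_true(all(pr3$vif < 1.5) || length(pr3$retained) == 2)
  expect_lte(nrow(pr3$log), 4)

  expect_error(vif_prune(env3[1:4, ]), "more rows")
})

test_that("environmental PCA matches the eigenvalue oracle", {
  set.seed(52)
  two <- data.frame(a = rnorm(50))
  two$b <- 2 * two$a + 3
  p2 <- pca_env(two)
  expect_equal(p2$percent[1], 100)

  X <- matrix(rnorm(400 * 4), 400, 4)
  env <- as.data.frame(X); names(env) <- paste0("v", 1:4)
  p <- pca_env(env)
  ev <- eigen(cor(X), symmetric = TRUE)$values
  expect_equal(p$percent, 100 * ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(p$percent), 100)
  expect_equal(crossprod(p$loadings), diag(4), ignore_attr = TRUE,
               tolerance = 1e-10)

  envc <- env; envc$flat <- 1
  expect_error(pca_env(envc), "flat")
})

test_that("Kruskal-Wallis statistics match the closed form for separation", {
  sc <- data.frame(PC1 = c(1:10, 101:110))
  g <- rep(c("a", "b"), each = 10)
  kw <- kw_species_test(sc, g)
  expect_equal(kw$chisq, 12 / (20 * 21) * (55^2 / 10 + 155^2 / 10) - 63,
               tolerance = 1e-10)
  expect_equal(kw$df, 1)

  tied <- data.frame(PC1 = rep(1, 10))
  expect_warning(kwt <- kw_species_test(tied, rep(c("a", "b"), 5)),
                 "tied")
  expect_equal(kwt$p, 1)
  expect_error(kw_species_test(sc, rep("a", 20)), ">= 2 groups")

  # null calibration: permuted labels give roughly uniform p
  set.seed(53)
  ps <- replicate(200, {
    kw_species_test(data.frame(PC1 = rnorm(24)),
                    sample(rep(c("a", "b"), 12)))$p
  })
  expect_gt(mean(ps), 0.4); expect_lt(mean(ps), 0.6)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("axis regressions reproduce the normal equations", {
  set.seed(54)
  axes <- data.frame(axis1 = rnorm(40), axis2 = rnorm(40))
  env <- data.frame(y1 = 2 * axes$axis1 + rnorm(40, 0, 0.3),
                    y2 = rnorm(40))
  g <- glm_on_axis(env, axes)
  X <- cbind(1, axes$axis1, axes$axis2)
  beta <- solve(crossprod(X), crossprod(X, env$y1))
  expect_equal(g$estimate[g$variable == "y1"], beta[2:3],
               ignore_attr = TRUE, tolerance = 1e-10)

  ident <- glm_on_axis(data.frame(z = axes$axis1), axes)
  expect_gt(ident$adj_r2[1], 0.999999)
  expect_lt(ident$model_p[1], 1e-12)
  orth <- g[g$variable == "y2", ]
  expect_lt(max(abs(orth$estimate)), 0.5)
  expect_error(glm_on_axis(env, axes[, 1, drop = FALSE]), "two axes")
  expect_error(glm_on_axis(env, data.frame(a = rep(1, 40),
                                           b = rnorm(40))),
               "zero-variance")
})

test_that("logistic regression flags structure and rejects degeneracy", {
  set.seed(55)
  n <- 60
  pcs <- data.frame(PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n))
  y <- ifelse(pcs$PC1 + rnorm(n, 0, 0.8) > 0, "sp1", "sp2")
  fit <- logistic_species(pcs, y)
  zz <- abs(fit$z[match(c("PC1", "PC2", "PC3"), fit$term)])
  expect_equal(as.integer(which.max(zz)), 1L)
  expect_false(attr(fit, "separation"))

  dup <- pcs; dup$PC1b <- dup$PC1
  expect_error(logistic_species(dup, y), "rank-deficient")

  sep <- data.frame(x = c(rnorm(20, -4), rnorm(20, 4)))
  ysep <- rep(c("a", "b"), each = 20)
  expect_warning(fsep <- logistic_species(sep, ysep), "separation")
  expect_true(attr(fsep, "separation"))

  # null calibration of the Wald test
  nulls <- replicate(120, {
    f <- logistic_species(data.frame(PC1 = rnorm(40)),
                          sample(rep(c("a", "b"), 20)))
    f$p[f$term == "PC1"] < 0.05
  })
  expect_lt(mean(nulls), 0.12)
})

test_that("dbRDA conserves inertia and matches a brute-force RDA", {
  set.seed(56)
  env <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  Y <- cbind(1.5 * env$x1 - env$x2, 0.5 * env$x1 + env$x2)
  perfect <- dbrda_env(Y, env, n_perm = 99, seed = 1)
  expect_gt(perfect$constrained_prop, 0.999999)
  expect_lt(perfect$unconstrained_inertia, 1e-8)

  # inertia conservation on noisy fixtures
  for (s in 1:3) {
    set.seed(s)
    Yn <- matrix(rnorm(20 * 2), 20, 2)
    fit <- dbrda_env(Yn, env, n_perm = 49, seed = s)
    expect_equal(fit$constrained_inertia + fit$unconstrained_inertia,
                 fit$total_inertia, tolerance = 1e-9)
    expect_gte(min(fit$tests$p), 1 / 50)
  }

  # tiny 6 x 2 response, 1 predictor: explicit projection oracle
  set.seed(57)
  Ys <- matrix(rnorm(12), 6, 2)
  es <- data.frame(x = rnorm(6))
  fit <- dbrda_env(Ys, es, n_perm = 19, seed = 2)
  Yc <- scale(Ys, scale = FALSE)
  Xc <- scale(es$x)
  H <- Xc %*% solve(crossprod(Xc), t(Xc))
  con <- sum((H %*% Yc)^2) / (6 - 1)
  expect_equal(fit$constrained_inertia, con, tolerance = 1e-9)
  expect_equal(fit$total_inertia, sum(Yc^2) / (6 - 1), tolerance = 1e-9)
  # Ezekiel adjustment oracle
  r2 <- con / (sum(Yc^2) / 5)
  expect_equal(fit$adj_r2, 1 - (1 - r2) * 5 / (6 - 1 - 1),
               tolerance = 1e-9)

  expect_error(dbrda_env(Ys, cbind(es, a = rnorm(6), b = rnorm(6),
                                   c = rnorm(6), d = rnorm(6),
                                   e = rnorm(6)), n_perm = 9),
               "more predictors")
})

test_that("Mantel statistics behave under identity and affine maps", {
  set.seed(58)
  pts <- matrix(rnorm(16), 8, 2)
  A <- as.matrix(dist(pts))
  expect_equal(mantel_test(A, A, n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(A, 2 * A + 3, n_perm = 99, seed = 1)$r, 1)
  B <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  mt <- mantel_test(A, B, n_perm = 99, seed = 2)
  expect_gte(mt$p, 1 / 100)
  expect_error(mantel_test(matrix(0, 4, 4), A[1:4, 1:4], n_perm = 9),
               "constant")
})

test_that("individuals inherit population-level environments by join", {
  ds <- random_geno(seed = 59, n_per_pop = c(2, 2, 2))
  env <- tibble::tibble(population = c("P1", "P2", "P3"),
                        alt = c(100, 200, 300))
  j <- join_env(ds, env)
  expect_equal(nrow(j), 6)
  expect_equal(j$alt, rep(c(100, 200, 300), each = 2))
  expect_error(join_env(ds, env[1:2, ]), "missing from env")
})
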