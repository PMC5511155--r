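test_that("summary statistics match their definitions on closed cases", {
  mono <- toy_geno(list(matrix(5L, 6, 2), matrix(5L, 6, 2)),
                   rep(c("a", "b"), each = 3))
  expect_warning(s <- summary_stats(mono), "monomorphic")
  expect_equal(unname(s[c("K_1", "H_1", "V_1", "dmu2_12", "FST_12")]),
               c(1, 0, 0, 0, 0))

  ds <- fixed_diff_geno(n_per_pop = 5, n_loci = 2)
  s <- suppressWarnings(summary_stats(ds))
  expect_equal(unname(s["dmu2_12"]), 100)
  expect_equal(unname(s["shared_12"]), 0)
  expect_equal(unname(s["FST_12"]), 1)
})

test_that("summary statistics agree with a brute-force oracle", {
  ds <- random_geno(seed = 31, n_per_pop = c(6, 5, 4), n_loci = 5,
                    miss = 0.05)
  s <- suppressWarnings(summary_stats(ds))
  pops <- unique(ds$individuals$population)
  copies_of <- function(p, l) {
    rows <- ds$individuals$population == p
    v <- c(ds$alleles[rows, l, 1], ds$alleles[rows, l, 2])
    v[!is.na(v)]
  }
  for (pi in seq_along(pops)) {
    K <- H <- V <- M <- numeric(0)
    for (l in seq_along(ds$loci)) {
      v <- copies_of(pops[pi], l)
      p <- table(v) / length(v)
      K <- c(K, length(p)); H <- c(H, 1 - sum(p^2))
      V <- c(V, var(v)); M <- c(M, length(p) / (diff(range(v)) + 1))
    }
    expect_equal(unname(s[paste0("K_", pi)]), mean(K))
    expect_equal(unname(s[paste0("H_", pi)]), mean(H))
    expect_equal(unname(s[paste0("V_", pi)]), mean(V))
    expect_equal(unname(s[paste0("M_", pi)]), mean(M))
  }
  # pair statistics for the first pair
  dmu2 <- shared <- numeric(0)
  for (l in seq_along(ds$loci)) {
    va <- copies_of(pops[1], l); vb <- copies_of(pops[2], l)
    dmu2 <- c(dmu2, (mean(va) - mean(vb))^2)
    shared <- c(shared, length(intersect(va, vb)) /
                  length(union(va, vb)))
  }
  expect_equal(unname(s["dmu2_12"]), mean(dmu2))
  expect_equal(unname(s["shared_12"]), mean(shared))
  # FST route-checked against the R two-group partition
  cm <- ssrdiverge:::copies_matrix(ds)
  sel <- rep(ds$individuals$population %in% pops[1:2], each = 2)
  grp <- rep(match(ds$individuals$population[
    ds$individuals$population %in% pops[1:2]], pops[1:2]), each = 2)
  expect_equal(unname(s["FST_12"]),
               ssrdiverge:::two_group_fst(cm[sel, , drop = FALSE], grp),
               tolerance = 1e-12)
})

test_that("Box-Cox + PLS recovers a planted linear map and projects identically", {
  set.seed(44)
  n <- 3000
  theta <- rnorm(n, 3, 0.4)
  ref <- tibble::tibble(model = "M",
                        theta = theta,
                        S_a = 3 * theta + rnorm(n, 0, 1e-3),
                        S_b = rnorm(n, 10, 1),
                        S_c = rnorm(n, 5, 2))
  obs <- c(S_a = 3 * 3.2, S_b = 10, S_c = 5)
  pls <- boxcox_pls(ref, obs, n_components = 1)
  expect_gt(abs(cor(pls$ref_scores[, 1], theta)), 0.999)

  # observed equal to a reference row projects onto that row's scores
  obs_row <- unlist(ref[17, c("S_a", "S_b", "S_c")])
  pls2 <- boxcox_pls(ref, obs_row, n_components = 2)
  expect_equal(unname(pls2$obs_scores), unname(pls2$ref_scores[17, ]),
               tolerance = 1e-8)

  expect_error(boxcox_pls(ref, obs, n_components = 7), "exceeds")
  refc <- dplyr::mutate(ref, S_d = 1)
  expect_warning(boxcox_pls(refc, c(obs, S_d = 1), n_components = 1),
                 "constant")
})

test_that("rejection keeps the exact nearest set with stable ties", {
  set.seed(45)
  sc <- matrix(rnorm(200), 100, 2)
  pls <- list(ref_scores = sc, obs_scores = c(0.3, -0.2))
  kept <- abc_reject(pls, n_keep = 100)
  expect_setequal(kept$index, 1:100)
  d <- sqrt(colSums((t(sc) - c(0.3, -0.2))^2))
  expect_equal(kept$index, order(d, seq_along(d)))

  pls$obs_scores <- sc[42, ]
  k1 <- abc_reject(pls, n_keep = 1)
  expect_equal(k1$index, 42)
  expect_equal(k1$distance, 0)

  k10 <- abc_reject(pls, n_keep = 10)
  expect_equal(k10$index, order(d2 <- sqrt(colSums((t(sc) - sc[42, ])^2)),
                                seq_along(d2))[1:10])
  expect_error(abc_reject(pls, n_keep = 0), "positive")
})

test_that("the GLM adjustment solves a linear-Gaussian toy exactly", {
  set.seed(46)
  n <- 600
  theta <- runif(n)
  stats <- cbind(2 * theta + rnorm(n, 0, 1e-4),
                 rnorm(n))
  target <- 0.37
  fit <- glm_adjust(cbind(theta = theta), stats, c(2 * target, 0))
  post <- posterior_summarize(theta, fit$weights)
  expect_lt(abs(post$mode - target), 0.01)
  expect_lt(abs(post$median - target), 0.01)

  # density decreases far from the cloud
  far <- glm_adjust(cbind(theta = theta), stats, c(2 * 0.5 + 50, 0))
  expect_lt(far$marginal_density, fit$marginal_density)

  expect_error(glm_adjust(cbind(theta = theta[1:5]), stats[1:5, ],
                          c(1, 0)), "too few")
})

test_that("model choice arithmetic and symmetry", {
  mc <- model_choice(c(A = 3, B = 1))
  expect_equal(mc$table$relative_density, c(75, 25))
  expect_equal(mc$bayes_factors["A", "B"], 3)
  expect_equal(mc$bayes_factors["B", "A"], 1 / 3)
  expect_equal(sum(mc$table$relative_density), 100)

  eq <- model_choice(c(A = 2e-8, B = 2e-8))
  expect_equal(eq$table$relative_density, c(50, 50))
  expect_error(model_choice(c(A = 0, B = 0)), "zero")
  expect_error(model_choice(c(A = 1)), ">= 2")

  # two identical models split the relative density evenly
  set.seed(47)
  theta <- runif(500)
  stats <- cbind(theta + rnorm(500, 0, 0.05))
  f1 <- glm_adjust(cbind(theta), stats, 0.5)
  f2 <- glm_adjust(cbind(theta), stats, 0.5)
  m <- model_choice(c(M1 = f1$marginal_density, M2 = f2$marginal_density))
  expect_equal(m$table$relative_density, c(50, 50))
})

test_that("posterior summaries match analytic shapes", {
  set.seed(48)
  x <- rnorm(5000, 3, 0.5)
  ps <- posterior_summarize(x)
  expect_lt(abs(ps$mode - ps$median), 0.08)
  expect_lt(ps$hpd50_hi - ps$hpd50_lo, ps$hpd95_hi - ps$hpd95_lo)

  pt <- posterior_summarize(rep(2.5, 200))
  expect_equal(pt$mode, 2.5)
  expect_equal(pt$median, 2.5)
  expect_equal(pt$hpd95_lo, 2.5)

  b <- rbeta(1e5, 2, 5)
  pb <- posterior_summarize(b)
  expect_lt(abs(pb$mode - 0.2), 0.02)

  expect_warning(posterior_summarize(rnorm(50)), "fewer than 100")
})

test_that("the ABC pipeline is bit-reproducible under a fixed seed", {
  sizes <- list(spA = c(p1 = 6), spB = c(p2 = 6))
  r1 <- build_reference_table(c("CI", "CM"), default_priors(), sizes,
                              n_loci = 4, n_sims = 200, seed = 9)
  r2 <- build_reference_table(c("CI", "CM"), default_priors(), sizes,
                              n_loci = 4, n_sims = 200, seed = 9)
  expect_identical(r1, r2)
  obs <- unlist(r1[5, grep("^S_", names(r1))])
  m1 <- abc_model_choice(r1, obs, n_components = 3, n_keep = 100)
  m2 <- abc_model_choice(r2, obs, n_components = 3, n_keep = 100)
  expect_identical(m1$table, m2$table)
})
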