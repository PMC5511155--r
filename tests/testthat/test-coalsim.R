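make_sizes <- function(n1 = 10, n2 = 10)
  list(spA = c(popA = n1), spB = c(popB = n2))

test_that("migration windows follow the scenario definitions", {
  base <- list(n1 = 100, n2 = 100, n_anc = 100, t2 = 1000,
               m12 = 0.05, m21 = 0.02, sample_sizes = make_sizes())
  ep <- function(model, t1) {
    sp <- do.call(scenario_spec, c(list(model = model, t1 = t1), base))
    migration_epochs(sp)
  }
  expect_equal(nrow(ep("CI", 0)), 0)
  expect_equal(as.numeric(ep("AM", 400)[1, ]), c(400, 1000, 0.05, 0.02))
  expect_equal(as.numeric(ep("SC", 400)[1, ]), c(0, 400, 0.05, 0.02))
  expect_equal(as.numeric(ep("CM", 400)[1, ]), c(0, 1000, 0.05, 0.02))
  # boundary collapses: AM with t1 = t2 and SC with t1 = 0 equal CI
  expect_equal(nrow(ep("AM", 1000)), 0)
  expect_equal(nrow(ep("SC", 0)), 0)
  # CM with zero rates keeps its window
  spz <- do.call(scenario_spec, c(list(model = "CM", t1 = 0),
                                  utils::modifyList(base, list(m12 = 0,
                                                               m21 = 0))))
  expect_equal(nrow(migration_epochs(spz)), 1)
  expect_equal(sum(migration_epochs(spz)[, c("m1", "m2")]), 0)
  expect_error(do.call(scenario_spec,
                       c(list(model = "AM", t1 = 2000), base)), "t1 <= t2")
})

test_that("degenerate simulator inputs behave as closed forms predict", {
  sp <- scenario_spec("CI", n1 = 200, n2 = 200, n_anc = 200, t2 = 5e4,
                      mu = 0, sample_sizes = make_sizes())
  ds <- simulate_dataset(sp, n_loci = 4, seed = 1)
  expect_true(all(ds$alleles == 100L))

  sp2 <- scenario_spec("CI", n1 = 200, n2 = 200, n_anc = 200, t2 = 5e4,
                       mu = 5e-4, f_is = 1, sample_sizes = make_sizes())
  ds2 <- simulate_dataset(sp2, n_loci = 6, seed = 2)
  expect_true(all(ds2$alleles[, , 1] == ds2$alleles[, , 2]))
  expect_true(all(diversity_table(ds2)$ho == 0))

  expect_error(scenario_spec("CI", 100, 100, 100, 1e4,
                             sample_sizes = list(a = c(x = 0),
                                                 b = c(y = 5))),
               "zero sample size")
  expect_error(scenario_spec("CI", 100, 100, 100, 1e4, mu = -1), ">= 0")
})

test_that("single-deme SMM allele-size variance matches theta / 2", {
  set.seed(4)
  N <- 400; mu <- 5e-4
  m <- ssrdiverge:::cpp_simulate_copies(
    40L, 0L, 1, 1, N, 0, matrix(numeric(0), 0, 4), rep(mu, 2500), 0)
  vbar <- mean(apply(m, 2, var))
  expect_lt(abs(vbar - 2 * N * mu) / (2 * N * mu), 0.1)
})

test_that("mean pairwise FST decreases with migration under CM", {
  sizes <- make_sizes(15, 15)
  mean_fst <- function(m, seed) {
    sp <- scenario_spec("CM", 300, 300, 300, t2 = 1e5, t1 = 0,
                        m12 = m, m21 = m, mu = 5e-4,
                        sample_sizes = sizes)
    set.seed(seed)
    mean(replicate(120, {
      ds <- simulate_dataset(sp, n_loci = 6)
      suppressWarnings(summary_stats(ds)[["FST_12"]])
    }), na.rm = TRUE)
  }
  f <- c(mean_fst(0, 11), mean_fst(0.01, 12), mean_fst(0.1, 13))
  expect_true(all(diff(f) < 0))
})

test_that("between-deme (delta mu)^2 grows linearly at rate about 2 mu t", {
  mu <- 5e-4
  sizes <- make_sizes(12, 12)
  tgrid <- c(3e4, 6e4, 9e4, 1.2e5)
  set.seed(9)
  dmu2 <- vapply(tgrid, function(tt) {
    sp <- scenario_spec("CI", 150, 150, 150, t2 = tt, mu = mu,
                        sample_sizes = sizes)
    mean(replicate(60, {
      ds <- simulate_dataset(sp, n_loci = 25)
      suppressWarnings(summary_stats(ds)[["dmu2_12"]])
    }))
  }, numeric(1))
  slope <- coef(lm(dmu2 ~ tgrid))[2]
  expect_lt(abs(slope - 2 * mu) / (2 * mu), 0.1)
})

test_that("prior draws respect bounds, conditioning and reproducibility", {
  pr <- list(a = list(dist = "uniform", min = 2, max = 6),
             t2 = list(dist = "loguniform", min = 1e3, max = 1e5),
             t1 = list(dist = "uniform_frac_t2", min = 0, max = 1),
             b = list(dist = "fixed", min = 7, max = 7))
  d <- draw_from_priors(pr, 10000, seed = 5)
  expect_true(all(d$a >= 2 & d$a <= 6))
  expect_true(all(d$t2 >= 1e3 & d$t2 <= 1e5))
  expect_true(all(d$t1 <= d$t2))
  expect_true(all(d$b == 7))
  expect_lt(abs(mean(d$a) - 4), 3 * sqrt(16 / 12) / sqrt(10000))
  expect_identical(draw_from_priors(pr, 10000, seed = 5), d)
  expect_error(draw_from_priors(
    list(a = list(dist = "uniform", min = 5, max = 1)), 10), "inverted")
  # point-mass priors collapse every draw
  d0 <- draw_from_priors(list(x = list(dist = "fixed", min = 3)), 5)
  expect_true(all(d0$x == 3))
})
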