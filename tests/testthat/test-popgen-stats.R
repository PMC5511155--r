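test_that("unbiased He reproduces the published small-sample correction", {
  # worked examples from the study populations (He, N) -> uHe at 3 d.p.
  expect_equal(round(unbiased_he(0.340, 10), 3), 0.358)
  expect_equal(round(unbiased_he(0.231, 19), 3), 0.237)
  expect_equal(round(unbiased_he(0.259, 22), 3), 0.265)
  expect_equal(round(unbiased_he(0.253, 15), 3), 0.262)
  expect_equal(round(unbiased_he(0.317, 15), 3), 0.328)
  expect_equal(unbiased_he(0, 7), 0)
  expect_error(unbiased_he(0.3, 0), ">= 1")
})

test_that("diversity table matches closed forms and a per-formula oracle", {
  # single locus, two alleles at 0.5 each, every individual heterozygous
  ds <- toy_geno(list(rbind(c(1L, 2L), c(1L, 2L), c(2L, 1L), c(2L, 1L))),
                 rep("p1", 4))
  d <- diversity_table(ds)
  expect_equal(d$ne, 2)
  expect_equal(d$he, 0.5)
  expect_equal(d$ho, 1)
  expect_equal(d$f, -1)

  mono <- toy_geno(list(matrix(3L, 5, 2), matrix(8L, 5, 2)), rep("p1", 5))
  dm <- diversity_table(mono)
  expect_equal(dm$na, 1)
  expect_equal(dm$ne, 1)
  expect_equal(dm$i, 0)
  expect_equal(dm$he, 0)

  # 10-individual random fixture against a direct evaluation of each
  # formula from raw copies
  ds <- random_geno(seed = 11, n_per_pop = c(10), n_loci = 5, miss = 0.05)
  d <- diversity_table(ds)
  per_locus <- sapply(seq_along(ds$loci), function(l) {
    copies <- c(ds$alleles[, l, 1], ds$alleles[, l, 2])
    copies <- copies[!is.na(copies)]
    p <- table(copies) / length(copies)
    both <- !is.na(ds$alleles[, l, 1]) & !is.na(ds$alleles[, l, 2])
    ho <- mean(ds$alleles[both, l, 1] != ds$alleles[both, l, 2])
    c(na = length(p), ne = 1 / sum(p^2), i = -sum(p * log(p)),
      ho = ho, he = 1 - sum(p^2),
      uhe = length(copies) / (length(copies) - 1) * (1 - sum(p^2)),
      f = if (sum(p^2) < 1) 1 - ho / (1 - sum(p^2)) else NA)
  })
  for (st in c("na", "ne", "i", "ho", "he", "uhe")) {
    expect_equal(d[[st]], mean(per_locus[st, ]), tolerance = 1e-12)
    expect_equal(d[[paste0(st, "_se")]],
                 sd(per_locus[st, ]) / sqrt(ncol(per_locus)),
                 tolerance = 1e-12)
  }
  expect_equal(d$f, mean(per_locus["f", ], na.rm = TRUE), tolerance = 1e-12)
})

test_that("per-locus identities He = 1 - 1/Ne and uHe/He = 2N/(2N-1) hold", {
  ds <- random_geno(seed = 3, n_per_pop = c(6, 8), n_loci = 6, miss = 0)
  pl <- ssrdiverge:::per_locus_stats(ds)
  expect_equal(pl$he, 1 - 1 / pl$ne, tolerance = 1e-12)
  poly <- pl$he > 0
  expect_equal((pl$uhe / pl$he)[poly],
               (pl$n_copies / (pl$n_copies - 1))[poly], tolerance = 1e-12)
})

test_that("AMOVA recovers complete fixation and the null case", {
  ds <- fixed_diff_geno(n_per_pop = 6, n_loci = 3)
  am <- amova(ds, n_perm = 49, seed = 1)
  expect_equal(am$f_st, 1)
  expect_equal(am$table$pct_var[3], 0)

  # identical allele distributions in all populations: frequencies equal,
  # permutation cannot beat the observed partition
  al <- lapply(1:3, function(l) {
    g <- rbind(c(1L, 2L), c(1L, 1L), c(2L, 2L), c(1L, 2L))
    do.call(rbind, rep(list(g), 4))
  })
  ds0 <- toy_geno(al, rep(c("a", "b", "c", "d"), each = 4),
                  rep(c("s1", "s1", "s2", "s2"), each = 4))
  am0 <- suppressWarnings(amova(ds0, n_perm = 49, seed = 2))
  expect_lt(abs(am0$table$sigma[1]), 1e-10)
  # data literally identical across pops sit below the sampling
  # expectation, so the (unclamped) middle component is <= 0
  expect_lte(am0$table$sigma[2], 1e-10)
  expect_equal(am0$table$p[1], 1)
})

test_that("AMOVA sums of squares match brute-force pairwise distances", {
  ds <- random_geno(seed = 21, n_per_pop = c(3, 4, 3, 2), n_loci = 4,
                    miss = 0)
  ds$individuals$species <- ifelse(ds$individuals$population %in%
                                     c("P1", "P2"), "spA", "spB")
  am <- amova(ds, n_perm = 0)
  # oracle: explicit pairwise identity distances between gene copies
  cm <- ssrdiverge:::copies_matrix(ds)
  pops <- rep(ds$individuals$population, each = 2)
  sps <- rep(ds$individuals$species, each = 2)
  ss_group <- function(labels) {
    tot <- 0
    for (g in unique(labels)) {
      rows <- which(labels == g)
      d2 <- 0
      for (i in rows) for (j in rows) for (l in seq_len(ncol(cm)))
        d2 <- d2 + (cm[i, l] != cm[j, l])
      tot <- tot + d2 / (2 * length(rows))  # i != j pairs counted twice
    }
    tot
  }
  ss_tot <- ss_group(rep("all", nrow(cm)))
  ss_ws <- ss_group(sps)
  ss_wp <- ss_group(pops)
  expect_equal(unname(am$table$ss),
               unname(c(ss_tot - ss_ws, ss_ws - ss_wp, ss_wp, ss_tot)),
               tolerance = 1e-9)
  expect_equal(am$table$df, c(1, 2, 20, 23))
})

test_that("AMOVA df follow the sampling design and p-values are seeded", {
  ds <- make_genotype_fixture(seed = 3)
  am1 <- amova(ds, n_perm = 99, seed = 5)
  expect_equal(am1$table$df, c(1, 3, 157, 161))
  expect_equal(sum(am1$table$df[1:3]), 2 * nrow(ds$individuals) - 1)
  expect_true(all(am1$table$p[1:3] %in% ((1:100) / 100)))
  am2 <- amova(ds, n_perm = 99, seed = 5)
  expect_identical(am1$table, am2$table)
})

test_that("published variance components give back the published table", {
  t1 <- amova_from_components(3.669, 1.423, 2.666)
  expect_equal(t1$f_ct, 0.473, tolerance = 1e-3)
  expect_equal(t1$f_sc, 0.348, tolerance = 1e-3)
  expect_equal(t1$f_st, 0.656, tolerance = 1e-3)
  expect_equal(t1$pct_among_species, 47.30, tolerance = 0.01)
  t2 <- amova_from_components(2.331, 1.198, 2.316)
  expect_equal(t2$f_ct, 0.399, tolerance = 1e-3)
  expect_true(t2$pct_among_species > 39.87 && t2$pct_among_species < 39.90)
  t3 <- amova_from_components(0, 0, 5)
  expect_equal(t3$f_ct, 0)
  expect_equal(t3$pct_within, 100)
  expect_error(amova_from_components(0, 0, 0), "zero")
})

test_that("pairwise FST matches fixation, identity and an algebraic case", {
  ds <- fixed_diff_geno()
  f <- pairwise_fst(ds)
  expect_equal(f["pop1", "pop2"], 1)
  expect_equal(diag(f), c(pop1 = 0, pop2 = 0))

  # identical populations -> 0
  al <- list(do.call(rbind, rep(list(rbind(c(1L, 2L), c(1L, 2L))), 4)))
  ds0 <- toy_geno(al, rep(c("x", "y"), each = 4))
  expect_equal(pairwise_fst(ds0)["x", "y"], 0)

  # two alleles, two pops: algebraic variance-partition oracle from
  # explicit distance sums
  al <- list(rbind(c(1L, 1L), c(1L, 2L), c(1L, 1L),
                   c(2L, 2L), c(2L, 1L), c(2L, 2L)))
  dsx <- toy_geno(al, rep(c("u", "v"), each = 3))
  cm <- ssrdiverge:::copies_matrix(dsx)
  grp <- rep(c(1, 2), each = 6)
  d2 <- outer(cm[, 1], cm[, 1], "!=") * 1
  ssw <- sum(d2[grp == 1, grp == 1]) / (2 * 6) +
    sum(d2[grp == 2, grp == 2]) / (2 * 6)
  sst <- sum(d2) / (2 * 12)
  msw <- ssw / 10
  msa <- sst - ssw
  sa <- (msa - msw) / 6
  expect_equal(pairwise_fst(dsx)["u", "v"], sa / (sa + msw),
               tolerance = 1e-12)
})
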