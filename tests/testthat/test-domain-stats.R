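# Observed/expected domain occurrence and chi-squared classification.

test_that("occurrence counting uses presence per protein, not copy number", {
  tab <- protein_table(
    c("p1", "p2", "p3"), rep("G", 3),
    domains = list(c("PF00001", "PF00001"), "PF00001", "PF00002"))
  vp <- as_proteome(tab)
  counts <- count_domain_occurrence(vp, c("PF00001", "PF00002", "PF00003"))
  expect_equal(counts, c(PF00001 = 2L, PF00002 = 1L, PF00003 = 0L))
})

test_that("occurrence counting matches a per-protein membership oracle", {
  genera <- sprintf("Genus%02d", 1:5)
  rates <- setNames(runif(6, 0.05, 0.5), sprintf("PF%05d", 1:6))
  tab <- random_protein_table(600L, genera, rates, seed = 3)
  vp <- as_proteome(tab)
  counts <- count_domain_occurrence(vp, names(rates))
  for (d in names(rates)) {
    manual <- sum(vapply(tab$domains, function(x) d %in% x, logical(1)))
    expect_equal(unname(counts[d]), manual)
  }
})

test_that("the expected model is linear in rate and size and rejects bad input", {
  expect_equal(unname(compute_expected(c(d = 0), c(A = 10, B = 20))[1, ]),
               c(0, 0))
  E <- compute_expected(c(d = 0.5), c(A = 10, B = 20))
  expect_equal(unname(E["d", ]), c(5, 10))
  expect_error(compute_expected(c(d = -0.1), c(A = 10)), "non-negative")
  expect_equal(estimate_background_rate(0, 100), 0)
  expect_equal(estimate_background_rate(5, 100), 0.05)
  expect_error(estimate_background_rate(5, 0), "positive")
  # defining property: expected ratios equal size ratios, at any rate
  set.seed(9)
  rates <- setNames(runif(10), sprintf("PF%05d", 1:10))
  sizes <- c(A = 1000, B = 1700, C = 400)
  E <- compute_expected(rates, sizes)
  for (i in which(rates > 0)) {
    expect_equal(unname(E[i, "A"] / E[i, "B"]), unname(sizes["A"] / sizes["B"]),
                 tolerance = 1e-12)
  }
})

test_that("pooled background rates equal a hand tally over groups", {
  genera <- sprintf("Genus%02d", 1:6)
  rates <- setNames(runif(4, 0.1, 0.4), sprintf("PF%05d", 1:4))
  tab <- random_protein_table(900L, genera, rates, seed = 21)
  proteomes <- list(
    A = build_virtual_proteome(tab, taxon_profile("A", genera[1:2])),
    B = build_virtual_proteome(tab, taxon_profile("B", genera[3:4])),
    C = build_virtual_proteome(tab, taxon_profile("C", genera[5:6])))
  occ <- build_occurrence_table(proteomes, names(rates))
  total_n <- sum(vapply(proteomes, function(p) p$n_proteins, integer(1)))
  for (d in names(rates)) {
    manual <- sum(vapply(proteomes, function(p) {
      sum(vapply(p$records$domains, function(x) d %in% x, logical(1)))
    }, numeric(1)))
    expect_equal(unname(occ$rates[d]), manual / total_n)
    expect_equal(unname(occ$expected[d, ]),
                 unname(manual / total_n * occ$group_sizes))
  }
})

test_that("chi-squared row test matches closed forms and both df conventions", {
  # O == E exactly
  t0 <- chisq_row_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p, 1)
  # published myosin-head row: chi2 = 3 * (1/3) = 1, p > 0.5 either way
  t1 <- chisq_row_test(c(2, 2, 2), c(3, 3, 3))
  expect_equal(t1$chi2, 1)
  expect_gt(t1$p, 0.5)
  expect_gt(chisq_row_test(c(2, 2, 2), c(3, 3, 3), df_mode = "k")$p, 0.5)
  # published EF-hand_1 row is far in the tail under either convention
  expect_lt(chisq_row_test(c(35, 16, 17), c(110, 100, 97))$p, 0.01)
  expect_lt(chisq_row_test(c(35, 16, 17), c(110, 100, 97),
                           df_mode = "k")$p, 0.01)
  # permutation invariance
  perm <- sample(3)
  expect_equal(chisq_row_test(c(35, 16, 17)[perm], c(110, 100, 97)[perm])$chi2,
               chisq_row_test(c(35, 16, 17), c(110, 100, 97))$chi2)
  # p monotone decreasing in chi2 at fixed df
  chis <- seq(0.5, 20, by = 0.5)
  ps <- pchisq(chis, 2, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
  expect_error(chisq_row_test(c(1, 1), c(0, 2)), "exclude")
})

test_that("chi-squared p agrees with a Monte-Carlo multinomial null", {
  # rows at the scale of the mid-sized occurrence rows (hundreds of
  # expected counts), where the asymptotic tail the test relies on is valid
  set.seed(101)
  for (rep in 1:5) {
    E <- runif(3, 200, 1000)
    O <- as.vector(rmultinom(1, size = round(sum(E)), prob = E / sum(E)))
    p_hat <- oracle_chi2_mc(O, E, n_draws = 1e5)
    p_an <- chisq_row_test(O, E)$p
    se <- sqrt(max(p_hat * (1 - p_hat), 1e-9) / 1e5)
    expect_lt(abs(p_an - p_hat), 3 * se + 1e-4)
  }
})

test_that("classification triage reproduces the published direction profiles", {
  occ <- published_occurrence()
  # the published rows already passed the near-zero triage upstream
  res <- classify_domain_rows(occ, near_zero_min = 0)
  rownames(res) <- res$domain
  # over-represented in all three groups
  expect_equal(res["PF00149", "direction"], "+++")
  # under-represented everywhere
  expect_equal(res["PF00036", "direction"], "---")
  expect_equal(res["PF00612", "direction"], "---")
  expect_equal(res["PF13202", "direction"], "---")
  # healthy-only over-representation
  expect_equal(res["PF00069", "direction"], "+--")
  expect_equal(res["PF13895", "direction"], "+--")
  expect_equal(res["PF13499", "direction"], "+--")
  # class labels honour the thresholds
  expect_equal(res["PF00036", "class"], "significant")
  expect_equal(res["PF00063", "class"], "not_significant")
  expect_true(all(res$p[res$class == "significant"] < 0.01, na.rm = TRUE))
})

test_that("absent and near-zero domains are triaged before testing", {
  O <- matrix(c(0L, 0L, 0L,
                2L, 1L, 3L,
                50L, 40L, 60L), nrow = 3, byrow = TRUE,
              dimnames = list(c("PF00001", "PF00002", "PF00003"),
                              c("A", "B", "C")))
  E <- matrix(rep(c(0, 2, 50), 3), nrow = 3,
              dimnames = dimnames(O))
  tab <- occurrence_table(O, expected = E)
  res <- classify_domain_rows(tab, near_zero_min = 10)
  expect_equal(res$class, c("absent", "near_zero", "intermediate"))
  expect_true(is.na(res$p[1]) && is.na(res$p[2]))
  # the near-zero cut-off is a configuration key, not a constant
  res2 <- classify_domain_rows(tab, near_zero_min = 5)
  expect_false(res2$class[2] == "near_zero")
})

test_that("null simulations are calibrated at alpha = 0.01 and 0.05", {
  # all effects at 1: the significant fraction should match alpha
  # groups must be genus-disjoint so their proteomes are independent draws
  cfg_cat <- data.frame(accession = sprintf("PF8%04d", 1:40),
                        rate = 0.02, partner = TRUE)
  ps <- c()
  for (seed in 1:6) {
    set.seed(seed)
    cfg_cat$rate <- runif(40, 0.005, 0.05)
    cfg <- simulation_config(
      seed = seed, n_shared_genera = 0L,
      n_specific_genera = c(CT = 2L, CD = 2L, UC = 2L),
      n_pairwise_genera = c(CT_CD = 0L, CT_UC = 0L, CD_UC = 0L),
      proteins_per_genus = 500L, domain_catalogue = cfg_cat,
      include_go = FALSE)
    sim <- simulate_metaproteome(cfg)
    groups <- unique(sim$taxa_profiles$group)
    proteomes <- lapply(setNames(groups, groups), function(g) {
      genera <- sim$taxa_profiles$genus[sim$taxa_profiles$group == g]
      build_virtual_proteome(sim$records, taxon_profile(g, genera))
    })
    occ <- build_occurrence_table(proteomes, cfg_cat$accession)
    res <- classify_domain_rows(occ, near_zero_min = 10)
    ps <- c(ps, res$p[!is.na(res$p)])
  }
  n <- length(ps)
  expect_gt(n, 150)
  for (alpha in c(0.01, 0.05)) {
    frac <- mean(ps < alpha)
    half <- 1.96 * sqrt(alpha * (1 - alpha) / n)
    expect_lt(abs(frac - alpha), half + 0.5 / n + 1e-12)
  }
})
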