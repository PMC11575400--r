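test_that("generation accounting reproduces the 1:100 daily protocol", {
  g <- generations_per_cycle(0.1, 9.9, days = 30)
  expect_equal(g$dilution, 100)
  expect_equal(round(g$generations_per_cycle, 1), 6.6)
  expect_equal(g$total_generations, 199.3, tolerance = 0.05)
  # a 2-fold dilution is exactly one generation
  expect_equal(generations_per_cycle(5, 5)$generations_per_cycle, 1)
})

test_that("Malthusian parameter and selection rate behave exactly", {
  expect_equal(malthusian(1e5, 1e7), log(100))
  expect_equal(malthusian(3, 3), 0)
  # scale invariance
  expect_equal(malthusian(7 * 1e5, 7 * 1e7), malthusian(1e5, 1e7))
  expect_error(malthusian(0, 10), "> 0")

  expect_equal(selection_rate(1, 1), 0)
  expect_equal(selection_rate(4.6052, 3.9120, 1), log(2), tolerance = 1e-3)
  # exact antisymmetry
  m <- runif(10); m2 <- runif(10)
  expect_identical(selection_rate(m, m2), -selection_rate(m2, m))
})

test_that("invasion analysis: nulls, power, and the pooled d.f. 28 design", {
  gi <- mk_genotype("i")
  gj <- mk_genotype("j")
  # identical genotypes, no noise: r = 0 everywhere, verdict indeterminate
  a0 <- generate_competition_assay(gi, gj, noise_cv = 0, seed = 1)
  expect_equal(nrow(a0), 15)
  inv0 <- invasion_analysis(a0)
  expect_true(all(abs(inv0$rates$r_ij) < 1e-8))
  expect_equal(inv0$verdicts$verdict, "indeterminate")

  # two identical-genotype conditions: pooled Welch test on 15 + 15 rows
  a1 <- dplyr::bind_rows(
    generate_competition_assay(gi, gj, noise_cv = 0.05,
                               condition = "monoculture", seed = 2),
    generate_competition_assay(gi, gj, noise_cv = 0.05,
                               condition = "co-culture", seed = 3))
  inv1 <- invasion_analysis(a1)
  expect_equal(inv1$pooled$n_a + inv1$pooled$n_b, 30)
  expect_equal(inv1$pooled$df, 28, tolerance = 4)
  expect_gt(inv1$pooled$p_two_tailed, 0.001)   # null: no systematic difference

  # genotype with higher mu_max wins at every frequency (no noise)
  gfast <- genotype("fast", Y = 0.05, V = 14, K = 0.06,
                    resource = "benzoate")
  a2 <- generate_competition_assay(gfast, gj, noise_cv = 0)
  inv2 <- invasion_analysis(a2)
  expect_true(all(inv2$rates$r_ij > 0))

  expect_error(invasion_analysis(a0[, -1]), "lacks columns")
})

test_that("invasion analysis recovers a ln 2 advantage with high power", {
  # effect ln 2 per day, lognormal density noise sd 0.05, n = 6 replicates
  set.seed(21)
  hits <- replicate(200, {
    rows <- tibble::tibble(
      genotype_i = "i", genotype_j = "j", condition = "mono",
      initial_freq_i = 0.05, replicate = 1:6,
      N0_i = 1e5 * exp(rnorm(6, 0, 0.05)),
      Nf_i = 2e7 * exp(rnorm(6, 0, 0.05)),
      N0_j = 1e5 * exp(rnorm(6, 0, 0.05)),
      Nf_j = 1e7 * exp(rnorm(6, 0, 0.05)),
      duration_days = 1)
    cell <- invasion_analysis(rows)$by_cell
    cell$p_two_tailed < 0.01 && cell$r_mean > 0
  })
  expect_gt(mean(hits), 0.9)
})

test_that("frequency filtering is idempotent and keeps the 5% boundary", {
  tbl <- table1_like()
  kept <- filter_mutations(tbl, 0.05)
  expect_true(all(kept$frequency >= 0.05))
  expect_identical(filter_mutations(kept, 0.05), kept)
  expect_identical(filter_mutations(tbl, 0), tbl)
  # a record at exactly 0.05 survives; 0.049 does not
  t2 <- tbl[1, ]
  t2$frequency <- 0.05
  expect_equal(nrow(filter_mutations(t2, 0.05)), 1)
  t2$frequency <- 0.049
  expect_equal(nrow(filter_mutations(t2, 0.05)), 0)
  # the co-culture #2 pair: fleQ at 35.6% survives, the <5% record drops
  co2 <- tbl[tbl$line_id == "co2", ]
  expect_equal(filter_mutations(co2, 0.05)$gene, "fleQ")
})

test_that("NS/S ratio counts point mutations only", {
  expect_equal(ns_ratio(tibble::tibble(
    mtype = rep("SNP", 9),
    effect = c(rep("nonsynonymous", 8), "synonymous")))$ratio, 8)
  r <- ns_ratio(tibble::tibble(mtype = "SNP", effect = "nonsynonymous"))
  expect_true(r$no_synonymous)
  expect_equal(r$ratio, Inf)
  r2 <- ns_ratio(tibble::tibble(
    mtype = c(rep("SNP", 29), "DEL"),
    effect = c(rep("nonsynonymous", 26), rep("synonymous", 3), "frameshift")))
  expect_equal(round(r2$ratio, 1), 8.7)
  expect_equal(r2$n_nonsynonymous, 26)
})

test_that("Poisson machinery: lambda, stable tail, monotonicity", {
  expect_equal(poisson_lambda(29, 100, 100), 29)
  expect_equal(poisson_lambda(0, 100, 10), 0)
  lam <- poisson_lambda(29, 6181863, 1476)
  expect_equal(lam, 29 / 6181863 * 1476)

  expect_equal(parallelism_pvalue(0, 5), 1)
  p <- parallelism_pvalue(4, lam)
  expect_equal(p, 9.524524e-11, tolerance = 1e-6)
  # agrees with R's high-precision upper tail over the whole working range
  for (lambda in c(1e-3, 0.05, 0.5, 2, 10)) {
    for (x in c(1, 2, 5, 10, 25, 50)) {
      expect_equal(parallelism_pvalue(x, lambda),
                   stats::ppois(x - 1, lambda, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  }
  # strictly decreasing in the observed count
  ps <- vapply(0:6, parallelism_pvalue, numeric(1), lambda = 0.007)
  expect_true(all(diff(ps) < 0))
})

test_that("gene-level parallelism flags the enriched gene on synthetic tables", {
  tbl <- generate_mutation_table(
    25, default_gene_catalog(), genome_size = 6181863,
    enriched_gene = list(gene = "fleQ", extra_hits = 4),
    freq_distribution = function(n) rep(0.5, n), seed = 42)
  par <- gene_parallelism(tbl, min_freq = 0)
  expect_equal(par$gene[1], "fleQ")
  expect_lt(par$p_value[1], 1e-6)
  expect_true(all(par$p_value <= 1))
})

test_that("convergence summary counts shared and exclusive gene sets", {
  mk <- function(genes, cond) tibble::tibble(
    line_id = "x", condition = cond, position = seq_along(genes),
    mtype = "SNP", size = 1L, gene = genes, gene_length = 1000,
    effect = "nonsynonymous", frequency = 0.5, censored = FALSE,
    genome_size = 1e6)
  disj <- convergence_summary(list(mk(c("a", "b"), "monoculture"),
                                   mk(c("c", "d"), "co-culture")))
  expect_equal(disj$shared, 0)

  same <- convergence_summary(list(mk(c("a", "b"), "monoculture"),
                                   mk(c("a", "b"), "co-culture")))
  expect_equal(same$frac_shared, 1)

  # 4 shared, 5 mono-only, 3 co-only of a 12-gene union
  mono_genes <- c(paste0("s", 1:4), paste0("m", 1:5))
  co_genes <- c(paste0("s", 1:4), paste0("c", 1:3))
  mix <- convergence_summary(list(mk(mono_genes, "monoculture"),
                                  mk(co_genes, "co-culture")))
  expect_equal(mix$union_size, 12)
  expect_equal(mix$frac_shared, 1 / 3)
  expect_equal(mix$frac_only_a, 5 / 12, tolerance = 1e-12)
  expect_equal(mix$frac_only_b, 0.25)
})

test_that("sweep classification is monotone with the published thresholds", {
  tbl <- classify_sweeps(table1_like())
  expect_equal(as.character(tbl$sweep_class[tbl$frequency == 1.00][1]), "fixed")
  expect_equal(as.character(tbl$sweep_class[tbl$frequency == 0.356]), "high")
  expect_equal(as.character(tbl$sweep_class[tbl$frequency == 0.04][1]), "low")
  # monotone in frequency
  f <- seq(0, 1, by = 0.01)
  cls <- classify_sweeps(tibble::tibble(frequency = f))$sweep_class
  expect_true(all(diff(as.integer(cls)) <= 0))
  # 0.99 absorbs reporting rounding of "100%"
  expect_equal(as.character(
    classify_sweeps(tibble::tibble(frequency = 0.995))$sweep_class), "fixed")
})

test_that("biofilm index is OD595/OD600 with a Welch test against a reference", {
  expect_equal(biofilm_index(0.30, 0.15), 2)
  expect_equal(biofilm_index(0, 5), 0)
  expect_error(biofilm_index(0.3, 0), "> 0")
  same <- biofilm_index(c(0.31, 0.30, 0.29), c(0.15, 0.15, 0.15),
                        ref_od595 = c(0.31, 0.30, 0.29),
                        ref_od600 = c(0.15, 0.15, 0.15))
  expect_equal(same$test$p_two_tailed, 1)
  diffr <- biofilm_index(c(0.62, 0.60, 0.58), c(0.15, 0.15, 0.15),
                         ref_od595 = c(0.31, 0.30, 0.29),
                         ref_od600 = c(0.15, 0.15, 0.15))
  expect_lt(diffr$test$p_two_tailed, 0.01)
})
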