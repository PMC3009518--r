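# Pedigree simulator and penetrance analytics.

test_that("penetrance analytics follow the closed forms", {
  sets <- penetrance_sets()
  # flat penetrance: prevalence equals the penetrance for any frequency
  for (p in c(0.05, 0.3, 0.9))
    expect_equal(prevalence(c(0.2, 0.2, 0.2), p), 0.2)
  expect_equal(prevalence(sets$C, 0.1), 0.0995)
  expect_equal(prevalence(sets$A, 0.1), 0.07)
  # flat penetrance: genotype|affected = HWE priors
  expect_equal(genotype_given_affected(c(0.3, 0.3, 0.3), 0.2),
               c(0.64, 0.32, 0.04))
  expect_equal(sum(genotype_given_affected(sets$B, 0.1)), 1)
  expect_equal(unname(relative_risks(c(0.1, 0.1, 0.4))), c(1, 4))
  expect_equal(unname(relative_risks(c(0, 0.1, 0.4))), c(Inf, Inf))
  expect_error(genotype_given_affected(c(0, 0, 0), 0.1), "zero")
})

test_that("structure sampling matches the generation mix and size range", {
  set.seed(101)
  two_gen_only <- replicate(50, n_members(sample_structure(p_three_gen = 0)))
  expect_true(all(two_gen_only >= 4 & two_gen_only <= 20))
  sk0 <- sample_structure(p_three_gen = 0, seed = 1)
  expect_true(all(is.na(sk0$father[1:2])))
  expect_equal(sum(is_founder(sk0)), 2)  # two generations: founder couple only
  sizes <- integer(10000)
  three <- logical(10000)
  for (i in seq_len(10000)) {
    sk <- sample_structure()
    sizes[i] <- n_members(sk)
    three[i] <- sum(is_founder(sk)) == 4
  }
  expect_true(all(sizes >= 4 & sizes <= 20))
  expect_lt(abs(mean(three) - 52 / 65), 0.02)
  expect_lt(abs(mean(sizes) - 13), 1)
  # reproducibility
  s1 <- sample_structure(seed = 42)
  s2 <- sample_structure(seed = 42)
  expect_identical(s1$id, s2$id)
})

test_that("gene dropping reproduces the population haplotype frequencies", {
  tab <- synthetic_cf_panel()
  # one pedigree of unrelated founders = i.i.d. haplotype draws
  n <- 25000
  sk <- fhm_pedigree("U", as.character(seq_len(n)), rep(NA, n), rep(NA, n),
                     rep(1, n), rep(NA, n), matrix(integer(0), n, 0))
  gd <- drop_genes(sk, tab, seed = 77)
  drawn <- c(apply(gd$truth$hap[, , 1], 1, paste, collapse = ""),
             apply(gd$truth$hap[, , 2], 1, paste, collapse = ""))
  counts <- table(factor(drawn, levels = tab$haplotype))
  gof <- chisq.test(as.vector(counts), p = tab$freq)
  expect_gt(gof$p.value, 0.01)
  # single-haplotype table: everyone homozygous for it
  tab1 <- hap_freq_table("121", 1)
  trio <- drop_genes(fhm_pedigree("T", c("f", "m", "c"), c(NA, NA, "f"),
                                  c(NA, NA, "m"), c(1, 2, 1), rep(NA, 3),
                                  matrix(integer(0), 3, 0)), tab1, seed = 1)
  expect_true(all(hap_strings(trio$truth) == "121"))
})

test_that("phenotype assignment converges to the penetrances per genotype class", {
  set.seed(303)
  tab <- hap_freq_table(c("1", "2"), c(0.7, 0.3))
  n <- 30000
  sk <- fhm_pedigree("U", as.character(seq_len(n)), rep(NA, n), rep(NA, n),
                     rep(1, n), rep(NA, n), matrix(integer(0), n, 0))
  gd <- drop_genes(sk, tab, seed = 5)
  f <- c(0.05, 0.3, 0.5)
  model <- penetrance_model(f[1], f[2], f[3], mode = "single-locus",
                            risk_snp = 1, risk_allele = 2)
  ped <- assign_phenotypes(gd$ped, gd$truth, model, seed = 6)
  g <- rowSums(ped$geno == 2)
  for (k in 0:2) {
    nk <- sum(g == k)
    rate <- mean(ped$phenotype[g == k])
    expect_lt(abs(rate - f[k + 1]), 3 * sqrt(f[k + 1] * (1 - f[k + 1]) / nk))
  }
  # degenerate penetrances
  none <- assign_phenotypes(gd$ped, gd$truth,
                            penetrance_model(0, 0, 0, mode = "single-locus",
                                             risk_snp = 1, risk_allele = 2))
  expect_true(all(none$phenotype == 0))
  all_aff <- assign_phenotypes(gd$ped, gd$truth,
                               penetrance_model(1, 1, 1, mode = "null"))
  expect_true(all(all_aff$phenotype == 1))
  expect_error(assign_phenotypes(gd$ped, gd$truth,
                                 penetrance_model(0.1, 0.2, 0.3,
                                                  mode = "single-locus",
                                                  risk_snp = 99,
                                                  risk_allele = 2)),
               "out of range")
})

test_that("population affected fraction matches the analytic prevalence", {
  set.seed(17)
  tab <- hap_freq_table(c("1", "2"), c(0.9, 0.1))  # risk allele 2 at 0.1
  n <- 20000
  sk <- fhm_pedigree("U", as.character(seq_len(n)), rep(NA, n), rep(NA, n),
                     rep(1, n), rep(NA, n), matrix(integer(0), n, 0))
  gd <- drop_genes(sk, tab, seed = 9)
  f <- penetrance_sets()$C
  ped <- assign_phenotypes(gd$ped, gd$truth,
                           penetrance_model(f[1], f[2], f[3],
                                            mode = "single-locus",
                                            risk_snp = 1, risk_allele = 2),
                           seed = 10)
  K <- prevalence(f, 0.1)  # 0.0995
  expect_lt(abs(mean(ped$phenotype) - K), 3 * sqrt(K * (1 - K) / n))
})

test_that("ascertainment keeps affected families and strips the risk SNP", {
  tab <- synthetic_cf_panel()
  model <- penetrance_model(1, 1, 1, mode = "null")
  sim <- simulate_families(5, tab, model, seed = 1)
  expect_equal(sim$attempted, 5)  # acceptance rate 1 when everyone affected
  model2 <- penetrance_model(0.05, 0.3, 0.5, mode = "single-locus",
                             risk_snp = 10, risk_allele = 2)
  sim2 <- simulate_families(8, tab, model2, seed = 2)
  expect_true(all(vapply(sim2$peds, function(p)
    any(p$phenotype == 1), TRUE)))
  expect_equal(n_markers(sim2$peds[[1]]), 18)      # risk SNP removed
  expect_equal(dim(sim2$truths[[1]]$hap)[2], 19)   # truth keeps the full panel
  # reproducibility from the root seed
  sim3 <- simulate_families(8, tab, model2, seed = 2)
  expect_identical(sim2$peds[[3]]$geno, sim3$peds[[3]]$geno)
  expect_identical(sim2$peds[[5]]$phenotype, sim3$peds[[5]]$phenotype)
})

test_that("rare-haplotype selection respects the threshold", {
  tab <- synthetic_cf_panel()
  eligible <- tab$haplotype[tab$freq < 0.02]
  expect_length(eligible, 22)
  all22 <- pick_rare_haplotypes(tab, 22, seed = 1)
  expect_setequal(all22, eligible)
  expect_identical(pick_rare_haplotypes(tab, 4, seed = 9),
                   pick_rare_haplotypes(tab, 4, seed = 9))
  expect_error(pick_rare_haplotypes(tab, 23), "22")
})

test_that("rare-haplotype phenotypes depend on true haplotype carriage", {
  tab <- synthetic_cf_panel()
  risk <- tab$haplotype[8]
  model <- penetrance_model(0, 1, 1, mode = "rare-haplotype",
                            risk_haplotypes = risk)
  set.seed(33)
  sk <- sample_structure("R")
  gd <- drop_genes(sk, tab)
  ped <- assign_phenotypes(gd$ped, gd$truth, model)
  carries <- rowSums(matrix(hap_strings(gd$truth) %in% risk, ncol = 2)) > 0
  expect_equal(ped$phenotype == 1, carries)
})
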