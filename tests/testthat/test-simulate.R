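test_that("simulate_panel degenerate settings collapse as expected", {
  # no variation injected: every haplotype equals the ancestral string
  p0 <- simulate_panel(3, 4, 50, 1e5, founder_div = 0, mutation_rate = 0,
                       recomb_switch_rate = 1e-7, seed = 11)
  expect_true(all(p0$panel_af %in% c(0, 1)))
  expect_equal(nrow(unique(p0$alleles)), 1L)
  # no recombination or mutation: haplotypes equal their breed founder
  p1 <- simulate_panel(3, 4, 80, 1e5, founder_div = 0.3, mutation_rate = 0,
                       recomb_switch_rate = 0, seed = 12)
  for (b in unique(p1$breed_label)) {
    rows <- p1$alleles[p1$breed_label == b, , drop = FALSE]
    expect_equal(nrow(unique(rows)), 1L)
  }
})

test_that("simulate_panel is bit-identical under a fixed seed and validates input", {
  a <- simulate_panel(2, 4, 50, 1e5, seed = 99)
  b <- simulate_panel(2, 4, 50, 1e5, seed = 99)
  expect_identical(a, b)
  expect_identical(a$panel_af, colMeans(a$alleles))
  expect_true(all(diff(a$positions) > 0))
  expect_error(simulate_panel(2, 3, 50, 1e5), "even")
  expect_error(simulate_panel(2, 4, 200, 100), "exceeds")
})

test_that("subset_panel keeps pairs together, recomputes frequencies, honours caps", {
  p <- simulate_panel(5, 8, 120, 1e6, seed = 21)
  full <- subset_panel(p, "breed1", nrow(p$alleles) / 2, seed = 1)
  expect_identical(full$alleles, p$alleles)
  expect_identical(full$panel_af, p$panel_af)
  sub <- subset_panel(p, "breed1", 9, include_target = FALSE, seed = 5)
  dip_breeds <- sub$breed_label[seq(1, nrow(sub$alleles), by = 2)]
  expect_lte(sum(dip_breeds == "breed1"), 1L)
  expect_true(all(table(dip_breeds[dip_breeds != "breed1"]) <= 2))
  # pairs stay together: odd/even rows share the breed label
  expect_identical(sub$breed_label[seq(1, nrow(sub$alleles), by = 2)],
                   sub$breed_label[seq(2, nrow(sub$alleles), by = 2)])
  # monomorphic columns stay in {0, 1}
  mono <- which(p$panel_af %in% c(0, 1))
  expect_true(all(sub$panel_af[mono] %in% c(0, 1)))
  expect_error(subset_panel(p, "nosuchbreed", 5), "absent")
  expect_error(subset_panel(p, "breed1", 999), "available")
})

test_that("cohort phenotype/genotype invariant holds and case count is exact", {
  p <- simulate_panel(4, 10, 300, 2e6, seed = 31)
  for (s in c(1, 7, 123)) {
    co <- simulate_cohort(p, 30, 6, seed = s)
    expect_equal(sum(co$phenotype), 6L)
    expect_identical(co$phenotype,
                     as.integer(co$hapA[, co$causal_site] == 1L &
                                co$hapB[, co$causal_site] == 1L))
    expect_true(all(co$genotype %in% 0:2))
    expect_identical(co$genotype, co$hapA + co$hapB)
  }
})

test_that("with zero rates non-case haplotypes exist verbatim in the panel", {
  p <- simulate_panel(4, 10, 300, 2e6, seed = 41)
  co <- simulate_cohort(p, 12, 3, mosaic_switch_rate = 0,
                        private_allele_rate = 0, seed = 3)
  panel_strs <- apply(p$alleles[p$breed_label == "breed1", ], 1, paste, collapse = "")
  ctrl <- setdiff(seq_len(12), co$cases)
  # controls may have had one causal allele zeroed; exclude the causal site
  keep <- setdiff(seq_len(300), co$causal_site)
  panel_sub <- apply(p$alleles[p$breed_label == "breed1", keep], 1, paste, collapse = "")
  for (i in ctrl) {
    expect_true(paste(co$hapA[i, keep], collapse = "") %in% panel_sub)
    expect_true(paste(co$hapB[i, keep], collapse = "") %in% panel_sub)
  }
  # case haplotypes match the shared donor inside the sweep window
  win <- which(abs(p$positions - p$positions[co$causal_site]) <= 5e5)
  for (i in co$cases)
    expect_identical(co$hapA[i, win], co$hapB[i, win])
})

test_that("private-allele mask density matches its rate", {
  p <- simulate_panel(4, 10, 5000, 2e7, seed = 51)
  rate <- 0.01
  co <- simulate_cohort(p, 30, 6, private_allele_rate = rate, seed = 8)
  ctrl <- setdiff(seq_len(30), co$cases)
  dens <- mean(co$private_mask[ctrl, , ])
  n <- length(ctrl) * 2 * 5000
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(dens - rate), 5 * se + 1e-4)
})

test_that("pileup depths follow the Poisson/binomial model", {
  p <- simulate_panel(3, 6, 2000, 1e7, seed = 61)
  co <- simulate_cohort(p, 30, 6, seed = 2)
  # epsilon ~ 0, hom-ref sites emit no alt reads
  pu0 <- simulate_pileup(co, 5, epsilon = 1e-12, seed = 3)
  ref_sites <- which(colSums(co$genotype) == 0)
  expect_true(all(pu0$alt_count[, ref_sites] == 0))
  # grand mean depth within 1% of lambda at 43.5X with flat profiles
  pu <- simulate_pileup(co, 43.5, seed = 4)
  d <- pu$ref_count + pu$alt_count
  expect_lt(abs(mean(d) / 43.5 - 1), 0.01)
  # a half-coverage segment halves mean depth there and is detectable
  prof <- rep(1, 2000); prof[500:700] <- 0.5
  pu2 <- simulate_pileup(co, 9.6, region_profile = prof, seed = 5)
  d2 <- pu2$ref_count + pu2$alt_count
  expect_lt(abs(mean(d2[, 500:700]) / (0.5 * 9.6) - 1), 0.05)
  pseg <- wilcoxon_signed_rank(rowMeans(d2[, 500:700]), rowMeans(d2))$p_value
  expect_lt(pseg, 0.05)
  expect_identical(simulate_pileup(co, 1.5, seed = 9),
                   simulate_pileup(co, 1.5, seed = 9))
})

test_that("thinning is binomial: edge cases, expectation, composition", {
  p <- simulate_panel(3, 6, 2000, 1e7, seed = 71)
  co <- simulate_cohort(p, 15, 3, seed = 2)
  pu <- simulate_pileup(co, 43.5, seed = 3)
  expect_identical(thin_pileup(pu, 1, seed = 1)$ref_count, pu$ref_count)
  expect_true(all(thin_pileup(pu, 0, seed = 1)$alt_count == 0))
  th <- thin_pileup(pu, 0.4, seed = 5)
  d <- th$ref_count + th$alt_count
  expect_lt(abs(mean(d) / 17.4 - 1), 0.01)
  # thin(thin(P, a), b) matches thin(P, ab) in mean and variance
  t_ab <- thin_pileup(thin_pileup(pu, 0.5, seed = 6), 0.4, seed = 7)
  t_c <- thin_pileup(pu, 0.2, seed = 8)
  d1 <- t_ab$ref_count + t_ab$alt_count
  d2 <- t_c$ref_count + t_c$alt_count
  expect_lt(abs(mean(d1) - mean(d2)), 0.05)
  expect_lt(abs(var(as.vector(d1)) - var(as.vector(d2))) / var(as.vector(d2)), 0.05)
})
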