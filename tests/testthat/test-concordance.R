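test_that("genotype discordance counts comparable cells only", {
  truth <- matrix(c(0L, 1L, 2L, 1L), 1)
  test <- matrix(c(0L, 1L, 2L, 1L), 1)
  expect_equal(genotype_discordance(test, truth)$discordance, 0)
  test2 <- matrix(c(0L, 0L, 2L, 1L), 1)
  r <- genotype_discordance(test2, truth)
  expect_equal(r$discordance, 0.25)
  expect_equal(r$n_compared, 4L)
  # depth filter removes cells
  depth <- matrix(c(5L, 0L, 5L, 5L), 1)
  r2 <- genotype_discordance(test2, truth, depth, min_depth = 1)
  expect_equal(r2$n_compared, 3L)
  expect_equal(r2$discordance, 0)
  expect_error(genotype_discordance(matrix(NA_integer_, 1, 2),
                                    matrix(0L, 1, 2)), "comparable")
  # truth-certainty filter applies when truth carries GPs
  gp <- array(1, c(1, 4, 3)) # nonsense triplets, max 1 everywhere
  gp[1, 1, ] <- c(0.5, 0.3, 0.2)
  r3 <- genotype_discordance(test2, truth, truth_gp = gp,
                             min_truth_certainty = 0.9999)
  expect_equal(r3$n_compared, 3L)
})

test_that("non-reference discordance follows its definition", {
  truth <- matrix(c(0L, 1L, 2L, 1L), 1)
  test <- matrix(c(0L, 0L, 2L, 2L), 1)
  expect_equal(nonref_discordance(test, truth), 2 / 3)
  expect_equal(nonref_discordance(truth, truth), 0)
  all_rr <- matrix(0L, 2, 3)
  expect_error(nonref_discordance(all_rr, all_rr), "undefined")
})

test_that("mismatch_by_class attributes errors to truth classes", {
  truth <- matrix(rep(0L, 10), 1)
  test <- truth; test[1, 3] <- 1L
  mc <- mismatch_by_class(test, truth)
  expect_equal(mc$mismatch_rate[mc$class == "RR"], 0.1)
  expect_true(is.na(mc$mismatch_rate[mc$class == "AA"])) # empty class flagged
  perfect <- mismatch_by_class(truth, truth)
  expect_equal(perfect$mismatch_rate[1], 0)
})

test_that("pooled MAF-bin r2 equals a direct Pearson computation", {
  set.seed(5)
  N <- 8; M <- 60
  truth <- matrix(sample(0:2, N * M, replace = TRUE), N, M)
  dosage <- truth + matrix(rnorm(N * M, 0, 0.3), N, M)
  af <- runif(M, 0.02, 0.95)
  bins <- c(0, 0.1, 0.3, 0.5)
  tab <- aggregate_r2_by_maf(dosage, truth, af, bins)
  maf <- pmin(af, 1 - af)
  for (b in 1:3) {
    sites <- which(maf > bins[b] & maf <= bins[b + 1])
    expected <- cor(as.vector(dosage[, sites]), as.vector(truth[, sites]))^2
    expect_equal(tab$r2[b], expected, tolerance = 1e-12)
  }
  # perfect dosages give r2 = 1 in every defined bin
  tab1 <- aggregate_r2_by_maf(truth, truth, af, bins)
  expect_true(all(tab1$r2[tab1$defined] == 1))
  # permuted cells decorrelate
  perm <- matrix(sample(as.vector(dosage)), N, M)
  tabp <- aggregate_r2_by_maf(perm, truth, af, c(0, 0.5))
  expect_lt(tabp$r2[1], 0.05)
  # empty bins are flagged, not zero
  tab_e <- aggregate_r2_by_maf(dosage, truth, rep(0.4, M), bins)
  expect_false(tab_e$defined[1])
  expect_true(is.na(tab_e$r2[1]))
})

test_that("r2 aggregation is invariant to individual and site relabelling", {
  set.seed(6)
  N <- 6; M <- 40
  truth <- matrix(sample(0:2, N * M, replace = TRUE), N, M)
  dosage <- truth + matrix(rnorm(N * M, 0, 0.5), N, M)
  af <- runif(M, 0.05, 0.5)
  t1 <- aggregate_r2_by_maf(dosage, truth, af)
  pi_ <- sample(N); ps <- sample(M)
  t2 <- aggregate_r2_by_maf(dosage[pi_, ps], truth[pi_, ps], af[ps])
  expect_equal(t1$r2, t2$r2)
})

test_that("haplotype discordance registers single phase flips per window", {
  N <- 3; M <- 20
  set.seed(7)
  hapA <- matrix(rbinom(N * M, 1, 0.5), N, M)
  hapB <- matrix(rbinom(N * M, 1, 0.5), N, M)
  truth <- list(hapA = hapA, hapB = hapB, missing = matrix(FALSE, N, M))
  test <- truth
  expect_equal(haplotype_discordance(test, truth, "A")$discordance, 0)
  # flip the phase of one het site for one individual
  het <- which(hapA[1, ] != hapB[1, ])[1]
  test$hapA[1, het] <- truth$hapB[1, het]
  test$hapB[1, het] <- truth$hapA[1, het]
  hdA <- haplotype_discordance(test, truth, "A")
  hdB <- haplotype_discordance(test, truth, "B")
  expect_equal(hdA$discordance, 1 / (N * M))
  expect_equal(hdB$discordance, 1 / (N * M))
  # re-pairing mode forgives a whole-individual label swap
  swapped <- list(hapA = rbind(hapB[1, ], hapA[-1, ]),
                  hapB = rbind(hapA[1, ], hapB[-1, ]),
                  missing = matrix(FALSE, N, M))
  lit <- haplotype_discordance(swapped, truth, "A")$discordance
  rep_ <- haplotype_discordance(swapped, truth, "A", repair = TRUE)$discordance
  expect_gt(lit, 0)
  expect_equal(rep_, 0)
  # window without comparable sites is flagged
  test2 <- truth
  test2$missing[, 1:10] <- TRUE
  wins <- rep(1:2, each = 10)
  hd <- haplotype_discordance(test2, truth, "A", wins)
  expect_true(is.na(hd$discordance[1]))
  expect_equal(hd$discordance[2], 0)
})

test_that("switch error: enumeration cases and the Bernoulli null", {
  M <- 8
  tr <- list(hapA = matrix(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), 1),
             hapB = matrix(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), 1),
             missing = matrix(FALSE, 1, M))
  expect_equal(switch_error_rate(tr, tr), 0)
  # alternating phase at the 4 het sites: all 3 consecutive pairs switch
  te <- tr
  te$hapA[1, 1:4] <- c(1L, 0L, 1L, 0L)
  te$hapB[1, 1:4] <- c(0L, 1L, 0L, 1L)
  expect_equal(switch_error_rate(te, tr), 1)
  # fewer than 2 het sites is flagged
  hom <- list(hapA = matrix(0L, 1, 4), hapB = matrix(0L, 1, 4),
              missing = matrix(FALSE, 1, 4))
  expect_true(is.na(switch_error_rate(hom, hom)))
  # random phase approaches 1/2
  set.seed(8)
  Mh <- 1001
  trA <- matrix(1L, 1, Mh); trB <- matrix(0L, 1, Mh)
  flip <- rbinom(Mh, 1, 0.5) == 1
  teA <- trA; teB <- trB
  teA[1, flip] <- 0L; teB[1, flip] <- 1L
  rate <- switch_error_rate(list(hapA = teA, hapB = teB,
                                 missing = matrix(FALSE, 1, Mh)),
                            list(hapA = trA, hapB = trB,
                                 missing = matrix(FALSE, 1, Mh)))
  expect_lt(abs(rate - 0.5), 0.05)
})
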