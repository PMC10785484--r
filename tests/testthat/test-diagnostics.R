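fake_callset <- function(hapA, hapB, missing = NULL) {
  list(hapA = hapA, hapB = hapB,
       missing = missing %||% matrix(FALSE, nrow(hapA), ncol(hapA)))
}

test_that("sample_regions emits fixed-variant-count regions deterministically", {
  pos <- sort(sample.int(1e6, 500))
  r1 <- sample_regions(pos, 200, 100, seed = 5)
  r2 <- sample_regions(pos, 200, 100, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$n_variants == 100L))
  expect_true(all(r1$end_idx - r1$start_idx + 1L == 100L))
  expect_true(all(r1$end_idx <= 500L))
  expect_equal(r1$size_bp, pos[r1$end_idx] - pos[r1$start_idx] + 1L)
  # the whole chromosome is the single possible region
  rall <- sample_regions(pos, 5, 500, seed = 1)
  expect_true(all(rall$start_idx == 1L))
  expect_error(sample_regions(pos, 10, 501), "cannot sample")
})

test_that("haplotype counts reproduce the expected consistency ceilings", {
  set.seed(6)
  N <- 2; M <- 12
  hapA <- matrix(rbinom(N * M, 1, 0.5), N, M)
  hapB <- matrix(rbinom(N * M, 1, 0.5), N, M)
  hapB[1, 1] <- 1L - hapA[1, 1] # ensure a het site
  cs <- fake_callset(hapA, hapB)
  reg <- list(start_idx = 1L, end_idx = M)
  # identical data across 5 depths with >= 1 het site: exactly 2
  expect_equal(count_region_haplotypes(rep(list(cs), 5), reg, 1), 2L)
  # identical and fully homozygous: 1
  hom <- fake_callset(hapA, hapA)
  expect_equal(count_region_haplotypes(rep(list(hom), 5), reg, 1), 1L)
  # one depth with a single-variant genotype change: exactly 3
  gch <- fake_callset(hapA, hapB)
  gch$hapA[1, 2] <- 1L - gch$hapA[1, 2]
  expect_equal(count_region_haplotypes(c(rep(list(cs), 4), list(gch)), reg, 1), 3L)
  # one depth with one het site phase-flipped: both labelled strings become
  # novel when the haplotypes differ at other sites too, giving 4
  flip <- fake_callset(hapA, hapB)
  het <- which(hapA[1, ] != hapB[1, ])[1]
  flip$hapA[1, het] <- hapB[1, het]; flip$hapB[1, het] <- hapA[1, het]
  expect_equal(count_region_haplotypes(c(rep(list(cs), 4), list(flip)), reg, 1), 4L)
  # with a single het site in the region a phase flip just relabels: still 2
  one_het <- fake_callset(matrix(0L, 1, 4), matrix(c(1L, 0L, 0L, 0L), 1))
  oh_flip <- fake_callset(matrix(c(1L, 0L, 0L, 0L), 1), matrix(0L, 1, 4))
  expect_equal(count_region_haplotypes(list(one_het, one_het, oh_flip),
                                       list(start_idx = 1L, end_idx = 4L), 1), 2L)
  # a novel single-site change raises the count by exactly 1
  mut <- fake_callset(hapA, hapB)
  mut$hapA[1, 2] <- 1L - mut$hapA[1, 2]
  before <- count_region_haplotypes(rep(list(cs), 3), reg, 1)
  after <- count_region_haplotypes(c(rep(list(cs), 2), list(mut)), reg, 1)
  expect_equal(after, before + 1L)
  # fewer than 2 usable positions is flagged
  miss <- fake_callset(hapA, hapB, matrix(TRUE, N, M))
  expect_true(is.na(count_region_haplotypes(list(miss), reg, 1)))
})

test_that("haplotype counting matches the brute-force oracle on random instances", {
  set.seed(7)
  for (rep in 1:15) {
    N <- 3; M <- sample(6:12, 1)
    n_d <- sample(2:5, 1)
    depths <- lapply(seq_len(n_d), function(d) {
      fake_callset(matrix(rbinom(N * M, 1, 0.5), N, M),
                   matrix(rbinom(N * M, 1, 0.5), N, M),
                   matrix(rbinom(N * M, 1, 0.15) == 1, N, M))
    })
    reg <- list(start_idx = 2L, end_idx = M - 1L)
    regions <- data.frame(region = 1L, start_idx = 2L, end_idx = M - 1L,
                          start_bp = 2L, end_bp = M - 1L,
                          size_bp = M - 2L, n_variants = M - 2L)
    all_counts <- count_region_haplotypes_all(depths, regions)
    for (i in 1:N) {
      expect_identical(count_region_haplotypes(depths, reg, i),
                       oracle_region_hap_count(depths, reg$start_idx:reg$end_idx, i))
      expect_identical(all_counts[1, i],
                       count_region_haplotypes(depths, reg, i))
    }
  }
})

test_that("haplotype count is at most 2 when all depth datasets agree", {
  set.seed(8)
  for (rep in 1:10) {
    N <- 4; M <- 30
    cs <- fake_callset(matrix(rbinom(N * M, 1, 0.5), N, M),
                       matrix(rbinom(N * M, 1, 0.5), N, M),
                       matrix(rbinom(N * M, 1, 0.1) == 1, N, M))
    reg <- list(start_idx = 1L, end_idx = M)
    for (i in 1:N) {
      cnt <- count_region_haplotypes(rep(list(cs), 5), reg, i)
      expect_true(is.na(cnt) || cnt <= 2L)
    }
  }
})

test_that("signed-rank test matches the exact enumeration oracle for n <= 10", {
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    if (rep %% 3 == 0) y[1:2] <- x[1:2]             # zeros
    if (rep %% 4 == 0) x <- round(x, 1)             # ties in |d|
    got <- wilcoxon_signed_rank(x, y)$p_value
    expect_equal(got, oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
  }
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p_value, 1)
})

test_that("region depth test: null calibration and power on a planted depression", {
  set.seed(10)
  null_p <- replicate(400, {
    d <- matrix(rpois(30 * 40, 5), 30)
    pu <- list(ref_count = d, alt_count = matrix(0L, 30, 40))
    region_depth_wilcoxon(pu, list(start_idx = 1L, end_idx = 10L))
  })
  rej <- mean(null_p < 0.05)
  expect_gt(rej, 0.02); expect_lt(rej, 0.08)
  # region at half coverage: overwhelmingly detected at lambda = 9.6
  power <- mean(replicate(50, {
    mu <- matrix(9.6, 30, 60); mu[, 1:15] <- 9.6 * 0.5
    d <- matrix(rpois(30 * 60, mu), 30)
    pu <- list(ref_count = d, alt_count = matrix(0L, 30, 60))
    region_depth_wilcoxon(pu, list(start_idx = 1L, end_idx = 15L)) < 0.05
  }))
  expect_gt(power, 0.95)
  # identical pairs give p = 1
  d <- matrix(5L, 30, 20)
  pu <- list(ref_count = d, alt_count = matrix(0L, 30, 20))
  expect_equal(region_depth_wilcoxon(pu, list(start_idx = 1L, end_idx = 5L)), 1)
  expect_error(region_depth_wilcoxon(list(ref_count = matrix(1L, 3, 5),
                                          alt_count = matrix(0L, 3, 5)),
                                     list(start_idx = 1L, end_idx = 2L)),
               "6 individuals")
})

test_that("ols_regress recovers exact fits and flags rank deficiency", {
  x <- 1:20
  fit <- suppressWarnings(ols_regress(2 * x, data.frame(x = x))) # exact fit

  expect_equal(fit$estimate[fit$term == "x"], 2, tolerance = 1e-12)
  expect_equal(attr(fit, "r.squared"), 1)
  # permutation invariance
  set.seed(11)
  y <- rnorm(20); X <- data.frame(x = rnorm(20), g = factor(rep(c("a", "b"), 10)))
  f1 <- ols_regress(y, X)
  pi_ <- sample(20)
  f2 <- ols_regress(y[pi_], X[pi_, ])
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-10)
  expect_error(ols_regress(y, data.frame(a = X$x, b = X$x)), "rank deficient")
  # null slope p-values are roughly uniform
  ps <- replicate(300, {
    yy <- rnorm(15)
    ols_regress(yy, data.frame(x = rnorm(15)))$p[2]
  })
  expect_gt(mean(ps < 0.5), 0.4); expect_lt(mean(ps < 0.5), 0.6)
})

test_that("correlation_suite handles self, anti-correlated and sparse input", {
  v <- list(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, NA, NA, NA))
  cs <- correlation_suite(v, "a")
  expect_equal(cs$summary$r[cs$summary$depth == "a"], 1)
  expect_equal(cs$summary$r[cs$summary$depth == "b"], -1)
  expect_true(is.na(cs$summary$r[cs$summary$depth == "c"]))
  expect_error(correlation_suite(v, "zz"), "not in the input")
})

test_that("window metrics: zero discordance against itself and quantile trim", {
  cfg <- tiny_config(seed = 21)
  sim <- simulate_experiment_inputs(cfg)
  cs <- impute_all_depths(sim, sim$panels$full, cfg)
  top <- cs[[sim$top_name]]
  xp <- setNames(rep(list(NULL), length(cs)), names(cs))
  wm <- window_metrics(cs[sim$top_name], hard_calls(top), top,
                       sim$pileups[sim$top_name], xp[sim$top_name],
                       sim$master_panel$positions, cfg$window_bp,
                       cfg$trim_quantiles)
  expect_true(all(wm$geno_disc == 0, na.rm = TRUE))
  expect_true(all(wm$hapA_disc == 0, na.rm = TRUE))
  # the 1%/99% trim drops only depth extremes
  expect_gte(mean(wm$kept), 0.7)
  if (any(!wm$kept)) {
    dropped <- wm$mean_depth[!wm$kept]
    expect_true(all(dropped <= min(wm$mean_depth[wm$kept]) |
                    dropped >= max(wm$mean_depth[wm$kept])))
  }
  # at many windows the quantile arithmetic keeps ~98%
  fake_depth <- rnorm(500, 10)
  kept <- fake_depth >= quantile(fake_depth, 0.01) &
          fake_depth <= quantile(fake_depth, 0.99)
  expect_equal(mean(kept), 0.98, tolerance = 0.01)
})
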