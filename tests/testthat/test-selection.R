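test_that("EHH curve values match combinatorial and pairwise-identity oracles", {
  # 4 haplotypes split {2,1,1} over the span: EHH = C(2,2)/C(4,2) = 1/6
  haps <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(1L, 0L))
  cv <- ehh_curve(haps, 1, "right", c(100L, 200L))
  expect_equal(cv$ehh, c(1, 0.5, 1 / 6))
  # identical haplotypes: EHH = 1 everywhere, no truncation
  same <- matrix(rep(c(0L, 1L, 0L), each = 3), 3)
  cs <- ehh_curve(same, 2, "right", c(1L, 50L, 90L))
  expect_true(all(cs$ehh == 1))
  # all distinct: EHH truncates immediately
  dist <- diag(1L, 4)[, 1:2]
  cd <- ehh_curve(rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)), 1,
                  "right", c(10L, 20L))
  expect_lt(cd$ehh[nrow(cd)], 0.5)
  expect_error(ehh_curve(matrix(0L, 1, 3), 1, "right", c(1L, 2L, 3L)), "2 haplotypes")
  # random instances vs the brute-force pairwise oracle
  set.seed(9)
  for (rep in 1:12) {
    n <- sample(2:10, 1); M <- sample(4:12, 1)
    haps <- matrix(rbinom(n * M, 1, 0.5), n, M)
    pos <- sort(sample.int(5000, M))
    core <- sample.int(M, 1)
    cv <- ehh_curve(haps, core, "right", pos, ehh_cutoff = 0)
    for (r in 2:nrow(cv)) {
      span <- core:cv$site[r]
      expect_equal(cv$ehh[r], oracle_ehh_span(haps, span))
    }
    # EHH is non-increasing: partitions only refine
    expect_true(all(diff(cv$ehh) <= 1e-12))
  }
})

test_that("iHH integrates curves exactly, with interpolation to the cutoff", {
  # single segment 1 -> 0.05 over 1000 bp: trapezoid (1 + 0.05)/2 * 1000
  cv <- data.frame(dist_bp = c(0, 1000), ehh = c(1, 0.05))
  expect_equal(ihh(cv), 525)
  # a segment ending below the cutoff is interpolated to the crossing
  cv2 <- data.frame(dist_bp = c(0, 1000), ehh = c(1, 0.02))
  d_cross <- (1 - 0.05) / (1 - 0.02) * 1000
  expect_equal(ihh(cv2), (1 + 0.05) / 2 * d_cross)
  expect_equal(ihh(cv2, interpolate = FALSE), 0)
  # collinear intermediate points do not change the integral
  cv3 <- data.frame(dist_bp = c(0, 400, 1000), ehh = c(1, 0.62, 0.05))
  expect_equal(ihh(cv3), ihh(cv))
  # EHH == 1 over d bp on each side gives iHH = 2d
  same <- matrix(rep(c(0L, 1L, 0L), each = 4), 4)
  r <- lowpasshap:::ihh_at_core(same, 2, c(0L, 500L, 1000L))
  expect_equal(r$ihh, 1000)
})

test_that("compiled iHH scan agrees with the R curve/integration path", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(2:12, 1); M <- sample(5:15, 1)
    haps <- matrix(rbinom(n * M, 1, 0.5), n, M)
    pos <- sort(sample.int(20000, M))
    core <- sample.int(M, 1)
    r_val <- lowpasshap:::ihh_at_core(haps, core, pos)$ihh
    c_val <- lowpasshap:::.ihh_scan_cpp(haps, as.numeric(pos), core - 1L, 0.05, TRUE)
    expect_equal(c_val, r_val, tolerance = 1e-9)
  }
})

test_that("xpehh_scan: identical populations, antisymmetry, sweep sign", {
  set.seed(11)
  n <- 8; M <- 40
  haps <- matrix(rbinom(n * M, 1, 0.5), n, M)
  pos <- sort(sample.int(2e5, M))
  xp <- xpehh_scan(haps, haps, pos)
  expect_true(all(abs(xp$raw[xp$included]) < 1e-12))
  hapsB <- matrix(rbinom(n * M, 1, 0.5), n, M)
  ab <- xpehh_scan(haps, hapsB, pos)
  ba <- xpehh_scan(hapsB, haps, pos)
  expect_equal(ab$raw, -ba$raw, tolerance = 1e-12)
  # B fixed for one long haplotype while A is diverse: raw < 0 at the core
  core_hap <- rbinom(M, 1, 0.5)
  fixedB <- matrix(rep(core_hap, 6), 6, byrow = TRUE)
  divA <- matrix(rbinom(12 * M, 1, 0.5), 12)
  sw <- xpehh_scan(divA, fixedB, pos)
  expect_true(all(sw$raw[sw$included] < 0))
  expect_error(xpehh_scan(haps, hapsB[, 1:10], pos), "site list")
})

test_that("standardisation matches the hand case and flags degenerate input", {
  z <- standardize_scores(c(-1, 0, 1))
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_error(standardize_scores(rep(2, 5)), "zero variance")
  expect_error(standardize_scores(1), "at least 2")
})

test_that("significant_z partitions by sign with sensible edge behaviour", {
  z <- c(-5, -1, 0, 2, 4.5, NA)
  s <- significant_z(z, 4)
  expect_equal(s$negative, 1L)
  expect_equal(s$positive, 5L)
  s0 <- significant_z(z, 0)
  expect_equal(sort(c(s0$positive, s0$negative)), c(1L, 2L, 4L, 5L))
  none <- significant_z(c(-1, 1), 4)
  expect_length(none$positive, 0)
  expect_length(none$negative, 0)
})

test_that("switch-error injection monotonically degrades XP-EHH correlation", {
  p <- simulate_panel(4, 10, 800, 4e6, seed = 61)
  co <- simulate_cohort(p, 30, 6, mosaic_switch_rate = 2e-6,
                        private_allele_rate = 0.015, seed = 62)
  popA <- which(co$phenotype == 0); popB <- which(co$phenotype == 1)
  hapsA <- rbind(co$hapA[popA, ], co$hapB[popA, ])
  base <- xpehh_scan(hapsA,
                     rbind(co$hapA[popB, ], co$hapB[popB, ]), co$positions)
  cors <- vapply(c(0, 0.02, 0.05), function(s) {
    pert <- lowpasshap:::inject_switch_errors(co$hapA[popB, , drop = FALSE],
                                              co$hapB[popB, , drop = FALSE],
                                              s, seed = 63)
    xp <- xpehh_scan(hapsA, rbind(pert$hapA, pert$hapB), co$positions)
    ok <- base$included & xp$included
    cor(base$z[ok], xp$z[ok])
  }, numeric(1))
  expect_equal(cors[1], 1, tolerance = 1e-12)
  expect_true(all(diff(cors) < 0))
})
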