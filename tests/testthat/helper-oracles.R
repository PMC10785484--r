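# Independent brute-force oracles used to validate the implementations.
# These deliberately use naive enumeration, not the package's algorithms.

# diploid Li-Stephens posteriors by exhaustive path enumeration over all
# (K^2)^M state paths
oracle_ls_fb <- function(gl, hap, rho, theta) {
  M <- nrow(gl); K <- nrow(hap); S <- K * K
  states <- expand.grid(j = 1:K, k = 1:K)
  gw <- function(m, j, k) {
    p1 <- ifelse(hap[j, m] == 1, 1 - theta, theta)
    p2 <- ifelse(hap[k, m] == 1, 1 - theta, theta)
    c((1 - p1) * (1 - p2), p1 * (1 - p2) + (1 - p1) * p2, p1 * p2)
  }
  emis <- function(m, j, k) sum(gl[m, ] * gw(m, j, k))
  trans <- function(m, s1, s2) {
    r <- rho[m]
    tj <- if (states$j[s1] == states$j[s2]) (1 - r) + r / K else r / K
    tk <- if (states$k[s1] == states$k[s2]) (1 - r) + r / K else r / K
    tj * tk
  }
  paths <- as.matrix(expand.grid(rep(list(1:S), M)))
  w <- numeric(nrow(paths))
  for (p in seq_len(nrow(paths))) {
    pr <- 1 / S * emis(1, states$j[paths[p, 1]], states$k[paths[p, 1]])
    if (M > 1) for (m in 2:M)
      pr <- pr * trans(m, paths[p, m - 1], paths[p, m]) *
            emis(m, states$j[paths[p, m]], states$k[paths[p, m]])
    w[p] <- pr
  }
  w <- w / sum(w)
  post <- matrix(0, M, S)
  for (m in 1:M) {
    tp <- tapply(w, paths[, m], sum)
    post[m, as.integer(names(tp))] <- tp
  }
  gp <- matrix(0, M, 3)
  for (m in 1:M) for (s in 1:S) {
    pg <- gl[m, ] * gw(m, states$j[s], states$k[s])
    gp[m, ] <- gp[m, ] + post[m, s] * pg / sum(pg)
  }
  list(gp = gp, states = post)
}

# EHH over a fixed span by direct pairwise identity counting
oracle_ehh_span <- function(haps, span_sites) {
  n <- nrow(haps)
  same <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (all(haps[i, span_sites] == haps[j, span_sites])) same <- same + 1L
  same / choose(n, 2)
}

# two-sided exact signed-rank p-value by looping over all 2^n sign vectors
oracle_wilcoxon_exact <- function(x, y) {
  d <- (x - y)
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  Ws <- numeric(2^n)
  for (b in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(b))[1:n]
    Ws[b + 1] <- sum(r[signs == 1])
  }
  p_lo <- mean(Ws <= W_obs)
  p_hi <- mean(Ws >= W_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# distinct haplotype strings by direct set construction
oracle_region_hap_count <- function(phased_by_depth, idx, individual) {
  usable <- idx
  for (cs in phased_by_depth) {
    miss <- cs$missing
    usable <- usable[!miss[individual, usable]]
  }
  if (length(usable) < 2) return(NA_integer_)
  strs <- character(0)
  for (cs in phased_by_depth)
    strs <- c(strs, paste(cs$hapA[individual, usable], collapse = "/"),
              paste(cs$hapB[individual, usable], collapse = "/"))
  length(unique(strs))
}

# small random GL matrix (rows normalised)
random_gl <- function(M) {
  g <- matrix(runif(M * 3), M, 3)
  g / rowSums(g)
}

# tiny cohort/panel pair for integration-style tests
tiny_config <- function(seed = 1L, ...) {
  default_config(
    seed = seed,
    chrom_length_bp = 2e6, n_sites = 400L,
    n_breeds = 4L, haps_per_breed = 8L,
    panel_full_diploids = 12L, panel_subset_diploids = 6L,
    n_individuals = 12L, n_cases = 3L,
    low_coverage_segments = data.frame(start = 0.5e6, end = 0.7e6,
                                       multiplier = 0.3),
    n_regions = 60L, variants_per_region = 25L,
    window_bp = 2.5e5,
    chunk_bp = 2e6,
    ...
  )
}
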