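# Haplotype-consistency diagnostics across sequencing depths: random region
# sampling, cross-depth distinct-haplotype counting, regional depth-deviation
# tests, 1-Mb window metrics, and the regression/correlation helpers used to
# summarise them.

#' Randomly sample fixed-variant-count regions
#'
#' Regions span `variants_per_region` consecutive sites; start indices are
#' sampled uniformly (with replacement across regions), so region bp sizes
#' vary with local variant density. Regions that would run past the
#' chromosome end are resampled.
#'
#' @param positions site positions in bp.
#' @param n_regions number of regions (default 10000).
#' @param variants_per_region sites per region (default 100).
#' @param seed integer seed.
#' @return An object of class `RegionSet`: data.frame with `region`,
#'   `start_idx`, `end_idx`, `start_bp`, `end_bp`, `size_bp`, `n_variants`.
#' @export
sample_regions <- function(positions, n_regions = 10000L,
                           variants_per_region = 100L, seed = 1L) {
  M <- length(positions)
  if (M < variants_per_region)
    stopf("chromosome has %d sites; cannot sample %d-variant regions", M,
          variants_per_region)
  with_seed(seed, {
    starts <- sample.int(M - variants_per_region + 1L, n_regions, replace = TRUE)
    ends <- starts + variants_per_region - 1L
    out <- data.frame(region = seq_len(n_regions),
                      start_idx = starts, end_idx = ends,
                      start_bp = positions[starts], end_bp = positions[ends],
                      size_bp = positions[ends] - positions[starts] + 1L,
                      n_variants = variants_per_region)
    class(out) <- c("RegionSet", class(out))
    out
  })
}

#' Distinct haplotypes for one individual in one region across depths
#'
#' Collects the `2 * n_depths` haplotype allele-strings over the region's
#' sites, restricted to positions that are non-missing in every depth
#' dataset for this individual, and counts the distinct strings. If the
#' genotype imputation and phasing were perfectly consistent across depths
#' the count is 1 (all homozygous) or 2; a single variant whose genotype or
#' phase differs in one depth raises it to 3. Fewer than 2 usable positions
#' gives a flagged `NA`.
#'
#' @param phased_by_depth list of phased callsets (each with `hapA`, `hapB`
#'   and a `missing` matrix).
#' @param region one row of a [sample_regions()] result (or any list with
#'   `start_idx`, `end_idx`).
#' @param individual individual (row) index.
#' @param respect_missing if `TRUE` (default), restrict to positions
#'   non-missing in every depth; if `FALSE`, use the retained phased alleles
#'   at masked cells too (the phased output of the imputation workflow
#'   carries a phase for every site, which is what haplotype-level analyses
#'   consume).
#' @return integer count, or `NA` if undefined.
#' @export
count_region_haplotypes <- function(phased_by_depth, region, individual,
                                    respect_missing = TRUE) {
  stopifnot(length(phased_by_depth) >= 1L)
  idx <- region$start_idx:region$end_idx
  usable <- rep(TRUE, length(idx))
  for (cs in phased_by_depth) {
    if (max(idx) > ncol(cs$hapA)) stopf("region exceeds the callset site range")
    miss <- if (respect_missing)
      (cs$missing %||% (is.na(cs$hapA) | is.na(cs$hapB)))[individual, idx]
    else rep(FALSE, length(idx))
    usable <- usable & !miss &
      !is.na(cs$hapA[individual, idx]) & !is.na(cs$hapB[individual, idx])
  }
  if (sum(usable) < 2L) return(NA_integer_)
  strs <- unlist(lapply(phased_by_depth, function(cs) {
    c(paste(cs$hapA[individual, idx][usable], collapse = ""),
      paste(cs$hapB[individual, idx][usable], collapse = ""))
  }))
  length(unique(strs))
}

#' Distinct-haplotype counts for all regions and individuals
#'
#' Vectorised version of [count_region_haplotypes()]: positions missing in
#' any depth for an individual are replaced by a common placeholder in all
#' of that individual's strings, which preserves equality relations over the
#' usable positions.
#'
#' @param phased_by_depth list of phased callsets.
#' @param regions a [sample_regions()] result.
#' @param respect_missing as in [count_region_haplotypes()].
#' @return integer matrix, regions x individuals (`NA` where fewer than 2
#'   usable positions).
#' @export
count_region_haplotypes_all <- function(phased_by_depth, regions,
                                        respect_missing = TRUE) {
  n_d <- length(phased_by_depth)
  N <- nrow(phased_by_depth[[1]]$hapA)
  miss_any <- Reduce(`|`, lapply(phased_by_depth, function(cs) {
    m <- if (respect_missing)
      cs$missing %||% matrix(FALSE, nrow(cs$hapA), ncol(cs$hapA))
    else matrix(FALSE, nrow(cs$hapA), ncol(cs$hapA))
    m | is.na(cs$hapA) | is.na(cs$hapB)
  }))
  counts <- matrix(NA_integer_, nrow(regions), N)
  for (r in seq_len(nrow(regions))) {
    idx <- regions$start_idx[r]:regions$end_idx[r]
    mr <- miss_any[, idx, drop = FALSE]
    usable_n <- ncol(mr) - rowSums(mr)
    strs <- matrix("", N, 2L * n_d)
    for (d in seq_len(n_d)) {
      for (h in 1:2) {
        hm <- (if (h == 1) phased_by_depth[[d]]$hapA else phased_by_depth[[d]]$hapB)[, idx, drop = FALSE]
        hm[mr] <- 9L # shared placeholder: contributes identically to all strings
        strs[, 2L * (d - 1L) + h] <- do.call(paste0, as.data.frame(hm))
      }
    }
    cnt <- apply(strs, 1L, function(s) length(unique(s)))
    cnt[usable_n < 2L] <- NA_integer_
    counts[r, ] <- cnt
  }
  counts
}

#' Paired Wilcoxon signed-rank test (exact for small n)
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (Wilcoxon convention; `zero_method = "pratt"` keeps them in the
#' ranking). Ties receive average ranks. For 30 or fewer non-zero pairs the
#' exact conditional distribution of the statistic is computed by dynamic
#' programming over the realised ranks; beyond that a normal approximation
#' with tie correction and continuity correction is used. All differences
#' zero gives p = 1 by convention.
#'
#' @param x,y paired numeric vectors.
#' @param zero_method `"wilcox"` (drop zeros) or `"pratt"`.
#' @return list with `statistic` (W+, rank sum of positive differences),
#'   `p_value`, `n_used`.
#' @export
wilcoxon_signed_rank <- function(x, y, zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  d <- x - y
  d <- d[!is.na(d)]
  if (zero_method == "wilcox") d <- d[d != 0]
  n <- length(d)
  if (n == 0L || all(d == 0)) return(list(statistic = 0, p_value = 1, n_used = n))
  r <- rank(abs(d))
  if (zero_method == "pratt") {
    keep <- d != 0
    r <- r[keep]; d <- d[keep]
    n_eff <- length(d)
    if (n_eff == 0L) return(list(statistic = 0, p_value = 1, n_used = 0L))
  } else n_eff <- n
  W <- sum(r[d > 0])
  if (n_eff <= 30L) {
    # exact distribution over 2^n sign assignments via DP on doubled ranks
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1L); f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1L):(tot + 1L)] <- g[(ri + 1L):(tot + 1L)] + f[1L:(tot - ri + 1L)]
      f <- g
    }
    f <- f / sum(f)
    W2 <- as.integer(round(2 * W))
    p_lo <- sum(f[1L:(W2 + 1L)])
    p_hi <- sum(f[(W2 + 1L):(tot + 1L)])
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4 # tie-corrected: ties enter through the realised ranks
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = W, p_value = p, n_used = n_eff)
}

#' Regional depth-deviation test
#'
#' Paired two-sided Wilcoxon signed-rank test on per-individual (mean region
#' depth, mean chromosome depth) pairs, asking whether the region's coverage
#' deviates from the chromosome average consistently across individuals.
#'
#' @param pileup a [simulate_pileup()] result.
#' @param region one row of a [sample_regions()] result.
#' @param zero_method passed to [wilcoxon_signed_rank()].
#' @return p-value.
#' @export
region_depth_wilcoxon <- function(pileup, region, zero_method = "wilcox") {
  depth <- pileup$ref_count + pileup$alt_count
  if (nrow(depth) < 6L)
    stopf("signed-rank depth test needs at least 6 individuals")
  idx <- region$start_idx:region$end_idx
  reg_mean <- rowMeans(depth[, idx, drop = FALSE])
  chr_mean <- rowMeans(depth)
  wilcoxon_signed_rank(reg_mean, chr_mean, zero_method)$p_value
}

#' Windowed depth/discordance/XP-EHH metrics
#'
#' Computes, per fixed-bp window and per depth dataset: mean sequencing
#' depth, genotype discordance against the top-depth pre-imputation calls,
#' haplotype A and B discordance against the top-depth post-imputation
#' haplotypes, and the median XP-EHH Z-score. Windows whose mean depth falls
#' in the extreme tails of that dataset's local depth distribution
#' (outside `trim_quantiles`) are marked dropped, reducing the influence of
#' stochastic coverage extremes.
#'
#' @param callsets_by_depth named list of masked `ImputedCallset`s.
#' @param ref_calls genotype matrix of top-depth pre-imputation calls.
#' @param ref_phased top-depth post-imputation callset.
#' @param pileups_by_depth named list of `ReadPileup`s (same names).
#' @param xpehh_by_depth named list of `XPEHHResult`s (same names).
#' @param positions site positions in bp.
#' @param window_bp window width (default 1 Mb).
#' @param trim_quantiles lower/upper quantiles of window mean depth to keep.
#' @return data.frame keyed by `depth` x `window` with the metrics and a
#'   `kept` flag.
#' @export
window_metrics <- function(callsets_by_depth, ref_calls, ref_phased,
                           pileups_by_depth, xpehh_by_depth, positions,
                           window_bp = 1e6, trim_quantiles = c(0.01, 0.99)) {
  win <- (positions - 1) %/% window_bp
  wins <- sort(unique(win))
  out <- list()
  for (dn in names(callsets_by_depth)) {
    cs <- callsets_by_depth[[dn]]
    pu <- pileups_by_depth[[dn]]
    xp <- xpehh_by_depth[[dn]]
    depth_mat <- pu$ref_count + pu$alt_count
    g <- hard_calls(cs)
    rows <- lapply(wins, function(w) {
      idx <- which(win == w)
      gd <- tryCatch(genotype_discordance(g[, idx, drop = FALSE],
                                          ref_calls[, idx, drop = FALSE])$discordance,
                     error = function(e) NA_real_)
      sub <- function(x) list(hapA = x$hapA[, idx, drop = FALSE],
                              hapB = x$hapB[, idx, drop = FALSE],
                              missing = (x$missing %||% matrix(FALSE, nrow(x$hapA), ncol(x$hapA)))[, idx, drop = FALSE])
      ha <- haplotype_discordance(sub(cs), sub(ref_phased), "A")$discordance
      hb <- haplotype_discordance(sub(cs), sub(ref_phased), "B")$discordance
      zm <- if (!is.null(xp)) median(xp$z[xp$site %in% idx], na.rm = TRUE) else NA_real_
      data.frame(depth = dn, window = w, start_bp = w * window_bp + 1,
                 mean_depth = mean(depth_mat[, idx]),
                 geno_disc = gd, hapA_disc = ha, hapB_disc = hb,
                 median_z = zm, n_sites = length(idx))
    })
    tab <- do.call(rbind, rows)
    qs <- quantile(tab$mean_depth, trim_quantiles, na.rm = TRUE)
    tab$kept <- tab$mean_depth >= qs[1] & tab$mean_depth <= qs[2]
    out[[dn]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ordinary least squares with named covariates
#'
#' Thin wrapper around [stats::lm()] that expands categorical covariates to
#' treatment contrasts against their first level, reports a tidy coefficient
#' table, and fails loudly on rank deficiency (naming the offending column).
#'
#' @param y response vector.
#' @param X data.frame of covariates (numeric or factor/character).
#' @return data.frame with `term`, `estimate`, `se`, `t`, `p`; the model
#'   r-squared is attached as attribute `r.squared`.
#' @export
ols_regress <- function(y, X) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stopf("response and design sizes differ")
  if (nrow(X) <= ncol(X) + 1L) stopf("need more rows than coefficients")
  dat <- cbind(.y = y, X)
  fit <- lm(.y ~ ., data = dat)
  mm <- model.matrix(fit)
  if (qr(mm)$rank < ncol(mm)) {
    alias <- stats::alias(fit)$Complete
    stopf("design is rank deficient (offending column: %s)",
          paste(rownames(alias), collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  out <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    t = co[, 3], p = co[, 4], row.names = NULL)
  attr(out, "r.squared") <- sm$r.squared
  out
}

#' Cross-depth correlation suite
#'
#' Pairwise-complete Pearson correlation of each depth's per-site score
#' vector against the reference depth's vector, with the biplot-ready pairs
#' retained. Depths with fewer than 3 complete pairs are flagged `NA`.
#'
#' @param vec_by_depth named list of equal-length score vectors.
#' @param reference_depth name of the reference entry.
#' @return list with `summary` (data.frame `depth`, `r`, `r2`, `n`) and
#'   `pairs` (data.frame `depth`, `x`, `y`).
#' @export
correlation_suite <- function(vec_by_depth, reference_depth) {
  if (!reference_depth %in% names(vec_by_depth))
    stopf("reference depth '%s' not in the input", reference_depth)
  ref <- vec_by_depth[[reference_depth]]
  pairs <- list(); rows <- list()
  for (dn in names(vec_by_depth)) {
    v <- vec_by_depth[[dn]]
    ok <- !is.na(v) & !is.na(ref)
    n <- sum(ok)
    r <- if (n >= 3L && stats::sd(v[ok]) > 0 && stats::sd(ref[ok]) > 0)
      cor(v[ok], ref[ok]) else NA_real_
    rows[[dn]] <- data.frame(depth = dn, r = r, r2 = r^2, n = n)
    pairs[[dn]] <- data.frame(depth = dn, x = ref[ok], y = v[ok])
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))))
}
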