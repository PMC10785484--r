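# Extended haplotype homozygosity statistics: EHH curves around a core site,
# their trapezoidal integral over physical distance (iHH), and the
# cross-population log-ratio XP-EHH with genome-wide Z-standardisation.
# Physical distance (bp) is used throughout; no genetic map is assumed.

# homozygosity of the current haplotype partition: sum_h C(n_h,2) / C(n,2)
partition_hh <- function(group_ids, n) {
  tab <- tabulate(group_ids)
  sum(tab * (tab - 1)) / (n * (n - 1))
}

#' Extended haplotype homozygosity curve from a core site
#'
#' Walking outwards from the core, haplotypes are partitioned by identity
#' over all spanned alleles (the core site included once the span is
#' non-empty); EHH at each extension is the probability that two randomly
#' drawn haplotypes are identical over the span. By convention EHH = 1 at a
#' span of zero sites. The curve stops at the first EHH below `ehh_cutoff`
#' (that point is retained for interpolation) or at the chromosome end.
#'
#' @param haps n x M 0/1 haplotype matrix.
#' @param core core site index.
#' @param direction `"left"` or `"right"`.
#' @param positions site positions in bp.
#' @param ehh_cutoff truncation threshold (default 0.05).
#' @return data.frame with `site`, `dist_bp`, `ehh`; first row is the core
#'   with `dist_bp = 0`, `ehh = 1`.
#' @export
ehh_curve <- function(haps, core, direction = c("right", "left"), positions,
                      ehh_cutoff = 0.05) {
  direction <- match.arg(direction)
  n <- nrow(haps)
  if (n < 2L) stopf("EHH needs at least 2 haplotypes")
  M <- ncol(haps)
  step <- if (direction == "right") 1L else -1L
  sites <- core
  dists <- 0
  ehhs <- 1
  g <- rep(1L, n)
  m <- core
  first <- TRUE
  repeat {
    if (first) { m2 <- core; first <- FALSE } else {
      m2 <- m + step
      if (m2 < 1L || m2 > M) break
      m <- m2
    }
    key <- g * 2L + haps[, m2]
    g <- match(key, unique(key))
    e <- partition_hh(g, n)
    sites <- c(sites, m2)
    dists <- c(dists, abs(positions[m2] - positions[core]))
    ehhs <- c(ehhs, e)
    if (e < ehh_cutoff) break
  }
  data.frame(site = sites, dist_bp = dists, ehh = ehhs)
}

#' Integrated EHH for one curve
#'
#' Trapezoidal integral of EHH against physical distance. If the curve ends
#' below `ehh_cutoff`, the final segment is linearly interpolated to the
#' exact cutoff crossing and integrated up to it (set
#' `interpolate = FALSE` to truncate at the last point at or above the
#' cutoff instead).
#'
#' @param curve data.frame from [ehh_curve()] (`dist_bp`, `ehh`).
#' @param ehh_cutoff the truncation threshold the curve was built with.
#' @param interpolate interpolate to the cutoff crossing (default `TRUE`).
#' @return non-negative scalar in bp * EHH units; `NA` for an empty curve.
#' @export
ihh <- function(curve, ehh_cutoff = 0.05, interpolate = TRUE) {
  d <- curve$dist_bp; e <- curve$ehh
  if (length(d) == 0L) return(NA_real_)
  if (length(d) == 1L) return(0)
  k <- length(d)
  if (e[k] < ehh_cutoff) {
    if (interpolate) {
      # replace the last point by the cutoff crossing
      frac <- (e[k - 1] - ehh_cutoff) / (e[k - 1] - e[k])
      d[k] <- d[k - 1] + frac * (d[k] - d[k - 1])
      e[k] <- ehh_cutoff
    } else {
      d <- d[-k]; e <- e[-k]
      if (length(d) < 2L) return(0)
    }
  }
  sum(diff(d) * (head(e, -1) + e[-1]) / 2)
}

# both-sided iHH at a core; a core on the chromosome edge contributes a
# one-sided integral (flagged, not dropped)
ihh_at_core <- function(haps, core, positions, ehh_cutoff = 0.05,
                        interpolate = TRUE) {
  left <- ehh_curve(haps, core, "left", positions, ehh_cutoff)
  right <- ehh_curve(haps, core, "right", positions, ehh_cutoff)
  il <- ihh(left, ehh_cutoff, interpolate)
  ir <- ihh(right, ehh_cutoff, interpolate)
  list(ihh = il + ir, one_sided = core == 1L || core == ncol(haps))
}

#' Cross-population XP-EHH scan
#'
#' For every core site with pooled MAF at or above `maf_cutoff`, computes
#' the integrated EHH in populations A and B and the raw statistic
#' `ln(iHH_A / iHH_B)`, then standardises raw scores genome-wide to
#' Z-scores. Haplotype fixation (selection) in population B inflates
#' `iHH_B` and drives the statistic negative. Cores with an undefined or
#' zero iHH on either side are excluded from standardisation.
#'
#' @param hapsA,hapsB haplotype matrices (rows = haplotypes) sharing the
#'   site list.
#' @param positions site positions in bp.
#' @param maf_cutoff pooled minor-allele-frequency cutoff (default 0.05).
#' @param ehh_cutoff EHH truncation threshold (default 0.05).
#' @param interpolate interpolate iHH to the cutoff crossing.
#' @return An object of class `XPEHHResult`: data.frame with `site`, `pos`,
#'   `ihh_a`, `ihh_b`, `raw`, `z`, `included`, `one_sided`.
#' @export
xpehh_scan <- function(hapsA, hapsB, positions, maf_cutoff = 0.05,
                       ehh_cutoff = 0.05, interpolate = TRUE) {
  if (nrow(hapsA) < 2L || nrow(hapsB) < 2L)
    stopf("both populations need at least 2 haplotypes")
  if (ncol(hapsA) != ncol(hapsB) || ncol(hapsA) != length(positions))
    stopf("populations must share the site list")
  pooled_af <- colMeans(rbind(hapsA, hapsB))
  maf <- pmin(pooled_af, 1 - pooled_af)
  M <- ncol(hapsA)
  out <- data.frame(site = seq_len(M), pos = positions,
                    ihh_a = NA_real_, ihh_b = NA_real_, raw = NA_real_,
                    z = NA_real_, included = FALSE, one_sided = FALSE)
  cores <- which(maf >= maf_cutoff)
  if (length(cores)) {
    storage.mode(hapsA) <- "integer"; storage.mode(hapsB) <- "integer"
    ia <- .ihh_scan_cpp(hapsA, as.numeric(positions), cores - 1L,
                        ehh_cutoff, interpolate)
    ib <- .ihh_scan_cpp(hapsB, as.numeric(positions), cores - 1L,
                        ehh_cutoff, interpolate)
    out$ihh_a[cores] <- ia; out$ihh_b[cores] <- ib
    out$one_sided[cores] <- cores == 1L | cores == M
    ok <- is.finite(ia) & is.finite(ib) & ia > 0 & ib > 0
    out$raw[cores[ok]] <- log(ia[ok] / ib[ok])
    out$included[cores[ok]] <- TRUE
  }
  if (sum(out$included) >= 2L && stats::sd(out$raw[out$included]) > 0)
    out$z[out$included] <- standardize_scores(out$raw[out$included])
  class(out) <- c("XPEHHResult", class(out))
  out
}

#' Genome-wide Z-standardisation of raw XP-EHH scores
#'
#' `z = (raw - mean) / sd` over included sites, with the population
#' (n-denominator) standard deviation, so the returned scores have mean 0
#' and sd 1 exactly.
#'
#' @param raw numeric vector of raw statistics (length >= 2).
#' @return numeric vector of Z-scores.
#' @export
standardize_scores <- function(raw) {
  if (length(raw) < 2L) stopf("standardisation needs at least 2 scores")
  mu <- mean(raw)
  sdp <- sqrt(mean((raw - mu)^2))
  if (sdp == 0) stopf("raw scores have zero variance; Z-scores undefined")
  (raw - mu) / sdp
}

#' Significant XP-EHH Z-scores, partitioned by sign
#'
#' @param z numeric vector of Z-scores (or an `XPEHHResult`).
#' @param threshold absolute Z threshold (default 4).
#' @return list with `positive` and `negative` index vectors.
#' @export
significant_z <- function(z, threshold = 4) {
  if (inherits(z, "XPEHHResult")) z <- z$z
  list(positive = which(!is.na(z) & z > threshold),
       negative = which(!is.na(z) & z < -threshold))
}

# inject switch errors into one phased individual pair: at each switch point
# the tail of the two haplotypes is exchanged
inject_switch_errors <- function(hapA, hapB, rate, seed = 1L) {
  with_seed(seed, {
    N <- nrow(hapA); M <- ncol(hapA)
    for (i in seq_len(N)) {
      sw <- which(runif(M - 1L) < rate) + 1L
      for (s in sw) {
        tmp <- hapA[i, s:M]
        hapA[i, s:M] <- hapB[i, s:M]
        hapB[i, s:M] <- tmp
      }
    }
    list(hapA = hapA, hapB = hapB)
  })
}
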