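# Genotype- and haplotype-level agreement metrics against a designated truth
# callset. All rates exclude non-comparable cells (missing on either side,
# depth-failing, or truth-uncertain); undefined rates are flagged NA, never
# silently 0.

comparable_mask <- function(test, truth, depth = NULL, min_depth = 0L,
                            truth_gp = NULL, min_truth_certainty = 0.9999) {
  ok <- !is.na(test) & !is.na(truth)
  if (!is.null(depth)) ok <- ok & depth >= min_depth
  if (!is.null(truth_gp)) {
    maxgp <- pmax(truth_gp[, , 1], truth_gp[, , 2], truth_gp[, , 3])
    ok <- ok & maxgp >= min_truth_certainty
  }
  ok
}

#' Genotype discordance rate
#'
#' Fraction of comparable cells where test and truth genotypes differ.
#' Comparable cells are non-missing in both callsets, pass the per-cell
#' depth filter, and (when the truth carries posterior triplets) pass the
#' truth-certainty filter. For simulated truth without GPs the certainty
#' filter is a no-op.
#'
#' @param test,truth N x M genotype matrices (0/1/2, `NA` = missing).
#' @param depth optional N x M read-depth matrix for the test dataset.
#' @param min_depth minimum depth for a cell to be compared.
#' @param truth_gp optional N x M x 3 posterior array for the truth calls.
#' @param min_truth_certainty maximum-GP threshold for truth cells.
#' @return list with `discordance` and `n_compared`.
#' @export
genotype_discordance <- function(test, truth, depth = NULL, min_depth = 0L,
                                 truth_gp = NULL, min_truth_certainty = 0.9999) {
  if (!all(dim(test) == dim(truth))) stopf("test/truth shapes differ")
  ok <- comparable_mask(test, truth, depth, min_depth, truth_gp, min_truth_certainty)
  n <- sum(ok)
  if (n == 0L) stopf("no comparable cells for genotype discordance")
  list(discordance = sum(test[ok] != truth[ok]) / n, n_compared = n)
}

#' MAF-binned aggregate genotype r-squared
#'
#' Sites are assigned to bins by panel MAF (`min(af, 1 - af)`); within each
#' bin all (dosage, truth genotype) cell pairs are pooled and the squared
#' Pearson correlation reported. Bins with fewer than 2 pairs or without
#' variation in the truth are flagged undefined (`r2 = NA`), not 0.
#'
#' @param dosage N x M imputed dosages.
#' @param truth N x M truth genotypes (`NA` = missing).
#' @param panel_af per-site alternate-allele frequency of the imputation
#'   panel.
#' @param bins bin edges over (0, 0.5]; sites with MAF equal to an edge fall
#'   in the lower bin (left-open intervals).
#' @return data.frame with `bin`, `maf_lo`, `maf_hi`, `r2`, `n_pairs`,
#'   `defined`.
#' @export
aggregate_r2_by_maf <- function(dosage, truth, panel_af,
                                bins = c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5)) {
  if (bins[1] != 0 || bins[length(bins)] < 0.5)
    stopf("bins must cover (0, 0.5]")
  maf <- pmin(panel_af, 1 - panel_af)
  bin_id <- cut(maf, breaks = bins, include.lowest = FALSE)
  out <- data.frame(bin = levels(bin_id),
                    maf_lo = bins[-length(bins)], maf_hi = bins[-1],
                    r2 = NA_real_, n_pairs = 0L, defined = FALSE)
  for (b in seq_along(levels(bin_id))) {
    sites <- which(as.integer(bin_id) == b)
    if (!length(sites)) next
    d <- as.vector(dosage[, sites]); t <- as.vector(truth[, sites])
    keep <- !is.na(d) & !is.na(t)
    d <- d[keep]; t <- t[keep]
    out$n_pairs[b] <- length(d)
    if (length(d) >= 2 && length(unique(t)) >= 2 && stats::sd(d) > 0) {
      out$r2[b] <- cor(d, t)^2
      out$defined[b] <- TRUE
    }
  }
  out
}

#' Dosage r-squared (pooled and per site)
#'
#' Squared Pearson correlation between imputed dosage and truth genotype,
#' pooled over all comparable cells and per site across individuals. Sites
#' without variation on either side are flagged `NA`.
#'
#' @inheritParams aggregate_r2_by_maf
#' @return list with `pooled` and `per_site` (length-M vector).
#' @export
dosage_r2 <- function(dosage, truth) {
  keep <- !is.na(dosage) & !is.na(truth)
  pooled <- if (sum(keep) >= 2 && stats::sd(truth[keep]) > 0 && stats::sd(dosage[keep]) > 0)
    cor(dosage[keep], truth[keep])^2 else NA_real_
  per_site <- vapply(seq_len(ncol(truth)), function(m) {
    k <- keep[, m]
    if (sum(k) >= 2 && stats::sd(truth[k, m]) > 0 && stats::sd(dosage[k, m]) > 0)
      cor(dosage[k, m], truth[k, m])^2 else NA_real_
  }, numeric(1))
  list(pooled = pooled, per_site = per_site)
}

#' Non-reference discordance rate
#'
#' With `e` the count of discordant comparable cells and `m_RA`, `m_AA` the
#' concordant heterozygous and homozygous-alternate counts,
#' `NRD = e / (e + m_RA + m_AA)`: concordant homozygous-reference cells are
#' excluded from the denominator, so the rate is not diluted by the
#' overwhelming hom-ref majority.
#'
#' @param test,truth N x M genotype matrices (`NA` = missing).
#' @return scalar rate in `[0, 1]`.
#' @export
nonref_discordance <- function(test, truth) {
  if (!all(dim(test) == dim(truth))) stopf("test/truth shapes differ")
  ok <- !is.na(test) & !is.na(truth)
  e <- sum(test[ok] != truth[ok])
  m_ra <- sum(test[ok] == truth[ok] & truth[ok] == 1L)
  m_aa <- sum(test[ok] == truth[ok] & truth[ok] == 2L)
  denom <- e + m_ra + m_aa
  if (denom == 0L)
    stopf("non-reference discordance undefined: no discordant or non-reference concordant cells")
  e / denom
}

#' Mismatch rates by truth genotype class
#'
#' Per truth class (RR, RA, AA): the fraction of comparable cells miscalled,
#' and each class's share of the total mismatch count. Empty classes are
#' flagged `NA`.
#'
#' @param test,truth N x M genotype matrices (`NA` = missing).
#' @return data.frame with `class`, `n`, `mismatch_rate`, `mismatch_share`.
#' @export
mismatch_by_class <- function(test, truth) {
  if (!all(dim(test) == dim(truth))) stopf("test/truth shapes differ")
  ok <- !is.na(test) & !is.na(truth)
  total_mis <- sum(test[ok] != truth[ok])
  out <- data.frame(class = c("RR", "RA", "AA"), n = NA_integer_,
                    mismatch_rate = NA_real_, mismatch_share = NA_real_)
  for (g in 0:2) {
    cls <- ok & truth == g
    n <- sum(cls)
    out$n[g + 1L] <- n
    if (n > 0L) {
      mis <- sum(test[cls] != g)
      out$mismatch_rate[g + 1L] <- mis / n
      out$mismatch_share[g + 1L] <- if (total_mis > 0L) mis / total_mis else 0
    }
  }
  out
}

#' Per-window haplotype discordance
#'
#' Compares same-labelled haplotypes of two phased callsets (splitting the
#' diploid into haplotype A and B files and comparing "equivalent"
#' haplotypes as emitted, with no optimal re-pairing, unless
#' `repair = TRUE`, which reports the minimum of the two label assignments
#' per individual). Positions missing in either callset for an individual
#' are excluded.
#'
#' @param test_phased,truth_phased `ImputedCallset`s, or lists with `hapA`,
#'   `hapB` and optional `missing`.
#' @param hap_index `"A"` or `"B"`.
#' @param windows integer vector of window ids per site, or `NULL` for one
#'   chromosome-wide window.
#' @param repair use the label assignment minimising discordance per
#'   individual (off by default; the literal split-and-compare is the
#'   reference behaviour).
#' @return data.frame with `window`, `discordance`, `n_compared`
#'   (`discordance = NA` flags windows without comparable sites).
#' @export
haplotype_discordance <- function(test_phased, truth_phased,
                                  hap_index = c("A", "B"), windows = NULL,
                                  repair = FALSE) {
  hap_index <- match.arg(hap_index)
  get <- function(x, nm) x[[nm]]
  te_A <- get(test_phased, "hapA"); te_B <- get(test_phased, "hapB")
  tr_A <- get(truth_phased, "hapA"); tr_B <- get(truth_phased, "hapB")
  miss_te <- test_phased$missing %||% (is.na(te_A) | is.na(te_B))
  miss_tr <- truth_phased$missing %||% (is.na(tr_A) | is.na(tr_B))
  ok <- !miss_te & !miss_tr & !is.na(te_A) & !is.na(tr_A)
  M <- ncol(te_A)
  windows <- windows %||% rep(1L, M)
  te <- if (hap_index == "A") te_A else te_B
  tr <- if (hap_index == "A") tr_A else tr_B
  mism <- (te != tr) & ok
  if (repair) {
    te2 <- if (hap_index == "A") te_B else te_A
    mism2 <- (te2 != tr) & ok
    # per individual, keep the orientation with fewer mismatches
    swap <- rowSums(mism2, na.rm = TRUE) < rowSums(mism, na.rm = TRUE)
    mism[swap, ] <- mism2[swap, ]
  }
  ids <- sort(unique(windows))
  n_cmp <- vapply(ids, function(w) sum(ok[, windows == w, drop = FALSE]), numeric(1))
  n_mis <- vapply(ids, function(w) sum(mism[, windows == w, drop = FALSE], na.rm = TRUE), numeric(1))
  data.frame(window = ids,
             discordance = ifelse(n_cmp > 0, n_mis / n_cmp, NA_real_),
             n_compared = as.integer(n_cmp))
}

#' Per-individual switch error rate
#'
#' Among consecutive pairs of truth-heterozygous sites (restricted to sites
#' where the test callset is also heterozygous and non-missing, since
#' relative phase is otherwise undefined), the fraction whose relative phase
#' in the test disagrees with the truth. Individuals with fewer than 2
#' usable heterozygous sites are flagged `NA`.
#'
#' @inheritParams haplotype_discordance
#' @return numeric vector, one rate per individual.
#' @export
switch_error_rate <- function(test_phased, truth_phased) {
  te_A <- test_phased$hapA; te_B <- test_phased$hapB
  tr_A <- truth_phased$hapA; tr_B <- truth_phased$hapB
  miss_te <- test_phased$missing %||% (is.na(te_A) | is.na(te_B))
  N <- nrow(te_A)
  vapply(seq_len(N), function(i) {
    usable <- which(tr_A[i, ] != tr_B[i, ] & te_A[i, ] != te_B[i, ] &
                    !miss_te[i, ] & !is.na(te_A[i, ]))
    if (length(usable) < 2L) return(NA_real_)
    agree <- te_A[i, usable] == tr_A[i, usable]
    mean(agree[-1] != agree[-length(agree)])
  }, numeric(1))
}
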