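#' Phased reference haplotype panel
#'
#' Container for a phased biallelic haplotype panel on a single chromosome.
#' Haplotypes come in diploid pairs (rows `2i-1`, `2i` belong to individual
#' `i`), each carrying a breed label. The per-site alternate-allele frequency
#' is the imputation prior and the source of MAF bins downstream.
#'
#' @param alleles integer matrix, K haplotypes x M sites, entries 0/1.
#' @param positions integer vector of 1-based bp coordinates, strictly
#'   increasing, single chromosome.
#' @param breed_label character vector of length K; identical within each
#'   diploid pair.
#' @param chrom chromosome name used in VCF output.
#' @param chrom_length_bp chromosome length in bp.
#'
#' @return An object of class `HaplotypePanel`: a list with elements
#'   `alleles`, `positions`, `panel_af` (column means of `alleles`),
#'   `breed_label`, `chrom`, `chrom_length_bp`.
#' @export
haplotype_panel <- function(alleles, positions, breed_label,
                            chrom = "chr1", chrom_length_bp = max(positions)) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  K <- nrow(alleles); M <- ncol(alleles)
  if (K %% 2L != 0L) stopf("haplotypes must come in diploid pairs (K even), got K = %d", K)
  if (length(positions) != M) stopf("positions length (%d) != site count (%d)", length(positions), M)
  if (M >= 2L && any(diff(positions) <= 0)) stopf("positions must be strictly increasing")
  if (!all(alleles %in% c(0L, 1L))) stopf("panel alleles must be 0/1")
  if (length(breed_label) != K) stopf("breed_label must have one entry per haplotype")
  structure(list(
    alleles = alleles,
    positions = as.integer(positions),
    panel_af = colMeans(alleles),
    breed_label = as.character(breed_label),
    chrom = chrom,
    chrom_length_bp = as.numeric(chrom_length_bp)
  ), class = "HaplotypePanel")
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat(sprintf("HaplotypePanel: %d haplotypes (%d diploids) x %d sites on %s (%.1f Mb)\n",
              nrow(x$alleles), nrow(x$alleles) / 2L, ncol(x$alleles),
              x$chrom, x$chrom_length_bp / 1e6))
  tab <- table(x$breed_label[seq(1, nrow(x$alleles), by = 2L)])
  cat("  diploids per breed:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  panel MAF: median %.3f, %d monomorphic sites\n",
              median(pmin(x$panel_af, 1 - x$panel_af)),
              sum(x$panel_af %in% c(0, 1))))
  invisible(x)
}

# mosaic of founder rows: switch between consecutive sites with probability
# 1 - exp(-rate * gap); on a switch the source row is redrawn uniformly
mosaic_row <- function(sources, start_row, gaps, rate_per_bp) {
  M <- ncol(sources)
  n_src <- nrow(sources)
  idx <- integer(M)
  idx[1L] <- start_row
  if (M > 1L) {
    sw <- runif(M - 1L) < switch_prob(rate_per_bp, gaps)
    cur <- start_row
    for (m in 2L:M) {
      if (sw[m - 1L]) cur <- sample.int(n_src, 1L)
      idx[m] <- cur
    }
  }
  sources[cbind(idx, seq_len(M))]
}

#' Simulate a multi-breed phased reference panel
#'
#' Builds breed structure with a founder-mosaic model: each breed has a
#' founder haplotype derived from a shared ancestral 0/1 string by independent
#' flips at rate `founder_div`; every panel haplotype is then a mosaic of its
#' breed founder and the other founders, with switch points occurring at rate
#' `recomb_switch_rate` per bp, plus private flips at `mutation_rate`. This
#' gives the haplotype sharing and allele-frequency structure that imputation
#' and haplotype statistics need, without a coalescent simulation.
#'
#' @param n_breeds number of breeds.
#' @param haps_per_breed haplotypes per breed; must be even (diploid pairs).
#' @param n_sites number of biallelic sites.
#' @param chrom_length_bp chromosome length; site positions are drawn
#'   uniformly without replacement from `1:chrom_length_bp` and sorted.
#' @param founder_div per-site probability that a breed founder differs from
#'   the ancestral string.
#' @param mutation_rate per-site private flip probability per haplotype.
#' @param recomb_switch_rate per-bp mosaic switch intensity.
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @param chrom chromosome name.
#'
#' @return A [haplotype_panel()].
#' @export
simulate_panel <- function(n_breeds, haps_per_breed, n_sites, chrom_length_bp,
                           founder_div = 0.15, mutation_rate = 0.002,
                           recomb_switch_rate = 2.5e-7, seed = 1L,
                           chrom = "chr1") {
  if (n_sites < 2L) stopf("n_sites must be >= 2")
  if (n_sites > chrom_length_bp) stopf("n_sites (%d) exceeds chrom_length_bp (%g)", n_sites, chrom_length_bp)
  if (haps_per_breed %% 2L != 0L) stopf("haps_per_breed must be even (diploid pairs)")
  assert_prob(founder_div, "founder_div")
  assert_prob(mutation_rate, "mutation_rate")
  if (recomb_switch_rate < 0) stopf("recomb_switch_rate must be >= 0")

  with_seed(seed, {
    positions <- sort(sample.int(chrom_length_bp, n_sites))
    gaps <- diff(positions)
    ancestral <- rbinom(n_sites, 1L, 0.5)
    founders <- matrix(0L, n_breeds, n_sites)
    for (b in seq_len(n_breeds)) {
      flip <- runif(n_sites) < founder_div
      founders[b, ] <- ifelse(flip, 1L - ancestral, ancestral)
    }
    K <- n_breeds * haps_per_breed
    alleles <- matrix(0L, K, n_sites)
    breed_label <- rep(sprintf("breed%d", seq_len(n_breeds)), each = haps_per_breed)
    for (h in seq_len(K)) {
      b <- (h - 1L) %/% haps_per_breed + 1L
      hap <- mosaic_row(founders, b, gaps, recomb_switch_rate)
      mut <- runif(n_sites) < mutation_rate
      alleles[h, ] <- ifelse(mut, 1L - hap, hap)
    }
    haplotype_panel(alleles, positions, breed_label, chrom, chrom_length_bp)
  })
}

#' Subset a reference panel, keeping diploid pairs together
#'
#' Emulates the construction of reduced imputation panels: a target-breed
#' enriched subset keeps the target-breed diploids and fills the remainder at
#' random, while a target-depleted subset keeps at most `target_cap` (default
#' 1) target diploids and caps every other breed at `breed_cap` diploids.
#' Panel allele frequencies are recomputed on the subset.
#'
#' @param panel a [haplotype_panel()].
#' @param target_breed breed label of the cohort's breed.
#' @param n_total_diploids diploids to retain.
#' @param include_target if `TRUE`, target-breed diploids are retained first
#'   (up to `target_cap`); if `FALSE` at most one target diploid is kept.
#' @param breed_cap maximum diploids per non-target breed (default unlimited
#'   when `include_target`, 2 otherwise).
#' @param target_cap maximum target-breed diploids.
#' @param seed integer seed for the random fill.
#'
#' @return A [haplotype_panel()] restricted to the selected diploids.
#' @export
subset_panel <- function(panel, target_breed, n_total_diploids,
                         include_target = TRUE,
                         breed_cap = if (include_target) Inf else 2L,
                         target_cap = if (include_target) Inf else 1L,
                         seed = 1L) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  K <- nrow(panel$alleles)
  n_dip <- K %/% 2L
  if (n_total_diploids > n_dip)
    stopf("requested %d diploids but only %d available", n_total_diploids, n_dip)
  dip_breed <- panel$breed_label[seq(1L, K, by = 2L)]
  is_target <- dip_breed == target_breed
  if (include_target && !any(is_target))
    stopf("target breed '%s' absent from the panel", target_breed)

  with_seed(seed, {
    target_ids <- which(is_target)
    n_keep_target <- min(length(target_ids), target_cap, n_total_diploids)
    keep <- if (n_keep_target > 0L) {
      if (n_keep_target < length(target_ids)) sort(sample(target_ids, n_keep_target)) else target_ids
    } else integer(0)
    # random fill from the other breeds subject to the per-breed cap
    pool <- setdiff(seq_len(n_dip), target_ids)
    pool <- sample(pool)
    counts <- integer(0)
    for (d in pool) {
      if (length(keep) >= n_total_diploids) break
      b <- dip_breed[d]
      cnt <- counts[b]
      if (is.na(cnt)) cnt <- 0L
      if (cnt < breed_cap) {
        keep <- c(keep, d)
        counts[b] <- cnt + 1L
      }
    }
    if (length(keep) < n_total_diploids)
      stopf("breed caps leave only %d of the requested %d diploids", length(keep), n_total_diploids)
    keep <- sort(keep)
    rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
    haplotype_panel(panel$alleles[rows, , drop = FALSE], panel$positions,
                    panel$breed_label[rows], panel$chrom, panel$chrom_length_bp)
  })
}
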