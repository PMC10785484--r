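#' Simulate a target cohort with a recessive causal locus
#'
#' Cohort truth haplotypes are mosaics of the target-breed haplotypes of the
#' reference panel (switch rate `mosaic_switch_rate` per bp) with private
#' flips at `private_allele_rate`; flipped alleles are recorded in
#' `private_mask` since they are, by construction, alleles the panel has
#' never seen at that haplotype background. A causal site is chosen among
#' sites with panel MAF inside `causal_maf_range`, and genotypes there are
#' overwritten so that exactly `n_cases` individuals are homozygous for the
#' alternate allele; the phenotype is fully penetrant recessive. To emulate
#' the haplotype homozygosity that selection for a recessive coat-colour
#' allele produces, case individuals carry two copies of a single donor panel
#' haplotype across a `sweep_bp` window centred on the causal site.
#'
#' @param panel a [haplotype_panel()]; the mosaic source is restricted to
#'   `target_breed` haplotypes.
#' @param n_individuals cohort size N.
#' @param n_cases number of affected (homozygous-alternate) individuals;
#'   `0 < n_cases < n_individuals`.
#' @param mosaic_switch_rate per-bp switch intensity of the truth mosaic.
#' @param private_allele_rate per-site flip probability per haplotype.
#' @param target_breed breed label the cohort belongs to.
#' @param sweep_bp width of the shared case haplotype around the causal site;
#'   0 disables the sweep (single-site overwrite only).
#' @param causal_maf_range admissible panel MAF window for the causal site.
#' @param seed integer seed.
#'
#' @return An object of class `CohortTruth`: list with `hapA`, `hapB`
#'   (N x M 0/1 matrices), `genotype` (hapA + hapB), `phenotype`, `sex`,
#'   `causal_site` (site index), `private_mask` (N x 2 x M logical),
#'   `cases`, `positions`, `chrom`, `sample_id`.
#' @export
simulate_cohort <- function(panel, n_individuals = 30L, n_cases = 6L,
                            mosaic_switch_rate = 2e-6,
                            private_allele_rate = 0.02,
                            target_breed = "breed1",
                            sweep_bp = 1e6,
                            causal_maf_range = c(0.15, 0.35),
                            seed = 1L) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  if (!(n_cases > 0L && n_cases < n_individuals))
    stopf("need 0 < n_cases (%d) < n_individuals (%d)", n_cases, n_individuals)
  assert_prob(private_allele_rate, "private_allele_rate")
  src <- panel$alleles[panel$breed_label == target_breed, , drop = FALSE]
  if (nrow(src) < 2L)
    stopf("panel has %d '%s' haplotypes; need at least 2", nrow(src), target_breed)
  M <- ncol(panel$alleles)
  pos <- panel$positions
  gaps <- diff(pos)
  maf <- pmin(panel$panel_af, 1 - panel$panel_af)
  eligible <- which(maf >= causal_maf_range[1] & maf <= causal_maf_range[2])
  if (length(eligible) == 0L)
    stopf("no site with panel MAF in [%.2f, %.2f] available for the causal locus",
          causal_maf_range[1], causal_maf_range[2])

  with_seed(seed, {
    N <- n_individuals
    hapA <- matrix(0L, N, M); hapB <- matrix(0L, N, M)
    maskA <- matrix(FALSE, N, M); maskB <- matrix(FALSE, N, M)
    for (i in seq_len(N)) {
      for (h in 1:2) {
        hap <- mosaic_row(src, sample.int(nrow(src), 1L), gaps, mosaic_switch_rate)
        flip <- runif(M) < private_allele_rate
        hap <- ifelse(flip, 1L - hap, hap)
        if (h == 1L) { hapA[i, ] <- hap; maskA[i, ] <- flip }
        else         { hapB[i, ] <- hap; maskB[i, ] <- flip }
      }
    }
    causal <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    # donor haplotype: a target-breed panel haplotype carrying the alternate
    # allele at the causal site (forced to carry it if none does)
    carriers <- which(src[, causal] == 1L)
    donor <- src[if (length(carriers)) carriers[1L] else 1L, ]
    donor[causal] <- 1L
    window <- which(pos >= pos[causal] - sweep_bp / 2 & pos <= pos[causal] + sweep_bp / 2)
    if (sweep_bp <= 0) window <- causal
    cases <- sort(sample.int(N, n_cases))
    for (i in cases) {
      hapA[i, window] <- donor[window]; maskA[i, window] <- FALSE
      hapB[i, window] <- donor[window]; maskB[i, window] <- FALSE
    }
    controls <- setdiff(seq_len(N), cases)
    homalt <- controls[hapA[controls, causal] + hapB[controls, causal] == 2L]
    if (length(homalt)) { # full penetrance: controls must not be homozygous-alt
      hapB[homalt, causal] <- 0L
      maskB[homalt, causal] <- FALSE
    }
    genotype <- hapA + hapB
    phenotype <- as.integer(genotype[, causal] == 2L)
    sex <- rbinom(N, 1L, 0.5)
    private_mask <- array(FALSE, dim = c(N, 2L, M))
    private_mask[, 1L, ] <- maskA
    private_mask[, 2L, ] <- maskB
    structure(list(
      hapA = hapA, hapB = hapB, genotype = genotype,
      phenotype = phenotype, sex = sex,
      causal_site = causal, cases = cases,
      private_mask = private_mask,
      positions = pos, chrom = panel$chrom,
      target_breed = target_breed,
      sample_id = sprintf("S%02d", seq_len(N))
    ), class = "CohortTruth")
  })
}

#' @export
print.CohortTruth <- function(x, ...) {
  cat(sprintf("CohortTruth: %d individuals x %d sites; %d cases (recessive, fully penetrant)\n",
              nrow(x$hapA), ncol(x$hapA), sum(x$phenotype)))
  cat(sprintf("  causal site index %d at %s:%d\n", x$causal_site, x$chrom,
              x$positions[x$causal_site]))
  invisible(x)
}
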