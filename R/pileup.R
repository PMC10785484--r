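#' Simulate per-site read pileups
#'
#' Depths are site-independent Poisson draws,
#' `d[i, m] ~ Poisson(lambda_target * region_profile[m] * indiv_profile[i])`,
#' and alternate read counts are `Binomial(d, q_g)` with
#' `q_g = (g/2) * (1 - epsilon) + (1 - g/2) * epsilon` for true genotype `g`.
#' Regional multipliers supply the only spatial depth structure (emulating
#' locally depressed coverage); there is no read-length correlation.
#'
#' @param truth a [simulate_cohort()] result.
#' @param lambda_target nominal mean depth (X).
#' @param epsilon per-base error probability.
#' @param region_profile per-site positive multiplier (default flat 1).
#' @param indiv_profile per-individual positive multiplier (default flat 1).
#' @param seed integer seed.
#'
#' @return An object of class `ReadPileup`: list with `ref_count`,
#'   `alt_count` (N x M integer), `epsilon`, `lambda_target`,
#'   `region_multiplier`, `individual_multiplier`, `positions`, `chrom`,
#'   `sample_id`.
#' @export
simulate_pileup <- function(truth, lambda_target, epsilon = 0.001,
                            region_profile = NULL, indiv_profile = NULL,
                            seed = 1L) {
  stopifnot(inherits(truth, "CohortTruth"))
  if (lambda_target <= 0) stopf("lambda_target must be positive")
  N <- nrow(truth$hapA); M <- ncol(truth$hapA)
  region_profile <- region_profile %||% rep(1, M)
  indiv_profile <- indiv_profile %||% rep(1, N)
  if (any(region_profile <= 0) || any(indiv_profile <= 0))
    stopf("depth profiles must be positive")
  if (length(region_profile) != M || length(indiv_profile) != N)
    stopf("profile lengths must match sites (M=%d) and individuals (N=%d)", M, N)

  with_seed(seed, {
    mu <- lambda_target * outer(indiv_profile, region_profile)
    d <- matrix(rpois(N * M, mu), N, M)
    g <- truth$genotype
    q <- (g / 2) * (1 - epsilon) + (1 - g / 2) * epsilon
    alt <- matrix(rbinom(N * M, d, q), N, M)
    structure(list(
      ref_count = d - alt, alt_count = alt,
      epsilon = epsilon, lambda_target = lambda_target,
      region_multiplier = region_profile,
      individual_multiplier = indiv_profile,
      positions = truth$positions, chrom = truth$chrom,
      sample_id = truth$sample_id
    ), class = "ReadPileup")
  })
}

#' @export
print.ReadPileup <- function(x, ...) {
  d <- x$ref_count + x$alt_count
  cat(sprintf("ReadPileup: %d individuals x %d sites, nominal %.1fX (realised mean %.2fX)\n",
              nrow(d), ncol(d), x$lambda_target, mean(d)))
  invisible(x)
}

#' Binomial read thinning
#'
#' Keeps each read independently with probability `retain_fraction`
#' (reference and alternate counts thinned separately), emulating in-silico
#' down-sampling of alignments. The error rate is unchanged.
#'
#' @param pileup a [simulate_pileup()] result.
#' @param retain_fraction probability in `[0, 1]` of keeping each read.
#' @param seed integer seed.
#' @return A `ReadPileup` with thinned counts and
#'   `lambda_target * retain_fraction` as the new nominal depth.
#' @export
thin_pileup <- function(pileup, retain_fraction, seed = 1L) {
  stopifnot(inherits(pileup, "ReadPileup"))
  assert_prob(retain_fraction, "retain_fraction")
  with_seed(seed, {
    out <- pileup
    dm <- dim(pileup$ref_count)
    out$ref_count <- matrix(rbinom(length(pileup$ref_count), pileup$ref_count,
                                   retain_fraction), dm[1], dm[2])
    out$alt_count <- matrix(rbinom(length(pileup$alt_count), pileup$alt_count,
                                   retain_fraction), dm[1], dm[2])
    out$lambda_target <- pileup$lambda_target * retain_fraction
    out
  })
}

#' Regional depth-depression profile
#'
#' Builds a per-site depth multiplier that is 1 everywhere except inside the
#' given segments, then rescales to mean 1 so the nominal depth of
#' [simulate_pileup()] remains the realised chromosome-wide mean.
#'
#' @param positions site positions in bp.
#' @param segments data.frame with columns `start`, `end` (bp, inclusive) and
#'   `multiplier`; `NULL` gives a flat profile.
#' @param normalise rescale the profile to mean 1 (default `TRUE`).
#' @return numeric vector of per-site multipliers.
#' @export
make_region_profile <- function(positions, segments = NULL, normalise = TRUE) {
  prof <- rep(1, length(positions))
  if (!is.null(segments) && nrow(segments) > 0) {
    for (r in seq_len(nrow(segments))) {
      inside <- positions >= segments$start[r] & positions <= segments$end[r]
      prof[inside] <- segments$multiplier[r]
    }
  }
  if (normalise) prof <- prof / mean(prof)
  prof
}
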