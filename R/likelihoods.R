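#' Genotype likelihoods from read pileups
#'
#' Per cell, the likelihood of genotype `g` given `a` reference and `b`
#' alternate reads under a symmetric single-parameter error model is
#' `L(g) proportional to (1 - q_g)^a * q_g^b` with
#' `q_g = (g/2) * (1 - epsilon) + (1 - g/2) * epsilon`. Triplets are
#' normalised to sum to 1; the computation runs in log space so deep pileups
#' do not underflow. Zero-depth cells are exactly uniform.
#'
#' @param pileup a [simulate_pileup()] result; `epsilon` must lie in (0, 0.5).
#' @return An object of class `GenotypeLikelihoods`: list with `gl`
#'   (N x M x 3 array, genotype order RR/RA/AA), `depth` (N x M), `epsilon`,
#'   `positions`, `chrom`, `sample_id`.
#' @export
pileup_to_gl <- function(pileup) {
  stopifnot(inherits(pileup, "ReadPileup"))
  eps <- pileup$epsilon
  if (!(eps > 0 && eps < 0.5)) stopf("epsilon must lie in (0, 0.5), got %g", eps)
  a <- pileup$ref_count; b <- pileup$alt_count
  if (any(a < 0) || any(b < 0)) stopf("negative read counts")
  N <- nrow(a); M <- ncol(a)
  q <- c(eps, 0.5, 1 - eps)
  ll <- array(0, dim = c(N, M, 3L))
  for (g in 1:3) ll[, , g] <- a * log1p(-q[g]) + b * log(q[g])
  mx <- pmax(ll[, , 1], ll[, , 2], ll[, , 3])
  for (g in 1:3) ll[, , g] <- exp(ll[, , g] - mx)
  tot <- ll[, , 1] + ll[, , 2] + ll[, , 3]
  for (g in 1:3) ll[, , g] <- ll[, , g] / tot
  structure(list(
    gl = ll, depth = a + b, epsilon = eps,
    positions = pileup$positions, chrom = pileup$chrom,
    sample_id = pileup$sample_id
  ), class = "GenotypeLikelihoods")
}

#' @export
print.GenotypeLikelihoods <- function(x, ...) {
  cat(sprintf("GenotypeLikelihoods: %d individuals x %d sites, epsilon = %g, mean depth %.2fX\n",
              nrow(x$depth), ncol(x$depth), x$epsilon, mean(x$depth)))
  invisible(x)
}

#' Naive pre-imputation genotype calls
#'
#' Per-cell argmax of the genotype-likelihood triplet, with cells set to
#' missing (`NA`) when the depth is below `min_depth` or the triplet is
#' uniform (no read information). Ties break toward the lower genotype index
#' (reference-first), mirroring common caller behaviour; this biases only
#' zero-information cells, which are masked anyway.
#'
#' @param gl a [pileup_to_gl()] result.
#' @param min_depth minimum read depth for a call.
#' @return N x M integer matrix with values 0/1/2 or `NA`.
#' @export
naive_calls <- function(gl, min_depth = 1L) {
  stopifnot(inherits(gl, "GenotypeLikelihoods"))
  if (min_depth < 0) stopf("min_depth must be >= 0")
  N <- nrow(gl$depth); M <- ncol(gl$depth)
  flat <- matrix(gl$gl, N * M, 3L)
  call <- max.col(flat, ties.method = "first") - 1L
  uniform <- abs(flat[, 1] - flat[, 2]) < 1e-12 & abs(flat[, 2] - flat[, 3]) < 1e-12
  call[uniform] <- NA_integer_
  call <- matrix(call, N, M)
  call[gl$depth < min_depth] <- NA_integer_
  call
}
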