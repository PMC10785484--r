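#' Li-Stephens copying-model parameters
#'
#' The diploid imputation HMM copies each target haplotype from the reference
#' panel with per-site switch probability
#' `rho_m = 1 - exp(-recomb_rate * ne_scale * delta_bp)` and per-site copying
#' error `mismatch_theta`. When `mismatch_theta` is `NULL` it is set at use
#' time from the panel size K with the Watterson-style rescaling
#' `lambda = 1 / sum(1/(1:(K-1)))`, `theta = lambda / (2 * (lambda + K))`.
#'
#' @param recomb_rate per-bp switch intensity of the copying process.
#' @param mismatch_theta per-site copying-error probability in (0, 0.5), or
#'   `NULL` for the Watterson default.
#' @param ne_scale dimensionless scalar multiplying the recombination
#'   distance (an effective-population-size style knob).
#' @return An object of class `LSParams`.
#' @export
ls_params <- function(recomb_rate = 1e-8, mismatch_theta = NULL, ne_scale = 50) {
  if (recomb_rate <= 0 || ne_scale <= 0) stopf("recomb_rate and ne_scale must be positive")
  if (!is.null(mismatch_theta) && !(mismatch_theta > 0 && mismatch_theta < 0.5))
    stopf("mismatch_theta must lie in (0, 0.5)")
  structure(list(recomb_rate = recomb_rate, mismatch_theta = mismatch_theta,
                 ne_scale = ne_scale), class = "LSParams")
}

resolve_theta <- function(params, K) {
  if (!is.null(params$mismatch_theta)) return(params$mismatch_theta)
  lambda <- 1 / sum(1 / seq_len(max(K - 1L, 1L)))
  max(min(lambda / (2 * (lambda + K)), 0.49), 1e-6)
}

ls_rho <- function(positions, params) {
  c(0, 1 - exp(-params$recomb_rate * params$ne_scale * diff(positions)))
}

#' Diploid Li-Stephens posteriors for one individual
#'
#' Exact forward-backward over ordered reference-haplotype pairs (j, k) in
#' `panel^2`. Transitions are the independent per-haplotype Li-Stephens
#' kernel; the emission at site m is
#' `sum_g GL[m, g] * P(g | alleles of j, k copied with error mismatch_theta)`.
#' Arithmetic is rescaled per site, so there is no underflow at thousands of
#' sites. The per-site genotype posterior is the marginal over states.
#'
#' @param gl_row M x 3 matrix of normalised genotype likelihoods for one
#'   individual.
#' @param panel a [haplotype_panel()]; K haplotypes (exact K^2-state HMM, so
#'   K is capped at 512).
#' @param params an [ls_params()].
#' @param return_states also return the M x K^2 ordered-pair state
#'   posteriors (row-major in k within j).
#' @param max_workspace workspace cap in bytes; exceeding it is an error that
#'   instructs chunking.
#' @return list with `gp` (M x 3 genotype posteriors), `or10`/`or01`
#'   (posterior of ordered heterozygote orientations), `loglik`, and
#'   optionally `states`.
#' @export
ls_posteriors <- function(gl_row, panel, params = ls_params(),
                          return_states = FALSE, max_workspace = 2e9) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  K <- nrow(panel$alleles)
  if (K > 512L) stopf("exact diploid HMM supports K <= 512 haplotypes, got %d", K)
  gl_row <- as.matrix(gl_row)
  if (ncol(gl_row) != 3L || nrow(gl_row) != ncol(panel$alleles))
    stopf("gl_row must be M x 3 with M matching the panel")
  theta <- resolve_theta(params, K)
  rho <- ls_rho(panel$positions, params)
  .ls_forward_backward_cpp(gl_row, panel$alleles, rho, theta,
                           return_states, max_workspace)
}

ls_viterbi <- function(gl_row, panel, params = ls_params(), max_workspace = 2e9) {
  theta <- resolve_theta(params, nrow(panel$alleles))
  rho <- ls_rho(panel$positions, params)
  .ls_viterbi_cpp(as.matrix(gl_row), panel$alleles, rho, theta, max_workspace)
}

# phased alleles for one individual on one chunk: genotype from argmax GP,
# heterozygote orientation from the Viterbi ordered-pair path (posterior
# orientation as fall-back when the Viterbi state copies equal alleles)
phase_one <- function(fb, vit, panel) {
  gp <- fb$gp
  M <- nrow(gp)
  g <- max.col(gp, ties.method = "first") - 1L
  aj <- panel$alleles[cbind(vit$path_j + 1L, seq_len(M))]
  ak <- panel$alleles[cbind(vit$path_k + 1L, seq_len(M))]
  hapA <- as.integer(g >= 1L)
  hapB <- as.integer(g == 2L)
  het <- which(g == 1L)
  for (m in het) {
    ori <- if (aj[m] != ak[m]) aj[m] == 1L else fb$or10[m] >= fb$or01[m]
    hapA[m] <- as.integer(ori)
    hapB[m] <- as.integer(!ori)
  }
  list(hapA = hapA, hapB = hapB)
}

chunk_plan <- function(positions, chunk_bp, overlap_bp) {
  lo <- min(positions); hi <- max(positions)
  n_chunks <- max(1L, ceiling((hi - lo + 1) / chunk_bp))
  core_starts <- lo + (seq_len(n_chunks) - 1L) * chunk_bp
  core_ends <- pmin(core_starts + chunk_bp - 1, hi)
  lapply(seq_len(n_chunks), function(ci) {
    ext_lo <- core_starts[ci] - overlap_bp
    ext_hi <- core_ends[ci] + overlap_bp
    sites <- which(positions >= ext_lo & positions <= ext_hi)
    own <- which(positions >= core_starts[ci] & positions <= core_ends[ci])
    list(sites = sites, own = own)
  })
}

#' Impute and phase a cohort against a reference panel
#'
#' Runs the exact diploid Li-Stephens HMM per individual in chunks of
#' `chunk_bp` (with `overlap_bp` flanks), assigning each site's posteriors to
#' the chunk that owns it. Phased alleles come from the Viterbi ordered-pair
#' path (deterministic); chunk ligation preserves within-individual haplotype
#' labelling by matching the two possible label orientations over the
#' overlap. Posterior triplets (GP), dosages (DS) and per-site INFO scores
#' are filled; nothing is masked yet (see [mask_low_gp()]).
#'
#' @param gl a [pileup_to_gl()] result; site list must equal the panel's.
#' @param panel a [haplotype_panel()].
#' @param params an [ls_params()].
#' @param chunk_bp chunk width in bp (default 20 Mb).
#' @param overlap_bp chunk overlap flank in bp.
#' @param max_workspace per-chunk HMM workspace cap in bytes.
#' @return An object of class `ImputedCallset`: list with `hapA`, `hapB`
#'   (N x M), `gp` (N x M x 3), `dosage`, `info`, `missing` (all `FALSE`),
#'   `panel_af_used`, `positions`, `chrom`, `sample_id`, `gp_threshold`
#'   (`NA` until masked).
#' @export
impute_phase <- function(gl, panel, params = ls_params(), chunk_bp = 20e6,
                         overlap_bp = 250e3, max_workspace = 2e9) {
  stopifnot(inherits(gl, "GenotypeLikelihoods"), inherits(panel, "HaplotypePanel"))
  if (length(gl$positions) != length(panel$positions) ||
      any(gl$positions != panel$positions)) {
    bad <- if (length(gl$positions) != length(panel$positions)) NA_integer_ else
      gl$positions[which(gl$positions != panel$positions)[1]]
    stopf("GL and panel site lists differ (first offending position: %s)",
          ifelse(is.na(bad), "different lengths", bad))
  }
  N <- dim(gl$gl)[1]; M <- dim(gl$gl)[2]
  chunks <- chunk_plan(panel$positions, chunk_bp, overlap_bp)
  hapA <- matrix(NA_integer_, N, M); hapB <- matrix(NA_integer_, N, M)
  gp <- array(NA_real_, dim = c(N, M, 3L))
  for (i in seq_len(N)) {
    gl_i <- matrix(gl$gl[i, , ], M, 3L)
    prevA <- NULL; prevB <- NULL
    for (ci in seq_along(chunks)) {
      ch <- chunks[[ci]]
      if (length(ch$own) == 0L) next
      sub_panel <- haplotype_panel(panel$alleles[, ch$sites, drop = FALSE],
                                   panel$positions[ch$sites],
                                   panel$breed_label, panel$chrom,
                                   panel$chrom_length_bp)
      fb <- ls_posteriors(gl_i[ch$sites, , drop = FALSE], sub_panel, params,
                          FALSE, max_workspace)
      vit <- ls_viterbi(gl_i[ch$sites, , drop = FALSE], sub_panel, params,
                        max_workspace)
      ph <- phase_one(fb, vit, sub_panel)
      if (!is.null(prevA)) {
        # ligate: choose the label orientation that best matches the
        # already-assembled haplotypes over the shared sites
        shared <- intersect(ch$sites, which(!is.na(prevA)))
        if (length(shared)) {
          loc <- match(shared, ch$sites)
          same <- sum(ph$hapA[loc] == prevA[shared]) +
                  sum(ph$hapB[loc] == prevB[shared])
          flip <- sum(ph$hapB[loc] == prevA[shared]) +
                  sum(ph$hapA[loc] == prevB[shared])
          if (flip > same) ph <- list(hapA = ph$hapB, hapB = ph$hapA)
        }
      }
      own_loc <- match(ch$own, ch$sites)
      hapA[i, ch$own] <- ph$hapA[own_loc]
      hapB[i, ch$own] <- ph$hapB[own_loc]
      gp[i, ch$own, ] <- fb$gp[own_loc, , drop = FALSE]
      prevA <- rep(NA_integer_, M); prevA[ch$sites] <- ph$hapA
      prevB <- rep(NA_integer_, M); prevB[ch$sites] <- ph$hapB
    }
  }
  dosage <- gp[, , 2] + 2 * gp[, , 3]
  if (N == 1L) dosage <- matrix(dosage, 1L, M)
  info <- vapply(seq_len(M), function(m)
    info_score(matrix(gp[, m, ], N, 3L)), numeric(1))
  structure(list(
    hapA = hapA, hapB = hapB, gp = gp, dosage = dosage, info = info,
    missing = matrix(FALSE, N, M), panel_af_used = panel$panel_af,
    positions = gl$positions, chrom = gl$chrom, sample_id = gl$sample_id,
    gp_threshold = NA_real_
  ), class = "ImputedCallset")
}

#' @export
print.ImputedCallset <- function(x, ...) {
  cat(sprintf("ImputedCallset: %d individuals x %d sites; median INFO %.3f; %.1f%% masked\n",
              nrow(x$hapA), ncol(x$hapA), median(x$info),
              100 * mean(x$missing)))
  invisible(x)
}

#' IMPUTE-style INFO score for one site
#'
#' With posterior triplets `gp_i` per individual, expected dosage
#' `e_i = gp_i[2] + 2 gp_i[3]`, second moment `f_i = gp_i[2] + 4 gp_i[3]`
#' and `theta_hat = sum(e_i) / (2N)`, the score is
#' `1 - sum(f_i - e_i^2) / (2 N theta_hat (1 - theta_hat))`, an estimate of
#' imputation certainty on a 0-1 scale. Defined as 1 when `theta_hat` is 0
#' or 1; clamped to `[0, 1]`.
#'
#' @param gp N x 3 matrix of posterior triplets at one site.
#' @return scalar in `[0, 1]`.
#' @export
info_score <- function(gp) {
  gp <- as.matrix(gp)
  if (nrow(gp) < 1L) stopf("info_score needs at least one individual")
  e <- gp[, 2] + 2 * gp[, 3]
  f <- gp[, 2] + 4 * gp[, 3]
  n2 <- 2 * nrow(gp)
  theta <- sum(e) / n2
  if (theta <= 0 || theta >= 1) return(1)
  info <- 1 - sum(f - e^2) / (n2 * theta * (1 - theta))
  min(max(info, 0), 1)
}

#' Mask low-certainty imputed genotypes
#'
#' Sets cells whose maximum genotype probability is below `gp_threshold` to
#' missing. Phased alleles are retained internally and flagged through the
#' `missing` matrix; downstream operations decide whether to use them.
#'
#' @param callset an [impute_phase()] result.
#' @param gp_threshold genotype-probability threshold in (0, 1].
#' @return the callset with its `missing` mask (and `gp_threshold`) set.
#' @export
mask_low_gp <- function(callset, gp_threshold = 0.95) {
  stopifnot(inherits(callset, "ImputedCallset"))
  if (!(gp_threshold > 0 && gp_threshold <= 1))
    stopf("gp_threshold must lie in (0, 1]")
  maxgp <- pmax(callset$gp[, , 1], callset$gp[, , 2], callset$gp[, , 3])
  if (is.null(dim(maxgp))) maxgp <- matrix(maxgp, nrow(callset$hapA))
  callset$missing <- maxgp < gp_threshold
  callset$gp_threshold <- gp_threshold
  callset
}

#' Hard genotype calls from an imputed callset
#'
#' argmax-GP genotypes with masked cells as `NA`.
#'
#' @param callset an `ImputedCallset`.
#' @param use_missing honour the `missing` mask (default `TRUE`).
#' @return N x M integer matrix with values 0/1/2 or `NA`.
#' @export
hard_calls <- function(callset, use_missing = TRUE) {
  g <- callset$hapA + callset$hapB
  if (use_missing) g[callset$missing] <- NA_integer_
  g
}
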