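# Single-marker mixed-model association on imputed genotypes: a centred GRM,
# one EMMAX-style REML variance-component fit under the null, then per-site
# generalised-least-squares Wald tests. The binary phenotype is analysed as
# quantitative, as linear mixed model software does for case/control coat
# colour here.

#' Centred genomic relationship matrix
#'
#' Columns are centred by `2 * p_hat` and scaled by
#' `sqrt(2 * p_hat * (1 - p_hat))`; `K = G_s %*% t(G_s) / M_used`.
#' Monomorphic sites carry no relationship information and are skipped.
#'
#' @param genotypes N x M dosages or hard calls in `[0, 2]` (`NA` tolerated,
#'   treated as the site mean).
#' @return N x N symmetric positive semidefinite matrix.
#' @export
kinship_matrix <- function(genotypes) {
  G <- as.matrix(genotypes)
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- which(p > 0 & p < 1)
  if (length(poly) < 2L) stopf("kinship needs at least 2 polymorphic sites")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  Gs <- sweep(G, 2, 2 * p, "-")
  Gs[is.na(Gs)] <- 0
  Gs <- sweep(Gs, 2, sqrt(2 * p * (1 - p)), "/")
  tcrossprod(Gs) / length(poly)
}

#' Minor-allele-frequency analysis filter
#'
#' Sample MAF computed from the genotypes themselves; sites with
#' `MAF >= threshold` are analysed (the boundary is included).
#'
#' @param genotypes N x M dosages or hard calls.
#' @param threshold MAF threshold in `[0, 0.5)`.
#' @return logical vector: `TRUE` = analysed.
#' @export
maf_filter <- function(genotypes, threshold = 0.01) {
  if (!(threshold >= 0 && threshold < 0.5)) stopf("threshold must lie in [0, 0.5)")
  p <- colMeans(as.matrix(genotypes), na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  !is.na(maf) & maf >= threshold
}

# REML profile log-likelihood for the rotated null model, as a function of
# delta = sigma_e^2 / sigma_g^2 (EMMA parameterisation)
reml_ll <- function(log_delta, d, ystar, Wstar) {
  delta <- exp(log_delta)
  v <- d + delta
  n <- length(ystar); c <- ncol(Wstar)
  WtVW <- crossprod(Wstar, Wstar / v)
  beta <- solve(WtVW, crossprod(Wstar, ystar / v))
  r <- ystar - Wstar %*% beta
  rss <- sum(r^2 / v)
  np <- n - c
  0.5 * (np * log(np / (2 * pi)) - np - np * log(rss) -
         sum(log(v)) - determinant(WtVW, logarithm = TRUE)$modulus)
}

#' Linear mixed-model association scan
#'
#' Fits `y = W alpha + x beta + u + e` with `u ~ N(0, sigma_g^2 K)`.
#' Variance components are estimated once by REML under the null via the
#' eigendecomposition of the kinship matrix (the EMMAX approximation), after
#' which each analysed site gets a generalised-least-squares Wald test for
#' `beta` (t reference distribution with `n - ncol(W) - 1` degrees of
#' freedom). Sites failing the MAF filter or without variation are not
#' analysed.
#'
#' @param genotypes N x M dosages (or hard calls).
#' @param phenotype length-N numeric; a binary phenotype is analysed as
#'   quantitative.
#' @param covariates N x c matrix of covariates (e.g. sex); an intercept is
#'   always added.
#' @param kinship N x N matrix from [kinship_matrix()].
#' @param maf_threshold MAF analysis filter (default 0.01).
#' @param force_sigma_g_zero skip the random effect (`sigma_g^2 = 0`); the
#'   scan then reduces to ordinary least squares.
#' @return An object of class `AssociationResult`: list with `sites`
#'   (data.frame: `site`, `beta`, `se`, `p`, `analysed`), `sigma_g2`,
#'   `sigma_e2`, `kinship`, `covariates`.
#' @export
lmm_assoc <- function(genotypes, phenotype, covariates = NULL, kinship,
                      maf_threshold = 0.01, force_sigma_g_zero = FALSE) {
  G <- as.matrix(genotypes)
  N <- nrow(G); M <- ncol(G)
  y <- as.numeric(phenotype)
  W <- cbind(intercept = rep(1, N), covariates)
  if (qr(W)$rank < ncol(W)) stopf("covariates are not full rank")
  analysed <- maf_filter(G, maf_threshold) & apply(G, 2, function(x) stats::sd(x, na.rm = TRUE) > 0)

  if (force_sigma_g_zero) {
    U <- diag(N); d <- rep(0, N); delta <- Inf
    v <- rep(1, N)
    sigma_g2 <- 0
    ystar <- y; Wstar <- W
  } else {
    ek <- eigen(kinship, symmetric = TRUE)
    U <- ek$vectors
    d <- pmax(ek$values, 0)
    ystar <- crossprod(U, y)
    Wstar <- crossprod(U, W)
    opt <- optimize(reml_ll, c(-10, 10), d = d, ystar = ystar, Wstar = Wstar,
                    maximum = TRUE, tol = 1e-8)
    if (!is.finite(opt$objective)) {
      grid <- seq(-10, 10, by = 0.5)
      lls <- vapply(grid, reml_ll, numeric(1), d = d, ystar = ystar, Wstar = Wstar)
      stopf("REML did not converge; profiled log-likelihood grid: %s",
            paste(sprintf("%.1f:%.2f", grid, lls), collapse = " "))
    }
    delta <- exp(opt$maximum)
    v <- d + delta
    c0 <- ncol(W)
    WtVW <- crossprod(Wstar, Wstar / v)
    beta0 <- solve(WtVW, crossprod(Wstar, ystar / v))
    sigma_g2 <- sum((ystar - Wstar %*% beta0)^2 / v) / (N - c0)
  }
  sigma_e2 <- if (force_sigma_g_zero) {
    c0 <- ncol(W)
    b <- solve(crossprod(W), crossprod(W, y))
    sum((y - W %*% b)^2) / (N - c0)
  } else sigma_g2 * delta

  Gimp <- G
  cm <- colMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(Gimp))
  if (length(na_idx)) Gimp[na_idx] <- cm[((na_idx - 1) %/% N) + 1]
  Gstar <- if (force_sigma_g_zero) Gimp else crossprod(U, Gimp)

  c1 <- ncol(W) + 1L
  df <- N - c1
  beta <- se <- p <- rep(NA_real_, M)
  sw <- Wstar / v
  WtW <- crossprod(Wstar, sw)
  Wty <- crossprod(sw, ystar)
  for (m in which(analysed)) {
    x <- Gstar[, m]
    sx <- x / v
    A <- rbind(cbind(WtW, crossprod(Wstar, sx)),
               c(crossprod(x, sw), sum(x * sx)))
    b <- c(Wty, sum(sx * ystar))
    coefs <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(coefs)) next
    r <- ystar - cbind(Wstar, x) %*% coefs
    s2 <- sum(r^2 / v) / df
    xtvx_inv <- solve(A)[c1, c1]
    beta[m] <- coefs[c1]
    se[m] <- sqrt(s2 * xtvx_inv)
    tt <- beta[m] / se[m]
    p[m] <- 2 * pt(-abs(tt), df)
  }
  analysed <- analysed & !is.na(p)
  structure(list(
    sites = data.frame(site = seq_len(M), beta = beta, se = se, p = p,
                       analysed = analysed),
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
    kinship = kinship, covariates = W
  ), class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("AssociationResult: %d/%d sites analysed; sigma_g2 = %.3g, sigma_e2 = %.3g\n",
              sum(x$sites$analysed), nrow(x$sites), x$sigma_g2, x$sigma_e2))
  if (any(x$sites$analysed))
    cat(sprintf("  min p = %.3g at site %d\n",
                min(x$sites$p[x$sites$analysed]),
                x$sites$site[x$sites$analysed][which.min(x$sites$p[x$sites$analysed])]))
  invisible(x)
}

#' Genome-wide significant association hits
#'
#' @param result an [lmm_assoc()] result.
#' @param alpha significance threshold on the Wald p-value.
#' @return integer vector of analysed site indices with `p < alpha`.
#' @export
significant_hits <- function(result, alpha = 1e-6) {
  s <- result$sites
  s$site[s$analysed & !is.na(s$p) & s$p < alpha]
}
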