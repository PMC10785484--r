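# Minimal VCF dialect: VCFv4.2, single chromosome, biallelic SNVs, phased GT
# with optional GP/DS/PL/DP per sample and a per-site IMPINFO INFO field.
# Files written by write_vcf() round-trip through read_vcf() byte-identically
# (the header carries no date line).

vcf_header <- function(chrom, chrom_length_bp, samples, has_gp, has_ds,
                       has_pl, has_dp, has_info) {
  h <- c("##fileformat=VCFv4.2",
         "##source=lowpasshap",
         sprintf("##contig=<ID=%s,length=%d>", chrom, as.integer(chrom_length_bp)),
         '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (has_gp) h <- c(h, '##FORMAT=<ID=GP,Number=3,Type=Float,Description="Genotype posterior probabilities">')
  if (has_ds) h <- c(h, '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Imputed dosage">')
  if (has_pl) h <- c(h, '##FORMAT=<ID=PL,Number=3,Type=Integer,Description="Phred-scaled genotype likelihoods">')
  if (has_dp) h <- c(h, '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (has_info) h <- c(h, '##INFO=<ID=IMPINFO,Number=1,Type=Float,Description="Imputation INFO score">')
  c(h, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
               "FORMAT", samples), collapse = "\t"))
}

#' Write a phased callset as minimal VCF
#'
#' Biallelic SNV records (REF `A`, ALT `C` placeholders), phased `GT` with
#' the `|` separator, optional `GP`/`DS`/`PL`/`DP` FORMAT fields and a
#' per-site `IMPINFO` INFO field. Cells flagged missing are written `./.`
#' (with their other FORMAT fields retained).
#'
#' @param path output file.
#' @param chrom chromosome name.
#' @param positions 1-based site positions.
#' @param hapA,hapB N x M allele matrices (`NA` allowed).
#' @param samples sample names.
#' @param missing optional N x M logical mask written as `./.`.
#' @param gp optional N x M x 3 posterior array.
#' @param ds optional N x M dosage matrix.
#' @param pl optional N x M x 3 Phred-scaled integer likelihood array.
#' @param dp optional N x M depth matrix.
#' @param info optional per-site INFO score.
#' @param chrom_length_bp contig length for the header.
#' @param phased write `|` (default) or `/` separators.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(path, chrom, positions, hapA, hapB, samples,
                      missing = NULL, gp = NULL, ds = NULL, pl = NULL,
                      dp = NULL, info = NULL,
                      chrom_length_bp = max(positions), phased = TRUE) {
  N <- nrow(hapA); M <- ncol(hapA)
  sep <- if (phased) "|" else "/"
  header <- vcf_header(chrom, chrom_length_bp, samples, !is.null(gp),
                       !is.null(ds), !is.null(pl), !is.null(dp), !is.null(info))
  fmt <- paste(c("GT", if (!is.null(gp)) "GP", if (!is.null(ds)) "DS",
                 if (!is.null(pl)) "PL", if (!is.null(dp)) "DP"), collapse = ":")
  gt <- matrix(paste0(hapA, sep, hapB), N, M)
  gt[is.na(hapA) | is.na(hapB)] <- "./."
  if (!is.null(missing)) gt[missing] <- "./."
  cells <- gt
  if (!is.null(gp)) {
    gps <- matrix(sprintf("%.4g,%.4g,%.4g", gp[, , 1], gp[, , 2], gp[, , 3]), N, M)
    cells <- matrix(paste0(cells, ":", gps), N, M)
  }
  if (!is.null(ds)) cells <- matrix(paste0(cells, ":", sprintf("%.4g", ds)), N, M)
  if (!is.null(pl)) {
    pls <- matrix(sprintf("%d,%d,%d", pl[, , 1], pl[, , 2], pl[, , 3]), N, M)
    cells <- matrix(paste0(cells, ":", pls), N, M)
  }
  if (!is.null(dp)) cells <- matrix(paste0(cells, ":", dp), N, M)
  info_col <- if (!is.null(info)) sprintf("IMPINFO=%.6g", info) else rep(".", M)
  body <- paste(chrom, positions, ".", "A", "C", ".", "PASS", info_col, fmt,
                apply(cells, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF
#'
#' Accepts the dialect written by [write_vcf()]: biallelic SNV records with
#' `GT` and optional `GP`/`DS`/`PL`/`DP`. Multi-allelic or INDEL records are
#' rejected explicitly. `./.` parses as missing with undefined phase.
#'
#' @param path VCF file (uncompressed).
#' @param require_phased error on unphased (`/`) genotypes, reporting the
#'   first offending record.
#' @return list with `chrom`, `positions`, `samples`, `hapA`, `hapB`
#'   (`NA` at missing cells), `phased` (N x M logical), `gp`, `ds`, `pl`,
#'   `dp` (present when in the file), `info`.
#' @export
read_vcf <- function(path, require_phased = FALSE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stopf("malformed VCF: no #CHROM header line")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  M <- length(body)
  N <- length(samples)
  fields <- strsplit(body, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[`, "", 1L)
  positions <- as.integer(vapply(fields, `[`, "", 2L))
  ref <- vapply(fields, `[`, "", 4L)
  alt <- vapply(fields, `[`, "", 5L)
  bad <- which(nchar(ref) != 1L | nchar(alt) != 1L | grepl(",", alt, fixed = TRUE))
  if (length(bad))
    stopf("unsupported record at %s:%s: only biallelic SNVs are handled",
          chrom[bad[1]], positions[bad[1]])
  info_raw <- vapply(fields, `[`, "", 8L)
  info <- suppressWarnings(as.numeric(sub("^.*IMPINFO=([^;]+).*$", "\\1", info_raw)))
  fmt <- strsplit(vapply(fields, `[`, "", 9L), ":", fixed = TRUE)
  hapA <- matrix(NA_integer_, N, M); hapB <- matrix(NA_integer_, N, M)
  phased <- matrix(NA, N, M)
  has_gp <- any(vapply(fmt, function(f) "GP" %in% f, logical(1)))
  has_ds <- any(vapply(fmt, function(f) "DS" %in% f, logical(1)))
  has_pl <- any(vapply(fmt, function(f) "PL" %in% f, logical(1)))
  has_dp <- any(vapply(fmt, function(f) "DP" %in% f, logical(1)))
  gp <- if (has_gp) array(NA_real_, c(N, M, 3L))
  ds <- if (has_ds) matrix(NA_real_, N, M)
  pl <- if (has_pl) array(NA_integer_, c(N, M, 3L))
  dp <- if (has_dp) matrix(NA_integer_, N, M)
  for (m in seq_len(M)) {
    f <- fmt[[m]]
    cells <- strsplit(fields[[m]][-(1:9)], ":", fixed = TRUE)
    gt <- vapply(cells, `[`, "", which(f == "GT"))
    sep_phased <- grepl("|", gt, fixed = TRUE)
    miss <- gt %in% c("./.", ".|.", ".")
    if (require_phased && any(!sep_phased & !miss))
      stopf("unphased genotype '%s' at record %s:%d (sample %s)",
            gt[which(!sep_phased & !miss)[1]], chrom[m], positions[m],
            samples[which(!sep_phased & !miss)[1]])
    al <- strsplit(gt, "[|/]")
    a1 <- suppressWarnings(as.integer(vapply(al, `[`, "", 1L)))
    a2 <- suppressWarnings(as.integer(vapply(al, function(x) if (length(x) > 1) x[2] else NA_character_, "")))
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    hapA[, m] <- a1; hapB[, m] <- a2
    phased[, m] <- ifelse(miss, NA, sep_phased)
    if (has_gp && "GP" %in% f) {
      v <- strsplit(vapply(cells, `[`, "", which(f == "GP")), ",", fixed = TRUE)
      gpm <- t(vapply(v, function(x) as.numeric(x[1:3]), numeric(3)))
      gp[, m, ] <- gpm
    }
    if (has_ds && "DS" %in% f)
      ds[, m] <- as.numeric(vapply(cells, `[`, "", which(f == "DS")))
    if (has_pl && "PL" %in% f) {
      v <- strsplit(vapply(cells, `[`, "", which(f == "PL")), ",", fixed = TRUE)
      pl[, m, ] <- t(vapply(v, function(x) as.integer(x[1:3]), integer(3)))
    }
    if (has_dp && "DP" %in% f)
      dp[, m] <- as.integer(vapply(cells, `[`, "", which(f == "DP")))
  }
  out <- list(chrom = chrom[1], positions = positions, samples = samples,
              hapA = hapA, hapB = hapB, phased = phased, info = info)
  if (has_gp) out$gp <- gp
  if (has_ds) out$ds <- ds
  if (has_pl) out$pl <- pl
  if (has_dp) out$dp <- dp
  out
}

#' Write a pileup as a long-format TSV
#'
#' Columns `CHROM`, `POS`, `SAMPLE`, `NREF`, `NALT`, one row per
#' site x individual.
#'
#' @param pileup a [simulate_pileup()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  N <- nrow(pileup$ref_count); M <- ncol(pileup$ref_count)
  df <- data.frame(CHROM = pileup$chrom,
                   POS = rep(pileup$positions, each = N),
                   SAMPLE = rep(pileup$sample_id, M),
                   NREF = as.vector(pileup$ref_count),
                   NALT = as.vector(pileup$alt_count))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Phred-scaled likelihood triplets from genotype likelihoods
#'
#' `PL = round(-10 log10(L / max L))` per cell, the conventional integer
#' encoding of normalised genotype likelihoods.
#'
#' @param gl a [pileup_to_gl()] result.
#' @return N x M x 3 integer array.
#' @export
gl_to_pl <- function(gl) {
  stopifnot(inherits(gl, "GenotypeLikelihoods"))
  N <- nrow(gl$depth); M <- ncol(gl$depth)
  mx <- pmax(gl$gl[, , 1], gl$gl[, , 2], gl$gl[, , 3])
  pl <- array(0L, c(N, M, 3L))
  for (g in 1:3)
    pl[, , g] <- as.integer(round(-10 * log10(pmax(gl$gl[, , g], 1e-30) / mx)))
  pl
}

#' Write genotype likelihoods as an unphased VCF with PL and DP
#'
#' The pre-imputation callset dialect: `GT` from the per-cell likelihood
#' argmax (unphased, missing below `min_depth`), integer `PL` triplets and
#' `DP`. [read_vcf()] reads the same dialect back.
#'
#' @param gl a [pileup_to_gl()] result.
#' @param path output file.
#' @param min_depth calls below this depth are written `./.`.
#' @param chrom_length_bp contig length for the header.
#' @return `path`, invisibly.
#' @export
write_gl_vcf <- function(gl, path, min_depth = 1L,
                         chrom_length_bp = max(gl$positions)) {
  calls <- naive_calls(gl, min_depth)
  hapA <- matrix(as.integer(calls >= 1L), nrow(calls), ncol(calls))
  hapB <- matrix(as.integer(calls == 2L), nrow(calls), ncol(calls))
  hapA[is.na(calls)] <- NA_integer_; hapB[is.na(calls)] <- NA_integer_
  write_vcf(path, gl$chrom, gl$positions, hapA, hapB, gl$sample_id,
            pl = gl_to_pl(gl), dp = gl$depth,
            chrom_length_bp = chrom_length_bp, phased = FALSE)
}
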