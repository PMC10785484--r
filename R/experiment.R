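# End-to-end experiment driver: simulate -> pileups -> GLs -> imputation per
# (depth x panel) -> masking -> concordance, association, XP-EHH ->
# haplotype-consistency diagnostics -> tidy report tables.

#' Simulate all experiment inputs for a configuration
#'
#' Builds the master panel, the three imputation panels (full / target
#' enriched / target depleted), the cohort, per-depth pileups (fresh
#' sequencing draws for the lower depths, binomial thinning of the top-depth
#' pileup for the depths the study down-sampled in silico), genotype
#' likelihoods per depth, and the top-depth pre-imputation validation calls.
#'
#' @param cfg an [default_config()] result.
#' @return list with `master_panel`, `panels`, `cohort`, `pileups`, `gls`,
#'   `validation_calls`, `region_profile`, `indiv_profile`, `depth_names`.
#' @export
simulate_experiment_inputs <- function(cfg) {
  cfg <- validate_config(cfg)
  master <- simulate_panel(cfg$n_breeds, cfg$haps_per_breed, cfg$n_sites,
                           cfg$chrom_length_bp, cfg$founder_div,
                           cfg$mutation_rate, cfg$recomb_switch_rate,
                           seed = derive_seed(cfg$seed, 1L), chrom = cfg$chrom)
  panels <- list(
    full = subset_panel(master, cfg$target_breed, cfg$panel_full_diploids,
                        include_target = TRUE, seed = derive_seed(cfg$seed, 2L)),
    panel1 = subset_panel(master, cfg$target_breed, cfg$panel_subset_diploids,
                          include_target = TRUE, seed = derive_seed(cfg$seed, 3L)),
    panel2 = subset_panel(master, cfg$target_breed, cfg$panel_subset_diploids,
                          include_target = FALSE, breed_cap = cfg$panel2_breed_cap,
                          target_cap = cfg$panel2_target_cap,
                          seed = derive_seed(cfg$seed, 4L))
  )
  cohort <- simulate_cohort(panels$full, cfg$n_individuals, cfg$n_cases,
                            cfg$mosaic_switch_rate, cfg$private_allele_rate,
                            cfg$target_breed, cfg$sweep_bp,
                            cfg$causal_maf_range,
                            seed = derive_seed(cfg$seed, 10L))
  region_profile <- make_region_profile(master$positions, cfg$low_coverage_segments)
  indiv_profile <- with_seed(derive_seed(cfg$seed, 11L), {
    p <- exp(rnorm(cfg$n_individuals, 0, cfg$indiv_profile_sdlog))
    p / mean(p)
  })
  depth_names <- format_depth(cfg$depths)
  top_name <- format_depth(cfg$top_depth)
  pileups <- list()
  pileups[[top_name]] <- simulate_pileup(cohort, cfg$top_depth, cfg$epsilon,
                                         region_profile, indiv_profile,
                                         seed = derive_seed(cfg$seed, 20L))
  for (i in seq_along(cfg$depths)) {
    d <- cfg$depths[i]; dn <- depth_names[i]
    if (dn == top_name) next
    if (d %in% cfg$thinned_depths) {
      pileups[[dn]] <- thin_pileup(pileups[[top_name]], d / cfg$top_depth,
                                   seed = derive_seed(cfg$seed, 30L + i))
    } else {
      pileups[[dn]] <- simulate_pileup(cohort, d, cfg$epsilon, region_profile,
                                       indiv_profile,
                                       seed = derive_seed(cfg$seed, 20L + i))
    }
  }
  pileups <- pileups[depth_names]
  gls <- lapply(pileups, pileup_to_gl)
  validation_calls <- naive_calls(gls[[top_name]],
                                  cfg$min_depth_map[[top_name]])
  list(master_panel = master, panels = panels, cohort = cohort,
       pileups = pileups, gls = gls, validation_calls = validation_calls,
       region_profile = region_profile, indiv_profile = indiv_profile,
       depth_names = depth_names, top_name = top_name)
}

#' Impute every depth against one panel
#'
#' @param sim a [simulate_experiment_inputs()] result.
#' @param panel a [haplotype_panel()].
#' @param cfg the experiment config.
#' @return named list (by depth) of masked `ImputedCallset`s.
#' @export
impute_all_depths <- function(sim, panel, cfg) {
  params <- ls_params(cfg$ls_recomb_rate, cfg$ls_mismatch_theta, cfg$ls_ne_scale)
  out <- list()
  for (dn in sim$depth_names) {
    cs <- impute_phase(sim$gls[[dn]], panel, params, cfg$chunk_bp,
                       cfg$chunk_overlap_bp)
    out[[dn]] <- mask_low_gp(cs, cfg$gp_threshold)
  }
  out
}

#' Run the full evaluation experiment
#'
#' Executes the complete workflow for one configuration: simulation, per
#' depth x panel imputation and GP masking, the concordance suite against
#' the top-depth pre-imputation validation calls, mixed-model association
#' and XP-EHH scans per dataset, and the haplotype-consistency diagnostics
#' (regional distinct-haplotype counts across depths, depth-deviation tests,
#' 1-Mb window metrics, and the summary regressions). Two runs with the same
#' configuration produce identical report tables.
#'
#' @param cfg an [default_config()] result.
#' @param panels character subset of `c("full", "panel1", "panel2")`.
#' @param outdir optional directory for TSV report tables plus a config copy.
#' @param keep_callsets retain the imputed callsets in the returned bundle.
#' @param verbose log stage progress.
#' @return An object of class `ExperimentReport`: list with `tables` (named
#'   data.frames), `assoc`, `xpehh`, `callsets` (optional), `sim`, `config`.
#' @export
run_experiment <- function(cfg = default_config(), panels = c("full", "panel1", "panel2"),
                           outdir = NULL, keep_callsets = TRUE,
                           verbose = FALSE) {
  cfg <- validate_config(cfg)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    say("stage %-12s ...", name)
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  t0 <- Sys.time()
  sim <- stage("simulate", simulate_experiment_inputs(cfg))
  depth_names <- sim$depth_names
  top <- sim$top_name
  truth_phased <- list(hapA = sim$cohort$hapA, hapB = sim$cohort$hapB,
                       missing = matrix(FALSE, cfg$n_individuals, cfg$n_sites))

  callsets <- list()
  for (pn in panels)
    callsets[[pn]] <- stage(paste0("impute_", pn),
                            impute_all_depths(sim, sim$panels[[pn]], cfg))

  ## concordance suite ------------------------------------------------------
  conc_rows <- list(); maf_rows <- list(); cls_rows <- list(); hap_rows <- list()
  win_ids <- (sim$master_panel$positions - 1) %/% cfg$window_bp
  for (pn in panels) {
    ref_phased <- callsets[[pn]][[top]]
    for (dn in depth_names) {
      cs <- callsets[[pn]][[dn]]
      g <- hard_calls(cs)
      depth_mat <- sim$pileups[[dn]]$ref_count + sim$pileups[[dn]]$alt_count
      gd <- genotype_discordance(g, sim$validation_calls, depth_mat,
                                 cfg$min_depth_map[[dn]])
      nrd <- tryCatch(nonref_discordance(g, sim$validation_calls),
                      error = function(e) NA_real_)
      dr2 <- dosage_r2(cs$dosage, sim$validation_calls)
      ser <- switch_error_rate(cs, truth_phased)
      conc_rows[[paste(pn, dn)]] <- data.frame(
        panel = pn, depth = dn,
        discordance = gd$discordance, n_compared = gd$n_compared,
        nrd = nrd, dosage_r2 = dr2$pooled,
        median_site_r2 = median(dr2$per_site, na.rm = TRUE),
        masking_rate = mean(cs$missing),
        median_info = median(cs$info),
        mean_switch_error = mean(ser, na.rm = TRUE))
      mb <- aggregate_r2_by_maf(cs$dosage, sim$validation_calls,
                                cs$panel_af_used, cfg$maf_bins)
      mb$panel <- pn; mb$depth <- dn
      maf_rows[[paste(pn, dn)]] <- mb
      mc <- mismatch_by_class(g, sim$validation_calls)
      mc$panel <- pn; mc$depth <- dn
      cls_rows[[paste(pn, dn)]] <- mc
      for (h in c("A", "B")) {
        hd <- haplotype_discordance(cs, ref_phased, h, win_ids)
        hap_rows[[paste(pn, dn, h)]] <- data.frame(
          panel = pn, depth = dn, hap = h,
          discordance = sum(hd$discordance * hd$n_compared, na.rm = TRUE) /
            sum(hd$n_compared[!is.na(hd$discordance)]),
          n_compared = sum(hd$n_compared))
      }
    }
  }

  ## association ------------------------------------------------------------
  assoc <- list(); assoc_rows <- list(); assoc_cor_rows <- list()
  for (pn in panels) {
    assoc[[pn]] <- list()
    logp <- list()
    hits <- list()
    for (dn in depth_names) {
      cs <- callsets[[pn]][[dn]]
      kin <- kinship_matrix(cs$dosage)
      res <- lmm_assoc(cs$dosage, sim$cohort$phenotype,
                       cbind(sex = sim$cohort$sex), kin, cfg$assoc_maf)
      assoc[[pn]][[dn]] <- res
      logp[[dn]] <- -log10(res$sites$p)
      hits[[dn]] <- significant_hits(res, cfg$assoc_alpha)
      assoc_rows[[paste(pn, dn)]] <- data.frame(
        panel = pn, depth = dn, n_analysed = sum(res$sites$analysed),
        n_hits = length(hits[[dn]]),
        min_p = min(res$sites$p[res$sites$analysed]),
        top_site = res$sites$site[which.min(replace(res$sites$p, !res$sites$analysed, Inf))])
    }
    cors <- correlation_suite(logp, top)$summary
    cors$panel <- pn
    cors$hits_shared_with_top <- vapply(depth_names, function(dn)
      length(intersect(hits[[dn]], hits[[top]])), integer(1))
    assoc_cor_rows[[pn]] <- cors
  }

  ## XP-EHH -----------------------------------------------------------------
  xpehh <- list(); xp_rows <- list(); xp_cor_rows <- list()
  popA <- which(sim$cohort$phenotype == 0L)
  popB <- which(sim$cohort$phenotype == 1L)
  for (pn in panels) {
    xpehh[[pn]] <- list()
    zs <- list()
    for (dn in depth_names) {
      cs <- callsets[[pn]][[dn]]
      hapsA <- rbind(cs$hapA[popA, , drop = FALSE], cs$hapB[popA, , drop = FALSE])
      hapsB <- rbind(cs$hapA[popB, , drop = FALSE], cs$hapB[popB, , drop = FALSE])
      xp <- xpehh_scan(hapsA, hapsB, cs$positions, cfg$xpehh_maf, cfg$ehh_cutoff)
      xpehh[[pn]][[dn]] <- xp
      zs[[dn]] <- xp$z
      sig <- significant_z(xp, cfg$z_threshold)
      xp_rows[[paste(pn, dn)]] <- data.frame(
        panel = pn, depth = dn, n_included = sum(xp$included),
        n_sig_pos = length(sig$positive), n_sig_neg = length(sig$negative),
        min_z = min(xp$z, na.rm = TRUE), max_z = max(xp$z, na.rm = TRUE))
    }
    cors <- correlation_suite(zs, top)$summary
    cors$panel <- pn
    xp_cor_rows[[pn]] <- cors
  }

  ## diagnostics -------------------------------------------------------------
  regions <- sample_regions(sim$master_panel$positions, cfg$n_regions,
                            cfg$variants_per_region,
                            seed = derive_seed(cfg$seed, 40L))
  diag_rows <- list(); region_tabs <- list(); s8_rows <- list()
  top_pileup <- sim$pileups[[top]]
  for (pn in panels) {
    # counts use the retained phase at masked cells: the phased output the
    # haplotype-level analyses consume carries an allele at every site
    counts <- count_region_haplotypes_all(callsets[[pn]], regions,
                                          respect_missing = FALSE)
    med_cnt <- apply(counts, 1, function(x) median(x, na.rm = TRUE))
    wil_p <- vapply(seq_len(nrow(regions)), function(r)
      region_depth_wilcoxon(top_pileup, regions[r, ]), numeric(1))
    med_z <- vapply(seq_len(nrow(regions)), function(r) {
      idx <- regions$start_idx[r]:regions$end_idx[r]
      median(xpehh[[pn]][[top]]$z[idx], na.rm = TRUE)
    }, numeric(1))
    rt <- data.frame(regions, panel = pn, median_haps = med_cnt,
                     haps_up = ceiling(med_cnt), wilcox_p = wil_p,
                     median_z_top = med_z,
                     flagged = !is.na(med_cnt) & med_cnt >= cfg$hap_flag_threshold)
    region_tabs[[pn]] <- rt
    ok <- !is.na(rt$median_haps)
    s8 <- ols_regress(rt$wilcox_p[ok], data.frame(haps = rt$haps_up[ok]))
    s8$panel <- pn
    s8_rows[[pn]] <- s8
    diag_rows[[pn]] <- data.frame(
      panel = pn,
      median_haps = median(med_cnt, na.rm = TRUE),
      upper5_haps = quantile(med_cnt, 0.95, na.rm = TRUE, names = FALSE),
      frac_flagged = mean(rt$flagged))
  }

  ## window metrics + delta-Z correlations -----------------------------------
  win_tabs <- list(); dz_rows <- list()
  for (pn in panels) {
    wm <- window_metrics(callsets[[pn]], sim$validation_calls,
                         callsets[[pn]][[top]], sim$pileups, xpehh[[pn]],
                         sim$master_panel$positions, cfg$window_bp,
                         cfg$trim_quantiles)
    wm$panel <- pn
    win_tabs[[pn]] <- wm
    topw <- wm[wm$depth == top, ]
    for (dn in setdiff(depth_names, top)) {
      sub <- wm[wm$depth == dn & wm$kept, ]
      dz <- abs(sub$median_z - topw$median_z[match(sub$window, topw$window)])
      for (metric in c("geno_disc", "hapA_disc", "hapB_disc")) {
        okm <- !is.na(dz) & !is.na(sub[[metric]])
        r <- if (sum(okm) >= 3 && stats::sd(dz[okm]) > 0 && stats::sd(sub[[metric]][okm]) > 0)
          cor(dz[okm], sub[[metric]][okm]) else NA_real_
        dz_rows[[paste(pn, dn, metric)]] <- data.frame(
          panel = pn, depth = dn, metric = metric, r = r, n = sum(okm))
      }
    }
  }

  ## summary regressions ------------------------------------------------------
  drop_degenerate <- function(X) X[, vapply(X, function(c)
    length(unique(c)) > 1L, logical(1)), drop = FALSE]
  maf_tab <- do.call(rbind, c(maf_rows, list(make.row.names = FALSE)))
  s5_dat <- maf_tab[maf_tab$defined, ]
  s5 <- ols_regress(s5_dat$r2, drop_degenerate(data.frame(
    MAF = (s5_dat$maf_lo + s5_dat$maf_hi) / 2,
    depth = as.numeric(s5_dat$depth), panel = s5_dat$panel)))
  conc_tab <- do.call(rbind, c(conc_rows, list(make.row.names = FALSE)))
  s6 <- ols_regress(conc_tab$dosage_r2, drop_degenerate(data.frame(
    depth = as.numeric(conc_tab$depth), panel = conc_tab$panel)))

  tables <- list(
    concordance = conc_tab,
    r2_by_maf = maf_tab,
    mismatch_class = do.call(rbind, c(cls_rows, list(make.row.names = FALSE))),
    haplotype_discordance = do.call(rbind, c(hap_rows, list(make.row.names = FALSE))),
    association = do.call(rbind, c(assoc_rows, list(make.row.names = FALSE))),
    association_correlation = do.call(rbind, c(assoc_cor_rows, list(make.row.names = FALSE))),
    xpehh = do.call(rbind, c(xp_rows, list(make.row.names = FALSE))),
    xpehh_correlation = do.call(rbind, c(xp_cor_rows, list(make.row.names = FALSE))),
    regions = do.call(rbind, c(region_tabs, list(make.row.names = FALSE))),
    region_summary = do.call(rbind, c(diag_rows, list(make.row.names = FALSE))),
    windows = do.call(rbind, c(win_tabs, list(make.row.names = FALSE))),
    deltaz_correlation = do.call(rbind, c(dz_rows, list(make.row.names = FALSE))),
    regression_r2_maf_depth_panel = s5,
    regression_dosage_r2_depth_panel = s6,
    regression_wilcoxp_haps = do.call(rbind, c(s8_rows, list(make.row.names = FALSE)))
  )
  say("done in %.1f min", as.numeric(difftime(Sys.time(), t0, units = "mins")))

  report <- structure(list(
    tables = tables, assoc = assoc, xpehh = xpehh,
    callsets = if (keep_callsets) callsets,
    sim = sim, config = cfg,
    provenance = list(seed = cfg$seed, panels = panels,
                      elapsed_min = as.numeric(difftime(Sys.time(), t0, units = "mins")))
  ), class = "ExperimentReport")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_config(cfg, file.path(outdir, "config.yaml"))
    for (tn in names(tables))
      write.table(tables[[tn]], file.path(outdir, paste0(tn, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    # per-site scan outputs, one file per panel x depth
    pos <- sim$master_panel$positions
    for (pn in panels) for (dn in depth_names) {
      a <- assoc[[pn]][[dn]]$sites
      write.table(data.frame(CHROM = cfg$chrom, POS = pos, BETA = a$beta,
                             SE = a$se, P = a$p, ANALYSED = a$analysed),
                  file.path(outdir, sprintf("assoc_%s_%sx.tsv", pn, dn)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      x <- xpehh[[pn]][[dn]]
      write.table(data.frame(POS = x$pos, IHH_A = x$ihh_a, IHH_B = x$ihh_b,
                             XPEHH = x$raw, Z = x$z, INCLUDED = x$included),
                  file.path(outdir, sprintf("xpehh_%s_%sx.tsv", pn, dn)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat(sprintf("ExperimentReport: seed %d, panels {%s}, depths {%s}X\n",
              x$config$seed, paste(x$provenance$panels, collapse = ", "),
              paste(names(x$sim$pileups), collapse = ", ")))
  cat(sprintf("  %d report tables: %s\n", length(x$tables),
              paste(names(x$tables), collapse = ", ")))
  invisible(x)
}
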