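# Shared depth-sweep fixture: the default simulation run across the depth
# grid for several seeds, with only small per-seed summaries retained.
# Computed lazily once per test session and reused by every test that needs
# the cross-depth behaviour of the full pipeline.

.sweep_cache <- new.env(parent = emptyenv())

depth_sweep_summaries <- function(n_seeds = 10L, n_regions = 800L) {
  key <- sprintf("sweep_%d_%d", n_seeds, n_regions)
  if (!is.null(.sweep_cache[[key]])) return(.sweep_cache[[key]])
  res <- lapply(seq_len(n_seeds), function(s) {
    cfg <- default_config(seed = s)
    sim <- simulate_experiment_inputs(cfg)
    cs <- impute_all_depths(sim, sim$panels$full, cfg)
    top <- cs[[sim$top_name]]
    lower <- setdiff(sim$depth_names, sim$top_name)
    disc <- mask <- hapd <- setNames(numeric(length(lower)), lower)
    for (dn in lower) {
      g <- hard_calls(cs[[dn]])
      depth_mat <- sim$pileups[[dn]]$ref_count + sim$pileups[[dn]]$alt_count
      disc[dn] <- genotype_discordance(g, sim$validation_calls, depth_mat,
                                       cfg$min_depth_map[[dn]])$discordance
      mask[dn] <- mean(cs[[dn]]$missing)
      hapd[dn] <- haplotype_discordance(cs[[dn]], top, "A")$discordance
    }
    regions <- sample_regions(sim$master_panel$positions, n_regions,
                              cfg$variants_per_region,
                              seed = derive_seed(cfg$seed, 40L))
    counts <- count_region_haplotypes_all(cs, regions, respect_missing = FALSE)
    med_cnt <- apply(counts, 1, function(x) median(x, na.rm = TRUE))
    segs <- cfg$low_coverage_segments
    planted <- Reduce(`|`, lapply(seq_len(nrow(segs)), function(r)
      regions$start_bp <= segs$end[r] & regions$end_bp >= segs$start[r]))
    extras <- NULL
    if (s == 1L) {
      logp <- list(); zs <- list()
      for (dn in sim$depth_names) {
        kin <- kinship_matrix(cs[[dn]]$dosage)
        ar <- lmm_assoc(cs[[dn]]$dosage, sim$cohort$phenotype,
                        cbind(sex = sim$cohort$sex), kin, cfg$assoc_maf)
        logp[[dn]] <- -log10(ar$sites$p)
        popA <- which(sim$cohort$phenotype == 0)
        popB <- which(sim$cohort$phenotype == 1)
        x <- cs[[dn]]
        zs[[dn]] <- xpehh_scan(rbind(x$hapA[popA, ], x$hapB[popA, ]),
                               rbind(x$hapA[popB, ], x$hapB[popB, ]),
                               x$positions, cfg$xpehh_maf, cfg$ehh_cutoff)$z
      }
      top_ar <- lmm_assoc(cs[[sim$top_name]]$dosage, sim$cohort$phenotype,
                          cbind(sex = sim$cohort$sex),
                          kinship_matrix(cs[[sim$top_name]]$dosage),
                          cfg$assoc_maf)
      extras <- list(
        logp = logp, z = zs,
        causal_site = sim$cohort$causal_site,
        causal_pos = sim$cohort$positions[sim$cohort$causal_site],
        positions = sim$cohort$positions,
        sweep_bp = cfg$sweep_bp,
        top_assoc = top_ar)
    }
    list(seed = s, disc = disc, mask = mask, hapd = hapd,
         med_cnt = med_cnt, planted = planted, extras = extras)
  })
  .sweep_cache[[key]] <- res
  res
}
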