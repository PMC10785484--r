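#' Default experiment configuration
#'
#' Desk-scale defaults for the end-to-end evaluation: one 20-Mb synthetic
#' chromosome with 5000 sites; a 9-breed master panel (16 haplotypes per
#' breed) from which a 24-diploid "full" panel, a 12-diploid target-enriched
#' "panel1" and a 12-diploid target-depleted "panel2" are drawn; a cohort of
#' 30 individuals with 6 recessive cases; the depth grid
#' 0.9 / 3.8 / 9.6 / 17.4 / 43.5X with 9.6X and 17.4X produced by binomial
#' thinning of the 43.5X pileup (retention = depth ratio; 0.40 for 17.4X)
#' and the lower depths as fresh sequencing draws; and the analysis
#' thresholds (GP 0.95, association alpha 1e-6, |Z| 4, EHH 0.05, MAF 0.01 /
#' 0.05, per-depth minimum call depths 1/2/5/10). Three depressed-coverage
#' segments emulate hard-to-map regions.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param ... named overrides of any default entry.
#' @return An object of class `ExperimentConfig` (a named list).
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom = "chr1",
    chrom_length_bp = 20e6,
    n_sites = 5000L,
    # master panel / breed structure
    n_breeds = 9L,
    haps_per_breed = 16L,
    founder_div = 0.15,
    mutation_rate = 0.002,
    recomb_switch_rate = 2.5e-7,
    target_breed = "breed1",
    # derived panels
    panel_full_diploids = 24L,
    panel_subset_diploids = 12L,
    panel2_breed_cap = 2L,
    panel2_target_cap = 1L,
    # cohort
    n_individuals = 30L,
    n_cases = 6L,
    mosaic_switch_rate = 2e-6,
    private_allele_rate = 0.02,
    sweep_bp = 1e6,
    causal_maf_range = c(0.15, 0.35),
    # sequencing
    depths = c(0.9, 3.8, 9.6, 17.4, 43.5),
    top_depth = 43.5,
    thinned_depths = c(9.6, 17.4), # generated by thinning the top pileup
    epsilon = 0.001,
    indiv_profile_sdlog = 0.1,
    low_coverage_segments = data.frame(
      start = c(2.0e6, 9.0e6, 16.0e6),
      end = c(2.4e6, 9.4e6, 16.4e6),
      multiplier = 0.3),
    # analysis thresholds
    min_depth_map = c("0.9" = 1L, "3.8" = 2L, "9.6" = 5L, "17.4" = 10L,
                      "43.5" = 10L),
    gp_threshold = 0.95,
    truth_certainty = 0.9999,
    assoc_alpha = 1e-6,
    assoc_maf = 0.01,
    z_threshold = 4,
    ehh_cutoff = 0.05,
    xpehh_maf = 0.05,
    maf_bins = c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5),
    # Li-Stephens engine
    ls_recomb_rate = 1e-8,
    ls_ne_scale = 50,
    ls_mismatch_theta = NULL,
    chunk_bp = 20e6,
    chunk_overlap_bp = 250e3,
    # diagnostics
    n_regions = 2000L,
    variants_per_region = 100L,
    window_bp = 1e6,
    trim_quantiles = c(0.01, 0.99),
    hap_flag_threshold = 8L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config entries: %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "ExperimentConfig"))
}

#' Validate an experiment configuration
#'
#' @param cfg an `ExperimentConfig`.
#' @return the config, invisibly-checked.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "ExperimentConfig") || is.list(cfg))
  assert_prob(cfg$gp_threshold, "gp_threshold", open_lower = TRUE)
  assert_prob(cfg$ehh_cutoff, "ehh_cutoff")
  assert_prob(cfg$xpehh_maf, "xpehh_maf")
  if (!(cfg$assoc_maf >= 0 && cfg$assoc_maf < 0.5)) stopf("assoc_maf outside [0, 0.5)")
  if (is.unsorted(cfg$depths, strictly = TRUE)) stopf("depth grid must be sorted ascending")
  if (!cfg$top_depth %in% cfg$depths) stopf("top_depth must be in the depth grid")
  if (!(cfg$epsilon > 0 && cfg$epsilon < 0.5)) stopf("epsilon outside (0, 0.5)")
  if (cfg$n_sites > cfg$chrom_length_bp) stopf("more sites than bp")
  miss_md <- setdiff(format_depth(cfg$depths), names(cfg$min_depth_map))
  if (length(miss_md)) stopf("min_depth_map lacks depths: %s", paste(miss_md, collapse = ", "))
  invisible(structure(cfg, class = "ExperimentConfig"))
}

format_depth <- function(d) format(d, trim = TRUE, drop0trailing = TRUE)

#' Read / write configuration as YAML
#'
#' @param path YAML file.
#' @return [read_config()]: an `ExperimentConfig` (defaults overridden by
#'   the file's entries).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  # YAML 1.1 treats exponent forms like "2.0e6" (no sign) as strings
  vals <- lapply(vals, function(v) {
    if (is.character(v) && length(v) == 1L &&
        grepl("^[-+]?[0-9.]+([eE][-+]?[0-9]+)?$", v)) as.numeric(v) else v
  })
  if (!is.null(vals$low_coverage_segments))
    vals$low_coverage_segments <- as.data.frame(vals$low_coverage_segments)
  if (!is.null(vals$min_depth_map))
    vals$min_depth_map <- unlist(vals$min_depth_map)
  do.call(default_config, c(list(seed = vals$seed %||% 1L),
                            vals[setdiff(names(vals), "seed")]))
}

#' @param cfg an `ExperimentConfig`.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  vals <- unclass(cfg)
  vals$low_coverage_segments <- as.list(vals$low_coverage_segments)
  vals$min_depth_map <- as.list(vals$min_depth_map)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @export
print.ExperimentConfig <- function(x, ...) {
  cat(sprintf("ExperimentConfig: %d sites / %.0f Mb, N=%d (%d cases), depths {%s}X, seed %d\n",
              x$n_sites, x$chrom_length_bp / 1e6, x$n_individuals, x$n_cases,
              paste(format_depth(x$depths), collapse = ", "), x$seed))
  invisible(x)
}
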