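#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the prioritization pipeline. Defaults
#' follow standard exome-filtering practice for recessive disease: sites with
#' read mapping quality below 20 are unreliable; only protein-affecting
#' classes are kept; any presence in a population database excludes a variant
#' from causal candidacy (a variant common enough to be catalogued is not a
#' fully penetrant recessive allele); the canonical splice dinucleotide
#' (2 intronic bases) counts as splice-site; bases under 5 reads are treated
#' as unsequenced and reported for orthogonal follow-up.
#'
#' @param min_mapping_quality minimum site mapping quality (default 20);
#'   variants with missing MQ are retained with a warning.
#' @param retained_impact_classes impact classes kept by [filter_impact()].
#' @param maf_exclusion_threshold database minor-allele-frequency at or above
#'   which presence excludes a variant (default 0: any presence excludes;
#'   entries present without a frequency always exclude).
#' @param splice_window intronic bases adjacent to an exon classified as
#'   splice-site (default 2).
#' @param depth_gap_threshold read depth below which a base counts as a
#'   coverage gap (default 5).
#' @param coverage_thresholds depths at which breadth-of-coverage fractions
#'   are reported (default `c(1, 10)`).
#' @param random_seed integer seed used by pipeline steps that randomize.
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(min_mapping_quality = 20,
                            retained_impact_classes = c("MISSENSE", "NONSENSE",
                                                        "SPLICE",
                                                        "FRAMESHIFT_INDEL",
                                                        "INFRAME_INDEL"),
                            maf_exclusion_threshold = 0,
                            splice_window = 2L,
                            depth_gap_threshold = 5,
                            coverage_thresholds = c(1, 10),
                            random_seed = 1L) {
  stopifnot(min_mapping_quality >= 0,
            maf_exclusion_threshold >= 0, maf_exclusion_threshold <= 1,
            splice_window >= 0, depth_gap_threshold >= 0,
            all(coverage_thresholds >= 0))
  bad <- setdiff(retained_impact_classes, IMPACT_CLASSES)
  if (length(bad)) stop("unknown impact class: ", paste(bad, collapse = ", "))
  structure(list(min_mapping_quality = min_mapping_quality,
                 retained_impact_classes = retained_impact_classes,
                 maf_exclusion_threshold = maf_exclusion_threshold,
                 splice_window = as.integer(splice_window),
                 depth_gap_threshold = depth_gap_threshold,
                 coverage_thresholds = sort(coverage_thresholds),
                 random_seed = as.integer(random_seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  cat("  min mapping quality     :", x$min_mapping_quality, "\n")
  cat("  retained impact classes :",
      paste(x$retained_impact_classes, collapse = ", "), "\n")
  cat("  MAF exclusion threshold :", x$maf_exclusion_threshold, "\n")
  cat("  splice window (bp)      :", x$splice_window, "\n")
  cat("  depth gap threshold     :", x$depth_gap_threshold, "\n")
  cat("  coverage thresholds     :",
      paste(x$coverage_thresholds, collapse = ", "), "\n")
  invisible(x)
}

#' Functional impact classes
#'
#' All impact classes assigned by [annotate_variants()].
#' @export
IMPACT_CLASSES <- c("MISSENSE", "NONSENSE", "SYNONYMOUS", "SPLICE",
                    "FRAMESHIFT_INDEL", "INFRAME_INDEL", "INTRONIC", "UTR",
                    "INTERGENIC")
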