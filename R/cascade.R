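#' Mapping-quality filter
#'
#' Retains variants whose site mapping quality meets the configured minimum.
#' Variants with no recorded mapping quality are retained, with a warning
#' giving their count (they cannot be judged, and dropping them silently
#' would hide signal).
#'
#' @param vs a [variant_set()].
#' @param cfg a [pipeline_config()].
#' @return filtered `variant_set`.
#' @export
filter_quality <- function(vs, cfg = pipeline_config()) {
  mq <- vs$site$mq
  n_missing <- sum(is.na(mq))
  if (n_missing)
    warning(n_missing, " variant(s) without mapping quality retained")
  vs[is.na(mq) | mq >= cfg$min_mapping_quality]
}

#' Functional-impact filter
#'
#' Retains variants whose impact class is in the configured retained set
#' (by default the protein-affecting classes: missense, nonsense, splice and
#' coding indels; synonymous, non-splice intronic, UTR and intergenic
#' variants are removed).
#'
#' @param vs a [variant_set()].
#' @param ann annotation data.frame from [annotate_variants()] covering every
#'   variant in `vs`.
#' @param cfg a [pipeline_config()].
#' @return filtered `variant_set`.
#' @export
filter_impact <- function(vs, ann, cfg = pipeline_config()) {
  impact <- ann$impact[match(vs$site$key, ann$key)]
  if (anyNA(impact))
    stop("unannotated variant(s): annotate before impact filtering")
  vs[impact %in% cfg$retained_impact_classes]
}

#' Population-database subtraction
#'
#' Removes variants present in the database: any entry recorded without a
#' frequency (membership semantics, as for a control-exome set) excludes,
#' and entries with a catalogued MAF exclude when the MAF is at or above
#' `maf_exclusion_threshold` (default 0, i.e. any catalogued presence
#' excludes). Subtraction is by site/allele identity and is genotype-blind.
#'
#' @param vs a [variant_set()].
#' @param db a [population_db()].
#' @param cfg a [pipeline_config()].
#' @return filtered `variant_set`.
#' @export
subtract_database <- function(vs, db, cfg = pipeline_config()) {
  m <- db$maf[match(vs$site$key, names(db$maf))]
  present <- vs$site$key %in% names(db$maf)
  excluded <- present & (is.na(m) | m >= cfg$maf_exclusion_threshold)
  vs[!excluded]
}

#' Gene-panel restriction
#'
#' Retains variants annotated to a gene in the panel of reported disease
#' genes; variants without a gene (intergenic) are removed.
#'
#' @param vs a [variant_set()].
#' @param ann annotation data.frame from [annotate_variants()].
#' @param panel character vector of panel gene symbols (case-insensitive),
#'   e.g. from [read_gene_panel()].
#' @return filtered `variant_set`.
#' @export
restrict_to_panel <- function(vs, ann, panel) {
  gene <- ann$gene[match(vs$site$key, ann$key)]
  vs[!is.na(gene) & toupper(gene) %in% toupper(panel)]
}

#' Run the per-sample filtering funnel
#'
#' Applies the full prioritization cascade to one sample's carried variants
#' in fixed order: mapping quality, functional impact, subtraction against
#' each population database in the order given (a control-exome set first,
#' then a SNP catalogue, mirrors common practice), then restriction to the
#' disease-gene panel. Two descriptive pre-stage counts are recorded first:
#' all carried variants, and carried variants in coding regions (CDS or
#' splice window).
#'
#' @param sample a sample id in `vs`.
#' @param vs the multi-sample [variant_set()].
#' @param ann annotation data.frame from [annotate_variants()].
#' @param dbs list of [population_db()] objects, applied in order.
#' @param panel character vector of panel gene symbols.
#' @param cfg a [pipeline_config()].
#' @param audit if `TRUE`, record retained variant keys per stage.
#' @return list with `variants` (the final `variant_set`) and `funnel`
#'   (a `filter_funnel`: data.frame of stage name and retained count, plus a
#'   `keys` attribute in audit mode).
#' @export
run_funnel <- function(sample, vs, ann, dbs, panel,
                       cfg = pipeline_config(), audit = FALSE) {
  coding <- c("MISSENSE", "NONSENSE", "SYNONYMOUS", "SPLICE",
              "FRAMESHIFT_INDEL", "INFRAME_INDEL")
  cur <- sample_variants(vs, sample)
  impact <- function(v) ann$impact[match(v$site$key, ann$key)]
  stages <- list()
  keys <- list()
  note <- function(name, v, pre = FALSE) {
    stages[[length(stages) + 1L]] <<- data.frame(stage = name,
                                                 retained = n_variants(v),
                                                 pre_stage = pre)
    if (audit) keys[[name]] <<- v$site$key
  }
  # two descriptive pre-stages (not part of the cascade ordering)
  note("total variants", cur, pre = TRUE)
  note("coding variants", cur[impact(cur) %in% coding], pre = TRUE)
  cur <- filter_quality(cur, cfg)
  note(sprintf("mapping quality >= %s", cfg$min_mapping_quality), cur)
  cur <- filter_impact(cur, ann, cfg)
  note("missense, nonsense, splice and indel variants", cur)
  for (db in dbs) {
    cur <- subtract_database(cur, db, cfg)
    note(paste0("after ", db$name, " filtering"), cur)
  }
  cur <- restrict_to_panel(cur, ann, panel)
  note("variants in panel genes", cur)
  funnel <- do.call(rbind, stages)
  funnel$sample <- sample
  funnel <- funnel[, c("sample", "stage", "retained", "pre_stage")]
  # descriptive pre-stages aside, cascade stage counts are non-increasing
  # and bounded by the raw total
  main <- funnel$retained[!funnel$pre_stage]
  stopifnot(all(diff(main) <= 0), main[1] <= funnel$retained[1])
  if (audit) attr(funnel, "keys") <- keys
  class(funnel) <- c("filter_funnel", "data.frame")
  list(variants = cur, funnel = funnel)
}

#' @export
print.filter_funnel <- function(x, ...) {
  cat("filter_funnel for sample", x$sample[1], "\n")
  print.data.frame(x[, c("stage", "retained")], row.names = FALSE)
  invisible(x)
}
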