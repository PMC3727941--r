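#' Run the full prioritization pipeline
#'
#' Orchestrates the whole analysis for one family: annotate all variants,
#' run the filtering funnel per affected sequenced sample, intersect the
#' siblings' surviving variants, apply the post-sharing frequency-catalogue
#' exclusion, call recessive-model candidates, check parental trans-phase
#' segregation, count control-cohort carriers and attach external in-silico
#' scores and protein-domain labels.
#'
#' @param vs a [variant_set()] (e.g. from [read_vcf()]); its samples must
#'   cover every pedigree member with `sample_available`.
#' @param ped a [pedigree()].
#' @param genes a [gene_model_list()].
#' @param panel character vector of panel gene symbols (non-empty).
#' @param funnel_dbs list of [population_db()] applied inside the per-sample
#'   funnel, in order (conventionally a control-exome set then a SNP
#'   catalogue).
#' @param exclusion_dbs list of [population_db()] applied to the shared
#'   variant set after sibling intersection (conventionally a
#'   genomes-project frequency catalogue); may be empty.
#' @param scores optional score table from [read_score_table()].
#' @param domain_map optional domain map from [read_domain_map()].
#' @param cohort optional [control_cohort()] for carrier counting.
#' @param depth optional list of [depth_track()] for gap auditing of genes
#'   with confirmed or uncertain candidates.
#' @param cfg a [pipeline_config()].
#' @return object of class `pipeline_result`: list with `funnels` (one
#'   `filter_funnel` per affected sample), `shared` (keys after
#'   intersection), `shared_after_exclusion`, `calls` (candidate calls with
#'   phase and segregation set), `candidates` (report data.frame, see
#'   [candidate_table()]), `gaps` (per audited gene), `status` (`"confirmed"`,
#'   `"uncertain"` or `"none"`) and `ann` (the annotation table).
#' @export
run_pipeline <- function(vs, ped, genes, panel, funnel_dbs,
                         exclusion_dbs = list(), scores = NULL,
                         domain_map = NULL, cohort = NULL, depth = NULL,
                         cfg = pipeline_config()) {
  if (!length(panel)) stop("gene panel is empty")
  need <- ped$id[ped$sample_available]
  missing <- setdiff(need, vs$samples)
  if (length(missing))
    stop("pedigree sample(s) absent from VCF: ",
         paste(missing, collapse = ", "))
  aff <- affected_samples(ped)
  if (!length(aff)) stop("no affected individual with an available sample")

  ann <- annotate_variants(vs, genes, cfg)
  ann <- assign_domain(join_scores(ann, scores), domain_map)

  runs <- lapply(aff, function(s)
    run_funnel(s, vs, ann, funnel_dbs, panel, cfg, audit = TRUE))
  names(runs) <- aff
  funnels <- lapply(runs, `[[`, "funnel")
  shared <- shared_variants(lapply(runs, function(r) r$variants$site$key))

  kept <- subset_by_key(vs, shared)
  for (db in exclusion_dbs) kept <- subtract_database(kept, db, cfg)
  shared_kept <- kept$site$key

  calls <- call_recessive(shared_kept, vs, ann, ped)
  calls <- lapply(calls, check_segregation, vs = vs, ped = ped)
  # cis-configured pairs are excluded from the causative report but kept in
  # the audit list
  report_calls <- Filter(function(cl) cl$phase_status != "CIS_REJECTED",
                         calls)
  candidates <- candidate_table(report_calls, vs, ann, ped, cohort, genes)

  gaps <- NULL
  if (!is.null(depth) && length(report_calls)) {
    audit_genes <- unique(vapply(report_calls, `[[`, "", "gene"))
    gaps <- do.call(rbind, lapply(audit_genes, function(g)
      gaps_for_gene(depth, genes[[g]], cfg)))
  }

  confirmed <- any(vapply(report_calls, function(cl)
    cl$model %in% c("COMPOUND_HET", "HOMOZYGOUS") &&
      cl$segregation_status == "CONSISTENT" &&
      cl$phase_status %in% c("TRANS_CONFIRMED", "NOT_APPLICABLE"),
    logical(1)))
  uncertain <- length(report_calls) > 0
  status <- if (confirmed) "confirmed" else if (uncertain) "uncertain"
            else "none"
  structure(list(funnels = funnels, shared = shared,
                 shared_after_exclusion = shared_kept, calls = calls,
                 candidates = candidates, gaps = gaps, status = status,
                 ann = ann),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$status, "\n")
  cat("  shared variants:", length(x$shared),
      "| after frequency exclusion:", length(x$shared_after_exclusion), "\n")
  for (cl in x$calls) print(cl)
  invisible(x)
}

#' Candidate report table
#'
#' Formats candidate calls the way clinical exome reports tabulate them:
#' one row per variant of each call, with family id, genomic position,
#' nucleotide change, amino-acid change, exon/intron location, protein
#' domain, control carrier counts (`x/n`), conservation and external
#' predictor scores, and a section label separating pathologic candidates
#' (trans-confirmed compound het or consistent homozygous) from variants
#' with uncertain pathogenicity.
#'
#' @param calls list of candidate calls (post-[check_segregation()]).
#' @param vs the [variant_set()].
#' @param ann annotation table (with scores and domains joined).
#' @param ped the [pedigree()].
#' @param cohort optional [control_cohort()].
#' @param genes optional [gene_model_list()], used to number exons in the
#'   `location` column (transcript order).
#' @return data.frame with one row per candidate variant.
#' @export
candidate_table <- function(calls, vs, ann, ped, cohort = NULL,
                            genes = NULL) {
  rows <- list()
  for (cl in calls) {
    pathologic <- (cl$model == "COMPOUND_HET" &&
                     cl$phase_status == "TRANS_CONFIRMED" &&
                     cl$segregation_status == "CONSISTENT") ||
      (cl$model == "HOMOZYGOUS" && cl$segregation_status == "CONSISTENT")
    section <- if (pathologic) "Pathologic variant"
               else "Variants with uncertain pathogenicity"
    for (k in cl$variants) {
      a <- ann[match(k, ann$key), ]
      i <- match(k, vs$site$key)
      ctrl <- if (is.null(cohort)) NA_character_ else {
        cc <- count_carriers(k, cohort)
        sprintf("%d/%d", cc["carriers"], cc["n"])
      }
      loc <- if (a$impact %in% c("SPLICE", "INTRONIC")) "Intron"
             else exon_label(vs$site$pos[i], cl$gene, genes)
      rows[[length(rows) + 1L]] <- data.frame(
        section = section, family = ped$fid[1], gene = cl$gene,
        position = sprintf("Chr%s:%d", norm_contig(vs$site$contig[i]),
                           vs$site$pos[i]),
        nucleotide_change = a$cdna,
        amino_acid_change = if (!is.na(a$ivs)) a$ivs else a$protein,
        location = loc, domain = a$domain, model = cl$model,
        phase = cl$phase_status, segregation = cl$segregation_status,
        controls = ctrl, conserved = a$conserved, sift = a$sift,
        polyphen2 = a$polyphen2, mupro = a$mupro,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(section = character(), family = character(),
                      gene = character(), position = character(),
                      nucleotide_change = character(),
                      amino_acid_change = character(),
                      location = character(), domain = character(),
                      model = character(), phase = character(),
                      segregation = character(), controls = character(),
                      conserved = logical(), sift = numeric(),
                      polyphen2 = numeric(), mupro = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$section), , drop = FALSE]
}

# "Exon k" label (transcript order) when the gene model is at hand.
exon_label <- function(pos, gene_sym, genes) {
  if (is.null(genes) || !gene_sym %in% names(genes)) return("Exon")
  ex <- tx_exons(genes[[gene_sym]])
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (!length(hit)) return("Exon")
  paste("Exon", hit[1])
}

#' Write the funnel table
#'
#' Tab-separated table with one row per funnel stage and one column per
#' sample, in stage order, with a final `shared variants` row for families
#' with several affected samples (`-` for single-sample runs).
#'
#' @param funnels list of `filter_funnel` objects (same stage structure).
#' @param path output path.
#' @param shared optional count of shared variants to append.
#' @return the table, invisibly; written to `path` when given.
#' @export
write_funnel <- function(funnels, path = NULL, shared = NULL) {
  stopifnot(length(funnels) >= 1)
  stages <- funnels[[1]]$stage
  tab <- data.frame(stage = stages, stringsAsFactors = FALSE)
  for (f in funnels) {
    stopifnot(identical(f$stage, stages))
    tab[[f$sample[1]]] <- f$retained
  }
  if (!is.null(shared)) {
    row <- c(list(stage = "shared variants"),
             as.list(rep(if (length(funnels) > 1) as.character(shared) else
               "-", length(funnels))))
    tab[] <- lapply(tab, as.character)
    names(row) <- names(tab)
    tab <- rbind(tab, as.data.frame(row, stringsAsFactors = FALSE,
                                    check.names = FALSE))
  }
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Write the candidate report
#'
#' @param candidates data.frame from [candidate_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "-")
  invisible(path)
}

#' Run manifest
#'
#' Records a reproducibility manifest for a pipeline run: the configuration,
#' the seed, input and output file digests and accumulated warnings. Reruns
#' on identical inputs give identical digests.
#'
#' @param inputs named character vector of input paths.
#' @param outputs named character vector of output paths.
#' @param cfg a [pipeline_config()].
#' @param warnings character vector of warning messages.
#' @param path optional JSON output path.
#' @return the manifest list, invisibly.
#' @export
run_manifest <- function(inputs, outputs, cfg, warnings = character(),
                         path = NULL) {
  digest <- function(p) unname(tools::md5sum(p[file.exists(p)]))
  man <- list(config = unclass(cfg), seed = cfg$random_seed,
              inputs = as.list(setNames(digest(inputs), names(inputs))),
              outputs = as.list(setNames(digest(outputs), names(outputs))),
              warnings = warnings)
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(man)
}
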