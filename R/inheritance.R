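SEX_CONTIGS <- c("X", "Y", "MT", "M")

#' Intersect affected siblings' candidate variants
#'
#' In a family with several affected, sequenced siblings a causal recessive
#' genotype must be present in all of them, so the per-sample filtered
#' variant lists are intersected by variant identity key. With a single
#' affected sample the set is returned unchanged.
#'
#' @param sets list of character vectors of variant keys, one per affected
#'   sample (at least one).
#' @return character vector of shared variant keys.
#' @export
shared_variants <- function(sets) {
  stopifnot(length(sets) >= 1)
  Reduce(intersect, sets)
}

new_call <- function(gene, keys, model, missing_geno = FALSE,
                     flagged = FALSE) {
  structure(list(gene = gene, variants = keys, model = model,
                 phase_status = "NOT_APPLICABLE",
                 segregation_status = "UNTESTABLE",
                 missing_genotypes = missing_geno, flagged = flagged),
            class = "candidate_call")
}

#' @export
print.candidate_call <- function(x, ...) {
  cat(sprintf("%s: %s [%s] phase=%s segregation=%s\n", x$gene,
              paste(x$variants, collapse = " + "), x$model,
              x$phase_status, x$segregation_status))
  invisible(x)
}

#' Call recessive-model candidates per gene
#'
#' Groups shared variants by gene and applies the autosomal recessive model
#' over the affected, sequenced siblings' genotypes: a variant homozygous
#' alternate in every affected sibling is a `HOMOZYGOUS` call; otherwise, if
#' two or more variants of the gene are heterozygous in every affected
#' sibling, each pair is a `COMPOUND_HET` call (genes with three or more
#' such variants emit all pairs, flagged); a single heterozygous variant
#' without a partner is `SINGLE_HET_UNCERTAIN`. Variants on sex chromosomes
#' are excluded (autosomal recessive scope). Missing genotypes in an
#' affected sample count as non-qualifying and flag the call.
#'
#' @param shared character vector of shared variant keys.
#' @param vs the multi-sample [variant_set()] (for genotypes).
#' @param ann annotation data.frame from [annotate_variants()].
#' @param ped a [pedigree()].
#' @return list of `candidate_call` objects (possibly empty).
#' @export
call_recessive <- function(shared, vs, ann, ped) {
  aff <- affected_samples(ped)
  if (!length(shared) || !length(aff)) return(list())
  keep <- shared[!(sub(":.*$", "", shared) %in% SEX_CONTIGS)]
  gene <- ann$gene[match(keep, ann$key)]
  calls <- list()
  for (g in unique(gene[!is.na(gene)])) {
    keys <- keep[!is.na(gene) & gene == g]
    gmat <- vs$geno[match(keys, vs$site$key), aff, drop = FALSE]
    missing_any <- anyNA(gmat)
    hom_all <- apply(gmat, 1, function(x) all(!is.na(x) & x == 2))
    het_all <- apply(gmat, 1, function(x) all(!is.na(x) & x == 1))
    for (k in keys[hom_all])
      calls[[length(calls) + 1L]] <- new_call(g, k, "HOMOZYGOUS",
                                              missing_any)
    hets <- keys[het_all]
    if (length(hets) >= 2) {
      pairs <- combn(hets, 2, simplify = FALSE)
      for (p in pairs)
        calls[[length(calls) + 1L]] <-
          new_call(g, p, "COMPOUND_HET", missing_any,
                   flagged = length(hets) > 2)
    } else if (length(hets) == 1 && !any(hom_all)) {
      calls[[length(calls) + 1L]] <- new_call(g, hets, "SINGLE_HET_UNCERTAIN",
                                              missing_any)
    }
  }
  calls
}

# All phased diplotypes (2 haplotypes x 2 variants, 0/1 entries) consistent
# with an allele-count genotype pair; NA genotypes are unconstrained.
diplotypes <- function(g) {
  out <- list()
  for (h1a in 0:1) for (h1b in 0:1) for (h2a in 0:1) for (h2b in 0:1) {
    if ((!is.na(g[1]) && h1a + h2a != g[1]) ||
        (!is.na(g[2]) && h1b + h2b != g[2])) next
    out[[length(out) + 1L]] <- rbind(c(h1a, h1b), c(h2a, h2b))
  }
  out
}

# Phase of a two-variant pair in a double-heterozygous child, by exhaustive
# enumeration of parental diplotypes and transmissions: TRANS_CONFIRMED when
# every Mendelian explanation puts the two variants on opposite parental
# origins and neither (unaffected) parent is homozygous alternate for either
# variant (full-penetrance overlay); CIS_REJECTED when every explanation
# puts both on one parental haplotype; PHASE_UNKNOWN otherwise (ambiguous or
# Mendelian-impossible).
phase_for_pair <- function(gfa, gmo) {
  kinds <- character()
  for (df in diplotypes(gfa)) for (dm in diplotypes(gmo)) {
    for (i in 1:2) for (j in 1:2) {
      p <- df[i, ]; m <- dm[j, ]
      if (p[1] + m[1] != 1L || p[2] + m[2] != 1L) next
      kinds <- c(kinds, if ((p[1] & m[2]) || (p[2] & m[1])) "trans"
                        else "cis")
    }
  }
  kinds <- unique(kinds)
  hom <- any(c(gfa, gmo) %in% 2L)
  if (identical(kinds, "trans") && !hom) "TRANS_CONFIRMED"
  else if (identical(kinds, "cis")) "CIS_REJECTED"
  else "PHASE_UNKNOWN"
}

geno_of <- function(vs, key, sample) {
  if (is.na(sample) || !(sample %in% vs$samples)) return(NA_integer_)
  vs$geno[match(key, vs$site$key), sample]
}

carrier_of <- function(g) !is.na(g) & g >= 1

#' Check parental segregation and trans-phase of a candidate
#'
#' For a `COMPOUND_HET` call with both parents sequenced, the trans/cis
#' configuration is inferred by exhaustive enumeration of parental
#' diplotypes and transmissions consistent with the observed genotypes: the
#' pair is `TRANS_CONFIRMED` when every Mendelian explanation places the two
#' variants on opposite parental origins — in the typical case, each parent
#' heterozygous for exactly one distinct variant of the pair — and neither
#' parent is homozygous alternate for either (an unaffected parent
#' homozygous for a causal allele contradicts a fully penetrant recessive
#' model); the pair is `CIS_REJECTED` when every explanation puts both
#' variants on one parental haplotype (e.g. both carried by one parent and
#' absent from the other); anything else — ambiguity, Mendelian
#' impossibility, or unsequenced parents — is `PHASE_UNKNOWN`. For `HOMOZYGOUS` calls, segregation is
#' `CONSISTENT` when every sequenced parent is a carrier. Segregation is
#' `INCONSISTENT` when a child genotype is not derivable from sequenced
#' parents, when an unaffected parent is homozygous alternate for a causal
#' variant, or when an unaffected sibling provably carries the full causal
#' genotype; it is `UNTESTABLE` when no parent is sequenced.
#'
#' @param call a `candidate_call` from [call_recessive()].
#' @param vs the multi-sample [variant_set()].
#' @param ped a [pedigree()].
#' @return the call with `phase_status` and `segregation_status` set.
#' @export
check_segregation <- function(call, vs, ped) {
  aff <- affected_samples(ped)
  pp <- parent_pair(ped, aff[1])
  fa <- pp$father; mo <- pp$mother
  keys <- call$variants
  gfa <- vapply(keys, geno_of, integer(1), vs = vs, sample = fa)
  gmo <- vapply(keys, geno_of, integer(1), vs = vs, sample = mo)
  parents_sampled <- !is.na(fa) && !is.na(mo)

  mendel_ok <- function() {
    # per-site: every affected child's allele count must be achievable from
    # the sequenced parents' genotypes (unsequenced parent contributes 0/1)
    for (i in seq_along(keys)) {
      for (s in aff) {
        gc <- geno_of(vs, keys[i], s)
        if (is.na(gc)) next
        from <- function(g) if (is.na(g)) 0:1 else unique(c(
          if (g >= 1) 1L else NULL, if (g <= 1) 0L else NULL))
        ok <- any(outer(from(gfa[i]), from(gmo[i]), `+`) == gc)
        if (!ok) return(FALSE)
      }
    }
    TRUE
  }

  unaffected <- ped$id[!(ped$affected %in% TRUE) & ped$sample_available &
                         ped$id %in% vs$samples]

  if (call$model == "COMPOUND_HET") {
    if (!parents_sampled) {
      call$phase_status <- "PHASE_UNKNOWN"
      call$segregation_status <- "UNTESTABLE"
      return(call)
    }
    hom_parent <- any(gfa %in% 2L) || any(gmo %in% 2L)
    call$phase_status <- phase_for_pair(gfa, gmo)
    trans <- call$phase_status == "TRANS_CONFIRMED"
    inconsistent <- !mendel_ok() || hom_parent
    if (trans && length(unaffected)) {
      # with each parent able to transmit only one variant of the pair, an
      # unaffected sibling heterozygous for both necessarily carries them in
      # trans, violating full penetrance
      sibs <- setdiff(unaffected, c(fa, mo))
      for (s in sibs) {
        gs <- vapply(keys, geno_of, integer(1), vs = vs, sample = s)
        if (all(carrier_of(gs))) inconsistent <- TRUE
      }
    }
    call$segregation_status <- if (inconsistent) "INCONSISTENT"
                               else "CONSISTENT"
  } else if (call$model == "HOMOZYGOUS") {
    call$phase_status <- "NOT_APPLICABLE"
    if (is.na(fa) && is.na(mo)) {
      call$segregation_status <- "UNTESTABLE"
    } else {
      sampled <- c(if (!is.na(fa)) gfa, if (!is.na(mo)) gmo)
      ok <- all(carrier_of(sampled)) && mendel_ok()
      hom_unaff <- any(vapply(unaffected, function(s)
        any(vapply(keys, geno_of, integer(1), vs = vs, sample = s) %in% 2L),
        logical(1)))
      call$segregation_status <- if (!ok || hom_unaff) "INCONSISTENT"
                                 else "CONSISTENT"
    }
  } else { # SINGLE_HET_UNCERTAIN
    call$phase_status <- "PHASE_UNKNOWN"
    call$segregation_status <- "UNTESTABLE"
  }
  call
}

#' Control cohort container
#'
#' @param geno integer matrix of allele counts, one row per variant key
#'   (rownames are keys), one column per control individual.
#' @return object of class `control_cohort` with fields `n` and `geno`.
#' @export
control_cohort <- function(geno) {
  structure(list(n = ncol(geno), geno = geno), class = "control_cohort")
}

#' @export
print.control_cohort <- function(x, ...) {
  cat(sprintf("control_cohort: %d individuals x %d variants\n",
              x$n, nrow(x$geno)))
  invisible(x)
}

#' Count carriers of a variant in a control cohort
#'
#' A carrier holds at least one alternate allele (heterozygous or
#' homozygous). A key the cohort was not genotyped at yields 0 carriers by
#' convention, with a warning.
#'
#' @param key a variant key.
#' @param cohort a [control_cohort()].
#' @return named numeric vector `c(carriers =, n =)`.
#' @export
count_carriers <- function(key, cohort) {
  if (cohort$n == 0) return(c(carriers = 0, n = 0))
  i <- match(key, rownames(cohort$geno))
  if (is.na(i)) {
    warning("cohort not genotyped at ", key, "; reporting 0 carriers")
    return(c(carriers = 0, n = cohort$n))
  }
  g <- cohort$geno[i, ]
  c(carriers = sum(!is.na(g) & g >= 1), n = cohort$n)
}
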