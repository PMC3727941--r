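# Worked-example families, reconstructed from published genotype figures and
# candidate tables on the synthetic toy gene models. All sequence content is
# synthetic; only the three reported hg19 variant positions are mirrored.

#' Construct a coding SNV for a gene model
#'
#' @param g a [gene_model()].
#' @param cpos 1-based CDS coordinate.
#' @param calt alternate base in coding-strand orientation.
#' @return one-row data.frame with `contig`, `pos`, `ref`, `alt` (genomic
#'   strand).
#' @export
cds_snv <- function(g, cpos, calt) {
  cref <- substr(g$cds_seq, cpos, cpos)
  stopifnot(nchar(calt) == 1, cref != calt)
  pos <- genomic_coord(g, cpos)
  if (g$strand == "+") {
    data.frame(contig = g$contig, pos = pos, ref = cref, alt = calt,
               stringsAsFactors = FALSE)
  } else {
    data.frame(contig = g$contig, pos = pos, ref = revcomp(cref),
               alt = revcomp(calt), stringsAsFactors = FALSE)
  }
}

# first synonymous third-base substitution in the CDS (deterministic)
synonymous_site <- function(g) {
  n <- nchar(g$cds_seq) %/% 3L
  for (ci in 2:(n - 1L)) {
    codon <- substr(g$cds_seq, (ci - 1L) * 3L + 1L, ci * 3L)
    aa0 <- Biostrings::GENETIC_CODE[[codon]]
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, 3, 3)) next
      mut <- codon; substr(mut, 3, 3) <- b
      if (Biostrings::GENETIC_CODE[[mut]] == aa0)
        return(cds_snv(g, (ci - 1L) * 3L + 3L, b))
    }
  }
  stop("no synonymous substitution found")
}

example_scaffold <- function() {
  panel_genes <- toy_deafness_genes()
  bg_genes <- toy_background_genes(2)
  list(genes = gene_model_list(c(unclass(panel_genes), unclass(bg_genes))),
       panel_genes = panel_genes, bg_genes = bg_genes,
       panel = names(panel_genes), domain_map = toy_domain_map())
}

#' Worked example: compound-heterozygous quartet
#'
#' Reconstructs the solved family of the study on toy gene models: two
#' affected siblings and their unaffected parents, with the heterozygous
#' splice-donor variant (c.4320+1G>A, IVS11+1) inherited from the mother and
#' the heterozygous missense p.R2146Q from the father, both carried by both
#' siblings. A third shared missense variant rides the paternal haplotype
#' but is catalogued at minor allele frequency 0.002 (it must fall to the
#' post-sharing frequency exclusion), and additional variants exercise every
#' funnel stage: a low-mapping-quality site, a synonymous site, variants
#' present in the control-exome and SNP-catalogue databases, a non-panel
#' gene variant and two proband-private panel variants (so the siblings'
#' panel candidate lists have sizes 5 and 3 with 3 shared).
#'
#' @return list with everything [run_pipeline()] consumes: `vs`, `ped`,
#'   `genes`, `panel`, `funnel_dbs`, `exclusion_dbs`, `scores`,
#'   `domain_map`, `cohort`, `depth`, plus `keys` (named causal/decoy keys).
#' @export
sr903_example <- function() {
  sc <- example_scaffold()
  myo <- sc$panel_genes$MYO15A
  grhl2 <- sc$panel_genes$GRHL2
  tecta <- sc$panel_genes$TECTA
  bg1 <- sc$bg_genes[[1]]

  splice <- data.frame(contig = "17", pos = 18035881L, ref = "G", alt = "A",
                       stringsAsFactors = FALSE)
  missense <- cds_snv(myo, 6437L, "A")          # p.R2146Q
  freq_decoy <- missense_site(myo, 1800L)        # catalogued at MAF 0.002
  grhl2_priv <- missense_site(grhl2, 200L)
  tecta_priv <- missense_site(tecta, 700L)
  low_mq <- missense_site(myo, 500L)
  syn <- synonymous_site(myo)
  ctl_present <- missense_site(myo, 950L)
  snp_present <- missense_site(myo, 1200L)
  bg_var <- missense_site(bg1, 50L)

  site <- rbind(splice, missense, freq_decoy[1:4], grhl2_priv[1:4],
                tecta_priv[1:4], low_mq[1:4], syn, ctl_present[1:4],
                snp_present[1:4], bg_var[1:4])
  site$mq <- c(58, 60, 55, 47, 52, 15, 44, 51, 49, 57)
  #            FA MO  P  B   (proband SR-903, sibling SR-903B)
  geno <- rbind(c(0, 1, 1, 1),   # splice (maternal)
                c(1, 0, 1, 1),   # missense (paternal)
                c(1, 0, 1, 1),   # frequency decoy (paternal haplotype)
                c(1, 0, 1, 0),   # GRHL2 proband-private
                c(0, 1, 1, 0),   # TECTA proband-private
                c(1, 0, 1, 1),   # low MQ
                c(0, 1, 1, 1),   # synonymous
                c(1, 0, 1, 1),   # control-exome present
                c(0, 1, 1, 1),   # SNP-catalogue present
                c(1, 0, 1, 1))   # non-panel gene
  colnames(geno) <- c("SR-903F", "SR-903M", "SR-903", "SR-903B")
  vs <- variant_set(site, geno)
  key <- vs$site$key

  ped <- quartet_pedigree(father = "SR-903F", mother = "SR-903M",
                          children = c("SR-903", "SR-903B"),
                          affected = c(TRUE, TRUE), fid = "SR-903")

  funnel_dbs <- list(
    population_db("control_exome", setNames(NA_real_, key[8])),
    population_db("snp_catalogue", setNames(0.12, key[9])))
  exclusion_dbs <- list(
    population_db("frequency_catalogue", setNames(0.002, key[3])))

  scores <- data.frame(
    key = key[c(1, 2)], conserved = c(TRUE, TRUE),
    sift = c(NA, 0), polyphen2 = c(NA, 0.99), mupro = c(NA, -0.743),
    stringsAsFactors = FALSE)

  cohort <- simulate_controls(key[1:3], 409, seed = 409L)

  span <- gene_span(myo)
  depth <- rep(56L, span[2] - span[1] + 1L)
  hole <- function(from, width) {
    idx <- (from - span[1] + 1L):(from - span[1] + width)
    depth[idx] <<- 0L
  }
  hole(myo$exons$start[5] + 40L, 25L)    # exonic: must be audited
  hole(myo$exons$end[20] + 150L, 40L)    # deep intronic: must be ignored
  list(vs = vs, ped = ped, genes = sc$genes, panel = sc$panel,
       funnel_dbs = funnel_dbs, exclusion_dbs = exclusion_dbs,
       scores = scores, domain_map = sc$domain_map, cohort = cohort,
       depth = list(depth_track(myo$contig, span[1], depth)),
       keys = c(splice = key[1], missense = key[2], freq_decoy = key[3]))
}

#' Worked example: affected sib pair without parental samples
#'
#' Reconstructs the uncertain family of the study: the proband carries three
#' panel-gene candidate variants (toy analogues of p.Q445R, p.T1321S and the
#' key missense p.S2161F), only the last shared with the affected sibling;
#' parental DNA is unavailable, so the surviving single heterozygous variant
#' cannot be phased or segregation-tested. A second shared missense variant
#' is present in the control-exome database and so is removed inside the
#' funnel.
#'
#' @return list as in [sr903_example()].
#' @export
sr285_example <- function() {
  sc <- example_scaffold()
  myo <- sc$panel_genes$MYO15A
  grhl2 <- sc$panel_genes$GRHL2
  tecta <- sc$panel_genes$TECTA
  bg1 <- sc$bg_genes[[1]]

  s2161f <- cds_snv(myo, 6482L, "T")     # p.S2161F
  q445r <- cds_snv(grhl2, 1334L, "G")    # p.Q445R
  t1321s <- cds_snv(tecta, 3961L, "T")   # p.T1321S
  ctl_present <- missense_site(myo, 1220L)  # control-exome polymorphism
  low_mq <- missense_site(myo, 333L)
  syn <- synonymous_site(tecta)
  snp_present <- missense_site(grhl2, 101L)
  bg_var <- missense_site(bg1, 80L)

  site <- rbind(s2161f, q445r, t1321s, ctl_present[1:4], low_mq[1:4], syn,
                snp_present[1:4], bg_var[1:4])
  site$mq <- c(59, 53, 48, 50, 12, 45, 51, 56)
  #             P  S   (proband SR-285, affected sibling SR-285S)
  geno <- rbind(c(1, 1),   # p.S2161F: shared
                c(1, 0),   # p.Q445R: proband only
                c(1, 0),   # p.T1321S: proband only
                c(1, 1),   # shared but in control exome
                c(1, 1),
                c(1, 1),
                c(1, 0),
                c(1, 1))
  colnames(geno) <- c("SR-285", "SR-285S")
  vs <- variant_set(site, geno)
  key <- vs$site$key

  ped <- quartet_pedigree(father = "SR-285F", mother = "SR-285M",
                          children = c("SR-285", "SR-285S"),
                          affected = c(TRUE, TRUE),
                          sampled = c(FALSE, FALSE, TRUE, TRUE),
                          fid = "SR-285")

  funnel_dbs <- list(
    population_db("control_exome", setNames(NA_real_, key[4])),
    population_db("snp_catalogue", setNames(0.2, key[7])))
  exclusion_dbs <- list(population_db("frequency_catalogue",
                                      setNames(numeric(), character())))
  scores <- data.frame(key = key[1], conserved = TRUE, sift = 0,
                       polyphen2 = 1, mupro = -0.543,
                       stringsAsFactors = FALSE)
  cohort <- simulate_controls(key[1], 409, seed = 409L)

  span <- gene_span(myo)
  depth <- rep(50L, span[2] - span[1] + 1L)
  idx <- (myo$exons$start[12] - span[1] + 1L):(myo$exons$end[12] - span[1] + 1L)
  depth[idx] <- 2L                        # a whole low-coverage exon
  list(vs = vs, ped = ped, genes = sc$genes, panel = sc$panel,
       funnel_dbs = funnel_dbs, exclusion_dbs = exclusion_dbs,
       scores = scores, domain_map = sc$domain_map, cohort = cohort,
       depth = list(depth_track(myo$contig, span[1], depth)),
       keys = c(s2161f = key[1], q445r = key[2], t1321s = key[3]))
}
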