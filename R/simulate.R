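#' Quartet pedigree helper
#'
#' Builds the standard study unit: two unaffected parents and their
#' children, all with available samples unless stated otherwise.
#'
#' @param father,mother parental ids.
#' @param children character vector of child ids.
#' @param affected logical vector over children.
#' @param sampled logical vector over all individuals (parents first), or a
#'   single value.
#' @param fid family id.
#' @return a [pedigree()].
#' @export
quartet_pedigree <- function(father = "FA", mother = "MO",
                             children = c("S1", "S2"),
                             affected = rep(TRUE, length(children)),
                             sampled = TRUE, fid = "FAM1") {
  n <- 2L + length(children)
  if (length(sampled) == 1L) sampled <- rep(sampled, n)
  pedigree(id = c(father, mother, children),
           father = c(NA, NA, rep(father, length(children))),
           mother = c(NA, NA, rep(mother, length(children))),
           sex = c(1, 2, rep(0, length(children))),
           affected = c(FALSE, FALSE, affected),
           sample_available = sampled, fid = fid)
}

#' Simulation configuration
#'
#' Declares the study conditions the simulator reproduces: an ascertained
#' nuclear family with a planted causal genotype in a panel gene that is
#' absent from every population database, a background of segregating
#' exome variation mostly present in the databases, decoy variants
#' exercising each exclusion rule, and per-base depth tracks with
#' low-coverage holes.
#'
#' @param ped a [pedigree()]; affected individuals must have parents in the
#'   pedigree when a causal model is planted.
#' @param panel_genes a [gene_model_list()] of panel genes.
#' @param background_genes a [gene_model_list()] of non-panel genes.
#' @param panel character vector of panel symbols.
#' @param n_background number of segregating background variant sites.
#' @param frac_catalogue fraction of background sites present in the SNP
#'   catalogue database.
#' @param frac_control fraction of background sites present in the
#'   control-exome database (membership assigned independently of the
#'   catalogue).
#' @param maf_range background minor-allele-frequency range (uniform draw).
#' @param frac_low_mq fraction of background sites given mapping quality
#'   below 20 (quality-filter decoys).
#' @param causal_model one of `"COMPOUND_HET"`, `"HOMOZYGOUS"`,
#'   `"SINGLE_HET"`, `"NONE"`.
#' @param causal_gene symbol of the panel gene carrying the causal genotype.
#' @param decoys plant the three decoy features (frequency-catalogue
#'   variant at MAF 0.002, cis-configured pair, control-exome-present
#'   variant)?
#' @param n_controls control cohort size.
#' @param depth_mean mean read depth of the simulated depth tracks.
#' @param n_depth_gaps number of engineered exonic low-coverage holes in the
#'   causal gene's track.
#' @param random_seed integer seed; identical configurations (including the
#'   seed) give byte-identical outputs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(ped = quartet_pedigree(),
                       panel_genes = toy_deafness_genes(),
                       background_genes = toy_background_genes(),
                       panel = names(panel_genes),
                       n_background = 800,
                       frac_catalogue = 0.86,
                       frac_control = 0.95,
                       maf_range = c(0.01, 0.5),
                       frac_low_mq = 0.05,
                       causal_model = c("COMPOUND_HET", "HOMOZYGOUS",
                                        "SINGLE_HET", "NONE"),
                       causal_gene = names(panel_genes)[1],
                       decoys = TRUE,
                       n_controls = 409,
                       depth_mean = 56,
                       n_depth_gaps = 2,
                       random_seed = 1L) {
  causal_model <- match.arg(causal_model)
  stopifnot(frac_catalogue >= 0, frac_catalogue <= 1,
            frac_control >= 0, frac_control <= 1,
            frac_low_mq >= 0, frac_low_mq <= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            n_background >= 0, n_controls >= 0)
  if (causal_model != "NONE" && !(causal_gene %in% panel))
    stop("causal gene must be in the panel")
  structure(list(ped = ped, panel_genes = panel_genes,
                 background_genes = background_genes, panel = panel,
                 n_background = as.integer(n_background),
                 frac_catalogue = frac_catalogue,
                 frac_control = frac_control, maf_range = maf_range,
                 frac_low_mq = frac_low_mq, causal_model = causal_model,
                 causal_gene = causal_gene, decoys = decoys,
                 n_controls = as.integer(n_controls),
                 depth_mean = depth_mean,
                 n_depth_gaps = as.integer(n_depth_gaps),
                 random_seed = as.integer(random_seed)),
            class = "sim_config")
}

# ---- internal site bookkeeping -------------------------------------------
# sites: data.frame(contig, pos, ref, alt, gene, maf, mq, in_catalogue,
#                   in_control, role)

#' Construct a missense SNV in a given codon
#'
#' Deterministically picks the first substitution in the codon that changes
#' the amino acid without creating or destroying a stop. Useful for building
#' fixtures against toy gene models.
#'
#' @param g a [gene_model()].
#' @param codon_idx 1-based codon index.
#' @return one-row data.frame with `contig`, `pos`, `ref`, `alt` (genomic
#'   strand orientation).
#' @export
missense_site <- function(g, codon_idx) {
  codon <- substr(g$cds_seq, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
  aa0 <- Biostrings::GENETIC_CODE[[codon]]
  for (frame in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, frame, frame)) next
      mut <- codon; substr(mut, frame, frame) <- b
      aa1 <- Biostrings::GENETIC_CODE[[mut]]
      if (aa1 != aa0 && aa1 != "*" && aa0 != "*") {
        cpos <- (codon_idx - 1L) * 3L + frame
        gpos <- genomic_coord(g, cpos)
        cref <- substr(codon, frame, frame)
        ref <- if (g$strand == "+") cref else revcomp(cref)
        alt <- if (g$strand == "+") b else revcomp(b)
        return(data.frame(contig = g$contig, pos = gpos, ref = ref,
                          alt = alt, stringsAsFactors = FALSE))
      }
    }
  }
  stop("no missense substitution available in codon ", codon_idx)
}

splice_site <- function(g, intron_tx_index) {
  # donor +1 position of the given intron (transcript numbering)
  ex <- tx_exons(g)
  stopifnot(intron_tx_index < nrow(ex))
  e <- ex[intron_tx_index, ]
  if (g$strand == "+") {
    data.frame(contig = g$contig, pos = e$end + 1L, ref = "G", alt = "A",
               stringsAsFactors = FALSE)
  } else {
    data.frame(contig = g$contig, pos = e$start - 1L, ref = "C", alt = "T",
               stringsAsFactors = FALSE)
  }
}

#' Plan the decoy variants for a simulation
#'
#' Returns the three planted decoy features that exercise the pipeline's
#' exclusion rules: (a) a panel-gene variant present in the frequency
#' catalogue at MAF 0.002, linked to a causal haplotype so it survives to
#' sibling sharing and is only removed by catalogue exclusion; (b) a
#' cis-configured pair on a single parental haplotype of another panel gene
#' (must be rejected by the trans-phase check, never confirmed); (c) a
#' panel-gene variant present in the control-exome database (removed at the
#' control-exome funnel stage).
#'
#' @param cfg a [sim_config()].
#' @return data.frame of decoy variant definitions with columns `contig`,
#'   `pos`, `ref`, `alt`, `gene`, `role`.
#' @export
plant_decoys <- function(cfg) {
  g <- cfg$panel_genes[[cfg$causal_gene]]
  other <- setdiff(intersect(cfg$panel, names(cfg$panel_genes)),
                   cfg$causal_gene)
  if (!length(other)) stop("decoys need a second panel gene")
  g2 <- cfg$panel_genes[[other[1]]]
  n_codons <- nchar(g$cds_seq) %/% 3L
  n2 <- nchar(g2$cds_seq) %/% 3L
  rbind(
    cbind(missense_site(g, n_codons - 5L), gene = g$symbol,
          role = "decoy_frequency"),
    cbind(missense_site(g, n_codons %/% 2L + 7L), gene = g$symbol,
          role = "decoy_control"),
    cbind(missense_site(g2, max(2L, n2 %/% 3L)), gene = g2$symbol,
          role = "decoy_cis_1"),
    cbind(missense_site(g2, max(3L, n2 %/% 3L + 4L)), gene = g2$symbol,
          role = "decoy_cis_2"))
}

causal_sites <- function(cfg) {
  g <- cfg$panel_genes[[cfg$causal_gene]]
  n_codons <- nchar(g$cds_seq) %/% 3L
  mid_intron <- max(1L, min(nrow(g$exons) - 1L, nrow(g$exons) %/% 3L + 1L))
  switch(cfg$causal_model,
    COMPOUND_HET = rbind(
      cbind(splice_site(g, mid_intron), gene = g$symbol,
            role = "causal_splice"),
      cbind(missense_site(g, (2L * n_codons) %/% 3L), gene = g$symbol,
            role = "causal_missense")),
    HOMOZYGOUS = cbind(missense_site(g, (2L * n_codons) %/% 3L),
                       gene = g$symbol, role = "causal_hom"),
    SINGLE_HET = cbind(missense_site(g, (2L * n_codons) %/% 3L),
                       gene = g$symbol, role = "causal_single"),
    NONE = NULL)
}

background_sites <- function(cfg) {
  genes <- cfg$background_genes
  n <- cfg$n_background
  if (!n) return(NULL)
  maps <- lapply(genes, cds_genomic_map)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- NULL
  guard <- 0L
  while ((is.null(out) || nrow(out) < n) && guard < 50L) {
    guard <- guard + 1L
    need <- n - if (is.null(out)) 0L else nrow(out)
    gi <- sample(length(genes), need, replace = TRUE)
    cpos <- vapply(gi, function(i)
      sample(4L:(length(maps[[i]]) - 3L), 1L), integer(1))
    gpos <- mapply(function(i, p) maps[[i]][p], gi, cpos)
    cref <- mapply(function(i, p) substr(genes[[i]]$cds_seq, p, p), gi, cpos)
    calt <- vapply(cref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    minus <- vapply(gi, function(i) genes[[i]]$strand == "-", logical(1))
    ref <- ifelse(minus, comp[cref], cref)
    alt <- ifelse(minus, comp[calt], calt)
    ctg <- vapply(gi, function(i) genes[[i]]$contig, "")
    d <- data.frame(contig = ctg, pos = as.integer(gpos), ref = ref,
                    alt = alt,
                    gene = vapply(gi, function(i) genes[[i]]$symbol, ""),
                    role = "background", stringsAsFactors = FALSE)
    out <- rbind(out, d)
    out <- out[!duplicated(variant_key(out$contig, out$pos, out$ref,
                                       out$alt)), ]
  }
  rownames(out) <- NULL
  out[seq_len(min(n, nrow(out))), ]
}

topo_order <- function(ped) {
  done <- character(); todo <- ped$id
  while (length(todo)) {
    ready <- vapply(todo, function(i) {
      k <- match(i, ped$id)
      all(is.na(c(ped$father[k], ped$mother[k])) |
            c(ped$father[k], ped$mother[k]) %in% done)
    }, logical(1))
    if (!any(ready)) stop("pedigree is not acyclic")
    done <- c(done, todo[ready]); todo <- todo[!ready]
  }
  done
}

#' Simulate a family exome study
#'
#' Generates one ascertained family's joint genotypes, population databases,
#' depth tracks and truth set under the declared [sim_config()]. Founders
#' draw background genotypes per site under Hardy-Weinberg equilibrium at
#' that site's minor allele frequency; children inherit one parental
#' haplotype per gene (variants of a gene travel together; genes are
#' unlinked). Haplotype phase is tracked internally but genotypes are
#' emitted unphased, so downstream trans-phase inference is honest. Causal
#' and decoy alleles are family-private: absent from every database and
#' carried by no founder outside the family's parents. Transmissions at the
#' causal (and cis-decoy) genes are rejection-sampled until the affected
#' children carry the causal genotype and no unaffected child does,
#' reproducing ascertainment without modelling penetrance.
#'
#' @param cfg a [sim_config()].
#' @return list of class `family_simulation` with elements `vs`
#'   ([variant_set()]), `ped`, `genes` (panel + background models), `panel`,
#'   `dbs` (list of [population_db()]: `control_exome`, `snp_catalogue`,
#'   `frequency_catalogue`), `depth` (list of [depth_track()]), `truth`
#'   (causal gene/keys/model, per-individual planted genotypes, decoy keys)
#'   and `cfg`.
#' @export
simulate_family <- function(cfg = sim_config()) {
  with_seed(cfg$random_seed, {
    ped <- cfg$ped
    aff <- ped$id[ped$affected %in% TRUE]
    if (cfg$causal_model != "NONE") {
      orphan <- aff[is.na(ped$father[match(aff, ped$id)]) |
                      is.na(ped$mother[match(aff, ped$id)])]
      if (length(orphan))
        stop("cannot plant a causal genotype: affected individual(s) ",
             paste(orphan, collapse = ", "), " have no parents in pedigree")
    }
    bg <- background_sites(cfg)
    ca <- causal_sites(cfg)
    de <- if (cfg$decoys && cfg$causal_model != "NONE") plant_decoys(cfg)
          else NULL
    sites <- rbind(bg, ca, de)
    sites <- sites[order(suppressWarnings(as.integer(norm_contig(sites$contig))),
                         norm_contig(sites$contig), sites$pos), ]
    rownames(sites) <- NULL
    n <- nrow(sites)
    key <- variant_key(sites$contig, sites$pos, sites$ref, sites$alt)
    planted <- sites$role != "background"

    # per-site attributes
    maf <- runif(n, cfg$maf_range[1], cfg$maf_range[2])
    maf[planted] <- 0
    in_cat <- !planted & rbinom(n, 1, cfg$frac_catalogue) == 1
    in_ctl <- !planted & rbinom(n, 1, cfg$frac_control) == 1
    mq <- round(runif(n, 20, 60), 1)
    low <- !planted & rbinom(n, 1, cfg$frac_low_mq) == 1
    mq[low] <- round(runif(sum(low), 2, 19.9), 1)
    if (!is.null(de)) {
      in_ctl[sites$role == "decoy_control"] <- TRUE
    }

    # founder haplotypes: 2 x n binary matrices
    ord <- topo_order(ped)
    hap <- list()
    for (id in ord) {
      k <- match(id, ped$id)
      if (is.na(ped$father[k]) || is.na(ped$mother[k])) {
        hap[[id]] <- rbind(rbinom(n, 1, maf), rbinom(n, 1, maf))
      } else {
        hap[[id]] <- matrix(0L, 2, n)  # filled by transmission below
      }
    }
    parents_of <- function(id) {
      k <- match(id, ped$id)
      c(ped$father[k], ped$mother[k])
    }
    gene_of_site <- sites$gene
    gene_ids <- unique(gene_of_site)
    transmit <- function(id, gene_set = gene_ids) {
      p <- parents_of(id)
      for (g in gene_set) {
        idx <- which(gene_of_site == g)
        hap[[id]][1, idx] <<- hap[[p[1]]][sample(2, 1), idx]
        hap[[id]][2, idx] <<- hap[[p[2]]][sample(2, 1), idx]
      }
    }
    nonfounders <- ord[vapply(ord, function(id)
      !anyNA(parents_of(id)), logical(1))]
    for (id in nonfounders) transmit(id)

    # plant causal (and decoy) alleles on parental haplotypes, then
    # rejection-sample the transmissions at the planted genes until the
    # affection pattern holds
    if (cfg$causal_model != "NONE") {
      fa <- parents_of(aff[1])[1]; mo <- parents_of(aff[1])[2]
      i_of <- function(role) which(sites$role == role)
      set_allele <- function(id, hrow, i, val = 1L) hap[[id]][hrow, i] <<- val
      if (cfg$causal_model == "COMPOUND_HET") {
        set_allele(fa, 1, i_of("causal_missense"))
        set_allele(mo, 1, i_of("causal_splice"))
      } else if (cfg$causal_model == "HOMOZYGOUS") {
        set_allele(fa, 1, i_of("causal_hom"))
        set_allele(mo, 1, i_of("causal_hom"))
      } else {
        set_allele(fa, 1, i_of("causal_single"))
      }
      if (!is.null(de)) {
        # frequency and control decoys ride the father's causal haplotype;
        # the cis pair sits together on one of the father's haplotypes of a
        # second panel gene
        set_allele(fa, 1, i_of("decoy_frequency"))
        set_allele(fa, 1, i_of("decoy_control"))
        set_allele(fa, 1, i_of("decoy_cis_1"))
        set_allele(fa, 1, i_of("decoy_cis_2"))
      }
      causal_keys <- key[grepl("^causal", sites$role)]
      causal_idx <- which(grepl("^causal", sites$role))
      planted_genes <- unique(sites$gene[planted])
      children <- ped$id[!is.na(ped$father) & !is.na(ped$mother)]
      ok <- function() {
        for (id in children) {
          gsum <- colSums(hap[[id]][, causal_idx, drop = FALSE])
          affec <- ped$affected[match(id, ped$id)] %in% TRUE
          want <- switch(cfg$causal_model,
                         COMPOUND_HET = all(gsum == 1),
                         HOMOZYGOUS = all(gsum == 2),
                         SINGLE_HET = all(gsum >= 1))
          if (affec && !want) return(FALSE)
          if (!affec && cfg$causal_model != "SINGLE_HET" && want)
            return(FALSE)
          if (affec && !is.null(de)) {
            ci <- which(grepl("^decoy_cis", sites$role))
            if (!all(colSums(hap[[id]][, ci, drop = FALSE]) >= 1))
              return(FALSE)
          }
        }
        TRUE
      }
      tries <- 0L
      while (!ok()) {
        tries <- tries + 1L
        if (tries > 10000L)
          stop("could not realize the configured affection pattern")
        for (id in nonfounders) transmit(id, planted_genes)
      }
    } else {
      causal_keys <- character()
    }

    samples <- ped$id[ped$sample_available]
    geno <- vapply(samples, function(id) as.integer(colSums(hap[[id]])),
                   integer(n))
    vs <- variant_set(data.frame(contig = sites$contig, pos = sites$pos,
                                 ref = sites$ref, alt = sites$alt, mq = mq,
                                 stringsAsFactors = FALSE),
                      matrix(geno, n, length(samples),
                             dimnames = list(NULL, samples)))

    dbs <- list(
      control_exome = population_db("control_exome",
                                    setNames(rep(NA_real_, sum(in_ctl)),
                                             key[in_ctl])),
      snp_catalogue = population_db("snp_catalogue",
                                    setNames(maf[in_cat], key[in_cat])),
      frequency_catalogue = population_db(
        "frequency_catalogue",
        setNames(c(maf[in_cat],
                   rep(0.002, sum(sites$role == "decoy_frequency"))),
                 c(key[in_cat], key[sites$role == "decoy_frequency"]))))

    depth <- simulate_depth(cfg)
    truth <- list(
      causal_gene = if (cfg$causal_model == "NONE") NA_character_
                    else cfg$causal_gene,
      causal_model = cfg$causal_model,
      causal_keys = causal_keys,
      planted_genotypes = if (length(causal_keys)) {
        m <- vapply(ped$id, function(id)
          as.integer(colSums(hap[[id]][, match(causal_keys, key),
                                       drop = FALSE])),
          integer(length(causal_keys)))
        matrix(m, length(causal_keys), nrow(ped),
               dimnames = list(causal_keys, ped$id))
      } else NULL,
      decoys = if (!is.null(de)) list(
        frequency = key[sites$role == "decoy_frequency"],
        frequency_maf = 0.002,
        cis_pair = key[grepl("^decoy_cis", sites$role)],
        control = key[sites$role == "decoy_control"]) else NULL,
      background_keys = key[!planted],
      background_maf = setNames(maf[!planted], key[!planted]),
      in_catalogue = setNames(in_cat[!planted], key[!planted]),
      in_control = setNames(in_ctl[!planted], key[!planted]))

    genes <- gene_model_list(c(unclass(cfg$panel_genes),
                               unclass(cfg$background_genes)))
    structure(list(vs = vs, ped = ped, genes = genes, panel = cfg$panel,
                   dbs = dbs, depth = depth, truth = truth, cfg = cfg),
              class = "family_simulation")
  })
}

simulate_depth <- function(cfg) {
  g <- cfg$panel_genes[[if (cfg$causal_model == "NONE")
    names(cfg$panel_genes)[1] else cfg$causal_gene]]
  span <- gene_span(g)
  len <- span[2] - span[1] + 1L
  depth <- rpois(len, cfg$depth_mean)
  if (cfg$n_depth_gaps > 0) {
    ex <- cfg$panel_genes[[g$symbol]]$exons
    pick <- sample(nrow(ex), min(cfg$n_depth_gaps, nrow(ex)))
    for (i in pick) {
      w <- min(30L, ex$end[i] - ex$start[i] + 1L)
      s <- ex$start[i] + sample(max(1L, ex$end[i] - ex$start[i] - w), 1L)
      idx <- (s - span[1] + 1L):(s - span[1] + w)
      depth[idx] <- sample(0:4, w, replace = TRUE)
    }
    # one mid-intron hole: must NOT be reported by exon-scoped gap audits
    if (nrow(ex) > 1) {
      mid <- (ex$end[1] + ex$start[2]) %/% 2L
      idx <- (mid - span[1] + 1L):(mid - span[1] + 10L)
      depth[idx] <- 0L
    }
  }
  list(depth_track(g$contig, span[1], depth))
}

#' @export
print.family_simulation <- function(x, ...) {
  cat(sprintf("family_simulation: %d sites, %d samples, causal model %s (%s)\n",
              n_variants(x$vs), length(x$vs$samples), x$truth$causal_model,
              ifelse(is.na(x$truth$causal_gene), "-", x$truth$causal_gene)))
  invisible(x)
}

#' Simulate a genotyped control cohort
#'
#' Controls never carry the family-private causal (or decoy) alleles;
#' background sites are drawn under Hardy-Weinberg equilibrium at their
#' stated minor allele frequencies.
#'
#' @param causal_keys variant keys the cohort must not carry.
#' @param n cohort size.
#' @param background_maf named numeric vector of background MAFs keyed by
#'   variant key (may be empty).
#' @param seed integer seed.
#' @return a [control_cohort()] genotyped at `causal_keys` and the
#'   background keys.
#' @export
simulate_controls <- function(causal_keys, n, background_maf = numeric(0),
                              seed = 1L) {
  with_seed(seed, {
    keys <- c(causal_keys, names(background_maf))
    if (n == 0 || !length(keys)) {
      return(control_cohort(matrix(integer(), length(keys), n,
                                   dimnames = list(keys, NULL))))
    }
    geno <- matrix(0L, length(keys), n, dimnames = list(keys, NULL))
    for (j in seq_along(background_maf)) {
      geno[length(causal_keys) + j, ] <-
        rbinom(n, 2, background_maf[j])
    }
    control_cohort(geno)
  })
}

#' Write a simulation bundle to disk
#'
#' Emits the file formats the pipeline consumes: `family.vcf`,
#' `family.ped`, `control_exome.tsv`, `snp_catalogue.tsv`,
#' `frequency_catalogue.tsv`, `depth.tsv`, `genes.json`, `panel.tsv` and
#' `truth.json`. Identical configurations produce byte-identical files.
#'
#' @param sim a `family_simulation` from [simulate_family()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "family.vcf"),
             ped = file.path(dir, "family.ped"),
             control_exome = file.path(dir, "control_exome.tsv"),
             snp_catalogue = file.path(dir, "snp_catalogue.tsv"),
             frequency_catalogue = file.path(dir, "frequency_catalogue.tsv"),
             depth = file.path(dir, "depth.tsv"),
             genes = file.path(dir, "genes.json"),
             panel = file.path(dir, "panel.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$vs, paths["vcf"])
  write_ped(sim$ped, paths["ped"])
  write_population_db(sim$dbs$control_exome, paths["control_exome"])
  write_population_db(sim$dbs$snp_catalogue, paths["snp_catalogue"])
  write_population_db(sim$dbs$frequency_catalogue,
                      paths["frequency_catalogue"])
  write_depth_track(sim$depth, paths["depth"])
  write_gene_models(sim$genes, paths["genes"])
  writeLines(sim$panel, paths["panel"])
  truth <- sim$truth
  truth$planted_genotypes <- if (!is.null(truth$planted_genotypes))
    as.data.frame(truth$planted_genotypes) else NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}
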