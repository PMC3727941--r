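small_cfg <- function(seed, ...) {
  sim_config(n_background = 60, random_seed = seed, ...)
}

test_that("identical configurations give byte-identical outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_family(small_cfg(13L)), d1)
  p2 <- write_simulation(simulate_family(small_cfg(13L)), d2)
  for (f in names(p1))
    expect_identical(unname(tools::md5sum(p1[f])),
                     unname(tools::md5sum(p2[f])), label = f)
  p3 <- write_simulation(simulate_family(small_cfg(14L)),
                         withr::local_tempdir())
  expect_false(identical(unname(tools::md5sum(p1["vcf"])),
                         unname(tools::md5sum(p3["vcf"]))))
})

test_that("the planted compound het matches the published configuration", {
  sim <- simulate_family(small_cfg(2L))
  tg <- sim$truth$planted_genotypes
  expect_equal(dim(tg), c(2L, 4L))
  # both affected siblings heterozygous at both causal sites
  expect_true(all(tg[, c("S1", "S2")] == 1L))
  # father carries exactly one causal variant, mother exactly the other
  expect_equal(sort(unname(tg[, "FA"])), c(0L, 1L))
  expect_equal(sort(unname(tg[, "MO"])), c(0L, 1L))
  expect_equal(tg[, "FA"] + tg[, "MO"], c(1L, 1L),
               ignore_attr = TRUE)
  # causal keys absent from every database
  for (db in sim$dbs)
    expect_false(any(sim$truth$causal_keys %in% names(db$maf)))
  # one splice-site and one missense causal variant in the causal gene
  ann <- annotate_variants(subset_by_key(sim$vs, sim$truth$causal_keys),
                           sim$genes)
  expect_setequal(ann$impact, c("SPLICE", "MISSENSE"))
  expect_true(all(ann$gene == sim$truth$causal_gene))
})

test_that("homozygous and single-het causal models plant as declared", {
  sim_h <- simulate_family(small_cfg(3L, causal_model = "HOMOZYGOUS"))
  tg <- sim_h$truth$planted_genotypes
  expect_true(all(tg[, c("S1", "S2")] == 2L))
  expect_true(all(tg[, c("FA", "MO")] == 1L))

  sim_s <- simulate_family(small_cfg(4L, causal_model = "SINGLE_HET"))
  expect_true(all(sim_s$truth$planted_genotypes[, c("S1", "S2")] >= 1L))

  sim_n <- simulate_family(small_cfg(5L, causal_model = "NONE"))
  expect_length(sim_n$truth$causal_keys, 0)
})

test_that("a causal model cannot be planted when affected founders lack
          parents", {
  bad_ped <- pedigree(id = c("A", "B"), father = NA, mother = NA,
                      affected = c(TRUE, TRUE))
  expect_error(simulate_family(small_cfg(1L, ped = bad_ped)),
               "no parents")
})

test_that("every child genotype is Mendelian-consistent with its parents", {
  sim <- simulate_family(sim_config(n_background = 200, random_seed = 17L))
  g <- sim$vs$geno
  from <- function(x) if (x == 0L) 0L else if (x == 2L) 1L else 0:1
  for (child in c("S1", "S2")) {
    for (i in seq_len(nrow(g))) {
      possible <- outer(from(g[i, "FA"]), from(g[i, "MO"]), `+`)
      expect_true(g[i, child] %in% possible,
                  label = sprintf("site %d child %s", i, child))
    }
  }
})

test_that("offspring of het x het parents are homozygous-alternate about a
          quarter of the time", {
  # one causal site het in both parents; 500 children give 1000 transmitted
  # haplotype pairs... use a single-site homozygous-model family with many
  # children, unconstrained by affection (causal NONE), and condition on
  # het x het background sites instead
  n_kids <- 1000L
  kids <- sprintf("K%03d", seq_len(n_kids))
  ped <- pedigree(id = c("FA", "MO", kids),
                  father = c(NA, NA, rep("FA", n_kids)),
                  mother = c(NA, NA, rep("MO", n_kids)),
                  affected = c(FALSE, FALSE, TRUE, rep(FALSE, n_kids - 1L)),
                  fid = "BIG")
  sim <- simulate_family(sim_config(ped = ped, n_background = 12,
                                    maf_range = c(0.45, 0.5),
                                    causal_model = "NONE", decoys = FALSE,
                                    frac_low_mq = 0, random_seed = 19L))
  g <- sim$vs$geno
  hh <- which(g[, "FA"] == 1L & g[, "MO"] == 1L)
  expect_gt(length(hh), 0)
  i <- hh[1]
  kid_g <- g[i, kids]
  p_hom <- mean(kid_g == 2L)
  se3 <- 3 * sqrt(0.25 * 0.75 / n_kids)
  expect_lt(abs(p_hom - 0.25), se3)
  # het fraction should likewise be near 1/2
  expect_lt(abs(mean(kid_g == 1L) - 0.5), 3 * sqrt(0.5 * 0.5 / n_kids))
})

test_that("background database membership is independent, so joint survival
          matches the product of the stage survival rates", {
  cfg <- sim_config(n_background = 4000, causal_model = "NONE",
                    decoys = FALSE, frac_low_mq = 0, random_seed = 23L)
  sim <- simulate_family(cfg)
  surv <- subtract_database(subtract_database(sim$vs,
                                              sim$dbs$control_exome),
                            sim$dbs$snp_catalogue)
  p_exp <- (1 - cfg$frac_control) * (1 - cfg$frac_catalogue)
  p_obs <- n_variants(surv) / n_variants(sim$vs)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 4000))
})

test_that("decoys are removed at their designed stages and never confirmed", {
  sim <- simulate_family(sim_config(random_seed = 29L))
  res <- suppressWarnings(run_sim_pipeline(sim))
  dk <- sim$truth$decoys

  # (a) the catalogued MAF-0.002 variant survives to sibling sharing and is
  # removed by the frequency-catalogue exclusion
  expect_true(dk$frequency %in% res$shared)
  expect_false(dk$frequency %in% res$shared_after_exclusion)
  expect_equal(length(res$shared) - length(res$shared_after_exclusion), 1)

  # (b) the cis pair reaches calling but is rejected, never trans-confirmed
  cis_calls <- Filter(function(cl) setequal(cl$variants, dk$cis_pair),
                      res$calls)
  expect_length(cis_calls, 1)
  expect_identical(cis_calls[[1]]$phase_status, "CIS_REJECTED")
  expect_false(any(dk$cis_pair %in% unlist(lapply(
    Filter(function(cl) cl$phase_status == "TRANS_CONFIRMED", res$calls),
    `[[`, "variants"))))

  # (c) the control-exome decoy disappears at the control-exome stage
  ann <- res$ann
  run <- suppressWarnings(run_funnel("S1", sim$vs, ann,
                                     default_funnel_dbs(sim), sim$panel,
                                     audit = TRUE))
  ks <- attr(run$funnel, "keys")
  expect_true(dk$control %in%
                ks[["missense, nonsense, splice and indel variants"]])
  expect_false(dk$control %in% ks[["after control_exome filtering"]])
})

test_that("control cohorts are private for causal keys and Hardy-Weinberg
          for background", {
  sim <- simulate_family(small_cfg(31L))
  cohort <- simulate_controls(sim$truth$causal_keys, 409,
                              sim$truth$background_maf, seed = 31L)
  for (k in sim$truth$causal_keys)
    expect_equal(unname(count_carriers(k, cohort)), c(0, 409))

  big <- simulate_controls(character(), 2000,
                           c("1:5:A:G" = 0.1), seed = 33L)
  p <- 1 - 0.9^2
  cc <- count_carriers("1:5:A:G", big)
  expect_lt(abs(cc["carriers"] / 2000 - p), 3 * sqrt(p * (1 - p) / 2000))
})
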