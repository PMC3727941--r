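test_that("sibling intersection is by variant key", {
  expect_setequal(shared_variants(list(c("a", "b", "c", "d", "e"),
                                       c("a", "b", "c"))),
                  c("a", "b", "c"))
  expect_identical(shared_variants(list(c("x", "y"))), c("x", "y"))
  expect_length(shared_variants(list(c("a"), c("b"))), 0)
})

test_that("recessive calling distinguishes homozygous, compound het and
          single het", {
  fx <- pair_fixture(rbind(c(0L, 1L, 1L, 1L),
                           c(1L, 0L, 1L, 1L)))
  ann <- annotate_variants(fx$vs, gene_model_list(list(fx$gene)))
  calls <- call_recessive(fx$vs$site$key, fx$vs, ann, fx$ped)
  expect_length(calls, 1)
  expect_identical(calls[[1]]$model, "COMPOUND_HET")
  expect_length(calls[[1]]$variants, 2)

  hom <- pair_fixture(rbind(c(1L, 1L, 2L, 2L),
                            c(0L, 0L, 0L, 0L)))
  calls_hom <- call_recessive(hom$vs$site$key[1], hom$vs, ann, hom$ped)
  expect_identical(calls_hom[[1]]$model, "HOMOZYGOUS")

  single <- pair_fixture(rbind(c(1L, 0L, 1L, 1L),
                               c(0L, 0L, 0L, 0L)))
  calls_s <- call_recessive(single$vs$site$key[1], single$vs, ann,
                            single$ped)
  expect_identical(calls_s[[1]]$model, "SINGLE_HET_UNCERTAIN")
})

test_that("three shared het variants in one gene emit all pairs, flagged", {
  g <- toy_deafness_genes()$GRHL2
  site <- rbind(cds_snv(g, 50L, "T"), cds_snv(g, 250L, "T"),
                cds_snv(g, 800L, "T"))
  site$mq <- 60
  geno <- matrix(1L, 3, 4,
                 dimnames = list(NULL, c("FA", "MO", "S1", "S2")))
  vs <- variant_set(site, geno)
  ped <- quartet_pedigree(father = "FA", mother = "MO",
                          children = c("S1", "S2"))
  ann <- annotate_variants(vs, gene_model_list(list(g)))
  calls <- call_recessive(vs$site$key, vs, ann, ped)
  expect_length(calls, 3)
  expect_true(all(vapply(calls, `[[`, "", "model") == "COMPOUND_HET"))
  expect_true(all(vapply(calls, `[[`, TRUE, "flagged")))
})

test_that("sex-chromosome variants are excluded from recessive calling", {
  fx <- pair_fixture(rbind(c(0L, 1L, 1L, 1L), c(1L, 0L, 1L, 1L)))
  ann <- annotate_variants(fx$vs, gene_model_list(list(fx$gene)))
  keys <- c(fx$vs$site$key, "X:500:A:T")
  calls <- call_recessive(keys, fx$vs, ann, fx$ped)
  genes <- vapply(calls, `[[`, "", "gene")
  expect_false(any(is.na(genes)))
  expect_length(calls, 1)
})

test_that("trans and cis configurations segregate as published", {
  # father het missense only, mother het splice only, sibs het/het
  fx <- pair_fixture(rbind(c(1L, 0L, 1L, 1L),
                           c(0L, 1L, 1L, 1L)))
  ann <- annotate_variants(fx$vs, gene_model_list(list(fx$gene)))
  call <- call_recessive(fx$vs$site$key, fx$vs, ann, fx$ped)[[1]]
  out <- check_segregation(call, fx$vs, fx$ped)
  expect_identical(out$phase_status, "TRANS_CONFIRMED")
  expect_identical(out$segregation_status, "CONSISTENT")

  # both variants in the father, absent from the mother: cis
  cis <- pair_fixture(rbind(c(1L, 0L, 1L, 1L),
                            c(1L, 0L, 1L, 1L)))
  call_cis <- call_recessive(cis$vs$site$key, cis$vs, ann, cis$ped)[[1]]
  out_cis <- check_segregation(call_cis, cis$vs, cis$ped)
  expect_identical(out_cis$phase_status, "CIS_REJECTED")

  # unsampled parents: phase cannot be established
  fx2 <- pair_fixture(rbind(c(1L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L)))
  ped_ns <- quartet_pedigree(father = "FA", mother = "MO",
                             children = c("S1", "S2"),
                             sampled = c(FALSE, FALSE, TRUE, TRUE))
  call2 <- call_recessive(fx2$vs$site$key, fx2$vs, ann, ped_ns)[[1]]
  out2 <- check_segregation(call2, fx2$vs, ped_ns)
  expect_identical(out2$phase_status, "PHASE_UNKNOWN")
  expect_identical(out2$segregation_status, "UNTESTABLE")
})

test_that("phase determination equals the 81-case exhaustive oracle", {
  ann <- NULL
  for (gfa_a in 0:2) for (gfa_b in 0:2) for (gmo_a in 0:2) for (gmo_b in 0:2) {
    fx <- pair_fixture(rbind(c(gfa_a, gmo_a, 1L, 1L),
                             c(gfa_b, gmo_b, 1L, 1L)))
    if (is.null(ann))
      ann <- annotate_variants(fx$vs, gene_model_list(list(fx$gene)))
    call <- call_recessive(fx$vs$site$key, fx$vs, ann, fx$ped)[[1]]
    got <- check_segregation(call, fx$vs, fx$ped)$phase_status
    want <- oracle_phase(c(gfa_a, gfa_b), c(gmo_a, gmo_b))
    expect_identical(got, want,
                     label = sprintf("father (%d,%d) mother (%d,%d): %s",
                                     gfa_a, gfa_b, gmo_a, gmo_b, got),
                     expected.label = want)
  }
})

test_that("full-penetrance violations mark segregation inconsistent", {
  # an unaffected parent homozygous for one causal variant
  hom_fa <- pair_fixture(rbind(c(2L, 0L, 1L, 1L),
                               c(0L, 1L, 1L, 1L)))
  ann <- annotate_variants(hom_fa$vs, gene_model_list(list(hom_fa$gene)))
  call <- call_recessive(hom_fa$vs$site$key, hom_fa$vs, ann, hom_fa$ped)[[1]]
  out <- check_segregation(call, hom_fa$vs, hom_fa$ped)
  expect_identical(out$segregation_status, "INCONSISTENT")
  expect_false(out$phase_status == "TRANS_CONFIRMED")

  # an unaffected sibling provably carrying the trans pair
  g <- toy_deafness_genes()$GRHL2
  site <- rbind(cds_snv(g, 100L, "G"), cds_snv(g, 400L, "T"))
  site$mq <- 60
  geno <- matrix(c(1L, 0L,   0L, 1L,   1L, 1L,   1L, 1L), 2, 4,
                 dimnames = list(NULL, c("FA", "MO", "S1", "U1")))
  vs <- variant_set(site, geno)
  ped <- pedigree(id = c("FA", "MO", "S1", "U1"),
                  father = c(NA, NA, "FA", "FA"),
                  mother = c(NA, NA, "MO", "MO"),
                  affected = c(FALSE, FALSE, TRUE, FALSE))
  call2 <- call_recessive(vs$site$key, vs,
                          annotate_variants(vs, gene_model_list(list(g))),
                          ped)[[1]]
  out2 <- check_segregation(call2, vs, ped)
  expect_identical(out2$phase_status, "TRANS_CONFIRMED")
  expect_identical(out2$segregation_status, "INCONSISTENT")

  # homozygous call requires both sequenced parents to be carriers
  hom <- pair_fixture(rbind(c(1L, 0L, 2L, 2L), c(0L, 0L, 0L, 0L)))
  call3 <- call_recessive(hom$vs$site$key[1], hom$vs, ann, hom$ped)[[1]]
  expect_identical(check_segregation(call3, hom$vs,
                                     hom$ped)$segregation_status,
                   "INCONSISTENT")
  hom_ok <- pair_fixture(rbind(c(1L, 1L, 2L, 2L), c(0L, 0L, 0L, 0L)))
  call4 <- call_recessive(hom_ok$vs$site$key[1], hom_ok$vs, ann,
                          hom_ok$ped)[[1]]
  expect_identical(check_segregation(call4, hom_ok$vs,
                                     hom_ok$ped)$segregation_status,
                   "CONSISTENT")
})

test_that("carrier counting matches presence semantics and Hardy-Weinberg
          expectation", {
  cohort0 <- simulate_controls(c("17:1:A:T", "17:2:G:C"), 409, seed = 21L)
  for (k in c("17:1:A:T", "17:2:G:C"))
    expect_equal(unname(count_carriers(k, cohort0)), c(0, 409))

  # carrier fraction at MAF 0.5 approaches 1 - (1-0.5)^2 = 0.75
  p_carrier <- 1 - 0.25
  se3 <- 3 * sqrt(p_carrier * (1 - p_carrier) / 100)
  for (seed in 1:4) {
    ch <- simulate_controls(character(), 100,
                            background_maf = c("1:9:A:G" = 0.5), seed = seed)
    cc <- count_carriers("1:9:A:G", ch)
    expect_lt(abs(cc["carriers"] / 100 - p_carrier), se3)
  }

  empty <- simulate_controls(character(), 0)
  expect_equal(unname(count_carriers("1:9:A:G", empty)), c(0, 0))

  ch2 <- simulate_controls("1:1:A:T", 10)
  expect_warning(cc2 <- count_carriers("2:2:C:G", ch2), "not genotyped")
  expect_equal(unname(cc2), c(0, 10))
})
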