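myo <- toy_deafness_genes()$MYO15A

test_that("coding SNVs are classified by codon translation with HGVS labels", {
  # arginine codon 2146 (CGG), second base G>A -> glutamine (oracle:
  # translating CGG and CAG gives R and Q)
  a <- classify_variant("17", 18049349, "G", "A", myo)
  expect_identical(a$impact, "MISSENSE")
  expect_identical(a$protein, "p.R2146Q")
  expect_identical(a$cdna, "c.6437G>A")
  expect_equal(a$aa_pos, 2146)

  # serine codon 2161 (TCC), second base C>T -> phenylalanine
  b <- classify_variant("17", 18049394, "C", "T", myo)
  expect_identical(b$impact, "MISSENSE")
  expect_identical(b$protein, "p.S2161F")
  expect_identical(b$cdna, "c.6482C>T")

  # third-base change within the arginine codon stays arginine
  s <- classify_variant("17", 18049350, substr(myo$cds_seq, 6438, 6438), "A",
                        myo)
  expect_identical(s$impact, "SYNONYMOUS")
})

test_that("splice-site variants get offset labels and IVS aliases", {
  a <- classify_variant("17", 18035881, "G", "A", myo)
  expect_identical(a$impact, "SPLICE")
  expect_identical(a$cdna, "c.4320+1G>A")
  expect_identical(a$ivs, "IVS11+1")
  expect_equal(a$aa_pos, 1440)

  # +2 still splice, +3 intronic under the default 2-base window
  a2 <- classify_variant("17", 18035882, "T", "C", myo)
  expect_identical(a2$impact, "SPLICE")
  expect_identical(a2$ivs, "IVS11+2")
  a3 <- classify_variant("17", 18035883, "T", "C", myo)
  expect_identical(a3$impact, "INTRONIC")

  # acceptor side of the same intron
  acc <- classify_variant("17", myo$exons$start[12] - 1L, "A", "G", myo)
  expect_identical(acc$impact, "SPLICE")
  expect_identical(acc$ivs, "IVS11-1")
})

test_that("indels are frameshift or in-frame by length modulo 3", {
  pos <- myo$exons$start[2] + 10L
  del2 <- classify_variant("17", pos, substr_ref(myo, pos, 3), "A", myo)
  expect_identical(del2$impact, "FRAMESHIFT_INDEL")
  del3 <- classify_variant("17", pos, substr_ref(myo, pos, 4), "A", myo)
  expect_identical(del3$impact, "INFRAME_INDEL")
  ins1 <- classify_variant("17", pos, "A", "AT", myo)
  expect_identical(ins1$impact, "FRAMESHIFT_INDEL")
})

test_that("reference mismatches against the gene model are errors", {
  ref_here <- substr(myo$cds_seq, 6437, 6437)   # "G"
  wrong <- setdiff(c("A", "C", "G", "T"), c(ref_here, "A"))[1]
  expect_error(classify_variant("17", 18049349, wrong, "A", myo),
               "disagrees")
})

test_that("UTR, intergenic and off-contig variants are classified", {
  g <- gene_model("UT", "5", "+",
                  cbind(c(101L, 301L), c(200L, 400L)),
                  cds_start = 111L, cds_end = 390L,
                  cds_seq = famexome:::rand_cds(60, seed = 5))
  expect_identical(classify_variant("5", 105, "A", "T", g)$impact, "UTR")
  expect_identical(classify_variant("5", 395, "A", "T", g)$impact, "UTR")
  expect_identical(classify_variant("5", 50, "A", "T", g)$impact,
                   "INTERGENIC")
  expect_identical(classify_variant("6", 150, "A", "T", g)$impact,
                   "INTERGENIC")
})

test_that("every CDS SNV gets exactly one coding class, agreeing with a
          full-CDS translation oracle", {
  set.seed(7)
  genes <- c(toy_deafness_genes()["GRHL2"], toy_background_genes(4))
  for (g in genes) {
    n <- nchar(g$cds_seq)
    for (cpos in sample(4:(n - 3), 30)) {
      cref <- substr(g$cds_seq, cpos, cpos)
      calt <- sample(setdiff(c("A", "C", "G", "T"), cref), 1)
      v <- cds_snv(g, cpos, calt)
      a <- classify_variant(v$contig, v$pos, v$ref, v$alt, g)
      expect_true(a$impact %in% c("MISSENSE", "NONSENSE", "SYNONYMOUS"))
      mutant <- g$cds_seq
      substr(mutant, cpos, cpos) <- calt
      p0 <- oracle_translate(g$cds_seq)
      p1 <- oracle_translate(mutant)
      codon_idx <- ceiling(cpos / 3)
      if (p0 == p1) {
        expect_identical(a$impact, "SYNONYMOUS")
      } else if (substr(p1, codon_idx, codon_idx) == "*") {
        expect_identical(a$impact, "NONSENSE")
      } else {
        expect_identical(a$impact, "MISSENSE")
        expect_identical(a$protein,
                         paste0("p.", substr(p0, codon_idx, codon_idx),
                                codon_idx, substr(p1, codon_idx, codon_idx)))
      }
    }
  }
})

test_that("a minus-strand gene annotates like its plus-strand twin", {
  minus <- toy_gene("TWINM", "3", "-", c(150L, 150L, 150L), 5000L,
                    intron_length = 300L, seed = 77)
  plus <- toy_gene("TWINP", "3", "+", c(150L, 150L, 150L), 9000L,
                   intron_length = 300L, seed = 77)
  expect_identical(minus$cds_seq, plus$cds_seq)
  for (cpos in c(10L, 151L, 200L, 448L)) {
    calt <- setdiff(c("A", "C", "G", "T"),
                    substr(plus$cds_seq, cpos, cpos))[1]
    vm <- cds_snv(minus, cpos, calt)
    vp <- cds_snv(plus, cpos, calt)
    am <- classify_variant(vm$contig, vm$pos, vm$ref, vm$alt, minus)
    ap <- classify_variant(vp$contig, vp$pos, vp$ref, vp$alt, plus)
    expect_identical(am$impact, ap$impact)
    expect_identical(am$protein, ap$protein)
    expect_identical(am$cdna, ap$cdna)
  }
})

test_that("classification is a pure function of its inputs", {
  a1 <- classify_variant("17", 18049349, "G", "A", myo)
  a2 <- classify_variant("17", 18049349, "G", "A", myo)
  expect_identical(a1, a2)
})

test_that("external scores are joined verbatim and never computed", {
  vs <- variant_set(data.frame(contig = "17",
                               pos = c(18049349L, 18049394L, 777L),
                               ref = c("G", "C", "A"),
                               alt = c("A", "T", "G")),
                    matrix(1L, 3, 1, dimnames = list(NULL, "S")))
  ann <- annotate_variants(vs, toy_deafness_genes())
  scores <- data.frame(key = c("17:18049349:G:A", "17:18049394:C:T"),
                       conserved = c(TRUE, TRUE), sift = c(0, 0),
                       polyphen2 = c(0.99, 1), mupro = c(-0.743, -0.543))
  out <- join_scores(ann, scores)
  expect_equal(out$polyphen2, c(0.99, 1, NA))
  expect_equal(out$mupro, c(-0.743, -0.543, NA))
  expect_true(is.na(out$sift[3]))
})

test_that("domain labels come from residue intervals, splice via CDS anchor", {
  vs <- variant_set(data.frame(contig = "17",
                               pos = c(18049349L, 18035881L),
                               ref = c("G", "G"), alt = c("A", "A")),
                    matrix(1L, 2, 1, dimnames = list(NULL, "S")))
  ann <- assign_domain(annotate_variants(vs, toy_deafness_genes()),
                       toy_domain_map())
  expect_identical(ann$domain, c("MyTH4", "Motor"))

  # residue 1900 sits between the mapped intervals
  far <- cds_snv(myo, 1900L * 3L - 1L,
                 setdiff(c("A", "C", "G", "T"),
                         substr(myo$cds_seq, 1900 * 3 - 1, 1900 * 3 - 1))[1])
  vs2 <- variant_set(cbind(far, mq = 60),
                     matrix(1L, 1, 1, dimnames = list(NULL, "S")))
  ann2 <- assign_domain(annotate_variants(vs2, toy_deafness_genes()),
                        toy_domain_map())
  expect_true(is.na(ann2$domain))

  bad_map <- data.frame(gene = "MYO15A", aa_start = c(1, 5),
                        aa_end = c(10, 20), label = c("A", "B"))
  expect_error(assign_domain(ann, bad_map), "overlapping")
})
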