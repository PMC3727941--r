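test_that("affected sample selection respects affection and availability", {
  ped <- quartet_pedigree(father = "SR-903F", mother = "SR-903M",
                          children = c("SR-903", "SR-903B"),
                          affected = c(TRUE, TRUE), fid = "SR-903")
  expect_identical(affected_samples(ped), c("SR-903", "SR-903B"))

  # affected individuals exist but none has an available sample
  ped2 <- pedigree(id = c("F", "M", "C"), father = c(NA, NA, "F"),
                   mother = c(NA, NA, "M"), affected = c(FALSE, FALSE, TRUE),
                   sample_available = c(TRUE, TRUE, FALSE))
  expect_warning(ids <- affected_samples(ped2), "no affected")
  expect_length(ids, 0)

  # sib pair with unsampled parents: parents never appear
  ped3 <- quartet_pedigree(father = "SR-285F", mother = "SR-285M",
                           children = c("SR-285", "SR-285S"),
                           affected = c(TRUE, TRUE),
                           sampled = c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(affected_samples(ped3), c("SR-285", "SR-285S"))
})

test_that("parent lookup resolves sampled parents only", {
  ped <- quartet_pedigree(father = "SR-903F", mother = "SR-903M",
                          children = c("SR-903", "SR-903B"))
  pp <- parent_pair(ped, "SR-903")
  expect_identical(pp$father, "SR-903F")
  expect_identical(pp$mother, "SR-903M")

  founder <- parent_pair(ped, "SR-903F")
  expect_true(is.na(founder$father) && is.na(founder$mother))

  ped285 <- quartet_pedigree(father = "SR-285F", mother = "SR-285M",
                             children = c("SR-285", "SR-285S"),
                             sampled = c(FALSE, FALSE, TRUE, TRUE))
  pp285 <- parent_pair(ped285, "SR-285")
  expect_true(is.na(pp285$father) && is.na(pp285$mother))
  expect_match(attr(pp285, "reason"), "sample not available", all = FALSE)

  expect_error(parent_pair(ped, "nobody"), "unknown individual")
})

test_that("pedigree validation rejects cycles and dangling references", {
  expect_error(
    pedigree(id = c("A", "B"), father = c("B", "A"), mother = c(NA, NA),
             affected = c(TRUE, FALSE)),
    "cycle")
  expect_error(
    pedigree(id = "A", father = "GHOST", mother = NA, affected = TRUE),
    "unresolved")
  expect_error(
    pedigree(id = c("A", "B"), father = c(NA, NA), mother = c(NA, NA),
             affected = c(FALSE, FALSE)),
    "no affected")
})

test_that("PED round trip preserves links, phenotype and availability", {
  ped <- quartet_pedigree(father = "FA", mother = "MO",
                          children = c("S1", "S2"),
                          affected = c(TRUE, FALSE),
                          sampled = c(TRUE, FALSE, TRUE, TRUE), fid = "F9")
  path <- withr::local_tempfile(fileext = ".ped")
  write_ped(ped, path)
  back <- read_ped(path)
  expect_identical(back$id, ped$id)
  expect_identical(back$father, ped$father)
  expect_identical(back$affected, ped$affected)
  expect_identical(back$sample_available, ped$sample_available)
})

test_that("multi-allelic decomposition preserves per-sample dosage", {
  set.seed(42)
  path <- withr::local_tempfile(fileext = ".vcf")
  n_samples <- 4
  gts <- replicate(n_samples, paste(sample(c("0", "1", "2"), 2, TRUE),
                                    collapse = "/"))
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", paste0("S", 1:n_samples)),
                   collapse = "\t"),
             paste(c("7", "100", ".", "G", "A,T", ".", ".", "MQ=50", "GT",
                     gts), collapse = "\t"))
  writeLines(lines, path)
  vs <- read_vcf(path)
  expect_equal(n_variants(vs), 2)
  dosage <- colSums(vs$geno)
  expected <- vapply(gts, function(g)
    sum(strsplit(g, "/")[[1]] != "0"), numeric(1))
  expect_equal(unname(dosage), unname(expected))
})

test_that("variant set enforces its invariants", {
  expect_error(variant_set(data.frame(contig = "1", pos = 0, ref = "A",
                                      alt = "T"), matrix(1L)),
               ">= 1")
  expect_error(variant_set(data.frame(contig = "1", pos = 5, ref = "A",
                                      alt = "A"), matrix(1L)),
               "differ")
  expect_error(variant_set(data.frame(contig = "1", pos = 5, ref = "A",
                                      alt = "T"), matrix(3L)),
               "allele counts")
  vs <- variant_set(data.frame(contig = "chr17", pos = 10, ref = "g",
                               alt = "a"),
                    matrix(1L, dimnames = list(NULL, "S")))
  expect_identical(vs$site$key, "17:10:G:A")
})
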