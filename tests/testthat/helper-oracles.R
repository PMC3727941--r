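# Independent oracles used to freeze expected values. These deliberately use
# different code paths than the package implementation.

# full-CDS translation through Biostrings (vs the single-codon classifier)
oracle_translate <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "error"))
}

# brute-force per-base scan for low-coverage runs (vs the rle-based finder)
oracle_gaps <- function(depth, start, threshold, contig = "1") {
  rows <- list()
  open <- NA_integer_
  for (i in seq_along(depth)) {
    if (depth[i] < threshold) {
      if (is.na(open)) open <- i
    } else if (!is.na(open)) {
      rows[[length(rows) + 1L]] <- c(open, i - 1L)
      open <- NA_integer_
    }
  }
  if (!is.na(open)) rows[[length(rows) + 1L]] <- c(open, length(depth))
  if (!length(rows))
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  m <- do.call(rbind, rows)
  data.frame(contig = contig, start = start + m[, 1] - 1L,
             end = start + m[, 2] - 1L, stringsAsFactors = FALSE)
}

# exhaustive phase oracle for a double-het child: enumerate every phased
# parental configuration (4 haplotype bits per parent via expand.grid) and
# every transmission that reproduces a het/het child, then classify
oracle_phase <- function(gfa, gmo) {
  bits <- expand.grid(fa1A = 0:1, fa1B = 0:1, fa2A = 0:1, fa2B = 0:1,
                      mo1A = 0:1, mo1B = 0:1, mo2A = 0:1, mo2B = 0:1)
  ok <- bits$fa1A + bits$fa2A == gfa[1] & bits$fa1B + bits$fa2B == gfa[2] &
    bits$mo1A + bits$mo2A == gmo[1] & bits$mo1B + bits$mo2B == gmo[2]
  bits <- bits[ok, , drop = FALSE]
  kinds <- character()
  for (r in seq_len(nrow(bits))) {
    b <- bits[r, ]
    paternal <- list(c(b$fa1A, b$fa1B), c(b$fa2A, b$fa2B))
    maternal <- list(c(b$mo1A, b$mo1B), c(b$mo2A, b$mo2B))
    for (p in paternal) for (m in maternal) {
      if (p[1] + m[1] == 1 && p[2] + m[2] == 1) {
        kinds <- c(kinds,
                   if ((p[1] == 1 && m[2] == 1) || (p[2] == 1 && m[1] == 1))
                     "trans" else "cis")
      }
    }
  }
  kinds <- unique(kinds)
  hom <- any(c(gfa, gmo) == 2)
  if (identical(kinds, "trans") && !hom) "TRANS_CONFIRMED"
  else if (identical(kinds, "cis")) "CIS_REJECTED"
  else "PHASE_UNKNOWN"
}

# two-variant quartet fixture with prescribed genotypes
# geno rows: variant A, variant B; columns: FA, MO, S1, S2
pair_fixture <- function(geno) {
  g <- toy_deafness_genes()$GRHL2
  a <- cds_snv(g, 100L, "G")
  b <- cds_snv(g, 400L, "T")
  site <- rbind(a, b)
  site$mq <- 60
  colnames(geno) <- c("FA", "MO", "S1", "S2")
  list(vs = variant_set(site, geno),
       ped = quartet_pedigree(father = "FA", mother = "MO",
                              children = c("S1", "S2")),
       gene = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genomic-strand reference sequence of a plus-strand gene, read from its CDS
substr_ref <- function(g, pos, len) {
  stopifnot(g$strand == "+")
  cstart <- famexome:::cds_coord(g, pos)
  substr(g$cds_seq, cstart, cstart + len - 1L)
}

default_funnel_dbs <- function(sim) {
  list(sim$dbs$control_exome, sim$dbs$snp_catalogue)
}

run_sim_pipeline <- function(sim, ...) {
  run_pipeline(sim$vs, sim$ped, sim$genes, sim$panel,
               default_funnel_dbs(sim), list(sim$dbs$frequency_catalogue),
               ...)
}
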