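# Deterministic toy gene construction. Sequences are generated from a fixed
# internal RNG stream so the models are stable constants of the package.

rand_cds <- function(n_codons, seed, planted = list()) {
  stopifnot(n_codons >= 2)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  body <- with_seed(seed, sample(sense, n_codons - 2L, replace = TRUE))
  all <- c("ATG", body, "TAA")
  for (idx in names(planted)) {
    i <- as.integer(idx)
    stopifnot(i >= 1, i <= n_codons)
    all[i] <- planted[[idx]]
  }
  paste(all, collapse = "")
}

# Evaluate code under a private seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old))
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Build a toy gene model
#'
#' Constructs a single-transcript gene whose CDS covers all exons, with a
#' reproducible random coding sequence (start codon first, single stop
#' last, no internal stops) into which specific codons can be planted.
#'
#' @param symbol gene symbol.
#' @param contig chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_lengths integer vector of exon lengths (sum divisible by 3).
#' @param gene_start genomic start of the first exon.
#' @param intron_length intron size between consecutive exons (scalar or
#'   vector of length `length(exon_lengths) - 1`).
#' @param planted_codons named list: names are codon indices, values codons,
#'   e.g. `list("2146" = "CGG")`.
#' @param seed seed for the sequence (independent of the global RNG).
#' @return a [gene_model()].
#' @export
toy_gene <- function(symbol, contig, strand, exon_lengths, gene_start,
                     intron_length = 500L, planted_codons = list(),
                     seed = 100) {
  stopifnot(sum(exon_lengths) %% 3 == 0)
  n <- length(exon_lengths)
  if (length(intron_length) == 1L) intron_length <- rep(intron_length, n - 1L)
  starts <- integer(n); ends <- integer(n)
  starts[1] <- as.integer(gene_start)
  for (i in seq_len(n)) {
    if (i > 1) starts[i] <- ends[i - 1L] + intron_length[i - 1L] + 1L
    ends[i] <- starts[i] + exon_lengths[i] - 1L
  }
  cds <- rand_cds(sum(exon_lengths) %/% 3L, seed, planted_codons)
  gene_model(symbol, contig, strand, cbind(starts, ends),
             starts[1], ends[n], cds)
}

#' Toy deafness gene panel
#'
#' A small panel of synthetic gene models standing in for reported
#' nonsyndromic deafness genes. The `MYO15A` model mirrors the structure of
#' myosin XVA's transcript where it matters for the worked examples: exon 11
#' ends at coding position 4320 (so its donor-site variant is c.4320+1,
#' alias IVS11+1), exon 29 carries codons 2146 (arginine, CGG) and 2161
#' (serine, TCC), and genomic coordinates of those sites match the hg19
#' positions reported for the real gene. All sequences are synthetic.
#'
#' @return a [gene_model_list()] with toy `MYO15A`, `GRHL2`, `TECTA`,
#'   `OTOF` and `CDH23` models.
#' @export
toy_deafness_genes <- function() {
  # MYO15A toy: 30 exons; exons 1-10 of 393 nt, exon 11 of 390 nt (CDS 4320
  # at its 3' edge), exons 12-28 of 120 nt, exon 29 of 180 nt (CDS
  # 6361-6540), exon 30 of 60 nt. Anchored so that exon 11 ends at
  # 17:18035880 and exon 29 starts at 17:18049273.
  ex_len <- c(rep(393L, 10), 390L, rep(120L, 17), 180L, 60L)
  # place exons 1..11 backwards from the exon-11 anchor with 500-bp introns
  e11_end <- 18035880L
  starts <- integer(30); ends <- integer(30)
  ends[11] <- e11_end; starts[11] <- ends[11] - ex_len[11] + 1L
  for (i in 10:1) {
    ends[i] <- starts[i + 1L] - 501L
    starts[i] <- ends[i] - ex_len[i] + 1L
  }
  for (i in 12:28) {
    starts[i] <- ends[i - 1L] + 631L
    ends[i] <- starts[i] + ex_len[i] - 1L
  }
  starts[29] <- 18049273L; ends[29] <- starts[29] + ex_len[29] - 1L
  stopifnot(starts[29] > ends[28])
  starts[30] <- ends[29] + 601L; ends[30] <- starts[30] + ex_len[30] - 1L
  cds <- rand_cds(sum(ex_len) %/% 3L, seed = 153,
                  planted = list("2146" = "CGG", "2161" = "TCC"))
  myo <- gene_model("MYO15A", "17", "+", cbind(starts, ends),
                    starts[1], ends[30], cds)
  grhl2 <- toy_gene("GRHL2", "8", "+", c(450L, 450L, 450L), 102500000L,
                    intron_length = 800L,
                    planted_codons = list("445" = "CAG"), seed = 154)
  tecta <- toy_gene("TECTA", "11", "+", c(999L, 999L, 999L, 993L),
                    120970000L, intron_length = 1200L,
                    planted_codons = list("1321" = "ACC"), seed = 155)
  otof <- toy_gene("OTOF", "2", "-", c(600L, 600L, 600L), 26680000L,
                   intron_length = 700L, seed = 156)
  cdh23 <- toy_gene("CDH23", "10", "+", c(900L, 900L), 73150000L,
                    intron_length = 900L, seed = 157)
  gene_model_list(list(myo, grhl2, tecta, otof, cdh23))
}

#' Toy background gene models
#'
#' Synthetic non-panel genes in which the simulator places background
#' variation.
#'
#' @param n number of genes.
#' @return a [gene_model_list()] of `n` three-exon genes named
#'   `BG01`, `BG02`, ...
#' @export
toy_background_genes <- function(n = 20) {
  gl <- lapply(seq_len(n), function(i) {
    toy_gene(sprintf("BG%02d", i), contig = as.character((i - 1L) %% 12L + 1L),
             strand = if (i %% 2) "+" else "-",
             exon_lengths = c(300L, 300L, 300L),
             gene_start = 40000000L + i * 100000L,
             intron_length = 400L, seed = 200 + i)
  })
  gene_model_list(gl)
}

#' Toy protein-domain map for the deafness panel
#'
#' Residue intervals labelling the motor and MyTH4 domains of the toy
#' `MYO15A` model (the splice-site anchor residue 1440 falls in the motor
#' span; residues 2146 and 2161 fall in the MyTH4 span).
#'
#' @return data.frame with columns `gene`, `aa_start`, `aa_end`, `label`.
#' @export
toy_domain_map <- function() {
  data.frame(gene = c("MYO15A", "MYO15A", "MYO15A"),
             aa_start = c(300L, 1960L, 2050L),
             aa_end = c(1750L, 2040L, 2270L),
             label = c("Motor", "IQ", "MyTH4"),
             stringsAsFactors = FALSE)
}
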