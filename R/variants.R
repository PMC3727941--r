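#' Variant set container
#'
#' A `variant_set` holds biallelic variant sites together with per-sample
#' genotype calls. Multi-allelic records are decomposed at read time, so
#' every row has exactly one alternate allele. Genotypes are stored as
#' alternate-allele counts (0, 1, 2) with `NA` for missing calls; missing is
#' distinct from homozygous reference.
#'
#' @param site data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `mq` (site mapping quality, `NA` when absent).
#' @param geno integer matrix, one row per site, one column per sample
#'   (column names are sample ids), entries in `{0, 1, 2, NA}`.
#' @return an object of class `variant_set`: a list with elements `site`
#'   (with an added identity `key` column), `geno` and `samples`.
#' @details The identity key of a variant is
#'   `contig:pos:REF:ALT` with a leading `"chr"` stripped from the contig and
#'   alleles uppercased; two variants are the same site if and only if their
#'   keys are equal. Inputs are required pre-normalized (no indel
#'   left-alignment is performed).
#' @export
variant_set <- function(site, geno) {
  stopifnot(is.data.frame(site),
            all(c("contig", "pos", "ref", "alt") %in% names(site)))
  if (is.null(site$mq)) site$mq <- NA_real_
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = nrow(site))
  stopifnot(nrow(geno) == nrow(site))
  site$contig <- as.character(site$contig)
  site$pos <- as.integer(site$pos)
  site$ref <- toupper(as.character(site$ref))
  site$alt <- toupper(as.character(site$alt))
  if (any(site$pos < 1)) stop("variant positions must be >= 1")
  if (any(site$ref == site$alt)) stop("ref and alt alleles must differ")
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) stop("genotype allele counts must be 0, 1, 2 or NA")
  site$key <- variant_key(site$contig, site$pos, site$ref, site$alt)
  geno <- matrix(as.integer(geno), nrow = nrow(site), ncol = ncol(geno),
                 dimnames = list(site$key, colnames(geno)))
  rownames(site) <- NULL
  structure(list(site = site, geno = geno, samples = colnames(geno)),
            class = "variant_set")
}

#' Variant identity key
#'
#' Builds the `contig:pos:REF:ALT` identity key used for all subtraction,
#' intersection and database lookups. Contig naming dialects are normalized
#' by stripping a leading `"chr"`; alleles are uppercased.
#'
#' @param contig,pos,ref,alt vectors describing biallelic variants.
#' @return character vector of keys.
#' @export
variant_key <- function(contig, pos, ref, alt) {
  paste(norm_contig(contig), as.integer(pos), toupper(ref), toupper(alt),
        sep = ":")
}

norm_contig <- function(contig) sub("^chr", "", as.character(contig),
                                    ignore.case = TRUE)

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d samples (%s)\n",
              nrow(x$site), length(x$samples),
              paste(head(x$samples, 6), collapse = ", ")))
  invisible(x)
}

#' @export
`[.variant_set` <- function(x, i, ...) {
  site <- x$site[i, , drop = FALSE]
  rownames(site) <- NULL
  geno <- x$geno[i, , drop = FALSE]
  structure(list(site = site, geno = geno, samples = x$samples),
            class = "variant_set")
}

#' Number of variants in a set
#'
#' @param vs a [variant_set()].
#' @return integer count of sites.
#' @export
n_variants <- function(vs) nrow(vs$site)

#' Subset a variant set by identity keys
#'
#' @param vs a [variant_set()].
#' @param keys character vector of variant keys to keep.
#' @return a `variant_set` restricted to `keys` (input order preserved).
#' @export
subset_by_key <- function(vs, keys) vs[vs$site$key %in% keys]

#' Carrier samples of a variant
#'
#' A sample is a carrier if it holds at least one alternate allele. Missing
#' genotypes count as non-carrier (presence-based semantics); callers that
#' need auditability should inspect the genotype matrix directly.
#'
#' @param vs a [variant_set()].
#' @param key a single variant key.
#' @return character vector of carrier sample ids.
#' @export
carriers <- function(vs, key) {
  g <- vs$geno[match(key, vs$site$key), ]
  vs$samples[!is.na(g) & g >= 1]
}

#' Per-sample carried variants
#'
#' @param vs a [variant_set()].
#' @param sample a sample id present in `vs`.
#' @return a `variant_set` of the sites where `sample` carries at least one
#'   alternate allele.
#' @export
sample_variants <- function(vs, sample) {
  if (!sample %in% vs$samples) stop("unknown sample: ", sample)
  g <- vs$geno[, sample]
  vs[!is.na(g) & g >= 1]
}
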