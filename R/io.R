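#' Read a multi-sample VCF
#'
#' Parses a VCF v4.x subset (CHROM POS ID REF ALT QUAL FILTER INFO FORMAT +
#' sample columns) with vcfR and converts it to a [variant_set()].
#' Multi-allelic records are decomposed into biallelic variants: for each
#' alternate allele, a sample's allele count is the number of genotype
#' alleles equal to that alternate, so per-sample counts summed over the
#' decomposed variants equal the original alternate-allele dosage. Site
#' mapping quality is taken from `INFO/MQ` when present (`NA` otherwise);
#' QUAL and FILTER are parsed but ignored. Phased separators (`|`) are read
#' as unphased. Record order is preserved.
#'
#' @param path VCF file path (plain text).
#' @return a [variant_set()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF ", path, ": ",
                                         conditionMessage(e)))
  samples <- colnames(v@gt)[-1]
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(variant_set(
      data.frame(contig = character(), pos = integer(), ref = character(),
                 alt = character(), mq = numeric()),
      matrix(integer(), 0, length(samples),
             dimnames = list(NULL, samples))))
  }
  gt_raw <- if (length(samples)) {
    sub(":.*$", "", v@gt[, -1, drop = FALSE])
  } else matrix(character(), nrow(fix), 0)
  mq <- suppressWarnings(as.numeric(sub("^.*?\\bMQ=([-0-9.eE+]+).*$", "\\1",
                                        paste0(";", fix[, "INFO"]))))
  has_mq <- grepl("(^|;)MQ=", fix[, "INFO"])
  mq[!has_mq] <- NA_real_

  rows <- vector("list", nrow(fix))
  for (r in seq_len(nrow(fix))) {
    pos <- suppressWarnings(as.integer(fix[r, "POS"]))
    if (is.na(pos))
      stop("malformed VCF record ", r, " in ", path, ": bad POS")
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    if (!length(alts) || any(alts == ""))
      stop("malformed VCF record ", r, " in ", path, ": bad ALT")
    alleles <- strsplit(gt_raw[r, ], "[/|]")
    counts <- vapply(seq_along(alts), function(k) {
      vapply(alleles, function(a) {
        a <- a[!is.na(a)]
        if (!length(a) || all(a == ".")) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
    }, integer(length(samples)))
    counts <- matrix(counts, nrow = length(alts), byrow = TRUE)
    rows[[r]] <- list(site = data.frame(contig = unname(fix[r, "CHROM"]),
                                        pos = pos,
                                        ref = unname(fix[r, "REF"]),
                                        alt = unname(alts),
                                        mq = unname(mq[r]),
                                        stringsAsFactors = FALSE),
                      geno = counts)
  }
  site <- do.call(rbind, lapply(rows, `[[`, "site"))
  geno <- do.call(rbind, lapply(rows, `[[`, "geno"))
  colnames(geno) <- samples
  variant_set(site, geno)
}

#' Write a variant set as VCF
#'
#' Emits the VCF subset read by [read_vcf()]: biallelic records with
#' `INFO/MQ` (when known) and per-sample unphased `GT`. Contigs are written
#' in the dialect stored in the variant set.
#'
#' @param vs a [variant_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  gt_str <- matrix("./.", n_variants(vs), length(vs$samples))
  gt_str[!is.na(vs$geno) & vs$geno == 0] <- "0/0"
  gt_str[!is.na(vs$geno) & vs$geno == 1] <- "0/1"
  gt_str[!is.na(vs$geno) & vs$geno == 2] <- "1/1"
  info <- ifelse(is.na(vs$site$mq), ".",
                 paste0("MQ=", format(vs$site$mq, trim = TRUE,
                                      scientific = FALSE)))
  body <- cbind(vs$site$contig, vs$site$pos, ".", vs$site$ref, vs$site$alt,
                ".", ".", info, "GT", gt_str)
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", vs$samples), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(body)) writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a population variant database
#'
#' Tab-separated table with columns `contig`, `pos`, `ref`, `alt`, `maf`
#' (an optional trailing `db_name` column is ignored). A blank `maf` records
#' presence without a frequency estimate, the membership semantics of a
#' control-exome set; a numeric `maf` in `[0, 1]` records a catalogued minor
#' allele frequency. Lookup is by exact variant identity key.
#'
#' @param path TSV path. A header line is detected and skipped.
#' @param name database label used in funnel stage names.
#' @return an object of class `population_db`: list with `name` and `maf`
#'   (named numeric vector keyed by variant key; `NA` = present without
#'   frequency).
#' @export
read_population_db <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) && grepl("^contig\\b", lines[1])) lines <- lines[-1]
  if (!length(lines)) return(population_db(name, setNames(numeric(), character())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 0L) < 4))
    stop("malformed population DB row in ", path)
  key <- vapply(parts, function(p)
    variant_key(p[1], p[2], p[3], p[4]), "")
  maf <- vapply(parts, function(p) {
    m <- if (length(p) >= 5) p[5] else ""
    if (is.na(m) || m == "" || m == ".") NA_real_ else as.numeric(m)
  }, numeric(1))
  if (any(!is.na(maf) & (maf < 0 | maf > 1)))
    stop("MAF outside [0,1] in ", path)
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      vals <- maf[key == k]
      if (length(unique(vals[!is.na(vals)])) > 1 ||
          (any(is.na(vals)) && any(!is.na(vals))))
        stop("duplicate key ", k, " with conflicting MAF in ", path)
    }
    maf <- maf[!dup]; key <- key[!dup]
  }
  population_db(name, setNames(maf, key))
}

#' Construct a population database in memory
#'
#' @param name database label.
#' @param maf named numeric vector: names are variant keys, values are MAFs
#'   in `[0,1]` or `NA` for presence-without-frequency.
#' @return an object of class `population_db`.
#' @export
population_db <- function(name, maf) {
  stopifnot(is.numeric(maf))
  structure(list(name = name, maf = maf), class = "population_db")
}

#' Write a population database as TSV
#'
#' @param db a [population_db()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_db <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("contig\tpos\tref\talt\tmaf\tdb_name", con)
  if (length(db$maf)) {
    p <- strsplit(names(db$maf), ":", fixed = TRUE)
    writeLines(vapply(seq_along(db$maf), function(i) {
      m <- db$maf[i]
      paste(p[[i]][1], p[[i]][2], p[[i]][3], p[[i]][4],
            if (is.na(m)) "" else format(m, scientific = FALSE, trim = TRUE),
            db$name, sep = "\t")
    }, ""), con)
  }
  invisible(path)
}

#' @export
print.population_db <- function(x, ...) {
  cat(sprintf("population_db '%s': %d entries (%d with MAF)\n",
              x$name, length(x$maf), sum(!is.na(x$maf))))
  invisible(x)
}

#' Read a gene panel
#'
#' One gene symbol per line; `#` starts a comment. Symbols are uppercased
#' and de-duplicated.
#'
#' @param path panel file path.
#' @return character vector of class `gene_panel`.
#' @export
read_gene_panel <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  sym <- unique(toupper(lines[nzchar(lines)]))
  if (!length(sym)) stop("gene panel is empty: ", path)
  structure(sym, class = "gene_panel")
}

#' Read an in-silico score table
#'
#' Pass-through annotations produced by external predictors; never computed
#' here. Tab-separated with header
#' `contig pos ref alt conserved sift polyphen2 mupro` (score columns
#' optional / may be blank).
#'
#' @param path TSV path.
#' @return data.frame keyed by variant `key` with columns `conserved`,
#'   `sift`, `polyphen2`, `mupro`.
#' @export
read_score_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("NA", "", "."))
  for (col in c("conserved", "sift", "polyphen2", "mupro"))
    if (is.null(tab[[col]])) tab[[col]] <- NA
  data.frame(key = variant_key(tab$contig, tab$pos, tab$ref, tab$alt),
             conserved = tab$conserved, sift = as.numeric(tab$sift),
             polyphen2 = as.numeric(tab$polyphen2),
             mupro = as.numeric(tab$mupro), stringsAsFactors = FALSE)
}

#' Read a protein-domain map
#'
#' Tab-separated `gene aa_start aa_end label` (1-based inclusive residue
#' coordinates). Overlapping intervals within a gene are rejected.
#'
#' @param path TSV path (header optional).
#' @return data.frame with columns `gene`, `aa_start`, `aa_end`, `label`.
#' @export
read_domain_map <- function(path) {
  tab <- read.table(path, header = grepl("^gene\\b", readLines(path, 1)),
                    sep = "\t", stringsAsFactors = FALSE)
  names(tab) <- c("gene", "aa_start", "aa_end", "label")
  validate_domain_map(tab)
}

validate_domain_map <- function(map) {
  map$aa_start <- as.integer(map$aa_start)
  map$aa_end <- as.integer(map$aa_end)
  for (g in unique(map$gene)) {
    m <- map[map$gene == g, ]
    m <- m[order(m$aa_start), ]
    if (nrow(m) > 1 && any(m$aa_start[-1] <= m$aa_end[-nrow(m)]))
      stop("overlapping domain intervals for gene ", g)
  }
  map
}

#' Read a per-base depth track
#'
#' Tab-separated `contig pos depth` with 1-based positions. Rows may be
#' unsorted; each contig's track spans its minimum to maximum listed
#' position, and unlisted positions inside that span have depth 0.
#'
#' @param path TSV path (header optional).
#' @return list of [depth_track()] objects, one per contig.
#' @export
read_depth_track <- function(path) {
  tab <- read.table(path, header = grepl("^contig\\b", readLines(path, 1)),
                    sep = "\t", stringsAsFactors = FALSE)
  names(tab) <- c("contig", "pos", "depth")
  if (any(tab$depth < 0)) stop("negative depth in ", path)
  out <- lapply(split(tab, tab$contig), function(d) {
    d <- d[order(d$pos), ]
    start <- min(d$pos); end <- max(d$pos)
    depth <- integer(end - start + 1L)
    depth[d$pos - start + 1L] <- as.integer(d$depth)
    depth_track(d$contig[1], start, depth)
  })
  unname(out)
}

#' Write a per-base depth track
#'
#' @param tracks list of [depth_track()] objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(tracks, path) {
  if (inherits(tracks, "depth_track")) tracks <- list(tracks)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("contig\tpos\tdepth", con)
  for (tr in tracks) {
    pos <- seq(tr$start, tr$end)
    writeLines(paste(tr$contig, pos, tr$depth, sep = "\t"), con)
  }
  invisible(path)
}

#' Merge overlapping or abutting intervals
#'
#' @param intervals data.frame with columns `contig`, `start`, `end`
#'   (1-based inclusive).
#' @return merged data.frame sorted by contig then start.
#' @export
merge_intervals <- function(intervals) {
  if (!nrow(intervals))
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  intervals <- intervals[order(intervals$contig, intervals$start), ]
  out <- intervals[1, , drop = FALSE]
  if (nrow(intervals) > 1) {
    for (i in 2:nrow(intervals)) {
      last <- nrow(out)
      if (intervals$contig[i] == out$contig[last] &&
          intervals$start[i] <= out$end[last] + 1L) {
        out$end[last] <- max(out$end[last], intervals$end[i])
      } else {
        out <- rbind(out, intervals[i, ])
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Write intervals as BED3
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open. Overlapping or abutting intervals are merged and the output is
#' sorted by contig then start.
#'
#' @param intervals data.frame with columns `contig`, `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  merged <- merge_intervals(intervals)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(merged))
    writeLines(paste(merged$contig, merged$start - 1L, merged$end,
                     sep = "\t"), con)
  invisible(path)
}

#' Read a BED3 file into 1-based inclusive intervals
#'
#' @param path BED path.
#' @return data.frame with columns `contig`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(contig = vapply(parts, `[`, "", 1),
             start = as.integer(vapply(parts, `[`, "", 2)) + 1L,
             end = as.integer(vapply(parts, `[`, "", 3)),
             stringsAsFactors = FALSE)
}
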