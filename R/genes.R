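#' Gene model
#'
#' A single-transcript gene model: exon intervals, the genomic CDS interval
#' and the (strand-corrected) coding sequence used for functional annotation.
#' Coordinates are 1-based inclusive genomic positions throughout.
#'
#' @param symbol gene symbol.
#' @param contig chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix or data.frame of exon `start`, `end`
#'   (1-based inclusive), non-overlapping, sorted in genomic order.
#' @param cds_start,cds_end genomic bounds of the coding region; must fall
#'   inside the exon union.
#' @param cds_seq coding nucleotide sequence in transcript orientation
#'   (5'-3' on the coding strand); length must equal the exonic span of
#'   `[cds_start, cds_end]` and be divisible by 3.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(symbol, contig, strand, exons, cds_start, cds_end,
                       cds_seq) {
  exons <- as.data.frame(exons)
  names(exons) <- c("start", "end")
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  stopifnot(strand %in% c("+", "-"), all(exons$start <= exons$end))
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop(symbol, ": exons must be sorted and non-overlapping")
  cds_seq <- toupper(cds_seq)
  if (nchar(cds_seq) %% 3 != 0)
    stop(symbol, ": CDS length must be divisible by 3")
  g <- structure(list(symbol = symbol, contig = as.character(contig),
                      strand = strand, exons = exons,
                      cds_start = as.integer(cds_start),
                      cds_end = as.integer(cds_end),
                      cds_seq = cds_seq),
                 class = "gene_model")
  # CDS interval must sit inside the exon union, and its exonic width must
  # match the supplied sequence
  if (!pos_in_exons(g, g$cds_start) || !pos_in_exons(g, g$cds_end))
    stop(symbol, ": CDS bounds outside exons")
  if (sum(exon_cds_width(g)) != nchar(cds_seq))
    stop(symbol, ": CDS sequence length (", nchar(cds_seq),
         ") does not match exonic CDS width (", sum(exon_cds_width(g)), ")")
  g$tx <- compute_tx_exons(g)
  g
}

exon_cds_width <- function(g) {
  pmax(0L, pmin(g$exons$end, g$cds_end) - pmax(g$exons$start, g$cds_start) + 1L)
}

pos_in_exons <- function(g, pos) {
  any(pos >= g$exons$start & pos <= g$exons$end)
}

gene_span <- function(g) c(min(g$exons$start), max(g$exons$end))

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d exons, CDS %d..%d (%d nt)\n",
              x$symbol, x$contig, x$strand, nrow(x$exons),
              x$cds_start, x$cds_end, nchar(x$cds_seq)))
  invisible(x)
}

# Exon table in transcript (5'->3') order with cumulative transcript offsets
# of the CDS portion of each exon. Used by the annotator.
tx_exons <- function(g) {
  if (!is.null(g$tx)) return(g$tx)
  compute_tx_exons(g)
}

compute_tx_exons <- function(g) {
  ex <- g$exons
  ex$index_tx <- if (g$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  ord <- order(ex$index_tx)
  ex <- ex[ord, , drop = FALSE]
  ex$cds_w <- exon_cds_width(g)[ord]
  ex$cds_tx_end <- cumsum(ex$cds_w)
  ex$cds_tx_start <- ex$cds_tx_end - ex$cds_w + 1L
  ex
}

# Map a genomic position to a CDS coordinate (1-based along cds_seq).
# Returns NA for positions outside the CDS.
cds_coord <- function(g, pos) {
  if (pos < g$cds_start || pos > g$cds_end) return(NA_integer_)
  ex <- tx_exons(g)
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (!length(hit)) return(NA_integer_)
  e <- ex[hit, ]
  lo <- max(e$start, g$cds_start); hi <- min(e$end, g$cds_end)
  if (pos < lo || pos > hi) return(NA_integer_)
  off <- if (g$strand == "+") pos - lo else hi - pos
  as.integer(e$cds_tx_start + off)
}

# Genomic position of every CDS coordinate (vector indexed by CDS position).
cds_genomic_map <- function(g) {
  ex <- tx_exons(g)
  out <- integer(nchar(g$cds_seq))
  for (i in seq_len(nrow(ex))) {
    if (ex$cds_w[i] == 0L) next
    lo <- max(ex$start[i], g$cds_start); hi <- min(ex$end[i], g$cds_end)
    idx <- ex$cds_tx_start[i]:ex$cds_tx_end[i]
    out[idx] <- if (g$strand == "+") lo:hi else hi:lo
  }
  out
}

# Inverse of cds_coord: genomic position of a 1-based CDS coordinate.
genomic_coord <- function(g, cpos) {
  ex <- tx_exons(g)
  hit <- which(cpos >= ex$cds_tx_start & cpos <= ex$cds_tx_end & ex$cds_w > 0)
  if (!length(hit)) stop("CDS coordinate out of range: ", cpos)
  e <- ex[hit[1], ]
  lo <- max(e$start, g$cds_start); hi <- min(e$end, g$cds_end)
  off <- cpos - e$cds_tx_start
  if (g$strand == "+") as.integer(lo + off) else as.integer(hi - off)
}

#' Read gene models from JSON
#'
#' Expects an array of objects with fields `symbol`, `contig`, `strand`,
#' `exons` (array of `[start, end]` pairs), `cds_start`, `cds_end`,
#' `cds_seq`.
#'
#' @param path JSON file path.
#' @return named list of [gene_model()] objects (class `gene_model_list`).
#' @export
read_gene_models <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  gl <- lapply(raw, function(r) {
    ex <- do.call(rbind, lapply(r$exons, function(e) as.integer(unlist(e))))
    gene_model(r$symbol, r$contig, r$strand, ex, r$cds_start, r$cds_end,
               r$cds_seq)
  })
  gene_model_list(gl)
}

#' Write gene models to JSON
#'
#' @param genes a `gene_model_list` or list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  raw <- lapply(unclass(genes), function(g) {
    list(symbol = g$symbol, contig = g$contig, strand = g$strand,
         exons = lapply(seq_len(nrow(g$exons)),
                        function(i) c(g$exons$start[i], g$exons$end[i])),
         cds_start = g$cds_start, cds_end = g$cds_end, cds_seq = g$cds_seq)
  })
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bundle gene models
#'
#' @param genes list of [gene_model()] objects.
#' @return named list of class `gene_model_list`.
#' @export
gene_model_list <- function(genes) {
  stopifnot(all(vapply(genes, inherits, TRUE, "gene_model")))
  names(genes) <- vapply(genes, `[[`, "", "symbol")
  structure(genes, class = "gene_model_list")
}

#' @export
print.gene_model_list <- function(x, ...) {
  cat("gene_model_list with", length(x), "genes:",
      paste(head(names(x), 10), collapse = ", "), "\n")
  invisible(x)
}
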