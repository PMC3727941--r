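#' Per-base depth track
#'
#' @param contig chromosome name.
#' @param start 1-based first position of the track.
#' @param depth integer vector of per-base read depths (non-negative); the
#'   track covers `start .. start + length(depth) - 1`.
#' @return object of class `depth_track`.
#' @export
depth_track <- function(contig, start, depth) {
  depth <- as.integer(depth)
  if (any(depth < 0)) stop("depths must be non-negative")
  structure(list(contig = as.character(contig), start = as.integer(start),
                 end = as.integer(start) + length(depth) - 1L,
                 depth = depth), class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track %s:%d-%d (mean %.1fx)\n", x$contig, x$start,
              x$end, mean(x$depth)))
  invisible(x)
}

#' Find low-coverage gaps in a depth track
#'
#' Returns the maximal runs of consecutive bases whose depth is below the
#' gap threshold — the regions that need orthogonal (e.g. Sanger) follow-up
#' sequencing.
#'
#' @param track a [depth_track()].
#' @param cfg a [pipeline_config()]; `cfg$depth_gap_threshold` (default 5)
#'   is the depth below which a base counts as missing.
#' @return data.frame with columns `contig`, `start`, `end` (1-based
#'   inclusive), possibly empty.
#' @export
find_gaps <- function(track, cfg = pipeline_config()) {
  low <- track$depth < cfg$depth_gap_threshold
  if (!any(low))
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  data.frame(contig = track$contig,
             start = track$start + starts[i] - 1L,
             end = track$start + ends[i] - 1L,
             stringsAsFactors = FALSE)
}

#' Summarize depth and breadth of coverage
#'
#' Computes the mean read depth over all track bases and, for each
#' configured threshold t, the fraction of bases with depth >= t (">= t"
#' semantics throughout).
#'
#' @param tracks list of [depth_track()] objects (or a single one).
#' @param cfg a [pipeline_config()].
#' @return object of class `coverage_summary`: list with `mean_depth`,
#'   `fraction` (named vector, one entry per threshold) and `n_bases`.
#' @export
summarize_coverage <- function(tracks, cfg = pipeline_config()) {
  if (inherits(tracks, "depth_track")) tracks <- list(tracks)
  depth <- unlist(lapply(tracks, `[[`, "depth"))
  if (!length(depth)) stop("no bases in depth tracks")
  fr <- vapply(cfg$coverage_thresholds, function(t) mean(depth >= t),
               numeric(1))
  names(fr) <- paste0("ge_", cfg$coverage_thresholds)
  structure(list(mean_depth = mean(depth), fraction = fr,
                 n_bases = length(depth)), class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("coverage over %d bases: mean depth %.1fx\n", x$n_bases,
              x$mean_depth))
  for (n in names(x$fraction))
    cat(sprintf("  fraction of bases at depth %s: %.1f%%\n",
                sub("ge_", ">=", n), 100 * x$fraction[n]))
  invisible(x)
}

#' Low-coverage gaps over a gene's exons
#'
#' Audits the sequencable footprint of a gene: each exon extended by the
#' splice window (so canonical splice sites are audited too). Bases of that
#' footprint not covered by any track are treated as depth 0, and gaps from
#' [find_gaps()] are clipped to the footprint, merged and sorted — ready for
#' [write_bed()].
#'
#' @param tracks list of [depth_track()] objects.
#' @param gene a [gene_model()].
#' @param cfg a [pipeline_config()].
#' @return data.frame with columns `contig`, `start`, `end` (1-based
#'   inclusive, merged).
#' @export
gaps_for_gene <- function(tracks, gene, cfg = pipeline_config()) {
  if (inherits(tracks, "depth_track")) tracks <- list(tracks)
  tracks <- Filter(function(t) norm_contig(t$contig) ==
                     norm_contig(gene$contig), tracks)
  w <- cfg$splice_window
  span <- gene_span(gene)
  # flank each exon by the splice window, but only into introns: the
  # transcript's outer edges have no splice sites to audit
  foot <- data.frame(contig = gene$contig,
                     start = pmax(gene$exons$start - w, span[1]),
                     end = pmin(gene$exons$end + w, span[2]))
  foot <- merge_intervals(foot)
  gaps <- list()
  for (i in seq_len(nrow(foot))) {
    pos <- seq(foot$start[i], foot$end[i])
    depth <- integer(length(pos))
    for (tr in tracks) {
      hit <- pos >= tr$start & pos <= tr$end
      if (any(hit)) depth[hit] <- tr$depth[pos[hit] - tr$start + 1L]
    }
    g <- find_gaps(depth_track(gene$contig, foot$start[i], depth), cfg)
    if (nrow(g)) gaps[[length(gaps) + 1L]] <- g
  }
  if (!length(gaps))
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  merge_intervals(do.call(rbind, gaps))
}
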