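.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  if (nchar(x) == 1L) {
    out <- .COMP[[x]]
    if (is.null(out)) stop("invalid base: ", x)
    return(out)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("invalid codon: ", codon)
  aa
}

empty_annotation <- function() {
  data.frame(key = character(), gene = character(), impact = character(),
             cdna = character(), ivs = character(), protein = character(),
             aa_pos = integer(), stringsAsFactors = FALSE)
}

#' Classify a variant against a gene model
#'
#' Assigns a functional impact class and HGVS-style labels from first
#' principles on the gene model: coding SNVs are classified by translating
#' the affected codon before and after the change (missense / nonsense /
#' synonymous, with a `p.` label); coding insertions or deletions are
#' frameshift when the length difference is not a multiple of 3, in-frame
#' otherwise; intronic positions within `splice_window` bases of an exon
#' boundary are splice-site, labelled with the `c.N+k` / `c.N-k` offset
#' convention plus the legacy `IVSk` alias (intron k follows exon k in
#' transcript order); exonic positions outside the CDS are UTR; everything
#' outside the gene span is intergenic. For minus-strand genes alleles are
#' reverse-complemented into transcript orientation before labelling.
#'
#' @param contig,pos,ref,alt a single biallelic variant (1-based position).
#' @param gene a [gene_model()].
#' @param cfg a [pipeline_config()].
#' @return one-row data.frame with columns `gene`, `impact`, `cdna`, `ivs`,
#'   `protein`, `aa_pos` (affected or nearest-flanking residue; `NA` when not
#'   mappable).
#' @export
classify_variant <- function(contig, pos, ref, alt, gene,
                             cfg = pipeline_config()) {
  ref <- toupper(ref); alt <- toupper(alt)
  pos <- as.integer(pos)
  span <- gene_span(gene)
  row <- function(impact, cdna = NA_character_, ivs = NA_character_,
                  protein = NA_character_, aa_pos = NA_integer_) {
    data.frame(gene = gene$symbol, impact = impact, cdna = cdna, ivs = ivs,
               protein = protein, aa_pos = aa_pos, stringsAsFactors = FALSE)
  }
  if (norm_contig(contig) != norm_contig(gene$contig) ||
      pos < span[1] || pos > span[2]) {
    out <- row("INTERGENIC")
    out$gene <- NA_character_
    return(out)
  }
  is_snv <- nchar(ref) == 1 && nchar(alt) == 1
  if (pos_in_exons(gene, pos)) {
    cpos <- cds_coord(gene, pos)
    if (is.na(cpos)) return(row("UTR"))
    if (!is_snv) {
      shift <- abs(nchar(ref) - nchar(alt))
      impact <- if (shift %% 3 != 0) "FRAMESHIFT_INDEL" else "INFRAME_INDEL"
      lab <- if (nchar(ref) > nchar(alt)) "del" else "ins"
      return(row(impact, cdna = paste0("c.", cpos, lab),
                 aa_pos = as.integer(ceiling(cpos / 3))))
    }
    cref <- if (gene$strand == "+") ref else revcomp(ref)
    calt <- if (gene$strand == "+") alt else revcomp(alt)
    seq_ref <- substr(gene$cds_seq, cpos, cpos)
    if (seq_ref != cref)
      stop(gene$symbol, ": reference allele ", cref, " at CDS position ",
           cpos, " disagrees with gene model sequence ", seq_ref)
    codon_idx <- as.integer(ceiling(cpos / 3))
    frame <- cpos - (codon_idx - 1L) * 3L
    codon <- substr(gene$cds_seq, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
    mcodon <- codon
    substr(mcodon, frame, frame) <- calt
    aa0 <- codon_aa(codon); aa1 <- codon_aa(mcodon)
    impact <- if (aa0 == aa1) "SYNONYMOUS"
              else if (aa1 == "*" || aa0 == "*") "NONSENSE"
              else "MISSENSE"
    row(impact, cdna = paste0("c.", cpos, cref, ">", calt),
        protein = paste0("p.", aa0, codon_idx, aa1), aa_pos = codon_idx)
  } else {
    # intronic: locate the intron in transcript order and the offset from
    # its donor (preceding exon) and acceptor (following exon) ends
    ex <- tx_exons(gene)
    if (gene$strand == "+") {
      j <- max(which(ex$end < pos))          # tx index of preceding exon
      donor_off <- pos - ex$end[j]
      acceptor_off <- ex$start[j + 1L] - pos
      donor_anchor_pos <- ex$end[j]
      acceptor_anchor_pos <- ex$start[j + 1L]
    } else {
      j <- max(which(ex$start > pos))
      donor_off <- ex$start[j] - pos
      acceptor_off <- pos - ex$end[j + 1L]
      donor_anchor_pos <- ex$start[j]
      acceptor_anchor_pos <- ex$end[j + 1L]
    }
    use_donor <- donor_off <= acceptor_off
    off <- if (use_donor) donor_off else acceptor_off
    anchor <- cds_coord(gene, if (use_donor) donor_anchor_pos
                              else acceptor_anchor_pos)
    sgn <- if (use_donor) "+" else "-"
    cref <- if (gene$strand == "+" || !is_snv) ref else revcomp(ref)
    calt <- if (gene$strand == "+" || !is_snv) alt else revcomp(alt)
    allele_tag <- if (is_snv) paste0(cref, ">", calt) else ""
    cdna <- if (is.na(anchor)) NA_character_
            else paste0("c.", anchor, sgn, off, allele_tag)
    if (off <= cfg$splice_window) {
      row("SPLICE", cdna = cdna, ivs = paste0("IVS", j, sgn, off),
          aa_pos = if (is.na(anchor)) NA_integer_
                   else as.integer(ceiling(anchor / 3)))
    } else {
      row("INTRONIC", cdna = cdna)
    }
  }
}

#' Annotate a variant set against gene models
#'
#' Locates each variant in the gene whose exon span contains it (gene models
#' are assumed non-overlapping; the first containing gene wins) and
#' classifies it with [classify_variant()]. Variants outside every gene are
#' `INTERGENIC` with gene `NA`.
#'
#' @param vs a [variant_set()].
#' @param genes a [gene_model_list()].
#' @param cfg a [pipeline_config()].
#' @return data.frame with one row per variant: `key`, `gene`, `impact`,
#'   `cdna`, `ivs`, `protein`, `aa_pos`; rows align with `vs$site`.
#' @export
annotate_variants <- function(vs, genes, cfg = pipeline_config()) {
  if (!n_variants(vs)) return(empty_annotation())
  spans <- data.frame(contig = vapply(genes, function(g) norm_contig(g$contig), ""),
                      lo = vapply(genes, function(g) gene_span(g)[1], 0L),
                      hi = vapply(genes, function(g) gene_span(g)[2], 0L),
                      sym = names(genes), stringsAsFactors = FALSE)
  ctg <- norm_contig(vs$site$contig)
  ann <- vector("list", n_variants(vs))
  for (i in seq_len(n_variants(vs))) {
    hit <- which(spans$contig == ctg[i] & spans$lo <= vs$site$pos[i] &
                   spans$hi >= vs$site$pos[i])
    if (length(hit)) {
      ann[[i]] <- classify_variant(vs$site$contig[i], vs$site$pos[i],
                                   vs$site$ref[i], vs$site$alt[i],
                                   genes[[spans$sym[hit[1]]]], cfg)
    } else {
      ann[[i]] <- data.frame(gene = NA_character_, impact = "INTERGENIC",
                             cdna = NA_character_, ivs = NA_character_,
                             protein = NA_character_, aa_pos = NA_integer_,
                             stringsAsFactors = FALSE)
    }
  }
  cbind(data.frame(key = vs$site$key, stringsAsFactors = FALSE),
        do.call(rbind, ann))
}

#' Join external in-silico scores onto annotations
#'
#' Scores (conservation flags and predictor outputs) are consumed as opaque
#' pass-through values keyed by variant identity; they are never computed
#' here. Variants absent from the table get `NA` in every score column.
#'
#' @param ann annotation data.frame from [annotate_variants()].
#' @param scores data.frame from [read_score_table()] (or `NULL`).
#' @return `ann` with columns `conserved`, `sift`, `polyphen2`, `mupro`
#'   appended.
#' @export
join_scores <- function(ann, scores = NULL) {
  if (is.null(scores)) {
    ann$conserved <- NA
    ann$sift <- ann$polyphen2 <- ann$mupro <- NA_real_
    return(ann)
  }
  i <- match(ann$key, scores$key)
  ann$conserved <- scores$conserved[i]
  ann$sift <- scores$sift[i]
  ann$polyphen2 <- scores$polyphen2[i]
  ann$mupro <- scores$mupro[i]
  ann
}

#' Assign protein-domain labels
#'
#' Labels each annotated variant with the protein domain containing its
#' affected residue. Splice variants use the residue of the flanking CDS
#' anchor position, so a donor-site variant inside a domain's coding span is
#' attributed to that domain.
#'
#' @param ann annotation data.frame from [annotate_variants()].
#' @param domain_map data.frame from [read_domain_map()] (or `NULL`).
#' @return `ann` with a `domain` column (`NA` when uncovered).
#' @export
assign_domain <- function(ann, domain_map = NULL) {
  ann$domain <- NA_character_
  if (is.null(domain_map) || !nrow(ann)) return(ann)
  domain_map <- validate_domain_map(domain_map)
  for (i in seq_len(nrow(ann))) {
    if (is.na(ann$gene[i]) || is.na(ann$aa_pos[i])) next
    hit <- which(domain_map$gene == ann$gene[i] &
                   domain_map$aa_start <= ann$aa_pos[i] &
                   domain_map$aa_end >= ann$aa_pos[i])
    if (length(hit)) ann$domain[i] <- domain_map$label[hit[1]]
  }
  ann
}
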