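#' Pedigree container
#'
#' Represents a nuclear (or extended) family: individuals, parental links,
#' affection status and whether a DNA sample is available for sequencing.
#' Parental references must resolve within the pedigree or be missing, no
#' individual may be its own ancestor, and at least one individual must be
#' affected.
#'
#' @param id,father,mother character vectors; `father`/`mother` entries are
#'   ids of other individuals or `NA` for founders.
#' @param sex integer or character (1/M = male, 2/F = female, 0 = unknown).
#' @param affected logical affection status (`NA` = unknown, treated as
#'   unaffected for analysis but never for exclusion logic).
#' @param sample_available logical; whether genotypes exist for the
#'   individual (defaults to `TRUE`).
#' @param fid family id (single value or vector).
#' @return a data.frame of class `pedigree`.
#' @export
pedigree <- function(id, father = NA, mother = NA, sex = 0,
                     affected = FALSE, sample_available = TRUE,
                     fid = "FAM1") {
  ped <- data.frame(fid = as.character(fid), id = as.character(id),
                    father = as.character(father),
                    mother = as.character(mother),
                    sex = as.character(sex),
                    affected = as.logical(affected),
                    sample_available = as.logical(sample_available),
                    stringsAsFactors = FALSE)
  ped$father[ped$father %in% c("0", "", "NA")] <- NA
  ped$mother[ped$mother %in% c("0", "", "NA")] <- NA
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  for (col in c("father", "mother")) {
    unresolved <- !is.na(ped[[col]]) & !(ped[[col]] %in% ped$id)
    if (any(unresolved))
      stop("unresolved ", col, " reference: ",
           paste(ped[[col]][unresolved], collapse = ", "))
  }
  # ancestor walk from every individual; revisiting the start is a cycle
  for (start in ped$id) {
    seen <- character()
    frontier <- start
    while (length(frontier)) {
      i <- match(frontier, ped$id)
      parents <- c(ped$father[i], ped$mother[i])
      parents <- unique(parents[!is.na(parents)])
      if (start %in% parents)
        stop("pedigree cycle: ", start, " is its own ancestor")
      frontier <- setdiff(parents, seen)
      seen <- union(seen, parents)
    }
  }
  if (!any(ped$affected %in% TRUE))
    stop("pedigree has no affected individual")
  invisible(ped)
}

#' Read a PED pedigree file
#'
#' Standard 6-column whitespace-delimited PED (family, individual, father,
#' mother, sex, phenotype) with phenotype coded 2 = affected, 1 = unaffected,
#' 0 or -9 = unknown. An optional 7th column `sample_available` in `{0, 1}`
#' marks individuals with sequenced DNA (defaults to 1).
#'
#' @param path path to the PED file.
#' @return a [pedigree()].
#' @export
read_ped <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "#")
  if (ncol(tab) < 6) stop("PED file must have at least 6 columns: ", path)
  pheno <- tab[[6]]
  affected <- ifelse(pheno == "2", TRUE,
                     ifelse(pheno == "1", FALSE, NA))
  avail <- if (ncol(tab) >= 7) tab[[7]] == "1" else TRUE
  pedigree(id = tab[[2]], father = tab[[3]], mother = tab[[4]],
           sex = tab[[5]], affected = affected, sample_available = avail,
           fid = tab[[1]])
}

#' Write a PED pedigree file
#'
#' @param ped a [pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(ped$fid, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    ped$sex,
                    ifelse(is.na(ped$affected), "0",
                           ifelse(ped$affected, "2", "1")),
                    ifelse(ped$sample_available, "1", "0"))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Affected individuals with available samples
#'
#' Returns the ids of affected pedigree members whose DNA was sequenced,
#' in pedigree order. These are the samples whose filtered variant sets are
#' intersected by [shared_variants()]. Warns when none qualify.
#'
#' @param ped a [pedigree()].
#' @return character vector of sample ids (possibly empty).
#' @export
affected_samples <- function(ped) {
  ids <- ped$id[ped$affected %in% TRUE & ped$sample_available]
  if (!length(ids))
    warning("pedigree has no affected individual with an available sample")
  ids
}

#' Sampled parents of an individual
#'
#' Resolves the father and mother of `child`, returning `NA` for founders
#' and for parents without an available DNA sample (an unsampled parent
#' cannot contribute genotypes to segregation analysis, as when parental DNA
#' could not be collected).
#'
#' @param ped a [pedigree()].
#' @param child an individual id present in `ped`.
#' @return named list with elements `father` and `mother` (id or `NA`), and
#'   attribute `"reason"` naming unsampled parents when applicable.
#' @export
parent_pair <- function(ped, child) {
  i <- match(child, ped$id)
  if (is.na(i)) stop("unknown individual: ", child)
  resolve <- function(pid) {
    if (is.na(pid)) return(list(id = NA_character_, reason = NULL))
    j <- match(pid, ped$id)
    if (!ped$sample_available[j])
      return(list(id = NA_character_,
                  reason = paste0(pid, ": sample not available")))
    list(id = pid, reason = NULL)
  }
  fa <- resolve(ped$father[i])
  mo <- resolve(ped$mother[i])
  out <- list(father = fa$id, mother = mo$id)
  reasons <- c(fa$reason, mo$reason)
  if (length(reasons)) attr(out, "reason") <- reasons
  out
}
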