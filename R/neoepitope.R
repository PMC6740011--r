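#' HLA alleles supported by the tetramer platform
#'
#' @return character vector of the six supported MHC class I alleles.
#' @export
supported_hla_panel <- function() {
  c("HLA-A*02:01", "HLA-A*01:01", "HLA-A*03:01", "HLA-A*11:01",
    "HLA-A*24:02", "HLA-B*07:02")
}

#' RNA-evidence filter for somatic mutations
#'
#' A mutation is retained only with 2 or more RNA-seq reads concordant with
#' the mutated allele. Mutations with exactly one supporting read sit in
#' the gap of the stated rule; they are discarded, with a warning so the
#' borderline cases are auditable.
#'
#' @param mutations data.frame with at least a `rna_reads` column (integer
#'   >= 0).
#' @return the retained rows.
#' @export
filter_expressed <- function(mutations) {
  stopifnot(is.data.frame(mutations))
  if (!nrow(mutations)) return(mutations)
  if (any(is.na(mutations$rna_reads) | mutations$rna_reads < 0))
    stop("validation error: rna_reads must be non-negative")
  n1 <- sum(mutations$rna_reads == 1)
  if (n1 > 0)
    warning(sprintf(
      "%d mutation(s) with exactly 1 supporting RNA read discarded", n1))
  mutations[mutations$rna_reads >= 2, , drop = FALSE]
}

#' Enumerate mutation-covering 8-11mer peptides
#'
#' All windows of length 8 to 11 that lie within the protein and cover the
#' mutated residue. Positions are 1-based and windows inclusive.
#'
#' @param protein protein sequence (single string).
#' @param position 1-based mutated residue position.
#' @param lengths window lengths to enumerate (default 8:11).
#' @return data.frame: peptide, length, start (1-based offset in the
#'   protein), mut_offset (position of the mutated residue within the
#'   peptide).
#' @export
enumerate_mutant_peptides <- function(protein, position, lengths = 8:11) {
  protein <- as.character(protein)
  L <- nchar(protein)
  if (position < 1 || position > L)
    stop(sprintf("validation error: position %d outside protein of length %d",
                 position, L))
  out <- list()
  for (len in lengths) {
    s_min <- max(1, position - len + 1)
    s_max <- min(position, L - len + 1)
    if (s_max < s_min) next
    for (s in s_min:s_max)
      out[[length(out) + 1]] <- data.frame(
        peptide = substr(protein, s, s + len - 1), length = len, start = s,
        mut_offset = position - s + 1, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(peptide = character(0), length = integer(0),
                      start = integer(0), mut_offset = integer(0)))
  res <- do.call(rbind, out)
  res[!duplicated(res[, c("peptide", "length", "start")]), , drop = FALSE]
}

#' Select binder candidates for tetramer generation
#'
#' Keeps candidates whose allele is both in the patient genotype and on the
#' supported platform panel, and whose predicted IC50 is strictly below the
#' cutoff (500 nM by convention; an IC50 of exactly 500 nM is excluded).
#'
#' @param candidates data.frame with columns `peptide`, `allele`,
#'   `ic50_nM` (> 0).
#' @param patient_alleles the patient's HLA genotype.
#' @param cutoff_nM strict IC50 cutoff (default 500).
#' @param panel supported allele panel (default [supported_hla_panel()]).
#' @return the selected rows.
#' @export
select_candidates <- function(candidates, patient_alleles, cutoff_nM = 500,
                              panel = supported_hla_panel()) {
  stopifnot(is.data.frame(candidates))
  if (!nrow(candidates)) return(candidates)
  if (any(is.na(candidates$ic50_nM) | candidates$ic50_nM <= 0))
    stop("validation error: ic50_nM must be positive")
  keep <- candidates$allele %in% intersect(patient_alleles, panel) &
    candidates$ic50_nM < cutoff_nM
  candidates[keep, , drop = FALSE]
}

#' Optimal HLA-neoepitope pair for a mutation
#'
#' The single (peptide, allele) pair with minimum predicted IC50 across all
#' alleles and mutation-covering 8-11mers. Ties break deterministically:
#' shorter peptide first, then lexicographic allele, then lexicographic
#' peptide.
#'
#' @param candidates data.frame with columns `peptide`, `allele`,
#'   `ic50_nM` for one mutation.
#' @return the winning row, or `NULL` when there are no candidates.
#' @export
optimal_pair <- function(candidates) {
  if (is.null(candidates) || !nrow(candidates)) return(NULL)
  ord <- order(candidates$ic50_nM, nchar(candidates$peptide),
               candidates$allele, candidates$peptide)
  candidates[ord[1], , drop = FALSE]
}

#' Full neoepitope candidate selection cascade
#'
#' Expressed-mutation filter, 8-11mer enumeration, binding-table join,
#' allele/IC50 selection, and the per-mutation optimal pairing. IC50
#' values are consumed from the supplied table; no predictor is run.
#'
#' @param mutations data.frame: protein_id, sequence, position, rna_reads.
#' @param bindings data.frame: protein_id, peptide, allele, ic50_nM
#'   (precomputed predictions for mutation-covering peptides).
#' @param patient_alleles the patient's HLA genotype.
#' @param cutoff_nM strict IC50 cutoff (default 500).
#' @return list with `selected` (all selected candidate rows, the peptide
#'   panel for tetramer generation) and `optimal` (one row per mutation
#'   with at least one selected candidate).
#' @export
select_neoepitopes <- function(mutations, bindings, patient_alleles,
                               cutoff_nM = 500) {
  expressed <- filter_expressed(mutations)
  keep_rows <- list()
  for (i in seq_len(nrow(expressed))) {
    peps <- enumerate_mutant_peptides(expressed$sequence[i],
                                      expressed$position[i])
    b <- bindings[bindings$protein_id == expressed$protein_id[i] &
                    bindings$peptide %in% peps$peptide, , drop = FALSE]
    if (nrow(b)) keep_rows[[length(keep_rows) + 1]] <- b
  }
  joined <- if (length(keep_rows)) do.call(rbind, keep_rows)
            else bindings[0, , drop = FALSE]
  selected <- select_candidates(joined, patient_alleles, cutoff_nM)
  rownames(selected) <- NULL
  optimal <- do.call(rbind, lapply(split(selected, selected$protein_id),
                                   optimal_pair))
  rownames(optimal) <- NULL
  list(selected = selected, optimal = optimal)
}
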