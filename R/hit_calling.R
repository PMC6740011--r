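#' Event-count detection threshold
#'
#' A putative population must contain at least 2 decoded events in each of
#' the two staining configurations, or at least 4 events when only one
#' configuration was stained. Populations failing this rule are excluded
#' from all subsequent hit criteria.
#'
#' @param counts integer vector of decoded event counts, one per available
#'   configuration.
#' @return logical: does the population pass the count threshold?
#' @export
apply_count_threshold <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (!length(counts)) return(FALSE)
  if (length(counts) >= 2) all(counts >= 2) else counts >= 4
}

#' Cross-configuration concordance
#'
#' A real antigen-specific population should be recovered at a similar
#' frequency under both independent barcode configurations: the criterion
#' passes when the ratio of the two frequencies is less than two-fold.
#' If one frequency is zero the ratio is reported as `Inf` and the
#' criterion fails; if both are zero it is not applicable (ratio `NA`,
#' cannot pass).
#'
#' @param f1,f2 frequencies (percent of gated CD8) in the two
#'   configurations.
#' @return list with `ratio` (>= 1, or `Inf`/`NA`) and `pass`.
#' @export
concordance <- function(f1, f2) {
  if (is.na(f1) || is.na(f2)) return(list(ratio = NA_real_, pass = FALSE))
  if (f1 == 0 && f2 == 0) return(list(ratio = NA_real_, pass = FALSE))
  if (f1 == 0 || f2 == 0) return(list(ratio = Inf, pass = FALSE))
  r <- max(f1, f2) / min(f1, f2)
  list(ratio = r, pass = r < 2)
}

#' CD8-versus-CD4 gate comparison
#'
#' Triple-coded tetramer positivity in the CD4 gate is background; the
#' criterion passes when the CD8-gate frequency strictly exceeds the
#' CD4-gate frequency in every configuration considered. A missing CD4
#' record makes the criterion unavailable (not passed, not an error).
#'
#' @param f_cd8,f_cd4 frequency vectors (percent), matched by
#'   configuration.
#' @return logical.
#' @export
cd4_comparison <- function(f_cd8, f_cd4) {
  if (!length(f_cd8)) return(FALSE)
  if (length(f_cd4) != length(f_cd8)) return(FALSE)
  if (any(is.na(f_cd8)) || any(is.na(f_cd4))) return(FALSE)
  all(f_cd8 > f_cd4)
}

#' Phenotypic homogeneity score
#'
#' Audit metric (never a hard filter): antigen-specific T cells of one
#' clonotype tend to be phenotypically uniform, so their mean pairwise
#' Euclidean distance in transformed descriptive-marker space should be
#' small relative to equal-sized random subsets of unspecific bulk CD8
#' cells. The score is the percentile of the hit statistic within the
#' bootstrap null distribution: lower = more homogeneous.
#'
#' @param hit_events [event_table()] of the decoded hit events (>= 2).
#' @param bulk_cd8 [event_table()] of bulk CD8 events from the same sample.
#' @param n_boot number of random bulk subsets for the null (default 100).
#' @param seed integer seed.
#' @return percentile score in \[0, 100\], or `NA` with fewer than 2 hit
#'   events.
#' @export
homogeneity_score <- function(hit_events, bulk_cd8, n_boot = 100, seed = 1) {
  stopifnot(inherits(hit_events, "event_table"),
            inherits(bulk_cd8, "event_table"))
  m <- n_events(hit_events)
  if (m < 2) return(NA_real_)
  dm <- intersect(channels(hit_events, "descriptive"),
                  channels(bulk_cd8, "descriptive"))
  stat <- mean(stats::dist(hit_events$exprs[, dm, drop = FALSE]))
  nb <- n_events(bulk_cd8)
  if (nb < m) return(NA_real_)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nb, m)
    mean(stats::dist(bulk_cd8$exprs[idx, dm, drop = FALSE]))
  }, numeric(1))
  100 * mean(null <= stat)
}

#' Patient-versus-healthy-donor background ratio
#'
#' Audit metric for neoantigen hits: the frequency of decoded events in the
#' patient CD8 gate relative to the corresponding gate among APC-negative
#' healthy-donor buffer cells stained in the same tube. The donor frequency
#' is floored at one event over the donor gate total so the ratio is always
#' finite.
#'
#' @param patient_freq patient CD8-gate frequency (percent).
#' @param donor_freq donor CD8-gate frequency (percent).
#' @param n_donor_gate donor CD8 gate total; if zero or `NA` the metric is
#'   missing.
#' @return ratio (>= 0), or `NA` when no donor events are available.
#' @export
donor_background <- function(patient_freq, donor_freq, n_donor_gate) {
  if (is.na(n_donor_gate) || n_donor_gate <= 0) return(NA_real_)
  if (is.na(patient_freq) || is.na(donor_freq)) return(NA_real_)
  patient_freq / max(donor_freq, 100 / n_donor_gate)
}

#' Call hits from detection records
#'
#' Applies the full criteria set per (sample, peptide): the population must
#' pass the per-configuration event-count threshold, and then either the
#' CD8-versus-CD4 comparison or the two-fold cross-configuration
#' concordance (`verdict = count AND (cd4 OR concordance)`). Homogeneity
#' and donor-background values, when supplied, are carried as audit
#' metrics and never gate the verdict.
#'
#' @param records detection data.frame from [tabulate_detections()],
#'   containing gates `"cd8"`, `"cd4"` and optionally `"donor_cd8"`.
#' @param n_candidates number of distinct neoantigen candidates screened
#'   (denominator of the discovery rate); defaults to the number of
#'   distinct neoantigen peptides in `records`.
#' @param patients optional named vector sample id -> patient id (unique
#'   hits are deduplicated per patient across its samples/time points);
#'   defaults to one patient per sample.
#' @param groups optional named vector patient id -> group label.
#' @return list of class `tetra_hits` with `hits` (one row per
#'   sample x peptide with all flags and metrics) and `summary` (a
#'   `screen_summary`).
#' @export
call_hits <- function(records, n_candidates = NULL, patients = NULL,
                      groups = NULL) {
  stopifnot(is.data.frame(records))
  cd8 <- records[records$gate == "cd8", ]
  cd4 <- records[records$gate == "cd4", ]
  donor <- records[records$gate == "donor_cd8", ]
  if (!nrow(cd8)) stop("no CD8-gate detection records")
  if (is.null(patients)) {
    ids <- unique(cd8$sample_id)
    patients <- stats::setNames(ids, ids)
  }
  keys <- unique(cd8[, c("sample_id", "peptide_id", "category")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    s <- keys$sample_id[i]; p <- keys$peptide_id[i]
    rec <- cd8[cd8$sample_id == s & cd8$peptide_id == p, ]
    rec <- rec[order(rec$configuration_id), ]
    cfgs <- rec$configuration_id
    counts <- rec$event_count
    freqs <- rec$frequency_pct
    passed_count <- apply_count_threshold(counts)
    # configurations individually meeting the per-config minimum
    min_ev <- if (length(cfgs) >= 2) 2 else 4
    ok_cfg <- counts >= min_ev
    crec <- cd4[cd4$sample_id == s & cd4$peptide_id == p, ]
    crec <- crec[match(cfgs, crec$configuration_id), ]
    passed_cd4 <- if (passed_count && any(ok_cfg))
      cd4_comparison(freqs[ok_cfg], crec$frequency_pct[ok_cfg]) else FALSE
    if (length(cfgs) >= 2 && passed_count) {
      conc <- concordance(freqs[1], freqs[2])
    } else conc <- list(ratio = NA_real_, pass = FALSE)
    drec <- donor[donor$sample_id == s & donor$peptide_id == p, ]
    donor_ratio <- if (nrow(drec)) {
      donor_background(mean(freqs), mean(drec$frequency_pct),
                       drec$n_gate_total[1])
    } else NA_real_
    verdict <- passed_count && (passed_cd4 || isTRUE(conc$pass))
    rows[[i]] <- data.frame(
      patient_id = unname(patients[s]), sample_id = s, peptide_id = p,
      category = keys$category[i],
      count_config1 = counts[1],
      count_config2 = if (length(counts) >= 2) counts[2] else NA_integer_,
      freq_config1 = freqs[1],
      freq_config2 = if (length(freqs) >= 2) freqs[2] else NA_real_,
      mean_frequency_pct = mean(freqs),
      threshold_pct = rec$threshold_pct[1],
      passed_count_threshold = passed_count,
      passed_cd4_comparison = passed_cd4,
      concordance_ratio = conc$ratio,
      passed_concordance = isTRUE(conc$pass),
      homogeneity_score = NA_real_,
      donor_background_ratio = donor_ratio,
      verdict = verdict,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  structure(list(hits = hits,
                 summary = screen_summary(hits, n_candidates, groups)),
            class = "tetra_hits")
}

#' Screen-level summary
#'
#' Unique hits are counted once per peptide within a patient (a specificity
#' seen at two time points of the same patient is one hit); the discovery
#' rate is unique neoantigen hits over neoantigen candidates screened.
#'
#' @param hits hit data.frame from [call_hits()].
#' @param n_candidates neoantigen candidates screened; defaults to the
#'   distinct neoantigen peptides appearing in `hits`.
#' @param groups optional named vector patient id -> group label.
#' @return object of class `screen_summary`.
#' @export
screen_summary <- function(hits, n_candidates = NULL, groups = NULL) {
  neo <- hits[hits$category == "neoantigen", ]
  if (is.null(n_candidates)) n_candidates <- length(unique(neo$peptide_id))
  called <- hits[hits$verdict, , drop = FALSE]
  uniq <- unique(called[, c("patient_id", "peptide_id", "category")])
  uniq_neo <- uniq[uniq$category == "neoantigen", , drop = FALSE]
  per_group <- NULL
  if (!is.null(groups)) {
    uniq_neo$group <- unname(groups[uniq_neo$patient_id])
    per_group <- table(uniq_neo$group)
  }
  fr <- called$mean_frequency_pct[called$category == "neoantigen"]
  structure(list(
    n_candidates_screened = n_candidates,
    n_unique_hits = nrow(uniq_neo),
    n_unique_viral = nrow(uniq[uniq$category != "neoantigen", ,
                               drop = FALSE]),
    discovery_rate_pct = if (n_candidates > 0)
      100 * nrow(uniq_neo) / n_candidates else NA_real_,
    hits_per_group = per_group,
    frequency_range_pct = if (length(fr)) range(fr) else c(NA_real_,
                                                           NA_real_)),
    class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("<screen_summary>\n")
  cat(sprintf("  neoantigen candidates screened: %d\n",
              x$n_candidates_screened))
  cat(sprintf("  unique neoantigen hits:         %d\n", x$n_unique_hits))
  cat(sprintf("  unique viral-control hits:      %d\n", x$n_unique_viral))
  if (!is.na(x$discovery_rate_pct))
    cat(sprintf("  discovery rate:                 %.2f%%\n",
                x$discovery_rate_pct))
  if (!is.null(x$hits_per_group)) {
    cat("  unique hits per group:          ")
    cat(paste(sprintf("%s=%d", names(x$hits_per_group), x$hits_per_group),
              collapse = " "), "\n")
  }
  if (!any(is.na(x$frequency_range_pct)))
    cat(sprintf("  hit frequency range:            %.3g%% - %.3g%% of CD8\n",
                x$frequency_range_pct[1], x$frequency_range_pct[2]))
  invisible(x)
}

#' @export
print.tetra_hits <- function(x, ...) {
  called <- x$hits[x$hits$verdict, , drop = FALSE]
  cat(sprintf("<tetra_hits> %d (sample x peptide) records, %d called\n",
              nrow(x$hits), nrow(called)))
  print(x$summary)
  invisible(x)
}
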