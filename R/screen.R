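#' Run the full tetramer screen pipeline on one acquisition
#'
#' From raw event tables (one per staining configuration, each possibly
#' containing several palladium-barcoded samples) to called hits:
#' logicle transformation, per-channel cutoff estimation, sample
#' de-barcoding, hierarchical lineage gating, triple-code deconvolution in
#' the patient CD8, patient CD4 and healthy-donor CD8 gates, detection
#' tabulation, and hit calling with audit metrics.
#'
#' @param tables named list configuration id -> raw [event_table()].
#' @param schemes list of `tetra_scheme` objects matching the
#'   configuration ids.
#' @param pd_scheme optional sample-barcode map from
#'   [sample_barcode_scheme()]; when `NULL` each table is treated as a
#'   single sample (its `meta$sample_id`).
#' @param categories optional named vector peptide id -> category.
#' @param n_candidates neoantigen candidates screened (discovery-rate
#'   denominator).
#' @param patients optional named vector sample id -> patient id.
#' @param groups optional named vector patient id -> group label.
#' @param params [logicle_params()] used for the transformation.
#' @param compute_homogeneity compute the phenotypic-homogeneity audit
#'   score for called hits (default TRUE).
#' @param homogeneity_boot bootstrap replicates for the homogeneity null.
#' @param seed integer seed (homogeneity bootstrap only; the pipeline
#'   itself is deterministic).
#' @return object of class `tetra_screen` with fields `hits`, `summary`,
#'   `records`, `gate_counts`, `thresholds`, `hit_events` (decoded events
#'   per called hit, pooled over configurations) and `bulk_cd8` (a bulk
#'   CD8 sample per sample id, for profiling context).
#' @export
run_screen <- function(tables, schemes, pd_scheme = NULL,
                       categories = NULL, n_candidates = NULL,
                       patients = NULL, groups = NULL,
                       params = logicle_params(),
                       compute_homogeneity = TRUE, homogeneity_boot = 50,
                       seed = 1) {
  if (inherits(schemes, "tetra_scheme")) schemes <- list(schemes)
  cfg_ids <- vapply(schemes, function(s) s$configuration_id, character(1))
  if (is.null(names(tables)) || !setequal(names(tables), cfg_ids))
    stop("`tables` must be named by the schemes' configuration ids")
  entries <- list()
  gate_rows <- list()
  thresholds <- list()
  cd8_events <- list()   # [[sample]][[config]] gated patient CD8 table
  for (cfg in cfg_ids) {
    scheme <- schemes[[match(cfg, cfg_ids)]]
    tab <- logicle_transform(tables[[cfg]], params)
    thr <- estimate_thresholds(tab)
    thresholds[[cfg]] <- thr
    if (!is.null(pd_scheme)) {
      samples <- debarcode_samples(tab, pd_scheme, thr)$samples
    } else {
      sid <- tab$meta$sample_id
      if (is.null(sid)) sid <- "sample1"
      samples <- stats::setNames(list(tab), sid)
    }
    for (sid in names(samples)) {
      sub <- samples[[sid]]
      if (n_events(sub) == 0) next
      tree <- gate_lineages(sub, thr)
      gc <- gate_counts(tree)
      gc$sample_id <- sid; gc$configuration_id <- cfg
      gate_rows[[length(gate_rows) + 1]] <- gc
      for (g in c(cd8 = "patient_cd8", cd4 = "patient_cd4",
                  donor_cd8 = "donor_cd8")) {
        mask <- gate_mask(tree, g)
        if (g == "donor_cd8" && sum(mask) == 0) next
        gated <- sub[which(mask)]
        asg <- assign_codes_to_events(gated, scheme, thr)
        entries[[length(entries) + 1]] <- list(
          assignment = asg,
          gate = names(which(c(cd8 = "patient_cd8", cd4 = "patient_cd4",
                               donor_cd8 = "donor_cd8") == g)),
          sample_id = sid, n_gate_total = sum(mask))
        if (g == "patient_cd8") {
          if (is.null(cd8_events[[sid]])) cd8_events[[sid]] <- list()
          cd8_events[[sid]][[cfg]] <- list(events = gated, calls = asg$call)
        }
      }
    }
  }
  records <- tabulate_detections(entries, categories)
  res <- call_hits(records, n_candidates = n_candidates,
                   patients = patients, groups = groups)
  hits <- res$hits
  # pooled decoded events per called hit + bulk CD8 context per sample
  hit_events <- list()
  bulk_cd8 <- list()
  for (sid in names(cd8_events)) {
    first <- cd8_events[[sid]][[1]]
    nb <- n_events(first$events)
    keep <- if (nb > 3000) sort(sample.int(nb, 3000)) else seq_len(nb)
    bulk_cd8[[sid]] <- first$events[keep]
  }
  called <- which(hits$verdict)
  for (i in called) {
    sid <- hits$sample_id[i]; pep <- hits$peptide_id[i]
    parts <- lapply(cd8_events[[sid]], function(cc)
      cc$events[which(cc$calls == pep)])
    ev <- parts[[1]]
    if (length(parts) > 1)
      for (j in 2:length(parts))
        ev$exprs <- rbind(ev$exprs, parts[[j]]$exprs)
    ev$truth <- NULL
    hit_events[[paste(sid, pep, sep = "|")]] <- ev
    if (compute_homogeneity)
      hits$homogeneity_score[i] <- homogeneity_score(
        ev, bulk_cd8[[sid]], n_boot = homogeneity_boot, seed = seed)
  }
  structure(list(hits = hits,
                 summary = screen_summary(hits, n_candidates, groups),
                 records = records,
                 gate_counts = do.call(rbind, gate_rows),
                 thresholds = thresholds,
                 hit_events = hit_events,
                 bulk_cd8 = bulk_cd8),
            class = "tetra_screen")
}

#' @export
print.tetra_screen <- function(x, ...) {
  cat(sprintf("<tetra_screen> %d detection records, %d sample x peptide evaluations\n",
              nrow(x$records), nrow(x$hits)))
  print(x$summary)
  invisible(x)
}

#' @param object a `tetra_screen`.
#' @param ... ignored.
#' @rdname run_screen
#' @export
summary.tetra_screen <- function(object, ...) {
  called <- object$hits[object$hits$verdict, , drop = FALSE]
  print(object$summary)
  if (nrow(called)) {
    cat("\ncalled hits:\n")
    cols <- c("sample_id", "peptide_id", "category", "count_config1",
              "count_config2", "mean_frequency_pct", "concordance_ratio",
              "homogeneity_score")
    print(called[, intersect(cols, names(called))], digits = 4,
          row.names = FALSE)
  }
  invisible(object$summary)
}

#' Scenario sized by its CD8 compartment
#'
#' Convenience constructor for screening scenarios where the condition of
#' interest is the number of gated patient CD8 events: the total event
#' count is derived from the requested CD8 count, the CD8 fraction of the
#' lineage mix and the buffer fraction.
#'
#' @param sample_id sample identifier.
#' @param n_cd8 desired patient CD8 event count.
#' @param planted list of [planted_population()] objects.
#' @param lineage_mix named lineage fractions; the default is CD8-rich, as
#'   appropriate for a screen aliquot.
#' @param buffer_fraction healthy-donor buffer fraction.
#' @param ... passed to [sample_scenario()].
#' @return a [sample_scenario()].
#' @export
screen_scenario <- function(sample_id, n_cd8, planted = list(),
                            lineage_mix = c(cd8 = 0.70, cd4 = 0.12,
                                            nk = 0.03, mono = 0.05,
                                            tcrgd = 0.02, dead = 0.04,
                                            debris = 0.02, other = 0.02),
                            buffer_fraction = 0.10, ...) {
  n_events <- round(n_cd8 / (lineage_mix[["cd8"]] * (1 - buffer_fraction)))
  sample_scenario(sample_id, n_events = n_events, lineage_mix = lineage_mix,
                  buffer_fraction = buffer_fraction, planted = planted, ...)
}

#' Simulate and screen a whole cohort
#'
#' Runs [simulate_sample()] and the full pipeline for every scenario of a
#' [simulate_cohort()] object, pools the detection records, calls hits
#' cohort-wide and computes marker-positivity profiles for every called
#' hit.
#'
#' @param cohort result of [simulate_cohort()].
#' @param seed integer seed; per-sample simulation seeds are derived from
#'   it.
#' @param categories optional named vector peptide id -> category.
#' @param ... passed to [run_screen()].
#' @return list of class `cohort_screen`: `screen` (a `tetra_screen` over
#'   the pooled records), `profiles` (named list of marker-positivity
#'   vectors for called hits), `hit_info` (data.frame with patient, group,
#'   peptide per profiled hit).
#' @export
run_cohort <- function(cohort, seed = 1, categories = NULL, ...) {
  records <- NULL
  hit_events_all <- list()
  thresholds1 <- list()
  n_cand <- length(cohort$schemes[[1]]$assignment)
  screens <- list()
  for (i in seq_along(cohort$scenarios)) {
    sc <- cohort$scenarios[[i]]
    tabs <- simulate_sample(sc, cohort$schemes, seed = seed + 1000L * i)
    scr <- run_screen(tabs, cohort$schemes,
                      pd_scheme = stats::setNames(list(sc$sample_barcode),
                                                  sc$sample_id),
                      categories = categories, n_candidates = n_cand,
                      seed = seed, ...)
    records <- rbind(records, scr$records)
    hit_events_all <- c(hit_events_all, scr$hit_events)
    thresholds1[[sc$sample_id]] <- scr$thresholds[[1]]
    screens[[sc$sample_id]] <- scr$hits
  }
  sample_ids <- vapply(cohort$scenarios, function(s) s$sample_id,
                       character(1))
  patient_ids <- vapply(cohort$scenarios, function(s) s$patient_id,
                        character(1))
  patients <- stats::setNames(patient_ids, sample_ids)
  res <- call_hits(records, n_candidates = n_cand, patients = patients,
                   groups = cohort$groups)
  hits <- res$hits
  # carry homogeneity scores from the per-sample runs
  per_sample <- do.call(rbind, screens)
  key <- paste(hits$sample_id, hits$peptide_id)
  m <- match(key, paste(per_sample$sample_id, per_sample$peptide_id))
  hits$homogeneity_score <- per_sample$homogeneity_score[m]
  profiles <- list()
  info <- NULL
  for (i in which(hits$verdict)) {
    k <- paste(hits$sample_id[i], hits$peptide_id[i], sep = "|")
    ev <- hit_events_all[[k]]
    if (is.null(ev) || n_events(ev) == 0) next
    profiles[[k]] <- marker_positivity(ev,
                                       thresholds1[[hits$sample_id[i]]])
    info <- rbind(info, data.frame(
      hit = k, patient_id = hits$patient_id[i],
      group = unname(cohort$groups[hits$patient_id[i]]),
      peptide_id = hits$peptide_id[i], category = hits$category[i],
      stringsAsFactors = FALSE))
  }
  structure(list(
    screen = structure(list(hits = hits,
                            summary = screen_summary(hits, n_cand,
                                                     cohort$groups),
                            records = records,
                            hit_events = hit_events_all),
                       class = "tetra_screen"),
    profiles = profiles, hit_info = info),
    class = "cohort_screen")
}

#' @export
print.cohort_screen <- function(x, ...) {
  cat("<cohort_screen>\n")
  print(x$screen$summary)
  invisible(x)
}
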