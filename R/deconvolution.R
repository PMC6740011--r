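#' Decode triple-coded tetramer signals on gated events
#'
#' Exact-match decoding: an event is assigned to peptide `p` if and only if
#' the set of tetramer channels in which it is positive equals `p`'s code
#' exactly. Events positive in more tetramer channels than the code size
#' are quarantined as multi-positive artifacts (never force-assigned);
#' events positive in exactly `k` channels matching no code are unassigned;
#' events positive in fewer than `k` channels are negative. Combinatorial
#' codes are only decodable under this rule -- coincident extra positivity
#' must be treated as artifact.
#'
#' @param events a gated, logicle-transformed [event_table()].
#' @param scheme a `tetra_scheme` for the matching configuration.
#' @param thresholds named cutoff vector (transformed scale) covering all
#'   tetramer channels of the scheme.
#' @return object of class `tetra_assignment`: character vector `call` of
#'   length `n_events` with values `"negative"`, `"unassigned"`,
#'   `"artifact"` or a peptide id, plus the configuration id and peptide
#'   universe.
#' @export
assign_codes_to_events <- function(events, scheme, thresholds) {
  stopifnot(inherits(events, "event_table"),
            inherits(scheme, "tetra_scheme"))
  tet <- scheme$metal_pool
  missing <- setdiff(tet, colnames(events$exprs))
  if (length(missing))
    stop("schema error: tetramer channel(s) absent from table: ",
         paste(missing, collapse = ", "))
  missing_thr <- setdiff(tet, names(thresholds))
  if (length(missing_thr))
    stop("schema error: no threshold for tetramer channel(s): ",
         paste(missing_thr, collapse = ", "))
  pos <- sweep(events$exprs[, tet, drop = FALSE], 2, thresholds[tet], ">")
  npos <- rowSums(pos)
  k <- scheme$k
  call <- rep("negative", nrow(pos))
  call[npos > k] <- "artifact"
  exact <- which(npos == k)
  if (length(exact)) {
    keys <- apply(pos[exact, , drop = FALSE], 1, function(r)
      paste(sort(tet[r]), collapse = "+"))
    code_keys <- vapply(scheme$assignment, code_key, character(1))
    hit <- match(keys, code_keys)
    call[exact] <- ifelse(is.na(hit), "unassigned",
                          names(scheme$assignment)[hit])
  }
  structure(list(call = call,
                 configuration_id = scheme$configuration_id,
                 peptide_ids = names(scheme$assignment),
                 k = k),
            class = "tetra_assignment")
}

#' @export
print.tetra_assignment <- function(x, ...) {
  tab <- table(factor(ifelse(x$call %in% c("negative", "unassigned",
                                           "artifact"), x$call, "assigned"),
                      levels = c("negative", "unassigned", "artifact",
                                 "assigned")))
  cat(sprintf("<tetra_assignment> %s: %s\n", x$configuration_id,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Detection threshold as percent of the gated denominator
#'
#' The minimum reportable population size, expressed as percent of total
#' gated CD8+ T cells in that sample: 2 events when two staining
#' configurations are available, 4 events when only one is.
#'
#' @param n_gate_total total gated events in the denominator (> 0).
#' @param n_configurations 1 or 2.
#' @return threshold in percent.
#' @export
detection_threshold <- function(n_gate_total, n_configurations) {
  if (!n_configurations %in% c(1, 2))
    stop("n_configurations must be 1 or 2")
  if (is.na(n_gate_total) || n_gate_total <= 0)
    stop("undefined threshold: gate total is zero")
  min_events <- if (n_configurations == 2) 2 else 4
  100 * min_events / n_gate_total
}

#' Tabulate per-peptide detection records
#'
#' One record per (peptide, sample, configuration, gate), with event count,
#' frequency against that gate's total, and the per-sample detection
#' threshold.
#'
#' @param assignments list of entries, each a list with fields
#'   `assignment` (a `tetra_assignment`), `gate` (e.g. `"cd8"`, `"cd4"`,
#'   `"donor_cd8"`), `sample_id` and `n_gate_total`.
#' @param categories optional named vector peptide id -> category
#'   (`"neoantigen"` / `"viral_control"`); defaults to `"neoantigen"`.
#' @return data.frame with columns sample_id, configuration_id, gate,
#'   peptide_id, category, event_count, n_gate_total, frequency_pct,
#'   threshold_pct.
#' @export
tabulate_detections <- function(assignments, categories = NULL) {
  if (!length(assignments))
    return(data.frame(sample_id = character(0),
                      configuration_id = character(0), gate = character(0),
                      peptide_id = character(0), category = character(0),
                      event_count = integer(0), n_gate_total = integer(0),
                      frequency_pct = numeric(0), threshold_pct = numeric(0),
                      stringsAsFactors = FALSE))
  n_cfg_by_sample <- tapply(
    vapply(assignments, function(a) a$assignment$configuration_id,
           character(1)),
    vapply(assignments, function(a) a$sample_id, character(1)),
    function(v) length(unique(v)))
  out <- lapply(assignments, function(a) {
    asg <- a$assignment
    peps <- asg$peptide_ids
    counts <- table(factor(asg$call, levels = peps))
    n_tot <- a$n_gate_total
    n_cfg <- min(2, n_cfg_by_sample[[a$sample_id]])
    thr <- if (n_tot > 0) detection_threshold(n_tot, n_cfg) else NA_real_
    data.frame(
      sample_id = a$sample_id,
      configuration_id = asg$configuration_id,
      gate = a$gate,
      peptide_id = peps,
      category = if (is.null(categories)) "neoantigen"
                 else unname(categories[peps]),
      event_count = as.integer(counts),
      n_gate_total = n_tot,
      frequency_pct = if (n_tot > 0) 100 * as.integer(counts) / n_tot
                      else NA_real_,
      threshold_pct = thr,
      row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
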