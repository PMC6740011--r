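#' Automated per-channel positivity cutoff
#'
#' Positivity is evaluated on the logicle-transformed scale, where the
#' zero-inflated negative component and the positive component of a channel
#' form separable modes.
#'
#' Methods:
#' \describe{
#'   \item{valley}{default two-component split: kernel-density valley
#'     between the negative mode and the positive mode. When no second mode
#'     is present the method falls back to the 99.5th percentile of a
#'     designated negative-control population (or of the channel itself if
#'     none is given).}
#'   \item{gap}{midpoint of the widest empty interval among the upper order
#'     statistics. Intended for tetramer channels, where a true population
#'     can be 0.01% of events and produces no density mode but is well
#'     separated from the negative tail.}
#'   \item{quantile}{the 99.5th percentile of the negative-control
#'     population directly.}
#' }
#'
#' @param values transformed intensities of one channel (>= 50 events).
#' @param method cutoff method; see Details.
#' @param negative_control optional transformed intensities of a designated
#'   negative-control population, used by the percentile fallback.
#' @param peak_min_frac minimum height of a density mode, as a fraction of
#'   the tallest mode, for it to count as a second component.
#' @param min_mode_sep minimum separation (transformed units) between the
#'   two modes.
#' @param upper_frac upper tail fraction searched by the gap method.
#' @param fallback_quantile percentile used by the fallback / quantile
#'   method.
#' @return a single cutoff on the transformed scale.
#' @export
channel_threshold <- function(values,
                              method = c("valley", "gap", "quantile"),
                              negative_control = NULL,
                              peak_min_frac = 1e-3, min_mode_sep = 0.5,
                              upper_frac = 0.02,
                              fallback_quantile = 0.995) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 50)
    stop("insufficient data: need at least 50 events for a cutoff")
  if (diff(range(values)) < sqrt(.Machine$double.eps))
    stop("insufficient data: channel is constant")
  fallback <- function() {
    ref <- if (!is.null(negative_control)) negative_control else values
    stats::quantile(ref, fallback_quantile, names = FALSE)
  }
  if (method == "quantile") return(fallback())
  if (method == "gap") {
    lo <- stats::quantile(values, 1 - upper_frac, names = FALSE)
    v <- sort(values[values >= lo])
    if (length(v) < 2) return(fallback())
    gaps <- diff(v)
    i <- which.max(gaps)
    if (gaps[i] <= 0) return(fallback())
    return((v[i] + v[i + 1]) / 2)
  }
  # valley
  d <- stats::density(values, n = 512)
  y <- d$y
  n <- length(y)
  ispeak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(ispeak & y >= peak_min_frac * max(y))
  if (length(peaks) >= 2) {
    main <- peaks[which.max(y[peaks])]
    far <- peaks[abs(d$x[peaks] - d$x[main]) >= min_mode_sep]
    if (length(far)) {
      second <- far[which.max(y[far])]
      lo <- min(main, second); hi <- max(main, second)
      valley <- lo + which.min(y[lo:hi]) - 1
      return(d$x[valley])
    }
  }
  fallback()
}

#' Estimate positivity cutoffs for every channel of a table
#'
#' Channel-role-aware wrapper over [channel_threshold()]: lineage,
#' descriptive, DNA, cisplatin and anti-APC channels use the density-valley
#' method per channel; the five palladium channels are pooled into one
#' valley cutoff (their staining intensities are comparable and pooling
#' guarantees both modes are represented whatever the barcode); tetramer
#' channels use the largest-gap method because true antigen-specific
#' populations can be far too rare to form a density mode.
#'
#' @param table a logicle-transformed [event_table()].
#' @param tetramer_method cutoff method for tetramer channels.
#' @return named numeric vector of cutoffs (transformed scale), one per
#'   channel.
#' @export
estimate_thresholds <- function(table, tetramer_method = "gap") {
  stopifnot(inherits(table, "event_table"))
  if (!isTRUE(table$meta$transformed))
    stop("thresholds are estimated on the logicle-transformed scale")
  ex <- table$exprs
  thr <- stats::setNames(numeric(ncol(ex)), colnames(ex))
  pd <- channels(table, "palladium")
  if (length(pd)) {
    pooled <- channel_threshold(as.vector(ex[, pd]), method = "valley")
    thr[pd] <- pooled
  }
  tet <- channels(table, "tetramer")
  for (ch in tet) thr[ch] <- channel_threshold(ex[, ch],
                                               method = tetramer_method)
  rest <- setdiff(colnames(ex), c(pd, tet))
  for (ch in rest) thr[ch] <- channel_threshold(ex[, ch], method = "valley")
  thr
}

#' De-barcode pooled samples by palladium channel positivity
#'
#' An event is assigned to sample `s` if and only if it is positive in
#' exactly the two palladium channels of `s`'s barcode. Events positive in
#' any other number of palladium channels, or in a pair matching no sample,
#' go to the unassigned pool; assigned plus unassigned is an exact
#' partition of the input.
#'
#' @param table a logicle-transformed [event_table()].
#' @param scheme named list sample id -> palladium code, from
#'   [sample_barcode_scheme()].
#' @param thresholds named cutoff vector from [estimate_thresholds()].
#' @return list with `samples` (named list of [event_table()]) and
#'   `unassigned` (an [event_table()]).
#' @export
debarcode_samples <- function(table, scheme, thresholds) {
  stopifnot(inherits(table, "event_table"))
  pd_needed <- sort(unique(unlist(scheme)))
  missing <- setdiff(pd_needed, colnames(table$exprs))
  if (length(missing))
    stop("schema error: missing palladium channel(s): ",
         paste(missing, collapse = ", "))
  pd <- channels(table, "palladium")
  pos <- sweep(table$exprs[, pd, drop = FALSE], 2, thresholds[pd], ">")
  npos <- rowSums(pos)
  # integer bitmask per event; codes map to their bitmask sum
  bits <- 2^(seq_along(pd) - 1)
  key <- as.vector(pos %*% bits)
  key[npos != length(scheme[[1]])] <- -1
  code_keys <- vapply(scheme, function(code)
    sum(bits[match(code, pd)]), numeric(1))
  assigned <- match(key, code_keys)
  samples <- lapply(seq_along(scheme), function(i) {
    sub <- table[which(!is.na(assigned) & assigned == i)]
    sub$meta$sample_id <- names(scheme)[i]
    sub
  })
  names(samples) <- names(scheme)
  list(samples = samples,
       unassigned = table[which(is.na(assigned))])
}

#' Hierarchical lineage gating
#'
#' Reproduces the standard CyTOF gating hierarchy for live CD8+ T cells:
#' live (DNA+, cisplatin-) -> CD45+ -> exclude monocytes (CD14+) ->
#' exclude NK cells (CD56+ CD16+) -> exclude TCRgd T cells (CD3+ TCRgd+)
#' -> CD3+ -> CD8+ (with a sibling CD4+ gate). Patient events are
#' identified by positivity in the anti-APC channel, healthy-donor buffer
#' cells by its absence; `patient_cd8`, `patient_cd4` and `donor_cd8`
#' leaves are provided. Dead cells are cisplatin-positive or DNA-negative.
#'
#' @param table a logicle-transformed [event_table()].
#' @param thresholds named cutoff vector from [estimate_thresholds()].
#' @return object of class `gate_tree`: named list of nodes, each with
#'   fields `mask` (logical over events) and `parent`.
#' @export
gate_lineages <- function(table, thresholds) {
  stopifnot(inherits(table, "event_table"))
  need <- c("CD45", "CD14", "CD56", "CD16", "TCRgd", "CD3", "CD4", "CD8",
            channels(table, "dna"), channels(table, "cisplatin"),
            channels(table, "apc"))
  missing <- setdiff(need, colnames(table$exprs))
  if (length(missing))
    stop("schema error: missing channel(s): ",
         paste(missing, collapse = ", "))
  missing_thr <- setdiff(need, names(thresholds))
  if (length(missing_thr))
    stop("schema error: missing threshold(s) for: ",
         paste(missing_thr, collapse = ", "))
  ex <- table$exprs
  p <- function(ch) ex[, ch] > thresholds[ch]
  dna <- channels(table, "dna")[1]
  cis <- channels(table, "cisplatin")[1]
  apc <- channels(table, "apc")[1]
  nodes <- list()
  add <- function(name, mask, parent) {
    nodes[[name]] <<- list(mask = mask, parent = parent)
  }
  add("all", rep(TRUE, nrow(ex)), NA_character_)
  add("live", p(dna) & !p(cis), "all")
  add("cd45", nodes$live$mask & p("CD45"), "live")
  add("not_mono", nodes$cd45$mask & !p("CD14"), "cd45")
  add("not_nk", nodes$not_mono$mask & !(p("CD56") & p("CD16")), "not_mono")
  add("not_tcrgd", nodes$not_nk$mask & !(p("CD3") & p("TCRgd")), "not_nk")
  add("cd3", nodes$not_tcrgd$mask & p("CD3"), "not_tcrgd")
  add("cd8", nodes$cd3$mask & p("CD8"), "cd3")
  add("cd4", nodes$cd3$mask & p("CD4"), "cd3")
  add("patient_cd8", nodes$cd8$mask & p(apc), "cd8")
  add("donor_cd8", nodes$cd8$mask & !p(apc), "cd8")
  add("patient_cd4", nodes$cd4$mask & p(apc), "cd4")
  structure(nodes, class = "gate_tree")
}

#' @param tree a `gate_tree`.
#' @param name gate name.
#' @rdname gate_lineages
#' @export
gate_mask <- function(tree, name) {
  stopifnot(inherits(tree, "gate_tree"))
  if (is.null(tree[[name]])) stop("no such gate: ", name)
  tree[[name]]$mask
}

#' @export
print.gate_tree <- function(x, ...) {
  cat("<gate_tree>\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %8d events (parent: %s)\n", nm, sum(x[[nm]]$mask),
                x[[nm]]$parent))
  invisible(x)
}

#' Per-gate event counts as an audit table
#'
#' @param tree a `gate_tree`.
#' @return data.frame with gate, parent and event count.
#' @export
gate_counts <- function(tree) {
  stopifnot(inherits(tree, "gate_tree"))
  data.frame(gate = names(tree),
             parent = vapply(tree, function(n) n$parent, character(1)),
             count = vapply(tree, function(n) sum(n$mask), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
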