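#' Single-cell event tables
#'
#' An `event_table` is the universal currency between pipeline stages: a
#' numeric matrix of events x named metal channels (non-negative intensities
#' on the untransformed scale, exact zeros allowed -- undetected metal is
#' recorded as zero by the instrument), together with a channel-role map and
#' optional per-event hidden truth labels used only by tests.
#'
#' @param exprs numeric matrix, events in rows, channels in columns; column
#'   names are the channel names and must be unique.
#' @param roles named character vector mapping every channel name to one of
#'   `"lineage"`, `"descriptive"`, `"tetramer"`, `"palladium"`, `"dna"`,
#'   `"cisplatin"`, `"apc"`.
#' @param meta list of table-level metadata (sample id, configuration id,
#'   transformation state, ...).
#' @param truth optional data.frame of per-event hidden truth labels
#'   (lineage, planted peptide id, source sample). Never consumed by any
#'   pipeline stage; retained for validation only.
#'
#' @return an object of class `event_table`.
#' @export
event_table <- function(exprs, roles, meta = list(), truth = NULL) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("`exprs` must be a numeric matrix")
  cn <- colnames(exprs)
  if (is.null(cn) || anyDuplicated(cn))
    stop("channel names must be present and unique")
  if (!all(cn %in% names(roles)))
    stop("missing role for channel(s): ",
         paste(setdiff(cn, names(roles)), collapse = ", "))
  roles <- roles[cn]
  bad <- setdiff(unique(unname(roles)), channel_roles())
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (!is.null(truth)) {
    truth <- as.data.frame(truth)
    if (nrow(truth) != nrow(exprs))
      stop("`truth` must have one row per event")
  }
  structure(list(exprs = exprs, roles = roles, meta = meta, truth = truth),
            class = "event_table")
}

#' @rdname event_table
#' @export
channel_roles <- function() {
  c("lineage", "descriptive", "tetramer", "palladium", "dna",
    "cisplatin", "apc")
}

#' @param x an `event_table`.
#' @param role optional role filter; return only channels with this role.
#' @rdname event_table
#' @export
channels <- function(x, role = NULL) {
  stopifnot(inherits(x, "event_table"))
  if (is.null(role)) return(colnames(x$exprs))
  names(x$roles)[x$roles %in% role]
}

#' @rdname event_table
#' @export
n_events <- function(x) {
  stopifnot(inherits(x, "event_table"))
  nrow(x$exprs)
}

#' Subset an event table by event index
#'
#' @param x an `event_table`.
#' @param i integer or logical event index.
#' @param ... ignored.
#' @return an `event_table` with the selected events; truth labels (if any)
#'   are subset in parallel.
#' @export
`[.event_table` <- function(x, i, ...) {
  ex <- x$exprs[i, , drop = FALSE]
  tr <- if (is.null(x$truth)) NULL else x$truth[i, , drop = FALSE]
  event_table(ex, x$roles, meta = x$meta, truth = tr)
}

#' Drop hidden truth labels from an event table
#'
#' Pipeline stages never read truth labels; this helper exists so tests can
#' assert that outputs are byte-identical with and without them.
#'
#' @param x an `event_table`.
#' @return `x` with `truth` set to `NULL`.
#' @export
drop_truth <- function(x) {
  stopifnot(inherits(x, "event_table"))
  x$truth <- NULL
  x
}

#' @export
print.event_table <- function(x, ...) {
  tab <- table(factor(x$roles, levels = channel_roles()))
  cat(sprintf("<event_table> %d events x %d channels\n",
              nrow(x$exprs), ncol(x$exprs)))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  if (length(x$meta)) {
    keep <- vapply(x$meta, function(v) is.atomic(v) && length(v) == 1,
                   logical(1))
    if (any(keep))
      cat("  meta:",
          paste(sprintf("%s=%s", names(x$meta)[keep],
                        unlist(x$meta[keep])), collapse = " "), "\n")
  }
  if (!is.null(x$truth)) cat("  truth labels retained (testing only)\n")
  invisible(x)
}

#' Write / read an event table as CSV
#'
#' The CSV mirror stores intensities with channel columns; roles are kept in
#' a header comment line. Truth labels are never written (they travel in a
#' separate ledger if needed).
#'
#' @param x an `event_table`.
#' @param path file path.
#' @export
write_event_csv <- function(x, path) {
  stopifnot(inherits(x, "event_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#roles,", paste(x$roles, collapse = ",")), con)
  utils::write.csv(as.data.frame(x$exprs), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#roles,"))
    stop("not an event-table CSV (missing #roles header)")
  roles <- strsplit(sub("^#roles,", "", first), ",", fixed = TRUE)[[1]]
  df <- utils::read.csv(path, comment.char = "#")
  m <- as.matrix(df)
  event_table(m, stats::setNames(roles, colnames(m)))
}

# Fixed marker panels ---------------------------------------------------

#' Marker panel used throughout the package
#'
#' Lineage markers identify the major PBMC populations; descriptive markers
#' are the 21-marker CD8 phenotyping panel; five palladium isotopes carry the
#' 2-of-5 sample barcode; iridium (DNA), cisplatin (viability) and a
#' metal-tagged anti-APC antibody (patient versus healthy-donor buffer cells)
#' complete the panel.
#'
#' @return named character vector mapping channel name to role.
#' @export
default_panel <- function() {
  lineage <- c("CD45", "CD14", "TCRgd", "CD3", "CD4", "CD8", "CD56", "CD16")
  pd <- palladium_channels()
  roles <- c(
    stats::setNames(rep("lineage", length(lineage)), lineage),
    stats::setNames(rep("descriptive", length(descriptive_markers())),
                    descriptive_markers()),
    stats::setNames(rep("palladium", length(pd)), pd),
    stats::setNames("dna", "Ir191_DNA"),
    stats::setNames("cisplatin", "Pt195_cisplatin"),
    stats::setNames("apc", "antiAPC")
  )
  roles
}

#' @rdname default_panel
#' @export
descriptive_markers <- function() {
  c("CD57", "HLA-DR", "CD49a", "CD69", "CD45RO", "OX40", "CD103", "CD38",
    "KLRG-1", "ICOS", "TIGIT", "CD27", "PD-1", "Tim-3", "CD127", "CD161",
    "CCR7", "CD25", "2B4", "CD28", "CD39")
}

#' @rdname default_panel
#' @export
palladium_channels <- function() {
  c("Pd102", "Pd104", "Pd105", "Pd106", "Pd108")
}

#' @param n_metals number of streptavidin channels in the tetramer pool.
#' @rdname default_panel
#' @export
default_metal_pool <- function(n_metals = 12) {
  sprintf("SAv%02d", seq_len(n_metals))
}
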