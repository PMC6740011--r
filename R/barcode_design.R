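#' Enumerate combinatorial metal barcodes
#'
#' All unordered k-subsets of a pool of metal channel labels, in a
#' deterministic canonical order (lexicographic by sorted member names).
#' With the standard triple-coded tetramer design (k = 3) and 12
#' metal-labelled streptavidins this yields choose(12, 3) = 220 unique
#' codes, so hundreds of peptide specificities can be screened in one tube.
#'
#' @param metal_pool character vector of metal labels, or a single integer n
#'   (labels are then taken from [default_metal_pool()]).
#' @param k subset size (3 for triple-coded tetramers, 2 for palladium
#'   sample barcoding).
#' @return list of character vectors, each a sorted k-subset of the pool.
#' @export
enumerate_codes <- function(metal_pool, k) {
  if (length(metal_pool) == 1 && is.numeric(metal_pool))
    metal_pool <- default_metal_pool(as.integer(metal_pool))
  metal_pool <- as.character(metal_pool)
  if (anyDuplicated(metal_pool)) stop("metal labels must be unique")
  n <- length(metal_pool)
  if (!is.numeric(k) || length(k) != 1 || k != as.integer(k) || k <= 0)
    stop("`k` must be a positive integer")
  if (k > n)
    stop(sprintf("invalid parameters: k = %d exceeds pool size n = %d", k, n))
  pool <- sort(metal_pool)
  codes <- utils::combn(pool, as.integer(k), simplify = FALSE)
  # combn over a sorted pool already yields sorted members in
  # lexicographic order of subsets
  codes
}

code_key <- function(code) paste(sort(code), collapse = "+")

#' Assign peptides to barcodes across staining configurations
#'
#' Each staining configuration is an independent replicate of the screen
#' with its own random injective peptide-to-code assignment. Configurations
#' beyond the first use a completely different scheme: no peptide keeps the
#' code it had in any earlier configuration, so cross-configuration
#' concordance of a decoded population is evidence of a real
#' antigen-specific T cell population rather than a staining artifact.
#'
#' @param peptide_ids character vector of unique peptide identifiers.
#' @param codes list of codes from [enumerate_codes()].
#' @param seed integer seed; the assignment is reproducible and the seed is
#'   recorded in the scheme metadata.
#' @param n_configurations number of staining configurations (default 2).
#' @return list of `tetra_scheme` objects, one per configuration, each with
#'   fields `configuration_id`, `assignment` (named list peptide -> code),
#'   `metal_pool`, `k`, `seed`.
#' @export
assign_codes <- function(peptide_ids, codes, seed, n_configurations = 2) {
  peptide_ids <- as.character(peptide_ids)
  if (anyDuplicated(peptide_ids)) stop("peptide ids must be unique")
  if (length(peptide_ids) > length(codes))
    stop(sprintf(
      "capacity exceeded: %d peptides but only %d codes available",
      length(peptide_ids), length(codes)))
  if (n_configurations < 1) stop("need at least one configuration")
  metal_pool <- sort(unique(unlist(codes)))
  k <- length(codes[[1]])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  np <- length(peptide_ids)
  prev_keys <- vector("list", np)  # per peptide, keys used in earlier configs
  for (i in seq_len(np)) prev_keys[[i]] <- character(0)
  schemes <- vector("list", n_configurations)
  for (cfg in seq_len(n_configurations)) {
    idx <- sample.int(length(codes), np)
    # re-draw until no peptide repeats a code from an earlier configuration;
    # if a handful of clashes persist, resolve them by pairwise swaps
    for (tries in seq_len(1000)) {
      clash <- which(vapply(seq_len(np), function(i)
        code_key(codes[[idx[i]]]) %in% prev_keys[[i]], logical(1)))
      if (!length(clash)) break
      if (tries < 50 || length(clash) > np / 2) {
        idx <- sample.int(length(codes), np)
      } else {
        for (i in clash) {
          j <- sample.int(np, 1)
          tmp <- idx[i]; idx[i] <- idx[j]; idx[j] <- tmp
        }
      }
    }
    if (length(clash <- which(vapply(seq_len(np), function(i)
      code_key(codes[[idx[i]]]) %in% prev_keys[[i]], logical(1)))))
      stop("could not find a configuration with all-new codes")
    assignment <- stats::setNames(codes[idx], peptide_ids)
    for (i in seq_len(np))
      prev_keys[[i]] <- c(prev_keys[[i]], code_key(codes[[idx[i]]]))
    schemes[[cfg]] <- structure(
      list(configuration_id = paste0("config", cfg),
           assignment = assignment, metal_pool = metal_pool, k = k,
           seed = seed),
      class = "tetra_scheme")
  }
  schemes
}

#' @export
print.tetra_scheme <- function(x, ...) {
  cat(sprintf("<tetra_scheme> %s: %d peptides, %d-of-%d metal codes (seed %s)\n",
              x$configuration_id, length(x$assignment), x$k,
              length(x$metal_pool), x$seed))
  invisible(x)
}

#' Palladium sample-barcode scheme
#'
#' Assigns each sample a unique unordered pair (by default) of palladium
#' channels, so pooled samples can be de-barcoded by the exactly-two-positive
#' rule. Assignment is deterministic: lexicographically ordered pair codes
#' in the order the sample ids are given.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param n_channels number of palladium channels available (default 5).
#' @param k channels per sample code (default 2).
#' @return named list sample id -> character vector of channel names.
#' @export
sample_barcode_scheme <- function(sample_ids, n_channels = 5, k = 2) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  chans <- if (n_channels == 5) palladium_channels()
           else sprintf("Pd%02d", seq_len(n_channels))
  codes <- enumerate_codes(chans, k)
  if (length(sample_ids) > length(codes))
    stop(sprintf(
      "capacity exceeded: %d samples but only %d %d-of-%d barcode codes",
      length(sample_ids), length(codes), k, n_channels))
  stats::setNames(codes[seq_along(sample_ids)], sample_ids)
}

#' Serialize / read a barcode scheme as JSON
#'
#' @param schemes list of `tetra_scheme` objects (or a single one).
#' @param path file path.
#' @export
write_scheme_json <- function(schemes, path) {
  if (inherits(schemes, "tetra_scheme")) schemes <- list(schemes)
  out <- lapply(schemes, function(s) list(
    configuration_id = s$configuration_id,
    metal_pool = s$metal_pool, k = s$k, seed = s$seed,
    assignment = s$assignment))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) structure(
    list(configuration_id = s$configuration_id,
         assignment = lapply(s$assignment, function(v) unlist(v)),
         metal_pool = unlist(s$metal_pool), k = s$k, seed = s$seed),
    class = "tetra_scheme"))
}

# save/restore the RNG state so seeded helpers do not perturb the caller's
# random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
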