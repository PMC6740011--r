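# shared fixtures: small schemes, scenarios and event-table builders

fix_schemes <- function(n_pep = 220, seed = 7) {
  assign_codes(sprintf("pep%03d", seq_len(n_pep)), enumerate_codes(12, 3),
               seed = seed)
}

# a small screening sample with optional planted populations
fix_sample <- function(n_cd8 = 6000, planted = list(), seed = 11,
                       schemes = fix_schemes(), ...) {
  sc <- screen_scenario("S1", n_cd8 = n_cd8, planted = planted, ...)
  simulate_sample(sc, schemes, seed = seed)
}

# bind several event tables (same channels) into one pooled acquisition,
# tracking each event's source sample in the truth ledger
pool_tables <- function(tabs) {
  ex <- do.call(rbind, lapply(tabs, function(t) t$exprs))
  tr <- do.call(rbind, lapply(tabs, function(t) {
    t$truth$source <- t$meta$sample_id
    t$truth
  }))
  event_table(ex, tabs[[1]]$roles, meta = list(transformed = FALSE),
              truth = tr)
}

# hand-built transformed event table with given positive channel sets
# (positive channels get value `hi`, the rest `lo`)
manual_table <- function(pos_sets, channels_roles, hi = 3, lo = 0.2) {
  ex <- matrix(lo, length(pos_sets), length(channels_roles),
               dimnames = list(NULL, names(channels_roles)))
  for (i in seq_along(pos_sets)) ex[i, pos_sets[[i]]] <- hi
  tab <- event_table(ex, channels_roles, meta = list(transformed = TRUE))
  tab
}

# transformed-scale marker positivity profile of a simulated template
# population: states -> zero-inflated log-normal intensities -> logicle ->
# percent positive against a fixed mid-gap cutoff
sim_profile <- function(template, n = 120, params = logicle_params(),
                        nz = noise_model()) {
  dm <- descriptive_markers()
  S <- matrix(stats::runif(n * length(dm)) < rep(template$positive_prob,
                                                 each = n),
              n, length(dm), dimnames = list(NULL, dm))
  raw <- matrix(0, n, length(dm), dimnames = list(NULL, dm))
  ip <- which(S)
  raw[ip] <- stats::rlnorm(length(ip), nz$pos_meanlog, nz$pos_sdlog)
  ineg <- which(!S)
  keep <- stats::runif(length(ineg)) > nz$neg_p_zero
  raw[ineg[keep]] <- stats::rlnorm(sum(keep), nz$neg_meanlog, nz$neg_sdlog)
  tv <- logicle(as.vector(raw), params)
  pos <- matrix(tv, n, length(dm)) > mid_gap_cutoff(params, nz)
  stats::setNames(100 * colMeans(pos), dm)
}

# deterministic cutoff halfway between the negative and positive components
mid_gap_cutoff <- function(params = logicle_params(), nz = noise_model()) {
  (logicle(exp(nz$neg_meanlog), params) +
     logicle(exp(nz$pos_meanlog), params)) / 2
}
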