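#' Phenotype templates for synthetic antigen-specific populations
#'
#' A phenotype template is a named vector of per-marker positive fractions
#' over the 21-marker descriptive panel. The built-in templates emulate the
#' canonical CD8 T cell states: a late-differentiated effector state (high
#' KLRG-1, 2B4, CD57, CD161, TIGIT, CD25; low CCR7/CD27/CD28/CD127), a
#' memory-like state (the reverse), an activated state (high HLA-DR, CD38,
#' PD-1, CD39) and the heterogeneous bulk mixture.
#'
#' @param name template name.
#' @param positive_prob named numeric vector of positive fractions in
#'   \[0, 1\]; names must cover [descriptive_markers()] (missing markers get
#'   the baseline 0.15).
#' @return object of class `phenotype_template`.
#' @export
phenotype_template <- function(name, positive_prob) {
  p <- rep(0.15, length(descriptive_markers()))
  names(p) <- descriptive_markers()
  bad <- setdiff(names(positive_prob), names(p))
  if (length(bad)) stop("unknown marker(s): ", paste(bad, collapse = ", "))
  p[names(positive_prob)] <- positive_prob
  if (any(p < 0 | p > 1)) stop("positive fractions must be in [0, 1]")
  structure(list(name = name, positive_prob = p),
            class = "phenotype_template")
}

#' @rdname phenotype_template
#' @export
phenotype_templates <- function() {
  list(
    late_effector = phenotype_template("late_effector", c(
      "KLRG-1" = 0.85, "2B4" = 0.85, CD57 = 0.80, CD161 = 0.75,
      TIGIT = 0.80, CD25 = 0.70, CD127 = 0.10, CD28 = 0.12, CD27 = 0.15,
      CCR7 = 0.05, CD45RO = 0.15, CD38 = 0.35, "PD-1" = 0.30)),
    memory_like = phenotype_template("memory_like", c(
      CD127 = 0.85, CD28 = 0.85, CD27 = 0.85, CCR7 = 0.75, CD45RO = 0.85,
      "KLRG-1" = 0.10, "2B4" = 0.15, CD57 = 0.08, CD161 = 0.15,
      TIGIT = 0.20, CD25 = 0.15)),
    activated = phenotype_template("activated", c(
      "HLA-DR" = 0.85, CD38 = 0.90, "PD-1" = 0.85, CD39 = 0.80,
      CD45RO = 0.80, CCR7 = 0.10, CD27 = 0.40, CD28 = 0.40,
      TIGIT = 0.55, CD25 = 0.45)))
}

# bulk CD8 sub-templates, one per CD45RO x CCR7 memory subset; bulk events
# are a mixture over these, which is what makes bulk CD8 phenotypically
# diffuse relative to a planted template population
.bulk_subtemplates <- function() {
  list(
    naive = phenotype_template("naive", c(
      CCR7 = 0.95, CD45RO = 0.03, CD27 = 0.90, CD28 = 0.90, CD127 = 0.70,
      "KLRG-1" = 0.03, "2B4" = 0.05, CD57 = 0.02, TIGIT = 0.05,
      CD25 = 0.05, CD38 = 0.10, "PD-1" = 0.05))$positive_prob,
    cm = phenotype_template("cm", c(
      CCR7 = 0.95, CD45RO = 0.95, CD27 = 0.85, CD28 = 0.85, CD127 = 0.80,
      "KLRG-1" = 0.10, CD57 = 0.05, CD38 = 0.15))$positive_prob,
    em = phenotype_template("em", c(
      CCR7 = 0.03, CD45RO = 0.95, CD27 = 0.40, CD28 = 0.45, CD127 = 0.50,
      "KLRG-1" = 0.35, "2B4" = 0.40, CD57 = 0.20, CD38 = 0.30))$positive_prob,
    eff = phenotype_template("eff", c(
      CCR7 = 0.03, CD45RO = 0.05, "KLRG-1" = 0.80, "2B4" = 0.80,
      CD57 = 0.70, CD161 = 0.50, TIGIT = 0.60, CD38 = 0.35, CD27 = 0.15,
      CD28 = 0.15, CD127 = 0.15))$positive_prob)
}

#' Planted antigen-specific population
#'
#' @param peptide_id peptide identifier; must exist in every barcode scheme
#'   the population is present in.
#' @param frequency population size as percent of CD8+ T cell events
#'   (observed range in multiplexed screens: 0.01--0.65).
#' @param template a [phenotype_template()] (or the name of a built-in one).
#' @param present_in configuration ids in which the population is stained.
#' @return object of class `planted_population`.
#' @export
planted_population <- function(peptide_id, frequency,
                               template = "late_effector",
                               present_in = c("config1", "config2")) {
  if (frequency < 0 || frequency > 100)
    stop("frequency must be a percent in [0, 100]")
  if (is.character(template))
    template <- phenotype_templates()[[match.arg(template,
                 names(phenotype_templates()))]]
  structure(list(peptide_id = as.character(peptide_id),
                 frequency = frequency, template = template,
                 present_in = present_in),
            class = "planted_population")
}

#' Noise model for the synthetic generator
#'
#' Per-channel intensities follow a zero-inflated log-normal: a point mass
#' at exact zero (undetected metal) plus a log-normal positive component.
#' Negative (marker-off) and positive (marker-on) states use separate
#' log-normal components separated on the transformed axis. Non-planted
#' events additionally acquire positive-level signal in each tetramer
#' channel independently with probability `bg_tet_rate`, so spurious triple
#' coincidences occur at about `bg_tet_rate^3` per code and the robustness
#' of hit calling can be probed by raising it.
#'
#' @param bg_tet_rate per-tetramer-channel false-positive probability for
#'   non-planted events (default 1e-3).
#' @param neg_p_zero zero-inflation rate of the negative component.
#' @param neg_meanlog,neg_sdlog log-normal parameters of the non-zero
#'   negative component (raw scale).
#' @param pos_meanlog,pos_sdlog log-normal parameters of the positive
#'   component (raw scale).
#' @return list of noise parameters.
#' @export
noise_model <- function(bg_tet_rate = 1e-3, neg_p_zero = 0.8,
                        neg_meanlog = log(2), neg_sdlog = 0.5,
                        pos_meanlog = log(500), pos_sdlog = 0.35) {
  list(bg_tet_rate = bg_tet_rate, neg_p_zero = neg_p_zero,
       neg_meanlog = neg_meanlog, neg_sdlog = neg_sdlog,
       pos_meanlog = pos_meanlog, pos_sdlog = pos_sdlog)
}

#' Sample scenario for the synthetic generator
#'
#' Describes one barcoded staining sample: total events, the lineage mix of
#' the patient compartment, the healthy-donor buffer fraction (APC-negative
#' carrier PBMC added to reach the staining cell number), planted
#' antigen-specific populations, the palladium sample barcode and the noise
#' model.
#'
#' @param sample_id sample identifier.
#' @param n_events total cells acquired.
#' @param lineage_mix named fractions over
#'   `cd8, cd4, nk, mono, tcrgd, dead, debris, other`; must sum to <= 1
#'   (any remainder is added to `other`).
#' @param buffer_fraction fraction of events that are healthy-donor buffer
#'   cells (APC-negative).
#' @param planted list of [planted_population()] objects.
#' @param sample_barcode character vector of palladium channels (the 2-of-5
#'   code); default first pair.
#' @param subset_mix mixing fractions of the bulk CD8 memory subsets
#'   (naive, cm, em, eff).
#' @param noise a [noise_model()].
#' @param patient_id patient the sample belongs to (hits are deduplicated
#'   per patient); defaults to the sample id.
#' @return object of class `sample_scenario`.
#' @export
sample_scenario <- function(sample_id, n_events = 50000,
                            lineage_mix = c(cd8 = 0.35, cd4 = 0.30,
                                            nk = 0.08, mono = 0.12,
                                            tcrgd = 0.04, dead = 0.05,
                                            debris = 0.03, other = 0.03),
                            buffer_fraction = 0.15,
                            planted = list(),
                            sample_barcode = sample_barcode_scheme(sample_id)[[1]],
                            subset_mix = c(naive = 0.30, cm = 0.25,
                                           em = 0.30, eff = 0.15),
                            noise = noise_model(),
                            patient_id = sample_id) {
  full <- c(cd8 = 0, cd4 = 0, nk = 0, mono = 0, tcrgd = 0, dead = 0,
            debris = 0, other = 0)
  bad <- setdiff(names(lineage_mix), names(full))
  if (length(bad)) stop("unknown lineage(s): ", paste(bad, collapse = ", "))
  full[names(lineage_mix)] <- lineage_mix
  s <- sum(full)
  if (s > 1 + 1e-9) stop("lineage fractions must sum to <= 1")
  full["other"] <- full["other"] + max(0, 1 - s)
  if (buffer_fraction < 0 || buffer_fraction >= 1)
    stop("buffer_fraction must be in [0, 1)")
  for (p in planted) {
    if (!inherits(p, "planted_population"))
      stop("`planted` must be a list of planted_population objects")
    if (p$frequency >= 100) stop("planted frequency must be < 100%")
  }
  subset_mix <- subset_mix / sum(subset_mix)
  structure(list(sample_id = as.character(sample_id),
                 patient_id = as.character(patient_id),
                 n_events = as.integer(n_events), lineage_mix = full,
                 buffer_fraction = buffer_fraction, planted = planted,
                 sample_barcode = sort(sample_barcode),
                 subset_mix = subset_mix, noise = noise),
            class = "sample_scenario")
}

# round-half-up; planted counts use it so expectations in tests are exact
round_half_up <- function(x) floor(x + 0.5)

# largest-remainder apportionment of n into integer counts by fractions
.apportion <- function(n, fracs) {
  raw <- n * fracs
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  cnt
}

#' Simulate a barcoded staining sample
#'
#' Generates one event table per staining configuration. Planted events are
#' signal-positive in exactly the three tetramer channels of their peptide's
#' code in that configuration and background-clean elsewhere; the number of
#' planted events per population is exactly
#' `round_half_up(frequency/100 * n_CD8)` where `n_CD8` is the patient CD8
#' event count, so frequency recovery is exactly testable. CD8 events carry
#' CD45+/DNA+/cisplatin-/CD3+/CD8+ signal, other lineages their defining
#' markers; palladium channels are positive only for the scenario's sample
#' barcode; buffer cells are APC-negative and carry no planted populations.
#'
#' @param scenario a [sample_scenario()].
#' @param schemes list of `tetra_scheme` objects (one per configuration,
#'   from [assign_codes()]).
#' @param seed integer seed; the full output is reproducible.
#' @return named list of [event_table()] objects, one per configuration.
#'   Truth labels (`lineage`, `compartment`, `peptide`) are attached for
#'   testing only and are never read by pipeline stages.
#' @export
simulate_sample <- function(scenario, schemes, seed) {
  stopifnot(inherits(scenario, "sample_scenario"))
  if (inherits(schemes, "tetra_scheme")) schemes <- list(schemes)
  cfg_ids <- vapply(schemes, function(s) s$configuration_id, character(1))
  for (p in scenario$planted) {
    for (cfg in p$present_in) {
      sc <- schemes[[match(cfg, cfg_ids)]]
      if (is.na(match(cfg, cfg_ids)))
        stop("planted population references unknown configuration: ", cfg)
      if (!p$peptide_id %in% names(sc$assignment))
        stop(sprintf("peptide '%s' is not assigned in scheme %s",
                     p$peptide_id, cfg))
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- lapply(schemes, function(sc) .simulate_configuration(scenario, sc))
  names(out) <- cfg_ids
  out
}

.simulate_configuration <- function(scenario, scheme) {
  panel <- c(default_panel(),
             stats::setNames(rep("tetramer", length(scheme$metal_pool)),
                             scheme$metal_pool))
  chan <- names(panel)
  n <- scenario$n_events
  nz <- scenario$noise

  n_buffer <- round_half_up(scenario$buffer_fraction * n)
  n_patient <- n - n_buffer
  lin_p <- .apportion(n_patient, scenario$lineage_mix)
  lin_b <- .apportion(n_buffer, scenario$lineage_mix)
  lineage <- c(rep(names(lin_p), lin_p), rep(names(lin_b), lin_b))
  compartment <- c(rep("patient", n_patient), rep("buffer", n_buffer))

  # planted populations occupy the leading patient CD8 rows
  peptide <- rep(NA_character_, n)
  cd8_rows <- which(lineage == "cd8" & compartment == "patient")
  n_cd8 <- length(cd8_rows)
  cursor <- 0
  for (p in scenario$planted) {
    if (!scheme$configuration_id %in% p$present_in) next
    k <- round_half_up(p$frequency / 100 * n_cd8)
    if (cursor + k > n_cd8)
      stop("planted populations exceed the CD8 compartment")
    if (k > 0) peptide[cd8_rows[cursor + seq_len(k)]] <- p$peptide_id
    cursor <- cursor + k
  }

  S <- matrix(FALSE, n, length(chan), dimnames = list(NULL, chan))
  live <- !(lineage %in% c("dead", "debris"))
  S[, "Ir191_DNA"] <- lineage != "debris"
  S[, "Pt195_cisplatin"] <- lineage == "dead"
  S[, "CD45"] <- lineage != "debris"
  S[, "CD3"] <- lineage %in% c("cd8", "cd4", "tcrgd", "dead")
  S[, "CD8"] <- lineage %in% c("cd8", "dead")
  S[, "CD4"] <- lineage == "cd4"
  S[, "CD56"] <- lineage == "nk"
  S[, "CD16"] <- lineage == "nk"
  S[, "CD14"] <- lineage == "mono"
  S[, "TCRgd"] <- lineage == "tcrgd"
  S[, "antiAPC"] <- compartment == "patient" & lineage != "debris"
  S[, scenario$sample_barcode] <- TRUE
  S[lineage == "debris", palladium_channels()] <- FALSE

  # descriptive markers: per-event positive probabilities
  dm <- descriptive_markers()
  P <- matrix(0.08, n, length(dm), dimnames = list(NULL, dm))
  bulk <- .bulk_subtemplates()
  is_bulk_cd8 <- lineage == "cd8" & is.na(peptide)
  if (any(is_bulk_cd8)) {
    cls <- sample(names(scenario$subset_mix), sum(is_bulk_cd8),
                  replace = TRUE, prob = scenario$subset_mix)
    for (s in names(bulk))
      if (any(sel <- cls == s))
        P[which(is_bulk_cd8)[sel], ] <-
          matrix(bulk[[s]], sum(sel), length(dm), byrow = TRUE)
  }
  if (any(lineage == "cd4"))
    P[lineage == "cd4", ] <- matrix(bulk$cm, sum(lineage == "cd4"),
                                    length(dm), byrow = TRUE)
  for (p in scenario$planted) {
    if (!scheme$configuration_id %in% p$present_in) next
    sel <- which(peptide == p$peptide_id)
    if (length(sel))
      P[sel, ] <- matrix(p$template$positive_prob, length(sel), length(dm),
                         byrow = TRUE)
  }
  S[, dm] <- matrix(stats::runif(n * length(dm)) < P, n, length(dm))

  # tetramer channels: planted events get exactly their code; everything
  # else is independent background at bg_tet_rate
  tet <- scheme$metal_pool
  S[, tet] <- matrix(stats::runif(n * length(tet)) < nz$bg_tet_rate,
                     n, length(tet))
  planted_rows <- which(!is.na(peptide))
  if (length(planted_rows)) {
    S[planted_rows, tet] <- FALSE
    for (p in scenario$planted) {
      sel <- which(peptide == p$peptide_id)
      if (length(sel))
        S[sel, scheme$assignment[[p$peptide_id]]] <- TRUE
    }
  }

  # states -> zero-inflated log-normal intensities
  vals <- matrix(0, n, length(chan), dimnames = list(NULL, chan))
  ipos <- which(S)
  vals[ipos] <- stats::rlnorm(length(ipos), nz$pos_meanlog, nz$pos_sdlog)
  ineg <- which(!S)
  keep <- stats::runif(length(ineg)) > nz$neg_p_zero
  ineg <- ineg[keep]
  vals[ineg] <- stats::rlnorm(length(ineg), nz$neg_meanlog, nz$neg_sdlog)

  ord <- sample.int(n)
  event_table(vals[ord, , drop = FALSE], panel,
              meta = list(sample_id = scenario$sample_id,
                          patient_id = scenario$patient_id,
                          configuration_id = scheme$configuration_id,
                          transformed = FALSE),
              truth = data.frame(lineage = lineage[ord],
                                 compartment = compartment[ord],
                                 peptide = peptide[ord],
                                 stringsAsFactors = FALSE))
}

#' Simulate a responder / non-responder screening cohort
#'
#' Builds one scenario per patient sample, plants the requested number of
#' hit specificities (responder hits drawn from the late-effector and
#' activated templates, non-responder hits from the memory-like template)
#' and returns the scenarios together with a full truth ledger. Hits are
#' spread over a subset of the patients in each group, mirroring screens in
#' which only some patients harbor detectable specificities.
#'
#' @param n_responders,n_nonresponders patients per group (defaults 8 / 6).
#' @param hits_per_group integer vector (responder hits, non-responder
#'   hits), e.g. `c(13, 7)`.
#' @param peptide_ids candidate peptide panel (hit peptides are drawn from
#'   it without replacement).
#' @param schemes barcode schemes from [assign_codes()] covering
#'   `peptide_ids`.
#' @param seed integer seed.
#' @param n_events events per sample.
#' @param freq_range log-uniform range (percent of CD8) for planted hit
#'   frequencies.
#' @param patients_with_hits how many patients per group carry hits
#'   (defaults 5 responders, 3 non-responders).
#' @param ... passed to [sample_scenario()] (e.g. `lineage_mix`, `noise`).
#' @return list with `scenarios` (list of [sample_scenario()]),
#'   `truth` (data.frame: patient_id, sample_id, group, peptide_id,
#'   frequency_pct, template), and the `schemes` used.
#' @export
simulate_cohort <- function(n_responders = 8, n_nonresponders = 6,
                            hits_per_group = c(13, 7), peptide_ids, schemes,
                            seed, n_events = 12000,
                            freq_range = c(0.1, 0.65),
                            patients_with_hits = c(5, 3), ...) {
  if (sum(hits_per_group) > length(peptide_ids))
    stop("more hits requested than peptides in the panel")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  groups <- c(rep("responder", n_responders),
              rep("non_responder", n_nonresponders))
  pats <- c(sprintf("R%02d", seq_len(n_responders)),
            sprintf("N%02d", seq_len(n_nonresponders)))
  hit_peps <- sample(peptide_ids, sum(hits_per_group))
  resp_peps <- hit_peps[seq_len(hits_per_group[1])]
  nonr_peps <- setdiff(hit_peps, resp_peps)
  carriers <- list(
    responder = pats[groups == "responder"][
      seq_len(min(patients_with_hits[1], n_responders))],
    non_responder = pats[groups == "non_responder"][
      seq_len(min(patients_with_hits[2], n_nonresponders))])
  truth <- NULL
  assign_to <- function(peps, group) {
    if (!length(peps)) return(NULL)
    host <- rep(carriers[[group]], length.out = length(peps))
    data.frame(patient_id = host, group = group, peptide_id = peps,
               stringsAsFactors = FALSE)
  }
  truth <- rbind(assign_to(resp_peps, "responder"),
                 assign_to(nonr_peps, "non_responder"))
  templates <- phenotype_templates()
  scenarios <- vector("list", length(pats))
  names(scenarios) <- pats
  pd_codes <- sample_barcode_scheme(pats[seq_len(min(length(pats), 10))])
  ledger <- NULL
  for (i in seq_along(pats)) {
    pid <- pats[i]
    rows <- if (!is.null(truth)) truth[truth$patient_id == pid, ] else NULL
    planted <- list()
    if (!is.null(rows) && nrow(rows)) {
      lo <- log(freq_range[1]); hi <- log(freq_range[2])
      for (j in seq_len(nrow(rows))) {
        f <- exp(stats::runif(1, lo, hi))
        tmpl <- if (rows$group[j] == "responder") {
          if (stats::runif(1) < 0.8) templates$late_effector
          else templates$activated
        } else templates$memory_like
        planted[[j]] <- planted_population(rows$peptide_id[j], f, tmpl)
        ledger <- rbind(ledger, data.frame(
          patient_id = pid, sample_id = pid, group = rows$group[j],
          peptide_id = rows$peptide_id[j], frequency_pct = f,
          template = tmpl$name, stringsAsFactors = FALSE))
      }
    }
    bc <- pd_codes[[((i - 1) %% length(pd_codes)) + 1]]
    scenarios[[i]] <- sample_scenario(pid, n_events = n_events,
                                      planted = planted,
                                      sample_barcode = bc, ...)
  }
  if (is.null(ledger))
    ledger <- data.frame(patient_id = character(0), sample_id = character(0),
                         group = character(0), peptide_id = character(0),
                         frequency_pct = numeric(0), template = character(0),
                         stringsAsFactors = FALSE)
  list(scenarios = scenarios, truth = ledger, schemes = schemes,
       groups = stats::setNames(groups, pats))
}

#' Synthetic mutation / binding fixture for the selection cascade
#'
#' Generates random protein sequences with one somatic missense mutation
#' each, RNA read support, and per-peptide per-allele predicted IC50
#' values. Boundary cases are planted by construction: the first three
#' mutations get RNA read counts 0, 1 and 2, and the first three binding
#' rows get IC50 exactly 499.9, 500.0 and 500.1 nM, so the strict selection
#' rules are exercised on both sides of each cutoff.
#'
#' @param n_mutations number of mutations.
#' @param protein_lengths integer vector (recycled) of protein lengths.
#' @param alleles HLA alleles to predict against (default the supported
#'   6-allele panel).
#' @param seed integer seed.
#' @return list with `mutations` (protein_id, sequence, position,
#'   rna_reads), `bindings` (protein_id, peptide, allele, ic50_nM) and
#'   `truth` (the candidate rows a correct cascade must select, assuming
#'   all alleles are in the patient genotype).
#' @export
simulate_binding_table <- function(n_mutations, protein_lengths = 60,
                                   alleles = supported_hla_panel(),
                                   seed = 1) {
  if (n_mutations == 0)
    return(list(
      mutations = data.frame(protein_id = character(0),
                             sequence = character(0), position = integer(0),
                             rna_reads = integer(0)),
      bindings = data.frame(protein_id = character(0), peptide = character(0),
                            allele = character(0), ic50_nM = numeric(0)),
      truth = data.frame(protein_id = character(0), peptide = character(0),
                         allele = character(0), ic50_nM = numeric(0))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- rep_len(protein_lengths, n_mutations)
  muts <- data.frame(
    protein_id = sprintf("PROT%03d", seq_len(n_mutations)),
    sequence = vapply(lens, function(L)
      paste(sample(aa, L, replace = TRUE), collapse = ""), character(1)),
    position = vapply(lens, function(L) sample.int(L, 1), integer(1)),
    rna_reads = stats::rpois(n_mutations, 4),
    stringsAsFactors = FALSE)
  fixed_reads <- c(0L, 1L, 2L)
  k <- min(3, n_mutations)
  muts$rna_reads[seq_len(k)] <- fixed_reads[seq_len(k)]
  bindings <- NULL
  for (i in seq_len(n_mutations)) {
    peps <- enumerate_mutant_peptides(muts$sequence[i], muts$position[i])
    take <- peps$peptide[seq_len(min(3, nrow(peps)))]
    for (pep in take) {
      al <- sample(alleles, min(2, length(alleles)))
      bindings <- rbind(bindings, data.frame(
        protein_id = muts$protein_id[i], peptide = pep, allele = al,
        ic50_nM = exp(stats::runif(length(al), log(10), log(5000))),
        stringsAsFactors = FALSE))
    }
  }
  fixed_ic50 <- c(499.9, 500.0, 500.1)
  k2 <- min(3, nrow(bindings))
  bindings$ic50_nM[seq_len(k2)] <- fixed_ic50[seq_len(k2)]
  expressed <- muts$protein_id[muts$rna_reads >= 2]
  sel <- bindings[bindings$protein_id %in% expressed &
                    bindings$allele %in% supported_hla_panel() &
                    bindings$ic50_nM < 500, , drop = FALSE]
  rownames(sel) <- NULL
  list(mutations = muts, bindings = bindings, truth = sel)
}
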