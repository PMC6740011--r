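test_that("valley thresholding separates clear bimodal channels", {
  set.seed(21)
  truth <- c(rep(FALSE, 4000), rep(TRUE, 1500))
  v <- c(stats::rnorm(4000, 0.2, 0.15), stats::rnorm(1500, 3.0, 0.3))
  cut <- channel_threshold(v, method = "valley")
  expect_gt(cut, 0.8); expect_lt(cut, 2.3)
  acc <- mean((v > cut) == truth)
  expect_gte(acc, 0.99)
})

test_that("unimodal channels fall back to the negative-control percentile", {
  set.seed(22)
  v <- stats::rnorm(5000, 0.3, 0.12)
  ctrl <- stats::rnorm(2000, 0.3, 0.12)
  cut <- channel_threshold(v, method = "valley", negative_control = ctrl)
  expect_equal(cut, stats::quantile(ctrl, 0.995, names = FALSE))
})

test_that("degenerate channels are rejected", {
  expect_error(channel_threshold(rep(1, 500)), "insufficient data")
  expect_error(channel_threshold(stats::rnorm(20)), "insufficient data")
})

test_that("gap thresholding isolates rare well-separated positives", {
  set.seed(23)
  v <- c(stats::rnorm(50000, 0.4, 0.2), stats::rnorm(5, 2.8, 0.15))
  cut <- channel_threshold(v, method = "gap")
  expect_gt(cut, max(v[1:50000]) - 0.05)
  expect_lt(cut, min(v[50001:50005]))
})

test_that("de-barcoding recovers pooled samples exactly and partitions events", {
  schemes <- fix_schemes(n_pep = 5)
  ids <- sprintf("S%02d", 1:10)
  pd <- sample_barcode_scheme(ids)
  tabs <- lapply(ids, function(sid) {
    sc <- sample_scenario(sid, n_events = 800,
                          sample_barcode = pd[[sid]],
                          noise = noise_model(bg_tet_rate = 0))
    simulate_sample(sc, schemes[1], seed = match(sid, ids))[[1]]
  })
  pooled <- logicle_transform(pool_tables(tabs))
  thr <- estimate_thresholds(pooled)
  parts <- debarcode_samples(pooled, pd, thr)
  n_assigned <- sum(vapply(parts$samples, n_events, numeric(1)))
  expect_equal(n_assigned + n_events(parts$unassigned), n_events(pooled))
  # every assigned event comes back to its source sample; debris (which
  # carries no barcode) never does
  for (sid in ids) {
    tr <- parts$samples[[sid]]$truth
    expect_true(all(tr$source == sid))
    expect_gt(n_events(parts$samples[[sid]]), 700)
    expect_true(all(tr$lineage != "debris"))
  }
})

test_that("events with the wrong palladium multiplicity go to the unassigned pool", {
  roles <- c(stats::setNames(rep("palladium", 5), palladium_channels()),
             stats::setNames("lineage", "CD3"))
  tab <- manual_table(list(
    c("Pd102", "Pd104"),                    # valid code
    c("Pd102", "Pd104", "Pd105"),           # 3 positive -> unassigned
    c("Pd102"),                             # 1 positive -> unassigned
    c("Pd105", "Pd106")),                   # pair matching no sample
    roles)
  thr <- stats::setNames(rep(1.5, 6), colnames(tab$exprs))
  sc <- list(S1 = c("Pd102", "Pd104"))
  parts <- debarcode_samples(tab, sc, thr)
  expect_equal(n_events(parts$samples$S1), 1)
  expect_equal(n_events(parts$unassigned), 3)

  empty <- tab[integer(0)]
  pe <- debarcode_samples(empty, sc, thr)
  expect_equal(n_events(pe$unassigned), 0)

  tab2 <- event_table(matrix(1, 2, 1, dimnames = list(NULL, "CD3")),
                      c(CD3 = "lineage"), meta = list(transformed = TRUE))
  expect_error(debarcode_samples(tab2, sc, thr), "missing palladium")
})

test_that("lineage gating recovers truth populations with high fidelity", {
  schemes <- fix_schemes(n_pep = 5)
  tabs <- fix_sample(n_cd8 = 5000, schemes = schemes, seed = 31)
  tab <- logicle_transform(tabs[[1]])
  thr <- estimate_thresholds(tab)
  tree <- gate_lineages(tab, thr)
  truth_cd8 <- tab$truth$lineage == "cd8" & tab$truth$compartment == "patient"
  called <- gate_mask(tree, "patient_cd8")
  recall <- sum(called & truth_cd8) / sum(truth_cd8)
  precision <- sum(called & truth_cd8) / sum(called)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
  # APC-negative buffer cells are excluded from the patient subset
  expect_equal(sum(called & tab$truth$compartment == "buffer"), 0)
  # hierarchical subset property at every node
  for (nm in setdiff(names(tree), "all")) {
    node <- tree[[nm]]
    expect_true(all(!node$mask | tree[[node$parent]]$mask))
  }
})

test_that("a monocyte-only table yields an empty CD8 gate", {
  roles <- default_panel()
  ex <- matrix(0.2, 50, length(roles), dimnames = list(NULL, names(roles)))
  ex[, c("CD45", "CD14", "Ir191_DNA", "antiAPC")] <- 3
  tab <- event_table(ex, roles, meta = list(transformed = TRUE))
  thr <- stats::setNames(rep(1.5, length(roles)), names(roles))
  tree <- gate_lineages(tab, thr)
  expect_equal(sum(gate_mask(tree, "cd8")), 0)
  expect_equal(sum(gate_mask(tree, "live")), 50)
})

test_that("gating reports missing channels as a schema error", {
  roles <- c(CD3 = "lineage", CD8 = "lineage")
  tab <- event_table(matrix(1, 10, 2, dimnames = list(NULL, names(roles))),
                     roles, meta = list(transformed = TRUE))
  expect_error(gate_lineages(tab, c(CD3 = 1, CD8 = 1)),
               "schema error.*CD45")
})

test_that("pipeline statistics are invariant to event order", {
  schemes <- fix_schemes(n_pep = 10)
  tabs <- fix_sample(n_cd8 = 3000,
                     planted = list(planted_population("pep004", 0.5)),
                     schemes = schemes, seed = 13)
  perm <- lapply(tabs, function(tab) {
    set.seed(99); tab[sample.int(n_events(tab))]
  })
  s1 <- run_screen(tabs, schemes, n_candidates = 10)
  s2 <- run_screen(perm, schemes, n_candidates = 10)
  ord <- function(df) df[order(df$configuration_id, df$gate, df$peptide_id), ]
  r1 <- ord(s1$records); r2 <- ord(s2$records)
  rownames(r1) <- rownames(r2) <- NULL
  expect_identical(r1, r2)
})
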