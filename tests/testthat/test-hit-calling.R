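test_that("the event-count threshold is evaluated per configuration", {
  expect_true(apply_count_threshold(c(2, 2)))
  expect_false(apply_count_threshold(c(1, 50)))
  expect_false(apply_count_threshold(c(50, 1)))
  expect_true(apply_count_threshold(c(2, 100)))
  expect_false(apply_count_threshold(3))
  expect_true(apply_count_threshold(4))
  expect_false(apply_count_threshold(integer(0)))
})

test_that("concordance applies the strict two-fold rule with zero handling", {
  r <- concordance(0.04, 0.05)
  expect_equal(r$ratio, 1.25); expect_true(r$pass)
  r <- concordance(0.02, 0.05)
  expect_equal(r$ratio, 2.5); expect_false(r$pass)
  r <- concordance(0.3, 0.3)
  expect_equal(r$ratio, 1); expect_true(r$pass)
  r <- concordance(0.02, 0.04)       # exactly two-fold: not less-than
  expect_equal(r$ratio, 2); expect_false(r$pass)
  r <- concordance(0, 0.05)
  expect_identical(r$ratio, Inf); expect_false(r$pass)
  r <- concordance(0, 0)
  expect_true(is.na(r$ratio)); expect_false(r$pass)
})

test_that("CD4 comparison is strict and fails safe on missing records", {
  expect_true(cd4_comparison(c(0.10, 0.08), c(0.00, 0.01)))
  expect_false(cd4_comparison(0.02, 0.05))
  expect_false(cd4_comparison(0.05, 0.05))     # strict inequality
  expect_false(cd4_comparison(c(0.1, 0.1), c(0.0, NA)))
  expect_false(cd4_comparison(numeric(0), numeric(0)))
})

test_that("donor background ratio floors the donor frequency at one event", {
  expect_equal(donor_background(0.5, 0, 10000), 50)
  expect_equal(donor_background(0.05, 0.05, 1000), 0.5)  # floor 0.1%
  expect_equal(donor_background(0.3, 0.3, 100000), 1)
  expect_true(is.na(donor_background(0.5, 0, 0)))
  expect_true(is.na(donor_background(0.5, 0, NA)))
})

test_that("homogeneity score separates tight clones from diffuse bulk", {
  dm <- descriptive_markers()
  roles <- stats::setNames(rep("descriptive", length(dm)), dm)
  make_tab <- function(m) event_table(m, roles,
                                      meta = list(transformed = TRUE))
  centers <- matrix(stats::rnorm(3 * length(dm), sd = 2), 3)
  scores <- vapply(1:20, function(s) {
    set.seed(s)
    bulk <- do.call(rbind, lapply(1:3, function(k)
      matrix(stats::rnorm(300 * length(dm), mean = centers[k, ], sd = 0.3),
             300, byrow = TRUE)))
    colnames(bulk) <- dm
    hits <- matrix(stats::rnorm(30 * length(dm), mean = centers[1, ],
                                sd = 0.1), 30, byrow = TRUE)
    colnames(hits) <- dm
    homogeneity_score(make_tab(hits), make_tab(bulk), n_boot = 100,
                      seed = s)
  }, numeric(1))
  expect_true(all(scores < 5))

  # null calibration: hits drawn from bulk itself score uniformly
  set.seed(1)
  bulk <- matrix(stats::rnorm(1000 * length(dm)), 1000)
  colnames(bulk) <- dm
  null_scores <- vapply(1:100, function(s) {
    set.seed(s)
    idx <- sample.int(1000, 25)
    homogeneity_score(make_tab(bulk[idx, ]), make_tab(bulk), n_boot = 60,
                      seed = s + 500)
  }, numeric(1))
  expect_gte(stats::median(null_scores), 30)
  expect_lte(stats::median(null_scores), 70)

  one <- make_tab(bulk[1, , drop = FALSE])
  expect_true(is.na(homogeneity_score(one, make_tab(bulk))))
})

test_that("verdicts decompose exactly into their stored criterion flags", {
  rec <- function(sample, pep, cfg, gate, count, total) data.frame(
    sample_id = sample, configuration_id = cfg, gate = gate,
    peptide_id = pep, category = "neoantigen", event_count = count,
    n_gate_total = total, frequency_pct = 100 * count / total,
    threshold_pct = 100 * 2 / total, stringsAsFactors = FALSE)
  records <- rbind(
    # concordant hit, clean CD4
    rec("S1", "A", "config1", "cd8", 20, 10000),
    rec("S1", "A", "config2", "cd8", 18, 10000),
    rec("S1", "A", "config1", "cd4", 0, 8000),
    rec("S1", "A", "config2", "cd4", 0, 8000),
    # fails count threshold in one configuration
    rec("S1", "B", "config1", "cd8", 1, 10000),
    rec("S1", "B", "config2", "cd8", 40, 10000),
    rec("S1", "B", "config1", "cd4", 0, 8000),
    rec("S1", "B", "config2", "cd4", 0, 8000),
    # discordant (>2x) but beats CD4
    rec("S1", "C", "config1", "cd8", 30, 10000),
    rec("S1", "C", "config2", "cd8", 9, 10000),
    rec("S1", "C", "config1", "cd4", 0, 8000),
    rec("S1", "C", "config2", "cd4", 0, 8000),
    # concordant but loses to CD4 background
    rec("S1", "D", "config1", "cd8", 10, 10000),
    rec("S1", "D", "config2", "cd8", 11, 10000),
    rec("S1", "D", "config1", "cd4", 20, 8000),
    rec("S1", "D", "config2", "cd4", 20, 8000))
  res <- call_hits(records, n_candidates = 4)
  h <- res$hits[order(res$hits$peptide_id), ]
  expect_identical(h$verdict, h$passed_count_threshold &
                     (h$passed_cd4_comparison | h$passed_concordance))
  expect_identical(h$verdict[h$peptide_id == "A"], TRUE)
  expect_identical(h$verdict[h$peptide_id == "B"], FALSE)
  expect_identical(h$verdict[h$peptide_id == "C"], TRUE)   # via CD4
  expect_identical(h$verdict[h$peptide_id == "D"], TRUE)   # via concordance
  expect_false(h$passed_cd4_comparison[h$peptide_id == "D"])
  expect_gte(h$concordance_ratio[h$peptide_id == "C"], 2)
})

test_that("single-configuration populations need four events", {
  rec <- function(pep, count) data.frame(
    sample_id = "S1", configuration_id = "config1", gate = "cd8",
    peptide_id = pep, category = "neoantigen", event_count = count,
    n_gate_total = 5000, frequency_pct = 100 * count / 5000,
    threshold_pct = 100 * 4 / 5000, stringsAsFactors = FALSE)
  cd4 <- data.frame(
    sample_id = "S1", configuration_id = "config1", gate = "cd4",
    peptide_id = c("E", "F"), category = "neoantigen", event_count = 0,
    n_gate_total = 4000, frequency_pct = 0, threshold_pct = 0.1,
    stringsAsFactors = FALSE)
  res <- call_hits(rbind(rec("E", 3), rec("F", 4), cd4), n_candidates = 2)
  h <- res$hits[order(res$hits$peptide_id), ]
  expect_false(h$verdict[h$peptide_id == "E"])
  expect_true(h$verdict[h$peptide_id == "F"])
})

test_that("unique hits deduplicate across samples of one patient", {
  rec <- function(sample, pep, cfg, count) data.frame(
    sample_id = sample, configuration_id = cfg, gate = "cd8",
    peptide_id = pep, category = "neoantigen", event_count = count,
    n_gate_total = 10000, frequency_pct = 100 * count / 10000,
    threshold_pct = 0.02, stringsAsFactors = FALSE)
  cd4 <- function(sample, pep, cfg) data.frame(
    sample_id = sample, configuration_id = cfg, gate = "cd4",
    peptide_id = pep, category = "neoantigen", event_count = 0,
    n_gate_total = 8000, frequency_pct = 0, threshold_pct = 0.025,
    stringsAsFactors = FALSE)
  records <- rbind(
    rec("P3_c1d1", "RLDSTLLLY", "config1", 60),
    rec("P3_c1d1", "RLDSTLLLY", "config2", 55),
    rec("P3_c4d1", "RLDSTLLLY", "config1", 50),
    rec("P3_c4d1", "RLDSTLLLY", "config2", 45),
    cd4("P3_c1d1", "RLDSTLLLY", "config1"),
    cd4("P3_c1d1", "RLDSTLLLY", "config2"),
    cd4("P3_c4d1", "RLDSTLLLY", "config1"),
    cd4("P3_c4d1", "RLDSTLLLY", "config2"))
  res <- call_hits(records, n_candidates = 126,
                   patients = c(P3_c1d1 = "P3", P3_c4d1 = "P3"))
  expect_equal(sum(res$hits$verdict), 2)       # called in both samples
  expect_equal(res$summary$n_unique_hits, 1)   # but one unique specificity
})
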