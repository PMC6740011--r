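test_that("marker positivity hits its boundary values", {
  dm <- descriptive_markers()
  roles <- stats::setNames(rep("descriptive", length(dm)), dm)
  ex <- matrix(3, 10, length(dm), dimnames = list(NULL, dm))
  ex[, "CD39"] <- 0                       # empty channel
  tab <- event_table(ex, roles, meta = list(transformed = TRUE))
  thr <- stats::setNames(rep(1.5, length(dm)), dm)
  prof <- marker_positivity(tab, thr)
  expect_equal(unname(prof["CD57"]), 100)
  expect_equal(unname(prof["CD39"]), 0)
  expect_error(marker_positivity(tab[integer(0)], thr), "undefined profile")
})

test_that("effector and memory templates separate by their defining markers", {
  set.seed(5)
  eff <- sim_profile(phenotype_templates()$late_effector, n = 300)
  mem <- sim_profile(phenotype_templates()$memory_like, n = 300)
  for (mk in c("KLRG-1", "2B4", "CD57"))
    expect_gt(eff[mk] - mem[mk], 30)
  for (mk in c("CD127", "CD28", "CCR7"))
    expect_gt(mem[mk] - eff[mk], 30)
})

test_that("memory-subset quadrants partition the CD8 compartment", {
  roles <- c(CD45RO = "descriptive", CCR7 = "descriptive",
             CD38 = "descriptive")
  ex <- matrix(0.2, 40, 3, dimnames = list(NULL, names(roles)))
  ex[, "CCR7"] <- 3                       # all naive: CD45RO- CCR7+
  tab <- event_table(ex, roles, meta = list(transformed = TRUE))
  thr <- c(CD45RO = 1.5, CCR7 = 1.5, CD38 = 1.5)
  f <- classify_subsets(tab, thr)
  expect_equal(unname(f["naive"]), 100)
  expect_equal(unname(f["activated"]), 0)
  expect_equal(sum(f[c("naive", "central_memory", "effector_memory",
                       "effector")]), 100)

  set.seed(8)
  ex2 <- matrix(stats::runif(3000 * 3, 0, 3), 3000,
                dimnames = list(NULL, names(roles)))
  tab2 <- event_table(ex2, roles, meta = list(transformed = TRUE))
  f2 <- classify_subsets(tab2, thr)
  expect_equal(sum(f2[c("naive", "central_memory", "effector_memory",
                        "effector")]), 100)
  expect_error(classify_subsets(tab, c(CD45RO = 1)), "missing")
})

test_that("an equal synthetic subset mix is recovered within two points", {
  schemes <- fix_schemes(n_pep = 3)
  sc <- screen_scenario("S1", n_cd8 = 10000,
                        subset_mix = c(naive = 0.25, cm = 0.25, em = 0.25,
                                       eff = 0.25))
  tab <- logicle_transform(simulate_sample(sc, schemes[1], seed = 6)[[1]])
  thr <- estimate_thresholds(tab)
  tree <- gate_lineages(tab, thr)
  cd8 <- tab[which(gate_mask(tree, "patient_cd8"))]
  f <- classify_subsets(cd8, thr)
  for (s in c("naive", "central_memory", "effector_memory", "effector"))
    expect_lt(abs(f[[s]] - 25), 2)
})

test_that("the hit matrix preserves order and rejects inconsistent panels", {
  p1 <- stats::setNames(c(10, 20, 30), c("A", "B", "C"))
  p2 <- stats::setNames(c(40, 50, 60), c("A", "B", "C"))
  m <- build_hit_matrix(list(h1 = p1, h2 = p2))
  expect_equal(dim(m), c(2, 3))
  expect_identical(colnames(m), c("A", "B", "C"))
  expect_equal(unname(m["h2", "B"]), 50)
  expect_identical(build_hit_matrix(list(only = p1))["only", ], p1)
  bad <- stats::setNames(1:2, c("A", "B"))
  expect_error(build_hit_matrix(list(p1, bad)), "inconsistent")
})

test_that("PCA clustering separates templates and is order-invariant", {
  set.seed(12)
  profs <- c(lapply(1:8, function(i)
    sim_profile(phenotype_templates()$late_effector, n = 150)),
    lapply(1:8, function(i)
      sim_profile(phenotype_templates()$memory_like, n = 150)))
  names(profs) <- sprintf("h%02d", 1:16)
  m <- build_hit_matrix(profs)
  cl <- pca_cluster_hits(m, k = 2, seed = 3)
  grp <- rep(c("eff", "mem"), each = 8)
  tab <- table(grp, cl$scores$cluster)
  expect_equal(max(tab["eff", ]), 8)      # perfect template agreement
  expect_equal(max(tab["mem", ]), 8)
  expect_equal(sum(diag(tab) == 8) + sum(tab[1, 2] == 8 & tab[2, 1] == 8) >
                 0, TRUE)

  perm <- sample(16)
  cl2 <- pca_cluster_hits(m[perm, ], k = 2, seed = 3)
  expect_identical(cl2$scores$cluster[order(perm)], cl$scores$cluster)

  dup <- m[c(1, 1, 9, 9), ]
  rownames(dup) <- sprintf("d%d", 1:4)
  cld <- pca_cluster_hits(dup, k = 2, seed = 1)
  expect_identical(cld$scores$cluster[1], cld$scores$cluster[2])
  expect_identical(cld$scores$cluster[3], cld$scores$cluster[4])

  expect_error(pca_cluster_hits(m[1:2, ], k = 3), "fewer hits")

  comp <- cluster_composition(cl, grp)
  expect_equal(unname(rowSums(comp)), c(100, 100))
})

test_that("rank-based marker comparison matches an exact permutation oracle", {
  perm_p <- function(x, y) {
    nx <- length(x); n <- nx + length(y)
    pooled <- c(x, y); r <- rank(pooled)
    obs <- sum(r[seq_len(nx)])
    combs <- utils::combn(n, nx)
    stat <- apply(combs, 2, function(idx) sum(r[idx]))
    pl <- mean(stat <= obs); pu <- mean(stat >= obs)
    min(1, 2 * min(pl, pu))
  }
  set.seed(31)
  for (rep in 1:8) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- stats::rnorm(nx); y <- stats::rnorm(ny, mean = rep %% 3)
    m <- cbind(M = c(x, y))
    rownames(m) <- sprintf("r%d", seq_len(nx + ny))
    res <- differential_markers(m, c(rep("a", nx), rep("b", ny)))
    expect_equal(res$p_value, perm_p(x, y), tolerance = 1e-12)
  }
})

test_that("marker comparison flags the template-defining markers", {
  up_eff <- c("KLRG-1", "2B4", "CD57", "CD161", "TIGIT", "CD25")
  up_mem <- c("CD127", "CD28", "CD27", "CCR7")
  for (seed in 1:3) {
    set.seed(seed)
    profs <- c(lapply(1:10, function(i)
      sim_profile(phenotype_templates()$late_effector, n = 100)),
      lapply(1:10, function(i)
        sim_profile(phenotype_templates()$memory_like, n = 100)))
    names(profs) <- sprintf("h%02d", 1:20)
    m <- build_hit_matrix(profs)
    res <- differential_markers(m, rep(c("eff", "mem"), each = 10))
    sig <- res[res$marker %in% up_eff, ]
    expect_true(all(sig$q_value < 0.05))
    expect_true(all(sig$direction == "eff"))
    sigm <- res[res$marker %in% up_mem, ]
    expect_true(all(sigm$q_value < 0.05))
    expect_true(all(sigm$direction == "mem"))
  }
  # identical groups: nothing significant
  one <- sim_profile(phenotype_templates()$late_effector, n = 200)
  m0 <- build_hit_matrix(stats::setNames(rep(list(one), 8),
                                         sprintf("h%d", 1:8)))
  res0 <- differential_markers(m0, rep(c("a", "b"), each = 4))
  expect_true(all(res0$p_value > 0.99))
  expect_error(differential_markers(m0, rep("a", 8)), "two groups")
})

test_that("t-SNE embedding is seeded, capped and separates distant clouds", {
  dm <- descriptive_markers()
  roles <- stats::setNames(rep("descriptive", length(dm)), dm)
  set.seed(2)
  a <- matrix(stats::rnorm(60 * length(dm), 0, 0.3), 60)
  b <- matrix(stats::rnorm(60 * length(dm), 4, 0.3), 60)
  ex <- rbind(a, b); colnames(ex) <- dm
  tab <- event_table(ex, roles, meta = list(transformed = TRUE))
  e1 <- tsne_embed(tab, perplexity = 15, n_iter = 300, seed = 4)
  e2 <- tsne_embed(tab, perplexity = 15, n_iter = 300, seed = 4)
  expect_identical(e1$coords, e2$coords)
  expect_length(e1$index, 120)            # no downsampling below the cap
  e3 <- tsne_embed(tab, max_per_sample = 50, perplexity = 10,
                   n_iter = 100, seed = 4)
  expect_length(e3$index, 50)
  # silhouette of the true grouping in the embedding
  grp <- rep(1:2, each = 60)
  d <- as.matrix(stats::dist(e1$coords))
  sil <- vapply(seq_len(120), function(i) {
    same <- setdiff(which(grp == grp[i]), i)
    a_i <- mean(d[i, same])
    b_i <- mean(d[i, grp != grp[i]])
    (b_i - a_i) / max(a_i, b_i)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_error(tsne_embed(tab[1:5]), "too few")
})
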