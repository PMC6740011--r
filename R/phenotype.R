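#' Marker-positivity profile
#'
#' Percent of events positive for each descriptive marker, evaluated on
#' the transformed scale against per-channel cutoffs.
#'
#' @param events a logicle-transformed [event_table()] with at least one
#'   event.
#' @param thresholds named cutoff vector covering the descriptive channels.
#' @param markers marker names (default: all descriptive channels of the
#'   table, in fixed panel order).
#' @return named numeric vector of percent-positive values in \[0, 100\].
#' @export
marker_positivity <- function(events, thresholds, markers = NULL) {
  stopifnot(inherits(events, "event_table"))
  if (n_events(events) == 0)
    stop("undefined profile: no events")
  if (is.null(markers)) markers <- channels(events, "descriptive")
  missing <- setdiff(markers, colnames(events$exprs))
  if (length(missing))
    stop("schema error: missing marker channel(s): ",
         paste(missing, collapse = ", "))
  pos <- sweep(events$exprs[, markers, drop = FALSE], 2,
               thresholds[markers], ">")
  100 * colMeans(pos)
}

#' Memory-subset frequencies of CD8 events
#'
#' Classifies events into the four CD45RO x CCR7 quadrants -- naive
#' (CD45RO- CCR7+), central memory (CD45RO+ CCR7+), effector memory
#' (CD45RO+ CCR7-), effector (CD45RO- CCR7-) -- which partition the CD8
#' compartment exactly, plus the overlapping activated subset
#' (CD38+ CCR7-), reported separately.
#'
#' @param cd8_events a logicle-transformed [event_table()].
#' @param thresholds named cutoff vector with entries for CD45RO, CCR7 and
#'   CD38.
#' @return named numeric vector of percentages: naive, central_memory,
#'   effector_memory, effector (summing to 100), activated.
#' @export
classify_subsets <- function(cd8_events, thresholds) {
  stopifnot(inherits(cd8_events, "event_table"))
  need <- c("CD45RO", "CCR7", "CD38")
  missing <- setdiff(need, colnames(cd8_events$exprs))
  if (length(missing))
    stop("schema error: missing channel(s): ",
         paste(missing, collapse = ", "))
  missing_thr <- need[is.na(match(need, names(thresholds)))]
  if (length(missing_thr))
    stop("schema error: missing threshold(s) for: ",
         paste(missing_thr, collapse = ", "))
  if (n_events(cd8_events) == 0)
    stop("undefined subsets: no events")
  ex <- cd8_events$exprs
  ro <- ex[, "CD45RO"] > thresholds["CD45RO"]
  r7 <- ex[, "CCR7"] > thresholds["CCR7"]
  c38 <- ex[, "CD38"] > thresholds["CD38"]
  n <- nrow(ex)
  c(naive = 100 * sum(!ro & r7) / n,
    central_memory = 100 * sum(ro & r7) / n,
    effector_memory = 100 * sum(ro & !r7) / n,
    effector = 100 * sum(!ro & !r7) / n,
    activated = 100 * sum(c38 & !r7) / n)
}

#' Assemble the hits x markers profile matrix
#'
#' @param profiles named list of profiles from [marker_positivity()] (one
#'   per hit; names are the hit identities).
#' @return numeric matrix, rows = hits, columns = markers in the fixed
#'   panel order of the first profile.
#' @export
build_hit_matrix <- function(profiles) {
  if (!length(profiles)) stop("no profiles")
  markers <- names(profiles[[1]])
  for (p in profiles)
    if (!identical(sort(names(p)), sort(markers)))
      stop("schema error: inconsistent marker sets across profiles")
  m <- do.call(rbind, lapply(profiles, function(p) p[markers]))
  rownames(m) <- names(profiles)
  colnames(m) <- markers
  m
}

#' PCA + k-means clustering of hit phenotypes
#'
#' Columns are centered and (by default) scaled to unit variance so markers
#' contribute comparably; k-means with `k` clusters is run on the first two
#' principal-component scores. Principal-component signs are fixed
#' deterministically (the loading with the largest magnitude on each
#' component is made positive, preferring effector-phenotype markers for
#' PC1 when present) and cluster labels are renumbered by descending mean
#' PC1 score, so labels are stable across runs and machine orderings.
#'
#' @param matrix hits x markers matrix from [build_hit_matrix()].
#' @param k number of clusters (default 3).
#' @param seed integer seed for the k-means initialization.
#' @param scale. scale columns to unit variance before PCA (default TRUE).
#' @param nstart k-means restarts (>= 10).
#' @return object of class `hit_clusters`: data.frame `scores` (hit, PC1,
#'   PC2, cluster), the `loadings`, per-cluster `centers` and the variance
#'   explained.
#' @export
pca_cluster_hits <- function(matrix, k = 3, seed = 1, scale. = TRUE,
                             nstart = 10) {
  if (nrow(matrix) < k)
    stop(sprintf("fewer hits (%d) than clusters (%d)", nrow(matrix), k))
  keep <- apply(matrix, 2, function(v) stats::sd(v) > 0)
  pc <- stats::prcomp(matrix[, keep, drop = FALSE], center = TRUE,
                      scale. = scale.)
  npc <- min(2, ncol(pc$x))
  eff <- intersect(c("KLRG-1", "2B4", "CD57", "CD161", "TIGIT", "CD25"),
                   colnames(matrix)[keep])
  for (j in seq_len(npc)) {
    s <- if (j == 1 && length(eff)) sum(pc$rotation[eff, j])
         else pc$rotation[which.max(abs(pc$rotation[, j])), j]
    if (s < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- pc$x[, seq_len(npc), drop = FALSE]
  if (npc == 1) scores <- cbind(scores, PC2 = 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = max(nstart, 10))
  ord <- order(tapply(scores[, 1], km$cluster, mean), decreasing = TRUE)
  relabel <- match(km$cluster, ord)
  df <- data.frame(hit = rownames(matrix), PC1 = scores[, 1],
                   PC2 = scores[, 2], cluster = relabel,
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(scores = df, loadings = pc$rotation[, seq_len(npc),
                                                     drop = FALSE],
                 centers = km$centers[ord, , drop = FALSE],
                 var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(npc)],
                 k = k),
            class = "hit_clusters")
}

#' @export
print.hit_clusters <- function(x, ...) {
  cat(sprintf("<hit_clusters> %d hits in %d clusters (PC1 %.0f%%, PC2 %.0f%% of variance)\n",
              nrow(x$scores), x$k, 100 * x$var_explained[1],
              100 * x$var_explained[min(2, length(x$var_explained))]))
  print(table(cluster = x$scores$cluster))
  invisible(x)
}

#' @param x a `hit_clusters` object.
#' @param ... passed to [graphics::plot()].
#' @rdname pca_cluster_hits
#' @export
plot.hit_clusters <- function(x, ...) {
  graphics::plot(x$scores$PC1, x$scores$PC2, col = x$scores$cluster,
                 pch = 19, xlab = "PC1", ylab = "PC2", ...)
  graphics::legend("topright", legend = paste("cluster", seq_len(x$k)),
                   col = seq_len(x$k), pch = 19, bty = "n")
  invisible(x)
}

#' Per-cluster composition by group
#'
#' @param clusters a `hit_clusters` object.
#' @param group_labels named (or positional) vector of group labels per hit.
#' @return matrix of row percentages: groups x clusters, rows summing to
#'   100.
#' @export
cluster_composition <- function(clusters, group_labels) {
  stopifnot(inherits(clusters, "hit_clusters"))
  tab <- table(group = group_labels, cluster = clusters$scores$cluster)
  100 * prop.table(tab, margin = 1)
}

#' Rank-based marker comparison between groups
#'
#' Two-sided rank test per marker between two groups of hit profiles:
#' unpaired rank-sum by default, with a paired signed-rank option.
#' Benjamini-Hochberg adjusted q-values are reported alongside the
#' unadjusted p-values.
#'
#' @param matrix hits x markers matrix from [build_hit_matrix()].
#' @param group_labels vector of two group labels, one per row.
#' @param paired use the paired signed-rank test (rows must be matched in
#'   order within each group).
#' @return data.frame: marker, statistic, p_value, q_value, direction (the
#'   group with the larger median), median per group.
#' @export
differential_markers <- function(matrix, group_labels, paired = FALSE) {
  groups <- unique(group_labels)
  if (length(groups) != 2)
    stop("exactly two groups are required")
  a <- matrix[group_labels == groups[1], , drop = FALSE]
  b <- matrix[group_labels == groups[2], , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) stop("a group is empty")
  res <- lapply(colnames(matrix), function(mk) {
    wt <- suppressWarnings(
      stats::wilcox.test(a[, mk], b[, mk], paired = paired, exact = TRUE))
    med_a <- stats::median(a[, mk]); med_b <- stats::median(b[, mk])
    # a marker constant across both groups carries no evidence
    pv <- wt$p.value
    if (is.na(pv)) pv <- 1
    data.frame(marker = mk, statistic = unname(wt$statistic),
               p_value = pv,
               direction = if (med_a == med_b) "none"
                           else as.character(groups[if (med_a > med_b) 1
                                                    else 2]),
               median_1 = med_a, median_2 = med_b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[names(out) == "median_1"] <- paste0("median_", groups[1])
  names(out)[names(out) == "median_2"] <- paste0("median_", groups[2])
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("marker", "statistic", "p_value", "q_value", "direction",
          paste0("median_", groups))]
}

#' t-SNE embedding of single-cell events
#'
#' Two-dimensional t-SNE of the descriptive-marker space, for visualization
#' only (no downstream statistic depends on it). Events are first
#' down-sampled without replacement to `max_per_sample`. The implementation
#' is exact t-SNE (full pairwise affinities, perplexity calibrated per
#' point by bisection, gradient descent with momentum and early
#' exaggeration); suitable for the post-gating event counts this package
#' works at.
#'
#' @param events a logicle-transformed [event_table()] (>= 10 events).
#' @param max_per_sample down-sampling cap (default 20000).
#' @param perplexity t-SNE perplexity (default 30).
#' @param n_iter gradient-descent iterations (default 500).
#' @param seed integer seed (down-sampling and initialization).
#' @return list with `coords` (n x 2 matrix), `index` (rows of `events`
#'   embedded) and the parameters used.
#' @export
tsne_embed <- function(events, max_per_sample = 20000, perplexity = 30,
                       n_iter = 500, seed = 1) {
  stopifnot(inherits(events, "event_table"))
  n0 <- n_events(events)
  if (n0 < 10) stop("too few events for an embedding (need >= 10)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- if (n0 > max_per_sample) sort(sample.int(n0, max_per_sample))
         else seq_len(n0)
  X <- events$exprs[idx, channels(events, "descriptive"), drop = FALSE]
  n <- nrow(X)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  D2 <- as.matrix(stats::dist(X))^2
  P <- .tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.xmin] <- .Machine$double.xmin
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  momentum <- 0.5; eta <- 200; gain <- matrix(1, n, 2)
  dY <- matrix(0, n, 2)
  exagg <- 12
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= 100) P * exagg else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < .Machine$double.xmin] <- .Machine$double.xmin
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gain <- ifelse(sign(grad) != sign(dY), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    dY <- momentum * dY - eta * gain * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == 250) momentum <- 0.8
  }
  list(coords = Y, index = idx,
       params = list(perplexity = perplexity, n_iter = n_iter,
                     max_per_sample = max_per_sample, seed = seed))
}

# per-point conditional affinities at fixed perplexity (bisection on the
# Gaussian precision)
.tsne_affinities <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (tries in 1:50) {
      w <- exp(-di * beta)
      s <- sum(w)
      if (s <= 0) { H <- 0 } else {
        H <- log(s) + beta * sum(di * w) / s
      }
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else { hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    pr <- w / sum(w)
    P[i, -i] <- pr
  }
  P
}
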