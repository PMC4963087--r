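#' UPGMA (average-linkage) agglomerative clustering
#'
#' Classical unweighted pair group method with arithmetic mean: at each step
#' the two clusters with the smallest mean cross-pair distance are merged and
#' the merge height recorded. Ties are broken by merging the pair whose sorted
#' label pair is lexicographically smallest. The result uses the `hclust`
#' merge/height/order encoding so that `stats::cutree()`,
#' `stats::cophenetic()` and `ape::as.phylo()` apply directly.
#'
#' @param D A symmetric distance matrix (or `dist`) with zero diagonal.
#' @param labels Leaf labels (default: dimnames of `D` or 1..n).
#' @return An object of classes `upgma`/`hclust`.
#' @export
upgma <- function(D, labels = NULL) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("need at least two leaves", call. = FALSE)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12)) ||
      any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(D))) rownames(D) else as.character(seq_len(n))
  }
  # active clusters: negative = leaf index, positive = merge row
  members <- as.list(seq_len(n))          # leaf indices per active cluster
  ids <- -seq_len(n)                      # hclust node coding
  key <- labels                           # lexicographic tie key per cluster
  Dc <- D                                 # current mean cross-pair distances
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(members)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        pair_key <- sort(c(key[i], key[j]))
        if (is.null(best) || Dc[i, j] < best$d - 1e-12 ||
            (abs(Dc[i, j] - best$d) <= 1e-12 &&
             (pair_key[1] < best$key[1] ||
              (pair_key[1] == best$key[1] && pair_key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = Dc[i, j], key = pair_key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- best$d
    ni <- length(members[[i]]); nj <- length(members[[j]])
    # UPGMA update: unweighted mean over all cross pairs
    newd <- (ni * Dc[i, ] + nj * Dc[j, ]) / (ni + nj)
    members[[i]] <- c(members[[i]], members[[j]])
    ids[i] <- step
    key[i] <- min(key[i], key[j])
    Dc[i, ] <- newd; Dc[, i] <- newd; Dc[i, i] <- 0
    members[[j]] <- NULL
    ids <- ids[-j]; key <- key[-j]
    Dc <- Dc[-j, -j, drop = FALSE]
  }
  if (any(diff(height) < -1e-9)) {
    stop("internal error: UPGMA merge heights decreased", call. = FALSE)
  }
  out <- structure(list(merge = merge, height = height,
                        order = hclust_order(merge, n),
                        labels = labels, method = "upgma",
                        call = match.call(),
                        dist.method = "euclidean"),
                   class = c("upgma", "hclust"))
  out
}

# leaf ordering by left-to-right traversal of the merge tree
hclust_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1)
}

#' Mean silhouette width of a partition
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean within-cluster
#' distance and `b` the mean distance to the nearest other cluster; members of
#' singleton clusters score 0 by convention.
#'
#' @param D Symmetric distance matrix (or `dist`).
#' @param labels Cluster labels (>= 2 distinct, all clusters nonempty).
#' @return Mean silhouette width over all items.
#' @export
silhouette_width <- function(D, labels) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  labels <- as.integer(as.factor(labels))
  n <- nrow(D)
  stopifnot(length(labels) == n)
  k <- max(labels)
  if (k < 2) stop("silhouette needs at least two clusters", call. = FALSE)
  s <- numeric(n)
  sizes <- tabulate(labels, k)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] == 1) { s[i] <- 0; next }
    a <- sum(D[i, labels == ci]) / (sizes[ci] - 1)
    b <- min(vapply(setdiff(seq_len(k), ci), function(cj)
      mean(D[i, labels == cj]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Harmonize zones across plots
#'
#' Pools the per-plot zone median tables, clusters the rows by UPGMA on
#' (unscaled) Euclidean distances, cuts the tree at every `k` in `k_range`,
#' and keeps the cut with the highest mean silhouette width. Final clusters
#' are relabelled 1..k by ascending median N concentration (the median over
#' member zones' medians).
#'
#' @param tables Named list of per-plot median tables; each a data.frame with
#'   columns `zone`, `median_n_conc`, `median_d15N`, `median_d13C` (the
#'   `$table` of [zone_summaries()] works directly). Names are plot ids.
#' @param k_range Candidate final cluster counts (default `2:(n - 1)`).
#' @return An object of class `harmonization`: list with `k`, `mapping`
#'   (data.frame: plot, zone, label `plot.zone` with Roman zone numerals,
#'   final cluster), `silhouette` (named by k), `tree` (the [upgma()] result),
#'   `medians` (the pooled table).
#' @export
harmonize <- function(tables, k_range = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables))) names(tables) <- as.character(seq_along(tables))
  pooled <- do.call(rbind, lapply(names(tables), function(pid) {
    t <- as.data.frame(tables[[pid]])
    data.frame(plot = pid, zone = t$zone,
               label = paste0(pid, ".", as.character(utils::as.roman(t$zone))),
               median_n_conc = t$median_n_conc,
               median_d15N = t$median_d15N,
               median_d13C = t$median_d13C,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(pooled)
  if (n < 3) stop("harmonization needs at least three zones in total", call. = FALSE)
  if (anyDuplicated(pooled$label)) stop("duplicate plot.zone labels", call. = FALSE)
  if (is.null(k_range)) k_range <- 2:(n - 1)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop("k_range must lie within 2..(n - 1)", call. = FALSE)
  }
  M <- as.matrix(pooled[, c("median_n_conc", "median_d15N", "median_d13C")])
  rownames(M) <- pooled$label
  D <- as.matrix(stats::dist(M))
  tree <- upgma(D, labels = pooled$label)
  sil <- vapply(k_range, function(k)
    silhouette_width(D, stats::cutree(tree, k = k)), numeric(1))
  names(sil) <- k_range
  k_best <- k_range[which.max(sil)]
  cl <- stats::cutree(tree, k = k_best)
  med_n <- tapply(pooled$median_n_conc, cl, stats::median)
  ord <- order(med_n)
  remap <- match(seq_along(ord), ord)
  final <- remap[cl]
  pooled$final_cluster <- final
  structure(list(k = k_best, mapping = pooled, silhouette = sil,
                 tree = tree, medians = M),
            class = "harmonization")
}

#' @export
print.harmonization <- function(x, ...) {
  cat(sprintf("<harmonization> %d zones -> %d final clusters (mean silhouette %.3f)\n",
              nrow(x$mapping), x$k, max(x$silhouette)))
  print(x$mapping[, c("label", "final_cluster")])
  invisible(x)
}

#' Export a UPGMA tree as Newick
#'
#' Branch lengths are merge-height differences (an ultrametric tree).
#'
#' @param tree A [upgma()] result (any `hclust` works).
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Relabel per-plot zone rasters with final harmonized clusters
#'
#' @param zonemap A [cluster_plot()] result for one plot.
#' @param harmonization A [harmonize()] result.
#' @param plot_id The plot's id, as named in [harmonize()]'s `tables`.
#' @return Integer [raster_layer()] of final cluster ids (0 = excluded).
#' @export
harmonized_raster <- function(zonemap, harmonization, plot_id) {
  map <- harmonization$mapping
  rows <- map[map$plot == plot_id, ]
  if (!nrow(rows)) stop("plot '", plot_id, "' not present in harmonization", call. = FALSE)
  lut <- stats::setNames(rows$final_cluster, rows$zone)
  v <- raster_values(zonemap$labels)
  out <- ifelse(v == 0, 0, lut[as.character(v)])
  raster_layer(zonemap$labels$grid, as.numeric(out), units = "final cluster")
}
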