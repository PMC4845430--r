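## Hierarchical complete-link clustering of countries by gene profiles,
## fuzzy c-means over genes with the four partition-validity indices
## (PC, CE, PI, XBI), a 2-D PCA projection for plotting, and the
## itemset / fuzzy-area cross-match.

#' Cosine distance matrix between rows
#'
#' `1 - cos(angle)` between row vectors; all-zero rows are at distance 1
#' from everything (and 0 from another all-zero row by convention 1 - 0).
#'
#' @param m Numeric matrix with row labels.
#' @return A symmetric matrix of distances in `[0, 2]`.
#' @export
cosine_distance <- function(m) {
  m <- as.matrix(m)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1 # leaves the zero vector with cosine 0 to everything
  mm <- m / nrm
  d <- 1 - tcrossprod(mm)
  d[d < 0] <- 0 # numerical guard
  diag(d) <- 0
  d
}

as_distance_matrix <- function(profiles, metric) {
  if (is.function(metric)) {
    n <- nrow(profiles)
    d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        d[i, j] <- metric(profiles[i, ], profiles[j, ])
      }
    }
    if (any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0)) {
      stop("metric must be symmetric with zero self-distance", call. = FALSE)
    }
    d
  } else if (identical(metric, "cosine")) {
    cosine_distance(profiles)
  } else if (identical(metric, "euclidean")) {
    as.matrix(stats::dist(profiles))
  } else {
    stop("unknown metric: ", metric, call. = FALSE)
  }
}

#' Agglomerative complete-link clustering
#'
#' Merges, at each step, the pair of clusters with the smallest maximum
#' pairwise distance between their members. Ties are broken by the
#' lexicographically smallest pair of cluster signatures (the sorted row
#' labels of the members), so the dendrogram is deterministic.
#'
#' @param profiles Numeric matrix: rows are entities (e.g. countries),
#'   columns features (e.g. per-gene abstract counts). Needs >= 2 rows
#'   with unique labels.
#' @param metric `"cosine"` (default: row magnitudes, i.e. publication
#'   volume, would otherwise dominate), `"euclidean"`, or a symmetric
#'   two-argument distance function.
#' @return Object of class `gene_dendrogram`: `merges` (data frame
#'   `a`, `b`, `height`, `new_id`; negative ids are leaves as in
#'   [stats::hclust()]), `labels`, and `heights`. Coerce with
#'   `as.hclust()` for plotting.
#' @export
hierarchical_complete <- function(profiles, metric = "cosine") {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2L) stop("need at least 2 rows to cluster", call. = FALSE)
  labels <- rownames(profiles) %||% as.character(seq_len(n))
  if (anyDuplicated(labels)) stop("row labels must be unique", call. = FALSE)
  d <- as_distance_matrix(profiles, metric)
  ## active clusters: id (hclust convention), members (row indices),
  ## signature (sorted labels) for the deterministic tie-break
  clusters <- lapply(seq_len(n), function(i) {
    list(id = -i, members = i, sig = labels[i])
  })
  merges <- data.frame(
    a = integer(n - 1), b = integer(n - 1),
    height = numeric(n - 1), new_id = integer(n - 1)
  )
  link <- function(ci, cj) max(d[ci$members, cj$members])
  for (step in seq_len(n - 1L)) {
    best <- NULL
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- link(clusters[[i]], clusters[[j]])
        pair_sig <- paste(sort(c(clusters[[i]]$sig, clusters[[j]]$sig)),
          collapse = "\r"
        )
        if (h < best_h - 1e-12 ||
          (abs(h - best_h) <= 1e-12 && (is.null(best) || pair_sig < best$sig))) {
          best <- list(i = i, j = j, sig = pair_sig)
          best_h <- h
        }
      }
    }
    ci <- clusters[[best$i]]
    cj <- clusters[[best$j]]
    ids <- sort(c(ci$id, cj$id)) # hclust prints smaller id first
    merges$a[step] <- ids[1]
    merges$b[step] <- ids[2]
    merges$height[step] <- best_h
    merges$new_id[step] <- step
    merged <- list(
      id = step,
      members = c(ci$members, cj$members),
      sig = paste(sort(c(ci$sig, cj$sig)), collapse = "\r")
    )
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  structure(
    list(merges = merges, labels = labels, heights = merges$height),
    class = "gene_dendrogram"
  )
}

#' @export
print.gene_dendrogram <- function(x, ...) {
  cat(sprintf(
    "<gene_dendrogram> %d leaves, merge heights %.4g .. %.4g\n",
    length(x$labels), min(x$heights), max(x$heights)
  ))
  invisible(x)
}

#' @export
as.hclust.gene_dendrogram <- function(x, ...) {
  n <- length(x$labels)
  merge <- as.matrix(x$merges[, c("a", "b")])
  dimnames(merge) <- NULL
  ## leaf order by left-to-right traversal of the final merge
  traverse <- function(id) {
    if (id < 0) return(-id)
    c(traverse(merge[id, 1]), traverse(merge[id, 2]))
  }
  structure(
    list(
      merge = merge,
      height = x$merges$height,
      order = traverse(n - 1L),
      labels = x$labels,
      method = "complete",
      call = match.call(),
      dist.method = "custom"
    ),
    class = "hclust"
  )
}

#' Write a dendrogram as Newick text
#'
#' @param x A [hierarchical_complete()] result.
#' @param path Output path.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "gene_dendrogram"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the ape package is required for Newick export", call. = FALSE)
  }
  ape::write.tree(ape::as.phylo(stats::as.hclust(x)), file = path)
  invisible(path)
}

## squared Euclidean distances between rows of x and rows of v
sq_dists <- function(x, v) {
  outer(rowSums(x^2), rep(1, nrow(v))) +
    outer(rep(1, nrow(x)), rowSums(v^2)) - 2 * tcrossprod(x, v)
}

fcm_memberships <- function(d2, m) {
  n <- nrow(d2)
  c_ <- ncol(d2)
  u <- matrix(0, n, c_)
  zero <- d2 < 1e-12
  for (k in seq_len(n)) {
    if (any(zero[k, ])) {
      ## limit convention: a point on a center belongs wholly to it
      u[k, zero[k, ]] <- 1 / sum(zero[k, ])
    } else {
      r <- d2[k, ]^(-1 / (m - 1))
      u[k, ] <- r / sum(r)
    }
  }
  u
}

#' Fuzzy c-means clustering
#'
#' Alternating optimization of the fuzzy objective
#' `J = sum_i sum_k u_ik^m ||x_k - v_i||^2`:
#' memberships `u_ik = 1 / sum_j (||x_k - v_i|| / ||x_k - v_j||)^(2/(m-1))`
#' and centers `v_i = sum_k u_ik^m x_k / sum_k u_ik^m`, iterated until the
#' maximum center shift drops below `tol` or `max_iter` is reached.
#' Initialization samples `c` distinct data points as centers under the
#' given seed, so a run is fully reproducible.
#'
#' @param data Numeric matrix, rows are the points to cluster.
#' @param c Number of clusters, `2 <= c <= nrow(data)`.
#' @param m Fuzzifier, `> 1` (default 2).
#' @param tol Convergence tolerance on the center shift.
#' @param max_iter Iteration cap.
#' @param seed Integer RNG seed for the initial centers.
#' @return Object of class `fcm_fit`: `centers` (`c x d`), `membership`
#'   (`n x c`, rows sum to 1), `m`, `objective` (final `J`),
#'   `objective_trace` (per iteration), `iterations`, `converged`.
#' @export
fcm <- function(data, c, m = 2, tol = 1e-5, max_iter = 300L, seed = 1L) {
  x <- as.matrix(data)
  n <- nrow(x)
  stopifnot(c >= 2, c <= n, m > 1, tol > 0, max_iter >= 1)
  v <- x[with_seed(seed, sample.int(n, c)), , drop = FALSE]
  trace <- numeric()
  converged <- FALSE
  iter <- 0L
  u <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- pmax(sq_dists(x, v), 0)
    u <- fcm_memberships(d2, m)
    um <- u^m
    v_new <- (t(um) %*% x) / colSums(um)
    trace[iter] <- sum(um * pmax(sq_dists(x, v_new), 0))
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  u <- fcm_memberships(pmax(sq_dists(x, v), 0), m)
  structure(
    list(
      centers = v,
      membership = u,
      m = m,
      objective = trace[length(trace)],
      objective_trace = trace,
      iterations = iter,
      converged = converged,
      data_rows = rownames(x) %||% as.character(seq_len(n))
    ),
    class = "fcm_fit"
  )
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf(
    "<fcm_fit> c = %d clusters, m = %g, J = %.6g (%d iterations%s)\n",
    nrow(x$centers), x$m, x$objective, x$iterations,
    if (x$converged) ", converged" else ", not converged"
  ))
  invisible(x)
}

#' Fuzzy partition validity indices
#'
#' For each fitted partition: the partition coefficient
#' `PC = (1/n) sum u_ik^2` (1 for a hard partition, `1/c` for a uniform
#' one), classification entropy `CE = -(1/n) sum u_ik log u_ik` (0 hard,
#' `log c` uniform), the partition index
#' `PI = sum_i [sum_k u_ik^m d2(x_k, v_i)] / [n_i sum_j d2(v_j, v_i)]`
#' with fuzzy cardinality `n_i = sum_k u_ik`, and the Xie-Beni index
#' `XBI = sum_ik u_ik^m d2(x_k, v_i) / (n min_{i != j} d2(v_i, v_j))`.
#' Duplicate centers make XBI undefined; it is reported as `NA`.
#'
#' @param data The matrix the fits were computed on.
#' @param fits List of [fcm()] results over candidate cluster counts.
#' @return Data frame `c`, `PC`, `CE`, `PI`, `XBI`, one row per fit.
#' @export
validity_indices <- function(data, fits) {
  x <- as.matrix(data)
  if (inherits(fits, "fcm_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    u <- f$membership
    n <- nrow(u)
    c_ <- ncol(u)
    d2 <- pmax(sq_dists(x, f$centers), 0)
    pc <- sum(u^2) / n
    ul <- u * log(u)
    ul[u == 0] <- 0
    ce <- -sum(ul) / n
    vd2 <- pmax(sq_dists(f$centers, f$centers), 0)
    pi_terms <- vapply(seq_len(c_), function(i) {
      sum(u[, i]^f$m * d2[, i]) / (sum(u[, i]) * sum(vd2[, i]))
    }, numeric(1))
    sep <- vd2[upper.tri(vd2)]
    min_sep <- if (length(sep)) min(sep) else NA_real_
    xbi <- if (!is.na(min_sep) && min_sep > 1e-12) {
      sum(u^f$m * d2) / (n * min_sep)
    } else {
      NA_real_
    }
    data.frame(c = c_, PC = pc, CE = ce, PI = sum(pi_terms), XBI = xbi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Project rows onto the top two principal axes
#'
#' Column-centered PCA, visualization only (clustering itself runs in the
#' full feature space). The sign of each axis is fixed so that its
#' largest-magnitude loading is positive. Rank-deficient data leaves the
#' second coordinate at zero with a warning.
#'
#' @param data Numeric matrix, >= 2 rows and >= 2 columns.
#' @return `n x 2` matrix of coordinates (`PC1`, `PC2`).
#' @export
pca_2d <- function(data) {
  x <- as.matrix(data)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 2L)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$rotation))
  scores <- matrix(0, nrow(x), 2L, dimnames = list(rownames(x), c("PC1", "PC2")))
  for (i in seq_len(k)) {
    rot <- p$rotation[, i]
    s <- sign(rot[which.max(abs(rot))])
    if (s == 0) s <- 1
    scores[, i] <- p$x[, i] * s
  }
  if (k < 2L || p$sdev[2] < 1e-10) {
    scores[, 2] <- 0
    warning("data are (numerically) rank 1; second axis set to zero")
  }
  scores
}

#' Entities in the fuzzy area of a partition
#'
#' The entities whose largest membership falls below `tau`: the ones no
#' cluster can claim outright.
#'
#' @param fit An [fcm()] result (or a bare membership matrix with row
#'   names).
#' @param tau Threshold on the maximum membership (default 0.6).
#' @return Character vector of entity labels.
#' @export
fuzzy_area_genes <- function(fit, tau = 0.6) {
  u <- if (inherits(fit, "fcm_fit")) fit$membership else as.matrix(fit)
  labs <- if (inherits(fit, "fcm_fit")) {
    fit$data_rows
  } else {
    rownames(u) %||% as.character(seq_len(nrow(u)))
  }
  labs[apply(u, 1, max) < tau]
}

#' Cross-match mined itemsets with the fuzzy area
#'
#' For each itemset, the fraction of its member genes that lie in the
#' fuzzy area. Genes absent from the clustered universe are excluded from
#' the fraction and reported in `n_unknown`.
#'
#' @param itemsets A `mined_itemsets` frame (see [mine_frequent()]).
#' @param fuzzy_area Character vector from [fuzzy_area_genes()].
#' @param universe Character vector of all clustered genes; defaults to
#'   treating every itemset gene as known.
#' @return The itemset frame with `fuzzy_fraction` and `n_unknown` added.
#' @export
crossmatch_itemsets <- function(itemsets, fuzzy_area, universe = NULL) {
  sets <- strsplit(itemsets$items, ",", fixed = TRUE)
  res <- vapply(sets, function(s) {
    known <- if (is.null(universe)) s else intersect(s, universe)
    frac <- if (length(known)) mean(known %in% fuzzy_area) else NA_real_
    c(frac, length(s) - length(known))
  }, numeric(2))
  itemsets$fuzzy_fraction <- res[1, ]
  itemsets$n_unknown <- as.integer(res[2, ])
  itemsets
}

#' Gene-by-feature matrices for clustering
#'
#' Transposes the country x gene count matrix into gene rows over country
#' features, or builds gene rows over year features, matching the feature
#' spaces used for the fuzzy clustering of genes.
#'
#' @param x An annotated, geo-resolved [corpus()].
#' @return Numeric matrix, genes x features.
#' @export
gene_feature_matrix <- function(x) {
  cc <- gene_country_counts(x)
  keep <- rownames(cc$counts) != UNRESOLVED_ROW
  t(cc$counts[keep, , drop = FALSE])
}

#' @rdname gene_feature_matrix
#' @export
gene_year_matrix <- function(x) {
  stopifnot(inherits(x, "lit_corpus"))
  recs <- Filter(function(r) !is.na(r$year) && length(r$genes %||% character()), x$records)
  genes <- sort(unique(unlist(lapply(recs, `[[`, "genes"))))
  years <- sort(unique(vapply(recs, `[[`, integer(1), "year")))
  m <- matrix(0L, length(genes), length(years),
    dimnames = list(genes, as.character(years))
  )
  for (r in recs) {
    m[r$genes, as.character(r$year)] <- m[r$genes, as.character(r$year)] + 1L
  }
  m
}
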