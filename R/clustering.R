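#' TF-IDF vectorisation of a relation dictionary
#'
#' Each disease's value phrases form one document. By default every whole
#' value phrase is one term (values are curated phrases); `term_unit =
#' "word"` splits phrases into word tokens instead. Term frequency is the
#' raw count, idf is smoothed (`ln((1+N)/(1+df)) + 1`), and the vectors are
#' L2-normalised, so a term shared by every disease (e.g. a generic
#' "treatment") carries the minimum weight in the corpus.
#'
#' @param dict A `relation_dictionary` with at least two diseases.
#' @param term_unit `"phrase"` (default) or `"word"`.
#' @return A numeric matrix, one row per disease (rownames), one column per
#'   term (colnames), with attribute `idf`.
#' @export
vectorize <- function(dict, term_unit = c("phrase", "word")) {
  term_unit <- match.arg(term_unit)
  if (length(dict$entries) < 2)
    stop("need at least two diseases to vectorize")
  docs <- lapply(dict$entries, function(values) {
    if (term_unit == "phrase") values
    else unlist(strsplit(values, "[[:space:]]+"))
  })
  terms <- sort(unique(unlist(docs, use.names = FALSE)))
  N <- length(docs)
  tf <- matrix(0, N, length(terms),
               dimnames = list(names(docs), terms))
  for (i in seq_len(N)) {
    tab <- table(docs[[i]])
    tf[i, names(tab)] <- as.numeric(tab)
  }
  df <- colSums(tf > 0)
  idf <- log((1 + N) / (1 + df)) + 1
  w <- sweep(tf, 2, idf, `*`)
  nrm <- sqrt(rowSums(w^2))
  nrm[nrm == 0] <- 1
  w <- w / nrm
  attr(w, "idf") <- idf
  w
}

#' PCA reduction of document vectors
#'
#' Mean-centred principal component analysis. By default the smallest
#' number of components explaining at least `variance_target` of the
#' variance is kept, capped at `min(50, n - 1)`.
#'
#' @param X Numeric matrix (rows = documents).
#' @param n_components Fixed component count (overrides `variance_target`).
#' @param variance_target Fraction of variance to retain (default 0.95).
#' @return The reduced matrix (rownames preserved) with attributes
#'   `explained_variance` (per kept component) and `rotation`.
#' @export
reduce_dim <- function(X, n_components = NULL, variance_target = 0.95) {
  stopifnot(nrow(X) >= 2)
  vars <- apply(X, 2, stats::var)
  if (all(vars < 1e-12)) {
    warning("zero-variance input; returning the data unchanged")
    return(X)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  prop <- ev / sum(ev)
  cap <- min(50L, nrow(X) - 1L, length(ev))
  if (is.null(n_components)) {
    n_components <- which(cumsum(prop) >= variance_target)[1]
    if (is.na(n_components)) n_components <- cap
    n_components <- min(n_components, cap)
  } else {
    n_components <- min(n_components, length(ev))
  }
  out <- pc$x[, seq_len(n_components), drop = FALSE]
  attr(out, "explained_variance") <- ev[seq_len(n_components)]
  attr(out, "rotation") <- pc$rotation[, seq_len(n_components),
                                       drop = FALSE]
  out
}

sq_dist_to <- function(X, center) {
  rowSums(sweep(X, 2, center)^2)
}

# D^2 sampling: successive centers drawn with probability proportional to
# the squared distance from the nearest already-chosen center.
kmeanspp_seed <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  d2 <- sq_dist_to(X, centers[1, ])
  if (k > 1) for (j in 2:k) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, sq_dist_to(X, centers[j, ]))
  }
  centers
}

# Lloyd iterations; inertia is non-increasing by construction and asserted.
# An emptied cluster is re-seeded at the point farthest from its center.
lloyd <- function(X, centers, max_iter = 300, tol = 1e-6) {
  k <- nrow(centers); n <- nrow(X)
  assign_pts <- function(centers) {
    d <- vapply(seq_len(k), function(j) sq_dist_to(X, centers[j, ]),
                numeric(n))
    d <- matrix(d, n, k)
    list(cl = max.col(-d, ties.method = "first"),
         d2 = d[cbind(seq_len(n), max.col(-d, ties.method = "first"))])
  }
  prev_inertia <- Inf
  for (it in seq_len(max_iter)) {
    a <- assign_pts(centers)
    inertia <- sum(a$d2)
    if (inertia > prev_inertia + 1e-9)
      stop("internal error: inertia increased during Lloyd iteration")
    for (j in seq_len(k)) {
      members <- a$cl == j
      if (!any(members)) {
        centers[j, ] <- X[which.max(a$d2), ]
      } else {
        centers[j, ] <- colMeans(X[members, , drop = FALSE])
      }
    }
    if (prev_inertia - inertia < tol) {
      prev_inertia <- inertia
      break
    }
    prev_inertia <- inertia
  }
  a <- assign_pts(centers)
  list(cluster = a$cl, centers = centers, inertia = sum(a$d2),
       iterations = it)
}

#' kmeans++ clustering with repeated restarts
#'
#' kmeans++ seeding (D-squared probability sampling) followed by Lloyd
#' iterations (tolerance 1e-6, at most 300 iterations), repeated
#' `n_repeats` times; the lowest-inertia run is kept and the silhouette
#' coefficients of all runs are averaged.
#'
#' @param X Numeric matrix of (reduced) document vectors.
#' @param k Number of clusters, `2 <= k <= nrow(X)`.
#' @param n_repeats Independent seeded runs (default 5).
#' @param seed Integer seed.
#' @param max_iter,tol Lloyd stopping rule.
#' @return List with `cluster` (named by rownames of `X`), `centers`,
#'   `inertia`, `silhouette_mean` (mean over repeats), `silhouette_best`
#'   (of the kept run), `k`.
#' @export
kmeanspp_cluster <- function(X, k, n_repeats = 5, seed = 1L,
                             max_iter = 300, tol = 1e-6) {
  n <- nrow(X)
  if (k > n) stop("k (", k, ") exceeds the number of points (", n, ")")
  if (k < 1) stop("k must be at least 1")
  runs <- lapply(seq_len(n_repeats), function(r) {
    with_seed(derive_seed(seed, r), {
      centers <- kmeanspp_seed(X, k)
      lloyd(X, centers, max_iter, tol)
    })
  })
  sils <- vapply(runs, function(r) {
    if (k < 2 || k >= n + 1) return(NA_real_)
    if (length(unique(r$cluster)) < 2) return(NA_real_)
    mean(silhouette_score(X, r$cluster)$s)
  }, numeric(1))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "inertia"))]]
  cl <- best$cluster
  names(cl) <- rownames(X)
  list(cluster = cl, centers = best$centers, inertia = best$inertia,
       silhouette_mean = mean(sils, na.rm = TRUE),
       silhouette_best = sils[[which.min(
         vapply(runs, `[[`, numeric(1), "inertia"))]],
       k = k)
}

#' Silhouette coefficients of a partition
#'
#' For each point, `a` is the mean distance to the other members of its own
#' cluster and `b` the mean distance to the points of the nearest other
#' cluster; `s = (b - a) / max(a, b)`. Points in singleton clusters score 0.
#'
#' @param X Numeric matrix of points.
#' @param cluster Integer vector of cluster assignments.
#' @return List with `s` (per-point values in [-1, 1]) and `mean`.
#' @export
silhouette_score <- function(X, cluster) {
  n <- nrow(X)
  ids <- unique(cluster)
  if (length(ids) < 2) stop("silhouette needs at least 2 clusters")
  D <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(ids, cluster[i]), function(j)
      mean(D[i, cluster == j]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(s = s, mean = mean(s))
}

default_k_for_kind <- function(kind) {
  switch(kind, DS = 15L, SFD = 20L, NSFD = 6L,
         stop("unknown dictionary kind ", dQuote(kind)))
}

#' Cluster a relation dictionary and report
#'
#' Runs TF-IDF vectorisation, PCA reduction and kmeans++ on the entries of
#' one dictionary. Either a fixed `k` is used (defaults per dictionary
#' kind: DS 15, SFD 20, NSFD 6) or a grid of k values is scanned and the
#' mean-silhouette maximiser chosen. Since the silhouette tends to keep
#' growing with k on sparse phrase vectors, grid scans should be capped.
#'
#' @param dict A `relation_dictionary`.
#' @param k Fixed cluster count; `NULL` uses the kind default unless
#'   `k_grid` is given.
#' @param k_grid Integer vector of candidate k values to scan.
#' @param n_repeats Seeded restarts per k (default 5).
#' @param seed Integer seed.
#' @param term_unit,n_components,variance_target Passed to [vectorize()]
#'   and [reduce_dim()].
#' @return An object of class `cluster_report`: `k`, `assignments` (named),
#'   `centers`, `silhouette_mean`, `per_k_trace` (data.frame k, mean
#'   silhouette), `summary` (data.frame category, n_diseases, diseases,
#'   shared_terms), `residual_category` (largest cluster if its mean
#'   silhouette is negative, else `NA`).
#' @export
select_k_and_report <- function(dict, k = NULL, k_grid = NULL,
                                n_repeats = 5, seed = 1L,
                                term_unit = "phrase",
                                n_components = NULL,
                                variance_target = 0.95) {
  if (length(dict$entries) == 0) stop("empty dictionary")
  V <- vectorize(dict, term_unit)
  R <- reduce_dim(V, n_components, variance_target)
  n <- nrow(R)
  per_k <- NULL
  if (!is.null(k_grid)) {
    k_grid <- k_grid[k_grid >= 2 & k_grid <= n - 1]
    if (length(k_grid) == 0) stop("no admissible k in grid for n = ", n)
    sil <- vapply(k_grid, function(kk)
      kmeanspp_cluster(R, kk, n_repeats, derive_seed(seed, kk))$silhouette_mean,
      numeric(1))
    per_k <- data.frame(k = k_grid, silhouette = sil)
    k <- k_grid[which.max(sil)]
  } else if (is.null(k)) {
    k <- default_k_for_kind(dict$kind)
  }
  if (k > n) stop("k (", k, ") exceeds the number of diseases (", n, ")")
  fit <- kmeanspp_cluster(R, k, n_repeats, seed)
  sil_pts <- if (k >= 2 && length(unique(fit$cluster)) >= 2)
    silhouette_score(R, fit$cluster)$s else rep(NA_real_, n)
  summary <- do.call(rbind, lapply(sort(unique(fit$cluster)), function(j) {
    members <- names(fit$cluster)[fit$cluster == j]
    sub <- V[members, , drop = FALSE]
    shared <- colnames(sub)[order(colSums(sub > 0), decreasing = TRUE)]
    shared <- shared[colSums(sub[, shared, drop = FALSE] > 0) > 0]
    data.frame(category = j, n_diseases = length(members),
               diseases = paste(members, collapse = "; "),
               shared_terms = paste(utils::head(shared, 5),
                                    collapse = "; "),
               mean_silhouette = mean(sil_pts[fit$cluster == j]),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  largest <- summary$category[which.max(summary$n_diseases)]
  residual <- if (!is.na(summary$mean_silhouette[
    summary$category == largest]) &&
    summary$mean_silhouette[summary$category == largest] < 0)
    largest else NA_integer_
  structure(list(k = k, assignments = fit$cluster, centers = fit$centers,
                 inertia = fit$inertia,
                 silhouette_mean = fit$silhouette_mean,
                 per_k_trace = per_k, summary = summary,
                 residual_category = residual,
                 kind = dict$kind),
            class = "cluster_report")
}
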