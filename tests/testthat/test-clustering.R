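test_that("TF-IDF weights match a hand computation", {
  dict <- structure(list(kind = "DS", entries = list(
    d1 = c("pain", "swelling", "pain"),
    d2 = c("pain", "stiffness"),
    d3 = c("numbness"))), class = "relation_dictionary")
  V <- vectorize(dict)
  # independent spreadsheet-style computation: tf raw counts,
  # idf = ln((1+N)/(1+df)) + 1, then L2 row normalisation
  N <- 3
  idf <- c(numbness = log(4 / 2) + 1, pain = log(4 / 3) + 1,
           stiffness = log(4 / 2) + 1, swelling = log(4 / 2) + 1)
  raw1 <- c(numbness = 0, pain = 2, stiffness = 0, swelling = 1) * idf
  expect_equal(V["d1", ], raw1 / sqrt(sum(raw1^2)), tolerance = 1e-12)
  raw3 <- c(numbness = 1, pain = 0, stiffness = 0, swelling = 0) * idf
  expect_equal(V["d3", ], raw3 / sqrt(sum(raw3^2)), tolerance = 1e-12)
  # a term in every document carries the minimum idf
  dict2 <- structure(list(kind = "DS", entries = list(
    a = c("treatment", "x"), b = c("treatment", "y"),
    c = c("treatment", "z"))), class = "relation_dictionary")
  idf2 <- attr(vectorize(dict2), "idf")
  expect_identical(names(which.min(idf2)), "treatment")
  # identical value lists give identical vectors
  dict3 <- structure(list(kind = "DS", entries = list(
    a = c("p", "q"), b = c("p", "q"), c = "r")),
    class = "relation_dictionary")
  V3 <- vectorize(dict3)
  expect_equal(V3["a", ], V3["b", ], tolerance = 1e-15)
  expect_error(vectorize(structure(list(kind = "DS",
                                        entries = list(a = "x")),
                                   class = "relation_dictionary")),
               "at least two")
})

test_that("word-level term units split phrases", {
  dict <- structure(list(kind = "SFD", entries = list(
    a = "hot compress", b = "cold compress")),
    class = "relation_dictionary")
  expect_identical(colnames(vectorize(dict, term_unit = "word")),
                   c("cold", "compress", "hot"))
  expect_identical(colnames(vectorize(dict)),
                   c("cold compress", "hot compress"))
})

test_that("PCA reduction matches the eigendecomposition of the covariance", {
  withr::with_seed(20, {
    X <- matrix(rnorm(60), 10, 6)
    R <- reduce_dim(X, n_components = 6)
    ev <- attr(R, "explained_variance")
    eig <- sort(eigen(stats::cov(X), symmetric = TRUE)$values,
                decreasing = TRUE)
    expect_equal(ev, eig, tolerance = 1e-8)
    expect_true(all(diff(ev) <= 1e-12))  # non-increasing variances
    # full-rank reconstruction is exact
    Xc <- scale(X, center = TRUE, scale = FALSE)
    expect_equal(unname(R %*% t(attr(R, "rotation"))), unname(Xc),
                 tolerance = 1e-8, ignore_attr = TRUE)
  })
  # points on a line need exactly one component
  t <- seq(0, 1, length.out = 8)
  line <- cbind(1 + 2 * t, -t, 3 * t)
  Rl <- reduce_dim(line, variance_target = 0.95)
  expect_identical(ncol(Rl), 1L)
  ev <- attr(Rl, "explained_variance")
  expect_equal(ev[1] / sum(ev), 1, tolerance = 1e-12)
  # zero variance falls back to the identity with a warning
  expect_warning(Z <- reduce_dim(matrix(1, 4, 3)), "zero-variance")
  expect_identical(dim(Z), c(4L, 3L))
})

test_that("kmeans++ recovers well-separated blobs", {
  withr::with_seed(21, {
    centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
    X <- do.call(rbind, lapply(1:4, function(j)
      sweep(matrix(rnorm(16, sd = 0.3), 8, 2), 2, centers[j, ], `+`)))
    truth <- rep(1:4, each = 8)
    fit <- kmeanspp_cluster(X, 4, n_repeats = 5, seed = 2)
    expect_equal(adjusted_rand_index(fit$cluster, truth), 1)
    expect_gt(mean(silhouette_score(X, fit$cluster)$s), 0.8)
    # k = n gives zero inertia, every point its own cluster
    small <- X[1:5, ]
    fit_n <- kmeanspp_cluster(small, 5, n_repeats = 3, seed = 2)
    expect_equal(fit_n$inertia, 0, tolerance = 1e-12)
    expect_identical(length(unique(fit_n$cluster)), 5L)
    # determinism and bounds
    expect_identical(kmeanspp_cluster(X, 4, seed = 7)$cluster,
                     kmeanspp_cluster(X, 4, seed = 7)$cluster)
    expect_error(kmeanspp_cluster(small, 6, seed = 1), "exceeds")
  })
})

test_that("kmeans++ matches exhaustive-search partitioning at small n", {
  withr::with_seed(22, {
    for (rep in 1:3) {
      X <- matrix(rnorm(16), 8, 2)
      best <- Inf; best_assign <- NULL
      for (code in seq_len(2^7 - 1)) {
        assign <- c(1L, as.integer(intToBits(code))[1:7] + 1L)
        if (length(unique(assign)) < 2) next
        inertia <- sum(vapply(1:2, function(j) {
          m <- X[assign == j, , drop = FALSE]
          sum(sweep(m, 2, colMeans(m))^2)
        }, numeric(1)))
        if (inertia < best) { best <- inertia; best_assign <- assign }
      }
      fit <- kmeanspp_cluster(X, 2, n_repeats = 10, seed = rep)
      expect_equal(fit$inertia, best, tolerance = 1e-8)
      expect_equal(adjusted_rand_index(fit$cluster, best_assign), 1)
    }
  })
})

test_that("silhouette values match a brute-force pairwise computation", {
  X <- rbind(c(0, 0), c(0, 1), c(0.5, 0.5), c(10, 10), c(10, 11),
             c(10.5, 10.5))
  cl <- c(1, 1, 1, 2, 2, 2)
  got <- silhouette_score(X, cl)
  D <- as.matrix(dist(X))
  want <- vapply(1:6, function(i) {
    a <- mean(D[i, cl == cl[i] & seq_len(6) != i])
    b <- mean(D[i, cl != cl[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(got$s, want, tolerance = 1e-8)
  expect_gt(got$mean, 0.9)  # tight, far-apart clusters
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(cl, dist(X))
  expect_equal(got$s, unname(ref[, "sil_width"]), tolerance = 1e-10)
})

test_that("silhouette handles boundary cases by convention", {
  # a point with equal mean distance to its own and the nearest other
  # cluster (a = b = 1) scores exactly 0
  X <- rbind(c(0, 0), c(2, 0), c(1, 0), c(1, 1))
  cl <- c(1, 1, 1, 2)
  s <- silhouette_score(X, cl)$s
  expect_equal(s[3], 0, tolerance = 1e-12)
  # singleton clusters score 0
  expect_equal(s[4], 0)
  expect_error(silhouette_score(X, rep(1, 4)), "at least 2")
  expect_true(all(s >= -1 & s <= 1))
})

test_that("planted partitions score above random shuffles", {
  withr::with_seed(23, {
    X <- rbind(matrix(rnorm(20, 0, 0.5), 10, 2),
               matrix(rnorm(20, 6, 0.5), 10, 2))
    cl <- rep(1:2, each = 10)
    planted <- mean(silhouette_score(X, cl)$s)
    shuffled <- mean(vapply(1:10, function(i)
      mean(silhouette_score(X, sample(cl))$s), numeric(1)))
    expect_gt(planted, shuffled)
  })
})

test_that("grid scans pick k = 2 for two blobs", {
  # two tight motifs: a shared three-term core plus one unique term each
  entries <- c(
    lapply(1:6, function(i) c("hot1", "hot2", "hot3", paste0("u", i))),
    lapply(1:6, function(i) c("ice1", "ice2", "ice3", paste0("v", i))))
  names(entries) <- paste0("d", 1:12)
  dict <- structure(list(kind = "DS", entries = entries),
                    class = "relation_dictionary")
  rep_ <- select_k_and_report(dict, k_grid = 2:5, seed = 3)
  expect_identical(rep_$k, 2L)
  expect_identical(nrow(rep_$per_k_trace), 4L)
  expect_true(which.max(rep_$per_k_trace$silhouette) == 1L)
})

test_that("fixed-k defaults follow the dictionary kind (15/20/6)", {
  big <- function(kind) {
    entries <- lapply(1:25, function(i)
      paste0("v", ((i * 7 + seq_len(3)) %% 11) + 1))
    names(entries) <- paste0("d", 1:25)
    structure(list(kind = kind, entries = entries),
              class = "relation_dictionary")
  }
  expect_identical(select_k_and_report(big("DS"), seed = 1)$k, 15L)
  expect_identical(select_k_and_report(big("SFD"), seed = 1)$k, 20L)
  expect_identical(select_k_and_report(big("NSFD"), seed = 1)$k, 6L)
  expect_error(select_k_and_report(
    planted_motif_dict(n_per = 2), k = 10, seed = 1), "exceeds")
})

test_that("planted motifs are recovered exactly at k = 3", {
  dict <- planted_motif_dict()
  rep_ <- select_k_and_report(dict, k = 3, seed = 5)
  truth <- rep(1:3, each = 8)
  expect_equal(adjusted_rand_index(rep_$assignments, truth), 1)
  expect_identical(sort(unique(rep_$summary$category)), 1:3)
  expect_identical(sum(rep_$summary$n_diseases), 24L)
  expect_true(all(vapply(seq_len(nrow(rep_$summary)), function(i)
    nzchar(rep_$summary$shared_terms[i]), logical(1))))
})

test_that("adjusted Rand agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(25, {
    for (rep in 1:5) {
      a <- sample(1:3, 20, replace = TRUE)
      b <- sample(1:4, 20, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  })
})
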