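test_that("gene sets collapse categories 1-3 per gene", {
  v <- variant_table("S1", "chr1", 1:4, "A", "G",
                     gene = c("G1", "G1", "G2", "G3"),
                     category = c(3L, 3L, 1L, 4L))
  sets <- collapse_gene_sets(v)
  expect_equal(sets$S1, c("G1", "G2"))
  # a sample with no category 1-3 variants keeps an empty set
  sets2 <- collapse_gene_sets(v, samples = c("S1", "S2"))
  expect_equal(sets2$S2, character(0))
})

test_that("Jaccard matrix matches set arithmetic, including conventions", {
  sets <- list(A = c("X", "Y"), B = c("Y", "Z"), C = c("X", "Y"))
  J <- jaccard_matrix(sets)
  expect_equal(J["A", "B"], 1 / 3)
  expect_equal(J["A", "C"], 1)
  expect_equal(diag(J), c(A = 1, B = 1, C = 1))
  # the published example pair: intersection 10 over union 96
  big <- list(P = c(sprintf("I%02d", 1:10), sprintf("p%02d", 1:40)),
              Q = c(sprintf("I%02d", 1:10), sprintf("q%02d", 1:46)),
              R = "other")
  expect_equal(jaccard_matrix(big)["P", "Q"], 10 / 96)
  # empty sets: similarity 0, including the diagonal of an empty set
  je <- jaccard_matrix(list(A = character(0), B = "X"))
  expect_equal(je["A", "B"], 0)
  expect_equal(je["A", "A"], 0)
  expect_error(jaccard_matrix(list(A = "X")), "2 samples")
})

test_that("Jaccard matrix equals a brute-force oracle on random sets", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    sets <- lapply(seq_len(n), function(i)
      sample(sprintf("G%02d", 1:25), sample(0:12, 1)))
    names(sets) <- sprintf("S%02d", seq_len(n))
    J <- jaccard_matrix(sets)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        inter <- sum(unique(sets[[i]]) %in% sets[[j]])
        uni <- length(unique(c(sets[[i]], sets[[j]])))
        expect_equal(J[i, j], if (uni == 0) 0 else inter / uni)
      }
    }
    # 1 - J is a metric: spot-check the triangle inequality on triples
    for (t in 1:10) {
      ijk <- sample(n, 3)
      expect_lte(1 - J[ijk[1], ijk[3]],
                 (1 - J[ijk[1], ijk[2]]) + (1 - J[ijk[2], ijk[3]]) + 1e-12)
    }
  }
})

test_that("Z-score standardisation uses the global pair population", {
  sets <- list(S1 = c("A", "B"), S2 = c("B", "C"), S3 = c("q", "r"))
  J <- jaccard_matrix(sets)  # pairwise 1/3, 0, 0
  Z <- standardize_zscores(J)
  # hand computation with the sample-sd convention:
  # mean 1/9, sd 1/(3 sqrt(3)), Z = (1/3 - 1/9) * 3 sqrt(3) = 2/sqrt(3)
  expect_equal(Z["S1", "S2"], 2 / sqrt(3))
  expect_true(is.na(Z["S1", "S1"]))
  # brute-force mean/sd oracle
  vals <- c(J[1, 2], J[1, 3], J[2, 3])
  expect_equal(Z["S1", "S3"], (J[1, 3] - mean(vals)) / sd(vals))

  const <- matrix(0.5, 3, 3, dimnames = list(1:3, 1:3)); diag(const) <- 1
  const[1, 2] <- const[2, 1] <- 0.5
  const[1, 3] <- const[3, 1] <- 0.5
  const[2, 3] <- const[3, 2] <- 0.5
  expect_error(standardize_zscores(const), "degenerate")

  # standardisation property on random matrices
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 1
    dimnames(m) <- list(paste0("S", 1:n), paste0("S", 1:n))
    z <- standardize_zscores(m)
    up <- z[upper.tri(z)]
    expect_equal(mean(up), 0, tolerance = 1e-12)
    expect_equal(sd(up), 1, tolerance = 1e-12)
    # population convention rescales by sqrt((k-1)/k)
    zp <- standardize_zscores(m, sd_convention = "population")
    k <- length(up)
    expect_equal(zp[upper.tri(zp)], up * sqrt(k / (k - 1)),
                 tolerance = 1e-9)
  }
})

test_that("pair ranking reports intersections above the threshold", {
  sets <- list(S1 = c("A", "B"), S2 = c("B", "C"), S3 = c("q", "r"))
  J <- jaccard_matrix(sets)
  Z <- standardize_zscores(J)
  top <- rank_pairs(Z, sets, z_threshold = 1)
  expect_equal(nrow(top), 1)
  expect_equal(top$sample_a, "S1")
  expect_equal(top$sample_b, "S2")
  expect_equal(top$intersection_genes, "B")
  expect_true(all(top$n_intersection <= top$n_union))
  expect_equal(nrow(rank_pairs(Z, sets, z_threshold = 99)), 0)
})

test_that("clustering matches a naive agglomeration oracle", {
  # two identical rows merge first at height 0
  m <- rbind(c(1, 0.9, 0.1), c(0.9, 1, 0.1), c(0.1, 0.1, 1))
  m2 <- rbind(m[1, ], m[1, ], m[2, ], m[3, ])
  dimnames(m2) <- list(paste0("S", 1:4), NULL)
  tree <- cluster_samples(m2)
  expect_equal(tree$height[1], 0)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))
  expect_equal(length(tree$height), 3)  # n - 1 merges

  set.seed(31)
  for (linkage in c("complete", "average", "single")) {
    for (rep in 1:4) {
      n <- sample(4:6, 1)
      m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 1
      dimnames(m) <- list(paste0("S", 1:n), paste0("S", 1:n))
      tree <- cluster_samples(m, linkage = linkage)
      D <- as.matrix(dist(m))
      expect_equal(tree$height, naive_agglomerate(D, linkage),
                   tolerance = 1e-9)
      if (linkage != "single")
        expect_true(all(diff(tree$height) >= -1e-12))  # monotone heights
    }
  }

  # 4 points on a line: merge order is pair-by-pair then the join
  line <- cbind(c(0, 1, 10, 11), 0)
  dl <- as.matrix(dist(line))
  diag(dl) <- 0
  treel <- stats::hclust(stats::dist(line), method = "complete")
  expect_equal(treel$height, naive_agglomerate(dl, "complete"))

  m_bad <- matrix(c(1, NA, NA, 1), 2, 2)
  expect_error(cluster_samples(m_bad), "non-finite")
})

test_that("relabelling samples permutes but does not change the Z multiset", {
  set.seed(17)
  sets <- lapply(1:6, function(i) sample(sprintf("G%02d", 1:20), 8))
  names(sets) <- paste0("S", 1:6)
  Z1 <- standardize_zscores(jaccard_matrix(sets))
  perm <- sample(6)
  Z2 <- standardize_zscores(jaccard_matrix(sets[perm]))
  expect_equal(sort(Z1[upper.tri(Z1)]), sort(Z2[upper.tri(Z2)]))
  # consistent row/column permutation
  expect_equal(Z2[names(sets)[perm], names(sets)[perm]],
               Z1[names(sets)[perm], names(sets)[perm]])
})

test_that("the full fingerprint wrapper chains the stages coherently", {
  set.seed(3)
  v <- toy_cohort_variants(list(S1 = c("A", "B", "C"), S2 = c("A", "B"),
                                S3 = c("x", "y"), S4 = c("y", "z")),
                           category = 3L)
  fp <- fingerprint(v, z_threshold = 0.5)
  expect_s3_class(fp, "fingerprint_result")
  expect_equal(fp$sample_ids, c("S1", "S2", "S3", "S4"))
  expect_equal(dim(fp$jaccard), c(4, 4))
  expect_equal(length(fp$tree$height), 3)
  expect_true(all(fp$top_pairs$zscore > 0.5))
})
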