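# Representational analysis: distance series, m - D similarity, covariance
# maps, UPGMA, non-metric MDS and silhouette, each against small hand
# oracles.

null_kernels <- function() {
  kernel_spec(manner_gains = matrix(1, 4, 4), acoustic_coupling = rep(0, 4),
              speaker_separation = 0)
}

coarsen <- function(ep, step_ms) prpkit:::coarsen_epochs(ep, step_ms)

fake_set <- function(vals, lag_ms = seq_len(dim(vals)[3])) {
  prpkit:::new_prp_set(vals, counts = rep(1L, dim(vals)[1]),
                       lag_ms = lag_ms,
                       electrodes = paste0("E", seq_len(dim(vals)[2])))
}

test_that("pairwise distances match hand values and the brute-force loop", {
  # two categories with vectors (0,0) and (3,4): distance 5
  vals <- array(0, dim = c(2, 2, 1), dimnames = list(c("A", "B"), NULL,
                                                     NULL))
  vals[2, , 1] <- c(3, 4)
  ds <- pairwise_distance_series(fake_set(vals))
  expect_equal(ds$values[1, 2, 1], 5)
  expect_symmetric_zero_diag(ds$values[, , 1])

  # identical categories -> all-zero matrix
  same <- array(1, dim = c(3, 4, 2), dimnames = list(c("A", "B", "C"),
                                                     NULL, NULL))
  expect_true(all(pairwise_distance_series(fake_set(same))$values == 0))

  # random instance vs an explicit double loop
  set.seed(21)
  r <- array(rnorm(5 * 3 * 4), dim = c(5, 3, 4),
             dimnames = list(LETTERS[1:5], NULL, NULL))
  ds2 <- pairwise_distance_series(fake_set(r))
  for (l in 1:4)
    for (i in 1:5)
      for (j in 1:5)
        expect_lt(abs(ds2$values[i, j, l] -
                        sqrt(sum((r[i, , l] - r[j, , l])^2))), 1e-12)

  one <- array(1, dim = c(1, 2, 1), dimnames = list("A", NULL, NULL))
  expect_error(pairwise_distance_series(fake_set(one)), "2 categories")
})

test_that("similarity transform m - D behaves as an order reversal", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3)
  s <- similarity_matrix(d)
  expect_equal(mean(s), 0)                       # zero mean by construction
  expect_equal(s, mean(d) - d)
  # the closest pair gets the largest off-diagonal similarity
  expect_equal(which.max(s[upper.tri(s)]), which.min(d[upper.tri(d)]))
  # constant off-diagonal matrix maps to a constant with zero mean
  dc <- matrix(3, 2, 2); diag(dc) <- 0
  expect_true(all(abs(similarity_matrix(dc) + c(-1.5, 1.5) * 0) ==
                    abs(mean(dc) - dc)))
})

test_that("cross covariance matches var on the diagonal and is
           shift-invariant", {
  set.seed(22)
  r <- array(rnorm(6 * 4 * 5), dim = c(6, 4, 5),
             dimnames = list(LETTERS[1:6], NULL, NULL))
  ds <- pairwise_distance_series(fake_set(r))
  cc <- cross_covariance(ds, ds)
  for (l in 1:5)
    expect_lt(abs(cc$values[l, l] -
                    var(prpkit:::lower_tri_vec(ds$values[, , l]))), 1e-12)

  # adding a constant to one series leaves the covariance unchanged
  ds2 <- ds
  ds2$values <- ds2$values + 7
  diag3 <- function(a) for (l in 1:5) diag(a$values[, , l]) <- 0
  # (shift the lower triangles directly through the internal vectorizer)
  xa <- prpkit:::series_lower_tri(ds)
  xb <- xa + 7
  p <- ncol(xa)
  v1 <- tcrossprod(xa - rowMeans(xa), xa - rowMeans(xa)) / (p - 1)
  v2 <- tcrossprod(xa - rowMeans(xa), xb - rowMeans(xb)) / (p - 1)
  expect_lt(max(abs(v1 - v2)), 1e-12)

  # oracle: explicit cov() per lag pair
  ds_b <- pairwise_distance_series(fake_set(
    array(rnorm(6 * 4 * 3), dim = c(6, 4, 3),
          dimnames = list(LETTERS[1:6], NULL, NULL))))
  cc2 <- cross_covariance(ds, ds_b)
  for (la in 1:5)
    for (lb in 1:3)
      expect_lt(abs(cc2$values[la, lb] -
                      cov(prpkit:::lower_tri_vec(ds$values[, , la]),
                          prpkit:::lower_tri_vec(ds_b$values[, , lb]))),
                1e-12)

  # category mismatch is rejected
  ds_c <- ds_b
  ds_c$categories <- letters[1:6]
  expect_error(cross_covariance(ds, ds_c), "categor")
})

test_that("bootstrap significance validates inputs and calibrates on null
           data", {
  sim <- small_session(duration = 20, seed = 23, noise_snr = 0,
                       kernels = null_kernels())
  rec <- preprocess_rec(sim$recording)
  ep <- extract_epochs(rec, sim$alignment, c(0, 300))
  # second, independent noise session stands in for the acoustic side
  sim2 <- small_session(duration = 20, seed = 77, noise_snr = 0,
                        kernels = null_kernels())
  ep2 <- extract_epochs(preprocess_rec(sim2$recording), sim2$alignment,
                        c(0, 300))
  # same token list, unrelated responses: truncate to a common length and
  # impose the first session's labels on the second
  n_common <- min(dim(ep$epochs)[1], dim(ep2$epochs)[1])
  ep <- subset_epochs(ep, seq_len(n_common))
  ep2 <- subset_epochs(ep2, seq_len(n_common))
  ep2$meta <- ep$meta
  cc <- bootstrap_significance(coarsen(ep, 20), coarsen(ep2, 20),
                               n = 8, q = 1e-4, seed = 3)
  expect_lt(mean(cc$mask), 0.01)
  expect_equal(dim(cc$mask), dim(cc$values))

  expect_error(bootstrap_significance(ep, ep2, n = 1), "2 bootstrap")
  expect_warning(bootstrap_significance(coarsen(ep, 50), coarsen(ep2, 50),
                                        n = 2, q = 0.01, seed = 1),
                 "low power")
})

test_that("UPGMA reproduces the hand-computed 4-leaf dendrogram", {
  # d(AB) = 1, d(CD) = 2, cross distances 8, 8.4, 8.8, 9.2
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 1
  d["C", "D"] <- d["D", "C"] <- 2
  d["A", "C"] <- d["C", "A"] <- 8
  d["A", "D"] <- d["D", "A"] <- 8.4
  d["B", "C"] <- d["C", "B"] <- 8.8
  d["B", "D"] <- d["D", "B"] <- 9.2
  hc <- hclust(as.dist(d), method = "average")
  # (A,B) joins at 1, (C,D) at 2, root at mean cross distance
  expect_equal(sort(hc$height), c(1, 2, mean(c(8, 8.4, 8.8, 9.2))))
  cut2 <- cutree(hc, 2)
  expect_equal(unname(cut2), c(1, 1, 2, 2))

  # the packaged wrapper agrees on synthetic PRPs with two categories
  vals <- array(0, dim = c(2, 2, 3), dimnames = list(c("A", "B"), NULL,
                                                     NULL))
  vals[2, , ] <- 3
  res <- upgma_cluster(fake_set(vals, lag_ms = c(0, 200, 400)))
  expect_equal(res$hclust$height, sqrt(6 * 9))   # single join at D
  # ultrametric tree puts each leaf at half the join distance
  depth <- ape::node.depth.edgelength(res$phylo)
  expect_equal(depth[1], sqrt(54) / 2)
  expect_match(res$newick, "^\\(")
})

test_that("UPGMA is invariant to category order and recovers planted
           structure", {
  ks <- kernel_spec()
  sim <- small_session(duration = 10, n_utterances = 2, kernels = ks,
                       noise_snr = Inf, seed = 2)
  ip <- ideal_prps(sim$ground_truth, fs_out = 500)
  res <- upgma_cluster(ip[[1]], window = c(0, 400))
  cut2 <- cutree(res$hclust, 2)
  manner <- manner_partition(sim$inventory)[names(cut2)]
  sonorant <- manner %in% c("vowel", "nasal")
  expect_true(all(cut2[sonorant] == cut2[sonorant][1]) &&
                all(cut2[!sonorant] == cut2[!sonorant][1]) &&
                cut2[sonorant][1] != cut2[!sonorant][1])

  # permuting the categories permutes the tree but not its topology
  perm <- sample(length(ip[[1]]$categories))
  ip_p <- ip[[1]]
  ip_p$values <- ip_p$values[perm, , , drop = FALSE]
  ip_p$categories <- ip_p$categories[perm]
  ip_p$counts <- ip_p$counts[perm]
  res_p <- upgma_cluster(ip_p, window = c(0, 400))
  expect_equal(sort(res_p$hclust$height), sort(res$hclust$height))
})

test_that("non-metric MDS embeds exact geometries", {
  # two points, distance 4 -> coordinates -2 and +2 (sign fixed)
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  y <- mds_embed(d2, dims = 1)
  expect_equal(unname(y[, 1]), c(2, -2))
  expect_lt(attr(y, "stress"), 1e-8)

  # three equidistant points in 2-D: all pairwise distances equal
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  y3 <- mds_embed(d3, dims = 2)
  dd <- dist(y3)
  expect_lt(max(dd) - min(dd), 1e-6)

  # a line geometry embeds in 1-D with the rank order preserved
  x_line <- c(0, 1, 3, 6, 10)
  dl <- as.matrix(dist(x_line))
  yl <- mds_embed(dl, dims = 1)
  # embeddings are reflection-invariant: accept either orientation
  expect_true(identical(order(yl[, 1]), order(x_line)) ||
                identical(order(yl[, 1]), rev(order(x_line))))

  expect_error(mds_embed(d3, dims = 3), "categories")

  # all-zero distances embed at the origin
  y0 <- mds_embed(matrix(0, 3, 3), dims = 1)
  expect_true(all(y0 == 0))
})

test_that("MDS trajectory respects the zero mask", {
  set.seed(24)
  r <- array(rnorm(4 * 3 * 3), dim = c(4, 3, 3),
             dimnames = list(LETTERS[1:4], NULL, NULL))
  ds <- pairwise_distance_series(fake_set(r))
  tr <- mds_trajectory(ds, dims = 1, zero_mask = c(FALSE, TRUE, FALSE))
  expect_true(all(tr[, , 2] == 0))
  expect_false(all(tr[, , 1] == 0))
  expect_error(mds_trajectory(ds, zero_mask = c(TRUE, FALSE)), "per lag")
})

test_that("silhouette matches the per-point brute force and its limits", {
  set.seed(25)
  a <- matrix(rnorm(20, sd = 0.1), 10, 2)
  b <- matrix(rnorm(20, sd = 0.1), 10, 2) + 10
  x <- rbind(a, b)
  labs <- rep(c("a", "b"), each = 10)
  s <- silhouette_index(x, labs)
  expect_gt(s, 0.95)                       # far-separated tight clusters

  # brute-force oracle
  dm <- as.matrix(dist(x))
  s_oracle <- mean(vapply(1:20, function(i) {
    own <- labs == labs[i]; own[i] <- FALSE
    a_i <- mean(dm[i, own])
    b_i <- mean(dm[i, labs != labs[i]])
    (b_i - a_i) / max(a_i, b_i)
  }, numeric(1)))
  expect_lt(abs(s - s_oracle), 1e-12)

  # random labels on one isotropic cloud: index near zero
  set.seed(26)
  vals <- replicate(30, {
    cloud <- matrix(rnorm(200), 100, 2)
    silhouette_index(cloud, sample(rep(c("a", "b"), 50)))
  })
  expect_true(all(abs(vals) < 0.1))

  expect_error(silhouette_index(x, rep("a", 20)), "2 distinct")
  expect_error(silhouette_index(x[1:2, ], c("a", "b")), "singleton")
})

test_that("distance series can be restricted to chosen electrodes", {
  set.seed(27)
  vals <- array(rnorm(4 * 3 * 2), dim = c(4, 3, 2),
                dimnames = list(LETTERS[1:4], NULL, NULL))
  fs <- fake_set(vals)
  fs$electrodes <- c("FCz", "Cz", "Pz")
  full <- pairwise_distance_series(fs)
  sub <- pairwise_distance_series(fs, electrodes = c("FCz", "Cz"))
  # oracle on the restricted feature axis
  expect_lt(abs(sub$values[1, 2, 1] -
                  sqrt(sum((vals[1, 1:2, 1] - vals[2, 1:2, 1])^2))), 1e-12)
  expect_false(isTRUE(all.equal(full$values, sub$values)))
  expect_error(pairwise_distance_series(fs, electrodes = "Oz"), "unknown")
})
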