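test_that("feature matrix has the fixed column order and derived columns", {
  prof <- data.frame(id = c("a", "b", "c"),
                     CORE_PROD = c(1, 2, 3), CORE_LISN = c(0, 1, 2),
                     CORE_READ = c(1, 1, 1) * c(1, 2, 3),
                     HUBS_PROD = c(2, 1, 0), HUBS_LISN = c(0.5, 1, 1.5),
                     HUBS_READ = c(3, 2, 1))
  met <- data.frame(id = c("c", "a", "b"),
                    rs_dc_left = c(8, 9.0, 7), rs_dc_right = c(8, 9.2, 7.5),
                    rs_dc_sum = c(16, 18.2, 14.5),
                    rs_dc_asym = c(0, -0.2, -0.5),
                    rs_dc_mean = c(8, 9.1, 7.25),
                    mihhc_z = c(0.6, 0.7, 0.5),
                    mihhc_r = tanh(c(0.6, 0.7, 0.5)))
  x <- build_features(prof, met)
  expect_equal(colnames(x), c("CORE_PROD", "CORE_LISN", "CORE_READ",
                              "HUBS_PROD", "HUBS_LISN", "HUBS_READ",
                              "rs_dc_sum", "rs_dc_asym", "mihhc"))
  expect_equal(x["a", "rs_dc_sum"], 18.2)
  expect_equal(x["a", "rs_dc_asym"], -0.2)
  z <- build_features(prof, met, standardize = TRUE)
  expect_equal(unname(colMeans(z)), rep(0, 9), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 9), tolerance = 1e-10)
  expect_equal(unname(z[, "CORE_PROD"]), c(-1, 0, 1))  # {1,2,3} -> {-1,0,1}
  met_bad <- met; met_bad$id[1] <- "zz"
  expect_error(build_features(prof, met_bad), "ids differ")
  prof0 <- prof; prof0$CORE_LISN <- 1
  expect_error(build_features(prof0, met, standardize = TRUE),
               "zero-variance")
})

test_that("ward tree matches the exhaustive minimum-variance oracle", {
  set.seed(10)
  for (rep in 1:3) {
    x <- matrix(rnorm(8 * 3), 8, 3)
    rownames(x) <- paste0("r", 1:8)
    tree <- ward_tree(x)
    oracle <- ward_oracle_partitions(x)
    for (k in 7:2) {
      got <- cutree(tree, k)
      want <- oracle[[8 - k]]
      # same partition up to label permutation
      expect_equal(ari_oracle(got, want), 1)
    }
    expect_true(all(diff(tree$height) >= -1e-12))
  }
})

test_that("ward tree handles edge cases", {
  x <- rbind(c(0, 0), c(3, 4))
  tr <- ward_tree(x)
  expect_equal(tr$height, 5)  # Euclidean distance of the single merge
  xx <- matrix(rnorm(20), 10, 2)
  expect_equal(length(ward_tree(xx)$height), 9L)
  xx[1] <- NA
  expect_error(ward_tree(xx), "NA")
})

test_that("clustering is invariant to row order", {
  run <- cohort_classification_run(1)
  fz <- build_features(run$profiles, run$metrics, standardize = TRUE)
  tree <- ward_tree(fz)
  set.seed(33)
  perm <- sample(nrow(fz))
  tree_p <- ward_tree(fz[perm, ])
  for (k in c(2, 3, 5)) {
    a <- cutree(tree, k)
    b <- cutree(tree_p, k)[rownames(fz)]
    expect_equal(ari_oracle(a, b), 1)
  }
})

test_that("validity vote recovers the true number on separated blobs", {
  set.seed(21)
  p <- 4
  mk <- function(k, n_per = 20, sep = 10) {
    ctr <- matrix(rnorm(k * p), k, p)
    ctr <- ctr / sqrt(rowSums(ctr^2)) * sep * seq_len(k)  # far apart
    do.call(rbind, lapply(seq_len(k), function(i)
      sweep(matrix(rnorm(n_per * p), n_per, p), 2, ctr[i, ], "+")))
  }
  x3 <- scale(mk(3))
  s3 <- select_k(x3, ward_tree(x3))
  expect_equal(s3$k, 3L)
  expect_gte(mean(s3$votes == 3), 0.8)
  x2 <- scale(mk(2))
  s2 <- select_k(x2, ward_tree(x2))
  expect_equal(s2$k, 2L)
  # one vote per index, all within range
  expect_length(s3$votes, length(validity_indices()))
  expect_true(all(s3$votes %in% 2:8))
  expect_error(select_k(x3, k_range = 1:4), "k_range")
})

test_that("group labels follow the asymmetry-based naming rule", {
  set.seed(5)
  # three planted clusters with task-asymmetry means +0.45, +0.24, -0.15
  mk <- function(mu, n) matrix(rnorm(n * 9, mu, 0.03), n, 9)
  x <- rbind(mk(0.45, 20), mk(0.24, 20), mk(-0.15, 20))
  colnames(x) <- c("CORE_PROD", "CORE_LISN", "CORE_READ",
                   "HUBS_PROD", "HUBS_LISN", "HUBS_READ",
                   "rs_dc_sum", "rs_dc_asym", "mihhc")
  rownames(x) <- paste0("S", 1:60)
  tree <- ward_tree(scale(x))
  grp <- assign_groups(x, tree, 3L)
  expect_setequal(unique(grp$group), c("TYP_STRONG", "TYP_MILD", "ATYP"))
  expect_equal(unique(grp$group[1:20]), "TYP_STRONG")
  expect_equal(unique(grp$group[21:40]), "TYP_MILD")
  expect_equal(unique(grp$group[41:60]), "ATYP")
  # all-positive cluster means trigger the unverified guard
  x_pos <- x; x_pos[41:60, 1:6] <- x_pos[41:60, 1:6] + 0.4
  tree_p <- ward_tree(scale(x_pos))
  expect_warning(grp_p <- assign_groups(x_pos, tree_p, 3L), "unverified")
  expect_true(all(grepl("_unverified", grp_p$group)))
  # non-canonical k gets generic labels
  expect_warning(g4 <- assign_groups(x, tree, 4L), "generic")
  expect_true(all(grepl("^cluster_", g4$group)))
})

test_that("dissociation rule matches its truth-table oracle exactly", {
  vals <- c(-0.2, 0, 0.2)  # R band, neutral, L band
  grid <- expand.grid(a1 = vals, a2 = vals, a3 = vals,
                      a4 = vals, a5 = vals, a6 = vals)
  prof <- data.frame(id = paste0("p", seq_len(nrow(grid))),
                     CORE_PROD = grid$a1, CORE_LISN = grid$a2,
                     CORE_READ = grid$a3, HUBS_PROD = grid$a4,
                     HUBS_LISN = grid$a5, HUBS_READ = grid$a6)
  got <- classify_dissociation(prof)
  want <- apply(as.matrix(grid), 1L, dissociation_oracle)
  expect_equal(got$dissociation, unname(want))
  # sign flip of all six asymmetries leaves the status unchanged
  prof_neg <- prof
  prof_neg[, -1L] <- -prof_neg[, -1L]
  expect_equal(classify_dissociation(prof_neg)$dissociation,
               got$dissociation)
})

test_that("dissociation rule handles the documented boundary cases", {
  prof <- data.frame(
    id = c("all_left", "crossed", "band", "hub_only"),
    CORE_PROD = c(0.3, 0.20, 0.2, 0.3),
    CORE_LISN = c(0.2, -0.15, 0.04, 0.2),
    CORE_READ = c(0.1, -0.18, -0.04, 0.1),
    HUBS_PROD = c(0.4, 0.25, 0.3, 0.1),
    HUBS_LISN = c(0.3, -0.29, 0.1, 0.06),
    HUBS_READ = c(0.2, -0.35, 0.02, -0.4))
  out <- classify_dissociation(prof)
  expect_equal(out$dissociation,
               c("CONGRUENT", "CROSSED", "CONGRUENT", "CROSSED"))
  expect_equal(out$DIR_CORE_PROD, c("L", "L", "L", "L"))
  expect_equal(out$DIR_CORE_LISN[3L], "N")
  # one_pole counts a supra-threshold task opposing any opposite sign
  one <- classify_dissociation(prof, rule = "one_pole")
  expect_equal(one$dissociation[3L], "CROSSED")  # READ at -0.04 opposes PROD
  expect_equal(one$dissociation[1L], "CONGRUENT")
})
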