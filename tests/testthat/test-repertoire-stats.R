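test_that("clonality matches the 1 - Pielou formula", {
  expect_equal(clonality(toy_repertoire(c(25, 25, 25, 25))), 0)
  expect_equal(clonality(toy_repertoire(c(50, 50))), 0)
  # frozen hand evaluation of 1 - (-sum p ln p)/ln 4 at (0.97, 0.01, 0.01, 0.01)
  skew <- toy_repertoire(c(9700, 100, 100, 100))
  expect_equal(clonality(skew), 0.879029633573, tolerance = 1e-10)
  expect_error(clonality(toy_repertoire(10)), "fewer than 2")
})

test_that("clonality is invariant to relabeling and count scaling", {
  counts <- c(400, 120, 60, 11, 9)
  a <- toy_repertoire(counts)
  b <- toy_repertoire(rev(counts))       # same distribution, other keys
  expect_equal(clonality(a), clonality(b))
  expect_equal(clonality(toy_repertoire(counts * 7)), clonality(a))
  expect_gt(clonality(a), 0)
  expect_lt(clonality(a), 1)
})

test_that("Morisita-Horn matches the printed formula on fixtures", {
  keys <- toy_keys(2)
  a <- keyed_repertoire(keys, c(3, 1))
  b <- keyed_repertoire(keys, c(1, 3))
  # hand oracle: 2*6 / ((10/16 + 10/16) * 4 * 4) = 0.6
  expect_equal(morisita_horn(a, b), 0.6, tolerance = 1e-12)
  expect_equal(morisita_horn(a, a), 1)
  disjoint <- toy_repertoire(c(5, 5))
  other <- keyed_repertoire(toy_keys(3)[3, , drop = FALSE], 10)
  expect_equal(morisita_horn(disjoint, other), 0)
})

test_that("Morisita-Horn is symmetric, bounded, and 1 iff identical", {
  for (s in 1:10) {
    a <- random_repertoire(40, seed = s, total = 800)
    b <- random_repertoire(40, seed = s + 100, total = 900)
    mh <- morisita_horn(a, b)
    expect_equal(mh, morisita_horn(b, a), tolerance = 1e-12)
    expect_gte(mh, 0)
    expect_lte(mh, 1)
    expect_lt(mh, 1)  # different random supports never fully coincide
    expect_equal(morisita_horn(a, a), 1, tolerance = 1e-12)
  }
})

test_that("overlap intersects key sets and reports both total modes", {
  keys <- toy_keys(3)
  a <- keyed_repertoire(keys[1:2, ], c(5, 5))  # k1, k2 at 0.5
  b <- keyed_repertoire(keys[c(1, 3), ], c(5, 5))  # k1, k3 at 0.5
  ov <- overlap(a, b)
  expect_equal(ov$n_shared, 1)
  expect_equal(ov$shared$geometric_mean_freq, 0.5)
  expect_equal(ov$total_overlap_frequency, 0.5)  # sqrt(0.5 * 0.5)
  expect_equal(overlap(a, b, "sum_of_geomeans")$total_overlap_frequency, 0.5)

  same <- overlap(a, a)
  expect_equal(same$total_overlap_frequency, 1)
  expect_equal(same$n_shared, 2)

  far <- keyed_repertoire(toy_keys(5)[4:5, ], c(1, 1))
  expect_equal(overlap(a, far)$n_shared, 0)
  expect_equal(overlap(a, far)$total_overlap_frequency, 0)
})

test_that("overlap agrees with a brute-force double-loop oracle", {
  for (s in 1:25) {
    a <- random_repertoire(30, seed = s, total = 500)
    b <- random_repertoire(30, seed = s + 500, total = 500)
    ov <- overlap(a, b)
    # naive oracle: loop both clone lists, match on the triple key
    acl <- as.data.frame(a$clones)
    bcl <- as.data.frame(b$clones)
    fa <- 0; fb <- 0; nsh <- 0
    for (i in seq_len(nrow(acl))) {
      for (k in seq_len(nrow(bcl))) {
        if (acl$v[i] == bcl$v[k] && acl$j[i] == bcl$j[k] &&
            acl$cdr3nt[i] == bcl$cdr3nt[k]) {
          nsh <- nsh + 1
          fa <- fa + acl$freq[i]
          fb <- fb + bcl$freq[k]
        }
      }
    }
    expect_equal(ov$n_shared, nsh)
    expect_equal(ov$total_overlap_frequency, sqrt(fa * fb),
                 tolerance = 1e-12)
    rev <- overlap(b, a)
    expect_equal(rev$total_overlap_frequency, ov$total_overlap_frequency,
                 tolerance = 1e-12)
    expect_equal(rev$n_shared, ov$n_shared)
  }
})

test_that("usage profiles are frequency-weighted and sum to one", {
  one <- toy_repertoire(10)
  up1 <- usage_profile(one)
  expect_equal(up1$v_usage$freq, 1)
  expect_equal(up1$j_usage$freq, 1)

  two <- make_repertoire(data.frame(
    v = "TRBV5", j = c("TRBJ1-1", "TRBJ1-2"),
    cdr3nt = c("TGTGCA", "TGTGCC"), count = c(5, 5)))
  up2 <- usage_profile(two)
  expect_equal(up2$v_usage$freq, 1)
  expect_equal(sort(up2$j_usage$freq), c(0.5, 0.5))

  r <- random_repertoire(120, seed = 17, total = 2000)
  up <- usage_profile(r)
  expect_equal(sum(up$v_usage$freq), 1, tolerance = 1e-9)
  expect_equal(sum(up$j_usage$freq), 1, tolerance = 1e-9)
  expect_equal(sum(up$vj_usage$freq), 1, tolerance = 1e-9)
  # brute-force grouping oracle for one V segment
  vseg <- up$v_usage$segment[1]
  expect_equal(up$v_usage$freq[1],
               sum(r$clones$freq[r$clones$v == vseg]))
})

test_that("usage PCA centers, fixes signs, and matches the 2-point case", {
  reps <- lapply(1:4, function(i)
    random_repertoire(80, seed = 20 + i, total = 1500,
                      sample_id = paste0("s", i)))
  profiles <- lapply(reps, usage_profile)

  same <- usage_pca(list(profiles[[1]], profiles[[1]], profiles[[1]]))
  expect_true(all(abs(as.matrix(same$scores[, -1])) < 1e-12))

  # 2 samples: single informative component, coordinates +/- half distance
  two <- usage_pca(profiles[1:2], space = "v")
  m <- bilatrep:::usage_matrix(profiles[1:2], "v")
  d <- sqrt(sum((m[1, ] - m[2, ])^2))
  expect_equal(sort(abs(two$scores$PC1)), rep(d / 2, 2), tolerance = 1e-9)
  expect_equal(sum(two$scores$PC1), 0, tolerance = 1e-9)

  # reconstruction from all components recovers the centered matrix
  full <- usage_pca(profiles, space = "v_and_j")
  mm <- bilatrep:::usage_matrix(profiles, "v_and_j")
  centered <- scale(mm, center = TRUE, scale = FALSE)
  rec <- as.matrix(full$scores[, -1]) %*% t(full$loadings)
  expect_equal(unname(rec), unname(centered), tolerance = 1e-9,
               ignore_attr = TRUE)

  # sample order only permutes rows of the score table
  perm <- usage_pca(profiles[c(3, 1, 4, 2)], space = "v_and_j")
  a <- full$scores[order(full$scores$sample_id), ]
  b <- perm$scores[order(perm$scores$sample_id), ]
  expect_equal(as.matrix(a[, -1]), as.matrix(b[, -1]), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(usage_pca(profiles[1]), "at least 2")
})

test_that("variance decomposition matches direct sums of squares", {
  vals <- list(m1 = c(0.50, 0.52), m2 = c(0.60, 0.63),
               m3 = c(0.40, 0.38), m4 = c(0.70, 0.69))
  vd <- clonality_variance_decomposition(vals)
  expect_equal(vd$df_within, 4L)
  expect_equal(vd$df_between, 3L)

  # brute-force oracle from group means
  all_v <- unlist(vals)
  grand <- mean(all_v)
  ssb <- sum(vapply(vals, function(g) length(g) * (mean(g) - grand)^2, 1))
  ssw <- sum(vapply(vals, function(g) sum((g - mean(g))^2), 1))
  expect_equal(vd$ss_between, ssb, tolerance = 1e-12)
  expect_equal(vd$ss_within, ssw, tolerance = 1e-12)
  expect_equal(vd$ss_between + vd$ss_within,
               sum((all_v - grand)^2), tolerance = 1e-9)

  with_seed(33, {
    rand <- list(a = rnorm(3), b = rnorm(3), c = rnorm(3))
  })
  vr <- clonality_variance_decomposition(rand)
  msb <- vr$ss_between / vr$df_between
  msw <- vr$ss_within / vr$df_within
  expect_equal(vr$f_statistic, msb / msw, tolerance = 1e-9)
  expect_equal(vr$p_value, stats::pf(vr$f_statistic, vr$df_between,
                                     vr$df_within, lower.tail = FALSE))

  ident <- clonality_variance_decomposition(list(a = c(1, 1), b = c(1, 1)))
  expect_true(is.na(ident$f_statistic))

  flat <- clonality_variance_decomposition(
    list(m1 = c(0.5, 0.5), m2 = c(0.6, 0.6)))
  expect_equal(flat$ss_within, 0)
})

test_that("group comparisons use Student's t with pooled df", {
  a <- c(1.2, 1.4, 1.1, 1.5)
  same <- compare_groups(a, a, paired = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # textbook pooled two-sample fixture
  x <- c(5.1, 4.9, 5.3, 5.0)
  y <- c(4.2, 4.5, 4.1)
  got <- compare_groups(x, y)
  sp2 <- (3 * var(x) + 2 * var(y)) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$df, 5)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_hand), 5),
               tolerance = 1e-12)

  expect_error(compare_groups(1:3, 1:4, paired = TRUE), "equal group sizes")
  expect_error(compare_groups(1, 1:3), "at least 2")
})
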