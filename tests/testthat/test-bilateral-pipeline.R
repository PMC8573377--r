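# deterministic 2-mouse fixture reused across pipeline tests
pipeline_fixture <- function() {
  if (is.null(.GlobalEnv$.bilat_pipe_fix)) {
    .GlobalEnv$.bilat_pipe_fix <- generate_dataset(small_config())
  }
  .GlobalEnv$.bilat_pipe_fix
}

side_pool <- function(reps, mouse, side) {
  pool_repertoires(reps[paste0(mouse, "_Tumor_", side, "_f", 1:2)],
                   sample_id = paste0(mouse, "_T", side))
}

test_that("pairwise matrices are symmetric with unit diagonal", {
  reps <- lapply(1:4, function(i)
    random_repertoire(50, seed = 40 + i, total = 900,
                      sample_id = paste0("s", i), subset = "CD8"))
  pm <- pairwise_matrix(reps, "morisita_horn")
  expect_equal(dim(pm$matrix), c(4, 4))
  expect_equal(pm$matrix, t(pm$matrix))
  expect_equal(unname(diag(pm$matrix)), rep(1, 4))
  # entries match the per-pair statistic
  expect_equal(pm$matrix[1, 3], morisita_horn(reps[[1]], reps[[3]]))
  ov <- pairwise_matrix(reps, "overlap_frequency")
  expect_equal(ov$matrix[2, 4],
               overlap(reps[[2]], reps[[4]])$total_overlap_frequency)

  two_same <- pairwise_matrix(list(reps[[1]], reps[[1]]), "morisita_horn")
  expect_equal(two_same$matrix[1, 2], 1)

  cd4 <- reps[[1]]; cd4$subset <- "CD4"
  expect_error(pairwise_matrix(c(list(cd4), reps[-1]), "morisita_horn"),
               "mix subsets")
})

test_that("within/between-mouse grouping matches the printed pair counts", {
  mice <- paste0("m", 1:4)
  reps <- unlist(lapply(seq_along(mice), function(i) {
    lapply(c("left", "right"), function(s)
      random_repertoire(60, seed = 50 + 2 * i + (s == "right"),
                        total = 1200, sample_id = paste0(mice[i], "_", s),
                        mouse_id = mice[i], tissue = "tumor", side = s,
                        subset = "CD8"))
  }), recursive = FALSE)
  gc <- within_between_mouse(reps, "overlap_frequency")
  expect_length(gc$groups$within_mouse, 4)    # within mice, n = 4
  expect_length(gc$groups$between_mouse, 12)  # between mice, n = 4 x 3
  # brute-force pair classification
  expect_equal(sum(gc$pairs$group == "within_mouse"), 4)
  expect_equal(nrow(unique(gc$pairs[gc$pairs$group == "between_mouse",
                                    c("a", "b")])), 12)
  expect_false(any(gc$pairs$a[gc$pairs$group == "between_mouse"] ==
                     gc$pairs$b[gc$pairs$group == "between_mouse"]))
  expect_false(is.null(gc$test))

  expect_warning(
    one <- within_between_mouse(reps[1:2], "overlap_frequency"),
    "only one mouse")
  expect_length(one$groups$between_mouse, 0)
})

test_that("fragment heterogeneity enumerates 2 within and 4 between pairs per mouse", {
  ds <- pipeline_fixture()
  frags <- ds$repertoires[grepl("Tumor", names(ds$repertoires))]
  gc <- fragment_heterogeneity(frags, "morisita_horn")
  n_mice <- ds$config$n_mice
  expect_length(gc$groups$within_tumor, 2 * n_mice)   # n = mice x 2
  expect_length(gc$groups$between_tumor, 4 * n_mice)  # n = mice x 4
  # identical fragments everywhere -> all values equal, p = 1
  same <- lapply(seq_len(8), function(i) {
    r <- random_repertoire(40, seed = 77, total = 800,
                           sample_id = paste0("f", i),
                           mouse_id = paste0("m", (i - 1) %/% 4 + 1),
                           tissue = "tumor",
                           side = c("left", "right")[(i - 1) %/% 2 %% 2 + 1],
                           subset = "CD8")
    r$fragment <- paste0("f", (i - 1) %% 2 + 1)
    r
  })
  gs <- fragment_heterogeneity(same, "morisita_horn")
  expect_equal(unique(unlist(gs$groups)), 1)
  expect_equal(gs$test$p_value, 1)

  expect_error(fragment_heterogeneity(frags[-1], "morisita_horn"),
               "2 fragments")
})

test_that("dLN-tumor OL repertoire equals brute-force key filtering", {
  ds <- pipeline_fixture()
  reps <- ds$repertoires
  dln <- reps$m1_dLN_left
  tl <- side_pool(reps, "m1", "left")
  tr <- side_pool(reps, "m1", "right")
  ol <- dln_tumor_overlap_repertoire(dln, tl, tr)
  tumor_keys <- unique(c(paste(tl$clones$v, tl$clones$j, tl$clones$cdr3nt),
                         paste(tr$clones$v, tr$clones$j, tr$clones$cdr3nt)))
  keep <- paste(dln$clones$v, dln$clones$j, dln$clones$cdr3nt) %in%
    tumor_keys
  expect_equal(nrow(ol$clones), sum(keep))
  expect_equal(ol$clones$count, dln$clones$count[keep])
  # frequencies kept on the whole-dLN scale by default
  expect_equal(ol$clones$freq, dln$clones$freq[keep])
  expect_lt(sum(ol$clones$freq), 1)
  renorm <- dln_tumor_overlap_repertoire(dln, tl, tr, renormalize = TRUE)
  expect_equal(sum(renorm$clones$freq), 1, tolerance = 1e-9)

  # subset case: dLN fully inside tumor keys -> identity filter
  sub <- make_repertoire(as.data.frame(tl$clones[1:20, ]),
                         sample_id = "sub")
  expect_equal(n_clones(dln_tumor_overlap_repertoire(sub, tl, tr)), 20)

  # disjoint case
  far <- random_repertoire(30, seed = 91, total = 600, sample_id = "far")
  expect_warning(empty <- dln_tumor_overlap_repertoire(far, tl, tr),
                 "no dLN clones")
  expect_equal(nrow(empty$clones), 0)
})

test_that("left-right concordance within OL repertoires", {
  a <- random_repertoire(40, seed = 61, total = 2000, sample_id = "olL")
  same <- left_right_overlap_within_OL(a, a)
  expect_equal(same$frequency_weighted_share, 1)
  expect_equal(same$clone_count_share_L, 1)
  expect_equal(same$pearson_r_log10, 1)

  b <- random_repertoire(40, seed = 62, total = 2000, sample_id = "olR")
  disj <- left_right_overlap_within_OL(a, b)
  expect_equal(disj$frequency_weighted_share, 0)
  expect_true(is.na(disj$pearson_r_log10))

  # fixture with known shared frequencies: r via the covariance formula
  keys <- toy_keys(5)
  x <- keyed_repertoire(keys, c(400, 200, 100, 50, 250), sample_id = "L")
  y <- keyed_repertoire(keys[1:4, ], c(300, 300, 200, 200), sample_id = "R")
  lr <- left_right_overlap_within_OL(x, y)
  fl <- log10(c(400, 200, 100, 50) / 1000)
  fr <- log10(c(300, 300, 200, 200) / 1000)
  r_hand <- sum((fl - mean(fl)) * (fr - mean(fr))) /
    sqrt(sum((fl - mean(fl))^2) * sum((fr - mean(fr))^2))
  expect_equal(lr$pearson_r_log10, r_hand, tolerance = 1e-12)
  expect_equal(lr$n_shared, 4)
  expect_equal(lr$clone_count_share_L, 4 / 5)
  expect_equal(lr$clone_count_share_R, 1)
  expect_equal(lr$frequency_weighted_share, sqrt(750 / 1000 * 1),
               tolerance = 1e-12)
})

test_that("ipsi/contra pairing covers every dLN and detects symmetry", {
  ds <- pipeline_fixture()
  reps <- ds$repertoires
  mice <- paste0("m", seq_len(ds$config$n_mice))
  dlns <- reps[paste0(rep(mice, each = 2), "_dLN_",
                      c("left", "right"))]
  tumors <- unlist(lapply(mice, function(m)
    list(side_pool(reps, m, "left"), side_pool(reps, m, "right"))),
    recursive = FALSE)
  gc <- ipsi_contra_comparison(dlns, tumors)
  expect_length(gc$groups$ipsilateral, 2 * length(mice))  # n = mice x 2
  expect_length(gc$groups$contralateral, 2 * length(mice))
  expect_true(gc$paired)
  expect_equal(nrow(gc$pairs), 2 * length(mice))
  # brute-force side bookkeeping on one dLN
  d <- dlns[[1]]
  ti <- tumors[[1]]; tc <- tumors[[2]]
  expect_equal(gc$pairs$ipsi[1],
               overlap(d, ti)$total_overlap_frequency)
  expect_equal(gc$pairs$contra[1],
               overlap(d, tc)$total_overlap_frequency)

  # perfectly mixed circulation: both tumors identical -> ipsi == contra
  twin_tumors <- unlist(lapply(mice, function(m) {
    t1 <- side_pool(reps, m, "left")
    t2 <- t1; t2$side <- "right"; t2$sample_id <- paste0(m, "_Tright")
    list(t1, t2)
  }), recursive = FALSE)
  sym <- ipsi_contra_comparison(dlns, twin_tumors)
  expect_equal(sym$groups$ipsilateral, sym$groups$contralateral,
               tolerance = 1e-12)
  expect_equal(sym$test$p_value, 1)

  expect_error(ipsi_contra_comparison(dlns, tumors[1]), "missing a tumor")
})

test_that("full analysis produces a complete, deterministic bundle", {
  ds <- pipeline_fixture()
  out1 <- file.path(tempdir(), "bundle1")
  out2 <- file.path(tempdir(), "bundle2")
  res <- run_full_analysis(ds$sheet, outdir = out1, reps = ds$repertoires)
  expect_true(all(file.exists(file.path(out1, c(
    "per_sample_stats.tsv", "rank_classes.tsv", "usage_pca_scores.tsv",
    "tumor_overlap_matrix.tsv", "tumor_morisita_horn_matrix.tsv",
    "dln_overlap_matrix.tsv", "dln_tumor_ol_summary.tsv",
    "ipsi_contra.tsv", "dex_m1.tsv", "summary.json")))))
  expect_gt(nrow(res$per_sample), 0)
  expect_gt(nrow(res$rank_classes), 0)
  # rank-class frequencies in the bundle each sum to 1
  sums <- tapply(res$rank_classes$frequency, res$rank_classes$sample_id, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
  # determinism: identical seed -> byte-identical summary
  run_full_analysis(ds$sheet, outdir = out2, reps = ds$repertoires)
  expect_identical(readLines(file.path(out1, "summary.json")),
                   readLines(file.path(out2, "summary.json")))
})

test_that("pooled-fragment statistics equal statistics on merged clone tables", {
  ds <- pipeline_fixture()
  reps <- ds$repertoires
  pl <- side_pool(reps, "m1", "left")
  pr <- side_pool(reps, "m1", "right")
  merged_l <- make_repertoire(rbind(
    as.data.frame(reps$m1_Tumor_left_f1$clones),
    as.data.frame(reps$m1_Tumor_left_f2$clones)))
  merged_r <- make_repertoire(rbind(
    as.data.frame(reps$m1_Tumor_right_f1$clones),
    as.data.frame(reps$m1_Tumor_right_f2$clones)))
  expect_equal(morisita_horn(pl, pr), morisita_horn(merged_l, merged_r),
               tolerance = 1e-12)
  expect_equal(overlap(pl, pr)$total_overlap_frequency,
               overlap(merged_l, merged_r)$total_overlap_frequency,
               tolerance = 1e-12)
})
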