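#' Repertoire clonality (1 - Pielou evenness)
#'
#' Clonality is one minus the Pielou evenness of the clone frequency
#' distribution: `1 - H / ln(n)`, where `H = -sum(p_i ln p_i)` is the
#' Shannon entropy in nats over the `n` unique clones with frequencies
#' `p_i`. A perfectly even repertoire scores 0; a repertoire dominated by a
#' single clone approaches 1. Undefined for fewer than two clones.
#'
#' @param rep A `tcr_repertoire` with at least 2 unique clones.
#' @return Clonality in `[0, 1]`.
#' @examples
#' r <- make_repertoire(data.frame(v = "TRBV1", j = "TRBJ1-1",
#'   cdr3nt = c("TGTGCA", "TGTGCC", "TGTGCG", "TGTGCT"), count = 25))
#' clonality(r) # 0: perfectly even
#' @export
clonality <- function(rep) {
  assert_repertoire(rep)
  n <- n_clones(rep)
  if (n < 2) {
    stop("clonality undefined for fewer than 2 unique clones", call. = FALSE)
  }
  p <- rep$clones$freq
  shannon <- -sum(p * log(p))
  1 - shannon / log(n)
}

# inner join of two clone tables on the clone key
shared_clones <- function(repA, repB) {
  inner_join(
    repA$clones[, c("v", "j", "cdr3nt", "count", "freq")],
    repB$clones[, c("v", "j", "cdr3nt", "count", "freq")],
    by = c("v", "j", "cdr3nt"), suffix = c("_a", "_b")
  )
}

#' Morisita-Horn similarity between two repertoires
#'
#' Abundance-weighted similarity
#' `C_H = 2 sum(x_i y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) X Y)`
#' where `x_i`, `y_i` are a clone's read counts in the two samples and `X`,
#' `Y` the sample read totals. Equals 1 when the two frequency
#' distributions are identical over identical support and 0 when no clone
#' is shared.
#'
#' @param repA,repB `tcr_repertoire` objects.
#' @return Similarity in `[0, 1]`; symmetric in its arguments.
#' @export
morisita_horn <- function(repA, repB) {
  assert_repertoire(repA)
  assert_repertoire(repB)
  sh <- shared_clones(repA, repB)
  fa <- repA$clones$freq
  fb <- repB$clones$freq
  cross <- sum(sh$freq_a * sh$freq_b)
  denom <- sum(fa^2) + sum(fb^2)
  ch <- 2 * cross / denom
  min(max(ch, 0), 1)
}

#' Overlap analysis of a sample pair
#'
#' Intersects the clone key sets of two repertoires and summarizes the
#' shared clones. Each shared clone's pair-level frequency is the geometric
#' mean of its frequencies within each sample. The total overlap frequency
#' is, in the default `geomean_of_totals` mode, the geometric mean of the
#' total frequency the shared clones hold in each sample,
#' `sqrt(sum(freq_A) * sum(freq_B))`; `sum_of_geomeans` instead sums the
#' per-clone geometric means. Both coincide for highly similar samples.
#'
#' @param repA,repB `tcr_repertoire` objects.
#' @param total_mode `"geomean_of_totals"` (default) or `"sum_of_geomeans"`.
#' @return An `overlap_result`: list with `shared` (tibble of shared clones
#'   with `freq_in_a`, `freq_in_b`, `geometric_mean_freq`), `n_shared`,
#'   `total_overlap_frequency`, `shared_freq_a`, `shared_freq_b`,
#'   `morisita_horn`, and `total_mode`.
#' @export
overlap <- function(repA, repB,
                    total_mode = c("geomean_of_totals", "sum_of_geomeans")) {
  total_mode <- match.arg(total_mode)
  assert_repertoire(repA)
  assert_repertoire(repB)
  sh <- shared_clones(repA, repB)
  shared <- tibble(
    v = sh$v, j = sh$j, cdr3nt = sh$cdr3nt,
    count_a = sh$count_a, count_b = sh$count_b,
    freq_in_a = sh$freq_a, freq_in_b = sh$freq_b,
    geometric_mean_freq = sqrt(sh$freq_a * sh$freq_b)
  )
  fa <- sum(shared$freq_in_a)
  fb <- sum(shared$freq_in_b)
  total <- switch(total_mode,
    geomean_of_totals = sqrt(fa * fb),
    sum_of_geomeans = sum(shared$geometric_mean_freq)
  )
  structure(
    list(
      sample_a = repA$sample_id, sample_b = repB$sample_id,
      shared = shared, n_shared = nrow(shared),
      shared_freq_a = fa, shared_freq_b = fb,
      total_overlap_frequency = total,
      morisita_horn = morisita_horn(repA, repB),
      total_mode = total_mode
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> ", x$sample_a, " vs ", x$sample_b, "\n", sep = "")
  cat(sprintf("  shared clones: %d\n  total overlap frequency (%s): %.4f\n",
              x$n_shared, x$total_mode, x$total_overlap_frequency))
  cat(sprintf("  Morisita-Horn: %.4f\n", x$morisita_horn))
  invisible(x)
}

#' Read-frequency-weighted V/J segment usage of a repertoire
#'
#' Sums clone frequencies by V segment, J segment and (V, J) pair, giving
#' usage profiles in which each segment's weight is the fraction of reads
#' carrying it.
#'
#' @param rep A `tcr_repertoire`.
#' @return A `usage_profile`: list of tibbles `v_usage`, `j_usage`
#'   (`segment`, `freq`) and `vj_usage` (`v`, `j`, `freq`), each summing
#'   to 1.
#' @export
usage_profile <- function(rep) {
  assert_repertoire(rep)
  cl <- rep$clones
  v_usage <- cl |>
    group_by(segment = .data$v) |>
    summarise(freq = sum(.data$freq), .groups = "drop") |>
    arrange(.data$segment)
  j_usage <- cl |>
    group_by(segment = .data$j) |>
    summarise(freq = sum(.data$freq), .groups = "drop") |>
    arrange(.data$segment)
  vj_usage <- cl |>
    group_by(.data$v, .data$j) |>
    summarise(freq = sum(.data$freq), .groups = "drop") |>
    arrange(.data$v, .data$j)
  structure(
    list(sample_id = rep$sample_id, v_usage = v_usage, j_usage = j_usage,
         vj_usage = vj_usage),
    class = "usage_profile"
  )
}

usage_matrix <- function(profiles, space = c("v_and_j", "v", "j")) {
  space <- match.arg(space)
  stopifnot(length(profiles) >= 2)
  ids <- vapply(seq_along(profiles), function(i) {
    profiles[[i]]$sample_id %||% paste0("sample", i)
  }, character(1))
  ids[is.na(ids)] <- paste0("sample", which(is.na(ids)))
  pick <- function(p) {
    v <- p$v_usage; j <- p$j_usage
    switch(space,
      v = stats::setNames(v$freq, paste0("V:", v$segment)),
      j = stats::setNames(j$freq, paste0("J:", j$segment)),
      v_and_j = c(stats::setNames(v$freq, paste0("V:", v$segment)),
                  stats::setNames(j$freq, paste0("J:", j$segment)))
    )
  }
  vecs <- lapply(profiles, pick)
  segs <- sort(unique(unlist(lapply(vecs, names))))
  m <- matrix(0, nrow = length(vecs), ncol = length(segs),
              dimnames = list(ids, segs))
  for (i in seq_along(vecs)) m[i, names(vecs[[i]])] <- vecs[[i]]
  m
}

#' PCA of V/J segment usage across samples
#'
#' Builds the sample-by-segment usage matrix over the union segment
#' vocabulary (segments absent from a sample enter as frequency 0),
#' column-mean-centers it and performs unscaled PCA via singular value
#' decomposition. Component signs are fixed deterministically by making
#' each component's largest-magnitude loading positive.
#'
#' @param profiles List of `usage_profile` objects (at least 2).
#' @param space Feature space: `"v_and_j"` (V and J usage concatenated,
#'   default), `"v"`, or `"j"`.
#' @return A `usage_pca`: list with `scores` (tibble, `sample_id` + PC
#'   columns), `loadings` (matrix), `sdev` and `var_explained`.
#' @export
usage_pca <- function(profiles, space = c("v_and_j", "v", "j")) {
  space <- match.arg(space)
  if (length(profiles) < 2) {
    stop("usage_pca needs at least 2 profiles", call. = FALSE)
  }
  m <- usage_matrix(profiles, space)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x)
  scores <- bind_cols(tibble(sample_id = rownames(m)), scores)
  structure(
    list(scores = scores, loadings = pc$rotation, sdev = pc$sdev,
         var_explained = var_explained, center = pc$center, space = space),
    class = "usage_pca"
  )
}

#' One-way variance decomposition of clonality across mice
#'
#' Splits the total variation of per-sample clonality values into
#' between-mouse and within-mouse sums of squares with their degrees of
#' freedom (`df_between = groups - 1`, `df_within = sum(n_g - 1)`), plus
#' the ordinary one-way ANOVA F statistic and p-value. With four mice
#' contributing a left and right tumor each, this is the homoscedasticity
#' summary with df_within = 4 and df_between = 3.
#'
#' @param values_by_group Named list: one numeric vector of clonality
#'   values per mouse (at least 2 groups, each non-empty).
#' @return A `variance_decomposition`: list with `ss_between`, `ss_within`,
#'   `df_between`, `df_within`, `f_statistic`, `p_value`. When all values
#'   are identical the F statistic is undefined and reported as `NA`.
#' @export
clonality_variance_decomposition <- function(values_by_group) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2)
  lens <- lengths(values_by_group)
  if (any(lens < 1)) stop("every group needs at least one value", call. = FALSE)
  df <- data.frame(
    value = unlist(values_by_group, use.names = FALSE),
    group = factor(rep(names(values_by_group) %||%
                         seq_along(values_by_group), lens))
  )
  out <- list(
    df_between = nlevels(df$group) - 1L,
    df_within = sum(lens - 1L)
  )
  if (length(unique(df$value)) == 1) {
    out <- c(out, list(ss_between = 0, ss_within = 0,
                       f_statistic = NA_real_, p_value = NA_real_,
                       note = "all values identical; F undefined"))
  } else {
    fit <- summary(stats::aov(value ~ group, data = df))[[1]]
    out <- c(out, list(
      ss_between = fit["group", "Sum Sq"],
      ss_within = fit["Residuals", "Sum Sq"],
      f_statistic = fit["group", "F value"],
      p_value = fit["group", "Pr(>F)"]
    ))
  }
  structure(out[c("ss_between", "ss_within", "df_between", "df_within",
                  "f_statistic", "p_value",
                  intersect("note", names(out)))],
            class = "variance_decomposition")
}

#' Two-sided Student's t comparison of two groups
#'
#' Paired or unpaired two-sided Student's t-test. The unpaired test uses
#' pooled variance (df `n1 + n2 - 2`), matching the convention of common
#' graphing/statistics software; Welch's correction is available via
#' `welch = TRUE`. Degenerate constant inputs with zero mean difference
#' return `t = 0`, `p = 1`.
#'
#' @param a,b Numeric vectors (equal length when `paired = TRUE`; at least
#'   2 values per group).
#' @param paired Paired test?
#' @param welch Use Welch's unequal-variance test instead of pooled?
#' @return List with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `method`.
#' @export
compare_groups <- function(a, b, paired = FALSE, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (paired && length(a) != length(b)) {
    stop("paired comparison requires equal group sizes", call. = FALSE)
  }
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  degenerate <- if (paired) {
    all(a - b == (a - b)[1]) && isTRUE(all.equal(mean(a - b), 0))
  } else {
    stats::sd(a) == 0 && stats::sd(b) == 0 && a[1] == b[1]
  }
  if (degenerate) {
    df <- if (paired) length(a) - 1L else length(a) + length(b) - 2L
    return(list(statistic = 0, df = df, p_value = 1,
                mean_a = mean(a), mean_b = mean(b),
                method = if (paired) "paired t" else "pooled t"))
  }
  tt <- stats::t.test(a, b, paired = paired,
                      var.equal = !welch && !paired,
                      alternative = "two.sided")
  list(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
    method = if (paired) "paired t" else if (welch) "Welch t" else "pooled t"
  )
}
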