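#' Estimated cell count of a clone
#'
#' Multiplies the T cell count sorted for library preparation by the clone
#' frequency and rounds half-up to the nearest integer.
#'
#' @param frequency Clone frequency in `[0, 1]` (vectorized).
#' @param cells_for_library Positive integer cell count.
#' @return Non-negative integer estimated cell count(s).
#' @examples
#' estimate_cell_count(0.01, 10000) # 100
#' @export
estimate_cell_count <- function(frequency, cells_for_library) {
  stopifnot(all(frequency >= 0 & frequency <= 1),
            cells_for_library >= 1,
            cells_for_library == floor(cells_for_library))
  as.integer(round_half_up(frequency * cells_for_library))
}

fisher_p_one <- function(a, b, c, d) {
  m <- a + b   # row 1 total
  n2 <- c + d  # row 2 total
  k <- a + c   # column 1 total
  if (m + n2 == 0) stop("all-zero 2x2 table", call. = FALSE)
  if (m == 0 || n2 == 0 || k == 0 || k == m + n2) return(1)
  supp <- max(0, k - n2):min(k, m)
  pr <- stats::dhyper(supp, m, n2, k)
  pobs <- stats::dhyper(a, m, n2, k)
  # minimum-likelihood two-sided convention, with the customary relative
  # tolerance guarding against floating-point ties
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

#' Two-sided Fisher exact test p-value for 2x2 tables
#'
#' Computes the two-sided p-value of the Fisher exact test on the table
#' `[a, b; c, d]` by summing the hypergeometric probabilities of all tables
#' with the same margins whose probability does not exceed that of the
#' observed table (the minimum-likelihood convention used by the common
#' reference implementations). Vectorized over table entries, which makes
#' per-clone testing over large clone universes fast.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectors are recycled to
#'   a common length).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  x <- cbind(a, b, c, d)
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  vapply(seq_len(n), function(i) fisher_p_one(a[i], b[i], c[i], d[i]),
         numeric(1))
}

#' q-values for multiple testing
#'
#' Converts p-values to q-values either by Benjamini-Hochberg step-up
#' (`"bh"`) or by Storey's method (`"storey"`): the null proportion `pi0`
#' is estimated on the lambda grid 0.05, 0.10, ..., 0.95 and smoothed with
#' a df-3 cubic smoothing spline, then `q = pi0 * BH`. With fewer than 50
#' p-values, or when the `pi0` estimate is unstable (non-positive), the
#' method falls back to BH (`pi0 = 1`); the method actually used is
#' recorded in the `"method"` attribute. Output order matches input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"storey"` (default) or `"bh"`.
#' @param pi0 Optional fixed null proportion overriding estimation
#'   (`pi0 = 1` reproduces BH exactly).
#' @return Numeric vector of q-values with attribute `"method"` and, for
#'   Storey, `"pi0"`.
#' @export
q_values <- function(p, method = c("storey", "bh"), pi0 = NULL) {
  method <- match.arg(method)
  if (length(p) == 0) stop("empty p-value list", call. = FALSE)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)

  used <- method
  if (method == "storey" && is.null(pi0)) {
    if (m < 50) {
      used <- "bh"
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      if (!is.finite(pi0) || pi0 <= 0) {
        used <- "bh"
        pi0 <- 1
      }
      pi0 <- min(pi0, 1)
    }
  }
  if (method == "bh") pi0 <- 1

  # BH step-up, then scale by pi0; enforce monotonicity from largest p down
  r <- rank(p, ties.method = "max")
  q <- pi0 * p * m / r
  o <- order(p, decreasing = TRUE)
  q[o] <- cummin(q[o])
  q <- pmin(q, 1)
  attr(q, "method") <- used
  if (used == "storey") attr(q, "pi0") <- pi0
  q
}

#' Differentially expanded clones between two samples
#'
#' Tests every clone in the union of the two key spaces (clones detected in
#' only one sample enter with frequency 0 on the other side) for
#' differential expansion with a two-sided Fisher exact test on estimated
#' cell counts: the 2x2 table for a clone is
#' `[est_A, cells_A - est_A; est_B, cells_B - est_B]` with estimated counts
#' from [estimate_cell_count()]. P-values are converted to q-values; a
#' clone is labeled expanded in a sample when `q < q_threshold` and its
#' frequency fold change in that direction exceeds `fc_threshold`. Clones
#' absent on one side have infinite fold change and pass the fold-change
#' criterion, so presence/absence calls rest on the q-value alone.
#'
#' @param repA,repB `tcr_repertoire` objects.
#' @param cells_A,cells_B T cells sorted for library preparation; default
#'   to each repertoire's `cell_count`.
#' @param q_threshold q-value threshold (default 0.01).
#' @param fc_threshold Frequency fold-change threshold (default 2).
#' @param q_method `"storey"` (default) or `"bh"`.
#' @return A `dex_result`: list with `table` (tibble: clone key columns,
#'   counts, frequencies, estimated cell counts, `fold_change` = freq_A /
#'   freq_B, `p_value`, `q_value`, `label` in `expanded_in_A` /
#'   `expanded_in_B` / `not_DE`), threshold metadata, totals and the
#'   q-value method actually used.
#' @export
differential_expansion <- function(repA, repB,
                                   cells_A = repA$cell_count,
                                   cells_B = repB$cell_count,
                                   q_threshold = 0.01, fc_threshold = 2,
                                   q_method = c("storey", "bh")) {
  q_method <- match.arg(q_method)
  assert_repertoire(repA)
  assert_repertoire(repB)
  if (is.na(cells_A) || is.na(cells_B) || cells_A < 1 || cells_B < 1) {
    stop("positive cell counts are required for both samples", call. = FALSE)
  }

  uni <- full_join(
    repA$clones[, c("v", "j", "cdr3nt", "cdr3aa", "count", "freq")],
    repB$clones[, c("v", "j", "cdr3nt", "cdr3aa", "count", "freq")],
    by = c("v", "j", "cdr3nt"), suffix = c("_a", "_b")
  ) |>
    mutate(
      cdr3aa = ifelse(is.na(.data$cdr3aa_a), .data$cdr3aa_b, .data$cdr3aa_a),
      count_a = ifelse(is.na(.data$count_a), 0, .data$count_a),
      count_b = ifelse(is.na(.data$count_b), 0, .data$count_b),
      freq_a = ifelse(is.na(.data$freq_a), 0, .data$freq_a),
      freq_b = ifelse(is.na(.data$freq_b), 0, .data$freq_b)
    )

  est_a <- estimate_cell_count(uni$freq_a, cells_A)
  est_b <- estimate_cell_count(uni$freq_b, cells_B)
  p <- fisher_two_sided(est_a, cells_A - est_a, est_b, cells_B - est_b)
  q <- q_values(p, method = q_method)

  fc <- uni$freq_a / uni$freq_b  # Inf when absent in B, 0 when absent in A
  label <- rep("not_DE", nrow(uni))
  label[q < q_threshold & fc > fc_threshold] <- "expanded_in_A"
  label[q < q_threshold & (1 / fc) > fc_threshold] <- "expanded_in_B"

  tab <- tibble(
    v = uni$v, j = uni$j, cdr3nt = uni$cdr3nt, cdr3aa = uni$cdr3aa,
    count_a = uni$count_a, count_b = uni$count_b,
    freq_a = uni$freq_a, freq_b = uni$freq_b,
    est_count_a = est_a, est_count_b = est_b,
    fold_change = fc, p_value = p, q_value = as.numeric(q),
    label = label
  ) |>
    arrange(.data$q_value, .data$p_value, .data$cdr3nt)

  structure(
    list(
      sample_a = repA$sample_id, sample_b = repB$sample_id,
      table = tab, cells_a = cells_A, cells_b = cells_B,
      q_threshold = q_threshold, fc_threshold = fc_threshold,
      q_method = attr(q, "method"),
      n_expanded_a = sum(tab$label == "expanded_in_A"),
      n_expanded_b = sum(tab$label == "expanded_in_B")
    ),
    class = "dex_result"
  )
}

#' @export
print.dex_result <- function(x, ...) {
  cat("<dex_result> ", x$sample_a, " vs ", x$sample_b, "\n", sep = "")
  cat(sprintf("  clone universe: %d   expanded in A: %d   expanded in B: %d\n",
              nrow(x$table), x$n_expanded_a, x$n_expanded_b))
  cat(sprintf("  thresholds: q < %g, fold change > %g (q method: %s)\n",
              x$q_threshold, x$fc_threshold, x$q_method))
  invisible(x)
}

#' Write a differential-expansion table to TSV
#'
#' One row per clone with metadata header lines prefixed `#` recording the
#' samples, cell totals, thresholds and q-value method.
#'
#' @param dex A `dex_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dex_table <- function(dex, path) {
  stopifnot(inherits(dex, "dex_result"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# sample_a=", dex$sample_a, " sample_b=", dex$sample_b),
    paste0("# cells_a=", dex$cells_a, " cells_b=", dex$cells_b),
    paste0("# q_threshold=", dex$q_threshold,
           " fc_threshold=", dex$fc_threshold,
           " q_method=", dex$q_method)
  ), con)
  utils::write.table(as.data.frame(dex$table), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
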