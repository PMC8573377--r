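#' Pairwise similarity/overlap matrix across samples
#'
#' Computes a chosen pair statistic (total overlap frequency or
#' Morisita-Horn similarity) for every unordered pair of repertoires and
#' fills a symmetric matrix with unit diagonal. All repertoires must share
#' the same T-cell subset unless `allow_mixed_subsets = TRUE`.
#'
#' @param reps List of `tcr_repertoire` objects (at least 2).
#' @param statistic `"overlap_frequency"` or `"morisita_horn"`.
#' @param total_mode Overlap-total mode passed to [overlap()].
#' @param allow_mixed_subsets Permit mixing CD4 and CD8 samples?
#' @return A `pairwise_matrix`: list with `sample_ids`, `matrix`
#'   (symmetric, named dims) and `statistic`.
#' @export
pairwise_matrix <- function(reps,
                            statistic = c("overlap_frequency",
                                          "morisita_horn"),
                            total_mode = "geomean_of_totals",
                            allow_mixed_subsets = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(length(reps) >= 2)
  lapply(reps, assert_repertoire)
  subsets <- unique(stats::na.omit(
    vapply(reps, function(r) r$subset, character(1))))
  if (length(subsets) > 1 && !allow_mixed_subsets) {
    stop("repertoires mix subsets (", paste(subsets, collapse = ", "),
         "); set allow_mixed_subsets = TRUE to override", call. = FALSE)
  }
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  k <- length(reps)
  m <- diag(1, k)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      val <- if (statistic == "morisita_horn") {
        morisita_horn(reps[[i]], reps[[j]])
      } else {
        overlap(reps[[i]], reps[[j]],
                total_mode = total_mode)$total_overlap_frequency
      }
      m[i, j] <- m[j, i] <- val
    }
  }
  structure(list(sample_ids = ids, matrix = m, statistic = statistic),
            class = "pairwise_matrix")
}

new_grouped_comparison <- function(groups, pairs, statistic, paired) {
  test <- if (all(lengths(groups) >= 2)) {
    compare_groups(groups[[1]], groups[[2]], paired = paired)
  } else {
    NULL
  }
  structure(
    list(groups = groups, pairs = pairs, statistic = statistic,
         paired = paired, test = test),
    class = "grouped_comparison"
  )
}

#' @export
print.grouped_comparison <- function(x, ...) {
  cat("<grouped_comparison> statistic:", x$statistic, "\n")
  for (g in names(x$groups)) {
    cat(sprintf("  %s: n = %d, mean = %.4g\n", g, length(x$groups[[g]]),
                mean(x$groups[[g]])))
  }
  if (!is.null(x$test)) {
    cat(sprintf("  %s test: t = %.3f, p = %.3g\n",
                if (x$paired) "paired" else "unpaired",
                x$test$statistic, x$test$p_value))
  }
  invisible(x)
}

pair_stat <- function(repA, repB, statistic, total_mode) {
  if (statistic == "morisita_horn") {
    morisita_horn(repA, repB)
  } else {
    overlap(repA, repB, total_mode = total_mode)$total_overlap_frequency
  }
}

#' Within- versus between-mouse comparison of paired samples
#'
#' Within-mouse values are the left-versus-right pair statistic for each
#' mouse (n values for n mice). Between-mouse values follow the
#' one-value-per-ordered-mouse-pair convention, n x (n - 1) values for n
#' mice: the statistic is computed between the per-mouse repertoires pooled
#' across sides, and each unordered mouse pair contributes its value twice.
#' Groups are compared with an unpaired two-sided Student's t-test.
#'
#' @param reps List of `tcr_repertoire` objects, one per mouse and side
#'   (each needs `mouse_id` and `side` metadata).
#' @param statistic `"overlap_frequency"` or `"morisita_horn"`.
#' @param total_mode Overlap-total mode.
#' @return A `grouped_comparison` with groups `within_mouse` and
#'   `between_mouse`.
#' @export
within_between_mouse <- function(reps,
                                 statistic = c("overlap_frequency",
                                               "morisita_horn"),
                                 total_mode = "geomean_of_totals") {
  statistic <- match.arg(statistic)
  lapply(reps, assert_repertoire)
  meta <- tibble(
    idx = seq_along(reps),
    mouse = vapply(reps, function(r) r$mouse_id, character(1)),
    side = vapply(reps, function(r) r$side, character(1))
  )
  if (any(is.na(meta$mouse)) || any(is.na(meta$side))) {
    stop("every repertoire needs mouse_id and side metadata", call. = FALSE)
  }
  mice <- unique(meta$mouse)

  within <- numeric(0)
  within_pairs <- NULL
  for (m in mice) {
    li <- meta$idx[meta$mouse == m & meta$side == "left"]
    ri <- meta$idx[meta$mouse == m & meta$side == "right"]
    if (length(li) != 1 || length(ri) != 1) {
      stop("mouse ", m, " must have exactly one left and one right sample",
           call. = FALSE)
    }
    within <- c(within, pair_stat(reps[[li]], reps[[ri]], statistic,
                                  total_mode))
    within_pairs <- bind_rows(within_pairs,
                              tibble(group = "within_mouse", a = m, b = m))
  }

  between <- numeric(0)
  between_pairs <- NULL
  if (length(mice) >= 2) {
    pooled <- lapply(mice, function(m) {
      pool_repertoires(reps[meta$idx[meta$mouse == m]],
                       sample_id = paste0(m, "_pooled"))
    })
    names(pooled) <- mice
    for (m1 in mice) for (m2 in mice) {
      if (m1 == m2) next
      between <- c(between, pair_stat(pooled[[m1]], pooled[[m2]], statistic,
                                      total_mode))
      between_pairs <- bind_rows(between_pairs,
                                 tibble(group = "between_mouse",
                                        a = m1, b = m2))
    }
  } else {
    warning("only one mouse present; between-mouse group is empty",
            call. = FALSE)
  }

  new_grouped_comparison(
    groups = list(within_mouse = within, between_mouse = between),
    pairs = bind_rows(within_pairs, between_pairs),
    statistic = statistic, paired = FALSE
  )
}

#' Within-tumor versus between-tumor fragment heterogeneity
#'
#' Each tumor is cut into two fragments sequenced separately. Within-tumor
#' values are the fragment-pair statistic inside one side (2 per mouse);
#' between-tumor values cross the sides (2 x 2 = 4 per mouse). Groups are
#' compared with an unpaired two-sided Student's t-test.
#'
#' @param fragments List of fragment `tcr_repertoire` objects with
#'   `mouse_id`, `side` and `fragment` metadata; every mouse-side must
#'   contribute exactly 2 fragments.
#' @param statistic `"overlap_frequency"` or `"morisita_horn"`.
#' @param total_mode Overlap-total mode.
#' @return A `grouped_comparison` with groups `within_tumor` and
#'   `between_tumor`.
#' @export
fragment_heterogeneity <- function(fragments,
                                   statistic = c("overlap_frequency",
                                                 "morisita_horn"),
                                   total_mode = "geomean_of_totals") {
  statistic <- match.arg(statistic)
  lapply(fragments, assert_repertoire)
  meta <- tibble(
    idx = seq_along(fragments),
    mouse = vapply(fragments, function(r) r$mouse_id, character(1)),
    side = vapply(fragments, function(r) r$side, character(1))
  )
  within <- numeric(0)
  between <- numeric(0)
  pairs <- NULL
  for (m in unique(meta$mouse)) {
    li <- meta$idx[meta$mouse == m & meta$side == "left"]
    ri <- meta$idx[meta$mouse == m & meta$side == "right"]
    if (length(li) != 2 || length(ri) != 2) {
      stop("mouse ", m, " must have exactly 2 fragments per side",
           call. = FALSE)
    }
    within <- c(within,
                pair_stat(fragments[[li[1]]], fragments[[li[2]]],
                          statistic, total_mode),
                pair_stat(fragments[[ri[1]]], fragments[[ri[2]]],
                          statistic, total_mode))
    pairs <- bind_rows(pairs,
                       tibble(group = "within_tumor", mouse = m,
                              side = c("left", "right")))
    for (i in li) for (j in ri) {
      between <- c(between,
                   pair_stat(fragments[[i]], fragments[[j]], statistic,
                             total_mode))
      pairs <- bind_rows(pairs,
                         tibble(group = "between_tumor", mouse = m,
                                side = "cross"))
    }
  }
  new_grouped_comparison(
    groups = list(within_tumor = within, between_tumor = between),
    pairs = pairs, statistic = statistic, paired = FALSE
  )
}

#' dLN repertoire restricted to clones shared with either tumor
#'
#' Filters a draining-lymph-node repertoire to the clones detected in
#' either the left or right tumor of the same mouse, enriching
#' tumor-associated clones. Original dLN counts are retained and, by
#' default, frequencies stay relative to the whole dLN (the overlapping
#' repertoire is a subset of the dLN distribution); set
#' `renormalize = TRUE` to recompute frequencies within the filtered set.
#'
#' @param dln dLN `tcr_repertoire`.
#' @param tumor_left,tumor_right Tumor `tcr_repertoire` objects.
#' @param renormalize Recompute frequencies within the filtered set?
#' @return A `tcr_repertoire` (possibly with zero clones, flagged with a
#'   warning, when the intersection is empty).
#' @export
dln_tumor_overlap_repertoire <- function(dln, tumor_left, tumor_right,
                                         renormalize = FALSE) {
  assert_repertoire(dln)
  assert_repertoire(tumor_left)
  assert_repertoire(tumor_right)
  tumor_keys <- unique(c(
    clone_key(tumor_left$clones$v, tumor_left$clones$j,
              tumor_left$clones$cdr3nt),
    clone_key(tumor_right$clones$v, tumor_right$clones$j,
              tumor_right$clones$cdr3nt)
  ))
  keep <- clone_key(dln$clones$v, dln$clones$j, dln$clones$cdr3nt) %in%
    tumor_keys
  out <- dln
  out$sample_id <- paste0(dln$sample_id, "_OL")
  out$clones <- dln$clones[keep, ]
  if (nrow(out$clones) == 0) {
    warning("no dLN clones shared with either tumor for ", dln$sample_id,
            call. = FALSE)
    return(out)
  }
  if (renormalize) out$clones$freq <- out$clones$count / sum(out$clones$count)
  out
}

#' Left-right concordance within dLN-tumor overlapping repertoires
#'
#' Given the left and right dLN repertoires already restricted to
#' tumor-shared clones (see [dln_tumor_overlap_repertoire()]), summarizes
#' how much of each side is shared with the other. The frequency-weighted
#' share is the total overlap frequency computed on frequencies
#' renormalized within each overlapping repertoire (shared mass over total
#' mass of the OL set, combined as a geometric mean); the count shares are
#' the fraction of each side's OL clones found on the other side; the
#' correlation is Pearson's r of log10 frequencies over the shared clones
#' (undefined, `NA`, with fewer than 3 shared clones). A linear-scale r is
#' also reported.
#'
#' @param olL,olR Left and right OL `tcr_repertoire` objects.
#' @return List with `frequency_weighted_share`, `clone_count_share_L`,
#'   `clone_count_share_R`, `n_shared`, `pearson_r_log10`,
#'   `pearson_r_linear`.
#' @export
left_right_overlap_within_OL <- function(olL, olR) {
  assert_repertoire(olL)
  assert_repertoire(olR)
  sh <- shared_clones(olL, olR)
  share_l <- sum(sh$count_a) / sum(olL$clones$count)
  share_r <- sum(sh$count_b) / sum(olR$clones$count)
  r_log <- r_lin <- NA_real_
  if (nrow(sh) >= 3) {
    # renormalization within the OL sets shifts log frequencies by a
    # constant, so r is computed on within-OL frequencies
    fl <- sh$count_a / sum(olL$clones$count)
    fr <- sh$count_b / sum(olR$clones$count)
    r_log <- stats::cor(log10(fl), log10(fr))
    r_lin <- stats::cor(fl, fr)
  }
  list(
    frequency_weighted_share = sqrt(share_l * share_r),
    clone_count_share_L = nrow(sh) / n_clones(olL),
    clone_count_share_R = nrow(sh) / n_clones(olR),
    n_shared = nrow(sh),
    pearson_r_log10 = r_log,
    pearson_r_linear = r_lin
  )
}

#' Ipsilateral versus contralateral dLN-tumor overlap
#'
#' For every dLN, computes the total overlap frequency with its same-side
#' (ipsilateral) and opposite-side (contralateral) tumor, then compares the
#' two with a two-sided paired Student's t-test across all dLNs (2 per
#' mouse). Under perfect circulation mixing the two are equal in
#' expectation.
#'
#' @param dlns List of dLN `tcr_repertoire` objects (one per mouse-side).
#' @param tumors List of tumor `tcr_repertoire` objects (one per
#'   mouse-side, fragments pooled).
#' @param total_mode Overlap-total mode.
#' @return A `grouped_comparison` with paired groups `ipsilateral` and
#'   `contralateral`, plus a `pairs` tibble of the per-dLN values.
#' @export
ipsi_contra_comparison <- function(dlns, tumors,
                                   total_mode = "geomean_of_totals") {
  lapply(c(dlns, tumors), assert_repertoire)
  key <- function(r) paste(r$mouse_id, r$side, sep = "|")
  tumor_map <- stats::setNames(tumors, vapply(tumors, key, character(1)))
  other <- c(left = "right", right = "left")
  ipsi <- contra <- numeric(0)
  rows <- NULL
  for (d in dlns) {
    ik <- paste(d$mouse_id, d$side, sep = "|")
    ck <- paste(d$mouse_id, other[[d$side]], sep = "|")
    if (!ik %in% names(tumor_map) || !ck %in% names(tumor_map)) {
      stop("mouse ", d$mouse_id, " is missing a tumor side", call. = FALSE)
    }
    iv <- overlap(d, tumor_map[[ik]],
                  total_mode = total_mode)$total_overlap_frequency
    cv <- overlap(d, tumor_map[[ck]],
                  total_mode = total_mode)$total_overlap_frequency
    ipsi <- c(ipsi, iv)
    contra <- c(contra, cv)
    rows <- bind_rows(rows, tibble(mouse = d$mouse_id, dln_side = d$side,
                                   ipsi = iv, contra = cv))
  }
  new_grouped_comparison(
    groups = list(ipsilateral = ipsi, contralateral = contra),
    pairs = rows, statistic = "overlap_frequency", paired = TRUE
  )
}
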