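pool_by <- function(reps, keys, label) {
  groups <- split(seq_along(reps), keys)
  out <- lapply(names(groups), function(g) {
    pool_repertoires(reps[groups[[g]]], sample_id = paste0(g, label))
  })
  names(out) <- names(groups)
  out
}

matrix_to_tibble <- function(pm) {
  m <- pm$matrix
  as_tibble(cbind(data.frame(sample_id = rownames(m)), as.data.frame(m)))
}

#' Run the complete bilateral-repertoire analysis
#'
#' Orchestrates the full comparison for one dataset: every sample is
#' depth-normalized by seeded downsampling to `downsample_factor` times its
#' cell count, tumor fragments are pooled per side, and the analysis
#' emits: per-sample clonality and rank-class breakdowns; V/J usage
#' profiles and PCA coordinates of the pooled tumors; pairwise overlap and
#' Morisita-Horn matrices; within/between-mouse comparisons for tumors and
#' dLNs; fragment heterogeneity; dLN-tumor overlapping-repertoire
#' analyses; ipsilateral/contralateral comparison; and a differential
#' expansion table per mouse (left versus right pooled tumor). With
#' `outdir` set, all tables are written as TSV plus a machine-readable
#' `summary.json` recording seeds and thresholds; reruns with identical
#' inputs and seed produce byte-identical summaries.
#'
#' @param sheet Sample-sheet tibble or path (see [read_sample_sheet()]).
#' @param config Configuration list (see [default_config()]).
#' @param outdir Output directory, or `NULL` for in-memory results only.
#' @param reps Optional pre-loaded named list of repertoires matching the
#'   sheet (bypasses file reading, e.g. straight from
#'   [generate_dataset()]).
#' @return A result bundle (list), invisibly when writing.
#' @export
run_full_analysis <- function(sheet, config = default_config(),
                              outdir = NULL, reps = NULL) {
  if (is.character(sheet)) {
    base_dir <- dirname(sheet)
    sheet <- read_sample_sheet(sheet)
  } else {
    sheet <- validate_sample_sheet(sheet)
    base_dir <- "."
  }
  config <- utils::modifyList(default_config(), config)
  if (is.null(reps)) {
    reps <- load_samples(sheet, dialect = config$dialect,
                         base_dir = base_dir)
  } else {
    stopifnot(all(sheet$sample_id %in% names(reps)))
    reps <- reps[sheet$sample_id]
  }

  # depth normalization first, then all statistics
  ds_seeds <- derive_seeds(config$seed, length(reps))
  reps <- lapply(seq_along(reps), function(i) {
    r <- reps[[i]]
    downsample(r, default_target_reads(r$cell_count,
                                       config$downsample_factor),
               seed = ds_seeds[i], on_excess = "keep")
  })
  names(reps) <- sheet$sample_id

  is_tumor <- sheet$tissue == "tumor"
  frags <- reps[is_tumor]
  dlns <- reps[!is_tumor]
  tumors <- pool_by(frags,
                    paste(sheet$mouse_id[is_tumor], sheet$side[is_tumor],
                          sep = "_Tumor_"),
                    label = "")

  per_sample <- bind_rows(lapply(c(tumors, dlns), function(r) {
    tibble(sample_id = r$sample_id, mouse_id = r$mouse_id,
           tissue = r$tissue, side = r$side, subset = r$subset,
           n_clones = n_clones(r), total_reads = total_reads(r),
           clonality = clonality(r))
  }))
  rank_classes <- bind_rows(lapply(c(tumors, dlns), function(r) {
    rank_class_breakdown(r) |> mutate(sample_id = r$sample_id, .before = 1)
  }))

  profiles <- lapply(tumors, usage_profile)
  pca <- usage_pca(profiles, space = "v_and_j")

  tumor_overlap_mx <- pairwise_matrix(tumors, "overlap_frequency",
                                      total_mode = config$overlap_total_mode)
  tumor_mh_mx <- pairwise_matrix(tumors, "morisita_horn")
  dln_overlap_mx <- pairwise_matrix(dlns, "overlap_frequency",
                                    total_mode = config$overlap_total_mode)

  tumor_wb <- within_between_mouse(tumors, "overlap_frequency",
                                   total_mode = config$overlap_total_mode)
  tumor_wb_mh <- within_between_mouse(tumors, "morisita_horn")
  dln_wb <- within_between_mouse(dlns, "overlap_frequency",
                                 total_mode = config$overlap_total_mode)
  frag_het <- fragment_heterogeneity(frags, "overlap_frequency",
                                     total_mode = config$overlap_total_mode)

  clon_by_mouse <- split(
    per_sample$clonality[per_sample$tissue == "tumor"],
    per_sample$mouse_id[per_sample$tissue == "tumor"]
  )
  clon_anova <- clonality_variance_decomposition(clon_by_mouse)

  # dLN-tumor overlapping repertoires and left-right concordance
  mice <- unique(sheet$mouse_id)
  side_key <- function(rs) vapply(rs, function(r)
    paste(r$mouse_id, r$side, sep = "|"), character(1))
  tumor_map <- stats::setNames(tumors, side_key(tumors))
  dln_map <- stats::setNames(dlns, side_key(dlns))
  ol_summary <- bind_rows(lapply(mice, function(m) {
    tl <- tumor_map[[paste(m, "left", sep = "|")]]
    tr <- tumor_map[[paste(m, "right", sep = "|")]]
    ol_l <- dln_tumor_overlap_repertoire(dln_map[[paste(m, "left",
                                                        sep = "|")]], tl, tr)
    ol_r <- dln_tumor_overlap_repertoire(dln_map[[paste(m, "right",
                                                        sep = "|")]], tl, tr)
    lr <- left_right_overlap_within_OL(ol_l, ol_r)
    tibble(mouse_id = m,
           frequency_weighted_share = lr$frequency_weighted_share,
           clone_count_share_L = lr$clone_count_share_L,
           clone_count_share_R = lr$clone_count_share_R,
           n_shared = lr$n_shared, pearson_r_log10 = lr$pearson_r_log10)
  }))

  ipsi_contra <- ipsi_contra_comparison(dlns, tumors,
                                        total_mode = config$overlap_total_mode)

  dex <- lapply(mice, function(m) {
    differential_expansion(
      tumor_map[[paste(m, "left", sep = "|")]],
      tumor_map[[paste(m, "right", sep = "|")]],
      q_threshold = config$q_threshold,
      fc_threshold = config$fc_threshold,
      q_method = config$q_method
    )
  })
  names(dex) <- mice

  bundle <- list(
    config = config,
    per_sample = per_sample,
    rank_classes = rank_classes,
    usage_pca = pca,
    matrices = list(tumor_overlap = tumor_overlap_mx,
                    tumor_morisita_horn = tumor_mh_mx,
                    dln_overlap = dln_overlap_mx),
    tumor_within_between = tumor_wb,
    tumor_within_between_mh = tumor_wb_mh,
    dln_within_between = dln_wb,
    fragment_heterogeneity = frag_het,
    clonality_anova = clon_anova,
    dln_tumor_ol = ol_summary,
    ipsi_contra = ipsi_contra,
    differential_expansion = dex
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, name) {
      utils::write.table(as.data.frame(x), file.path(outdir, name),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    wt(per_sample, "per_sample_stats.tsv")
    wt(rank_classes, "rank_classes.tsv")
    wt(pca$scores, "usage_pca_scores.tsv")
    wt(matrix_to_tibble(tumor_overlap_mx), "tumor_overlap_matrix.tsv")
    wt(matrix_to_tibble(tumor_mh_mx), "tumor_morisita_horn_matrix.tsv")
    wt(matrix_to_tibble(dln_overlap_mx), "dln_overlap_matrix.tsv")
    wt(ol_summary, "dln_tumor_ol_summary.tsv")
    wt(ipsi_contra$pairs, "ipsi_contra.tsv")
    for (m in mice) {
      write_dex_table(dex[[m]], file.path(outdir, paste0("dex_", m, ".tsv")))
    }
    grp_means <- function(gc) lapply(gc$groups, function(v)
      list(n = length(v), mean = mean(v)))
    summary <- list(
      package_version = as.character(utils::packageVersion("bilatrep")),
      seed = config$seed,
      downsample_factor = config$downsample_factor,
      q_threshold = config$q_threshold,
      fc_threshold = config$fc_threshold,
      q_method = config$q_method,
      overlap_total_mode = config$overlap_total_mode,
      n_samples = length(reps),
      clonality = stats::setNames(as.list(per_sample$clonality),
                                  per_sample$sample_id),
      tumor_within_between = grp_means(tumor_wb),
      tumor_within_between_mh = grp_means(tumor_wb_mh),
      dln_within_between = grp_means(dln_wb),
      fragment_heterogeneity = grp_means(frag_het),
      clonality_anova = unclass(clon_anova),
      dln_tumor_ol_mean_share = mean(ol_summary$frequency_weighted_share),
      ipsi_contra_p = ipsi_contra$test$p_value,
      n_dex_clones = lapply(dex, function(d)
        list(expanded_in_left = d$n_expanded_a,
             expanded_in_right = d$n_expanded_b))
    )
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(bundle))
  }
  bundle
}
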