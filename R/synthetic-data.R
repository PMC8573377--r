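#' @importFrom stats rnorm rlnorm runif rgamma
NULL

default_trbv <- function() {
  c("TRBV1", "TRBV2", "TRBV3", "TRBV4", "TRBV5", "TRBV12-1", "TRBV12-2",
    "TRBV13-1", "TRBV13-2", "TRBV13-3", "TRBV14", "TRBV15", "TRBV16",
    "TRBV17", "TRBV19", "TRBV20", "TRBV23", "TRBV26", "TRBV29", "TRBV31")
}

default_trbj <- function() {
  c("TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5", "TRBJ1-6",
    "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4", "TRBJ2-5", "TRBJ2-7")
}

# the 61 sense codons with their amino acids, derived once via seqinr
sense_codons <- function() {
  if (is.null(.bilatrep_cache$sense)) {
    nts <- c("A", "C", "G", "T")
    codons <- apply(expand.grid(nts, nts, nts, stringsAsFactors = FALSE),
                    1, paste0, collapse = "")
    aa <- vapply(codons, function(cd) {
      seqinr::translate(strsplit(cd, "")[[1]])
    }, character(1))
    keep <- aa != "*"
    .bilatrep_cache$sense <- stats::setNames(aa[keep], codons[keep])
  }
  .bilatrep_cache$sense
}

translate_cdr3 <- function(cdr3nt) {
  tab <- sense_codons()
  lens <- nchar(cdr3nt)
  out <- character(length(cdr3nt))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    starts <- seq(1, L, by = 3)
    aam <- matrix("", nrow = length(idx), ncol = length(starts))
    for (k in seq_along(starts)) {
      aam[, k] <- tab[substr(cdr3nt[idx], starts[k], starts[k] + 2)]
    }
    out[idx] <- do.call(paste0, asplit(aam, 2))
  }
  out
}

#' Configuration of the synthetic bilateral-tumor generator
#'
#' All parameters of the proportional-infiltration model: per-mouse private
#' clone key spaces, heavy-tailed (log-normal) clonal expansion, partial
#' left/right dLN priming overlap, mixing of primed clones in circulation,
#' proportional seeding of both tumors with in-situ expansion noise, tumor
#' fragmentation, and finite read sampling at `reads_factor` times the cell
#' count. See the package vignette for the rationale behind each default.
#'
#' @param n_mice Number of mice (default 4).
#' @param n_reactive_clones Tumor-reactive clones per mouse (default 500).
#' @param n_bystander_dln_clones Non-tumor-associated CD44hi clones per dLN
#'   (default 20000); these never enter tumors.
#' @param n_bystander_tumor_clones Locally detected non-reactive clones per
#'   tumor (default 5000).
#' @param p_dual_priming Probability a reactive clone is primed in both
#'   dLNs (default 0.5); the rest split evenly left/right.
#' @param expansion_lognormal_sigma Log-scale sigma of latent clonal
#'   expansion (default 2.0).
#' @param dln_expansion_correlation Log-scale Pearson correlation of the
#'   left/right latent expansions of dual-primed clones (default 0.4).
#' @param tumor_insitu_shared_sigma Log-scale sigma of the per-clone
#'   in-situ expansion factor shared by both tumors (default 1.0).
#' @param tumor_insitu_noise_sigma Log-scale sigma of per-tumor expansion
#'   noise (default 0.3).
#' @param fragment_noise_sigma Log-scale sigma of per-fragment spatial
#'   noise (default 0.15).
#' @param public_clone_fraction Fraction of clone keys drawn from a shared
#'   cross-mouse public pool (default 0.01).
#' @param n_public_pool Size of the public key pool (default 1000).
#' @param tumor_reactive_mass_fraction Latent mass share of tumor-reactive
#'   clones within each tumor (default 0.80), fixing how strongly in-situ
#'   expansion amplifies infiltrating clones over local bystanders.
#' @param cells_per_tumor_sample,cells_per_dln_sample Sorted T cells per
#'   tumor-fragment / dLN sample (default 10000 each).
#' @param reads_factor Reads sequenced per sorted cell (default 6).
#' @param v_segment_vocabulary,j_segment_vocabulary Segment name pools.
#' @param v_usage_concentration Dirichlet concentration of each mouse's V
#'   usage (default 2; smaller values make usage cluster more strongly by
#'   mouse).
#' @param cdr3_length_range In-frame CDR3 nucleotide length range, both
#'   ends multiples of 3 (default 30-45).
#' @param subset T-cell subset label for emitted samples (default "CD8").
#' @param seed Master seed (default 1).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_mice = 4L,
                             n_reactive_clones = 500L,
                             n_bystander_dln_clones = 20000L,
                             n_bystander_tumor_clones = 5000L,
                             p_dual_priming = 0.5,
                             expansion_lognormal_sigma = 2.0,
                             dln_expansion_correlation = 0.4,
                             tumor_insitu_shared_sigma = 1.0,
                             tumor_insitu_noise_sigma = 0.3,
                             fragment_noise_sigma = 0.15,
                             public_clone_fraction = 0.01,
                             n_public_pool = 1000L,
                             tumor_reactive_mass_fraction = 0.80,
                             cells_per_tumor_sample = 10000L,
                             cells_per_dln_sample = 10000L,
                             reads_factor = 6L,
                             v_segment_vocabulary = default_trbv(),
                             j_segment_vocabulary = default_trbj(),
                             v_usage_concentration = 2,
                             cdr3_length_range = c(30L, 45L),
                             subset = "CD8",
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(p_dual_priming, public_clone_fraction,
             tumor_reactive_mass_fraction, dln_expansion_correlation)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities and fractions must lie in [0, 1]", call. = FALSE)
  }
  sig <- c(expansion_lognormal_sigma, tumor_insitu_shared_sigma,
           tumor_insitu_noise_sigma, fragment_noise_sigma)
  if (any(sig < 0)) stop("sigmas must be non-negative", call. = FALSE)
  if (length(v_segment_vocabulary) == 0 ||
      length(j_segment_vocabulary) == 0) {
    stop("segment vocabularies must be non-empty", call. = FALSE)
  }
  if (length(cdr3_length_range) != 2 ||
      any(cdr3_length_range %% 3 != 0) ||
      any(cdr3_length_range < 3) ||
      cdr3_length_range[1] > cdr3_length_range[2]) {
    stop("cdr3_length_range must be an increasing pair of positive ",
         "multiples of 3", call. = FALSE)
  }
  counts <- c(n_mice, n_reactive_clones, n_bystander_dln_clones,
              n_bystander_tumor_clones, cells_per_tumor_sample,
              cells_per_dln_sample, reads_factor, n_public_pool)
  if (any(counts < 1)) stop("counts must be positive", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

random_cdr3 <- function(n, config) {
  lens <- seq(config$cdr3_length_range[1], config$cdr3_length_range[2],
              by = 3L)
  n_codons <- sample(lens / 3L, n, replace = TRUE)
  codons <- names(sense_codons())
  draws <- sample(codons, sum(n_codons), replace = TRUE)
  grp <- factor(rep.int(seq_len(n), n_codons), levels = seq_len(n))
  unname(vapply(split(draws, grp), paste0, character(1), collapse = ""))
}

#' Generate unique clone keys
#'
#' Draws V segments from the supplied usage weights (per-mouse Dirichlet
#' weights make V usage cluster by mouse), J segments uniformly, and
#' in-frame CDR3 nucleotide sequences from the 61 sense codons (so every
#' clone is productive; the amino-acid CDR3 is the standard-code
#' translation). A `public_clone_fraction` of keys is replaced by draws
#' from the shared cross-mouse public pool. Keys are unique within the
#' call and disjoint from `exclude`.
#'
#' @param n Number of keys.
#' @param config A `synthetic_config`.
#' @param v_probs Optional V-segment weights (default uniform).
#' @param public_pool Optional tibble of public keys (`v`, `j`, `cdr3nt`,
#'   `cdr3aa`).
#' @param exclude Character vector of key strings to avoid.
#' @param seed Optional seed (the surrounding generator seeds the stream).
#' @return Tibble with columns `v`, `j`, `cdr3nt`, `cdr3aa`.
#' @export
generate_clone_keys <- function(n, config, v_probs = NULL,
                                public_pool = NULL, exclude = character(0),
                                seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    vv <- config$v_segment_vocabulary
    if (is.null(v_probs)) v_probs <- rep(1 / length(vv), length(vv))
    draw <- function(k) {
      tibble(
        v = sample(vv, k, replace = TRUE, prob = v_probs),
        j = sample(config$j_segment_vocabulary, k, replace = TRUE),
        cdr3nt = random_cdr3(k, config)
      )
    }
    keys <- draw(n)
    if (!is.null(public_pool) && config$public_clone_fraction > 0) {
      idx <- which(runif(n) < config$public_clone_fraction)
      if (length(idx) > 0) {
        pick <- sample.int(nrow(public_pool), length(idx), replace = TRUE)
        keys[idx, c("v", "j", "cdr3nt")] <-
          public_pool[pick, c("v", "j", "cdr3nt")]
      }
    }
    # enforce uniqueness (also against exclude) by redrawing private keys
    for (i in 1:20) {
      ks <- clone_key(keys$v, keys$j, keys$cdr3nt)
      bad <- which(duplicated(ks) | ks %in% exclude)
      if (length(bad) == 0) break
      keys[bad, ] <- draw(length(bad))
    }
    keys$cdr3aa <- translate_cdr3(keys$cdr3nt)
    keys
  })
}

sample_reads <- function(masses, n_reads) {
  as.numeric(rmultinom(1, n_reads, masses))
}

# correlated standard-normal pair with correlation r (shared + independent
# Gaussian decomposition)
corr_normals <- function(n, r) {
  z0 <- rnorm(n); z1 <- rnorm(n); z2 <- rnorm(n)
  list(left = sqrt(r) * z0 + sqrt(1 - r) * z1,
       right = sqrt(r) * z0 + sqrt(1 - r) * z2)
}

#' Simulate one mouse of the bilateral-tumor model
#'
#' Implements the proportional-infiltration mechanism: (1) each
#' tumor-reactive clone is primed in the left dLN, right dLN or both
#' (probability `p_dual_priming`), with log-normal latent expansions that
#' are log-scale correlated between sides for dual-primed clones; (2) each
#' CD44hi dLN sample is the primed reactive clones plus private bystander
#' clones, read-sampled to `reads_factor` x cell count; (3) the circulating
#' tumor-reactive distribution is the per-clone sum of the two dLN latent
#' outputs; (4) each tumor receives every circulating clone in proportion
#' to its circulating mass, times a per-clone in-situ expansion factor
#' shared by both tumors and per-tumor log-normal noise, plus private
#' tumor bystander clones; (5) each tumor is split into two fragments with
#' per-fragment log-normal noise before read sampling.
#'
#' @param config A `synthetic_config`.
#' @param mouse_id Mouse label.
#' @param seed Seed for this mouse.
#' @param public_pool Shared public key pool tibble (or `NULL`).
#' @return List with `repertoires` (named list: 2 dLNs and 4 tumor
#'   fragments) and `truth` (per-clone provenance tibble).
#' @export
generate_mouse <- function(config, mouse_id = "m1", seed = NULL,
                           public_pool = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    sig <- config$expansion_lognormal_sigma
    used <- character(0)

    # per-mouse V usage (clusters V/J usage by mouse)
    v_probs <- rgamma(length(config$v_segment_vocabulary),
                      shape = config$v_usage_concentration)
    v_probs <- v_probs / sum(v_probs)

    ## (1) reactive clones and dLN priming
    n_r <- config$n_reactive_clones
    reactive <- generate_clone_keys(n_r, config, v_probs = v_probs,
                                    public_pool = public_pool)
    used <- clone_key(reactive$v, reactive$j, reactive$cdr3nt)
    u <- runif(n_r)
    dual <- u < config$p_dual_priming
    left_only <- !dual & runif(n_r) < 0.5
    right_only <- !dual & !left_only
    z <- corr_normals(n_r, config$dln_expansion_correlation)
    w_left <- ifelse(dual | left_only, exp(sig * z$left), 0)
    w_right <- ifelse(dual | right_only, exp(sig * z$right), 0)

    ## (2) dLN samples
    n_bd <- config$n_bystander_dln_clones
    dln_reads <- config$reads_factor * config$cells_per_dln_sample
    make_dln <- function(side, w) {
      bys <- generate_clone_keys(n_bd, config, v_probs = v_probs,
                                 public_pool = public_pool, exclude = used)
      used <<- c(used, clone_key(bys$v, bys$j, bys$cdr3nt))
      # raw latent masses: primed reactive clones sit among the bystanders
      # at whatever share their expansions give them
      w_b <- rlnorm(n_bd, 0, sig)
      sel <- which(w > 0)
      tab <- bind_rows(
        reactive[sel, ] |> mutate(mass = w[sel]),
        bys |> mutate(mass = w_b)
      )
      counts <- sample_reads(tab$mass, dln_reads)
      rep <- make_repertoire(
        tab |> mutate(count = counts) |> filter(count > 0),
        sample_id = paste0(mouse_id, "_dLN_", side),
        mouse_id = mouse_id, tissue = "dLN", side = side,
        subset = config$subset,
        cell_count = config$cells_per_dln_sample
      )
      list(rep = rep, bys = bys, w_b = w_b)
    }
    dln_l <- make_dln("left", w_left)
    dln_r <- make_dln("right", w_right)

    ## (3) circulation: mixed output of both dLNs
    circulating <- w_left + w_right
    s_shared <- rlnorm(n_r, 0, config$tumor_insitu_shared_sigma)

    ## (4)+(5) tumors and fragments
    n_bt <- config$n_bystander_tumor_clones
    frag_reads <- config$reads_factor * config$cells_per_tumor_sample
    make_tumor <- function(side) {
      noise <- rlnorm(n_r, 0, config$tumor_insitu_noise_sigma)
      mass_r <- circulating * s_shared * noise
      bys <- generate_clone_keys(n_bt, config, v_probs = v_probs,
                                 public_pool = public_pool, exclude = used)
      used <<- c(used, clone_key(bys$v, bys$j, bys$cdr3nt))
      w_b <- rlnorm(n_bt, 0, sig)
      f <- config$tumor_reactive_mass_fraction
      w_b <- w_b * ((1 - f) / f) * sum(mass_r) / sum(w_b)
      tab <- bind_rows(
        reactive |> mutate(mass = mass_r),
        bys |> mutate(mass = w_b)
      )
      frags <- lapply(1:2, function(k) {
        fm <- tab$mass * rlnorm(nrow(tab), 0, config$fragment_noise_sigma)
        counts <- sample_reads(fm, frag_reads)
        make_repertoire(
          tab |> mutate(count = counts) |> filter(count > 0),
          sample_id = paste0(mouse_id, "_Tumor_", side, "_f", k),
          mouse_id = mouse_id, tissue = "tumor", side = side,
          subset = config$subset, fragment = paste0("f", k),
          cell_count = config$cells_per_tumor_sample
        )
      })
      list(frags = frags, bys = bys, w_b = w_b, mass_r = mass_r)
    }
    tum_l <- make_tumor("left")
    tum_r <- make_tumor("right")

    truth <- bind_rows(
      reactive |>
        mutate(category = "reactive",
               primed_left = dual | left_only,
               primed_right = dual | right_only,
               latent_dln_left = w_left, latent_dln_right = w_right,
               latent_tumor_left = tum_l$mass_r,
               latent_tumor_right = tum_r$mass_r),
      dln_l$bys |> mutate(category = "dln_bystander_left",
                          latent_dln_left = dln_l$w_b),
      dln_r$bys |> mutate(category = "dln_bystander_right",
                          latent_dln_right = dln_r$w_b),
      tum_l$bys |> mutate(category = "tumor_bystander_left",
                          latent_tumor_left = tum_l$w_b),
      tum_r$bys |> mutate(category = "tumor_bystander_right",
                          latent_tumor_right = tum_r$w_b)
    ) |>
      mutate(
        mouse_id = mouse_id,
        primed_left = ifelse(is.na(.data$primed_left), FALSE,
                             .data$primed_left),
        primed_right = ifelse(is.na(.data$primed_right), FALSE,
                              .data$primed_right)
      )

    reps <- c(
      stats::setNames(list(dln_l$rep, dln_r$rep),
                      c(paste0(mouse_id, "_dLN_left"),
                        paste0(mouse_id, "_dLN_right"))),
      stats::setNames(tum_l$frags,
                      paste0(mouse_id, "_Tumor_left_f", 1:2)),
      stats::setNames(tum_r$frags,
                      paste0(mouse_id, "_Tumor_right_f", 1:2))
    )
    list(repertoires = reps, truth = truth)
  })
}

#' Generate a full synthetic bilateral-tumor dataset
#'
#' Simulates `n_mice` mice (see [generate_mouse()]) with a shared public
#' clone pool, and optionally writes the dataset to disk: one
#' VDJtools-dialect clone table per sample, a sample sheet ingestible by
#' [read_sample_sheet()], a per-clone ground-truth TSV for
#' parameter-recovery checks, and a YAML echo of the configuration. Fully
#' reproducible from the seed.
#'
#' @param config A `synthetic_config`.
#' @param outdir Output directory, or `NULL` (default) to keep the dataset
#'   in memory only.
#' @param seed Overrides `config$seed` when given.
#' @return (Invisibly when writing) a list with `repertoires` (named list,
#'   `n_mice * 6` samples), `sheet` (sample-sheet tibble), `truth` and
#'   `config`.
#' @export
generate_dataset <- function(config = synthetic_config(), outdir = NULL,
                             seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- seed %||% config$seed
  mice <- paste0("m", seq_len(config$n_mice))
  seeds <- derive_seeds(seed, config$n_mice + 1L)

  pool <- if (config$public_clone_fraction > 0) {
    generate_clone_keys(config$n_public_pool, config,
                        seed = seeds[config$n_mice + 1L])
  } else {
    NULL
  }

  per_mouse <- lapply(seq_along(mice), function(i) {
    generate_mouse(config, mouse_id = mice[i], seed = seeds[i],
                   public_pool = pool)
  })
  reps <- do.call(c, lapply(per_mouse, function(x) x$repertoires))
  truth <- bind_rows(lapply(per_mouse, function(x) x$truth))

  sheet <- bind_rows(lapply(reps, function(r) {
    tibble(
      sample_id = r$sample_id,
      file = paste0(r$sample_id, ".txt"),
      mouse_id = r$mouse_id, tissue = r$tissue, side = r$side,
      subset = r$subset, fragment = r$fragment, cell_count = r$cell_count
    )
  }))

  out <- list(repertoires = reps, sheet = sheet, truth = truth,
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (r in reps) {
      write_clone_table(r, file.path(outdir, paste0(r$sample_id, ".txt")))
    }
    write_sample_sheet(sheet, file.path(outdir, "sample_sheet.tsv"))
    utils::write.table(as.data.frame(truth),
                       file.path(outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- config
    class(cfg) <- NULL
    cfg$seed <- seed
    yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
    return(invisible(out))
  }
  out
}
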