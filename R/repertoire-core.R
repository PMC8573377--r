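#' @importFrom dplyr group_by summarise arrange mutate filter bind_rows
#'   bind_cols first n left_join full_join inner_join
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats rhyper rmultinom
NULL

TISSUES <- c("tumor", "dLN")
SIDES   <- c("left", "right")
SUBSETS <- c("CD4", "CD8")

# A clone is identified by (V segment, J segment, CDR3 nucleotide sequence);
# this builds the composite key string used for all set operations.
clone_key <- function(v, j, cdr3nt) paste(v, j, cdr3nt, sep = "|")

validate_cdr3nt <- function(cdr3nt) {
  cdr3nt <- toupper(as.character(cdr3nt))
  bad <- which(is.na(cdr3nt) | cdr3nt == "" | !grepl("^[ACGT]+$", cdr3nt))
  if (length(bad) > 0) {
    stop("malformed CDR3 nucleotide sequence at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (must be non-empty, A/C/G/T only)", call. = FALSE)
  }
  cdr3nt
}

#' Construct a TCR repertoire from clone records
#'
#' Builds a validated repertoire from per-clone records. Records sharing the
#' same clone key -- identical V segment, J segment and CDR3 nucleotide
#' sequence -- are merged by summing read counts (the first non-missing
#' amino-acid CDR3 annotation is kept). Zero-count records are dropped and
#' clone frequencies are recomputed as count over total reads.
#'
#' @param clones Data frame with columns `v`, `j`, `cdr3nt`, `count` and
#'   optionally `cdr3aa`. CDR3 nucleotide sequences are uppercased and must
#'   be A/C/G/T only; counts must be non-negative integers.
#' @param sample_id,mouse_id Sample and mouse identifiers.
#' @param tissue One of `"tumor"`, `"dLN"`, or `NA`.
#' @param side One of `"left"`, `"right"`, or `NA`.
#' @param subset One of `"CD4"`, `"CD8"`, or `NA`.
#' @param fragment Optional tumor-fragment label.
#' @param cell_count Sorted T-cell count used for library preparation
#'   (positive integer or `NA`).
#' @return An object of class `tcr_repertoire`: a list with the metadata
#'   fields and a `clones` tibble (`v`, `j`, `cdr3nt`, `cdr3aa`, `count`,
#'   `freq`) whose frequencies sum to 1.
#' @examples
#' rep <- make_repertoire(data.frame(
#'   v = c("TRBV1", "TRBV1", "TRBV2"), j = "TRBJ1-1",
#'   cdr3nt = c("TGTGCA", "TGTGCA", "TGTGCC"), count = c(3, 2, 5)
#' ))
#' rep$clones
#' @export
make_repertoire <- function(clones, sample_id = NA_character_,
                            mouse_id = NA_character_, tissue = NA_character_,
                            side = NA_character_, subset = NA_character_,
                            fragment = NA_character_,
                            cell_count = NA_integer_) {
  stopifnot(is.data.frame(clones))
  req <- c("v", "j", "cdr3nt", "count")
  miss <- setdiff(req, names(clones))
  if (length(miss) > 0) {
    stop("clone records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"cdr3aa" %in% names(clones)) clones$cdr3aa <- NA_character_
  clones <- as_tibble(clones)[, c("v", "j", "cdr3nt", "cdr3aa", "count")]

  if (any(is.na(clones$v) | clones$v == "") ||
      any(is.na(clones$j) | clones$j == "")) {
    stop("V and J segment names must be non-empty", call. = FALSE)
  }
  clones$cdr3nt <- validate_cdr3nt(clones$cdr3nt)

  cnt <- clones$count
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt))) {
    bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
    stop("counts must be non-negative integers; bad row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  clones$count <- as.numeric(cnt)

  merged <- clones |>
    group_by(.data$v, .data$j, .data$cdr3nt) |>
    summarise(
      cdr3aa = first(.data$cdr3aa[!is.na(.data$cdr3aa)], default = NA_character_),
      count = sum(.data$count),
      .groups = "drop"
    ) |>
    filter(.data$count > 0)

  if (nrow(merged) == 0) {
    stop("empty repertoire: all clone counts are zero", call. = FALSE)
  }
  merged$freq <- merged$count / sum(merged$count)
  merged <- merged[, c("v", "j", "cdr3nt", "cdr3aa", "count", "freq")]

  check_enum <- function(x, allowed, what) {
    if (!is.na(x) && !x %in% allowed) {
      stop(what, " must be one of: ", paste(allowed, collapse = ", "),
           " (got '", x, "')", call. = FALSE)
    }
    x
  }
  if (!is.na(cell_count) && cell_count < 1) {
    stop("cell_count must be a positive integer", call. = FALSE)
  }

  structure(
    list(
      sample_id = as.character(sample_id),
      mouse_id = as.character(mouse_id),
      tissue = check_enum(as.character(tissue), TISSUES, "tissue"),
      side = check_enum(as.character(side), SIDES, "side"),
      subset = check_enum(as.character(subset), SUBSETS, "subset"),
      fragment = as.character(fragment),
      cell_count = cell_count,
      clones = merged
    ),
    class = "tcr_repertoire"
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat("<tcr_repertoire> ", x$sample_id,
      "  [mouse ", x$mouse_id, ", ", x$tissue, " ", x$side,
      if (!is.na(x$fragment)) paste0(" frag ", x$fragment), ", ",
      x$subset, "]\n", sep = "")
  cat("  clones: ", n_clones(x), "   reads: ", total_reads(x),
      "   cells: ", x$cell_count, "\n", sep = "")
  invisible(x)
}

#' Total reads and unique clone number of a repertoire
#' @param rep A `tcr_repertoire`.
#' @return Scalar numeric / integer.
#' @export
total_reads <- function(rep) sum(rep$clones$count)

#' @rdname total_reads
#' @export
n_clones <- function(rep) nrow(rep$clones)

is_repertoire <- function(x) inherits(x, "tcr_repertoire")

assert_repertoire <- function(rep) {
  if (!is_repertoire(rep)) stop("expected a tcr_repertoire", call. = FALSE)
  if (nrow(rep$clones) == 0) stop("empty repertoire", call. = FALSE)
  invisible(rep)
}

#' Pool several repertoires into one
#'
#' Concatenates clone tables and re-merges on the clone key, summing read
#' counts -- e.g. to pool the two fragments of one tumor, or the left and
#' right tumors of one mouse. Metadata fields shared by all inputs are kept;
#' conflicting fields become `NA`; cell counts are summed.
#'
#' @param reps List of `tcr_repertoire` objects.
#' @param sample_id Identifier for the pooled repertoire.
#' @return A `tcr_repertoire`.
#' @export
pool_repertoires <- function(reps, sample_id = "pooled") {
  stopifnot(length(reps) >= 1)
  lapply(reps, assert_repertoire)
  common <- function(field) {
    vals <- unique(vapply(reps, function(r) as.character(r[[field]]),
                          character(1)))
    if (length(vals) == 1) vals else NA_character_
  }
  cells <- vapply(reps, function(r) as.numeric(r$cell_count %||% NA), 1)
  make_repertoire(
    bind_rows(lapply(reps, function(r) r$clones)),
    sample_id = sample_id,
    mouse_id = common("mouse_id"), tissue = common("tissue"),
    side = common("side"), subset = common("subset"),
    fragment = NA_character_,
    cell_count = if (any(is.na(cells))) NA_integer_ else as.integer(sum(cells))
  )
}

#' Default downsampling target: six times the sorted cell count
#'
#' Sequencing libraries are normalized to a read depth of six times the
#' number of T cells sorted for library preparation, making repertoire
#' statistics depth-comparable across samples.
#'
#' @param cell_count Positive integer cell count.
#' @param factor Reads-per-cell factor (default 6).
#' @return Integer target read count.
#' @examples
#' default_target_reads(10000) # 60000
#' @export
default_target_reads <- function(cell_count, factor = 6L) {
  stopifnot(length(cell_count) >= 1, all(cell_count >= 1),
            all(cell_count == floor(cell_count)), factor >= 1)
  as.integer(factor * cell_count)
}

#' Downsample a repertoire to a fixed read total
#'
#' Draws `target_reads` reads uniformly without replacement from the multiset
#' of reads (a multivariate hypergeometric over clones), the standard
#' depth-normalization for repertoire comparison. Clones reduced to zero
#' reads are removed and frequencies recomputed. A with-replacement
#' multinomial mode is available for simulation parity.
#'
#' @param rep A `tcr_repertoire`.
#' @param target_reads Target read total; defaults to
#'   [default_target_reads()] of the repertoire's cell count.
#' @param seed Integer seed; the operation is deterministic given the seed.
#' @param method `"hypergeometric"` (without replacement, default) or
#'   `"multinomial"` (with replacement).
#' @param on_excess What to do when `target_reads` exceeds the available
#'   reads: `"error"` (default) or `"keep"` (return the repertoire unchanged
#'   with a warning).
#' @return A downsampled `tcr_repertoire` with exactly `target_reads` reads
#'   (or the input, under `on_excess = "keep"`).
#' @export
downsample <- function(rep, target_reads = NULL, seed = NULL,
                       method = c("hypergeometric", "multinomial"),
                       on_excess = c("error", "keep")) {
  assert_repertoire(rep)
  method <- match.arg(method)
  on_excess <- match.arg(on_excess)
  if (is.null(target_reads)) {
    if (is.na(rep$cell_count)) {
      stop("target_reads not given and repertoire has no cell_count",
           call. = FALSE)
    }
    target_reads <- default_target_reads(rep$cell_count)
  }
  stopifnot(target_reads >= 1, target_reads == floor(target_reads))
  total <- total_reads(rep)
  if (target_reads > total) {
    if (on_excess == "error") {
      stop("target_reads (", target_reads, ") exceeds total reads (", total,
           ") for sample ", rep$sample_id, call. = FALSE)
    }
    warning("sample ", rep$sample_id, ": total reads ", total,
            " below target ", target_reads, "; kept as is", call. = FALSE)
    return(rep)
  }
  if (target_reads == total && method == "hypergeometric") return(rep)

  counts <- rep$clones$count
  new_counts <- with_seed(seed, {
    if (method == "multinomial") {
      as.numeric(rmultinom(1, target_reads, counts))
    } else {
      # sequential conditional hypergeometric draws: exact multivariate
      # hypergeometric in O(#clones)
      out <- numeric(length(counts))
      rem_total <- total
      rem_draw <- target_reads
      for (i in seq_along(counts)) {
        if (rem_draw == 0) break
        x <- rhyper(1, counts[i], rem_total - counts[i], rem_draw)
        out[i] <- x
        rem_draw <- rem_draw - x
        rem_total <- rem_total - counts[i]
      }
      out
    }
  })

  kept <- rep$clones
  kept$count <- new_counts
  make_repertoire(kept[kept$count > 0, ],
                  sample_id = rep$sample_id, mouse_id = rep$mouse_id,
                  tissue = rep$tissue, side = rep$side, subset = rep$subset,
                  fragment = rep$fragment, cell_count = rep$cell_count)
}

#' Rank-class breakdown of clone frequencies
#'
#' Partitions clones by their abundance rank into classes (default: top 10,
#' 11th-20th, 21st-40th, 41st-100th, and all remaining clones) and totals
#' the repertoire frequency held by each class. Ties in count are broken by
#' descending frequency then lexicographic (CDR3nt, V, J) so the breakdown
#' is reproducible.
#'
#' @param rep A `tcr_repertoire`.
#' @param boundaries Strictly increasing integer upper rank bounds
#'   (default `c(10, 20, 40, 100)`).
#' @return A tibble with one row per class: `class` label, `n_clones`,
#'   `frequency`; frequencies sum to 1. The boundaries used are attached as
#'   attribute `"boundaries"`.
#' @export
rank_class_breakdown <- function(rep, boundaries = c(10L, 20L, 40L, 100L)) {
  assert_repertoire(rep)
  stopifnot(length(boundaries) >= 1, all(boundaries == floor(boundaries)),
            all(diff(boundaries) > 0), boundaries[1] >= 1)
  cl <- rep$clones
  ord <- order(-cl$count, cl$cdr3nt, cl$v, cl$j)
  rank <- integer(nrow(cl))
  rank[ord] <- seq_len(nrow(cl))

  labels <- c(
    paste0("top", boundaries[1]),
    if (length(boundaries) > 1) {
      paste0(utils::head(boundaries, -1) + 1, "-", boundaries[-1])
    },
    "others"
  )
  cls <- cut(rank, breaks = c(0, boundaries, Inf), labels = labels)
  out <- tibble(class = factor(labels, levels = labels)) |>
    left_join(
      tibble(class = cls, freq = cl$freq) |>
        group_by(.data$class) |>
        summarise(n_clones = n(), frequency = sum(.data$freq),
                  .groups = "drop"),
      by = "class"
    ) |>
    mutate(
      n_clones = ifelse(is.na(.data$n_clones), 0L, .data$n_clones),
      frequency = ifelse(is.na(.data$frequency), 0, .data$frequency)
    )
  attr(out, "boundaries") <- boundaries
  out
}
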