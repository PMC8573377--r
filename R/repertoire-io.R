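#' Read a clone table into a repertoire
#'
#' Supports two dialects: `"vdjtools"` clonotype tables (columns `count`,
#' `freq`, `cdr3nt`, `cdr3aa`, `v`, `d`, `j`) and `"airr"` Rearrangement TSV
#' (columns `duplicate_count`, `junction`, `junction_aa`, `v_call`,
#' `j_call`, `productive`). Frequencies are always recomputed from counts --
#' a file's frequency column is advisory only, which protects against
#' upstream rounding. The AIRR dialect keeps only productive rows, and
#' strips allele suffixes (`*01`) from V/J calls by default so clone keys
#' are at IMGT gene level.
#'
#' @param path Path to a TSV file with header.
#' @param dialect `"vdjtools"` or `"airr"`.
#' @param strip_alleles Drop `*NN` allele suffixes from AIRR V/J calls
#'   (default `TRUE`).
#' @param ... Metadata passed to [make_repertoire()] (`sample_id`,
#'   `mouse_id`, `tissue`, `side`, `subset`, `fragment`, `cell_count`).
#' @return A `tcr_repertoire`.
#' @export
read_clone_table <- function(path, dialect = c("vdjtools", "airr"),
                             strip_alleles = TRUE, ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  req <- switch(dialect,
    vdjtools = c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j"),
    airr = c("duplicate_count", "junction", "junction_aa", "v_call",
             "j_call", "productive")
  )
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stop("clone table ", path, " missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  if (dialect == "vdjtools") {
    rec <- data.frame(
      v = tab$v, j = tab$j, cdr3nt = tab$cdr3nt, cdr3aa = tab$cdr3aa,
      count = tab$count, stringsAsFactors = FALSE
    )
  } else {
    keep <- tolower(tab$productive) %in% c("t", "true", "1")
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) == 0) {
      stop("clone table ", path, ": no productive rows", call. = FALSE)
    }
    v <- tab$v_call
    j <- tab$j_call
    if (strip_alleles) {
      v <- sub("\\*.*$", "", v)
      j <- sub("\\*.*$", "", j)
    }
    rec <- data.frame(
      v = v, j = j, cdr3nt = tab$junction, cdr3aa = tab$junction_aa,
      count = tab$duplicate_count, stringsAsFactors = FALSE
    )
  }

  cnt <- suppressWarnings(as.numeric(rec$count))
  bad <- which(is.na(cnt) | cnt != floor(cnt) | cnt < 0)
  if (length(bad) > 0) {
    stop("clone table ", path, ": non-integer count at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  rec$count <- cnt
  rec$cdr3aa[rec$cdr3aa %in% c("", ".")] <- NA_character_
  make_repertoire(rec, ...)
}

#' Write a repertoire to a clone table
#'
#' Emits plain TSV with header, UTF-8, Unix newlines. The written table
#' round-trips through [read_clone_table()] with counts preserved exactly.
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output path.
#' @param dialect `"vdjtools"` or `"airr"`.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(rep, path, dialect = c("vdjtools", "airr")) {
  dialect <- match.arg(dialect)
  assert_repertoire(rep)
  cl <- rep$clones
  out <- if (dialect == "vdjtools") {
    data.frame(
      count = format(cl$count, scientific = FALSE, trim = TRUE),
      freq = cl$freq, cdr3nt = cl$cdr3nt,
      cdr3aa = ifelse(is.na(cl$cdr3aa), ".", cl$cdr3aa),
      v = cl$v, d = ".", j = cl$j,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      duplicate_count = format(cl$count, scientific = FALSE, trim = TRUE),
      junction = cl$cdr3nt,
      junction_aa = ifelse(is.na(cl$cdr3aa), "", cl$cdr3aa),
      v_call = cl$v, j_call = cl$j, productive = "T",
      stringsAsFactors = FALSE
    )
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet maps each sample to its clone table and metadata:
#' columns `sample_id`, `file`, `mouse_id`, `tissue`, `side`, `subset`,
#' `fragment`, `cell_count`. Tab- or comma-separated is auto-detected from
#' the header line. Sample ids must be unique; `tissue`, `side` and
#' `subset` must come from their vocabularies (`tumor`/`dLN`,
#' `left`/`right`, `CD4`/`CD8`); cell counts must be positive.
#'
#' @param path Path to the sheet.
#' @return A tibble with the validated rows.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  sheet <- utils::read.delim(path, sep = sep, header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "file", "mouse_id", "tissue", "side", "subset",
           "fragment", "cell_count")
  miss <- setdiff(req, names(sheet))
  if (length(miss) > 0) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sheet <- as_tibble(sheet)[, req]
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup) > 0) {
    stop("duplicated sample_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  check <- function(col, allowed) {
    bad <- setdiff(unique(sheet[[col]]), allowed)
    if (length(bad) > 0) {
      stop("unknown ", col, " value(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
    }
  }
  check("tissue", TISSUES)
  check("side", SIDES)
  check("subset", SUBSETS)
  cc <- suppressWarnings(as.numeric(sheet$cell_count))
  if (any(is.na(cc) | cc < 1)) {
    stop("cell_count must be positive for every sample", call. = FALSE)
  }
  sheet$cell_count <- as.integer(cc)
  sheet$fragment <- as.character(sheet$fragment)
  sheet$fragment[sheet$fragment %in% c("", "NA", ".")] <- NA_character_
  sheet
}

#' Write a sample sheet
#' @param sheet Sample-sheet tibble (see [read_sample_sheet()]).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  out <- as.data.frame(sheet)
  out$fragment[is.na(out$fragment)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Load samples listed in a sample sheet
#'
#' Reads every clone table named in a sample sheet and attaches the sheet's
#' metadata. Relative file paths are resolved against the sheet's directory
#' when `base_dir` is not given.
#'
#' @param sheet Sample-sheet tibble or path to one.
#' @param dialect Clone-table dialect for all files.
#' @param base_dir Directory against which relative paths resolve.
#' @return Named list of `tcr_repertoire` (names = sample ids).
#' @export
load_samples <- function(sheet, dialect = "vdjtools", base_dir = NULL) {
  if (is.character(sheet)) {
    if (is.null(base_dir)) base_dir <- dirname(sheet)
    sheet <- read_sample_sheet(sheet)
  } else {
    sheet <- validate_sample_sheet(sheet)
    if (is.null(base_dir)) base_dir <- "."
  }
  reps <- lapply(seq_len(nrow(sheet)), function(i) {
    row <- sheet[i, ]
    p <- row$file
    if (!file.exists(p)) p <- file.path(base_dir, row$file)
    read_clone_table(p, dialect = dialect,
                     sample_id = row$sample_id, mouse_id = row$mouse_id,
                     tissue = row$tissue, side = row$side,
                     subset = row$subset, fragment = row$fragment,
                     cell_count = row$cell_count)
  })
  names(reps) <- sheet$sample_id
  reps
}

#' Default run configuration
#'
#' Analysis-wide settings: clone-table dialect, reads-per-cell downsampling
#' factor (default 6), differential-expansion thresholds (q < 0.01, fold
#' change > 2), q-value method, overlap-total mode and the master seed.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    dialect = "vdjtools",
    downsample_factor = 6L,
    q_threshold = 0.01,
    fc_threshold = 2,
    q_method = "storey",
    overlap_total_mode = "geomean_of_totals",
    seed = 1L
  )
}

#' Read a run configuration file (YAML or JSON)
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, cfg)
}
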