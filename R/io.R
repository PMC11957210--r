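# Tabular I/O. All tables are tab-separated with a single header row; the
# missing token on write is the empty cell, and both "" and "NA" are accepted
# on read. Dates, when present, are expected as ISO-8601 and converted to
# age-in-years upstream of this layer.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = c("", "NA"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Load a study (abundance matrix, sample metadata, optional CDR visits)
#'
#' Reads the three tab-separated study tables and returns validated typed
#' objects. The matrix file is wide (rows = samples, first column
#' `sample_id`); per-(analyte, plate) scale factors and LODs are read from
#' optional side tables with columns `analyte_id`, `plate`, `value`.
#'
#' @param matrix_path TSV of abundances, first column `sample_id`.
#' @param metadata_path TSV of sample metadata; must contain `plate` plus the
#'   columns required by [validate_samples()] and cover every matrix sample.
#' @param cdr_path Optional TSV of CDR visits.
#' @param scale_factor_path,lod_path Optional long-format TSVs
#'   (`analyte_id`, `plate`, `value`) of per-plate scale factors / LODs.
#' @return A list with elements `matrix` (a [proteomics_matrix()]), `samples`
#'   and, when requested, `cdr`.
#' @export
load_study <- function(matrix_path, metadata_path, cdr_path = NULL,
                       scale_factor_path = NULL, lod_path = NULL) {
  raw <- read_tsv_checked(matrix_path)
  if (names(raw)[1] != "sample_id")
    stop("matrix file must have `sample_id` as its first column")
  ids <- as.character(raw$sample_id)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric abundance cell(s) found in ",
         paste(colnames(vals)[!apply(vals, 2, is.numeric)], collapse = ", "))
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (any(vals < 0, na.rm = TRUE)) stop("negative abundance value in matrix")

  meta <- validate_samples(read_tsv_checked(metadata_path))
  meta$sample_id <- as.character(meta$sample_id)
  uncovered <- setdiff(ids, meta$sample_id)
  if (length(uncovered))
    stop("metadata missing matrix sample(s): ", paste(uncovered, collapse = ", "))
  if (is.null(meta$plate)) stop("metadata must contain a `plate` column")
  plate <- stats::setNames(as.character(meta$plate), meta$sample_id)[ids]

  read_pair_table <- function(path) {
    if (is.null(path)) return(NULL)
    long <- read_tsv_checked(path)
    req <- c("analyte_id", "plate", "value")
    if (!all(req %in% names(long)))
      stop("expected columns analyte_id, plate, value in ", path)
    an <- unique(as.character(long$analyte_id))
    pl <- unique(as.character(long$plate))
    m <- matrix(NA_real_, length(an), length(pl), dimnames = list(an, pl))
    m[cbind(as.character(long$analyte_id), as.character(long$plate))] <- long$value
    m
  }

  pm <- proteomics_matrix(vals, plate,
                          scale_factor = read_pair_table(scale_factor_path),
                          lod = read_pair_table(lod_path))
  out <- list(matrix = pm, samples = meta)
  if (!is.null(cdr_path)) {
    cdr <- validate_cdr(read_tsv_checked(cdr_path))
    cdr$sample_id <- as.character(cdr$sample_id)
    out$cdr <- cdr
  }
  out
}

#' Write a proteomics matrix (and annotation) to TSV files
#'
#' @param pm A [proteomics_matrix()].
#' @param path Output TSV path for the wide matrix.
#' @export
write_matrix <- function(pm, path) {
  df <- data.frame(sample_id = rownames(pm$values), pm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_results_table(df, path)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT dialect: one set per line, `name TAB description TAB member ...`.
#' Duplicate members within one set are deduplicated; duplicate set names
#' are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors; the `description` attribute
#'   holds the per-set descriptions.
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short))
    stop("GMT line with fewer than 3 fields (line ", which(short)[1], ")")
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name: ", nms[duplicated(nms)][1])
  sets <- lapply(parts, function(p) {
    members <- unique(p[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set: ", p[[1]])
    members
  })
  names(sets) <- nms
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L), nms)
  sets
}

#' Write a results table as TSV
#'
#' Writes any homogeneous record table with a header row, representing
#' missing values by the empty cell and keeping full float precision (values
#' survive a write/read round trip bit-for-bit via 17 significant digits).
#'
#' @param records A data.frame.
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) {
      x <- sprintf("%.17g", fmt[[j]])
      x[is.na(fmt[[j]])] <- NA_character_
      fmt[[j]] <- x
    }
  }
  ok <- tryCatch({
    utils::write.table(fmt, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write to ", path, ": ", conditionMessage(e)))
  invisible(ok)
}

#' Read back a results table written by [write_results_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_table <- function(path) read_tsv_checked(path)
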