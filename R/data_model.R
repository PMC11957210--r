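#' @keywords internal
"_PACKAGE"

# Closed vocabulary for clinical status labels.
STATUS_LEVELS <- c("CO", "AD", "FTD", "DLB", "PD")
CDR_GLOBAL_LEVELS <- c(0, 0.5, 1, 2, 3)

#' Construct a samples x analytes proteomics matrix
#'
#' The central abundance container: a wide matrix of non-negative relative
#' fluorescence units (RFU) with one row per sample, together with the plate
#' each sample was run on and, optionally, per-(analyte, plate) scale factors
#' and limits of detection (LOD).
#'
#' @param values Numeric matrix, samples x analytes, with row and column
#'   names. Missing values (`NA`) are allowed; non-missing values must be
#'   non-negative.
#' @param plate_of_sample Character vector of plate labels, one per sample
#'   (named by sample id or in row order).
#' @param scale_factor Optional numeric matrix, analytes x plates, of
#'   per-plate scale factors.
#' @param lod Optional numeric matrix, analytes x plates, of non-negative
#'   limits of detection on the RFU scale.
#' @return An object of class `proteomics_matrix`.
#' @export
proteomics_matrix <- function(values, plate_of_sample,
                              scale_factor = NULL, lod = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample ids as rownames and analyte ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated analyte id")
  if (any(values < 0, na.rm = TRUE))
    stop("abundance values must be non-negative")
  if (length(plate_of_sample) != nrow(values))
    stop("`plate_of_sample` must have one entry per sample")
  if (anyNA(plate_of_sample))
    stop("every sample must have a plate label")
  if (!is.null(names(plate_of_sample))) {
    if (!setequal(names(plate_of_sample), rownames(values)))
      stop("`plate_of_sample` names do not match sample ids")
    plate_of_sample <- plate_of_sample[rownames(values)]
  } else {
    names(plate_of_sample) <- rownames(values)
  }
  plates <- unique(plate_of_sample)
  for (nm in c("scale_factor", "lod")) {
    m <- get(nm)
    if (!is.null(m)) {
      if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m)))
        stop("`", nm, "` must be an analytes x plates matrix with dimnames")
      missing_an <- setdiff(colnames(values), rownames(m))
      missing_pl <- setdiff(plates, colnames(m))
      if (length(missing_an) || length(missing_pl))
        stop("`", nm, "` does not cover every (analyte, plate) pair; missing ",
             paste(c(missing_an, missing_pl), collapse = ", "))
    }
  }
  if (!is.null(lod) && any(lod < 0, na.rm = TRUE))
    stop("LOD values must be non-negative")
  structure(list(values = values,
                 plate_of_sample = plate_of_sample,
                 scale_factor = scale_factor,
                 lod = lod),
            class = "proteomics_matrix")
}

#' @export
print.proteomics_matrix <- function(x, ...) {
  cat(sprintf("proteomics_matrix: %d samples x %d analytes, %d plate(s), %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$plate_of_sample)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.proteomics_matrix <- function(x) dim(x$values)

# Subset a proteomics_matrix by sample / analyte ids (internal helper; keeps
# plate labels and per-plate annotation aligned).
pm_subset <- function(pm, samples = NULL, analytes = NULL) {
  v <- pm$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(analytes)) v <- v[, analytes, drop = FALSE]
  sf <- pm$scale_factor
  ld <- pm$lod
  if (!is.null(analytes)) {
    if (!is.null(sf)) sf <- sf[analytes, , drop = FALSE]
    if (!is.null(ld)) ld <- ld[analytes, , drop = FALSE]
  }
  structure(list(values = v,
                 plate_of_sample = pm$plate_of_sample[rownames(v)],
                 scale_factor = sf, lod = ld),
            class = "proteomics_matrix")
}

#' Validate a sample metadata table
#'
#' Checks the per-sample record invariants: unique sample ids, positive age
#' at blood draw, sex in \{female, male\} and clinical status drawn from the
#' closed set CO / AD / FTD / DLB / PD. Optional biomarker columns
#' (`csf_abeta42`, `csf_ptau181`, `pet_composite`, `plasma_ptau217`) are kept
#' as-is.
#'
#' @param df A data.frame with at least `sample_id`, `age_at_draw`, `sex`,
#'   `clinical_status`; optionally `cohort` and `dataset_cluster`.
#' @return The validated data.frame (invisibly the same content).
#' @export
validate_samples <- function(df) {
  req <- c("sample_id", "age_at_draw", "sex", "clinical_status")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(!is.na(df$age_at_draw) & df$age_at_draw <= 0))
    stop("age_at_draw must be > 0")
  bad_sex <- setdiff(unique(stats::na.omit(df$sex)), c("female", "male"))
  if (length(bad_sex)) stop("unknown sex label: ", paste(bad_sex, collapse = ", "))
  bad <- setdiff(unique(stats::na.omit(df$clinical_status)), STATUS_LEVELS)
  if (length(bad))
    stop("unknown clinical_status: ", paste(bad, collapse = ", "))
  if (is.null(df$cohort)) df$cohort <- "cohort1"
  if (is.null(df$dataset_cluster)) df$dataset_cluster <- df$cohort
  df
}

#' Validate a longitudinal CDR visit table
#'
#' @param df A data.frame with `sample_id`, `visit_age` (years),
#'   `cdr_global` and `cdr_sb`.
#' @return The validated data.frame, ordered by subject and visit age.
#' @export
validate_cdr <- function(df) {
  req <- c("sample_id", "visit_age", "cdr_global", "cdr_sb")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("CDR table missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(stats::na.omit(df$cdr_global)), CDR_GLOBAL_LEVELS)
  if (length(bad)) stop("cdr_global outside {0, 0.5, 1, 2, 3}: ",
                        paste(bad, collapse = ", "))
  if (any(!is.na(df$cdr_sb) & df$cdr_sb < 0)) stop("cdr_sb must be >= 0")
  df[order(df$sample_id, df$visit_age), , drop = FALSE]
}
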