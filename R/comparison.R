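#' Build the cross-scanner reconstruction design matrix
#'
#' Emits the full design: for each enabled dataset, the PET-CT arm carries
#' 3 FBP (5/10/15 mm filters) plus 3 OSEM rows, and the PET-MR arm carries
#' 3 OSEM rows plus one BSREM row per beta value (10 by default, so 13
#' PET-MR rows). NEMA datasets use 4 iterations x 8 subsets for OSEM;
#' Hoffman datasets use 4 x 16.
#'
#' @param datasets dataset tags, subset of
#'   `c("F18_NEMA", "F18_HOFFMAN", "C11_HOFFMAN")`.
#' @param modalities scanner arms, subset of `c("PET-CT", "PET-MR")`.
#' @param filters_mm Gaussian filter grid (mm) for FBP and OSEM.
#' @param beta_grid BSREM penalty weights (PET-MR arm only).
#' @return data.frame of class `recon_matrix` with columns `dataset`,
#'   `modality`, `nomenclature`, `algorithm`, `iterations`, `subsets`,
#'   `post_filter_fwhm_mm`, `beta`. The matching [recon_config()] objects
#'   are in the `configs` attribute (same row order).
#' @export
build_recon_matrix <- function(datasets = c("F18_NEMA", "F18_HOFFMAN",
                                            "C11_HOFFMAN"),
                               modalities = c("PET-CT", "PET-MR"),
                               filters_mm = c(5, 10, 15),
                               beta_grid = seq(100, 1000, by = 100)) {
  valid <- c("F18_NEMA", "F18_HOFFMAN", "C11_HOFFMAN")
  if (length(datasets) && !all(datasets %in% valid))
    stop("config error: unknown dataset tag(s): ",
         paste(setdiff(datasets, valid), collapse = ", "))
  if (length(modalities) && !all(modalities %in% c("PET-CT", "PET-MR")))
    stop("config error: unknown modality")
  rows <- list(); cfgs <- list()
  add <- function(dataset, modality, cfg) {
    rows[[length(rows) + 1L]] <<- data.frame(
      dataset = dataset, modality = modality,
      nomenclature = cfg$nomenclature, algorithm = cfg$algorithm,
      iterations = cfg$iterations, subsets = cfg$subsets,
      post_filter_fwhm_mm = cfg$post_filter_fwhm_mm, beta = cfg$beta)
    cfgs[[length(cfgs) + 1L]] <<- cfg
  }
  for (ds in datasets) {
    osem_subsets <- if (grepl("NEMA", ds)) 8L else 16L
    for (mod in modalities) {
      if (mod == "PET-CT") {
        for (f in filters_mm)
          add(ds, mod, recon_config("FBP", post_filter_fwhm_mm = f))
        for (f in filters_mm)
          add(ds, mod, recon_config("OSEM", iterations = 4L,
                                    subsets = osem_subsets,
                                    post_filter_fwhm_mm = f))
      } else {
        for (f in filters_mm)
          add(ds, mod, recon_config("OSEM", iterations = 4L,
                                    subsets = osem_subsets,
                                    post_filter_fwhm_mm = f))
        for (b in beta_grid)
          add(ds, mod, recon_config("BSREM", iterations = 25L,
                                    subsets = 16L, beta = b))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dataset = character(0), modality = character(0),
               nomenclature = character(0), algorithm = character(0),
               iterations = integer(0), subsets = integer(0),
               post_filter_fwhm_mm = numeric(0), beta = numeric(0))
  attr(out, "configs") <- cfgs
  class(out) <- c("recon_matrix", class(out))
  out
}

#' Metric differences relative to a reference reconstruction
#'
#' For every metric record, computes `reference value - method value`,
#' pairing on `(dataset, metric, sphere_diameter_mm)`. The sign convention
#' (reference minus method) makes a method that exceeds the reference show
#' a negative difference.
#'
#' @param records tidy metric table: columns `dataset`, `nomenclature`,
#'   `metric`, `value`, and optionally `sphere_diameter_mm` (NA for
#'   whole-phantom metrics).
#' @param reference_nomenclature reference reconstruction name (default
#'   `"FBP_5mm"`).
#' @return the records of non-reference rows with an added `difference`
#'   column; pairs with no reference value are returned in the
#'   `exclusions` attribute rather than silently dropped.
#' @export
difference_vs_reference <- function(records,
                                    reference_nomenclature = "FBP_5mm") {
  need <- c("dataset", "nomenclature", "metric", "value")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (!"sphere_diameter_mm" %in% names(records))
    records$sphere_diameter_mm <- NA_real_
  key <- function(df) paste(df$dataset, df$metric, df$sphere_diameter_mm,
                            sep = "\r")
  ref <- records[records$nomenclature == reference_nomenclature, ]
  meth <- records[records$nomenclature != reference_nomenclature, ]
  ref_val <- stats::setNames(ref$value, key(ref))
  meth$difference <- unname(ref_val[key(meth)]) - meth$value
  excl <- meth[is.na(meth$difference) & !is.na(meth$value), ]
  out <- meth[!(rownames(meth) %in% rownames(excl)), ]
  attr(out, "exclusions") <- excl
  out
}

#' Bland-Altman agreement analysis
#'
#' Paired differences `a - b`: bias (mean difference), their sample (N - 1)
#' standard deviation, and the 95% limits of agreement
#' `bias +/- 1.96 * SD`.
#'
#' @param series_a,series_b paired numeric series of equal length >= 2.
#' @return list of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n_pairs`, `means`, `diffs`.
#' @export
bland_altman <- function(series_a, series_b) {
  if (length(series_a) != length(series_b))
    stop("pairing error: series lengths differ")
  if (length(series_a) < 2L) stop("at least 2 pairs required")
  d <- series_a - series_b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 n_pairs = length(d),
                 means = (series_a + series_b) / 2, diffs = d),
            class = "bland_altman_result")
}

#' @exportS3Method print bland_altman_result
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4g, LoA [%.4g, %.4g], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n_pairs))
  invisible(x)
}

#' Summary statistics across reconstructions
#'
#' Mean, sample (N - 1) standard deviation, median and coefficient of
#' variation (`100 * SD / mean`) of a metric series.
#'
#' @param values numeric vector, length >= 2.
#' @return list: `mean`, `sd`, `median`, `cv_percent`.
#' @export
summary_stats <- function(values) {
  if (length(values) < 2L) stop("at least 2 values required")
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero")
  list(mean = m, sd = stats::sd(values), median = stats::median(values),
       cv_percent = 100 * stats::sd(values) / m)
}
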