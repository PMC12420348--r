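#' Pseudocounted log2 expression
#'
#' `log2(x + pseudocount)`, the transform used for plotting and ratio
#' construction; the pseudocount keeps zero-expression samples finite.
#'
#' @param x Non-negative expression value(s) (FPKM or TPM).
#' @param pseudocount Positive pseudocount, default 0.01.
#' @return `log2(x + pseudocount)`.
#' @examples
#' log_expression(0)     # log2(0.01) = -6.64...
#' log_expression(3.99)  # 2
#' @export
log_expression <- function(x, pseudocount = 0.01) {
  if (any(x < 0)) stop("expression values must be non-negative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2(x + pseudocount)
}

#' Pseudocounted log2 variant ratio
#'
#' `log2((num + pseudocount) / (den + pseudocount))`. Antisymmetric in its
#' arguments and finite for any non-negative inputs, including the
#' zero/zero case, which maps to 0.
#'
#' @param fpkm_num,fpkm_den Non-negative expression of the numerator and
#'   denominator variant (FPKM, TPM, or per-bp rates — any common scale).
#' @param pseudocount Positive pseudocount, default 0.01.
#' @return The log2 ratio.
#' @examples
#' log_ratio(10, 1)  # log2(10.01 / 1.01)
#' log_ratio(0, 0)   # 0
#' @export
log_ratio <- function(fpkm_num, fpkm_den, pseudocount = 0.01) {
  if (any(fpkm_num < 0) || any(fpkm_den < 0)) {
    stop("expression values must be non-negative")
  }
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2((fpkm_num + pseudocount) / (fpkm_den + pseudocount))
}

#' Assign cohort samples to tertile ratio groups
#'
#' Partitions a cohort at the 33rd and 66th percentiles of the log2 variant
#' ratio: Group 1 holds the lowest ratios (<= 33rd percentile), Group 2 the
#' mid-range (> 33rd and <= 66th), Group 3 the highest (> 66th). Cutpoints
#' use the linear-interpolation quantile convention (type 7, the default of
#' mainstream statistics environments) and are recorded in the output so
#' downstream survival / ordinal fits are reproducible.
#'
#' @param sample_id Character vector of sample labels.
#' @param log2_ratio Numeric vector of finite log2 ratios, same length.
#' @return A `cohort_table` data.frame with columns `sample_id`,
#'   `log2_ratio`, `group` (integer 1/2/3), and attributes `percentile_33`,
#'   `percentile_66`, `median`, `iqr`, `quantile_type`.
#' @examples
#' assign_tertile_groups(letters[1:3], c(0, 10, 20))  # groups 1, 2, 3
#' @export
assign_tertile_groups <- function(sample_id, log2_ratio) {
  if (length(sample_id) != length(log2_ratio)) {
    stop("sample_id and log2_ratio must have the same length")
  }
  if (length(log2_ratio) < 3L) {
    stop("at least 3 samples are required for tertile grouping")
  }
  if (any(!is.finite(log2_ratio))) stop("log2_ratio must be finite")
  p33 <- unname(stats::quantile(log2_ratio, 0.33, type = 7))
  p66 <- unname(stats::quantile(log2_ratio, 0.66, type = 7))
  group <- ifelse(log2_ratio <= p33, 1L, ifelse(log2_ratio <= p66, 2L, 3L))
  if (p33 == p66 && all(group == 1L)) {
    warning("all ratios identical: every sample assigned to group 1")
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    log2_ratio = log2_ratio, group = group,
                    stringsAsFactors = FALSE)
  attr(out, "percentile_33") <- p33
  attr(out, "percentile_66") <- p66
  attr(out, "median") <- unname(stats::median(log2_ratio))
  attr(out, "iqr") <- unname(stats::IQR(log2_ratio, type = 7))
  attr(out, "quantile_type") <- 7L
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Cohort median and interquartile range
#'
#' Computed under the same linear-interpolation quantile convention as the
#' tertile cutpoints.
#'
#' @param x Numeric vector of ratios (or a `cohort_table`).
#' @return A list with `median` and `iqr`.
#' @export
cohort_summary <- function(x) {
  if (inherits(x, "cohort_table")) x <- x$log2_ratio
  if (!length(x)) stop("cohort_summary requires at least one value")
  list(median = unname(stats::median(x)),
       iqr = unname(stats::IQR(x, type = 7)))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort tertile table: ", nrow(x), " samples\n", sep = "")
  cat(sprintf("cutpoints: P33 = %.4g, P66 = %.4g (quantile type %d)\n",
              attr(x, "percentile_33"), attr(x, "percentile_66"),
              attr(x, "quantile_type")))
  cat(sprintf("median = %.4g, IQR = %.4g\n", attr(x, "median"), attr(x, "iqr")))
  cat("group sizes:", paste(table(factor(x$group, levels = 1:3)), collapse = "/"), "\n")
  invisible(x)
}

#' Write a cohort table and its metadata sidecar
#'
#' The data TSV carries `sample_id`, `log2_ratio`, `group`; the sidecar
#' (`<path>.meta.yaml`) records the cutpoints, quantile convention and
#' pseudocount so the grouping is reproducible.
#'
#' @param cohort A `cohort_table`.
#' @param path Output TSV path.
#' @param pseudocount Pseudocount used when the ratios were formed
#'   (recorded in the sidecar).
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path, pseudocount = 0.01) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(
    percentile_33 = attr(cohort, "percentile_33"),
    percentile_66 = attr(cohort, "percentile_66"),
    median = attr(cohort, "median"),
    iqr = attr(cohort, "iqr"),
    quantile_type = attr(cohort, "quantile_type"),
    quantile_convention = "linear interpolation between order statistics",
    pseudocount = pseudocount
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}
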