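#' Spearman rank correlation with a large-sample p-value
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks (ties
#' share their average rank) and a two-sided p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom. A vector with zero variance has no defined rank correlation
#' and is flagged rather than reported as rho = 0.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @return A list: `rho`, `p_value`, `n`, `testable` (FALSE with `rho` and
#'   `p_value` NA when either input has zero variance).
#' @examples
#' spearman(1:5, c(2, 4, 6, 8, 10))$rho  # 1
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("at least 4 paired observations are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, testable = FALSE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, testable = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate correction:
#' `p_adj(i) = min over j >= i of (m / rank_j) * p_(j)`, capped at 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Build an expression matrix with an optional ingest transform
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   dimnames.
#' @param transform `"raw"` (default), `"log2_tpm_plus1"` or
#'   `"log2_rpm_plus1"`; the log transforms apply `log2(v + 1)` at ingest,
#'   the convention for transcript TPM and miRNA RPM tables. Rank
#'   statistics are invariant to these monotone transforms.
#' @return An `expression_matrix`: the (transformed) matrix with attributes
#'   `transform` and `zero_variance` (feature ids with no variation,
#'   flagged as untestable by the screens).
#' @export
expression_matrix <- function(values,
                              transform = c("raw", "log2_tpm_plus1", "log2_rpm_plus1")) {
  transform <- match.arg(transform)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (nrow(values) > 0L && is.null(rownames(values))) {
    stop("values must carry feature ids as rownames")
  }
  if (ncol(values) > 0L && is.null(colnames(values))) {
    stop("values must carry sample ids as colnames")
  }
  if (transform != "raw") {
    if (any(values < 0)) stop("expression values must be non-negative for log transforms")
    values <- log2(values + 1)
  }
  zv <- rownames(values)[apply(values, 1, function(v) stats::var(v) == 0)]
  structure(values, transform = transform, zero_variance = zv,
            class = c("expression_matrix", class(values)))
}

#' Read a features-by-samples expression TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#'
#' @inheritParams expression_matrix
#' @param path Path to the TSV.
#' @return An `expression_matrix`.
#' @export
read_expression_tsv <- function(path, transform = c("raw", "log2_tpm_plus1", "log2_rpm_plus1")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  expression_matrix(as.matrix(df), transform = match.arg(transform))
}

#' Correlation screen of one focal feature against a candidate matrix
#'
#' Correlates the focal expression vector with every candidate feature by
#' Spearman rank correlation and applies Benjamini-Hochberg correction
#' across the whole screen. Zero-variance candidates are reported as
#' untestable (NA rho and p) and excluded from the adjustment.
#'
#' @param focal Named numeric vector (names = sample ids), or unnamed when
#'   `candidates` columns are positionally aligned.
#' @param candidates An [expression_matrix] (features x samples).
#' @param alpha Significance level recorded for the `significant` flag
#'   (`p_adj < alpha`), default 0.05.
#' @return A data.frame sorted by `p_adj` then decreasing `|rho|`:
#'   `feature`, `rho`, `p_value`, `p_adj`, `significant`, `testable`.
#' @export
screen_focal <- function(focal, candidates, alpha = 0.05) {
  if (!is.null(names(focal)) && !is.null(colnames(candidates))) {
    missing <- setdiff(colnames(candidates), names(focal))
    extra <- setdiff(names(focal), colnames(candidates))
    if (length(missing) || length(extra)) {
      stop("sample mismatch between focal and candidates; missing from focal: ",
           paste(missing, collapse = ", "), "; absent from candidates: ",
           paste(extra, collapse = ", "))
    }
    focal <- focal[colnames(candidates)]
  } else if (length(focal) != ncol(candidates)) {
    stop("focal length does not match the number of candidate samples")
  }
  feats <- rownames(candidates)
  if (!length(feats)) {
    return(data.frame(feature = character(), rho = numeric(),
                      p_value = numeric(), p_adj = numeric(),
                      significant = logical(), testable = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(feats, function(f) spearman(focal, as.numeric(candidates[f, ])))
  out <- data.frame(
    feature = feats,
    rho = vapply(res, `[[`, numeric(1), "rho"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    testable = vapply(res, `[[`, logical(1), "testable"),
    stringsAsFactors = FALSE
  )
  out$p_adj <- NA_real_
  # p = 0 (perfect monotone association) is a valid output of the t
  # approximation; BH of 0 is 0
  ok <- out$testable
  if (any(ok)) {
    out$p_adj[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  ord <- order(out$p_adj, -abs(out$rho), out$feature)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen for ceRNA sponge triads
#'
#' A sponge triad is a focal transcript that sequesters a miRNA and
#' thereby sustains one of the miRNA's targets. It is diagnosed by a sign
#' pattern of rank correlations: transcript vs miRNA negative, transcript
#' vs target positive, miRNA vs target negative, each significant after
#' Benjamini-Hochberg correction applied within its own correlation family
#' (the transcript-miRNA screen, the transcript-target screen, and the
#' miRNA-target pairs).
#'
#' @param transcript Named numeric vector of focal transcript expression.
#' @param mirnas,targets [expression_matrix] objects with the same samples.
#' @param interaction_whitelist Optional data.frame with columns `mirna_id`
#'   and `target_id`; when supplied, only listed (miRNA, target) pairs are
#'   eligible (e.g. experimentally validated interactions).
#' @param alpha Adjusted-p significance threshold, default 0.05.
#' @return A data.frame of triads: `transcript`, `mirna`, `target`,
#'   `rho_tm`, `rho_tt`, `rho_mt` and the three adjusted p-values. Zero
#'   rows when no triad satisfies the sign and significance constraints.
#' @export
find_sponge_triads <- function(transcript, mirnas, targets,
                               interaction_whitelist = NULL, alpha = 0.05) {
  tm <- screen_focal(transcript, mirnas, alpha = alpha)
  tt <- screen_focal(transcript, targets, alpha = alpha)
  sig_m <- tm$feature[tm$significant & !is.na(tm$rho) & tm$rho < 0]
  sig_t <- tt$feature[tt$significant & !is.na(tt$rho) & tt$rho > 0]
  empty <- data.frame(transcript = character(), mirna = character(),
                      target = character(), rho_tm = numeric(),
                      rho_tt = numeric(), rho_mt = numeric(),
                      p_adj_tm = numeric(), p_adj_tt = numeric(),
                      p_adj_mt = numeric(), stringsAsFactors = FALSE)
  if (!length(sig_m) || !length(sig_t)) return(empty)
  pairs <- expand.grid(mirna = sig_m, target = sig_t,
                       stringsAsFactors = FALSE)
  if (!is.null(interaction_whitelist)) {
    key <- paste(pairs$mirna, pairs$target)
    wl <- paste(interaction_whitelist$mirna_id, interaction_whitelist$target_id)
    pairs <- pairs[key %in% wl, , drop = FALSE]
  }
  if (!nrow(pairs)) return(empty)
  mt <- lapply(seq_len(nrow(pairs)), function(i) {
    spearman(as.numeric(mirnas[pairs$mirna[i], ]),
             as.numeric(targets[pairs$target[i], ]))
  })
  rho_mt <- vapply(mt, `[[`, numeric(1), "rho")
  p_mt <- vapply(mt, `[[`, numeric(1), "p_value")
  testable <- vapply(mt, `[[`, logical(1), "testable")
  p_adj_mt <- rep(NA_real_, length(p_mt))
  if (any(testable)) {
    p_adj_mt[testable] <- stats::p.adjust(p_mt[testable], method = "BH")
  }
  keep <- testable & rho_mt < 0 & !is.na(p_adj_mt) & p_adj_mt < alpha
  if (!any(keep)) return(empty)
  name_tr <- if (!is.null(attr(transcript, "feature_id")))
    attr(transcript, "feature_id") else "focal"
  out <- data.frame(
    transcript = name_tr,
    mirna = pairs$mirna[keep],
    target = pairs$target[keep],
    rho_tm = tm$rho[match(pairs$mirna[keep], tm$feature)],
    rho_tt = tt$rho[match(pairs$target[keep], tt$feature)],
    rho_mt = rho_mt[keep],
    p_adj_tm = tm$p_adj[match(pairs$mirna[keep], tm$feature)],
    p_adj_tt = tt$p_adj[match(pairs$target[keep], tt$feature)],
    p_adj_mt = p_adj_mt[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
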