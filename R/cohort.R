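# Polynomial rolling hash mod 2^31 - 1 over a character scalar; cheap
# content hash for provenance headers (not cryptographic).
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read and validate a cohort run configuration
#'
#' The configuration is a YAML file binding one cohort run together: the
#' region specification, the per-sample manifest (BAM path plus either a
#' library size or a sliced flag), the counting policy, the ratio
#' definition, the output directory and the seed. Validation is aggregated:
#' all problems are reported at once.
#'
#' @param path Path to the YAML config.
#' @param strict When TRUE (default, and overridable by a `strict` key in
#'   the file), missing BAM files are a validation error before any
#'   processing starts.
#' @return A `run_config` list with defaults filled in; the effective
#'   configuration is stored in the `effective_yaml` attribute.
#' @export
read_run_config <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$strict)) strict <- isTRUE(cfg$strict)
  problems <- character(0)
  need <- function(key) {
    if (is.null(cfg[[key]])) problems <<- c(problems, paste0("missing key: ", key))
  }
  need("region_spec"); need("samples"); need("numerator"); need("denominator")
  if (!is.null(cfg$region_spec) && !file.exists(cfg$region_spec)) {
    problems <- c(problems, paste0("region_spec file not found: ", cfg$region_spec))
  }
  ids <- vapply(cfg$samples, function(s) as.character(s$sample_id %||% NA), character(1))
  if (anyNA(ids)) problems <- c(problems, "every sample needs a sample_id")
  if (anyDuplicated(ids)) {
    problems <- c(problems, paste0("duplicate sample_id: ",
                                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (s in cfg$samples) {
    if (is.null(s$bam)) {
      problems <- c(problems, paste0("sample ", s$sample_id, ": missing bam path"))
    } else if (strict && !file.exists(s$bam)) {
      problems <- c(problems, paste0("sample ", s$sample_id, ": bam not found: ", s$bam))
    }
    if (!isTRUE(s$sliced) && is.null(s$library_size)) {
      problems <- c(problems, paste0("sample ", s$sample_id,
                                     ": needs library_size or sliced: true"))
    }
  }
  if (length(problems)) {
    stop("invalid run configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  defaults <- list(region_dialect = "gtf", pseudocount = 0.01,
                   output_dir = ".", seed = 1L, strict = strict,
                   policy = list())
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$policy <- do.call(counting_policy, cfg$policy)
  attr(cfg, "effective_yaml") <- yaml::as.yaml(
    cfg[c("region_spec", "region_dialect", "numerator", "denominator",
          "pseudocount", "output_dir", "seed", "strict", "samples")])
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a cohort: quantify every sample and build the ratio/group table
#'
#' Quantifies each manifest sample over the configured discriminating
#' regions, writes one quantification TSV per sample, computes the
#' pseudocounted log2 variant ratio (from FPKM when a library size is
#' available, from per-bp rates in sliced mode; the grouping is identical
#' because the library-size term cancels in the ratio), assigns tertile
#' groups across the cohort and writes the cohort table with its metadata
#' sidecar. Every output carries a provenance header with the package
#' version, a config hash and the counting policy. Outputs are
#' deterministic for a fixed config.
#'
#' @param config A `run_config` from [read_run_config], or a path to one.
#' @return A list: `quants` (named list of `sample_quant`), `cohort` (a
#'   `cohort_table`), `failed` (named character vector of per-sample error
#'   messages; empty in strict mode, which stops on the first error),
#'   `output_dir`.
#' @export
run_cohort <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- read_region_spec(config$region_spec, dialect = config$region_dialect)
  cfg_hash <- content_hash(attr(config, "effective_yaml"))
  version <- as.character(utils::packageVersion("isoregion"))
  provenance <- c(
    paste0("isoregion version ", version),
    paste0("config hash ", cfg_hash),
    paste0("policy ", paste(names(config$policy), "=",
                            vapply(config$policy, as.character, character(1)),
                            collapse = ", "))
  )
  quants <- list(); failed <- character(0)
  for (s in config$samples) {
    res <- tryCatch({
      sliced <- isTRUE(s$sliced)
      quantify_sample(
        s$bam, spec, policy = config$policy, sample_id = s$sample_id,
        library_size = s$library_size,
        library_size_source = if (sliced) "absent" else "provided"
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (isTRUE(config$strict)) {
        stop("sample ", s$sample_id, " failed: ", conditionMessage(res))
      }
      failed[s$sample_id] <- conditionMessage(res)
      next
    }
    quants[[s$sample_id]] <- res
    write_quant_tsv(res, file.path(config$output_dir,
                                   paste0(s$sample_id, ".quant.tsv")),
                    header_comments = provenance)
  }
  if (length(quants) < 3L) {
    stop("fewer than 3 samples quantified; cannot build tertile groups")
  }
  ratios <- vapply(quants, function(q) {
    num <- q[q$variant_id == config$numerator, ]
    den <- q[q$variant_id == config$denominator, ]
    if (!nrow(num) || !nrow(den)) {
      stop("ratio variants not found in quantification: ",
           config$numerator, " / ", config$denominator)
    }
    if (!is.na(num$fpkm) && !is.na(den$fpkm)) {
      log_ratio(num$fpkm, den$fpkm, config$pseudocount)
    } else {
      log_ratio(num$rate, den$rate, config$pseudocount)
    }
  }, numeric(1))
  cohort <- assign_tertile_groups(names(quants), unname(ratios))
  write_cohort_table(cohort, file.path(config$output_dir, "cohort_groups.tsv"),
                     pseudocount = config$pseudocount)
  writeLines(c(paste0("# ", provenance), attr(config, "effective_yaml")),
             file.path(config$output_dir, "effective_config.yaml"))
  list(quants = quants, cohort = cohort, failed = failed,
       output_dir = config$output_dir)
}
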