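#' Normalize a genomic coordinate pair into a discriminating region
#'
#' Variant-discriminating regions are often communicated with minus-strand
#' coordinates printed in descending order (e.g. chr7:140725145-140719327).
#' This helper accepts either order and returns the canonical 1-based
#' inclusive interval with `start <= end`.
#'
#' @param chrom Chromosome / contig name.
#' @param a,b Positive integer genomic coordinates, in either order.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @param variant_id Optional variant identifier attached to the region.
#'
#' @return A one-row data.frame with columns `variant_id`, `chrom`, `start`,
#'   `end`, `strand`, `length_bp` (`end - start + 1`).
#' @examples
#' normalize_coordinates("chr7", 140725145, 140719327, "-", "BRAF-204")
#' @export
normalize_coordinates <- function(chrom, a, b, strand = ".", variant_id = NA_character_) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b) ||
      a < 1 || b < 1 || a != round(a) || b != round(b)) {
    stop("coordinates must be positive integers (1-based); got a=", a, ", b=", b)
  }
  if (!strand %in% c("+", "-", ".")) {
    stop("strand must be one of '+', '-', '.'")
  }
  start <- min(a, b); end <- max(a, b)
  data.frame(
    variant_id = variant_id, chrom = chrom,
    start = start, end = end, strand = strand,
    length_bp = end - start + 1,
    stringsAsFactors = FALSE
  )
}

#' Build a region specification from discriminating regions
#'
#' A region specification names, for each transcript variant, the genomic
#' interval covered by that variant alone, so that fragments aligned there
#' identify the variant unambiguously. Regions must be pairwise
#' non-overlapping on the same chromosome; otherwise a "specifically
#' mapping" count would be ambiguous.
#'
#' @param regions data.frame with columns `variant_id`, `chrom`, `start`,
#'   `end`, and optionally `strand`. Coordinate pairs may be in either
#'   order; they are normalized.
#' @param genome_build Informational genome build label.
#'
#' @return An object of class `region_spec`: a data.frame with columns
#'   `variant_id`, `chrom`, `start`, `end`, `strand`, `length_bp` and a
#'   `genome_build` attribute.
#' @examples
#' region_spec(data.frame(
#'   variant_id = c("BRAF-204", "BRAF-220"),
#'   chrom = "chr7",
#'   start = c(140725145, 140732564),
#'   end = c(140719327, 140730665),
#'   strand = "-"
#' ))
#' @export
region_spec <- function(regions, genome_build = NA_character_) {
  required <- c("variant_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols)) {
    stop("regions is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(regions$strand)) regions$strand <- rep(".", nrow(regions))
  if (nrow(regions) == 0L) {
    out <- data.frame(
      variant_id = character(), chrom = character(),
      start = numeric(), end = numeric(), strand = character(),
      length_bp = numeric(), stringsAsFactors = FALSE
    )
  } else {
    rows <- lapply(seq_len(nrow(regions)), function(i) {
      normalize_coordinates(
        regions$chrom[i], regions$start[i], regions$end[i],
        as.character(regions$strand[i]), as.character(regions$variant_id[i])
      )
    })
    out <- do.call(rbind, rows)
  }
  validate_region_spec(out)
  attr(out, "genome_build") <- genome_build
  class(out) <- c("region_spec", "data.frame")
  out
}

validate_region_spec <- function(df) {
  dup <- df$variant_id[duplicated(df$variant_id)]
  if (length(dup)) {
    stop("duplicate variant_id in region specification: ",
         paste(unique(dup), collapse = ", "))
  }
  if (nrow(df) >= 2L) {
    for (i in seq_len(nrow(df) - 1L)) {
      for (j in seq((i + 1L), nrow(df))) {
        if (df$chrom[i] == df$chrom[j] &&
            df$start[i] <= df$end[j] && df$start[j] <= df$end[i]) {
          stop("overlapping regions: ", df$variant_id[i], " (", df$chrom[i],
               ":", df$start[i], "-", df$end[i], ") and ", df$variant_id[j],
               " (", df$chrom[j], ":", df$start[j], "-", df$end[j], ")")
        }
      }
    }
  }
  invisible(df)
}

#' Read a region specification from a GTF or BED file
#'
#' The GTF dialect is tab-separated, 1-based inclusive, with a
#' `variant_id "<id>";` attribute; coordinate pairs printed in descending
#' order (the minus-strand convention) are accepted and normalized. The BED
#' dialect is BED6 (0-based half-open) with the name column carrying the
#' variant id; intervals are converted to 1-based inclusive internally
#' (`start = bed_start + 1`).
#'
#' @param path Path to the file.
#' @param dialect `"gtf"` or `"bed"`.
#' @param genome_build Informational genome build label.
#'
#' @return A [region_spec] object.
#' @seealso [write_region_spec()] for the inverse operation.
#' @export
read_region_spec <- function(path, dialect = c("gtf", "bed"), genome_build = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (dialect == "gtf") {
      if (length(fields) < 9L) {
        stop("malformed GTF line ", i, " in ", path, ": expected 9 tab-separated fields, got ",
             length(fields))
      }
      m <- regmatches(fields[9], regexec('variant_id[ =]+"?([^";]+)"?', fields[9]))[[1]]
      if (length(m) < 2L) {
        stop("malformed GTF line ", i, " in ", path, ": no variant_id attribute")
      }
      a <- suppressWarnings(as.numeric(fields[4]))
      b <- suppressWarnings(as.numeric(fields[5]))
      if (is.na(a) || is.na(b)) {
        stop("malformed GTF line ", i, " in ", path, ": non-numeric coordinates")
      }
      rows[[k]] <- normalize_coordinates(fields[1], a, b, fields[7], m[2])
    } else {
      if (length(fields) < 4L) {
        stop("malformed BED line ", i, " in ", path, ": expected >= 4 tab-separated fields, got ",
             length(fields))
      }
      bed_start <- suppressWarnings(as.numeric(fields[2]))
      bed_end <- suppressWarnings(as.numeric(fields[3]))
      if (is.na(bed_start) || is.na(bed_end)) {
        stop("malformed BED line ", i, " in ", path, ": non-numeric coordinates")
      }
      if (bed_end <= bed_start) {
        stop("malformed BED line ", i, " in ", path, ": end must exceed start in half-open BED")
      }
      strand <- if (length(fields) >= 6L) fields[6] else "."
      rows[[k]] <- normalize_coordinates(fields[1], bed_start + 1, bed_end, strand, fields[4])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character(), length_bp = numeric(),
               stringsAsFactors = FALSE)
  region_spec(df, genome_build = genome_build)
}

#' Write a region specification to a GTF or BED file
#'
#' Round-trips with [read_region_spec()]: internal 1-based inclusive
#' coordinates are written as-is for GTF and converted back to 0-based
#' half-open for BED.
#'
#' @param spec A [region_spec] object.
#' @param path Output path.
#' @param dialect `"gtf"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_region_spec <- function(spec, path, dialect = c("gtf", "bed")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(spec, "region_spec"))
  if (dialect == "gtf") {
    lines <- sprintf(
      '%s\tisoregion\tdiscriminating_region\t%d\t%d\t.\t%s\t.\tvariant_id "%s";',
      spec$chrom, as.integer(spec$start), as.integer(spec$end),
      spec$strand, spec$variant_id
    )
  } else {
    lines <- sprintf(
      "%s\t%d\t%d\t%s\t.\t%s",
      spec$chrom, as.integer(spec$start) - 1L, as.integer(spec$end),
      spec$variant_id, spec$strand
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.region_spec <- function(x, ...) {
  cat("Region specification (", nrow(x), " discriminating region",
      if (nrow(x) != 1L) "s", ")\n", sep = "")
  if (!is.na(attr(x, "genome_build"))) {
    cat("genome build:", attr(x, "genome_build"), "\n")
  }
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# Apply a chromosome alias map (e.g. c(chr7 = "7")) to a spec so region
# names match the naming convention of a particular BAM.
apply_chrom_alias <- function(spec, alias = NULL) {
  if (is.null(alias) || !length(alias)) return(spec)
  hit <- spec$chrom %in% names(alias)
  spec$chrom[hit] <- unname(alias[spec$chrom[hit]])
  spec
}

regions_as_granges <- function(spec, alias = NULL) {
  spec <- apply_chrom_alias(spec, alias)
  GenomicRanges::GRanges(
    seqnames = spec$chrom,
    ranges = IRanges::IRanges(start = spec$start, end = spec$end),
    strand = ifelse(spec$strand == ".", "*", spec$strand),
    variant_id = spec$variant_id
  )
}
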