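#' Read a BED file as an interval tibble
#'
#' Parses a BED3+ file (tab- or whitespace-separated, optionally
#' gzip-compressed) into a tibble of genomic intervals. Coordinates follow
#' the BED convention: 0-based, half-open `[start, end)`. Columns beyond the
#' third (name, score, strand, ...) are ignored; strand is ignored
#' throughout the package. Lines starting with `#`, `track` or `browser`
#' and blank lines are skipped. Input order is preserved and overlapping
#' intervals are NOT merged here; see [merge_intervals()].
#'
#' @param path Path to a BED file (`.bed` or `.bed.gz`).
#' @param name Optional label for the set, stored in the `"coloc_name"`
#'   attribute (defaults to the file's base name).
#' @return A tibble with columns `chrom` (character), `start`, `end`
#'   (doubles holding non-negative integers, `end > start`).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t10\t20", "chr1\t15\t30"), bed)
#' read_bed(bed)
#' @export
read_bed <- function(path, name = NULL) {
  if (!file.exists(path)) {
    abort(paste0("BED file not found: ", path))
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*$|^#|^track\\b|^browser\\b", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- idx[which(nf < 3)[1]]
    abort(paste0("line ", bad, ": fewer than 3 columns"))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad_num <- which(is.na(start) | is.na(end) |
                     start != floor(start) | end != floor(end))
  if (length(bad_num) > 0) {
    abort(paste0("line ", idx[bad_num[1]],
                 ": non-integer coordinate"))
  }
  bad_coord <- which(end <= start | start < 0)
  if (length(bad_coord) > 0) {
    abort(paste0("line ", idx[bad_coord[1]],
                 ": invalid interval (need 0 <= start < end), got [",
                 start[bad_coord[1]], ", ", end[bad_coord[1]], ")"))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  attr(out, "coloc_name") <- name %||% sub("\\.bed(\\.gz)?$", "", basename(path))
  out
}

#' Write an interval tibble as BED3
#'
#' @param x Interval tibble (columns `chrom`, `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  readr::write_tsv(
    dplyr::select(x, "chrom", "start", "end"),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read a chrom.sizes file as a genome tibble
#'
#' A genome is the background against which coverage probabilities are
#' computed: a two-column (chromosome name, length in bases) table whose
#' total length is the background size G.
#'
#' @param path Path to a UCSC-style chrom.sizes TSV.
#' @return A tibble with columns `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("chrom.sizes file not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$|^#", lines)]
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < 2)) {
    abort("chrom.sizes: every line needs a name and a length")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  size <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(size) || any(size != floor(size))) {
    abort("chrom.sizes: non-integer chromosome length")
  }
  if (any(size <= 0)) {
    abort(paste0("chrom.sizes: non-positive length for ",
                 chrom[which(size <= 0)[1]]))
  }
  if (anyDuplicated(chrom)) {
    abort(paste0("chrom.sizes: duplicate chromosome name ",
                 chrom[duplicated(chrom)][1]))
  }
  tibble(chrom = chrom, size = size)
}

#' Total genome size
#'
#' @param genome Genome tibble from [read_chrom_sizes()] or [sim_genome()].
#' @return Total length in bases.
#' @export
genome_size <- function(genome) {
  check_genome(genome)
  sum(genome$size)
}
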