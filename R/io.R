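#' Read a BED3/BED4/BED6 file
#'
#' Parses 0-based half-open BED records; `#`, `track` and `browser` lines
#' are skipped. Missing optional columns get defaults (`name = "."`,
#' `score = 0`, `strand = "+"`; a "." strand also maps to "+"). A malformed
#' line (too few fields, non-numeric coordinates, start >= end) is an error
#' naming the offending line number.
#'
#' @param path Path to the BED file.
#' @return BED6-style data.frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`); empty files give an empty data.frame, not an error.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$|^#|^track\\b|^browser\\b", lines)
  lnum <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_bed())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED line ", lnum[which(nf < 3)[1]], ": fewer than 3 fields")
  get <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i) f[i] else default, character(1))
  chrom <- get(1, NA_character_)
  start_s <- get(2, NA_character_)
  end_s <- get(3, NA_character_)
  start <- suppressWarnings(as.numeric(start_s))
  end <- suppressWarnings(as.numeric(end_s))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad))
    stop("BED line ", lnum[bad[1]], ": non-numeric coordinates ('",
         start_s[bad[1]], "', '", end_s[bad[1]], "')")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("BED line ", lnum[bad[1]], ": invalid interval [",
         start[bad[1]], ", ", end[bad[1]], ")")
  score <- suppressWarnings(as.numeric(get(5, "0")))
  score[!is.finite(score)] <- 0
  strand <- get(6, "+")
  strand[!strand %in% c("+", "-")] <- "+"
  as_bed_df(chrom, start, end, name = get(4, "."), score = score,
            strand = strand)
}

#' Write records as BED6
#'
#' @param x BED-style data.frame; missing `name`/`score`/`strand` columns
#'   get defaults.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- data.frame(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if (is.null(x$name)) "." else x$name,
    score = if (is.null(x$score)) 0 else x$score,
    strand = if (is.null(x$strand)) "+" else x$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an occupancy track as fixed-step WIG
#'
#' Emits one `fixedStep` block per chromosome with `span = step = bin_size`
#' and the mean track value within each bin; a trailing partial bin is
#' written as its own block with `span` equal to its actual width, averaged
#' over that width. WIG coordinates are 1-based.
#'
#' @param track An `occupancy_track` (raw or normalized).
#' @param path Output path.
#' @param bin_size Bin width in bp (default 200).
#' @return `path`, invisibly.
#' @export
write_wig <- function(track, path, bin_size = 200) {
  stopifnot(inherits(track, "occupancy_track"))
  if (bin_size < 1) stop("bin_size must be >= 1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("track type=wiggle_0 name=nucleosome_occupancy_",
                    track$kind), con)
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    L <- length(v)
    nfull <- L %/% bin_size
    if (nfull > 0) {
      means <- colMeans(matrix(v[seq_len(nfull * bin_size)],
                               nrow = bin_size))
      writeLines(c(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                           chrom, bin_size, bin_size),
                   format(means, scientific = FALSE, trim = TRUE)), con)
    }
    rem <- L - nfull * bin_size
    if (rem > 0) {
      writeLines(c(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                           chrom, nfull * bin_size + 1, rem, rem),
                   format(mean(v[(nfull * bin_size + 1):L]),
                          scientific = FALSE, trim = TRUE)), con)
    }
  }
  invisible(path)
}

#' Read a run configuration file
#'
#' The configuration is a YAML (or plain `key: value`) file whose entries
#' mirror the arguments of [run_config()]; entries not present fall back to
#' the defaults.
#'
#' @param path Path to the YAML config file.
#' @param ... Overrides applied after the file is read (flags beat file).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(run_config, cfg)
}
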