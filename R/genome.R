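#' Define a genome model
#'
#' A genome model is the minimal reference the pipeline needs: an ordered set
#' of chromosome names with their lengths in bp. All coordinates in the
#' package are 0-based half-open (BED convention).
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#'   Names must be unique and lengths strictly positive.
#'
#' @return An object of class `genome_model`: a named integer-valued numeric
#'   vector of chromosome lengths.
#' @examples
#' genome_model(c(chrS = 1e5))
#' @export
genome_model <- function(chromosomes) {
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(chromosomes)))
    stop("chromosome names must be unique")
  if (any(!is.finite(chromosomes)) || any(chromosomes <= 0))
    stop("chromosome lengths must be positive and finite")
  x <- floor(as.numeric(chromosomes))
  names(x) <- names(chromosomes)
  class(x) <- "genome_model"
  x
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x), "chromosome(s),",
      format(sum(unclass(x)), big.mark = ","), "bp total\n")
  for (nm in names(x)) cat(" ", nm, unclass(x)[[nm]], "bp\n")
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  unclass(genome)[[chrom]]
}

check_chroms <- function(chroms, genome, what = "record") {
  bad <- setdiff(unique(chroms), names(genome))
  if (length(bad))
    stop(what, " on unknown chromosome(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Derive a bounded child seed from a base seed and a stream index, keeping
# results inside R's 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + k * 7919) %% .Machine$integer.max)
}

empty_bed <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

as_bed_df <- function(chrom, start, end, name = ".", score = 0, strand = "+") {
  if (length(chrom) == 0) return(empty_bed())
  data.frame(chrom = chrom, start = start, end = end,
             name = name, score = score, strand = strand,
             stringsAsFactors = FALSE)
}
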