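#' Estimate the genome-average read count
#'
#' The Poisson rate for the occupancy test: the mean of the raw per-base
#' fragment counts, genome-wide or per chromosome. Only raw (integer-count)
#' tracks are meaningful here; the 0-100 normalized scale is not a count.
#'
#' @param track A raw `occupancy_track`.
#' @param scope `"genome"` (one rate) or `"chromosome"` (named vector).
#' @return Positive mean count(s); an all-zero track is an error because the
#'   Poisson test is undefined at rate 0.
#' @export
estimate_lambda <- function(track, scope = c("genome", "chromosome")) {
  stopifnot(inherits(track, "occupancy_track"))
  if (track$kind != "raw")
    stop("lambda must be estimated from the raw count track")
  scope <- match.arg(scope)
  lam <- if (scope == "genome") {
    tot <- sum(vapply(track$values, sum, numeric(1)))
    nb <- sum(vapply(track$values, length, numeric(1)))
    tot / nb
  } else {
    vapply(track$values, mean, numeric(1))
  }
  if (any(lam <= 0))
    stop("track has zero mean coverage; Poisson rate undefined")
  lam
}

#' Poisson significance of a read count
#'
#' Two modes. `"upper"` (default) returns the upper-tail p-value
#' `P(X >= k) = 1 - sum_{i<k} e^(-lambda) lambda^i / i!`, the probability of
#' seeing at least the observed count under the genome-average rate — a
#' proper p-value, non-increasing in `k`. `"pmf"` returns the point mass
#' `e^(-lambda) lambda^k / k!` itself; it is kept because some published
#' analyses threshold the pmf directly, but note it is not monotone in `k`
#' and is small for *any* k when lambda is large. Both are computed through
#' log-space-stable routines.
#'
#' @param k Non-negative integer count(s).
#' @param lambda Positive Poisson rate.
#' @param mode `"upper"` or `"pmf"`.
#' @return p-value(s) in `[0, 1]`; `k = 0` gives 1 in upper-tail mode.
#' @examples
#' poisson_pvalue(5, 2)            # ~0.0527
#' poisson_pvalue(0, 1, "pmf")     # exp(-1)
#' @export
poisson_pvalue <- function(k, lambda, mode = c("upper", "pmf")) {
  mode <- match.arg(mode)
  if (any(k < 0)) stop("k must be >= 0")
  if (any(k != floor(k))) stop("k must be integer-valued")
  if (any(lambda <= 0)) stop("lambda must be > 0")
  switch(mode,
         upper = stats::ppois(k - 1, lambda, lower.tail = FALSE),
         pmf = stats::dpois(k, lambda))
}

#' Call nucleosome occupancy at SNP sites
#'
#' For each SNP the observed count `k` is the raw track value at the SNP
#' base (fragments covering that base); its significance against the
#' genome-average rate `lambda` is the Poisson p-value, and the site is
#' called occupied when `p <= alpha` (default 0.05). An optional window
#' takes the maximum per-base count within `+/-window` bp instead of the
#' single base.
#'
#' @param snps BED-style data.frame of SNP sites (`chrom`, `start`, and a
#'   `name` column used as site id when present).
#' @param track A raw `occupancy_track`.
#' @param lambda Poisson rate; estimated genome-wide from `track` when NULL.
#' @param alpha Significance cutoff in (0, 1).
#' @param mode Passed to [poisson_pvalue()].
#' @param window Half-window in bp for the count (0 = the SNP base only).
#' @param adjust Apply Benjamini-Hochberg correction across sites before
#'   thresholding (off by default; the classical analysis uses raw p).
#'
#' @return data.frame (`site_id`, `chrom`, `pos`, `k`, `lambda`, `p_value`,
#'   `occupied`), one row per SNP in input order.
#' @export
classify_snp_occupancy <- function(snps, track, lambda = NULL, alpha = 0.05,
                                   mode = c("upper", "pmf"), window = 0,
                                   adjust = FALSE) {
  stopifnot(is.data.frame(snps), inherits(track, "occupancy_track"))
  mode <- match.arg(mode)
  if (track$kind != "raw")
    stop("occupancy calls require the raw count track")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (window < 0) stop("window must be >= 0")
  if (is.null(lambda)) lambda <- estimate_lambda(track, "genome")
  bad <- setdiff(unique(snps$chrom), names(track$values))
  if (length(bad))
    stop("SNP on unknown chromosome(s): ", paste(bad, collapse = ", "))
  k <- vapply(seq_len(nrow(snps)), function(i) {
    v <- track$values[[snps$chrom[i]]]
    p <- snps$start[i]
    if (p < 0 || p >= length(v))
      stop("SNP position ", p, " outside ", snps$chrom[i])
    lo <- max(p - window, 0)
    hi <- min(p + window, length(v) - 1)
    max(v[(lo + 1):(hi + 1)])
  }, numeric(1))
  p <- poisson_pvalue(k, lambda, mode)
  p_eff <- if (adjust) stats::p.adjust(p, "BH") else p
  ids <- if (!is.null(snps$name)) snps$name else
    paste0(snps$chrom, ":", snps$start)
  data.frame(site_id = ids, chrom = snps$chrom, pos = snps$start,
             k = k, lambda = lambda, p_value = p,
             occupied = p_eff <= alpha,
             stringsAsFactors = FALSE)
}

#' Combine occupancy calls across cell types
#'
#' A SNP reaches consensus only when it is called occupied in *every* cell
#' type, the conservative rule for declaring a variant nucleosomal across
#' contexts.
#'
#' @param results Named list of per-cell-type data.frames from
#'   [classify_snp_occupancy()]; all must cover the same SNPs in the same
#'   order.
#' @return data.frame with `site_id`, one `occupied_<cell type>` column per
#'   input, and `consensus`.
#' @export
consensus_across_celltypes <- function(results) {
  stopifnot(is.list(results), length(results) >= 1)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("results must be a named list (one entry per cell type)")
  ids <- results[[1]]$site_id
  for (r in results) {
    if (!identical(r$site_id, ids))
      stop("SNP sets differ across cell types")
  }
  flags <- lapply(results, function(r) r$occupied)
  out <- data.frame(site_id = ids, stringsAsFactors = FALSE)
  for (ct in names(results)) out[[paste0("occupied_", ct)]] <- flags[[ct]]
  out$consensus <- Reduce(`&`, flags)
  out
}
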