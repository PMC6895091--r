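#' Intersect sites with a peak set
#'
#' BEDTools-default semantics: an overlap is at least 1 shared bp between
#' half-open intervals, strand-blind. Point sites (an SNP base) overlap a
#' peak iff the peak's interval contains the base; interval sites use the
#' >= 1 bp rule. An optional `slop` widens every peak on both sides to
#' support "near a peak" annotation.
#'
#' @param sites data.frame with `chrom`, `start` and optionally `end`
#'   (defaults to `start + 1`, i.e. point sites).
#' @param peaks data.frame with `chrom`, `start`, `end`.
#' @param slop Extend each peak by this many bp on both sides (default 0 =
#'   strict overlap).
#'
#' @return list with `overlaps` (logical, one per site) and `hits`
#'   (data.frame `site`, `peak` of overlapping index pairs). Sites on
#'   chromosomes absent from the peak set simply do not overlap; an unknown
#'   chromosome triggers a warning, not an error.
#' @export
intersect_sites <- function(sites, peaks, slop = 0) {
  stopifnot(is.data.frame(sites), is.data.frame(peaks))
  if (slop < 0) stop("slop must be >= 0")
  send <- if (is.null(sites$end)) sites$start + 1 else sites$end
  if (nrow(sites) == 0 || nrow(peaks) == 0)
    return(list(overlaps = logical(nrow(sites)),
                hits = data.frame(site = integer(), peak = integer())))
  if (any(peaks$start >= peaks$end)) stop("peak intervals must have start < end")
  novel <- setdiff(unique(sites$chrom), unique(peaks$chrom))
  if (length(novel))
    warning("site chromosome(s) absent from peak set: ",
            paste(novel, collapse = ", "))
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$start + 1, send))
  pgr <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(peaks$start + 1 - slop,
                                                 peaks$end + slop))
  hits <- GenomicRanges::findOverlaps(sgr, pgr)
  ov <- logical(nrow(sites))
  ov[unique(S4Vectors::queryHits(hits))] <- TRUE
  list(overlaps = ov,
       hits = data.frame(site = S4Vectors::queryHits(hits),
                         peak = S4Vectors::subjectHits(hits)))
}

#' Membership of sites in several peak sets
#'
#' @param sites data.frame of anchor sites (`chrom`, `start`, optional
#'   `name` used for row names).
#' @param peaksets Uniquely named list of peak data.frames (histone marks,
#'   open chromatin, repeats, ...).
#' @param slop Passed to [intersect_sites()].
#' @return Logical matrix, one row per site, one column per peak set, in the
#'   order given.
#' @export
annotate_sites <- function(sites, peaksets, slop = 0) {
  stopifnot(is.data.frame(sites), is.list(peaksets))
  if (length(peaksets) > 0 &&
      (is.null(names(peaksets)) || anyDuplicated(names(peaksets))))
    stop("peak set names must be unique and non-empty")
  m <- matrix(logical(0), nrow = nrow(sites), ncol = length(peaksets),
              dimnames = list(sites$name, names(peaksets)))
  for (mark in names(peaksets))
    m[, mark] <- suppressWarnings(
      intersect_sites(sites, peaksets[[mark]], slop = slop)$overlaps)
  m
}

#' Classify chromatin state from histone-mark membership
#'
#' Marks are partitioned into an activating set (default H3K27ac, H3K4me1,
#' H3K4me3, H3K36me3) and a repressive set (default H3K27me3, H3K9me3). A
#' site carrying at least one mark from each set is *bivalent* (poised
#' between active and repressed states); only activating marks -> *active*;
#' only repressive marks -> *repressed*; no marks -> *none*. H3K36me3 sits
#' in the activating set as a transcription-elongation mark, but the
#' partition is fully configurable.
#'
#' @param membership Logical matrix or data.frame (sites x marks), e.g. from
#'   [annotate_sites()]. Every column must belong to one of the two sets.
#' @param active_marks,repressive_marks Character vectors partitioning the
#'   mark columns.
#' @return data.frame with `site_id` and `state`
#'   (active/repressed/bivalent/none), plus one logical column per mark.
#' @export
classify_chromatin_state <- function(membership,
                                     active_marks = c("H3K27ac", "H3K4me1",
                                                      "H3K4me3", "H3K36me3"),
                                     repressive_marks = c("H3K27me3",
                                                          "H3K9me3")) {
  m <- as.matrix(membership)
  if (!is.logical(m)) stop("membership must be logical")
  marks <- colnames(m)
  if (is.null(marks)) stop("membership must have mark column names")
  both <- intersect(active_marks, repressive_marks)
  if (length(both))
    stop("mark(s) in both sets: ", paste(both, collapse = ", "))
  unknown <- setdiff(marks, c(active_marks, repressive_marks))
  if (length(unknown))
    stop("mark(s) in neither the active nor the repressive set: ",
         paste(unknown, collapse = ", "))
  a <- if (any(marks %in% active_marks))
    rowSums(m[, marks %in% active_marks, drop = FALSE]) > 0 else
      rep(FALSE, nrow(m))
  r <- if (any(marks %in% repressive_marks))
    rowSums(m[, marks %in% repressive_marks, drop = FALSE]) > 0 else
      rep(FALSE, nrow(m))
  state <- ifelse(a & r, "bivalent",
                  ifelse(a, "active", ifelse(r, "repressed", "none")))
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  out <- data.frame(site_id = ids, state = state, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(m, row.names = NULL))
}

#' Build a position weight matrix
#'
#' Converts a 4 x L count (or probability) matrix over A, C, G, T into a
#' pseudocount-regularised probability matrix whose columns each sum to 1.
#'
#' @param counts Numeric matrix, rows A, C, G, T (row names optional but
#'   checked when present), one column per motif position.
#' @param tf_name Transcription factor name.
#' @param pseudocount Added to every cell before column normalization.
#' @return A `pwm` object: list with `tf_name`, `prob` (4 x L), `logodds`
#'   (log2(p / 0.25) against a uniform background) and `length`.
#' @export
pwm <- function(counts, tf_name = "TF", pseudocount = 0.25) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM needs 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts)) &&
      !identical(toupper(rownames(counts)), c("A", "C", "G", "T")))
    stop("PWM rows must be A, C, G, T in order")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  p <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  if (any(!is.finite(p))) stop("empty PWM column")
  rownames(p) <- c("A", "C", "G", "T")
  structure(list(tf_name = tf_name, prob = p, logodds = log2(p / 0.25),
                 length = ncol(p)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm:", x$tf_name, "-", x$length, "positions, consensus",
      paste(c("A", "C", "G", "T")[apply(x$prob, 2, which.max)],
            collapse = ""), "\n")
  invisible(x)
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "")[[1]]),
        collapse = "")
}

seq_to_index <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("sequence contains non-ACGT characters")
  idx
}

#' Best PWM match score in a sequence
#'
#' Scans every offset on both strands; the score at an offset is the sum of
#' per-position log2 odds (motif probability over a uniform 0.25
#' background). Used to quantify how well a window harbours a binding site.
#'
#' @param pwm A [pwm()] object.
#' @param seq DNA string (A/C/G/T), at least as long as the motif.
#' @return list with `score` (the maximum), `offset` (0-based, on the given
#'   strand's forward coordinates) and `strand`.
#' @export
scan_pwm <- function(pwm, seq) {
  stopifnot(inherits(pwm, "pwm"))
  if (nchar(seq) < pwm$length)
    stop("sequence shorter than the motif (", pwm$length, " bp)")
  best <- list(score = -Inf, offset = NA_integer_, strand = NA_character_)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    idx <- seq_to_index(s)
    n_off <- length(idx) - pwm$length + 1
    for (o in seq_len(n_off)) {
      sc <- sum(pwm$logodds[cbind(idx[o:(o + pwm$length - 1)],
                                  seq_len(pwm$length))])
      if (sc > best$score)
        best <- list(score = sc, offset = o - 1L, strand = strand)
    }
  }
  best
}

#' Score a variant's effect on a TF motif
#'
#' Scores the reference and alternate windows around a variant with
#' [scan_pwm()] (all offsets, both strands) and reports the change in best
#' match score; a large negative `delta` means the alternate allele disrupts
#' the binding site, a large positive one creates or strengthens it.
#'
#' @param pwm A [pwm()] object.
#' @param ref_window,alt_window Equal-length DNA windows differing at
#'   exactly one base, each at least as long as the motif.
#' @return list with `best_ref_score`, `best_alt_score` and
#'   `delta = best_alt_score - best_ref_score`.
#' @export
score_variant_tf_effect <- function(pwm, ref_window, alt_window) {
  stopifnot(inherits(pwm, "pwm"))
  if (nchar(ref_window) != nchar(alt_window))
    stop("ref and alt windows must have equal length")
  if (nchar(ref_window) < pwm$length)
    stop("windows shorter than the motif (", pwm$length, " bp)")
  diffs <- which(strsplit(toupper(ref_window), "")[[1]] !=
                   strsplit(toupper(alt_window), "")[[1]])
  if (length(diffs) != 1)
    stop("windows must differ at exactly one base (found ",
         length(diffs), " differences)")
  ref <- scan_pwm(pwm, ref_window)
  alt <- scan_pwm(pwm, alt_window)
  list(best_ref_score = ref$score, best_alt_score = alt$score,
       delta = alt$score - ref$score)
}
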