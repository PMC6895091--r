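#' Describe the promoter nucleosome architecture to simulate
#'
#' Parameters of the canonical metazoan promoter chromatin layout: a
#' nucleosome-depleted region (NDR) centred on the TSS, flanked by
#' well-positioned -1 and +1 nucleosomes, with an equally spaced array of
#' nucleosomes downstream of the +1.
#'
#' @param tss_positions data.frame with columns `chrom`, `pos` (0-based bp)
#'   and `strand` ("+" or "-").
#' @param ndr_width Width of the nucleosome-free region in bp (>= 0).
#' @param spacing Centre-to-centre nucleosome repeat length in bp (>= 147).
#' @param n_array Number of phased array nucleosomes downstream of the +1.
#' @param fuzziness_sd Standard deviation in bp of Gaussian jitter applied to
#'   each dyad position (0 = perfectly positioned nucleosomes).
#' @param occupancy_prob Probability that a chromatin template carries each
#'   nucleosome; thins the sampled read depth per nucleosome.
#' @param background_rate Non-nucleosomal background reads per bp.
#'
#' @return An object of class `nucleosome_model` (a validated list).
#' @examples
#' tss <- data.frame(chrom = "chrS", pos = 5e4, strand = "+")
#' nucleosome_model(tss, spacing = 200, n_array = 5)
#' @export
nucleosome_model <- function(tss_positions,
                             ndr_width = 140,
                             spacing = 200,
                             n_array = 5,
                             fuzziness_sd = 10,
                             occupancy_prob = 0.9,
                             background_rate = 0.01) {
  stopifnot(is.data.frame(tss_positions),
            all(c("chrom", "pos") %in% names(tss_positions)))
  if (is.null(tss_positions$strand)) tss_positions$strand <- "+"
  if (!all(tss_positions$strand %in% c("+", "-")))
    stop("TSS strand must be '+' or '-'")
  if (ndr_width < 0) stop("ndr_width must be >= 0")
  if (spacing < 147) stop("spacing must be >= 147 bp (nucleosome footprint)")
  if (n_array < 0) stop("n_array must be >= 0")
  if (fuzziness_sd < 0) stop("fuzziness_sd must be >= 0")
  if (occupancy_prob < 0 || occupancy_prob > 1)
    stop("occupancy_prob must be in [0, 1]")
  if (background_rate < 0) stop("background_rate must be >= 0")
  structure(list(tss_positions = tss_positions,
                 ndr_width = ndr_width,
                 spacing = spacing,
                 n_array = n_array,
                 fuzziness_sd = fuzziness_sd,
                 occupancy_prob = occupancy_prob,
                 background_rate = background_rate),
            class = "nucleosome_model")
}

#' Lay out nucleosome dyads around every TSS
#'
#' For each TSS the NDR is centred on the TSS; the +1 dyad sits
#' `ndr_width/2 + 73` bp downstream of the TSS (so the +1 footprint abuts the
#' NDR edge), the -1 dyad mirrors it upstream, and `n_array` further dyads
#' follow the +1 at multiples of `spacing`, all strand-aware. Each dyad is
#' then jittered by `Normal(0, fuzziness_sd)`; jitter never moves a dyad into
#' the NDR (draws violating the NDR exclusion are truncated to its edge).
#'
#' @param genome A [genome_model()].
#' @param model A [nucleosome_model()].
#' @param seed Integer seed; the layout is deterministic given (inputs, seed).
#'
#' @return A `synthetic_truth` object: a list with `genome`, `model`, `tss`,
#'   and `dyads` (data.frame `chrom`, `pos`, `tss_id`, `role`).
#' @export
build_nucleosome_map <- function(genome, model, seed = NULL) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(model, "nucleosome_model"))
  tss <- model$tss_positions
  check_chroms(tss$chrom, genome, "TSS")
  lens <- unclass(genome)[tss$chrom]
  if (any(tss$pos < 0) || any(tss$pos >= lens))
    stop("TSS position outside its chromosome")

  half_ndr <- model$ndr_width / 2
  plus1_off <- half_ndr + 73
  offs <- c(-plus1_off, plus1_off,
            if (model$n_array > 0) plus1_off + seq_len(model$n_array) * model$spacing)
  roles <- c("-1", "+1",
             if (model$n_array > 0) paste0("+", 1 + seq_len(model$n_array)))

  dyads <- with_seed(seed, {
    out <- vector("list", nrow(tss))
    for (i in seq_len(nrow(tss))) {
      dir <- if (tss$strand[i] == "-") -1 else 1
      pos <- tss$pos[i] + dir * offs
      if (model$fuzziness_sd > 0) {
        jit <- stats::rnorm(length(pos), 0, model$fuzziness_sd)
        pos <- pos + round(jit)
        # keep the NDR nucleosome-free: clamp any dyad jittered into it
        d <- dir * (pos - tss$pos[i])
        pos <- ifelse(d <= half_ndr, tss$pos[i] + dir * ceiling(half_ndr + 1), pos)
      }
      L <- chrom_length(genome, tss$chrom[i])
      pos <- pmin(pmax(pos, 0), L - 1)
      out[[i]] <- data.frame(chrom = tss$chrom[i], pos = pos,
                             tss_id = i, role = roles,
                             stringsAsFactors = FALSE)
    }
    if (length(out) == 0)
      data.frame(chrom = character(), pos = numeric(), tss_id = integer(),
                 role = character(), stringsAsFactors = FALSE)
    else do.call(rbind, out)
  })
  rownames(dyads) <- NULL
  structure(list(genome = genome, model = model, tss = tss, dyads = dyads),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", nrow(x$tss), "TSS,", nrow(x$dyads), "dyads")
  if (!is.null(x$snps)) cat(",", nrow(x$snps), "labelled SNPs")
  cat("\n")
  invisible(x)
}

#' Sample MNase-seq-like aligned reads from a nucleosome map
#'
#' Each nucleosome sheds `Poisson(depth_per_nucleosome * occupancy_prob)`
#' mononucleosomal fragments of 147 bp centred on its dyad; each fragment is
#' reported as a single-end read of `read_length` bp sequenced from a
#' uniformly chosen fragment end ("+" from the left end, "-" from the right).
#' Uniform strand-balanced background reads are added at
#' `model$background_rate` per bp. Reads are clipped to chromosome bounds.
#'
#' @param truth A `synthetic_truth` from [build_nucleosome_map()].
#' @param depth_per_nucleosome Mean fragments per fully occupied nucleosome.
#' @param read_length Read length in bp (>= 1).
#' @param seed Integer seed.
#'
#' @return BED6-style data.frame of aligned reads (`chrom`, `start`, `end`,
#'   `name`, `score`, `strand`), 0-based half-open.
#' @export
sample_reads <- function(truth, depth_per_nucleosome = 50, read_length = 36,
                         seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (depth_per_nucleosome < 0) stop("depth_per_nucleosome must be >= 0")
  if (read_length < 1) stop("read_length must be >= 1")
  genome <- truth$genome
  model <- truth$model

  with_seed(seed, {
    parts <- list()
    # nucleosomal reads
    if (nrow(truth$dyads) > 0 && depth_per_nucleosome > 0) {
      rate <- depth_per_nucleosome * model$occupancy_prob
      nfrag <- stats::rpois(nrow(truth$dyads), rate)
      idx <- rep.int(seq_len(nrow(truth$dyads)), nfrag)
      if (length(idx)) {
        d <- truth$dyads$pos[idx]
        chrom <- truth$dyads$chrom[idx]
        plus <- stats::runif(length(idx)) < 0.5
        start <- ifelse(plus, d - 73, d + 74 - read_length)
        parts$nuc <- data.frame(chrom = chrom, start = start,
                                end = start + read_length,
                                strand = ifelse(plus, "+", "-"),
                                stringsAsFactors = FALSE)
      }
    }
    # background reads, uniform and strand-balanced per chromosome
    if (model$background_rate > 0) {
      bg <- lapply(names(genome), function(chrom) {
        L <- chrom_length(genome, chrom)
        n <- stats::rpois(1, model$background_rate * L)
        if (n == 0) return(NULL)
        start <- floor(stats::runif(n, 0, max(L - read_length, 1)))
        data.frame(chrom = chrom, start = start, end = start + read_length,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
      })
      parts$bg <- do.call(rbind, bg)
    }
    reads <- do.call(rbind, parts)
    if (is.null(reads) || nrow(reads) == 0) return(empty_bed())
    # clip to chromosome bounds
    L <- unclass(genome)[reads$chrom]
    reads$start <- pmax(reads$start, 0)
    reads$end <- pmin(reads$end, L)
    reads <- reads[reads$end > reads$start, , drop = FALSE]
    rownames(reads) <- NULL
    as_bed_df(reads$chrom, reads$start, reads$end,
              name = paste0("read_", seq_len(nrow(reads))),
              score = 0, strand = reads$strand)
  })
}

#' Place labelled SNPs on nucleosomes and in linkers
#'
#' `n_on` SNPs are placed uniformly within +/-40 bp of randomly chosen dyads;
#' `n_linker` SNPs are placed by rejection sampling at least 100 bp from
#' every dyad. Labels are recorded in the returned truth object.
#'
#' @param truth A `synthetic_truth`.
#' @param n_on Number of on-nucleosome SNPs.
#' @param n_linker Number of linker/background SNPs.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling attempts per linker SNP before the
#'   placement is declared infeasible.
#'
#' @return The updated `synthetic_truth`, with `$snps`: a BED6-style
#'   data.frame plus a `label` column ("on_nucleosome" or "in_linker").
#' @export
generate_snp_sites <- function(truth, n_on, n_linker, seed = NULL,
                               max_tries = 1000L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_on < 0 || n_linker < 0) stop("SNP counts must be >= 0")
  if (n_on > 0 && nrow(truth$dyads) == 0)
    stop("no dyads available for on-nucleosome SNP placement")
  genome <- truth$genome

  snps <- with_seed(seed, {
    rows <- list()
    if (n_on > 0) {
      di <- sample.int(nrow(truth$dyads), n_on, replace = TRUE)
      off <- sample(-40:40, n_on, replace = TRUE)
      pos <- truth$dyads$pos[di] + off
      L <- unclass(genome)[truth$dyads$chrom[di]]
      pos <- pmin(pmax(pos, 0), L - 1)
      rows$on <- data.frame(chrom = truth$dyads$chrom[di], pos = pos,
                            label = "on_nucleosome", stringsAsFactors = FALSE)
    }
    if (n_linker > 0) {
      got <- list()
      for (j in seq_len(n_linker)) {
        placed <- FALSE
        for (t in seq_len(max_tries)) {
          chrom <- sample(names(genome), 1)
          pos <- floor(stats::runif(1, 0, chrom_length(genome, chrom)))
          dd <- truth$dyads[truth$dyads$chrom == chrom, "pos"]
          if (length(dd) == 0 || min(abs(dd - pos)) >= 100) {
            got[[j]] <- data.frame(chrom = chrom, pos = pos,
                                   label = "in_linker",
                                   stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place linker SNP >= 100 bp from every dyad; ",
               "genome too dense with nucleosomes")
      }
      rows$linker <- do.call(rbind, got)
    }
    do.call(rbind, rows)
  })
  if (is.null(snps)) snps <- data.frame(chrom = character(), pos = numeric(),
                                        label = character())
  rownames(snps) <- NULL
  bed <- as_bed_df(snps$chrom, snps$pos, snps$pos + 1,
                   name = paste0("snp_", seq_len(nrow(snps))),
                   score = 0, strand = "+")
  bed$label <- snps$label
  truth$snps <- bed
  truth
}

#' Build histone-mark peak sets over chosen sites
#'
#' For each configured mark one peak of the given width is centred on each
#' covered site, so mark co-occurrence (and hence downstream bivalency) is
#' controlled exactly by which marks share a site.
#'
#' @param sites BED-style data.frame of anchor sites; the `name` column
#'   identifies sites in `mark_config`.
#' @param mark_config Named list: mark name -> `list(width =, sites =)` where
#'   `sites` is a character vector of site names the mark covers.
#' @param genome Optional [genome_model()]; peaks are clipped to it.
#' @param seed Unused (peak placement is deterministic); accepted so all
#'   generators share a signature.
#'
#' @return Named list of BED4-style peak data.frames, one per mark.
#' @export
generate_peak_sets <- function(sites, mark_config, genome = NULL, seed = NULL) {
  stopifnot(is.data.frame(sites))
  if (length(mark_config) == 0) return(stats::setNames(list(), character(0)))
  if (is.null(names(mark_config)) || anyDuplicated(names(mark_config)))
    stop("mark_config must be a uniquely named list")
  lapply(stats::setNames(nm = names(mark_config)), function(mark) {
    cfg <- mark_config[[mark]]
    if (is.null(cfg$width) || cfg$width <= 0) stop("peak width must be > 0")
    unknown <- setdiff(cfg$sites, sites$name)
    if (length(unknown))
      stop("unknown site id(s) for mark ", mark, ": ",
           paste(unknown, collapse = ", "))
    sel <- sites[sites$name %in% cfg$sites, , drop = FALSE]
    if (nrow(sel) == 0) return(empty_bed()[, 1:4])
    centre <- sel$start
    start <- centre - cfg$width %/% 2
    end <- start + cfg$width
    if (!is.null(genome)) {
      L <- unclass(genome)[sel$chrom]
      start <- pmax(start, 0)
      end <- pmin(end, L)
    }
    data.frame(chrom = sel$chrom, start = start, end = end,
               name = paste0(mark, "_peak_", seq_len(nrow(sel))),
               stringsAsFactors = FALSE)
  })
}
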