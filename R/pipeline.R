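#' Configure a pipeline run
#'
#' Collects every knob of the end-to-end analysis: the synthetic genome and
#' nucleosome architecture, sequencing depth per cell type, the profile
#' flank, the Poisson test settings, WIG binning and the master seed. When
#' `reads_paths` is supplied (a named list of BED files, one per cell type)
#' the simulation stage is skipped and those reads are analysed instead;
#' `snps_path` / `tss_path` likewise override the simulated anchors.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed; every stage derives its own stream.
#' @param chrom_name,chrom_length Synthetic genome (single chromosome).
#' @param n_tss Number of TSSs, spaced evenly with a margin.
#' @param ndr_width,spacing,n_array,fuzziness_sd,occupancy_prob,background_rate
#'   Passed to [nucleosome_model()].
#' @param depth_per_nucleosome,read_length Passed to [sample_reads()].
#' @param n_on,n_linker Passed to [generate_snp_sites()].
#' @param cell_types Character vector of cell-type labels; one independent
#'   read sample per label.
#' @param flank Profile half-window in bp.
#' @param alpha,test_mode,window Poisson occupancy-test settings.
#' @param bin_size WIG bin width in bp.
#' @param mark_config Peak-set configuration for [generate_peak_sets()];
#'   NULL builds a default assignment over the simulated SNPs (see
#'   [default_mark_config()]).
#' @param tf_window Half-width in bp of the sequence window scored around
#'   each SNP for TF-motif effects.
#' @param write_reads Also write the per-cell-type read BEDs.
#' @param reads_paths,snps_path,tss_path Optional input files replacing the
#'   simulation stage.
#' @return A `run_config` object (validated list).
#' @export
run_config <- function(out_dir = "nucsnp_run",
                       seed = 1L,
                       chrom_name = "chrS",
                       chrom_length = 3e5,
                       n_tss = 20,
                       ndr_width = 140,
                       spacing = 200,
                       n_array = 5,
                       fuzziness_sd = 10,
                       occupancy_prob = 0.9,
                       background_rate = 0.01,
                       depth_per_nucleosome = 50,
                       read_length = 36,
                       n_on = 40,
                       n_linker = 40,
                       cell_types = c("lymphoblastoid", "keratinocyte",
                                      "IMR90"),
                       flank = 1000,
                       alpha = 0.05,
                       test_mode = "upper",
                       window = 0,
                       bin_size = 200,
                       mark_config = NULL,
                       tf_window = 10,
                       write_reads = TRUE,
                       reads_paths = NULL,
                       snps_path = NULL,
                       tss_path = NULL) {
  stopifnot(length(cell_types) >= 1, flank >= 1, bin_size >= 1,
            chrom_length > 0, n_tss >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Default histone-mark assignment over simulated SNPs
#'
#' Randomly covers subsets of the SNPs with four marks so that every
#' chromatin state arises: ~40% of SNPs get H3K4me3 (600 bp peaks), ~25%
#' H3K27ac (600 bp), ~30% H3K27me3 (1000 bp) and ~15% H3K9me3 (1000 bp);
#' assignments are independent, so active/repressive co-occurrence
#' (bivalency) appears at the product rate.
#'
#' @param snps BED-style SNP data.frame with a `name` column.
#' @param seed Integer seed.
#' @return Named list suitable for [generate_peak_sets()].
#' @export
default_mark_config <- function(snps, seed = NULL) {
  with_seed(seed, {
    pick <- function(frac) sample(snps$name, round(frac * nrow(snps)))
    list(H3K4me3 = list(width = 600, sites = pick(0.40)),
         H3K27ac = list(width = 600, sites = pick(0.25)),
         H3K27me3 = list(width = 1000, sites = pick(0.30)),
         H3K9me3 = list(width = 1000, sites = pick(0.15)))
  })
}

#' A small example transcription-factor motif
#'
#' An 8-position CREB/ATF-like motif (consensus TGACGTCA) with strongly
#' informative columns, for demonstration and synthetic TF-effect scoring.
#'
#' @return A [pwm()] object.
#' @export
example_pwm <- function() {
  consensus <- c("T", "G", "A", "C", "G", "T", "C", "A")
  counts <- matrix(1, nrow = 4, ncol = length(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus))
    counts[consensus[j], j] <- 12
  pwm(counts, tf_name = "CREB_like", pseudocount = 0.25)
}

random_windows <- function(n, width, seed = NULL) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- vapply(seq_len(n), function(i)
      paste(sample(bases, width, replace = TRUE), collapse = ""), character(1))
    centre <- (width + 1) %/% 2
    alt <- vapply(seq_len(n), function(i) {
      ch <- strsplit(ref[i], "")[[1]]
      ch[centre] <- sample(setdiff(bases, ch[centre]), 1)
      paste(ch, collapse = "")
    }, character(1))
    list(ref = ref, alt = alt)
  })
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full variant-centric nucleosome/chromatin pipeline
#'
#' Stages: simulate (or load) reads, SNPs and TSSs; build and normalize an
#' occupancy track per cell type; compute TSS- and SNP-anchored occupancy
#' profiles and the nucleosome repeat length; Poisson occupancy calls per
#' cell type and the across-cell-type consensus; histone-mark annotation
#' and chromatin-state (incl. bivalent) classification; TF-motif ref/alt
#' delta scores. All result tables are tab-separated with one header line;
#' tracks are written as fixed-step WIG; a plain-text run log records every
#' parameter and derived seed, so identical configs give byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the truth object, per-cell-type tracks
#'   and call tables, profiles, consensus, chromatin states, TF scores and
#'   the paths of everything written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(log = file.path(config$out_dir, "run_log.txt"))
  log_lines <- c("nucsnp pipeline run log",
                 paste0("started: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  logp <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- "setup"
  result <- tryCatch({
    for (nm in setdiff(names(config), c("mark_config", "reads_paths")))
      logp("param ", nm, " = ", paste(deparse(config[[nm]]), collapse = ""))

    stage <- "simulate"
    genome <- genome_model(stats::setNames(config$chrom_length,
                                           config$chrom_name))
    if (is.null(config$tss_path)) {
      margin <- config$flank + 147 + config$n_array * config$spacing
      pos <- round(seq(margin, config$chrom_length - margin,
                       length.out = config$n_tss))
      tss <- data.frame(chrom = config$chrom_name, pos = pos, strand = "+")
    } else {
      b <- read_bed(config$tss_path)
      tss <- data.frame(chrom = b$chrom, pos = b$start, strand = b$strand)
    }
    model <- nucleosome_model(tss,
                              ndr_width = config$ndr_width,
                              spacing = config$spacing,
                              n_array = config$n_array,
                              fuzziness_sd = config$fuzziness_sd,
                              occupancy_prob = config$occupancy_prob,
                              background_rate = config$background_rate)
    truth <- build_nucleosome_map(genome, model,
                                  seed = derive_seed(config$seed, 1))
    if (is.null(config$snps_path)) {
      truth <- generate_snp_sites(truth, config$n_on, config$n_linker,
                                  seed = derive_seed(config$seed, 2))
    } else {
      truth$snps <- read_bed(config$snps_path)
    }
    snps <- truth$snps
    tss_bed <- as_bed_df(tss$chrom, tss$pos, tss$pos + 1,
                         name = paste0("tss_", seq_len(nrow(tss))),
                         strand = tss$strand)
    paths$snps <- file.path(config$out_dir, "snps.bed")
    write_bed(snps, paths$snps)
    paths$tss <- file.path(config$out_dir, "tss.bed")
    write_bed(tss_bed, paths$tss)
    logp("simulated ", nrow(truth$dyads), " dyads, ", nrow(snps), " SNPs, ",
         nrow(tss), " TSSs")

    stage <- "track"
    tracks <- list(); calls <- list(); prof_tss <- list(); prof_snp <- list()
    for (i in seq_along(config$cell_types)) {
      ct <- config$cell_types[i]
      ct_seed <- derive_seed(config$seed, 10 + i)
      reads <- if (is.null(config$reads_paths)) {
        sample_reads(truth, config$depth_per_nucleosome,
                     config$read_length, seed = ct_seed)
      } else read_bed(config$reads_paths[[ct]])
      logp("cell type ", ct, ": ", nrow(reads), " reads (seed ", ct_seed, ")")
      if (config$write_reads && is.null(config$reads_paths)) {
        p <- file.path(config$out_dir, paste0("reads_", ct, ".bed"))
        write_bed(reads, p)
        paths[[paste0("reads_", ct)]] <- p
      }
      track <- build_track(reads, genome)
      tracks[[ct]] <- track
      lam <- estimate_lambda(track, "genome")
      logp("cell type ", ct, ": lambda = ", format(lam, digits = 6))
      paths[[paste0("wig_", ct)]] <-
        file.path(config$out_dir, paste0("occupancy_", ct, ".wig"))
      write_wig(normalize_track(track), paths[[paste0("wig_", ct)]],
                bin_size = config$bin_size)

      stage <- "profile"
      prof_tss[[ct]] <- profile_around_sites(normalize_track(track), tss_bed,
                                             flank = config$flank)
      prof_snp[[ct]] <- profile_around_sites(normalize_track(track), snps,
                                             flank = config$flank)
      per <- detect_periodicity(prof_tss[[ct]], 100,
                                min(300, config$flank - 1))
      logp("cell type ", ct, ": TSS profile repeat length = ", per$period,
           " bp (acf ", format(per$score, digits = 3), ")")

      stage <- "test"
      calls[[ct]] <- classify_snp_occupancy(snps, track, lambda = lam,
                                            alpha = config$alpha,
                                            mode = config$test_mode,
                                            window = config$window)
      p <- file.path(config$out_dir, paste0("occupancy_calls_", ct, ".tsv"))
      write_tsv(calls[[ct]], p)
      paths[[paste0("calls_", ct)]] <- p
    }
    prof_tab <- function(profs) {
      out <- data.frame(offset = profs[[1]]$offset)
      for (ct in names(profs)) out[[ct]] <- profs[[ct]]$value
      out
    }
    paths$profile_tss <- file.path(config$out_dir, "profile_tss.tsv")
    write_tsv(prof_tab(prof_tss), paths$profile_tss)
    paths$profile_snp <- file.path(config$out_dir, "profile_snp.tsv")
    write_tsv(prof_tab(prof_snp), paths$profile_snp)

    stage <- "consensus"
    consensus <- consensus_across_celltypes(calls)
    paths$consensus <- file.path(config$out_dir, "consensus.tsv")
    write_tsv(consensus, paths$consensus)
    logp("consensus-occupied SNPs: ", sum(consensus$consensus), " / ",
         nrow(consensus))

    stage <- "annotate"
    mark_config <- config$mark_config
    if (is.null(mark_config))
      mark_config <- default_mark_config(snps, seed = derive_seed(config$seed, 3))
    peaks <- generate_peak_sets(snps, mark_config, genome = genome)
    for (mark in names(peaks)) {
      p <- file.path(config$out_dir, paste0("peaks_", mark, ".bed"))
      write_bed(peaks[[mark]], p)
      paths[[paste0("peaks_", mark)]] <- p
    }
    membership <- annotate_sites(snps, peaks)
    states <- classify_chromatin_state(
      membership,
      active_marks = intersect(colnames(membership),
                               c("H3K27ac", "H3K4me1", "H3K4me3", "H3K36me3")),
      repressive_marks = intersect(colnames(membership),
                                   c("H3K27me3", "H3K9me3")))
    paths$states <- file.path(config$out_dir, "chromatin_states.tsv")
    write_tsv(states, paths$states)
    logp("chromatin states: ",
         paste(names(table(states$state)), table(states$state),
               sep = "=", collapse = ", "))

    stage <- "tf_score"
    motif <- example_pwm()
    win <- random_windows(nrow(snps), 2 * config$tf_window + 1,
                          seed = derive_seed(config$seed, 4))
    tf <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
      s <- score_variant_tf_effect(motif, win$ref[i], win$alt[i])
      data.frame(site_id = snps$name[i], tf = motif$tf_name,
                 ref_window = win$ref[i], alt_window = win$alt[i],
                 best_ref_score = s$best_ref_score,
                 best_alt_score = s$best_alt_score, delta = s$delta,
                 stringsAsFactors = FALSE)
    }))
    paths$tf_scores <- file.path(config$out_dir, "tf_scores.tsv")
    write_tsv(tf, paths$tf_scores)

    list(truth = truth, tracks = tracks, calls = calls,
         profiles_tss = prof_tss, profiles_snp = prof_snp,
         consensus = consensus, membership = membership, states = states,
         tf_scores = tf, peaks = peaks, paths = paths)
  }, error = function(e) {
    log_lines <- c(log_lines,
                   paste0("ERROR in stage '", stage, "': ",
                          conditionMessage(e)),
                   "outputs may be partial")
    writeLines(log_lines, paths$log)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  logp("completed all stages")
  writeLines(log_lines, paths$log)
  invisible(result)
}
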