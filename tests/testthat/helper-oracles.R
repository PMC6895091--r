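# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately avoid the code paths they check.

# Per-base membership count: enumerate every (fragment, base) pair.
naive_coverage <- function(frags, chrom_len) {
  covered <- unlist(mapply(function(s, e) seq.int(s + 1, e),
                           pmax(frags$start, 0), pmin(frags$end, chrom_len),
                           SIMPLIFY = FALSE))
  tabulate(covered, nbins = chrom_len)
}

# All-pairs containment check for point sites against peaks.
naive_point_overlap <- function(sites, peaks) {
  vapply(seq_len(nrow(sites)), function(i) {
    same <- peaks$chrom == sites$chrom[i]
    any(same & peaks$start <= sites$start[i] & sites$start[i] < peaks$end)
  }, logical(1))
}

# All-pairs >=1 bp overlap check for interval sites against peaks.
naive_interval_overlap <- function(sites, peaks) {
  vapply(seq_len(nrow(sites)), function(i) {
    same <- peaks$chrom == sites$chrom[i]
    any(same & peaks$start < sites$end[i] & sites$start[i] < peaks$end)
  }, logical(1))
}

# Exhaustive PWM scan: every offset on both strands, scores recomputed from
# the probability matrix, not from the pwm object's cached log-odds.
naive_best_pwm_score <- function(prob, seq) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  bases <- c("A", "C", "G", "T")
  L <- ncol(prob)
  best <- -Inf
  for (s in c(seq, rc(seq))) {
    ch <- strsplit(s, "")[[1]]
    for (o in seq_len(length(ch) - L + 1)) {
      sc <- 0
      for (j in seq_len(L))
        sc <- sc + log2(prob[match(ch[o + j - 1], bases), j] / 0.25)
      if (sc > best) best <- sc
    }
  }
  unname(best)
}

# Direct-summation Poisson oracle (plain factorials, no ppois/dpois).
naive_poisson_upper <- function(k, lambda) {
  if (k == 0) return(1)
  i <- 0:(k - 1)
  1 - sum(exp(-lambda) * lambda^i / factorial(i))
}

random_reads <- function(n, chrom, chrom_len, read_length = 36) {
  start <- sample.int(chrom_len - read_length, n, replace = TRUE) - 1
  data.frame(chrom = chrom, start = start, end = start + read_length,
             name = paste0("r", seq_len(n)), score = 0,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# A small promoter-architecture truth object on one chromosome.
small_truth <- function(n_tss = 20, chrom_len = 3e5, spacing = 200,
                        fuzziness_sd = 10, n_array = 5,
                        background_rate = 0.01, occupancy_prob = 0.9,
                        seed = 1) {
  genome <- genome_model(c(chrS = chrom_len))
  margin <- 2500
  tss <- data.frame(chrom = "chrS",
                    pos = round(seq(margin, chrom_len - margin,
                                    length.out = n_tss)),
                    strand = "+")
  model <- nucleosome_model(tss, spacing = spacing,
                            fuzziness_sd = fuzziness_sd, n_array = n_array,
                            background_rate = background_rate,
                            occupancy_prob = occupancy_prob)
  build_nucleosome_map(genome, model, seed = seed)
}

# Build an occupancy_track directly from per-chromosome value vectors.
manual_track <- function(values, kind = "raw") {
  structure(list(values = values, kind = kind,
                 genome_max = max(vapply(values, max, numeric(1)), 0)),
            class = "occupancy_track")
}
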