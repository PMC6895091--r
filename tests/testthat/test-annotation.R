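test_that("half-open boundary semantics match intersectBed defaults", {
  peaks <- data.frame(chrom = "c1", start = 100, end = 200)
  at_start <- data.frame(chrom = "c1", start = 100)
  at_end <- data.frame(chrom = "c1", start = 200)
  expect_true(intersect_sites(at_start, peaks)$overlaps)
  expect_false(suppressWarnings(intersect_sites(at_end, peaks)$overlaps))

  # interval form: >= 1 shared bp either way round (symmetric)
  a <- data.frame(chrom = "c1", start = 150, end = 250)
  expect_true(intersect_sites(a, peaks)$overlaps)
  expect_true(intersect_sites(peaks, a)$overlaps)
  touching <- data.frame(chrom = "c1", start = 200, end = 300)
  expect_false(intersect_sites(touching, peaks)$overlaps)

  # slop turns a near-miss into a hit
  near <- data.frame(chrom = "c1", start = 210)
  expect_false(intersect_sites(near, peaks)$overlaps)
  expect_true(intersect_sites(near, peaks, slop = 20)$overlaps)
})

test_that("intersection equals the all-pairs oracle on random fixtures", {
  for (seed in 1:3) {
    set.seed(seed)
    sites <- data.frame(chrom = sample(c("c1", "c2"), 100, replace = TRUE),
                        start = sample.int(10000, 100))
    peaks <- data.frame(chrom = sample(c("c1", "c2"), 50, replace = TRUE),
                        start = s <- sample.int(9000, 50))
    peaks$end <- peaks$start + sample.int(500, 50)
    got <- suppressWarnings(intersect_sites(sites, peaks))
    expect_equal(got$overlaps, naive_point_overlap(sites, peaks))

    sites$end <- sites$start + sample.int(200, 100)
    got2 <- suppressWarnings(intersect_sites(sites, peaks))
    expect_equal(got2$overlaps, naive_interval_overlap(sites, peaks))
  }
})

test_that("site membership matrices follow the configured peak sets", {
  sites <- data.frame(chrom = "c1", start = c(100, 500, 900),
                      name = c("s1", "s2", "s3"))
  peaksets <- list(
    H3K27ac = data.frame(chrom = "c1", start = 80, end = 120),
    H3K27me3 = data.frame(chrom = "c1", start = c(80, 880),
                          end = c(120, 920)))
  m <- annotate_sites(sites, peaksets)
  expect_equal(dim(m), c(3, 2))
  expect_equal(m[, "H3K27ac"], c(s1 = TRUE, s2 = FALSE, s3 = FALSE))
  expect_equal(m[, "H3K27me3"], c(s1 = TRUE, s2 = FALSE, s3 = TRUE))

  expect_equal(ncol(annotate_sites(sites, list())), 0)
  expect_error(annotate_sites(sites, list(a = peaksets[[1]],
                                          a = peaksets[[2]])), "unique")
})

test_that("chromatin states follow the bivalency rule", {
  m <- rbind(c(TRUE, FALSE, TRUE, FALSE), # H3K4me3 + H3K27me3 -> bivalent
             c(FALSE, TRUE, TRUE, FALSE), # H3K4me1 + H3K27me3 -> bivalent
             c(FALSE, FALSE, FALSE, TRUE), # H3K9me3 only -> repressed
             c(TRUE, TRUE, FALSE, FALSE),  # active marks only -> active
             c(FALSE, FALSE, FALSE, FALSE)) # nothing -> none
  colnames(m) <- c("H3K4me3", "H3K4me1", "H3K27me3", "H3K9me3")
  st <- classify_chromatin_state(m)
  expect_equal(st$state,
               c("bivalent", "bivalent", "repressed", "active", "none"))

  colnames(m) <- c("H3K4me3", "H3K4me1", "H3K27me3", "H4K20me1")
  expect_error(classify_chromatin_state(m), "neither")
  expect_error(classify_chromatin_state(
    m[, 1:2], active_marks = c("H3K4me3", "H3K4me1"),
    repressive_marks = "H3K4me3"), "both")
})

test_that("PWM columns normalize and the consensus scores maximally", {
  counts <- matrix(c(10, 0, 0, 0,
                     0, 10, 0, 0,
                     0, 0, 0, 10), nrow = 4)
  p <- pwm(counts, "toy", pseudocount = 0.5)
  expect_equal(colSums(p$prob), rep(1, 3))
  cons <- "ACT"
  expect_equal(scan_pwm(p, cons)$score,
               naive_best_pwm_score(p$prob, cons))
  # a deviation (not the consensus reverse complement) scores below it
  expect_lt(scan_pwm(p, "TCT")$score, scan_pwm(p, cons)$score)

  unif <- pwm(matrix(1, 4, 3), pseudocount = 0)
  expect_equal(scan_pwm(unif, "ACGTT")$score, 0)
  r <- score_variant_tf_effect(unif, "ACGTT", "ACTTT")
  expect_equal(r$delta, 0)
})

test_that("variant motif scoring equals the brute-force scan", {
  bases <- c("A", "C", "G", "T")
  for (seed in 1:5) {
    set.seed(seed)
    p <- pwm(matrix(stats::runif(24, 0.1, 5), nrow = 4), pseudocount = 0)
    ref <- paste(sample(bases, 12, replace = TRUE), collapse = "")
    ch <- strsplit(ref, "")[[1]]
    ch[7] <- sample(setdiff(bases, ch[7]), 1)
    alt <- paste(ch, collapse = "")
    got <- score_variant_tf_effect(p, ref, alt)
    expect_equal(got$best_ref_score, naive_best_pwm_score(p$prob, ref))
    expect_equal(got$best_alt_score, naive_best_pwm_score(p$prob, alt))
    expect_equal(got$delta, got$best_alt_score - got$best_ref_score)
  }
})

test_that("motif scoring is reverse-complement invariant", {
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                       "")[[1]]), collapse = "")
  set.seed(3)
  p <- example_pwm()
  ref <- "ATGACGTCATTG"
  alt <- "ATGACTTCATTG"
  fwd <- score_variant_tf_effect(p, ref, alt)
  rev <- score_variant_tf_effect(p, rc(ref), rc(alt))
  expect_equal(fwd$best_ref_score, rev$best_ref_score)
  expect_equal(fwd$best_alt_score, rev$best_alt_score)
  expect_equal(fwd$delta, rev$delta)
})

test_that("variant scoring rejects malformed windows", {
  p <- example_pwm()
  expect_error(score_variant_tf_effect(p, "ACGT", "ACTT"), "shorter")
  expect_error(score_variant_tf_effect(p, "ACGTACGTACGT", "ACTTACTTACGT"),
               "exactly one")
  expect_error(score_variant_tf_effect(p, "ACGTACGTACGT", "ACGTACGTACG"),
               "equal length")
})
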