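test_that("zero-jitter dyad layout is exact, strand-aware and NDR-free", {
  genome <- genome_model(c(chrS = 5e4))
  tss <- data.frame(chrom = "chrS", pos = c(10000, 40000),
                    strand = c("+", "-"))
  model <- nucleosome_model(tss, ndr_width = 140, spacing = 200,
                            n_array = 3, fuzziness_sd = 0)
  truth <- build_nucleosome_map(genome, model, seed = 1)

  fwd <- truth$dyads[truth$dyads$tss_id == 1, ]
  # +1 dyad abuts the NDR edge: 70 + 73 = 143 bp downstream of the TSS
  expect_equal(fwd$pos, 10000 + c(-143, 143, 343, 543, 743))
  expect_equal(diff(fwd$pos[-1]), rep(200, 3))
  rev <- truth$dyads[truth$dyads$tss_id == 2, ]
  expect_equal(rev$pos, 40000 - c(-143, 143, 343, 543, 743))
  # no dyad inside the NDR
  expect_true(all(abs(truth$dyads$pos -
                        tss$pos[truth$dyads$tss_id]) > 70))
})

test_that("nucleosome map generation is deterministic per seed", {
  t1 <- small_truth(n_tss = 5, seed = 11)
  t2 <- small_truth(n_tss = 5, seed = 11)
  t3 <- small_truth(n_tss = 5, seed = 12)
  expect_identical(t1$dyads, t2$dyads)
  expect_false(identical(t1$dyads, t3$dyads))
})

test_that("TSS outside its chromosome is rejected", {
  genome <- genome_model(c(chrS = 1000))
  tss <- data.frame(chrom = "chrS", pos = 2000, strand = "+")
  expect_error(build_nucleosome_map(genome, nucleosome_model(tss), seed = 1),
               "outside")
})

test_that("read sampling honours depth, geometry and determinism", {
  genome <- genome_model(c(chrS = 1e4))
  tss <- data.frame(chrom = "chrS", pos = 5000, strand = "+")
  model <- nucleosome_model(tss, fuzziness_sd = 0, n_array = 0,
                            occupancy_prob = 1, background_rate = 0)

  # zero depth and zero background: no reads at all
  truth <- build_nucleosome_map(genome, model, seed = 1)
  expect_equal(nrow(sample_reads(truth, depth_per_nucleosome = 0, seed = 1)),
               0)

  # fixed dyads: every + read starts at d - 73, every - read ends at d + 74
  reads <- sample_reads(truth, depth_per_nucleosome = 200, read_length = 36,
                        seed = 2)
  d <- truth$dyads$pos
  plus <- reads[reads$strand == "+", ]
  minus <- reads[reads$strand == "-", ]
  expect_true(all(plus$start %in% (d - 73)))
  expect_true(all(minus$end %in% (d + 74)))
  expect_true(all(reads$end - reads$start == 36))

  expect_identical(sample_reads(truth, 50, seed = 3),
                   sample_reads(truth, 50, seed = 3))
})

test_that("total nucleosomal read count matches the Poisson expectation", {
  # 100 fully occupied nucleosomes at depth 50: sum ~ Poisson(5000)
  genome <- genome_model(c(chrS = 1e6))
  tss <- data.frame(chrom = "chrS",
                    pos = seq(5000, 995000, length.out = 20), strand = "+")
  model <- nucleosome_model(tss, n_array = 3, occupancy_prob = 1,
                            background_rate = 0, fuzziness_sd = 0)
  truth <- build_nucleosome_map(genome, model, seed = 1)
  expect_equal(nrow(truth$dyads), 100)
  n <- nrow(sample_reads(truth, depth_per_nucleosome = 50, seed = 4))
  expect_lt(abs(n - 5000), 3 * sqrt(5000))
})

test_that("SNP placement respects labels, distances and the seed", {
  truth <- generate_snp_sites(small_truth(seed = 5), n_on = 5, n_linker = 5,
                              seed = 6)
  snps <- truth$snps
  expect_equal(nrow(snps), 10)
  expect_equal(sum(snps$label == "on_nucleosome"), 5)
  expect_equal(sum(snps$label == "in_linker"), 5)
  dmin <- vapply(snps$start, function(p) min(abs(truth$dyads$pos - p)),
                 numeric(1))
  expect_true(all(dmin[snps$label == "on_nucleosome"] <= 40))
  expect_true(all(dmin[snps$label == "in_linker"] >= 100))
  again <- generate_snp_sites(small_truth(seed = 5), 5, 5, seed = 6)
  expect_identical(snps, again$snps)
})

test_that("infeasible linker placement errors out", {
  # a genome saturated with nucleosomes leaves no base >= 100 bp from a dyad
  genome <- genome_model(c(chrS = 2000))
  tss <- data.frame(chrom = "chrS", pos = seq(100, 1900, by = 300),
                    strand = "+")
  model <- nucleosome_model(tss, ndr_width = 0, n_array = 1, spacing = 150,
                            fuzziness_sd = 0)
  truth <- build_nucleosome_map(genome, model, seed = 1)
  expect_error(generate_snp_sites(truth, 0, 3, seed = 1, max_tries = 50),
               "linker")
})

test_that("peak sets are centred intervals controlled by the config", {
  sites <- data.frame(chrom = "chrS", start = c(10000, 20000),
                      end = c(10001, 20001), name = c("s1", "s2"),
                      score = 0, strand = "+")
  peaks <- generate_peak_sets(sites,
                              list(H3K4me3 = list(width = 600,
                                                  sites = c("s1", "s2")),
                                   H3K27me3 = list(width = 400,
                                                   sites = "s1")))
  expect_equal(peaks$H3K4me3$start, c(9700, 19700))
  expect_equal(peaks$H3K4me3$end, c(10300, 20300))
  expect_equal(nrow(peaks$H3K27me3), 1)
  expect_equal(length(generate_peak_sets(sites, list())), 0)
  expect_error(generate_peak_sets(sites, list(X = list(width = 10,
                                                       sites = "nope"))),
               "unknown site")
})

test_that("simulated reads round-trip through the BED writer and reader", {
  truth <- small_truth(n_tss = 2, chrom_len = 2e4, seed = 7)
  reads <- sample_reads(truth, 10, seed = 8)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(reads, path)
  back <- read_bed(path)
  expect_equal(back$chrom, reads$chrom)
  expect_equal(back$start, reads$start)
  expect_equal(back$end, reads$end)
  expect_equal(back$strand, reads$strand)
})
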