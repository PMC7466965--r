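test_that("simulate_population matches its Poisson branch model", {
  # zero split branch -> strains identical
  sim0 <- simulate_population(pop_sim_config(
    n_syn_sites = 1e4, n_nonsyn_sites = 0, mu = 1e-6, T_outgroup = 1e4,
    T_split = 0, theta_anc = 0.01, seed = 1))
  expect_identical(sim0$vt$gt[, "focal"], sim0$vt$gt[, "relative"])

  # focal-vs-reference synonymous differences ~ 2 mu T_out n
  cfg <- pop_sim_config(n_syn_sites = 1e5, n_nonsyn_sites = 0, mu = 1e-7,
                        T_outgroup = 2e5, T_split = 2e4, theta_anc = 0,
                        seed = 2)
  sim <- simulate_population(cfg)
  d <- alt_dosage(sim$vt)
  n_diff <- sum(d[, "focal"] > 0)  # all divergence variants are fixed
  expected <- 2 * cfg$mu * cfg$T_outgroup * cfg$n_syn_sites
  expect_lt(abs(n_diff - expected), 4 * sqrt(expected))

  # symmetric split: private counts share one Poisson mean
  cfg2 <- pop_sim_config(n_syn_sites = 1e5, n_nonsyn_sites = 0, mu = 1e-7,
                         T_outgroup = 1e5, T_split = 1e5, theta_anc = 0,
                         seed = 3)
  tr <- simulate_population(cfg2)$truth$counts$syn
  lam <- 1e-7 * 1e5 * 1e5
  expect_lt(abs(tr[["focal_private"]] - tr[["relative_private"]]),
            4 * sqrt(2 * lam))

  # infinite-sites guard
  expect_error(simulate_population(pop_sim_config(
    n_syn_sites = 100, n_nonsyn_sites = 0, mu = 1e-3, T_outgroup = 1e3,
    T_split = 10)), class = "brewtrace_infinite_sites")
})

test_that("simulate_population branch counts pass a chi-square GOF check", {
  cfg <- pop_sim_config(n_syn_sites = 5e4, n_nonsyn_sites = 0, mu = 1e-7,
                        T_outgroup = 1e5, T_split = 2e4, theta_anc = 0)
  lambda <- c(focal_private = 1e-7 * 2e4 * 5e4,
              relative_private = 1e-7 * 2e4 * 5e4,
              shared = 1e-7 * (2e5 - 2e4) * 5e4)
  n_rep <- 50L
  counts <- t(vapply(seq_len(n_rep), function(i) {
    cfg$seed <- 1000L + i
    unlist(simulate_population(cfg)$truth$counts$syn[names(lambda)])
  }, numeric(3)))
  for (b in names(lambda)) {
    stat <- sum((counts[, b] - lambda[[b]])^2 / lambda[[b]])
    p <- stats::pchisq(stat, df = n_rep, lower.tail = FALSE)
    expect_gt(p, 0.001)
  }
})

test_that("simulate_coverage honors its closed-form window model", {
  # identity
  t0 <- simulate_coverage(coverage_sim_config(c(chrI = 10000), slope = 0,
                                              noise_sd = 0, seed = 1))
  expect_true(all(t0$windows$value == 1))
  # 5 copies on 4n baseline -> 1.25 inside the event
  ev <- data.frame(chrom = "chrI", start = 2000, end = 4000, copy_number = 5)
  t1 <- simulate_coverage(coverage_sim_config(c(chrI = 10000),
                                              baseline_ploidy = 4,
                                              events = ev, noise_sd = 0))
  w <- t1$windows
  expect_true(all(w$value[w$start >= 2000 & w$end <= 4000] == 1.25))
  expect_true(all(w$value[w$end <= 2000 | w$start >= 4000] == 1))
  # end-slope recovered exactly without noise
  t2 <- simulate_coverage(coverage_sim_config(c(chrI = 1e5), slope = 0.2,
                                              noise_sd = 0))
  expect_equal(end_slope(t2)$slope, 0.2, tolerance = 1e-8)
})

test_that("simulate_translocation conserves length and is an involution", {
  ref <- toy_reference()
  bp <- repeat_breakpoint()
  tr <- simulate_translocation(ref, bp$a, bp$b)
  expect_equal(sum(tr$genome$lengths), sum(ref$lengths))
  tr2 <- simulate_translocation(tr, bp$a, bp$b)
  expect_identical(tr2$genome$lengths, ref$lengths)
  m <- tr2$map[order(chrom, start)]
  expect_true(all(m$chrom == m$ref_chrom & m$start == m$ref_start))

  # same chromosome unsupported
  expect_error(simulate_translocation(
    ref, list(chrom = "chrI", start = 1000, end = 2000),
    list(chrom = "chrI", start = 5000, end = 6000)),
    class = "brewtrace_unsupported")

  # cut = 0 places the junction exactly at the interval starts
  tr0 <- simulate_translocation(ref, bp$a, bp$b, cut = 0)
  expect_equal(tr0$junctions$posA, bp$a$start)
  expect_equal(tr0$junctions$posB, bp$b$start)
})

test_that("translocation between real-coordinate gene loci conserves length", {
  # chromosome V and X of the S288C assembly, with the two single-copy gene
  # breakpoint intervals used for the genic power benchmark
  g <- genome_model(c(chrV = 576874, chrX = 745751))
  tr <- simulate_translocation(
    g, list(chrom = "chrV", start = 293281, end = 295044),
    list(chrom = "chrX", start = 462156, end = 463691))
  expect_equal(sum(tr$genome$lengths[c("chrV", "chrX")]), 576874 + 745751)
})

test_that("simulate_long_reads is an exact split-mapping oracle", {
  ref <- toy_reference()
  # collinear genome: no supplementary records at all
  sim <- simulate_long_reads(ref, read_sim_config(depth = 5, seed = 4))
  expect_false(any(sim$split$records$flag == "supplementary"))
  # depth definition: total bases within 5% of depth * G
  sim20 <- simulate_long_reads(
    genome_model(c(chrI = 1e6)), read_sim_config(depth = 20, seed = 5))
  expect_lt(abs(sim20$split$total_read_bases - 2e7) / 2e7, 0.05)
  # determinism
  a <- simulate_long_reads(ref, read_sim_config(depth = 2, seed = 6))
  b <- simulate_long_reads(ref, read_sim_config(depth = 2, seed = 6))
  expect_identical(a$reads, b$reads)
  expect_error(simulate_long_reads(genome_model(c(chrI = 1)[0])),
               class = "brewtrace_empty")

  # reads fully inside a translocated segment map to one donor chromosome
  bp <- genic_breakpoint()
  tr <- simulate_translocation(ref, bp$a, bp$b)
  simt <- simulate_long_reads(tr, read_sim_config(depth = 10, seed = 7,
                                                  length_mean = 5000,
                                                  length_sd = 1000))
  recs <- simt$split$records
  junc <- tr$junctions
  # reads on derived chrIII beyond the junction: single segment on chrIV
  per_read <- split(recs, recs$read_id)
  inside <- simt$reads[chrom == "chrIII" & start > junc$posA + 100]
  for (id in head(inside$read_id, 50)) {
    rr <- per_read[[id]]
    expect_equal(nrow(rr), 1L)
    expect_equal(rr$chrom, "chrIV")
  }
})

test_that("growth and cytometry generators match their stated models", {
  # r = 0 -> constant
  c0 <- simulate_growth_curve(r = 0, K = 1.2, od0 = 0.1)
  expect_true(all(abs(c0$od - 0.1) < 1e-12))
  expect_length(c0$times, 97L)
  # dense noiseless logistic: max slope ~ r K / 4
  cd <- simulate_growth_curve(r = 0.5, K = 1.2, od0 = 0.01, dt = 0.01,
                              horizon = 40)
  expect_equal(max(diff(cd$od) / diff(cd$times)), 0.5 * 1.2 / 4,
               tolerance = 0.01)
  # determinism
  expect_identical(simulate_growth_curve(0.4, noise_sd = 0.01, seed = 8)$od,
                   simulate_growth_curve(0.4, noise_sd = 0.01, seed = 8)$od)

  s <- simulate_cytometry(g1_mean = 200, cv = 0.03, g2_fraction = 0.4,
                          n_cells = 5000, seed = 9)
  expect_length(s$values, 5000L)
  expect_error(cytometry_peaks(simulate_cytometry(g2_fraction = 0,
                                                  n_cells = 2000, seed = 10)),
               class = "brewtrace_single_peak")
})

test_that("simulate_sv_callsets controls sharing and jitter", {
  cl <- c(chrI = 5e6, chrII = 5e6)
  # fully shared, no jitter -> identical call tables
  p1 <- simulate_sv_callsets(50, shared_fraction = 1, jitter_sd = 0,
                             chrom_lengths = cl, seed = 11)
  expect_identical(p1$a$calls[, .(chrom, pos, class)],
                   p1$b$calls[, .(chrom, pos, class)])
  # unshared -> independent sets of the right size
  p0 <- simulate_sv_callsets(50, shared_fraction = 0, chrom_lengths = cl,
                             seed = 12)
  expect_equal(nrow(p0$a$calls), 50L)
  expect_equal(p0$n_shared, 0L)

  # jitter: nearest-mate distances of shared calls follow a half-normal;
  # sparse genome so the true mate is the nearest one
  pj <- simulate_sv_callsets(200, shared_fraction = 1, jitter_sd = 50,
                             chrom_lengths = c(chrI = 5e7), seed = 13)
  d <- proximity_distribution(pj$a, pj$b, "deletion", c(chrI = 5e7))
  hn_mean <- 50 * sqrt(2 / pi)
  hn_sd <- 50 * sqrt(1 - 2 / pi)
  expect_lt(abs(mean(d) - hn_mean), 3 * hn_sd / sqrt(length(d)))
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(
    simulate_coverage(coverage_sim_config(c(chrI = 5e4), noise_sd = 0.1,
                                          seed = 14))$windows,
    simulate_coverage(coverage_sim_config(c(chrI = 5e4), noise_sd = 0.1,
                                          seed = 14))$windows)
  expect_identical(simulate_population(pop_sim_config(seed = 15))$vt$gt,
                   simulate_population(pop_sim_config(seed = 15))$vt$gt)
  expect_identical(simulate_cytometry(seed = 16)$values,
                   simulate_cytometry(seed = 16)$values)
})
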