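test_that("VCF parsing infers ploidy, flags site classes, honors missing", {
  path <- write_test_vcf(c(
    vcf_rec("chrI", 10, "A", "T", "QD=5;MQ=50;SYN", "0/0/0/1:50:30", "0/0:40:20"),
    vcf_rec("chrI", 20, "C", "G", "QD=1.5;MQ=50", "./././.:.:.", "0/1:40:20"),
    vcf_rec("chrI", 30, "G", "A,C", "QD=5;MQ=50", "0/1/1/2:50:30", "1/1:40:20"),
    vcf_rec("chrI", 40, "G", "GA", "QD=5;MQ=50", "0/0/1/1:50:30", "0/1:40:20")))
  vt <- read_variant_table(path)
  expect_identical(vt$ploidy, c(s1 = 4L, s2 = 2L))
  expect_equal(nrow(vt$sites), 4L)
  expect_identical(vt$sites$pos, c(9, 19, 29, 39))  # 0-based
  expect_true(is.na(vt$gt[2, "s1"]))
  expect_identical(vt$sites$multiallelic, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(vt$sites$is_snp, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(vt$site_ann$QD, c(5, 1.5, 5, 5))
  expect_identical(vt$site_ann$SYN, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(alt_dosage(vt)[, "s1"], c(1L, NA, 3L, 2L))
})

test_that("mixed genotype arity within a strain is a ploidy conflict", {
  path <- write_test_vcf(c(
    vcf_rec("chrI", 10, "A", "T", "QD=5;MQ=50", "0/1:50:30", "0/0:40:20"),
    vcf_rec("chrI", 20, "C", "G", "QD=5;MQ=50", "0/1/1:50:30", "0/1:40:20")))
  expect_error(read_variant_table(path), class = "brewtrace_ploidy")
})

test_that("malformed VCF raises a format error", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("this is not", "a VCF at all"), bad)
  expect_error(read_variant_table(bad), class = "brewtrace_format")
})

test_that("VCF round-trip preserves the in-memory object", {
  path <- write_test_vcf(c(
    vcf_rec("chrI", 10, "A", "T", "QD=5;MQ=50;SYN", "0/0/0/1:50:30", "0/0:40:20"),
    vcf_rec("chrII", 20, "C", "G", "QD=1.5;MQ=41.5", "./././.:.:.", "0/1:40:20")))
  vt <- read_variant_table(path)
  out <- tempfile(fileext = ".vcf")
  write_variant_table(vt, out)
  vt2 <- read_variant_table(out)
  expect_identical(vt2$gt, vt$gt)
  expect_identical(vt2$ploidy, vt$ploidy)
  expect_equal(vt2$sites$pos, vt$sites$pos)
  expect_equal(vt2$site_ann$QD, vt$site_ann$QD)
  expect_equal(vt2$gq, vt$gq)
  expect_equal(vt2$dp, vt$dp)
})

test_that("BED and bedGraph round-trips are stable", {
  iv <- data.table::data.table(chrom = c("chrI", "chrII"),
                               start = c(0, 500), end = c(100, 900),
                               label = c("a", "b"), value = c(1.5, NA),
                               strand = c("+", "-"))
  p <- tempfile(fileext = ".bed")
  write_bed(iv, p)
  expect_equal(read_bed(p)$start, iv$start)
  expect_equal(read_bed(p)$strand, iv$strand)

  tr <- simulate_coverage(coverage_sim_config(c(chrI = 10000), seed = 1))
  pb <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, pb)
  tr2 <- read_bedgraph(pb, strain = tr$strain)
  expect_equal(tr2$windows$value, tr$windows$value, tolerance = 1e-9)
})

test_that("project_genotypes substitutes, masks and preserves length", {
  ref <- genome_model(c(chrI = "ACGT"))
  # tetraploid {ref,ref,alt,alt} at pos 2 -> two ACGT, two ACTT
  vt <- vt_from_dosage(matrix(2L, 1, 1, dimnames = list(NULL, "s")),
                       ploidy = 4L, pos = 2)
  h <- project_genotypes(ref, vt, "s")
  seqs <- vapply(h, function(x) as.character(x[["chrI"]]), "")
  expect_identical(unname(seqs), c("ACGT", "ACGT", "ACTT", "ACTT"))

  # missing genotype -> N everywhere
  vtm <- vt_from_dosage(matrix(NA_integer_, 1, 1, dimnames = list(NULL, "s")),
                        ploidy = 4L, pos = 2)
  hm <- project_genotypes(ref, vtm, "s")
  expect_identical(as.character(hm[[1]][["chrI"]]), "ACNT")

  # no variants -> identical copies; length preserved always
  vt0 <- vt_from_dosage(matrix(0L, 1, 1, dimnames = list(NULL, "s")),
                        ploidy = 4L, pos = 2)
  h0 <- project_genotypes(ref, vt0, "s")
  expect_true(all(vapply(h0, function(x)
    as.character(x[["chrI"]]) == "ACGT", logical(1))))
  expect_true(all(vapply(h, function(x)
    length(x[["chrI"]]) == 4L, logical(1))))
})

test_that("concatenate_cds is additive, strand-aware and invertible", {
  g <- genome_model(c(chrI = "AAAATGCCCC", chrII = "GGGGTTTTTT"))
  feats <- data.frame(chrom = c("chrI", "chrII"), start = c(2, 1),
                      end = c(8, 7), strand = c("+", "-"), kind = "cds",
                      id = c("g1", "g2"))
  cc <- concatenate_cds(g, feats)
  expect_equal(cc$total_length, 12)
  # minus-strand part appears reverse-complemented
  expect_identical(as.character(concat_sequence(g, cc)), "AATGCCAAACCC")
  # round-trip coordinate identity
  back <- concat_to_genome(cc, 0:11)
  expect_identical(genome_to_concat(cc, back$chrom, back$pos), as.numeric(0:11))
  # overlapping CDS rejected naming offenders
  bad <- rbind(feats, data.frame(chrom = "chrI", start = 5, end = 9,
                                 strand = "+", kind = "cds", id = "g3"))
  expect_error(concatenate_cds(g, bad), class = "brewtrace_overlap")
  expect_error(concatenate_cds(g, bad), "g3")
})

test_that("split-read and SV call TSV round-trips are stable", {
  ref <- toy_reference()
  sim <- simulate_long_reads(ref, read_sim_config(depth = 2, seed = 3))
  p <- tempfile(fileext = ".tsv")
  write_split_reads(sim$split, p)
  s2 <- read_split_reads(p)
  expect_equal(s2$genome_length, sim$split$genome_length)
  expect_equal(nrow(s2$records), nrow(sim$split$records))
  expect_equal(s2$records$start, sim$split$records$start)

  sv <- simulate_sv_callsets(20, 0.5, 100, c(chrI = 1e6), seed = 1)$a
  ps <- tempfile(fileext = ".tsv")
  write_sv_calls(sv, ps)
  sv2 <- read_sv_calls(ps)
  expect_equal(sv2$depth, sv$depth)
  expect_equal(sv2$calls$pos, sv$calls$pos)
})
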