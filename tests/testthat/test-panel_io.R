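# Readers/writers for the SNP2HLA dialect, dosage collapse, diploid QC.

test_that("read_markers classifies SNP and HLA presence markers", {
  f <- withr::local_tempfile(lines = c(
    "rs9260157 29912280 C T",
    "HLA_A_0101 30018226 P A"))
  mk <- read_markers(f)
  expect_equal(mk$id, c("rs9260157", "HLA_A_0101"))
  expect_equal(mk$pos, c(29912280L, 30018226L))
  expect_equal(mk$kind, c("snp", "hla_presence"))
  expect_equal(mk$gene[2], "HLA-A")
  expect_equal(mk$allele[2], "A*01:01")
})

test_that("read_markers handles empty files and rejects malformed input", {
  empty <- withr::local_tempfile(lines = character())
  expect_equal(nrow(read_markers(empty)), 0L)

  bad <- withr::local_tempfile(lines = c("rs1 100 A", "rs2 200 C T"))
  expect_error(read_markers(bad), "line 1")

  dup <- withr::local_tempfile(lines = c("rs1 100 A G", "rs1 200 C T"))
  expect_error(read_markers(dup), "duplicate")
})

test_that("presence-marker ids parse to gene and two-field allele names", {
  ann <- parse_hla_marker_id(c("HLA_DRB1_0401", "HLA_B_150101", "weird_id"))
  expect_equal(ann$gene[1:2], c("HLA-DRB1", "HLA-B"))
  expect_equal(ann$allele[1:2], c("DRB1*04:01", "B*15:0101"))
  expect_false(ann$parsed[3])
  expect_equal(ann$allele[3], "weird_id")  # kept verbatim, flagged
})

test_that("read_bgl_phased maps allele characters against declared alleles", {
  mfile <- withr::local_tempfile(lines = c("rs1 100 A G", "HLA_A_0101 200 P A"))
  pfile <- withr::local_tempfile(lines = c(
    "I id S1 S1",
    "M rs1 A G",
    "M HLA_A_0101 P A"))
  mk <- read_markers(mfile)
  p <- read_bgl_phased(mk, pfile)
  expect_equal(p$sample_ids, "S1")
  expect_equal(unname(p$snp[, 1]), c(0L, 1L))
  expect_equal(unname(p$presence[, 1]), c(1L, 0L))
})

test_that("read_bgl_phased rejects unknown allele characters and odd columns", {
  mfile <- withr::local_tempfile(lines = "rs1 100 A G")
  mk <- read_markers(mfile)
  bad_char <- withr::local_tempfile(lines = c("I id S1 S1", "M rs1 A T"))
  expect_error(read_bgl_phased(mk, bad_char), "rs1")
  odd <- withr::local_tempfile(lines = c("I id S1 S1 S2", "M rs1 A G A"))
  expect_error(read_bgl_phased(mk, odd), "odd|pairs")
})

test_that("panel write/read round-trips bit-identically, including randomized fixtures", {
  toy <- write_toy_panel()
  mk <- read_markers(toy$markers_path)
  expect_equal(mk[, names(toy$markers)[1:4]], toy$markers[, 1:4])
  p <- read_bgl_phased(mk, toy$bgl_path)
  expect_equal(unname(cbind(p$snp, p$presence)), unname(toy$hap))
  expect_equal(p$sample_ids, toy$sample_ids)

  set.seed(11)
  for (trial in 1:5) {
    n <- sample(1:6, 1); m <- sample(1:8, 1)
    markers <- data.frame(id = sprintf("rs%d", seq_len(m)),
                          pos = sort(sample.int(1e6, m)),
                          allele_a = sample(c("A", "C"), m, TRUE),
                          allele_b = sample(c("G", "T"), m, TRUE),
                          stringsAsFactors = FALSE)
    hap <- matrix(rbinom(2 * n * m, 1, 0.5), 2 * n, m)
    dir <- withr::local_tempdir()
    write_panel(markers, hap, sprintf("S%d", seq_len(n)),
                file.path(dir, "r.markers"), file.path(dir, "r.bgl"))
    mk2 <- read_markers(file.path(dir, "r.markers"))
    p2 <- read_bgl_phased(mk2, file.path(dir, "r.bgl"))
    expect_equal(unname(p2$snp), unname(hap))
  }
})

test_that("write_panel validates alignment and supports zero samples", {
  toy_markers <- data.frame(id = "rs1", pos = 1L, allele_a = "A",
                            allele_b = "G", stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  expect_error(write_panel(toy_markers, matrix(0L, 2, 2), "S1",
                           file.path(dir, "a"), file.path(dir, "b")),
               "columns")
  write_panel(toy_markers, matrix(0L, 0, 1), character(),
              file.path(dir, "e.markers"), file.path(dir, "e.bgl"))
  mk <- read_markers(file.path(dir, "e.markers"))
  p <- read_bgl_phased(mk, file.path(dir, "e.bgl"))
  expect_equal(length(p$sample_ids), 0L)
})

test_that("haplotypes_to_dosage sums haplotype pairs and stays in {0,1,2}", {
  hap <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L))
  expect_equal(unname(haplotypes_to_dosage(hap)[1, ]), c(2L, 1L, 0L))
  expect_equal(unname(haplotypes_to_dosage(matrix(0L, 4, 3))),
               matrix(0L, 2, 3))
  set.seed(3)
  h <- matrix(rbinom(40, 1, 0.5), 8, 5)
  expect_true(all(haplotypes_to_dosage(h) %in% 0:2))
  expect_error(haplotypes_to_dosage(matrix(0L, 3, 2)), "even")
})

test_that("diploid-presence QC keeps exactly the samples summing to 2 per gene", {
  pm <- data.frame(gene = c("HLA-A", "HLA-A", "HLA-B"),
                   allele = c("A*01:01", "A*02:01", "B*07:02"),
                   stringsAsFactors = FALSE)
  d <- rbind(het = c(1L, 1L, 2L),     # kept: 1+1 and 2
             hom = c(2L, 0L, 2L),     # kept: homozygote sums to 2
             half = c(1L, 0L, 2L),    # removed: HLA-A sums to 1
             extra = c(2L, 1L, 2L))   # removed: HLA-A sums to 3
  res <- qc_diploid_presence(d, pm)
  expect_equal(res$kept, c("het", "hom"))
  expect_equal(res$removed, c("half", "extra"))

  # brute-force recount on a random fixture
  set.seed(9)
  d2 <- matrix(sample(0:2, 60, TRUE), 20, 3)
  rownames(d2) <- sprintf("S%02d", 1:20)
  res2 <- qc_diploid_presence(d2, pm)
  manual <- rownames(d2)[sapply(1:20, function(i)
    sum(d2[i, 1:2]) == 2 && d2[i, 3] == 2)]
  expect_equal(res2$kept, manual)
})

test_that("HLA truth tables read, reject duplicates, allow header-only", {
  f <- withr::local_tempfile(lines = c(
    "sample\tgene\tallele1\tallele2",
    "S1\tHLA-A\tA*01:01\tA*02:01"))
  tr <- read_hla_truth(f)
  expect_equal(tr$allele2, "A*02:01")

  dupf <- withr::local_tempfile(lines = c(
    "sample\tgene\tallele1\tallele2",
    "S1\tHLA-A\tA*01:01\tA*02:01",
    "S1\tHLA-A\tA*03:01\tA*02:01"))
  expect_error(read_hla_truth(dupf), "duplicate")

  hdr <- withr::local_tempfile(lines = "sample\tgene\tallele1\tallele2")
  expect_equal(nrow(read_hla_truth(hdr)), 0L)

  miss <- withr::local_tempfile(lines = c("sample\tgene\tallele1", "S1\tHLA-A\tA*01:01"))
  expect_error(read_hla_truth(miss), "allele2")
})

test_that("truth_from_presence reconstructs pairs from QC-passed dosages", {
  pm <- data.frame(gene = "HLA-A", allele = c("A*01:01", "A*02:01"),
                   stringsAsFactors = FALSE)
  d <- rbind(S1 = c(1L, 1L), S2 = c(2L, 0L), S3 = c(1L, 0L))
  tr <- truth_from_presence(d, pm)
  expect_equal(nrow(tr), 2L)  # S3 fails the invariant and is skipped
  expect_equal(sort(unlist(tr[tr$sample == "S1", c("allele1", "allele2")],
                           use.names = FALSE)),
               c("A*01:01", "A*02:01"))
  expect_equal(tr$allele1[tr$sample == "S2"], "A*01:01")
  expect_equal(tr$allele2[tr$sample == "S2"], "A*01:01")
})
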