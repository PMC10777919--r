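test_that("fragment rows parse against the CpG map", {
  map <- linear_map(10)  # CpGs at 100,110,...,190
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "s1\tchr1\t100\t150\tMMUMN"), path)
  fr <- read_fragments(path, map)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$states, "MMUMN")   # 5 CpGs in [100,150)
  expect_equal(fr$first_ord, 1L)
})

test_that("malformed fragment rows are reported with their line numbers", {
  map <- linear_map(10)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tchr1\t100\t150\tMMU"), path)       # 3 states, 5 CpGs
  expect_error(read_fragments(path, map), "line 1")
  writeLines(c("# hdr", "s1\tchr1\t100\t120\tMX"), path)
  expect_error(read_fragments(path, map), "line 2")
  writeLines(c("s1\tchr1\t100\t120"), path)
  expect_error(read_fragments(path, map), "format error")
})

test_that("fragments round-trip through write/read unchanged", {
  set.seed(101)
  map <- linear_map(50)
  fr <- random_fragments(1000, map)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(fr, path)
  back <- read_fragments(path, map)
  rownames(fr) <- rownames(back) <- NULL
  expect_identical(back, fr)
})

test_that("DMR tables round-trip bit-identically", {
  set.seed(102)
  n <- 500
  rec <- dmr_records(label = sample(c("Lung", "Breast"), n, TRUE),
                     chrom = "chr05", first_cpg_pos = sort(sample.int(1e6, n)),
                     pattern = sample(c("MMMMM", "UUUUU", "MUMUM"), n, TRUE),
                     noise_rate = runif(n) * 1e-3,
                     prevalence = runif(n), efficiency = runif(n, 0.01, 1),
                     sex_chrom = sample(c(TRUE, FALSE), n, TRUE),
                     assay_ok = sample(c(TRUE, FALSE), n, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dmr_table(rec, path)
  back <- read_dmr_table(path)
  expect_identical(back, rec[, names(back)])

  one <- dmr_records("Lung", "chr01", 500L, "MMMMM",
                     noise_rate = 1e-5, prevalence = 0.4, efficiency = 0.8)
  write_dmr_table(one, path)
  b1 <- read_dmr_table(path)
  expect_identical(b1$noise_rate, 1e-5)
  expect_identical(b1$prevalence, 0.4)
  expect_identical(b1$efficiency, 0.8)

  write_dmr_table(rec[0, ], path)
  expect_equal(nrow(read_dmr_table(path)), 0L)
  expect_equal(length(readLines(path)), 1L)  # header only
})

test_that("derived strong_pattern flag matches the pattern", {
  rec <- dmr_records("Lung", "chr01", c(100L, 200L, 300L),
                     c("MMMMM", "UUUUU", "MUMUM"),
                     noise_rate = 0, prevalence = 0.5, efficiency = 0.5)
  expect_equal(rec$strong_pattern, c(TRUE, TRUE, FALSE))
})

test_that("CpG ordinal lookups agree with a naive linear scan", {
  set.seed(103)
  for (rep in 1:10) {
    chrom <- sort(sample(sprintf("chr%02d", 1:3), 30, TRUE))
    pos <- unlist(lapply(split(seq_len(30), chrom), function(i)
      sort(sample.int(500, length(i)))))
    map <- cpg_map(chrom, pos)
    a <- sample.int(500, 1); b <- a + sample.int(100, 1)
    ch <- sample(unique(chrom), 1)
    naive <- which(vapply(seq_len(nrow(map)), function(i)
      map$chrom[i] == ch && map$pos[i] >= a && map$pos[i] < b, logical(1)))
    expect_identical(cpg_ordinals(map, ch, a, b), naive)
  }
})

test_that("CpG map construction rejects duplicates and sorts sites", {
  expect_error(cpg_map(c("chr1", "chr1"), c(5L, 5L)), "duplicate")
  m <- cpg_map(c("chr2", "chr1"), c(7L, 9L))
  expect_equal(m$chrom, c("chr1", "chr2"))
})

test_that("window validation enforces the 5-CpG contract", {
  map <- cpg_map(rep(c("chr1", "chr2"), each = 4L), rep(c(0L, 10L, 20L, 30L), 2))
  expect_error(validate_window(map, 1L, "MMMM"), "MU")
  expect_error(validate_window(map, 6L, "MMMMM"), "off the CpG map")
  expect_error(validate_window(map, 2L, "MMMMM"), "chromosome boundary")
})

test_that("manifest validation enforces group and label rules", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,cancer_label,stage,tumor_size_cm,assay",
               "a,cancer_tissue,Lung,II,3.1,wgbs",
               "b,noncancer_plasma,,,,targeted"), path)
  m <- read_manifest(path)
  expect_equal(m$cancer_label[1], "Lung")
  writeLines(c("sample_id,group,cancer_label,stage,tumor_size_cm,assay",
               "a,cancer_tissue,,II,3.1,wgbs"), path)
  expect_error(read_manifest(path), "require a cancer_label")
  writeLines(c("sample_id,group,cancer_label,stage,tumor_size_cm,assay",
               "a,mystery,,II,3.1,wgbs"), path)
  expect_error(read_manifest(path), "unknown group")
})
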