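test_that("sync lines parse into records and bad lines name the culprit", {
  rec <- parse_sync_line("2L 5002 A 10:0:0:5:0:0 8:0:0:7:0:0")
  expect_s3_class(rec, "sync_record")
  expect_equal(rec$chrom, "2L")
  expect_equal(rec$pos, 5002L)
  expect_equal(rec$ref, "A")
  expect_equal(unname(rec$counts[1, ]), c(10L, 0L, 0L, 5L, 0L, 0L))
  expect_equal(unname(rec$counts[2, ]), c(8L, 0L, 0L, 7L, 0L, 0L))

  expect_error(parse_sync_line("2L 5002 A 10:0:0:5:0", 7),
               "line 7.*column 4.*sextet")
  expect_error(parse_sync_line("2L 5002 A 1:2:3:x:0:0"), "sextet")
  expect_error(parse_sync_line("2L 5002"), ">= 4 columns")
  expect_error(parse_sync_line("2L zero A 0:0:0:0:0:0"), "position")
  expect_error(parse_sync_line("2L 5002 Z 0:0:0:0:0:0"), "reference base")
})

test_that("write -> parse round-trips arbitrary records", {
  set.seed(41)
  recs <- lapply(1:10, function(i) {
    ns <- sample(2:20, 1)
    structure(list(chrom = sample(c("2L", "3R", "X"), 1),
                   pos = sample.int(1e6, 1),
                   ref = sample(c("A", "T", "C", "G"), 1),
                   counts = matrix(rpois(ns * 6, 8), ns, 6,
                                   dimnames = list(NULL, c("A","T","C","G","N","del")))),
              class = "sync_record")
  })
  path <- withr::local_tempfile(fileext = ".sync")
  write_sync(recs, path)
  back <- read_sync(path)
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$chrom, recs[[i]]$chrom)
    expect_equal(back[[i]]$pos, recs[[i]]$pos)
    expect_equal(back[[i]]$counts, matrix(as.integer(recs[[i]]$counts),
                                          nrow(recs[[i]]$counts), 6,
                                          dimnames = dimnames(recs[[i]]$counts)))
  }
})

test_that("focal allele choice: single alternate, argmax, tie order, depth rule", {
  lay <- sync_layout(1, 2)
  # only T segregates against ref A
  r1 <- parse_sync_line("c 1 A 10:3:0:0:1:2 5:8:0:0:0:0")
  lc1 <- to_locus_counts(r1, lay, c(0, 10))
  expect_equal(lc1$focal_allele, "T")
  expect_equal(as.vector(lc1$focal), c(3L, 8L))
  expect_equal(as.vector(lc1$coverage), c(13L, 13L))  # N and del never counted

  # T total 30 beats C total 12
  r2 <- parse_sync_line("c 1 A 4:20:6:0:0:0 4:10:6:0:0:0")
  expect_equal(to_locus_counts(r2, lay, c(0, 10))$focal_allele, "T")

  # tie between T and C: fixed A,T,C,G order -> T wins
  r3 <- parse_sync_line("c 1 A 4:6:6:0:0:0 4:6:6:0:0:0")
  expect_equal(to_locus_counts(r3, lay, c(0, 10))$focal_allele, "T")

  # all-zero sextet is legal: coverage 0 recorded
  r4 <- parse_sync_line("c 1 A 0:0:0:0:0:0 3:7:0:0:0:0")
  lc4 <- to_locus_counts(r4, lay, c(0, 10))
  expect_equal(as.vector(lc4$coverage), c(0L, 10L))
  expect_true(all(lc4$focal <= lc4$coverage))
})

test_that("sample layout is a pure function of the declared ordering", {
  R <- 5L; Tn <- 4L
  lay_t <- sync_layout(R, Tn, "time_major")
  lay_r <- sync_layout(R, Tn, "replicate_major")
  set.seed(42)
  cnt <- matrix(0L, R * Tn, 6, dimnames = list(NULL, c("A","T","C","G","N","del")))
  cnt[, "T"] <- rpois(R * Tn, 10); cnt[, "A"] <- rpois(R * Tn, 10)
  rec_t <- structure(list(chrom = "c", pos = 1L, ref = "A", counts = cnt),
                     class = "sync_record")
  # permute the columns into replicate-major order, declare that layout
  key_t <- paste(lay_t$replicate, lay_t$time)
  key_r <- paste(lay_r$replicate, lay_r$time)
  rec_r <- rec_t
  rec_r$counts <- cnt[match(key_r, key_t), , drop = FALSE]
  g <- c(0, 5, 10, 15)
  expect_equal(to_locus_counts(rec_t, lay_t, g)$focal,
               to_locus_counts(rec_r, lay_r, g)$focal)
  expect_equal(to_locus_counts(rec_t, lay_t, g)$coverage,
               to_locus_counts(rec_r, lay_r, g)$coverage)
  # 20 sextets for a 5 x 4 design parse and map
  expect_equal(dim(to_locus_counts(rec_t, lay_t, g)$focal), c(R, Tn))
  expect_error(to_locus_counts(rec_t, sync_layout(3, 4), g), "3 x 4")
})

test_that("results tables round-trip with filtered and degenerate markers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(list(), path)
  expect_equal(readLines(path),
               "chrom\tpos\tmean_sigma\tlog_BF\talpha\tbeta\tfiltered\tdegenerate")

  res <- list(
    structure(list(chrom = "2L", pos = 1L, mean_sigma = 0.0123456789,
                   log_bf = 4.59512, alpha = 12.3, beta = 11.9,
                   filtered = FALSE, degenerate = FALSE), class = "locus_result"),
    structure(list(chrom = "2L", pos = 2L, mean_sigma = NA_real_,
                   log_bf = NA_real_, alpha = NA_real_, beta = NA_real_,
                   filtered = TRUE, degenerate = FALSE), class = "locus_result"))
  write_results(res, path)
  back <- read_results(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$mean_sigma[1], 0.0123456789, tolerance = 1e-6)
  expect_equal(back$log_BF[1], 4.59512, tolerance = 1e-6)
  expect_equal(back$filtered, c(0L, 1L))
  expect_true(all(is.na(back[2, c("mean_sigma", "log_BF", "alpha", "beta")])))
})
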