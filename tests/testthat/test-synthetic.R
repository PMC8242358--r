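test_that("generation is deterministic for a fixed seed", {
  ds1 <- generate_dataset(small_config(seed = 4, n_fragments = 500,
                                       n_genes = 30))
  ds2 <- generate_dataset(small_config(seed = 4, n_fragments = 500,
                                       n_genes = 30))
  expect_identical(ds1$calls, ds2$calls)
  expect_identical(ds1$fragments, ds2$fragments)
  expect_identical(ds1$expression, ds2$expression)
  ds3 <- generate_dataset(small_config(seed = 5, n_fragments = 500,
                                       n_genes = 30))
  expect_false(identical(ds1$calls, ds3$calls))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_dataset(ds1, d1)
  m2 <- write_dataset(ds2, d2)
  for (k in names(m1))   # byte-identical emitted files
    expect_identical(readLines(m1[[k]]), readLines(m2[[k]]), label = k)
})

test_that("planted structure honours the configuration", {
  cfg <- small_config(seed = 8, n_fragments = 2000, n_genes = 40)
  ds <- generate_dataset(cfg)
  # active and repressed regions are disjoint
  expect_equal(intersect_bases(ds$active_regions, ds$repressed_regions), 0)
  expect_equal(nrow(ds$active_regions), cfg$n_active_regions)
  expect_equal(nrow(ds$repressed_regions), cfg$n_repressed_regions)
  # every emitted interval is valid on the genome
  len <- setNames(ds$genome$length, ds$genome$chrom)
  for (df in list(ds$calls, ds$fragments, ds$annotation))
    expect_true(all(df$start >= 0 & df$end <= len[df$chrom]))
  # true calls sit inside active regions, decoys inside repressed
  truth <- unlist(ds$ledger$call_is_true)
  calls <- as.data.frame(ds$calls)
  true_calls <- calls[truth[calls$name], ]
  decoys <- calls[!truth[calls$name], ]
  expect_equal(intersect_bases(true_calls, ds$active_regions),
               total_bases(true_calls))
  expect_equal(intersect_bases(decoys, ds$repressed_regions),
               total_bases(decoys))
  # scores separate: true peaks high, decoys low
  expect_gt(min(true_calls$score), max(decoys$score) - 4)
  expect_gt(mean(true_calls$score), mean(decoys$score) + 5)
  # planted open promoters classify open against the true calls
  pr <- promoter_regions(ds$annotation, ds$genome)
  cls <- classify_promoters(pr, ds$calls)
  planted <- unlist(ds$ledger$gene_promoter_open)[cls$gene_id]
  expect_equal(unname(planted), cls$open)
})

test_that("ledger precision is exact at an all-inclusive cutoff", {
  ds <- generate_dataset(small_config(seed = 10))
  ts <- build_truth_sets(ds$histone$h3k4me1, ds$histone$h3k4me3,
                         ds$histone$h3k27ac, ds$histone$h3k27me3)
  vp <- validation_point(ds$calls, ts, -Inf)
  expect_equal(vp$precision, ds$ledger$expected_precision_all_calls)
})

test_that("a decoy-free dataset has perfect subset precision", {
  ds <- generate_dataset(small_config(seed = 12, n_decoy_peaks = 0))
  ts <- build_truth_sets(ds$histone$h3k4me1, ds$histone$h3k4me3,
                         ds$histone$h3k27ac, ds$histone$h3k27me3)
  expect_equal(subset_precision(ds$calls, ts), 1)
})

test_that("neutral decoys exercise the no-FP path", {
  ds <- generate_dataset(small_config(seed = 14, decoy_mode = "neutral"))
  truth <- unlist(ds$ledger$call_is_true)
  calls <- as.data.frame(ds$calls)
  decoys <- calls[!truth[calls$name], ]
  expect_equal(intersect_bases(decoys, ds$active_regions), 0)
  expect_equal(intersect_bases(decoys, ds$repressed_regions), 0)
  ts <- build_truth_sets(ds$histone$h3k4me1, ds$histone$h3k4me3,
                         ds$histone$h3k27ac, ds$histone$h3k27me3)
  # decoys alone touch neither truth set: undefined precision, flagged
  dec_ps <- peak_set(decoys$chrom, decoys$start, decoys$end)
  expect_warning(out <- subset_precision(dec_ps, ts), "undefined")
  expect_true(is.na(out))
})

test_that("an overcrowded genome is rejected with advice", {
  expect_error(generate_dataset(
    synthetic_config(seed = 1, n_chroms = 1, chrom_length = 5e4,
                     n_active_regions = 40, n_repressed_regions = 20,
                     region_length = c(1000, 5000),
                     n_true_peaks = 5, n_decoy_peaks = 5,
                     n_fragments = 0, n_genes = 0)),
    "larger genome")
})

test_that("written datasets read back consistently", {
  ds <- generate_dataset(small_config(seed = 16, n_fragments = 300,
                                      n_genes = 25))
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_true(all(file.exists(manifest)))
  back <- read_dataset(dir)

  expect_equal(back$genome, ds$genome)
  for (mark in names(ds$histone))
    expect_equal(
      as.data.frame(back$histone[[mark]])[, c("chrom", "start", "end")],
      as.data.frame(ds$histone[[mark]])[, c("chrom", "start", "end")])
  expect_equal(back$calls$score, ds$calls$score)
  expect_equal(back$calls$name, ds$calls$name)
  expect_equal(back$calls$start, ds$calls$start)
  sort_df <- function(df) {
    df <- as.data.frame(df)[, c("chrom", "start", "end")]
    df <- df[order(df$chrom, df$start, df$end), ]
    rownames(df) <- NULL
    df
  }
  # the BED writer canonicalises order; compare as sets
  expect_equal(sort_df(back$fragments), sort_df(ds$fragments))
  expect_equal(as.data.frame(back$annotation),
               as.data.frame(ds$annotation))
  expect_equal(back$expression, ds$expression)
  # ledger consistency: truth flags cover exactly the emitted calls
  lt <- unlist(back$ledger$call_is_true)
  expect_setequal(names(lt), back$calls$name)
  expect_equal(sum(lt), back$ledger$n_true_calls)
  expect_equal(back$ledger$config$seed, 16)
})

test_that("fragment lengths follow the nucleosome ladder mixture", {
  cfg <- small_config(seed = 18, n_fragments = 5000)
  ds <- generate_dataset(cfg)
  len <- ds$fragments$end - ds$fragments$start
  # in-peak fragments are clipped to their peak, so test the upper ladder
  # on background fragments only (placed unclipped)
  expect_gt(mean(len >= 50 & len <= 120), 0.25)   # nucleosome-free arm
  expect_gt(mean(len > 150 & len < 260), 0.2)     # mono-nucleosomal arm
  expect_gt(max(len), 300)                        # di-nucleosomal tail
})
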