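make_gpr_lines <- function() {
  c("ATF\t1.0",
    "2\t8",
    '"Type=GenePix Results 3"',
    '"Wavelengths=635"',
    paste('"Block"', '"Column"', '"Row"', '"Name"', '"ID"',
          '"F635 Median"', '"B635 Median"', '"Flags"', sep = "\t"),
    "1\t1\t1\t\"ProtA\"\t\"ID_1\"\t1200\t60\t0",
    "1\t2\t1\t\"ProtA\"\t\"ID_1\"\t1100\t55\t0",
    "1\t3\t1\t\"ProtB\"\t\"ID_2\"\t300\t50\t-50",
    "1\t4\t1\t\"Control-1\"\t\"CTRL_1\"\t5000\t80\t0")
}

test_that("read_gpr parses an ATF fixture exactly", {
  f <- withr::local_tempfile(fileext = ".gpr")
  writeLines(make_gpr_lines(), f)
  scan <- read_gpr(f)
  expect_s3_class(scan, "array_scan")
  expect_equal(nrow(scan$spots), 4)
  expect_equal(scan$spots$f_median, c(1200, 1100, 300, 5000))
  expect_equal(scan$spots$b_median, c(60, 55, 50, 80))
  expect_equal(scan$spots$flags, c(0L, 0L, -50L, 0L))
  expect_equal(scan$spots$name[3], "ProtB")
  expect_equal(scan$spots$id[4], "CTRL_1")
  expect_equal(unname(scan$meta["Type"]), "GenePix Results 3")
  expect_equal(scan$sample_id, sub("\\.gpr$", "", basename(f)))
})

test_that("read_gpr reports missing columns and malformed numbers by name/line", {
  lines <- make_gpr_lines()
  lines[5] <- gsub('\t"F635 Median"', "", lines[5], fixed = TRUE)
  lines[6:9] <- sub("\t1200", "", lines[6:9])  # keep cell counts consistent
  f <- withr::local_tempfile(fileext = ".gpr")
  writeLines(lines, f)
  expect_error(read_gpr(f), "F635 Median")

  lines2 <- make_gpr_lines()
  lines2[7] <- sub("1100", "oops", lines2[7])
  writeLines(lines2, f)
  expect_error(read_gpr(f), "line 7")
  expect_error(read_gpr(f), "oops")
})

test_that("extra columns are tolerated and ignored", {
  lines <- make_gpr_lines()
  lines[5] <- paste0(lines[5], '\t"F635 Mean"')
  lines[6:9] <- paste0(lines[6:9], "\t999")
  f <- withr::local_tempfile(fileext = ".gpr")
  writeLines(lines, f)
  expect_equal(nrow(read_gpr(f)$spots), 4)
})

test_that("write_gpr / read_gpr round-trips records exactly, flags included", {
  for (seed in 1:5) {
    scan <- random_scan(n_spots = 40, seed = seed)
    f <- withr::local_tempfile(fileext = ".gpr")
    write_gpr(scan, f)
    back <- read_gpr(f, sample_id = scan$sample_id)
    expect_identical(back$spots, scan$spots)
    expect_equal(unname(back$meta["lot"]), "lot1")
    # second round trip is byte-stable
    f2 <- withr::local_tempfile(fileext = ".gpr")
    write_gpr(back, f2)
    expect_identical(readLines(f), readLines(f2))
  }
  # full array-sized scan
  big <- random_scan(n_spots = 9504, seed = 99)
  f <- withr::local_tempfile(fileext = ".gpr")
  write_gpr(big, f)
  expect_identical(read_gpr(f, sample_id = big$sample_id)$spots, big$spots)
})

test_that("load_study matches design rows to files and reports mismatches", {
  dir <- withr::local_tempdir()
  design <- study_design(data.frame(
    sample_id = sprintf("S%d", 1:6),
    group = rep(c("HC", "PD", "DC"), 2),
    lot = rep(c("lot1", "lot2"), 3), stringsAsFactors = FALSE))
  for (i in 1:6) write_gpr(random_scan(10, sprintf("S%d", i), seed = i),
                           file.path(dir, sprintf("S%d.gpr", i)))
  study <- load_study(design, dir)
  expect_length(study$scans, 6)
  expect_equal(names(study$scans), design$sample_id)
  expect_equal(unname(study$scans$S2$meta["lot"]), "lot2")

  file.remove(file.path(dir, "S4.gpr"))
  expect_error(load_study(design, dir), "S4")
  write_gpr(random_scan(10, "S4", 4), file.path(dir, "S4.gpr"))
  write_gpr(random_scan(10, "S7", 7), file.path(dir, "S7.gpr"))
  expect_warning(load_study(design, dir), "S7")
})

test_that("collapse_features aggregates duplicates, drops flags and controls", {
  mk <- function(sid, f) {
    spots <- data.frame(
      block = 1L, row = 1L, column = 1:4,
      name = c("X", "X", "Control-1", "Control-1"),
      id = c("X", "X", "C1", "C1"),
      f_median = f, b_median = 0, flags = 0L, stringsAsFactors = FALSE)
    array_scan(sid, spots)
  }
  m <- collapse_features(list(mk("A", c(100, 110, 7, 7)),
                              mk("B", c(200, 220, 7, 7))),
                         background = "none")
  expect_equal(dim(m$values), c(1L, 2L))
  expect_equal(unname(m$values["X", ]), c(105, 210))
  expect_equal(rownames(attr(m, "controls")), "C1")

  # flagged spot excluded from the mean
  s1 <- mk("A", c(100, 110, 7, 7)); s1$spots$flags[2] <- -50L
  m2 <- collapse_features(list(s1, mk("B", c(200, 220, 7, 7))),
                          background = "none")
  expect_equal(unname(m2$values["X", ]), c(100, 210))

  # all replicates flagged on one array -> imputed array minimum, warning
  s2 <- mk("A", c(100, 110, 7, 7)); s2$spots$flags[1:2] <- -50L
  s2$spots <- rbind(s2$spots,
                    data.frame(block = 1L, row = 2L, column = 1L, name = "Y",
                               id = "Y", f_median = 55, b_median = 0, flags = 0L))
  s3 <- mk("B", c(200, 220, 7, 7))
  s3$spots <- rbind(s3$spots,
                    data.frame(block = 1L, row = 2L, column = 1L, name = "Y",
                               id = "Y", f_median = 66, b_median = 0, flags = 0L))
  expect_warning(m3 <- collapse_features(list(s2, s3), background = "none"),
                 "imputed")
  expect_equal(unname(m3$values["X", "A"]), 55)  # array minimum
  # layouts must match
  s4 <- mk("B", c(1, 2, 3, 4)); s4$spots$id[1] <- "Z"
  expect_error(collapse_features(list(mk("A", c(1, 2, 3, 4)), s4)), "layout")
})

test_that("collapsed row count equals distinct non-control proteins by construction", {
  cfg <- sim_config(n_proteins = 4652L, n_controls = 100L,
                    group_sizes = c(HC = 2L), case_group = "HC",
                    n_markers = 0L, n_lot_features = 0L, lots = "lot1",
                    n_days = 1L, flag_rate = 0, seed = 3)
  sim <- simulate_study(cfg)
  expect_equal(nrow(sim$scans[[1]]$spots), 9504L)
  m <- collapse_features(sim$scans)
  expect_equal(nrow(m$values), 4652L)
  expect_equal(nrow(attr(m, "controls")), 100L)
})

test_that("identical duplicates aggregate to that exact value", {
  spots <- data.frame(block = 1L, row = 1L, column = 1:2, name = "X", id = "X",
                      f_median = c(123.5, 123.5), b_median = 0, flags = 0L,
                      stringsAsFactors = FALSE)
  m <- collapse_features(list(array_scan("A", spots)), background = "none")
  expect_identical(unname(m$values["X", "A"]), 123.5)
})

test_that("matrix TSV round trip preserves values and provenance", {
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
  m <- intensity_matrix(vals, provenance = c("collapse", "log2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, f)
  back <- read_matrix(f)
  expect_equal(back$values, m$values, tolerance = 1e-12)
  expect_identical(back$provenance, m$provenance)
})
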