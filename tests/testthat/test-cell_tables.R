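test_that("canonical CSV parses into a validated cell table", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,roi_id,timepoint,cell_id,x_um,y_um,CD3,CD8",
               "S1,R1,week1,c1,10.5,20.5,1,0",
               "S1,R1,week1,c2,30.0,40.0,1,1",
               "S1,R1,week1,c3,50.0,60.0,0,0"), f)
  ct <- read_cell_table(f, toy_panel())
  expect_s3_class(ct, "cell_table")
  expect_equal(nrow(ct), 3L)
  expect_equal(ct$CD3, c(1L, 1L, 0L))
  expect_equal(ct$x_um, c(10.5, 30, 50))
  expect_equal(nrow(attr(ct, "rejected")), 0L)
})

test_that("vendor-style header synonyms and positivity encodings are accepted", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sample Name,Region,Week,Cell ID,Cell X Position,Cell Y Position,CD3,CD8",
               "S1,R1,week1,c1,10.5,20.5,pos,neg",
               "S1,R1,week1,c2,30.0,40.0,+,TRUE",
               "S1,R1,week1,c3,50.0,60.0,no,0"), f)
  ct <- read_cell_table(f, toy_panel())
  expect_equal(ct$CD3, c(1L, 1L, 0L))
  expect_equal(ct$CD8, c(0L, 1L, 0L))
  expect_equal(names(ct)[1:6],
               c("sample_id", "roi_id", "timepoint", "cell_id", "x_um", "y_um"))
})

test_that("read errors and row rejections are explicit", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,roi_id,timepoint,x_um,y_um,CD3",
               "S1,R1,week1,1,2,1"), f)
  expect_error(read_cell_table(f), "cell_id")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,roi_id,timepoint,cell_id,x_um,y_um,CD3",
               "S1,R1,week1,c1,abc,2,1",
               "S1,R1,week1,c2,5,6,1",
               "S1,R1,week1,c3,7,8,maybe"), f2)
  ct <- suppressMessages(read_cell_table(f2))
  expect_equal(nrow(ct), 1L)
  rej <- attr(ct, "rejected")
  expect_equal(rej$line, c(2L, 4L))
  expect_match(rej$reason[1], "non-numeric coordinate")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,roi_id,timepoint,cell_id,x_um,y_um,CD3",
               "S1,R1,week1,c1,1,2,1",
               "S1,R1,week1,c1,3,4,0"), f3)
  expect_error(suppressMessages(read_cell_table(f3)), "duplicate cell_id")
})

test_that("write -> read is the identity, and counts match generator bookkeeping", {
  panel <- default_panels(1)[["1"]]
  cfg <- sim_config()
  ct <- simulate_roi(cfg, panel, seed = 11)
  recorded <- colSums(as.data.frame(ct)[cell_table_markers(ct)])
  f <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(ct, f)
  back <- read_cell_table(f, panel)
  expect_equal(strip_attrs(back), strip_attrs(ct))
  expect_equal(colSums(as.data.frame(back)[cell_table_markers(back)]), recorded)

  # empty table -> header-only file
  empty <- make_ct(numeric(0), numeric(0), markers = list(CD3 = integer(0)),
                   cell_id = character(0))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(empty, f2)
  expect_equal(length(readLines(f2)), 1L)
  expect_equal(nrow(read_cell_table(f2)), 0L)
})

test_that("coordinate merge joins markers, drops mismatches, conserves rows", {
  a <- make_ct(c(1, 2, 3), c(1, 2, 3), markers = list(CD3 = c(1, 0, 1)))
  b <- make_ct(c(1, 2, 8), c(1, 2, 3), markers = list(CD8 = c(0, 1, 1)))
  m <- merge_marker_tables(list(cd3 = a, cd8 = b))
  expect_equal(nrow(m), 2L)
  expect_setequal(cell_table_markers(m), c("CD3", "CD8"))
  expect_equal(m$CD3, c(1L, 0L))
  expect_equal(m$CD8, c(0L, 1L))
  rep <- attr(m, "merge_report")
  expect_equal(rep$cd3$n_dropped, 1L)
  expect_equal(rep$cd8$n_dropped, 1L)
  for (r in rep) expect_equal(r$n_matched + r$n_dropped, r$n_rows)
})

test_that("a 5 um offset exceeds the 0.1 um tolerance and is dropped", {
  a <- make_ct(c(10, 20), c(10, 20), markers = list(CD3 = c(1, 1)))
  b <- make_ct(c(10, 25), c(10, 20), markers = list(CD8 = c(1, 1)))
  m <- merge_marker_tables(list(a = a, b = b))
  expect_equal(nrow(m), 1L)
  expect_equal(attr(m, "merge_report")$a$n_dropped, 1L)
})

test_that("split/re-merge round-trips a consolidated table and is order-independent", {
  panel <- default_panels(1)[["1"]]
  cfg <- sim_config(nest_parent_rate = 2, nest_offspring_mean = 50,
                    immune_rate = 80, macrophage_rate = 20, other_rate = 50)
  ct <- simulate_roi(cfg, panel, seed = 5)
  ct <- cell_table(utils::head(strip_attrs(ct), 200))
  split_one <- function(mk) {
    cell_table(as.data.frame(ct)[c("sample_id", "roi_id", "timepoint",
                                   "cell_id", "x_um", "y_um", mk)])
  }
  parts <- lapply(c("CD3", "CD8", "CK"), split_one)
  merged <- merge_marker_tables(parts)
  keep <- c("sample_id", "roi_id", "timepoint", "cell_id", "x_um", "y_um",
            "CD3", "CD8", "CK")
  orig <- strip_attrs(ct)[keep]
  orig <- orig[order(orig$x_um, orig$y_um), ]
  rownames(orig) <- NULL
  expect_equal(strip_attrs(merged)[keep], orig)
  for (r in attr(merged, "merge_report")) expect_equal(r$n_dropped, 0L)

  merged2 <- merge_marker_tables(rev(parts))
  expect_equal(strip_attrs(merged2)[keep], strip_attrs(merged)[keep])
})

test_that("ambiguous coordinate collisions and disjoint frames fail loudly", {
  a <- make_ct(c(10, 10.01), c(10, 10.01), markers = list(CD3 = c(1, 0)))
  b <- make_ct(c(10, 20), c(10, 20), markers = list(CD8 = c(1, 1)))
  expect_error(merge_marker_tables(list(a = a, b = b)), "ambiguity")

  c1 <- make_ct(1, 1, markers = list(CD3 = 1), sample_id = "S1")
  c2 <- make_ct(1, 1, markers = list(CD8 = 1), sample_id = "S2")
  expect_error(merge_marker_tables(list(c1, c2)), "no .*frame is shared")
})

test_that("cell table invariants are enforced", {
  expect_error(make_ct(1000, 10, markers = list(CD3 = 1)), "x coordinates")
  expect_error(make_ct(10, 10, markers = list(CD3 = 2)), "0/1")
  expect_error(cell_table(data.frame(sample_id = "S"), width_um = 0),
               "strictly positive")
  ct <- make_ct(10, 10, markers = list(CD3 = 1))
  expect_error(validate_cell_table(ct, toy_panel()), "CD8")
})
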