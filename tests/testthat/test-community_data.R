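test_that("CSV workbook round-trips to an identical dataset", {
  for (seed in 1:5) {
    ds <- random_dataset(6, 4, seed = seed)
    td <- withr::local_tempdir()
    write_workbook(ds, td)
    ds2 <- read_workbook(td)
    expect_identical(ds$counts, ds2$counts)
    expect_identical(ds$points, ds2$points)
  }
  # zero counts come back as zero; empty table stays empty
  m <- matrix(c(0L, 2L, 0L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("p1", "p2")))
  ds <- make_dataset(m)
  td <- withr::local_tempdir()
  write_workbook(ds, td)
  expect_identical(read_workbook(td)$counts, ds$counts)
  empty <- edna_dataset(matrix(integer(), 0, 2,
                               dimnames = list(NULL, c("p1", "p2"))),
                        make_points(c("p1", "p2")))
  td2 <- withr::local_tempdir()
  write_workbook(empty, td2)
  expect_equal(nrow(read_workbook(td2)$counts), 0)
})

test_that("XLSX workbooks with Read/Location sheets are read", {
  tf <- withr::local_tempfile(fileext = ".xlsx")
  py <- sprintf("
import openpyxl
wb = openpyxl.Workbook()
ws = wb.active; ws.title = 'Read'
ws.append(['feature_id', 'P1', 'P2'])
ws.append(['ASV_1', 5, 0])
ws.append(['ASV_2', None, 3])   # blank cell must read as 0
loc = wb.create_sheet('Location')
loc.append(['point_id','station_id','latitude','longitude','depth_m','dataset_label','is_control'])
loc.append(['P1','S1',30.5,130.25,10,'cruise','FALSE'])
loc.append(['P2','S1',30.5,130.25,50,'cruise','FALSE'])
wb.save(%s)", deparse(tf))
  res <- system2("python", c("-c", shQuote(py)))
  expect_identical(res, 0L)
  ds <- read_workbook(tf)
  expect_equal(dim(ds$counts), c(2, 2))
  expect_identical(ds$counts["ASV_2", "P1"], 0L)
  expect_identical(ds$counts["ASV_1", "P1"], 5L)
  expect_equal(ds$points$depth_m, c(10, 50))
})

test_that("validation rejects malformed workbooks", {
  m <- matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("p1", "p2")))
  # orphan point: Location lacks p2
  expect_error(edna_dataset(m, make_points("p1")), "p2")
  # out-of-range latitude
  expect_error(edna_dataset(m, make_points(c("p1", "p2"), lat = 95)),
               "latitude")
  # duplicate ids
  expect_error(edna_dataset(matrix(1L, 2, 2,
                                   dimnames = list(c("a", "a"), c("p1", "p2"))),
                            make_points(c("p1", "p2"))), "duplicate feature")
  # negative / fractional counts
  expect_error(edna_dataset(matrix(c(-1, 1, 1, 1), 2, 2,
                                   dimnames = dimnames(m)),
                            make_points(c("p1", "p2"))), "negative")
  expect_error(edna_dataset(matrix(c(0.5, 1, 1, 1), 2, 2,
                                   dimnames = dimnames(m)),
                            make_points(c("p1", "p2"))), "fractional")
  # missing Location sheet in a CSV directory
  td <- withr::local_tempdir()
  write.csv(data.frame(feature_id = "a", p1 = 1), file.path(td, "Read.csv"),
            row.names = FALSE)
  expect_error(read_workbook(td), "location")
})

test_that("longitudes are normalized into [-180, 180]", {
  m <- matrix(1L, 1, 2, dimnames = list("a", c("p1", "p2")))
  ds <- edna_dataset(m, make_points(c("p1", "p2"), lon = c(190, -200)))
  expect_equal(ds$points$longitude, c(-170, 160))
})

test_that("merge_datasets takes the feature union and conserves counts", {
  m1 <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
               dimnames = list(c("ASV_1", "ASV_2"), c("a1", "a2")))
  m2 <- matrix(c(5L, 6L, 7L, 8L), 2, 2,
               dimnames = list(c("ASV_1", "ASV_3"), c("b1", "b2")))
  d1 <- make_dataset(m1, label = "A")
  d2 <- make_dataset(m2, label = "B")
  merged <- merge_datasets(list(d1, d2))
  # hand-computed union: ASV_1 concatenates both, others padded with 0
  expect_setequal(rownames(merged$counts), c("ASV_1", "ASV_2", "ASV_3"))
  expect_equal(merged$counts["ASV_1", ], c(a1 = 1L, a2 = 3L, b1 = 5L, b2 = 7L))
  expect_equal(merged$counts["ASV_2", c("b1", "b2")], c(b1 = 0L, b2 = 0L))
  expect_equal(sum(merged$counts), sum(m1) + sum(m2))
  expect_equal(merged$points$dataset_label,
               c("A", "A", "B", "B"))
  # single-dataset merge is the identity
  expect_identical(merge_datasets(list(d1)), d1)
  # shared point_id is an error
  d3 <- make_dataset(matrix(1L, 1, 1, dimnames = list("x", "a1")))
  expect_error(merge_datasets(list(d1, d3)), "duplicate point_id")
  # associativity up to row ordering, on count content
  d4 <- make_dataset(matrix(2L, 1, 1, dimnames = list("ASV_9", "c1")))
  left <- merge_datasets(list(merge_datasets(list(d1, d2)), d4))
  right <- merge_datasets(list(d1, merge_datasets(list(d2, d4))))
  feats <- sort(rownames(left$counts))
  expect_identical(left$counts[feats, ], right$counts[feats, ])
})

test_that("to_presence_absence maps onto {0,1}, idempotently", {
  set.seed(42)
  m <- matrix(rpois(30, 2), 5, 6,
              dimnames = list(paste0("f", 1:5), paste0("p", 1:6)))
  b <- to_presence_absence(m)
  expect_true(all(b %in% c(0L, 1L)))
  expect_true(all(b <= m))
  expect_identical(to_presence_absence(b), b)
  expect_identical(to_presence_absence(c(0, 1, 7)), c(0L, 1L, 1L))
  zero <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("p", "q")))
  expect_identical(to_presence_absence(zero), zero)
})
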