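test_that("bundled standard parses with the published structure", {
  std <- slope_standard()
  expect_s3_class(std, "grade_standard")
  expect_identical(index_ids(std), paste0("X", 1:15))
  expect_identical(std$grade_labels, c("I", "II", "III", "IV", "V"))
  x5 <- std$indexes$X5
  expect_equal(x5$lo[1], 95)          # grade-I vegetation coverage (95,100]
  expect_equal(x5$hi[1], 100)
  x6 <- std$indexes$X6
  expect_identical(x6$kind, "qualitative")
  expect_equal(x6$lo, as.numeric(1:5))
  # decreasing (X1) and increasing (X3) interval directions both validate
  expect_equal(std$indexes$X1$lo, c(60, 50, 40, 30, 0))
  expect_equal(std$indexes$X3$lo, c(0, 5, 15, 25, 35))
})

test_that("standard validation rejects malformed tables", {
  hdr <- "index_id,name,kind,units,g1_lo,g1_hi,g2_lo,g2_hi,g3_lo,g3_hi,g4_lo,g4_hi,g5_lo,g5_hi"
  # grade-II interval with lo >= hi
  expect_error(
    read_grade_standard(c(hdr, "X2,perm,quantitative,,30,40,20,15,10,20,5,10,0,5")),
    "X2.*grade 2|empty interval")
  # negative bound
  expect_error(
    read_grade_standard(c(hdr, "X1,s,quantitative,,60,100,50,60,40,50,30,40,-1,30")),
    "negative")
  # non-contiguous intervals
  expect_error(
    read_grade_standard(c(hdr, "X1,s,quantitative,,60,100,50,59,40,50,30,40,0,30")),
    "contiguous")
  # qualitative scores must be 1..5 in grade order
  expect_error(
    read_grade_standard(c(hdr, "X6,dr,qualitative,,5,,4,,3,,2,,1,")),
    "scores")
  expect_error(grade_standard(list(index_definition("A", kind = "qualitative"),
                                   index_definition("A", kind = "qualitative"))),
               "duplicate")
})

test_that("structured config parses like its delimited-text twin", {
  cfg <- list(
    list(index_id = "X5", name = "Vegetation coverage",
         kind = "quantitative", units = "%",
         g1_lo = 95, g1_hi = 100, g2_lo = 80, g2_hi = 95,
         g3_lo = 65, g3_hi = 80, g4_lo = 40, g4_hi = 65,
         g5_lo = 0, g5_hi = 40),
    list(index_id = "X6", name = "Drought resistance",
         kind = "qualitative", units = "",
         g1_lo = 1, g1_hi = "", g2_lo = 2, g2_hi = "",
         g3_lo = 3, g3_hi = "", g4_lo = 4, g4_hi = "",
         g5_lo = 5, g5_hi = ""))
  std <- read_grade_standard(cfg)
  expect_identical(index_ids(std), c("X5", "X6"))
  expect_equal(std$indexes$X5$lo, c(95, 80, 65, 40, 0))
  expect_identical(std$indexes$X6$kind, "qualitative")
})

test_that("round-trip write/read preserves bounds exactly", {
  for (s in c(2, 7)) {
    std <- random_grade_standard(n_indexes = 6, seed = s)
    path <- withr::local_tempfile(fileext = ".csv")
    write_grade_standard(std, path)
    back <- read_grade_standard(path)
    expect_identical(index_ids(back), index_ids(std))
    for (id in index_ids(std)) {
      expect_identical(back$indexes[[id]]$kind, std$indexes[[id]]$kind)
      expect_equal(back$indexes[[id]]$lo, std$indexes[[id]]$lo)
      expect_equal(back$indexes[[id]]$hi, std$indexes[[id]]$hi)
    }
  }
})

test_that("grade intervals partition their union under (lo, hi]", {
  std <- random_grade_standard(n_indexes = 10, seed = 31)
  for (d in std$indexes) {
    if (d$kind != "quantitative") next
    pts <- sort(unique(c(
      stats::runif(50, min(d$lo), max(d$hi)),
      d$hi)))                       # include shared endpoints
    pts <- pts[pts > min(d$lo) & pts <= max(d$hi)]
    for (v in pts) {
      hits <- sum(v > d$lo & v <= d$hi)
      expect_identical(hits, 1L)
    }
  }
})

test_that("grade_of_value follows the half-open boundary convention", {
  std <- slope_standard()
  expect_identical(grade_of_value("X5", 97.27, std), "I")
  # a shared endpoint belongs to the interval where it is the upper bound
  expect_identical(grade_of_value("X1", 50, std), "III")
  expect_identical(grade_of_value("X1", 150, std), NA_character_)
  expect_identical(grade_of_value("X6", 3, std), "III")
})

test_that("read_objects aligns, validates and accepts the bundled data", {
  std <- slope_standard()
  sites <- slope_sites()
  expect_length(sites, 7)
  s4 <- sites[[4]]
  expect_equal(unname(s4$values[c("X1", "X5", "X13")]), c(58.79, 97.27, 1.32))
  # every bundled value is in range of the bundled standard: no warning
  expect_no_warning(slope_sites())

  # order-insensitive columns
  two <- read_objects(c("object_id,X2,X1,X3",
                        "a,35,0.5,3", "b,12,4.2,1"),
                      tiny_standard())
  expect_equal(unname(two[[1]]$values), c(0.5, 35, 3))

  expect_error(read_objects(c("object_id,X1,X2", "a,1,2"), tiny_standard()),
               "X3")
  expect_error(read_objects(c("object_id,X1,X2,X3", "a,1,-0.2,3"),
                            tiny_standard()),
               "negative")
  expect_error(read_objects(c("object_id,X1,X2,X3", "a,1,oops,3"),
                            tiny_standard()),
               "row 1.*X2")
  expect_identical(read_objects("object_id,X1,X2,X3", tiny_standard()),
                   list())
})

test_that("out-of-range observed values are accepted with a warning", {
  std <- tiny_standard()
  expect_warning(o <- evaluation_object("far", c(9.5, 20, 3), std),
                 "outside")
  expect_equal(unname(o$values[1]), 9.5)
  # qualitative scores outside 1..5 are rejected outright
  expect_error(evaluation_object("bad", c(1, 20, 7), std), "1..5")
})
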