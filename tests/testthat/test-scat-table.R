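test_that("a long-format file parses into grouped, validated records", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scat_id,predator,prey_taxon,volume_fraction",
               "S1,tiger,wild_pig,0.7",
               "S1,tiger,serow,0.3"), f)
  x <- read_scat_table(f)
  expect_s3_class(x, "scat_table")
  expect_equal(n_scats(x), 1)
  expect_equal(x$prey_taxon, c("wild_pig", "serow"))
  expect_equal(x$volume_fraction, c(0.7, 0.3))
})

test_that("volume-fraction sums are renormalized within 2% and rejected beyond", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scat_id,predator,prey_taxon,volume_fraction",
               "S1,tiger,wild_pig,0.70",
               "S1,tiger,serow,0.31"), f)
  x <- read_scat_table(f)
  expect_equal(sum(x$volume_fraction), 1)

  writeLines(c("scat_id,predator,prey_taxon,volume_fraction",
               "BAD7,tiger,wild_pig,0.5"), f)
  expect_error(read_scat_table(f), "BAD7")
})

test_that("schema mapping, missing columns and unknown predators are caught", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,cat,prey,frac",
               "S1,tiger,wild_pig,1.0"), f)
  x <- read_scat_table(f, schema = c(scat_id = "sample", predator = "cat",
                                     prey_taxon = "prey",
                                     volume_fraction = "frac"))
  expect_equal(x$prey_taxon, "wild_pig")
  expect_error(read_scat_table(f), "missing column")
  expect_error(
    read_scat_table(f, schema = c(scat_id = "sample", predator = "cat",
                                  prey_taxon = "prey",
                                  volume_fraction = "frac"),
                    known_predators = c("clouded_leopard", "leopard")),
    "unknown predator")
})

test_that("within-scat duplicates and non-positive fractions are invalid", {
  df <- data.frame(scat_id = "S1", predator = "tiger",
                   prey_taxon = c("wild_pig", "wild_pig"),
                   volume_fraction = c(0.5, 0.5))
  expect_error(scat_table(df), "duplicated prey taxon")
  df2 <- data.frame(scat_id = "S1", predator = "tiger",
                    prey_taxon = c("wild_pig", "serow"),
                    volume_fraction = c(1.2, -0.2))
  expect_error(scat_table(df2), "positive")
})

test_that("write then read round-trips records", {
  x <- mk_scats(list(c(A = 0.123456, B = 0.876544), "C", c("A", "D")))
  x$date <- as.Date("2009-01-10") + seq_len(nrow(x))
  x <- scat_table(as.data.frame(x))
  f <- withr::local_tempfile(fileext = ".csv")
  write_scat_table(x, f)
  y <- read_scat_table(f)
  expect_equal(y$scat_id, x$scat_id)
  expect_equal(y$predator, x$predator)
  expect_equal(y$prey_taxon, x$prey_taxon)
  expect_equal(round(y$volume_fraction, 6), round(x$volume_fraction, 6))
  expect_equal(y$date, x$date)
})

test_that("seasons follow the monsoon calendar with inclusive boundaries", {
  expect_equal(assign_season(as.Date("2009-06-01")), "rainy")
  expect_equal(assign_season(as.Date("2009-12-01")), "dry")
  expect_equal(assign_season(as.Date(c("2009-05-14", "2009-05-15",
                                       "2009-10-31", "2009-11-01"))),
               c("dry", "rainy", "rainy", "dry"))
  expect_error(assign_season(NA), "invalid date")
})

test_that("the packaged example data has the published structure", {
  x <- nepl_fixture("both")
  cl <- nepl_fixture("clouded_leopard")
  tg <- nepl_fixture("tiger")
  expect_equal(n_scats(x), 35)
  expect_equal(n_scats(cl), 14)
  expect_equal(n_scats(tg), 21)
  # single-item scat counts and item-count range as reported
  expect_equal(sum(table(cl$scat_id) == 1), 8)
  expect_equal(sum(table(tg$scat_id) == 1), 14)
  expect_true(all(table(x$scat_id) %in% 1:3))
  # species-level prey richness
  expect_equal(length(unique(cl$prey_taxon)), 7)
  expect_equal(length(unique(tg$prey_taxon)), 8)
  # synthesized metadata is complete and mostly dry-season
  expect_true(all(!is.na(x$date)))
  expect_equal(sum(tapply(x$season, x$scat_id, `[`, 1) == "dry"), 28)
})
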