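test_that("listwise deletion drops exactly the rows with missing items", {
  # 348 respondents, 30 of whom skipped at least one item
  set.seed(42)
  vals <- matrix(sample(0:3, 348 * 21, replace = TRUE), 348, 21)
  df <- as.data.frame(vals)
  colnames(df) <- paste0("item", 1:21)
  miss_rows <- sample(348, 30)
  for (r in miss_rows) df[r, sample(21, sample(1:3, 1))] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)

  x <- read_responses(path)
  expect_equal(x$n, 318)
  expect_equal(attr(x, "n_read"), 348)
  expect_equal(attr(x, "n_dropped"), 30)
  expect_true(all(x$values %in% 0:3))

  # idempotence: re-reading the retained matrix drops nothing
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(x, path2)
  x2 <- read_responses(path2)
  expect_equal(attr(x2, "n_dropped"), 0)
  expect_equal(x2$values, x$values, ignore_attr = TRUE)
})

test_that("complete files pass through untouched", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_response_csv(matrix(sample(0:3, 5 * 4, replace = TRUE), 5, 4),
                     path, paste0("item", 1:4))
  x <- read_responses(path)
  expect_equal(x$n, 5)
  expect_equal(attr(x, "n_dropped"), 0)
})

test_that("out-of-range scores drop the row with a warning, or error in strict mode", {
  vals <- matrix(sample(0:3, 6 * 3, replace = TRUE), 6, 3)
  vals[2, 1] <- 4
  path <- withr::local_tempfile(fileext = ".csv")
  write_response_csv(vals, path, paste0("item", 1:3))
  expect_warning(x <- read_responses(path), "outside 0\\.\\.3")
  expect_equal(x$n, 5)
  expect_error(read_responses(path, strict = TRUE), "outside 0\\.\\.3")
})

test_that("schema and validation failures are informative", {
  expect_error(read_responses(file.path(tempdir(), "no-such-file.csv")),
               "not found")

  vals <- matrix(sample(0:3, 4 * 3, replace = TRUE), 4, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_response_csv(vals, path, paste0("item", 1:3))
  expect_error(read_responses(path, item_ids = paste0("item", 1:4)),
               "item4")

  vals2 <- matrix(sample(0:3, 4 * 3, replace = TRUE), 4, 3)
  storage.mode(vals2) <- "double"
  vals2[3, 2] <- 1.5
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_response_csv(vals2, path2, paste0("item", 1:3))
  expect_error(read_responses(path2), "row 3, item 'item2'")
})

test_that("the DASS-21 preset allocates three subscales of seven items", {
  cm <- load_community_map(preset = "dass21")
  expect_setequal(cm$communities, c("Stress", "Anxiety", "Depression"))
  sizes <- table(cm$assignment)
  expect_true(all(sizes == 7))
  expect_equal(unname(cm$assignment["item3"]), "Stress")
  expect_equal(unname(cm$assignment["item11"]), "Anxiety")
  expect_equal(unname(cm$assignment["item18"]), "Depression")
})

test_that("community maps validate coverage and uniqueness", {
  cm <- community_map(list(all = paste0("item", 1:21)))
  expect_silent(validate_communities(cm, paste0("item", 1:21)))

  expect_error(community_map(list(A = c("i1", "i2"), B = c("i2"))),
               "more than one community")

  cm20 <- community_map(list(
    Stress = paste0("item", 1:7), Anxiety = paste0("item", 8:14),
    Depression = paste0("item", 15:20)
  ))
  expect_error(validate_communities(cm20, paste0("item", 1:21)), "item21")
})

test_that("community maps round-trip through YAML and JSON", {
  m <- list(Stress = c("item1", "item2"), Anxiety = c("item3"))
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(m, ypath)
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(m, jpath)
  for (cm in list(load_community_map(ypath), load_community_map(jpath))) {
    expect_s3_class(cm, "community_map")
    expect_equal(unname(cm$assignment[c("item1", "item3")]),
                 c("Stress", "Anxiety"))
  }
})

test_that("sample summaries reproduce printed two-decimal percentages", {
  counts <- data.frame(
    variable = c("worked", "worked", "x", "y"),
    category = c("yes", "no", "a", "a"),
    count = c(284, 34, 0, 1)
  )
  out <- summarize_sample(counts[1:2, ], n = 318)
  expect_equal(out$percent, c(89.31, 10.69))
  expect_equal(summarize_sample(counts[3, ], n = 10)$percent, 0)
  expect_equal(summarize_sample(counts[4, ], n = 3)$percent, 33.33)
  expect_error(
    summarize_sample(data.frame(variable = "v", category = "a", count = 11),
                     n = 10),
    "exceed"
  )
})

test_that("percentages within a variable sum to 100 up to rounding", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    n <- sample(50:500, 1)
    cnt <- as.vector(stats::rmultinom(1, n, runif(k)))
    out <- summarize_sample(
      data.frame(variable = "v", category = letters[1:k], count = cnt), n)
    expect_lt(abs(sum(out$percent) - 100), 0.02 * k)
  }
})
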