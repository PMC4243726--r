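test_that("csv ingest round-trips and reports bad rows with line numbers", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  sim <- simulate_paired_data(synthetic_config(n = 3, seed = 15))
  write_paired_csv(sim$data, tmp)
  back <- read_paired_csv(tmp)
  expect_equal(as.matrix(back[item_names]),
               as.matrix(as.data.frame(sim$data)[item_names]),
               ignore_attr = TRUE)
  expect_equal(back$chu9d, sim$data$chu9d, tolerance = 1e-12)
  back2 <- read_paired_csv(tmp)
  expect_identical(back, back2)

  # observed utility above 1 is an ingest error, located by file line
  df <- as.data.frame(sim$data)
  df$chu9d[2] <- 1.2
  utils::write.csv(df, tmp, row.names = FALSE)
  expect_error(read_paired_csv(tmp), "line 3.*1.2")

  # header-only file: empty dataset with a warning
  utils::write.csv(df[0, ], tmp, row.names = FALSE)
  expect_warning(empty <- read_paired_csv(tmp), "header only")
  expect_identical(nrow(empty), 0L)

  # missing required column named in the error
  utils::write.csv(df[, setdiff(names(df), "ks_i4")], tmp, row.names = FALSE)
  expect_error(read_paired_csv(tmp), "ks_i4")
})

test_that("the map subcommand reproduces the published maximum on one record", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  infile <- file.path(dir, "r.csv")
  outfile <- file.path(dir, "p.csv")
  utils::write.csv(all_items_row(5), infile, row.names = FALSE)
  status <- suppressMessages(
    run_cli(c("map", "--in", infile, "--algorithm", "AU/MM/model2",
              "--out", outfile)))
  expect_identical(status, 0L)
  out <- utils::read.csv(outfile)
  expect_equal(round(out$raw, 4), 1.0555)
  expect_equal(out$truncated, 1.0000, tolerance = 1e-9)
})

test_that("unknown algorithms exit non-zero and list the registry", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  infile <- file.path(dir, "r.csv")
  utils::write.csv(all_items_row(5), infile, row.names = FALSE)
  msgs <- character()
  status <- withCallingHandlers(
    run_cli(c("map", "--in", infile, "--algorithm", "AU/XX/model9",
              "--out", file.path(dir, "p.csv"))),
    message = function(m) { msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage") })
  expect_identical(status, 1L)
  expect_true(any(grepl("AU/MM/model2", msgs)))
  # usage errors exit 2
  expect_identical(suppressMessages(run_cli(c("map", "--in", infile))), 2L)
  expect_identical(suppressMessages(run_cli(c("bogus"))), 2L)
})

test_that("simulate is reproducible from the seed and fit round-trips a spec", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  f1 <- file.path(dir, "s1.csv"); f2 <- file.path(dir, "s2.csv")
  expect_identical(suppressMessages(
    run_cli(c("simulate", "--n", "10", "--seed", "7", "--out", f1))), 0L)
  expect_identical(suppressMessages(
    run_cli(c("simulate", "--n", "10", "--seed", "7", "--out", f2))), 0L)
  expect_identical(readLines(f1), readLines(f2))

  big <- file.path(dir, "big.csv")
  suppressMessages(run_cli(c("simulate", "--n", "250", "--seed", "8",
                             "--out", big)))
  specfile <- file.path(dir, "spec.json")
  status <- suppressMessages(
    run_cli(c("fit", "--in", big, "--model", "model2", "--estimator", "ols",
              "--stepwise", "--out", specfile)))
  expect_identical(status, 0L)
  spec <- read_mapping_spec(specfile)
  expect_s3_class(spec, "chu9d_spec")
  expect_identical(spec$form, "item_linear")

  report <- file.path(dir, "report.json")
  status <- suppressMessages(
    run_cli(c("validate", "--in", big, "--spec", specfile, "--scheme",
              "subsample", "--sizes", "50,100", "--seed", "3",
              "--report", report)))
  expect_identical(status, 0L)
  rep <- jsonlite::read_json(report)
  expect_named(rep$results, c("n50", "n100"))
})
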