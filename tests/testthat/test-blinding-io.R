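lab_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("pid,date,value", lines), path)
  path
}

test_that("lab reports parse values, below-LOD tokens, and bad rows", {
  path <- lab_csv(c("P01,2014-01-06,0.72",
                    "P02,2014-01-06,<LOD",
                    "P03,2014-01-06,0.55"))
  rows <- read_lab_report(path)
  expect_equal(nrow(rows), 3)
  expect_equal(rows$below_lod, c(FALSE, TRUE, FALSE))
  expect_equal(rows$value, c(0.72, NA, 0.55))

  bad <- read_lab_report(lab_csv(c("P01,2014-01-06,0.72",
                                   "P02,2014-01-06,abc",
                                   "P03,2014-01-06,0.55")))
  expect_equal(nrow(bad), 2)
  errs <- attr(bad, "errors")
  expect_equal(nrow(errs), 1)
  expect_equal(errs$pid, "P02")
  expect_match(errs$reason, "unparseable")

  noval <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pid,date", "P01,2014-01-06"), noval)
  expect_error(read_lab_report(noval), "missing required column")
})

test_that("re-blinding passes treatment rows through and substitutes placebo rows", {
  rows <- read_lab_report(lab_csv(c("P01,2014-01-06,0.72",
                                    "P02,2014-01-06,<LOD",
                                    "P03,2014-01-06,0.55",
                                    "P04,2014-01-06,<LOD")))
  alloc <- c(P01 = "treatment", P02 = "placebo",
             P03 = "treatment", P04 = "placebo")
  set.seed(12)
  res <- reblind(rows, alloc, fed_sampler())
  out <- res$reblinded
  expect_equal(nrow(out), nrow(rows))
  expect_identical(names(out), c("pid", "date", "concentration"))
  # treatment values byte-identical, below-LOD treatment rows included
  expect_equal(out$concentration[out$pid == "P01"], "0.72")
  expect_equal(out$concentration[out$pid == "P03"], "0.55")
  # placebo rows carry sham values inside the current window
  sham <- as.numeric(out$concentration[out$pid %in% c("P02", "P04")])
  expect_true(all(sham >= 0.6 & sham <= 1.0))
  # one audit line per substitution, carrying parameters and window
  expect_equal(nrow(res$audit), 2)
  expect_true(all(c("mean_hat", "sd_hat", "lower", "upper", "value")
                  %in% names(res$audit)))
})

test_that("treatment below-LOD rows are never replaced", {
  rows <- read_lab_report(lab_csv(c("P01,2014-01-06,<LOD")))
  res <- reblind(rows, c(P01 = "treatment"), fed_sampler())
  expect_equal(res$reblinded$concentration, "<LOD")
  expect_null(res$audit)
})

test_that("an all-treatment batch is returned unmodified", {
  rows <- read_lab_report(lab_csv(c("P01,2014-01-06,0.72",
                                    "P02,2014-01-06,0.48")))
  res <- reblind(rows, c(P01 = "treatment", P02 = "treatment"),
                 fed_sampler())
  expect_identical(res$reblinded$concentration, c("0.72", "0.48"))
})

test_that("estimates refresh with the batch before sham drawing", {
  rows <- read_lab_report(lab_csv(c("P01,2014-01-06,0.70",
                                    "P02,2014-01-06,<LOD")))
  s <- update(sham_sampler(n_min = 1), c(0.5, 0.6))
  res <- reblind(rows, c(P01 = "treatment", P02 = "placebo"), s)
  expect_equal(res$sampler$mean_hat, mean(c(0.5, 0.6, 0.7)))
})

test_that("a pid absent from the allocation list is a hard error", {
  rows <- read_lab_report(lab_csv(c("P01,2014-01-06,0.72",
                                    "P99,2014-01-06,<LOD")))
  expect_error(reblind(rows, c(P01 = "treatment"), fed_sampler()), "P99")
})

test_that("the re-blinded file leaks no arm information", {
  tr <- tiny_trial(seed = 19)
  dir <- withr::local_tempdir()
  paths <- write_trial(tr, dir)
  rows <- read_lab_report(paths[["lab"]])
  set.seed(3)
  res <- reblind(rows, alloc_of(tr), fed_sampler())
  out_path <- file.path(dir, "reblinded.csv")
  write_reblinded(res$reblinded, out_path)
  raw <- readLines(out_path)
  expect_false(any(grepl("arm|treatment|placebo|lithium", raw,
                         ignore.case = TRUE)))
  expect_equal(length(raw) - 1L, nrow(rows))
  # all values are formatted alike: a number at report precision or <LOD
  vals <- vapply(strsplit(raw[-1], ","), `[[`, "", 3)
  expect_true(all(grepl("^([0-9]+\\.[0-9]{2}|<LOD)$", vals)))
})

test_that("re-running a batch from saved state reproduces the bytes", {
  rows <- read_lab_report(lab_csv(c("P01,2014-01-06,0.72",
                                    "P02,2014-01-06,<LOD",
                                    "P03,2014-01-06,<LOD")))
  alloc <- c(P01 = "treatment", P02 = "placebo", P03 = "placebo")
  dir <- withr::local_tempdir()
  state <- file.path(dir, "state.json")
  set.seed(88)
  write_sampler(fed_sampler(), state)
  run_once <- function() {
    s <- read_sampler(state)
    res <- reblind(rows, alloc, s)
    p <- file.path(dir, "out.csv")
    write_reblinded(res$reblinded, p)
    readBin(p, "raw", file.size(p))
  }
  expect_identical(run_once(), run_once())
})
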