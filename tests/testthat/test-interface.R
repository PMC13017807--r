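# CSV round trips, run configuration, bundled tables, CLI wiring.

test_that("gas-exchange write/read round trip is lossless", {
  p <- default_params()
  cfg <- synth_config(n_days = 2, points_per_day = 8L, seed = 2)
  gx <- gen_gas_exchange(gen_meteo(cfg), p, 1787.10, noise_sd = 0.05,
                         seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gas_exchange(gx, path)
  back <- read_gas_exchange(path)
  for (cc in c("Q", "Ta", "D", "ca", "P", "A", "E", "gs", "ci"))
    expect_equal(back[[cc]], gx[[cc]], tolerance = 1e-12)
})

test_that("rows with missing required fields are skipped and logged", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("day_id,Q,Ta,D,ca,P,A,E,gs,ci",
               "d1,1000,30,2,400,95,10,2,0.15,290",
               "d1,1000,30,2,400,95,10,2,,290",
               "d2,500,25,1.5,400,95,8,1.5,0.12,300"), path)
  expect_message(df <- read_gas_exchange(path), "skipped 1")
  expect_equal(nrow(df), 2)
  expect_equal(df$day_id, c("d1", "d2"))
})

test_that("missing columns fail hard, naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("day_id,Q,Ta,D,ca,P,A,E,gs", "d1,1,2,3,4,5,6,7,8"), path)
  expect_error(read_gas_exchange(path), "ci")
})

test_that("thousands separators are accepted on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("day_id,Q,Ta,D,ca,P,A,E,gs,ci",
               'd1,"1,000",30,2,400,95,10,2,0.15,"1,787.10"'), path)
  df <- read_gas_exchange(path)
  expect_equal(df$Q, 1000)
  expect_equal(df$ci, 1787.10)
})

test_that("A-ci read groups by curve preserving order; empty file warns", {
  path <- withr::local_tempfile(fileext = ".csv")
  c1 <- gen_aci(default_params(), Tl = 25, curve_id = "a")
  c2 <- gen_aci(default_params(), Tl = 31, curve_id = "b")
  # interleave the two curves row-wise
  rows <- rbind(data.frame(curve_id = "a", ci = c1$ci, A = c1$A, Tl = 25,
                           Q = 1000),
                data.frame(curve_id = "b", ci = c2$ci, A = c2$A, Tl = 31,
                           Q = 1000))
  rows <- rows[order(rep(seq_len(15), 2)), ]
  utils::write.csv(rows, path, row.names = FALSE)
  curves <- read_aci(path)
  expect_length(curves, 2)
  expect_equal(curves[[1]]$ci, c1$ci)
  expect_equal(curves[[2]]$A, c2$A, tolerance = 1e-12)
  # single curve round trip
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_aci(c1, path2)
  one <- read_aci(path2)
  expect_length(one, 1)
  expect_equal(one[[1]]$A, c1$A, tolerance = 1e-12)
  # empty file
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("curve_id,ci,A,Tl,Q", path3)
  expect_warning(expect_length(read_aci(path3), 0), "no data")
})

test_that("run config parses, validates and rejects unknown keys", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"species": {"Vcmax25": 50}, "lambda": {"co": 1500},
              "trim": [5, 95], "seed": 42}', path)
  cfg <- read_run_config(path)
  expect_equal(cfg$params$Vcmax25, 50)
  expect_equal(cfg$params$Jmax25, 75.56)
  expect_equal(unname(cfg$lambda["co"]), 1500)
  expect_equal(unname(cfg$lambda["Vj"]), 2703.65)
  expect_equal(cfg$trim, c(5, 95))
  expect_equal(cfg$seed, 42L)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"speciess": {}}', bad)
  expect_error(read_run_config(bad), "unknown key")
  bad2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"species": {"Vcmax": 1}}', bad2)
  expect_error(read_run_config(bad2), "unknown species key")
})

test_that("bundled citrus tables load with expected shapes and values", {
  days <- citrus_measurement_days()
  expect_equal(nrow(days), 17)
  expect_equal(sum(days$n_obs), 1852)
  lam <- citrus_daily_lambda()
  expect_equal(nrow(lam), 17)
  expect_equal(lam$lambda_co[13], 3135.39)
  expect_true(is.na(lam$lambda_vj[13]))
  aci <- citrus_aci_parameters()
  expect_equal(nrow(aci), 5)
  expect_equal(mean(aci$Vcmax25), 43.21, tolerance = 5e-4)
})

test_that("CLI: usage and unknown subcommand exit 2; simulate works", {
  expect_output(code <- oscm_cli(character(0)), "usage")
  expect_equal(code, 2L)
  expect_output(code2 <- oscm_cli("definitely-not-a-subcommand"),
                "unknown subcommand")
  expect_equal(code2, 2L)

  td <- withr::local_tempdir()
  mcsv <- file.path(td, "m.csv")
  utils::write.csv(data.frame(Q = c(1000, 500), Ta = c(30, 25),
                              D = c(2, 1.5), ca = 400, P = 95),
                   mcsv, row.names = FALSE)
  out <- file.path(td, "pred.csv")
  code3 <- oscm_cli(c("simulate", "--form", "combined", "--lambda",
                      "1787.10", "--meteo", mcsv, "--out", out))
  expect_equal(code3, 0L)
  pred <- utils::read.csv(out)
  expect_true(all(c("ci", "A", "gs", "E", "branch") %in% names(pred)))
  expect_equal(nrow(pred), 2)
  # validation failure -> non-zero exit
  expect_message(code4 <- oscm_cli(c("simulate", "--meteo",
                                     "no-such-file.csv")),
                 "not found")
  expect_gt(code4, 0L)
})

test_that("CLI runs are reproducible byte for byte", {
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a.csv"); f2 <- file.path(td, "b.csv")
  expect_equal(oscm_cli(c("synth", "gasex", "--seed", "5", "--out", f1)),
               0L)
  expect_equal(oscm_cli(c("synth", "gasex", "--seed", "5", "--out", f2)),
               0L)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("CLI lambda pipeline produces table and summary", {
  td <- withr::local_tempdir()
  gx <- file.path(td, "gx.csv")
  p <- default_params()
  cfg <- synth_config(n_days = 2, points_per_day = 20L, seed = 8)
  dat <- gen_gas_exchange(gen_meteo(cfg), p, 1787.10, noise_sd = 0.05,
                          seed = 8)
  write_gas_exchange(dat[!dat$floored, ], gx)
  out <- file.path(td, "lam.csv"); summ <- file.path(td, "summ.csv")
  code <- oscm_cli(c("lambda", "--input", gx, "--trim", "10,90",
                     "--out", out, "--summary", summ))
  expect_equal(code, 0L)
  est <- utils::read.csv(out)
  expect_true(all(c("lam", "limitation", "valid") %in% names(est)))
  s <- utils::read.csv(summ)
  lt <- s[s$scope == "long_term" & s$limitation == "co", ]
  expect_lt(abs(lt$median_lam - 1787.10) / 1787.10, 0.05)
})
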