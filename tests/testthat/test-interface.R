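test_that("scan CSV round trip reproduces the dataset exactly", {
  ds <- generate_dataset(dmph_typing(), example_params(), noise_sd = 0.7,
                         seed = 13)
  f <- withr::local_tempfile(fileext = ".csv")
  tyf <- withr::local_tempfile(fileext = ".csv")
  write_scan_csv(ds, f)
  write_typing_csv(ds$typing, tyf)
  back <- read_scan_csv(f, typing = tyf)
  expect_equal(back$e_target, ds$e_target, tolerance = 1e-9)
  expect_equal(back$angles, ds$angles, tolerance = 1e-12)
  expect_identical(back$conformer_id, ds$conformer_id)
  expect_identical(back$scanned_dihedral, ds$scanned_dihedral)
  expect_equal(back$typing$type_of, ds$typing$type_of)
  expect_equal(back$typing$type_labels, ds$typing$type_labels)
  ## header layout is the documented hybrid format
  header <- readLines(f, n = 1)
  expect_match(header,
               "^conformer_id,scanned_dihedral,scan_angle,e_target,phi_1,")
})

test_that("malformed scan CSVs produce descriptive parse errors", {
  ds <- generate_dataset(dihedral_typing(c(1, 2)), example_params(2),
                         grid_step = 45, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_scan_csv(ds, f)

  lines <- readLines(f)
  no_target <- sub("e_target", "energy", lines[1])
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(no_target, lines[-1]), f2)
  expect_error(read_scan_csv(f2), "e_target")

  f3 <- withr::local_tempfile(fileext = ".csv")
  bad <- lines
  bad[3] <- sub("^([^,]*,[^,]*,[^,]*,)[^,]*", "\\1abc", bad[3])
  writeLines(bad, f3)
  expect_error(read_scan_csv(f3), "non-numeric.*e_target|e_target.*line 2")

  f4 <- withr::local_tempfile(fileext = ".csv")
  dup <- c(lines, lines[2])
  writeLines(dup, f4)
  expect_error(read_scan_csv(f4), "duplicate conformer_id")

  expect_error(read_scan_csv(withr::local_tempfile()), "not found")
})

test_that("typing and coefficient CSVs round trip including offsets", {
  ty <- dmph_typing()
  tf <- withr::local_tempfile(fileext = ".csv")
  write_typing_csv(ty, tf)
  ty2 <- read_typing_csv(tf)
  expect_equal(ty2$type_of, ty$type_of)
  expect_equal(ty2$type_labels, ty$type_labels)

  p <- fourier_params(matrix(c(1.25, -3.5, 0.125, 7, 0, -1, 2, 0.5), 2, 4),
                      offset = -4.75)
  pf <- withr::local_tempfile(fileext = ".csv")
  write_params_csv(p, pf)
  p2 <- read_params_csv(pf)
  expect_equal(p2$k, p$k)
  expect_equal(p2$offset, p$offset)

  rb <- fourier_to_rb(p)
  rf <- withr::local_tempfile(fileext = ".csv")
  write_rb_csv(rb, rf)
  rb2 <- read_rb_csv(rf)
  expect_equal(rb2$C, rb$C)
  expect_equal(rb2$offset, rb$offset)
})

test_that("itp export writes the documented dihedraltypes fragments", {
  ty1 <- dihedral_typing(1, "CT-OS-P-OS")
  zero <- fourier_params(matrix(0, 1, 4))
  f <- withr::local_tempfile(fileext = ".itp")
  write_itp(zero, ty1, f)
  lines <- readLines(f)
  expect_true(any(grepl("\\[ dihedraltypes \\]", lines)))
  dat <- grep("^\\s+CT", lines, value = TRUE)
  expect_length(dat, 1L)
  fields <- strsplit(trimws(dat), "\\s+")[[1]]
  expect_identical(fields[1:5], c("CT", "OS", "P", "OS", "3"))
  expect_identical(fields[6:11], rep("0.000000", 6))

  ## k = (1,0,0,0) converts to C = (1,-1,0,0,0,0)
  p1 <- fourier_params(matrix(c(1, 0, 0, 0), 1, 4))
  write_itp(p1, ty1, f)
  dat <- grep("^\\s+CT", readLines(f), value = TRUE)
  expect_match(dat,
    "1\\.000000\\s+-1\\.000000\\s+0\\.000000\\s+0\\.000000\\s+0\\.000000\\s+0\\.000000")

  ## fourier_func5 round trip: re-parsed coefficients identical
  p <- fourier_params(matrix(c(1.5, -2.25, 0.125, 3, 0.5, 1, -1, 0), 2, 4),
                      offset = 1.5)
  ty2 <- dihedral_typing(c(1, 2), c("CT-OS-P-OS", "HC-CT-OS-P"))
  write_itp(p, ty2, f, style = "fourier_func5")
  back <- read_itp_fourier(f)
  expect_equal(back$params$k, p$k)
  expect_equal(back$params$offset, p$offset)
  expect_identical(back$labels, ty2$type_labels)

  ## byte-identical re-export
  f2 <- withr::local_tempfile(fileext = ".itp")
  write_itp(p, ty2, f2, style = "fourier_func5")
  write_itp(p, ty2, f, style = "fourier_func5")
  expect_identical(readLines(f), readLines(f2))

  expect_error(write_itp(p, dihedral_typing(c(1, 2)), f), "type_labels")
  expect_error(write_itp(p, dihedral_typing(c(1, 2), c("A-B", "C-D")), f),
               "quadruple")
})

test_that("the model object methods give a coherent account of the fit", {
  ds <- dmph_dataset(noise_sd = 0.5, seed = 6)
  fit <- torsion_fit(ds)
  expect_s3_class(fit, "torsion_fit")
  expect_equal(dim(coef(fit)), c(6L, 4L))
  expect_equal(rownames(coef(fit))[4], "HC-CT-OS-P")
  expect_equal(fitted(fit), predict(fit, ds))
  expect_equal(length(residuals(fit)), 540L)
  expect_equal(stats::sd(residuals(fit)), 0.5, tolerance = 0.15)
  out <- capture.output(print(fit))
  expect_true(any(grepl("exact global least squares", out)))
  sm <- summary(fit)
  out2 <- capture.output(print(sm))
  expect_true(any(grepl("Ryckaert-Bellemans", out2)))
  expect_true(any(grepl("average RMSD", out2)))
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2L)
  expect_equal(length(sims[[1]]), 540L)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, which = 1:2))
})

test_that("the command-line interface runs end to end and validates flags", {
  dir <- withr::local_tempdir()
  scans <- file.path(dir, "scans.csv")
  tyf <- file.path(dir, "typing.csv")
  report <- file.path(dir, "report.csv")
  itp <- file.path(dir, "fit.itp")
  pout <- file.path(dir, "params.csv")

  expect_equal(suppressMessages(torsionfit_cli(
    c("simulate", "--out", scans, "--typing-out", tyf,
      "--noise-sd", "0.5", "--seed", "4"))), 0L)
  expect_true(file.exists(scans) && file.exists(tyf))

  expect_equal(suppressMessages(torsionfit_cli(
    c("fit", "--scans", scans, "--typing", tyf, "--report", report,
      "--out-itp", itp, "--params-out", pout))), 0L)
  expect_true(file.exists(report) && file.exists(itp) && file.exists(pout))
  rep_lines <- readLines(report)
  expect_match(rep_lines[1], "scanned_dihedral,type_label")
  expect_match(rep_lines[length(rep_lines)], "^average")

  ## the reported average RMSD is close to the simulated noise level
  avg <- as.numeric(sub("average,,,", "", rep_lines[length(rep_lines)]))
  expect_gt(avg, 0.25)
  expect_lt(avg, 0.75)

  ## conversion round trip through the CLI
  rbout <- file.path(dir, "rb.csv")
  pback <- file.path(dir, "back.csv")
  expect_equal(suppressMessages(torsionfit_cli(
    c("convert", "--params", pout, "--out", rbout))), 0L)
  expect_equal(suppressMessages(torsionfit_cli(
    c("convert", "--params", rbout, "--out", pback,
      "--direction", "rb2fourier"))), 0L)
  expect_equal(read_params_csv(pback)$k, read_params_csv(pout)$k,
               tolerance = 1e-12)

  ## usage errors: nonzero status, no R-level error
  expect_equal(suppressMessages(torsionfit_cli(
    c("fit", "--scans", scans, "--method", "local", "--bound", "-5"))), 2L)
  msg <- capture_messages(status <- torsionfit_cli(
    c("fit", "--scans", scans, "--terms", "5")))
  expect_equal(status, 2L)
  expect_match(paste(msg, collapse = " "), "\\{3, 4\\}")
  expect_equal(suppressMessages(torsionfit_cli(
    c("fit", "--scans", scans, "--method", "global", "--bound", "10"))), 2L)
  expect_equal(suppressMessages(torsionfit_cli(
    c("unknown-cmd"))), 2L)
  expect_equal(suppressMessages(torsionfit_cli(character())), 2L)

  ## YAML config supplies defaults; explicit flags still win
  cfg <- file.path(dir, "cfg.yaml")
  writeLines(c("noise-sd: 0.25", "seed: 9"), cfg)
  scans2 <- file.path(dir, "scans2.csv")
  expect_equal(suppressMessages(torsionfit_cli(
    c("simulate", "--out", scans2, "--config", cfg))), 0L)
  ds2 <- read_scan_csv(scans2)
  ds_ref <- generate_dataset(dmph_typing(), example_params(),
                             noise_sd = 0.25, seed = 9)
  expect_equal(ds2$e_target, ds_ref$e_target, tolerance = 1e-9)
})
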