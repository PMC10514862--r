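test_that("NIfTI write -> read round trips values and affine", {
  ph <- generate_phantom(phantom_spec(shape = c(12, 10, 8), spacing = c(1, 1.5, 2), seed = 2))
  t1 <- ph$maps$maps$T1
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(t1, f)
  back <- read_map(f, "T1")
  # noiseless phantom values (0 and integer-valued tissue T1s) are exactly
  # representable in the 32-bit float storage
  expect_identical(back$values, t1$values)
  expect_equal(back$grid$affine, t1$grid$affine)
  expect_equal(back$grid$spacing, t1$grid$spacing)

  # float32 storage bounds the error for arbitrary values
  vol <- small_volume("SE")
  f2 <- withr::local_tempfile(fileext = ".nii")
  write_nifti(vol, f2)
  back2 <- read_map(f2, "S", units = "arbitrary")
  expect_lt(rel_err(back2$values, vol$values), 2^-23)
})

test_that("all-zero volumes round trip to all-zero", {
  vol <- synth_volume(array(0, c(4, 4, 2)), ms_grid(c(4, 4, 2)))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(vol, f)
  expect_identical(read_map(f, "S", units = "arbitrary")$values, array(0, c(4, 4, 2)))
})

test_that("4D NIfTI inputs are rejected with a clear message", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 2, 3))), f)
  expect_error(read_map(f, "T1"), "4D")
})

test_that("DICOM export writes one instance per slice and fresh UIDs", {
  vol <- small_volume("SE", shape = c(16, 16, 12))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  expect_identical(write_dicom(vol, out_dir = d1, subject = "a"), 12L)
  expect_length(list.files(d1, pattern = "\\.dcm$"), 12)
  write_dicom(vol, out_dir = d2, subject = "a")
  s1 <- parse_dicom_file(list.files(d1, full.names = TRUE)[1])
  s2 <- parse_dicom_file(list.files(d2, full.names = TRUE)[1])
  expect_false(identical(dcm_string(s1[["0020,000E"]]), dcm_string(s2[["0020,000E"]])))
  expect_false(identical(dcm_string(s1[["0008,0018"]]), dcm_string(s2[["0008,0018"]])))
})

test_that("DICOM round trip is quantization-bounded and preserves geometry", {
  grid <- ms_grid(c(10, 12, 6), spacing = c(0.9, 1.1, 2.4))
  set.seed(31)
  ph <- generate_phantom(phantom_spec(shape = c(10, 12, 6), spacing = c(0.9, 1.1, 2.4),
                                      noise_sd = c(T1 = 25, T2 = 5, PD = 0.02), seed = 31))
  vol <- evaluate_model(builtin_presets()$DIR, ph$maps)
  d <- withr::local_tempdir()
  write_dicom(vol, out_dir = d, subject = "q")
  back <- read_dicom_series(d)
  slope <- max(abs(vol$values)) / 32767
  expect_lte(max(abs(back$values - vol$values)), slope / 2 * (1 + 1e-9))
  expect_equal(back$grid$affine, vol$grid$affine, tolerance = 1e-6)
  expect_equal(back$grid$spacing, vol$grid$spacing, tolerance = 1e-6)
})

test_that("acquisition tags follow the provenance for every preset", {
  ph <- generate_phantom(phantom_spec(shape = c(8, 8, 4), seed = 6))
  tpl <- dicom_template()
  for (m in builtin_presets()) {
    vol <- evaluate_model(m, ph$maps)
    d <- withr::local_tempdir()
    write_dicom(vol, tpl, export_settings("dicom"), d, subject = "t")
    meta <- read_dicom_series(d)$meta
    expect_identical(meta$series_description, m$name)
    p <- unclass(vol$provenance$params)
    tag_expect <- function(tag, sym) {
      if (sym %in% names(p)) expect_equal(as.numeric(tag), p[[sym]], label = paste(m$name, sym))
      else expect_identical(tag, "", label = paste(m$name, sym))
    }
    tag_expect(meta$repetition_time, "TR")
    tag_expect(meta$echo_time, "TE")
    # TI falls back to TI1 for the double-inversion model
    if ("TI" %in% names(p)) {
      expect_equal(as.numeric(meta$inversion_time), p[["TI"]])
    } else if ("TI1" %in% names(p)) {
      expect_equal(as.numeric(meta$inversion_time), p[["TI1"]])
    } else {
      expect_identical(meta$inversion_time, "")
    }
    # the full parameter set is recoverable from the comments JSON
    com <- jsonlite::fromJSON(meta$comments)
    expect_identical(com$model, m$name)
    for (sym in names(p)) expect_equal(com[[sym]], p[[sym]], label = paste(m$name, sym))
  }
})

test_that("mixed series in one directory are rejected", {
  vol <- small_volume("GRE", shape = c(8, 8, 2))
  d <- withr::local_tempdir()
  write_dicom(vol, out_dir = d, subject = "s1")
  write_dicom(vol, out_dir = d, subject = "s2",
              settings = export_settings("dicom", pattern = "x_{slice}.dcm"))
  expect_error(read_dicom_series(d), "2 DICOM series")
})

test_that("format detection is content-based", {
  vol <- small_volume("GRE", shape = c(6, 6, 2))
  fn <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(vol, fn)
  expect_identical(detect_format(fn), "NIFTI")
  # NIfTI magic survives a misleading extension
  fn2 <- withr::local_tempfile(fileext = ".dat")
  file.copy(fn, fn2)
  expect_identical(detect_format(fn2), "NIFTI")
  d <- withr::local_tempdir()
  write_dicom(vol, out_dir = d, subject = "s")
  expect_identical(detect_format(d), "DICOM")
  expect_identical(detect_format(file.path(d, list.files(d)[1])), "DICOM")
  empty <- withr::local_tempfile()
  file.create(empty)
  expect_identical(detect_format(empty), "UNKNOWN")
  txt <- withr::local_tempfile(fileext = ".nii")
  writeLines("not an image at all, just text padding to some length", txt)
  expect_identical(detect_format(txt), "UNKNOWN")
})

test_that("template validation catches missing mutable slots", {
  vol <- small_volume("GRE", shape = c(4, 4, 2))
  tpl <- dicom_template()
  tpl$WindowCenter <- NULL
  expect_error(write_dicom(vol, tpl, out_dir = withr::local_tempdir()), "WindowCenter")
  vol$values[1] <- NaN
  expect_error(write_dicom(vol, out_dir = withr::local_tempdir()), "non-finite")
})
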