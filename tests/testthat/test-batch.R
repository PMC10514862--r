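make_subject_tree <- function(root, n, shape = c(12, 12, 6), drop = list()) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    id <- sprintf("sub%02d", i)
    spec <- phantom_spec(shape = shape, seed = i)
    write_phantom(generate_phantom(spec), spec, file.path(root, id))
    for (sym in drop[[id]]) unlink(file.path(root, id, paste0(sym, ".nii.gz")))
  }
  root
}

test_that("subject discovery finds complete map sets and flags gaps", {
  root <- make_subject_tree(withr::local_tempdir(), 3,
                            drop = list(sub02 = "T2"))
  subs <- discover_subjects(root)
  expect_identical(subs$id, c("sub01", "sub02", "sub03"))
  expect_identical(subs$status, c("ok", "missing_maps", "ok"))
  expect_match(subs$detail[2], "T2")
  expect_setequal(names(subs$paths[[1]]), c("T1", "T2", "PD"))

  # ambiguity: two files match the T1 pattern
  file.create(file.path(root, "sub01", "extra_T1_copy.nii.gz"))
  subs2 <- discover_subjects(root)
  expect_identical(subs2$status[1], "io_error")
  expect_match(subs2$detail[1], "ambiguous")

  # the default pattern is symbol-bounded: T1 does not match TI or T12
  d <- withr::local_tempdir()
  dir.create(file.path(d, "s1"))
  file.create(file.path(d, "s1", "TI_map.nii.gz"),
              file.path(d, "s1", "T12.nii.gz"))
  subs3 <- discover_subjects(d, required_maps = "T1")
  expect_identical(subs3$status, "missing_maps")

  expect_identical(nrow(discover_subjects(withr::local_tempdir())), 0L)
})

test_that("batch synthesization writes one volume per ok subject and model", {
  root <- make_subject_tree(withr::local_tempdir(), 2)
  out <- withr::local_tempdir()
  models <- builtin_presets()[c("GRE", "SE", "FLAIR")]
  rep <- batch_synthesize(discover_subjects(root), models, out_dir = out, quiet = TRUE)
  expect_identical(rep$totals$subjects, 2L)
  expect_equal(rep$totals$volumes_written, 6)
  expect_equal(rep$totals$failures, 0)
  expect_true(all(file.exists(file.path(out, "sub01", c("GRE", "SE", "FLAIR"),
                                        paste0("sub01_", c("GRE", "SE", "FLAIR"), ".nii.gz")))))
  expect_true(file.exists(file.path(out, "batch_report.json")))
  # tidy/glance accessors
  expect_identical(nrow(generics::tidy(rep)), 6L)
  expect_identical(generics::glance(rep)$volumes_written, 6L)
})

test_that("a subject with missing maps is skipped, not fatal", {
  root <- make_subject_tree(withr::local_tempdir(), 2, drop = list(sub02 = "PD"))
  out <- withr::local_tempdir()
  rep <- batch_synthesize(discover_subjects(root), builtin_presets()["GRE"],
                          out_dir = out, quiet = TRUE)
  expect_equal(rep$totals$volumes_written, 1)
  expect_equal(rep$totals$skips, 1)
  items <- generics::tidy(rep)
  expect_identical(items$outcome[items$subject == "sub02"], "skipped")
})

test_that("count conservation: written + skips + failures = subjects x models", {
  root <- make_subject_tree(withr::local_tempdir(), 3, drop = list(sub03 = "T2"))
  out <- withr::local_tempdir()
  models <- builtin_presets()[c("SE", "DIR")]
  rep <- batch_synthesize(discover_subjects(root), models, out_dir = out, quiet = TRUE)
  t <- rep$totals
  expect_identical(t$volumes_written + t$skips + t$failures,
                   t$subjects * t$models)
})

test_that("batch runs are deterministic: identical reports, bit-identical NIfTI", {
  root <- make_subject_tree(withr::local_tempdir(), 2)
  subs <- discover_subjects(root)
  models <- builtin_presets()[c("GRE", "MP2RAGE")]
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  rep1 <- batch_synthesize(subs, models, out_dir = out1, quiet = TRUE)
  rep2 <- batch_synthesize(subs, models, out_dir = out2, quiet = TRUE)
  expect_identical(rep1$totals, rep2$totals)
  expect_identical(generics::tidy(rep1)[c("subject", "model", "outcome")],
                   generics::tidy(rep2)[c("subject", "model", "outcome")])
  rel1 <- list.files(out1, recursive = TRUE, pattern = "\\.nii\\.gz$")
  rel2 <- list.files(out2, recursive = TRUE, pattern = "\\.nii\\.gz$")
  expect_identical(rel1, rel2)
  for (f in rel1) {
    b1 <- readBin(file.path(out1, f), "raw", n = file.size(file.path(out1, f)))
    b2 <- readBin(file.path(out2, f), "raw", n = file.size(file.path(out2, f)))
    expect_identical(b1, b2, label = f)
  }
})

test_that("per-model parameter overrides reach the export provenance", {
  root <- make_subject_tree(withr::local_tempdir(), 1)
  out <- withr::local_tempdir()
  rep <- batch_synthesize(discover_subjects(root), builtin_presets()["FLAIR"],
                          params = list(FLAIR = scanner_parameters(TI = 1900)),
                          settings = export_settings("dicom"),
                          out_dir = out, quiet = TRUE)
  expect_equal(rep$totals$volumes_written, 1)
  meta <- read_dicom_series(file.path(out, "sub01", "FLAIR"))$meta
  expect_identical(meta$inversion_time, "1900")
  expect_identical(meta$series_description, "FLAIR")
})

test_that("the CLI subcommands cover synthesize, batch, validate and phantom", {
  pdir <- withr::local_tempdir()
  expect_identical(run_cli(c("phantom", "-o", pdir, "--seed", "5", "--shape", "12,12,6")), 0L)
  expect_true(file.exists(file.path(pdir, "T1.nii.gz")))

  sdir <- withr::local_tempdir()
  code <- run_cli(c("synthesize", "--t1", file.path(pdir, "T1.nii.gz"),
                    "--t2", file.path(pdir, "T2.nii.gz"),
                    "--pd", file.path(pdir, "PD.nii.gz"),
                    "--model", "FLAIR", "--set", "TI=2000", "--set", "TE=90",
                    "--format", "nifti", "-o", sdir))
  expect_identical(code, 0L)
  expect_true(file.exists(file.path(sdir, "synth_FLAIR.nii.gz")))

  root <- withr::local_tempdir()
  dir.create(file.path(root, "s1"))
  for (f in c("T1", "T2", "PD")) {
    file.copy(file.path(pdir, paste0(f, ".nii.gz")), file.path(root, "s1"))
  }
  bdir <- withr::local_tempdir()
  code <- suppressMessages(run_cli(c("batch", "--root", root,
                                     "--config", default_config_path(),
                                     "--preset", "3T", "--models", "GRE,SE",
                                     "--format", "nifti", "-o", bdir,
                                     "--log-level", "quiet")))
  expect_identical(code, 0L)
  expect_true(file.exists(file.path(bdir, "s1", "SE", "s1_SE.nii.gz")))

  expect_identical(run_cli(c("validate-config", default_config_path())), 0L)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"accepted_maps": {}, "presets": {}}', bad)
  expect_identical(run_cli(c("validate-config", bad)), 1L)
  expect_identical(run_cli(c("frobnicate")), 1L)
})
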