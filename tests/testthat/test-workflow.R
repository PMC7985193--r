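# cli_workflow: manifest-driven batch processing and report regeneration.

study <- NULL

test_that("a phantom study runs end to end and aggregates the report", {
  root <- file.path(tempdir(), "lvecho-study")
  study <<- build_study_fixture(root)
  out <- file.path(root, "run1")
  res <- run_study(study$manifest, out)
  expect_false(res$partial)
  expect_length(res$failures, 0)
  expect_equal(nrow(res$report), 4)  # 2 subjects x (B-mode + M-mode) rows
  expect_true(file.exists(file.path(out, "s1", "bmode_ED_mask.png")))
  expect_true(file.exists(file.path(out, "s1", "bmode_ES_mask.png")))
  expect_true(file.exists(file.path(out, "s2", "mmode_traces.csv")))
  expect_true(file.exists(file.path(out, "run_log.json")))
  # B-mode EF should be physiologic for a 30% diameter-contraction phantom
  bm <- res$report[res$report$mode == "B-mode", ]
  expect_true(all(bm$EF_pct > 30 & bm$EF_pct < 90))
})

test_that("a corrupt subject is isolated; the rest still succeed", {
  root <- study$root
  manifest <- jsonlite::read_json(study$manifest, simplifyVector = FALSE)
  bad <- manifest$subjects[[1]]
  bad$id <- "s_bad"
  bad$bmode_path <- file.path(root, "nonexistent.tif")
  manifest$subjects <- c(manifest$subjects, list(bad))
  mpath <- file.path(root, "study_bad.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  out <- file.path(root, "run_bad")
  res <- run_study(mpath, out)
  expect_true(res$partial)
  expect_named(res$failures, "s_bad")
  expect_equal(nrow(res$report), 4)
})

test_that("rerunning an identical study reproduces the report byte for byte", {
  out2 <- file.path(study$root, "run2")
  run_study(study$manifest, out2)
  f1 <- file.path(study$root, "run1", "report.csv")
  f2 <- file.path(out2, "report.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("report regeneration reflects stored edits and flags missing files", {
  out <- file.path(study$root, "run1")
  before <- utils::read.csv(file.path(out, "report.csv"))
  reg <- regenerate_reports(out)
  after <- reg$report
  # no edits: measures unchanged
  expect_equal(after$EF_pct, before$EF_pct, tolerance = 1e-9)
  # edit one wall trace: only that subject's M-mode row may change
  tr_path <- file.path(out, "s1", "mmode_traces.csv")
  tr <- utils::read.csv(tr_path)
  tr$POST_ENDO <- tr$POST_ENDO + 0.08  # dilate the cavity slightly
  tr$POST_EPI <- tr$POST_EPI + 0.08
  utils::write.csv(tr, tr_path, row.names = FALSE)
  reg2 <- regenerate_reports(out)
  r2 <- reg2$report
  key <- paste(r2$subject_id, r2$mode)
  keyb <- paste(before$subject_id, before$mode)
  changed <- r2$LVID_d_mm[key == "s1 M-mode"] - before$LVID_d_mm[keyb == "s1 M-mode"]
  expect_equal(changed, 0.08, tolerance = 1e-6)
  expect_equal(r2$EF_pct[key == "s2 M-mode"], before$EF_pct[keyb == "s2 M-mode"],
               tolerance = 1e-9)
  expect_equal(r2$EF_pct[key == "s1 B-mode"], before$EF_pct[keyb == "s1 B-mode"],
               tolerance = 1e-9)
  # deleting a subject's segmentations flags it as missing
  unlink(file.path(out, "s2", c("bmode_ED_contour.json", "bmode_ES_contour.json",
                                "mmode_traces.csv", "mmode_marks.json")))
  reg3 <- regenerate_reports(out)
  expect_true("s2" %in% reg3$missing)
})
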