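test_that("vocabulary enforces exactly 22 unique labels", {
  expect_length(quality_vocabulary(), 22L)
  expect_error(quality_vocabulary(letters[1:21]), "exactly 22")
  expect_error(quality_vocabulary(c(default_qualities()[1:21], "bitter")),
               "duplicate")
})

test_that("drug table loads, parses genus, and rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug_id,taxon_name,plant_part",
               "d001,Cinnamomum verum,bark",
               "d002,Anemone coronaria,root"), path)
  d <- load_drug_table(path)
  expect_s3_class(d, "drug_table")
  expect_equal(d$genus, c("Cinnamomum", "Anemone"))

  writeLines(c("drug_id,taxon_name,plant_part",
               "d001,Cinnamomum verum,bark",
               "d001,Anemone coronaria,root"), path)
  expect_error(load_drug_table(path), "duplicate drug_id")

  writeLines(c("drug_id,taxon_name", "d001,Cinnamomum verum"), path)
  expect_error(load_drug_table(path), "plant_part")
})

test_that("wide trial layout fills unscored qualities with zero", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial_id,drug_id,panellist_id,days,bitter,sweet",
               "t1,d1,p1,10,2,1",
               "t2,d1,p2,10,,"), path)
  tr <- load_trials(path)
  sm <- as.matrix(tr[, unclass(vocab22)])
  expect_equal(sum(sm[1, ] > 0), 2L)
  expect_equal(sum(sm[1, ]), 3L)
  expect_equal(sum(sm[2, ]), 0L)
})

test_that("trial scores outside the ordinal scale are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial_id,drug_id,panellist_id,days,bitter",
               "t1,d1,p1,10,4"), path)
  expect_error(load_trials(path), "range error")
  writeLines(c("trial_id,drug_id,panellist_id,days,umami",
               "t1,d1,p1,10,2"), path)
  expect_error(load_trials(path), "vocabulary error")
})

test_that("long trial layout agrees with the wide layout", {
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial_id,drug_id,panellist_id,days,bitter,woody",
               "t1,d1,p1,3,2,1", "t2,d2,p2,5,0,3"), wide)
  writeLines(c("trial_id,drug_id,panellist_id,days,quality,score",
               "t1,d1,p1,3,bitter,2", "t1,d1,p1,3,woody,1",
               "t2,d2,p2,5,woody,3"), long)
  expect_equal(load_trials(wide), load_trials(long, layout = "long"),
               ignore_attr = "row.names")
})

test_that("use matrix requires binary cells and a total category map", {
  mpath <- withr::local_tempfile(fileext = ".csv")
  cpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug_id,u1,u2", "d1,1,0", "d2,0,2"), mpath)
  writeLines(c("use_id,category_id", "u1,catA", "u2,catB"), cpath)
  expect_error(load_use_matrix(mpath, cpath), "range error")
  writeLines(c("drug_id,u1,u2", "d1,1,0", "d2,0,1"), mpath)
  writeLines(c("use_id,category_id", "u1,catA"), cpath)
  expect_error(load_use_matrix(mpath, cpath), "mapping error")
  writeLines(c("use_id,category_id", "u1,catA", "u2,catB"), cpath)
  um <- load_use_matrix(mpath, cpath)
  expect_s3_class(um, "use_matrix")
  expect_equal(unname(um$category_map), c("catA", "catB"))
})

test_that("validation cross-references tables and counts perception reports", {
  ds <- tiny_dataset()
  rep <- validate_dataset(ds$drugs, ds$trials, ds$uses)
  expect_true(is_loadable(rep))
  expect_equal(rep$counts$trials, 4L)
  expect_equal(rep$counts$perception_reports, 6L)
  expect_equal(rep$counts$perception_reports,
               sum(trial_complexity(ds$trials)))

  bad <- ds$trials
  bad$drug_id[1] <- "ghost"
  rep2 <- validate_dataset(ds$drugs, bad, ds$uses)
  expect_false(is_loadable(rep2))
  expect_match(rep2$errors$message[1], "unknown drug")

  rep3 <- validate_dataset(ds$drugs, ds$trials[0, ], ds$uses)
  expect_equal(rep3$counts$trials, 0L)
  expect_true(any(rep3$errors$severity == "warning"))
})

test_that("write then read round-trips a dataset field by field", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds$drugs, ds$trials, ds$uses, dir)
  drugs2 <- load_drug_table(file.path(dir, "drugs.csv"))
  trials2 <- load_trials(file.path(dir, "trials.csv"))
  uses2 <- load_use_matrix(file.path(dir, "uses.csv"),
                           file.path(dir, "use_categories.csv"))
  expect_equal(as.data.frame(drugs2), as.data.frame(ds$drugs))
  expect_equal(as.data.frame(trials2), as.data.frame(ds$trials))
  expect_equal(uses2$matrix, ds$uses$matrix)
  expect_equal(uses2$category_map, ds$uses$category_map)
})
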