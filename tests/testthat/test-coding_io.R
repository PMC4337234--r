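test_that("read_codings parses a valid file and preserves rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- rbind(coding_row("p1", 1, "A"), coding_row("p1", 1, "B"))
  write_codings(df, path)
  got <- read_codings(path)
  expect_equal(nrow(got), 2)
  expect_true(all(got[change_variables()] == 0))
  expect_identical(got$coder_id, c("A", "B"))
})

test_that("read_codings rejects malformed files with named errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- rbind(coding_row("p1", 1, "A"))

  write_codings(df, path)
  txt <- readLines(path)
  # drop the neg_somatic column
  keep <- setdiff(seq_along(strsplit(txt[1], ",")[[1]]),
    which(strsplit(txt[1], ",")[[1]] == "neg_somatic"))
  writeLines(sapply(txt, function(l) {
    paste(strsplit(l, ",")[[1]][keep], collapse = ",")
  }), path)
  expect_error(read_codings(path), "neg_somatic")

  df_bad <- df
  df_bad$pos_hope <- 4
  write_codings(df_bad, path)
  expect_error(read_codings(path), "pos_hope")

  writeLines(c(
    paste(c("patient_id", "session_number", "coder_id", change_variables()),
      collapse = ","),
    paste(c("p1", "1", "A", "x", rep("0", 12)), collapse = ",")
  ), path)
  expect_error(read_codings(path), "pos_view_self")
})

test_that("codings round-trip through write and read unchanged", {
  co <- generate_cohort(synthetic_config(seed = 3, n_patients = 27))
  path <- withr::local_tempfile(fileext = ".csv")
  write_codings(co$codings, path)
  back <- read_codings(path)
  expect_equal(back, co$codings)
  expect_length(unique(back$patient_id), 27)
  per_session <- table(paste(back$patient_id, back$session_number))
  expect_true(all(per_session == 2)) # two coders everywhere
})

test_that("outcome tables round-trip and are validated", {
  co <- generate_cohort(synthetic_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_outcomes(co$outcomes, path)
  expect_equal(read_outcomes(path), co$outcomes)

  bad <- co$outcomes
  bad$scid_pre[1] <- -2
  write_outcomes(bad, path)
  expect_error(read_outcomes(path), "non-negative")
})

test_that("average_coders takes per-variable means and keeps n_coders", {
  df <- rbind(
    coding_row("p1", 1, "A", fill = 0, neg_emotion = 3),
    coding_row("p1", 1, "B", fill = 0, neg_emotion = 2)
  )
  avg <- average_coders(df)
  expect_equal(nrow(avg), 1)
  expect_equal(avg$neg_emotion, 2.5)
  expect_equal(avg$n_coders, 2L)

  # opposite extremes average to the midpoint everywhere
  df2 <- rbind(coding_row(fill = 0), coding_row(coder = "B", fill = 3))
  expect_true(all(average_coders(df2)[change_variables()] == 1.5))

  # identical coders reproduce either input
  df3 <- rbind(coding_row(fill = 2), coding_row(coder = "B", fill = 2))
  expect_true(all(average_coders(df3)[change_variables()] == 2))
})

test_that("average_coders is coder-order invariant and single-coder stable", {
  df <- rbind(
    coding_row("p1", 1, "A", fill = 1, pos_hope = 3),
    coding_row("p1", 1, "B", fill = 2, pos_hope = 0)
  )
  expect_equal(average_coders(df), average_coders(df[2:1, ]))

  solo <- coding_row("p2", 3, "A", fill = 1)
  avg <- average_coders(solo)
  expect_equal(avg$n_coders, 1L)
  expect_true(all(avg[change_variables()] == 1))

  dup <- rbind(coding_row(), coding_row())
  expect_error(average_coders(dup), "duplicate")
})

test_that("missing ratings propagate as NA, never as zero", {
  df <- rbind(
    coding_row("p1", 1, "A", fill = 2, neg_somatic = NA),
    coding_row("p1", 1, "B", fill = 2, neg_somatic = NA)
  )
  avg <- average_coders(df)
  expect_true(is.na(avg$neg_somatic))
  nd <- node_scores(avg, "negative")
  expect_true(is.na(nd$somatic))
  expect_true(is.na(pattern_strength(nd)))
})

test_that("validate_dataset reports coverage and range violations", {
  co <- generate_cohort(synthetic_config(seed = 5))
  rep <- validate_dataset(co$codings, co$outcomes)
  expect_s3_class(rep, "change_validation")
  expect_true(rep$ok)
  expect_equal(nrow(rep$violations), 0)

  # strip every phase-2 session (keep baseline, phase 1, and post)
  cd <- co$codings
  post <- 34
  drop <- cd$session_number > 10 & cd$session_number != post
  rep2 <- validate_dataset(cd[!drop, ], co$outcomes)
  expect_false(rep2$ok)
  expect_true("insufficient_phase_coverage" %in% rep2$violations$check)

  cd2 <- co$codings
  cd2$neg_hope[5] <- 4L
  rep3 <- validate_dataset(cd2, co$outcomes)
  expect_true("out_of_range" %in% rep3$violations$check)
  # validation never mutates its input
  expect_equal(cd2$neg_hope[5], 4L)
})

test_that("trajectory export writes GridWare-style files that round-trip", {
  pts <- data.frame(
    patient_id = "p1", phase = "phase2",
    x = c(0, 1, 2), y = c(4, 3, 2), stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  export_trajectories(pts, path)
  lines <- readLines(path)
  expect_length(lines, 4) # header + 3 ordered data lines
  expect_match(lines[1], "Onset")
  back <- read_trajectories(path)
  expect_equal(back[c("x", "y")], pts[c("x", "y")])
  expect_equal(back$onset, 1:3)

  expect_error(export_trajectories(transform(pts, x = c(0, 1, 5)), path),
    "0..4")
  expect_warning(export_trajectories(pts[0, ], path), "header only")
  expect_length(readLines(path), 1)
})
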