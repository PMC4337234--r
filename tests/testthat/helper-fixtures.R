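# hand-buildable fixtures for the coding pipeline

# one coding row with every rating set to `fill`, overridable by name
coding_row <- function(patient = "p1", session = 1, coder = "A", fill = 0, ...) {
  row <- as.list(setNames(rep(fill, 13), change_variables()))
  over <- list(...)
  row[names(over)] <- over
  cbind(
    data.frame(patient_id = patient, session_number = session,
      coder_id = coder, stringsAsFactors = FALSE),
    as.data.frame(row)
  )
}

# full two-coder dataset for one patient covering both phases; all ratings
# `fill` unless per-session overrides are given as a named list
patient_codings <- function(patient = "p1",
                            sessions = c(1, 3, 5, 7, 14, 18, 22, 34),
                            coders = c("A", "B"), fill = 0) {
  do.call(rbind, lapply(sessions, function(s) {
    do.call(rbind, lapply(coders, function(cd) {
      coding_row(patient, s, cd, fill = fill)
    }))
  }))
}

small_outcomes <- function(patients, pre = 10, post = 5) {
  data.frame(
    patient_id = patients, scid_pre = pre, scid_post = post,
    assessment_session = 34, stringsAsFactors = FALSE
  )
}
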