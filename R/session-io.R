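#' Trial-log CSV input / output
#'
#' One documented dialect: columns `subject_id, group, session, trial, c1,
#' side1, transition, state, c2, side2, reward, rt1, rt2`, UTF-8, header
#' mandatory, missing responses encoded as empty fields. `write_session_csv`
#' followed by `read_session_csv` is the identity on valid data, including
#' missing markers.
#'
#' @param sessions a list of `twostep_session` objects.
#' @param path file path.
#' @return `read_session_csv` returns a list of `twostep_session`;
#'   `write_session_csv` returns `path` invisibly.
#' @rdname session_io
#' @export
write_session_csv <- function(sessions, path) {
  if (inherits(sessions, "twostep_session")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    cbind(data.frame(subject_id = s$subject_id, group = s$group,
                     session = s$session, stringsAsFactors = FALSE),
          trial = s$trials$t,
          s$trials[, c("c1", "side1", "transition", "state", "c2", "side2",
                       "reward", "rt1", "rt2")])
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(subject_id = character(), group = character(),
                     session = character(), trial = integer(),
                     stringsAsFactors = FALSE),
          empty_trials(0)[, c("c1", "side1", "transition", "state", "c2",
                              "side2", "reward", "rt1", "rt2")])
  write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname session_io
#' @export
read_session_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 colClasses = c(subject_id = "character"))
  needed <- c("subject_id", "group", "session", "trial", "c1", "side1",
              "transition", "state", "c2", "side2", "reward", "rt1", "rt2")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stopf("trial log %s lacks column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(list())
  for (col in c("side1", "side2", "transition")) {
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  check_codes(df, "c1", c(0L, 1L), path)
  check_codes(df, "c2", c(0L, 1L), path)
  check_codes(df, "state", c(0L, 1L), path)
  check_codes(df, "reward", c(0L, 1L), path)
  check_codes(df, "transition", c("common", "rare"), path)
  check_codes(df, "side1", c("left", "right"), path)
  check_codes(df, "side2", c("left", "right"), path)

  key <- paste(df$subject_id, df$session, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, unique(key))), function(i) {
    block <- df[i, ]
    if (!identical(as.integer(block$trial), seq_len(nrow(block)))) {
      stopf("non-monotone trial indices for subject %s session %s in %s",
            block$subject_id[1], block$session[1], path)
    }
    tr <- empty_trials(nrow(block))
    for (col in c("c1", "state", "c2", "reward")) tr[[col]] <- as.integer(block[[col]])
    for (col in c("side1", "side2", "transition")) tr[[col]] <- as.character(block[[col]])
    tr$rt1 <- as.numeric(block$rt1); tr$rt2 <- as.numeric(block$rt2)
    twostep_session(block$subject_id[1], block$group[1], block$session[1], tr)
  })
  names(out) <- NULL
  out
}

check_codes <- function(df, col, allowed, path) {
  bad <- !is.na(df[[col]]) & !(df[[col]] %in% allowed)
  if (any(bad)) {
    stopf("unknown %s code '%s' at row %d of %s", col,
          df[[col]][which(bad)[1]], which(bad)[1], path)
  }
}

#' Flatten sessions to one data.frame of trials
#'
#' @param sessions list of `twostep_session`.
#' @return a data.frame with metadata columns plus the trial columns.
#' @export
sessions_to_df <- function(sessions) {
  do.call(rbind, lapply(sessions, function(s) {
    cbind(data.frame(subject_id = s$subject_id, group = s$group,
                     session = s$session, stringsAsFactors = FALSE),
          s$trials)
  }))
}
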