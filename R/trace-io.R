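#' Column mapping for Trace-dialect CSV exports
#'
#' Trace exports vary across capture versions, so all column names are
#' user-configurable. The defaults match the common dialect: a
#' `participant` id column, a `timestamp` column (milliseconds or seconds,
#' auto-detected), a `landmarks` cell holding the 68 X/Y pairs as JSON, and
#' seven `<emotion>Detection` score columns.
#'
#' @param participant Name of the participant id column.
#' @param grouping Character vector of grouping-variable column names
#'   (conditions, stimuli, ...).
#' @param timestamp Name of the timestamp column.
#' @param landmarks Name of the landmark JSON cell column.
#' @param emotions Named character vector mapping canonical emotion names
#'   (happiness, sadness, fear, anger, disgust, surprise, neutral) to
#'   column names.
#' @param timestamp_unit `"auto"` (default: a median inter-sample gap above
#'   10 is taken to mean milliseconds), `"s"`, or `"ms"`.
#' @return An object of class `trace_column_map`.
#' @export
trace_column_map <- function(participant = "participant",
                             grouping = character(),
                             timestamp = "timestamp",
                             landmarks = "landmarks",
                             emotions = setNames(
                               paste0(emotion_names(), "Detection"),
                               emotion_names()),
                             timestamp_unit = c("auto", "s", "ms")) {
  cols <- c(participant, timestamp, landmarks, grouping, unname(emotions))
  if (anyDuplicated(cols)) abort("mapped column names must be distinct")
  structure(
    list(participant = participant, grouping = grouping,
         timestamp = timestamp, landmarks = landmarks, emotions = emotions,
         timestamp_unit = match.arg(timestamp_unit)),
    class = "trace_column_map"
  )
}

#' Parse one landmark cell of JSON text
#'
#' Accepts either a nested array of 68 two-element `[x, y]` arrays or a
#' flat array of 136 numbers ordered `x1, y1, x2, y2, ..., x68, y68`
#' (pair i is then elements 2i-1 and 2i, 1-based). Never raises: malformed
#' text, wrong cardinality or non-numeric content yield `NULL` with the
#' reason in the `"reason"` attribute.
#'
#' @param text A character scalar of JSON (or `NA`).
#' @return A 68 x 2 numeric matrix (columns x, y) in landmark order
#'   1..68, or `NULL`. (Failure reasons are tallied per recording in the
#'   parse logs of [read_trace_folder()].)
#' @examples
#' m <- parse_landmark_cell(
#'   jsonlite::toJSON(cbind(1:68, 101:168))
#' )
#' dim(m)
#' is.null(parse_landmark_cell("[[1,2],[3,4]]"))  # wrong cardinality
#' @export
parse_landmark_cell <- function(text) {
  parse_landmark_cell_impl(text)$value
}

# Internal worker returning both the parsed value and a failure reason.
parse_landmark_cell_impl <- function(text) {
  fail <- function(reason) list(value = NULL, reason = reason)
  ok <- function(m) list(value = m, reason = NA_character_)
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    return(fail("empty cell"))
  }
  parsed <- tryCatch(jsonlite::fromJSON(text),
                     error = function(e) NULL)
  if (is.null(parsed)) return(fail("malformed JSON"))
  if (is.list(parsed)) {
    parsed <- tryCatch(do.call(rbind, lapply(parsed, as.numeric)),
                       error = function(e) NULL)
    if (is.null(parsed)) return(fail("non-numeric content"))
  }
  if (!is.numeric(parsed)) return(fail("non-numeric content"))
  if (is.matrix(parsed)) {
    if (!identical(dim(parsed), c(68L, 2L))) {
      return(fail(sprintf("expected 68 x 2 pairs, got %d x %d",
                          nrow(parsed), ncol(parsed))))
    }
    m <- parsed
  } else {
    if (length(parsed) != 136) {
      return(fail(sprintf("expected 136 numbers, got %d", length(parsed))))
    }
    m <- matrix(parsed, ncol = 2, byrow = TRUE)
  }
  if (anyNA(m)) return(fail("missing values in cell"))
  colnames(m) <- c("x", "y")
  ok(m)
}

group_label <- function(group_values) {
  if (length(group_values) == 0) return("all")
  paste(group_values, collapse = "|")
}

normalise_timestamps <- function(ts, unit) {
  if (unit == "ms") return(ts / 1000)
  if (unit == "s") return(ts)
  gaps <- diff(sort(ts))
  gaps <- gaps[gaps > 0]
  if (length(gaps) > 0 && median(gaps) > 10) ts / 1000 else ts
}

#' Read a folder of Trace-dialect CSV files into raw recordings
#'
#' Produces one raw recording per (file x participant x grouping
#' combination), rows sorted by timestamp. Rows whose landmark cell fails
#' to parse are retained as gaps (they count towards missingness) with the
#' failure counted in the recording's parse log. Emotion scores outside
#' `[0, 1]` are set to `NA` and logged.
#'
#' @param path Directory containing `.csv` files.
#' @param column_map A [trace_column_map()].
#' @return A list of `raw_recording` objects, each with `participant_id`,
#'   `group_values` (named character), `frames` (tibble: `time` in seconds,
#'   `valid`, `landmarks` list column, emotion columns), `source_file` and
#'   `parse_log` (list of row/failure counts).
#' @export
read_trace_folder <- function(path, column_map = trace_column_map()) {
  if (!dir.exists(path)) abort(sprintf("folder '%s' does not exist", path))
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) {
    abort(sprintf("no CSV files found in '%s'", path))
  }
  out <- list()
  for (f in files) {
    df <- readr::read_csv(f, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = "c"))
    mandatory <- c(column_map$participant, column_map$timestamp,
                   column_map$landmarks, column_map$grouping)
    missing_cols <- setdiff(mandatory, names(df))
    if (length(missing_cols) > 0) {
      abort(sprintf("file '%s' lacks mapped column(s): %s", basename(f),
                    paste(missing_cols, collapse = ", ")))
    }
    emo_present <- column_map$emotions[column_map$emotions %in% names(df)]
    key_cols <- c(column_map$participant, column_map$grouping)
    keys <- do.call(paste, c(lapply(key_cols, function(k) df[[k]]),
                             sep = "\r"))
    for (key in unique(keys)) {
      sub <- df[keys == key, , drop = FALSE]
      ts <- normalise_timestamps(as.numeric(sub[[column_map$timestamp]]),
                                 column_map$timestamp_unit)
      ord <- order(ts)
      sub <- sub[ord, , drop = FALSE]
      ts <- ts[ord]
      parsed <- lapply(sub[[column_map$landmarks]], parse_landmark_cell_impl)
      lms <- lapply(parsed, `[[`, "value")
      reasons <- vapply(parsed, `[[`, character(1), "reason")
      valid <- !vapply(lms, is.null, logical(1))
      frames <- tibble(time = ts, valid = valid, landmarks = lms)
      n_bad_scores <- 0L
      for (emo in names(emo_present)) {
        v <- suppressWarnings(as.numeric(sub[[emo_present[[emo]]]]))
        bad <- !is.na(v) & (v < 0 | v > 1)
        n_bad_scores <- n_bad_scores + sum(bad)
        v[bad] <- NA_real_
        frames[[emo]] <- v
      }
      gv <- vapply(column_map$grouping, function(g) {
        val <- unique(sub[[g]])
        as.character(val[1])
      }, character(1))
      names(gv) <- column_map$grouping
      rec <- structure(
        list(participant_id = as.character(sub[[column_map$participant]][1]),
             group_values = gv, frames = frames, source_file = basename(f),
             parse_log = list(
               n_rows = nrow(frames),
               n_missing_landmarks = sum(!valid),
               n_out_of_range_scores = n_bad_scores,
               reasons = table(reasons[!valid])
             )),
        class = "raw_recording")
      out[[length(out) + 1]] <- rec
    }
  }
  n_bad <- sum(vapply(out, function(r) r$parse_log$n_missing_landmarks,
                      integer(1)))
  if (n_bad > 0) {
    inform(sprintf("%d row(s) with unparseable landmark cells retained as gaps",
                   n_bad))
  }
  out
}

#' Partition recordings by grouping-variable values
#'
#' @param recordings List of raw or processed recordings carrying
#'   `group_values`.
#' @param keys Character vector of grouping-column names; the group label
#'   is the ordered tuple of key values. With no keys, all recordings fall
#'   into one `"all"` group. A recording lacking a key value is assigned to
#'   an `"ungrouped:<key>"` group and reported.
#' @return A named list of recording lists; the partition is exhaustive and
#'   disjoint.
#' @export
group_records <- function(recordings, keys = character()) {
  labels <- vapply(recordings, function(r) {
    vals <- as.character(r$group_values[keys])
    bad <- is.na(vals) | !nzchar(vals)
    if (length(keys) > 0 && any(bad)) {
      paste0("ungrouped:", keys[which(bad)[1]])
    } else {
      group_label(vals)
    }
  }, character(1))
  if (any(startsWith(labels, "ungrouped:"))) {
    inform(sprintf("%d recording(s) lack a grouping value",
                   sum(startsWith(labels, "ungrouped:"))))
  }
  split(recordings, labels)
}

#' Write / read an aligned recording set in the processed CSV layout
#'
#' Each recording is written as one CSV with columns
#' `time, x1, y1, ..., x68, y68, HeadMovement` (the per-second head
#' movement value repeated across the frames of its second), plus a single
#' JSON manifest recording participants, group values, rate and the full
#' preprocessing settings. The round trip `read_processed(write_processed())`
#' reproduces all numeric content exactly.
#'
#' @param set An aligned `recording_set` (head movement computed).
#' @param path Output directory (created if needed).
#' @return `write_processed` invisibly returns the manifest path;
#'   `read_processed` returns the reconstructed `recording_set`.
#' @export
write_processed <- function(set, path) {
  stopifnot(inherits(set, "recording_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  coord_names <- paste0(rep(c("x", "y"), times = 68),
                        rep(1:68, each = 2))
  entries <- list()
  for (i in seq_along(set$recordings)) {
    r <- set$recordings[[i]]
    t_n <- length(r$time)
    flat <- matrix(NA_real_, nrow = t_n, ncol = 136)
    flat[, seq(1, 135, by = 2)] <- r$landmarks[, , 1]
    flat[, seq(2, 136, by = 2)] <- r$landmarks[, , 2]
    colnames(flat) <- coord_names
    hm <- r$head_movement
    bin <- pmin((seq_len(t_n) - 1) %/% r$rate, nrow(hm) - 1)
    df <- dplyr::bind_cols(tibble(time = r$time), as_tibble(flat),
                           tibble(HeadMovement =
                                    hm$head_movement[bin + 1]))
    fn <- sprintf("rec_%03d.csv", i)
    readr::write_csv(df, file.path(path, fn))
    entries[[i]] <- list(file = fn, participant = r$participant_id,
                         group_values = as.list(r$group_values))
  }
  manifest <- list(recordings = entries, rate = set$rate,
                   n_samples = length(set$time),
                   settings = set$settings)
  mp <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mp)
}

#' @rdname write_processed
#' @export
read_processed <- function(path) {
  mp <- file.path(path, "manifest.json")
  if (!file.exists(mp)) abort(sprintf("no manifest.json under '%s'", path))
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  rate <- manifest$rate
  recs <- lapply(manifest$recordings, function(e) {
    # read as text and convert through strtod: exact round trip of the
    # shortest-representation doubles the writer emits
    df <- readr::read_csv(file.path(path, e$file), show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = "c"))
    df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.numeric))
    t_n <- nrow(df)
    lm_arr <- array(NA_real_, dim = c(t_n, 68, 2))
    lm_arr[, , 1] <- as.matrix(df[, paste0("x", 1:68)])
    lm_arr[, , 2] <- as.matrix(df[, paste0("y", 1:68)])
    bin <- (seq_len(t_n) - 1) %/% rate
    first_of_bin <- !duplicated(bin)
    hm_bins <- bin[first_of_bin]
    hm_vals <- df$HeadMovement[first_of_bin]
    keep_bins <- hm_bins <= max((t_n - 2) %/% rate, 0)
    structure(
      list(time = df$time, landmarks = lm_arr, emotions = NULL,
           head_movement = tibble(second = as.numeric(hm_bins[keep_bins]),
                                  head_movement = hm_vals[keep_bins]),
           participant_id = e$participant,
           group_values = unlist(e$group_values) %||%
             setNames(character(0), character(0)),
           rate = rate, settings = manifest$settings),
      class = "recording")
  })
  structure(list(recordings = recs, time = recs[[1]]$time, rate = rate,
                 settings = manifest$settings),
            class = "recording_set")
}

channel_matrix <- function(set, channel) {
  stopifnot(inherits(set, "recording_set"))
  ids <- vapply(set$recordings, function(r) r$participant_id, character(1))
  if (identical(channel, "head_movement")) {
    m <- t(vapply(set$recordings, function(r) r$head_movement$head_movement,
                  numeric(nrow(set$recordings[[1]]$head_movement))))
    rownames(m) <- ids
    return(m)
  }
  avail <- colnames(set$recordings[[1]]$emotions) %||% character(0)
  if (!channel %in% avail) {
    abort(sprintf("unknown channel '%s'; available: %s", channel,
                  paste(c("head_movement", avail), collapse = ", ")))
  }
  m <- t(vapply(set$recordings, function(r) r$emotions[, channel],
                numeric(length(set$time))))
  rownames(m) <- ids
  m
}
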