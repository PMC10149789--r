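# Plain-text serialization. Cohorts and protocols travel as CSV; protocol
# metadata rides in `#key=value` comment headers so a file round-trips to
# an identical object. Censored thresholds are written as the literal token
# "NA_censored" (distinct from plain missing values).

CENSORED_TOKEN <- "NA_censored"

# full-precision formatting so doubles survive a write/read round trip
fmt_full <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 17, format = "g"))
}

write_meta_csv <- function(meta, df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    writeLines(paste0("#", k, "=", if (is.null(v)) "" else as.character(v)),
               con)
  }
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], fmt_full)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, na = "NA")
}

read_meta_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_lines <- sub("^#", "", lines[is_meta])
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  meta <- stats::setNames(
    lapply(kv, function(p) if (length(p) < 2L) "" else
      paste(p[-1L], collapse = "=")),
    vapply(kv, `[[`, "", 1L))
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"),
                        stringsAsFactors = FALSE)
  list(meta = meta, df = df)
}

meta_num <- function(meta, key) {
  v <- meta[[key]]
  if (is.null(v) || identical(v, "")) NULL else as.numeric(v)
}

#' Write a protocol object to CSV
#'
#' One row per trial (pitch identification, backward masking) or per gap
#' (Gaps-in-Noise); protocol-level fields are stored in `#key=value` header
#' lines. [read_protocol_csv()] reconstructs an identical object.
#'
#' @param x A protocol from [build_pitch_id_protocol()],
#'   [build_gin_track()] or [build_bmt_session()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_protocol_csv <- function(x, path) {
  if (inherits(x, "pitch_id_protocol")) {
    meta <- list(type = "pitch_id_protocol", variant = x$variant,
                 iti_s = x$iti_s, level_db_sl = x$level_db_sl,
                 timbre = x$timbre, seed = x$seed)
    df <- x$trials
  } else if (inherits(x, "gin_track")) {
    meta <- list(type = "gin_track", track_id = x$track_id,
                 n_segments = x$n_segments, segment_ms = x$segment_ms,
                 isi_s = x$isi_s, seed = x$seed)
    df <- x$gaps
  } else if (inherits(x, "bmt_session")) {
    meta <- list(type = "bmt_session", tone_ms = x$tone_ms,
                 masker_ms = x$masker_ms,
                 tone_level_db_sl = x$tone_level_db_sl, snr_db = x$snr_db,
                 seed = x$seed)
    df <- x$trials
  } else {
    stop("not a protocol object", call. = FALSE)
  }
  write_meta_csv(meta, df, path)
  invisible(path)
}

#' Read a protocol object from CSV
#'
#' @param path A file written by [write_protocol_csv()].
#' @return The reconstructed protocol object.
#' @export
read_protocol_csv <- function(path) {
  parsed <- read_meta_csv(path)
  meta <- parsed$meta
  df <- parsed$df
  seed <- meta_num(meta, "seed")
  switch(
    meta$type,
    pitch_id_protocol = structure(
      list(variant = meta$variant, trials = df,
           iti_s = meta_num(meta, "iti_s"),
           level_db_sl = meta_num(meta, "level_db_sl"),
           timbre = meta$timbre, seed = seed),
      class = "pitch_id_protocol"),
    gin_track = structure(
      list(track_id = meta$track_id,
           n_segments = as.integer(meta_num(meta, "n_segments")),
           segment_ms = meta_num(meta, "segment_ms"),
           isi_s = meta_num(meta, "isi_s"), gaps = df, seed = seed),
      class = "gin_track"),
    bmt_session = structure(
      list(trials = df, tone_ms = meta_num(meta, "tone_ms"),
           masker_ms = meta_num(meta, "masker_ms"),
           tone_level_db_sl = meta_num(meta, "tone_level_db_sl"),
           snr_db = meta_num(meta, "snr_db"), seed = seed),
      class = "bmt_session"),
    stop("unknown protocol type: ", meta$type, call. = FALSE)
  )
}

#' Write a cohort table to CSV
#'
#' Censored averaged thresholds (GDT/BMTT) are written as the token
#' `"NA_censored"`; plain missing values (e.g. pitch scores of screened-out
#' subjects) stay `NA`. The experiment id is kept in a header line.
#'
#' @param cohort A cohort data frame (see [simulate_cohort()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (thr in intersect(c("gdt", "bmtt"), names(df))) {
    flag <- paste0(thr, "_censored")
    col <- fmt_full(df[[thr]])
    if (flag %in% names(df)) {
      col[!is.na(df[[flag]]) & df[[flag]]] <- CENSORED_TOKEN
    }
    df[[thr]] <- col
  }
  meta <- list(type = "cohort",
               experiment = attr(cohort, "experiment") %||% "")
  write_meta_csv(meta, df, path)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path A file written by [write_cohort_csv()].
#' @return A cohort data frame; censored thresholds come back as `NA` with
#'   their `_censored` flag set.
#' @export
read_cohort_csv <- function(path) {
  parsed <- read_meta_csv(path)
  df <- parsed$df
  for (thr in intersect(c("gdt", "bmtt"), names(df))) {
    col <- as.character(df[[thr]])
    cens <- !is.na(col) & col == CENSORED_TOKEN
    col[cens] <- NA
    df[[thr]] <- as.numeric(col)
    flag <- paste0(thr, "_censored")
    if (!flag %in% names(df)) df[[flag]] <- cens
  }
  expn <- meta_num(parsed$meta, "experiment")
  if (!is.null(expn)) attr(df, "experiment") <- expn
  df
}
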