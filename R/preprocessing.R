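#' Construct a sequence set
#'
#' A sequence set is the package's tabular container for response sequences:
#' a long tibble (`participant_id`, `group`, `task`, `position`, `value`)
#' carrying two attributes — `excluded`, a tibble accounting for every
#' sequence dropped by filtering, and `provenance`, a list describing the
#' source and the filters applied.
#'
#' @param data Long-format tibble of responses.
#' @param excluded Tibble with columns `participant_id`, `group`, `task`,
#'   `length`, `reason`.
#' @param provenance Named list (source path, filters, parameters).
#' @return A tibble of class `sequence_set`.
#' @export
sequence_set <- function(data, excluded = NULL, provenance = list()) {
  data <- as_tibble(data)
  if (is.null(excluded)) {
    excluded <- tibble(participant_id = character(), group = character(),
                       task = character(), length = integer(), reason = character())
  }
  structure(data, excluded = as_tibble(excluded), provenance = provenance,
            class = c("sequence_set", class(data)))
}

#' @rdname sequence_set
#' @param x A `sequence_set`.
#' @export
excluded_sequences <- function(x) attr(x, "excluded") %||% tibble()

`%||%` <- function(a, b) if (is.null(a)) b else a

seq_keys <- function(data) intersect(c("participant_id", "group", "task"), names(data))

GROUPS <- c("expert", "beginner")
TASKS <- c("morra", "rngt")

#' Read response sequences from a delimited text file
#'
#' Accepts either long form (`participant_id`, `group`, `task`, `position`,
#' `value`) or wide form (`participant_id`, `group`, `task`, `v1`...`vK`,
#' trailing `NA`s marking shorter sequences); the delimiter (comma or tab)
#' and the dialect are sniffed from the header. Group and task labels are
#' validated against the closed vocabularies `expert`/`beginner` and
#' `morra`/`rngt`; positions must be contiguous from 1 within each sequence
#' and values must lie in the alphabet, with violations reported by row
#' number.
#'
#' @param path Path to a UTF-8 delimited text file with a header.
#' @param alphabet Response alphabet (default `1:5`).
#' @return A [sequence_set()] in long form, unstandardized.
#' @export
read_sequences <- function(path, alphabet = 1:5) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  nm <- names(raw)
  wide_cols <- grep("^v[0-9]+$", nm, value = TRUE)
  long_form <- all(c("position", "value") %in% nm)
  if (!long_form && !length(wide_cols)) {
    stop_input("File is neither long form (position,value) nor wide form (v1..vK).")
  }
  need <- c("participant_id", "group", "task")
  if (!all(need %in% nm)) {
    stop_input(sprintf("Missing required column(s): %s.",
                       paste(setdiff(need, nm), collapse = ", ")))
  }

  if (long_form) {
    data <- raw[, c(need, "position", "value")]
    data$.row <- seq_len(nrow(data)) + 1L  # file line numbers (header = 1)
  } else {
    wide_cols <- wide_cols[order(as.integer(sub("^v", "", wide_cols)))]
    raw$.row <- seq_len(nrow(raw)) + 1L
    data <- tidyr::pivot_longer(raw[, c(need, wide_cols, ".row")],
                                dplyr::all_of(wide_cols),
                                names_to = "position", values_to = "value")
    data$position <- as.integer(sub("^v", "", data$position))
    # trailing NAs encode sequence end; internal NAs are an error
    data <- dplyr::arrange(data, .data$participant_id, .data$task, .data$position)
    data <- dplyr::group_by(data, .data$participant_id, .data$group, .data$task)
    data <- dplyr::mutate(data, .last = max(c(0L, .data$position[!is.na(.data$value)])))
    data <- dplyr::ungroup(data)
    if (any(is.na(data$value) & data$position <= data$.last)) {
      bad <- data$.row[is.na(data$value) & data$position <= data$.last]
      stop_input(sprintf("Internal missing values at file row(s) %s.",
                         paste(unique(head(bad, 10)), collapse = ", ")))
    }
    data <- data[!is.na(data$value), c(need, "position", "value", ".row")]
  }

  bad_group <- !(data$group %in% GROUPS)
  if (any(bad_group)) {
    stop_input(sprintf("Unknown group label(s) %s at file row(s) %s.",
                       paste(unique(data$group[bad_group]), collapse = ", "),
                       paste(head(unique(data$.row[bad_group]), 10), collapse = ", ")))
  }
  bad_task <- !(data$task %in% TASKS)
  if (any(bad_task)) {
    stop_input(sprintf("Unknown task label(s) %s at file row(s) %s.",
                       paste(unique(data$task[bad_task]), collapse = ", "),
                       paste(head(unique(data$.row[bad_task]), 10), collapse = ", ")))
  }
  bad_val <- !(data$value %in% alphabet)
  if (any(bad_val)) {
    stop_input(sprintf("Off-alphabet value(s) at file row(s) %s.",
                       paste(head(data$.row[bad_val], 10), collapse = ", ")))
  }
  chk <- dplyr::summarise(
    dplyr::group_by(data, .data$participant_id, .data$group, .data$task),
    ok = identical(sort(as.integer(.data$position)), seq_along(.data$position)),
    .groups = "drop"
  )
  if (any(!chk$ok)) {
    bad <- chk[!chk$ok, ]
    stop_input(sprintf("Non-contiguous positions for sequence(s): %s.",
                       paste(paste(bad$participant_id, bad$task, sep = "/"),
                             collapse = ", ")))
  }
  data <- dplyr::arrange(data, .data$participant_id, .data$task, .data$position)
  data$value <- as.integer(data$value)
  data$position <- as.integer(data$position)
  data$.row <- NULL
  sequence_set(data, provenance = list(source = path, alphabet = alphabet,
                                       filters = character()))
}

#' Standardize sequence lengths
#'
#' Applies the study's length standardization: sequences at least
#' `standard_length` long are truncated to their first `standard_length`
#' responses; shorter ones are excluded (recorded in the `excluded`
#' attribute with reason `"below minimum length"`, not an error). The
#' default 57 is the tradeoff between sequence length and number of
#' retained sequences used throughout; the operation is idempotent.
#'
#' @param set A [sequence_set()] (or any long-format data frame).
#' @param standard_length Target length (default 57).
#' @return A [sequence_set()] in which every retained sequence has length
#'   exactly `standard_length`.
#' @export
standardize <- function(set, standard_length = 57L) {
  standard_length <- check_count(standard_length, "standard_length")
  data <- as_tibble(set)
  keys <- seq_keys(data)
  if (!length(keys)) stop_input("`set` must carry at least a participant_id column.")
  lens <- dplyr::summarise(dplyr::group_by(data, dplyr::across(dplyr::all_of(keys))),
                           length = dplyr::n(), .groups = "drop")
  short <- lens[lens$length < standard_length, ]
  newly_excluded <- tibble(
    participant_id = as.character(short$participant_id),
    group = if ("group" %in% keys) short$group else NA_character_,
    task = if ("task" %in% keys) short$task else NA_character_,
    length = as.integer(short$length),
    reason = rep("below minimum length", nrow(short))
  )
  kept <- dplyr::anti_join(data, short[, keys, drop = FALSE], by = keys)
  kept <- dplyr::group_by(kept, dplyr::across(dplyr::all_of(keys)))
  if ("position" %in% names(kept)) kept <- dplyr::arrange(kept, .data$position, .by_group = TRUE)
  kept <- dplyr::filter(kept, dplyr::row_number() <= standard_length)
  kept <- dplyr::mutate(kept, position = dplyr::row_number())
  kept <- dplyr::ungroup(kept)
  prov <- attr(set, "provenance") %||% list()
  prov$filters <- c(prov$filters, sprintf("standardize(standard_length=%d)", standard_length))
  sequence_set(kept,
               excluded = dplyr::bind_rows(excluded_sequences(set), newly_excluded),
               provenance = prov)
}

#' Write randomness profiles and the exclusion report
#'
#' Writes one row per retained sequence in a stable column order
#' (`participant_id`, `group`, `task`, `n`, `redundancy`, `fpr`, `nsq`,
#' `coupon`, `rep_gap`, `flags`) plus a sidecar `<path>.exclusions.csv`
#' echoing every sequence the preprocessing dropped.
#'
#' @param set The [sequence_set()] the profiles were computed from.
#' @param profiles Output of [randomness_profile()] on `set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(set, profiles, path) {
  keys <- seq_keys(profiles)
  set_ids <- dplyr::distinct(as_tibble(set)[, seq_keys(set), drop = FALSE])
  prof_ids <- profiles[, keys, drop = FALSE]
  if (!identical(dim(dplyr::semi_join(prof_ids, set_ids, by = keys)), dim(prof_ids)) ||
      nrow(prof_ids) != nrow(set_ids)) {
    stop_input("Profiles and sequence set do not describe the same sequences.")
  }
  cols <- c(keys, "n", "redundancy", "fpr", "nsq", "coupon", "rep_gap", "flags")
  readr::write_csv(profiles[, cols], path)
  readr::write_csv(excluded_sequences(set), paste0(path, ".exclusions.csv"))
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(flags = readr::col_character(),
                                          .default = readr::col_guess()))
}
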