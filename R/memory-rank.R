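#' Actual frequency ranking of a response sequence
#'
#' Orders the alphabet from most to least frequently produced. Ties (which
#' can occur in real 57-response sequences) are broken by ascending face
#' value and flagged, so downstream users can exclude tied cases; the
#' ranking of a sequence depends only on its frequency table, not on order.
#'
#' @inheritParams randomness_indices
#' @return A tibble with columns `rank`, `value`, `count` and `tied`
#'   (logical: shares its count with another value).
#' @export
#' @examples
#' actual_ranking_from_sequence(c(1, 1, 1, 2, 2, 3))
actual_ranking_from_sequence <- function(x, alphabet = 1:5) {
  x <- check_sequence(x, alphabet, min_n = 1L)
  counts <- singlet_counts(x, alphabet)
  ord <- order(-counts, alphabet)
  tied <- duplicated(counts) | duplicated(counts, fromLast = TRUE)
  tibble(rank = seq_along(alphabet), value = alphabet[ord],
         count = as.integer(counts[ord]), tied = tied[ord])
}

rnd_half_up <- function(x) floor(x + 0.5)

#' Maximum Spearman footrule distance
#'
#' The largest achievable total rank displacement between two rankings of
#' `m` items, `floor(m^2 / 2)` (attained by reversing the ranking): 12 for
#' the five hand numbers.
#'
#' @param alphabet_size Number of ranked items.
#' @return An integer.
#' @export
#' @examples
#' max_footrule(5)  # 12
max_footrule <- function(alphabet_size) {
  m <- check_count(alphabet_size, "alphabet_size")
  as.integer(floor(m^2 / 2))
}

#' Spearman footrule distance between subjective and actual rankings
#'
#' The declarative-memory score: each item's displacement is the absolute
#' difference between its position in the subjective ranking (believed
#' most- to least-frequent) and in the actual ranking; displacements are
#' reported in subjective-rank order, summed to a total (0-12 for five
#' items, always even) and expressed as a half-up-rounded percentage of the
#' maximum. Zero means perfect memory of the frequencies just played.
#'
#' @param subjective,actual Permutations of the same alphabet, ordered from
#'   (believed/observed) most to least frequent. `actual` may also be given
#'   as the output of [actual_ranking_from_sequence()].
#' @return A one-row tibble: list-columns `subjective`, `actual` and
#'   `per_rank_distance`, plus `total_distance`, `max_distance` and
#'   `percent_of_max`.
#' @export
#' @examples
#' footrule_distance(c(5, 4, 3, 2, 1), c(1, 2, 5, 4, 3))$total_distance  # 12
footrule_distance <- function(subjective, actual) {
  if (is.data.frame(actual) && "value" %in% names(actual)) actual <- actual$value
  subjective <- as.integer(subjective)
  actual <- as.integer(actual)
  if (length(subjective) != length(actual) ||
      !setequal(subjective, actual) ||
      anyDuplicated(subjective) || anyDuplicated(actual)) {
    stop_input("`subjective` and `actual` must be permutations of the same alphabet.")
  }
  disp <- abs(seq_along(subjective) - match(subjective, actual))
  total <- sum(disp)
  maxd <- max_footrule(length(subjective))
  tibble(
    subjective = list(subjective), actual = list(actual),
    per_rank_distance = list(as.integer(disp)),
    total_distance = as.integer(total),
    max_distance = maxd,
    percent_of_max = as.integer(rnd_half_up(100 * total / maxd))
  )
}

#' Read a ranking table
#'
#' Expects two rows per participant: columns `participant_id`,
#' `kind` (`"subjective"` or `"actual"`), and `r1`...`rK` giving the ranked
#' items from most to least frequent. Comma or tab delimited, sniffed.
#'
#' @param path Path to the delimited file.
#' @return A tibble.
#' @export
read_rankings <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  need <- c("participant_id", "kind")
  rcols <- grep("^r[0-9]+$", names(raw), value = TRUE)
  if (!all(need %in% names(raw)) || !length(rcols)) {
    stop_input("Ranking table must have participant_id, kind, r1..rK columns.")
  }
  if (!all(raw$kind %in% c("subjective", "actual"))) {
    stop_input("`kind` must be 'subjective' or 'actual'.")
  }
  raw
}

#' Per-participant rank-distance report
#'
#' Computes the footrule memory score for every participant in a ranking
#' table, in the shape of the study's per-sequence summary: the two
#' rankings, the five per-rank displacements, the total distance and the
#' percentage of the maximum.
#'
#' @param rankings A tibble as returned by [read_rankings()], or any data
#'   frame with `participant_id`, `kind` and `r1`...`rK` columns.
#' @return A tibble with one row per participant.
#' @export
rank_distance_report <- function(rankings) {
  rcols <- grep("^r[0-9]+$", names(rankings), value = TRUE)
  rcols <- rcols[order(as.integer(sub("^r", "", rcols)))]
  split_rows <- split(rankings, rankings$participant_id)
  rows <- purrr::map(split_rows, function(d) {
    subj <- d[d$kind == "subjective", rcols]
    act <- d[d$kind == "actual", rcols]
    if (nrow(subj) != 1 || nrow(act) != 1) {
      stop_input(sprintf("Participant %s needs exactly one subjective and one actual row.",
                         d$participant_id[1]))
    }
    fd <- footrule_distance(unlist(subj), unlist(act))
    dplyr::bind_cols(tibble(participant_id = as.character(d$participant_id[1])), fd)
  })
  dplyr::bind_rows(rows)
}
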