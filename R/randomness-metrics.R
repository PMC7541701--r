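#' Randomness indices for bounded-alphabet response sequences
#'
#' Five classical indices quantify how far a response sequence (here,
#' hand numbers 1-5) deviates from an iid-uniform ideal:
#'
#' * `redundancy()` — percentage shortfall of the single-response entropy
#'   from its maximum, `R = 100 (1 - H / log2 a)` with
#'   `H = log2 n - (1/n) sum_i n_i log2 n_i`; 0% equifrequent, 100% constant.
#' * `fpr_index()` — frequency of paired responses (the RNG index):
#'   `sum_ij n_ij log2 n_ij / sum_i n_i log2 n_i` over adjacent ordered
#'   pairs; rises towards 1 when particular digrams are favoured.
#' * `nsq()` — null-score quotient: the percentage of the `a^2` possible
#'   digrams never produced, scaled by the maximum achievable null score
#'   `a^2 - 1` (a constant sequence leaves only one digram).
#' * `coupon_score()` — mean responses needed to cycle through all `a`
#'   alternatives, scanning non-overlapping segments left to right and
#'   discarding the incomplete tail; floor `a`, iid-uniform expectation
#'   `a * sum(1/(1:a))` (11.4167 for `a = 5`).
#' * `repetition_gap_mean()` — mean positional distance between successive
#'   occurrences of the same value (adjacent repeat = 1), averaged over all
#'   recurrences.
#'
#' Each index errors (class `morrarand_error_undefined`) when its defining
#' counts make it undefined; [randomness_profile()] converts those errors
#' into explicit flags instead.
#'
#' @param x Integer vector of responses over `alphabet`.
#' @param alphabet Response alphabet (default `1:5`).
#' @return A single numeric value.
#' @name randomness_indices
#' @examples
#' cyc <- rep(1:5, length.out = 57)
#' coupon_score(cyc)        # 5, the floor
#' repetition_gap_mean(cyc) # 5, the ceiling attained by perfect cycling
#' redundancy(rep(3, 57))   # 100
NULL

check_sequence <- function(x, alphabet, min_n = 1L) {
  if (is.data.frame(x)) stop_input("Pass a single sequence as a vector here; use randomness_profile() for tables.")
  if (!is.numeric(x) || anyNA(x)) stop_input("Sequence must be numeric without missing values.")
  bad <- which(!(x %in% alphabet))
  if (length(bad)) {
    stop_input(sprintf("Values outside the alphabet at position(s) %s.",
                       paste(head(bad, 10), collapse = ", ")),
               positions = bad)
  }
  if (length(x) < min_n) {
    stop_undefined(sprintf("Sequence of length %d is too short (need >= %d).",
                           length(x), min_n), index = NA_character_)
  }
  as.integer(x)
}

#' Singlet and digram counts
#'
#' @inheritParams randomness_indices
#' @return `singlet_counts()`: a named integer vector over the alphabet.
#'   `digram_counts()`: an `a x a` integer matrix, rows = first element.
#' @export
singlet_counts <- function(x, alphabet = 1:5) {
  x <- check_sequence(x, alphabet)
  tab <- table(factor(x, levels = alphabet))
  setNames(as.integer(tab), as.character(alphabet))
}

#' @rdname singlet_counts
#' @export
digram_counts <- function(x, alphabet = 1:5) {
  x <- check_sequence(x, alphabet)
  a <- length(alphabet)
  m <- matrix(0L, a, a, dimnames = list(as.character(alphabet), as.character(alphabet)))
  if (length(x) >= 2) {
    from <- factor(x[-length(x)], levels = alphabet)
    to <- factor(x[-1], levels = alphabet)
    tab <- table(from, to)
    m[] <- as.integer(tab)
  }
  m
}

xlog2x <- function(n) sum(ifelse(n > 1, n * log2(n), 0))

#' @rdname randomness_indices
#' @export
redundancy <- function(x, alphabet = 1:5) {
  x <- check_sequence(x, alphabet, min_n = 1L)
  n <- length(x)
  ni <- singlet_counts(x, alphabet)
  h <- log2(n) - xlog2x(ni) / n
  r <- 100 * (1 - h / log2(length(alphabet)))
  min(max(r, 0), 100)
}

#' @rdname randomness_indices
#' @export
fpr_index <- function(x, alphabet = 1:5) {
  x <- check_sequence(x, alphabet, min_n = 2L)
  den <- xlog2x(singlet_counts(x, alphabet))
  if (den <= 0) {
    stop_undefined("FPR undefined: no single response is repeated.", index = "fpr")
  }
  xlog2x(digram_counts(x, alphabet)) / den
}

#' @rdname randomness_indices
#' @export
nsq <- function(x, alphabet = 1:5) {
  x <- check_sequence(x, alphabet, min_n = 2L)
  a <- length(alphabet)
  ns <- a^2 - sum(digram_counts(x, alphabet) > 0)
  100 * ns / (a^2 - 1)
}

#' @rdname randomness_indices
#' @export
coupon_score <- function(x, alphabet = 1:5) {
  x <- check_sequence(x, alphabet, min_n = length(alphabet))
  a <- length(alphabet)
  seen <- logical(a)
  start <- 1L
  segs <- integer(0)
  idx <- match(x, alphabet)
  for (i in seq_along(idx)) {
    seen[idx[i]] <- TRUE
    if (all(seen)) {
      segs <- c(segs, i - start + 1L)
      start <- i + 1L
      seen <- logical(a)
    }
  }
  if (!length(segs)) {
    stop_undefined("Coupon score undefined: no complete cycle through all alternatives.",
                   index = "coupon")
  }
  mean(segs)
}

#' @rdname randomness_indices
#' @export
repetition_gap_mean <- function(x, alphabet = 1:5) {
  x <- check_sequence(x, alphabet, min_n = 2L)
  idx <- match(x, alphabet)
  last <- rep(NA_integer_, length(alphabet))
  gaps <- integer(0)
  for (i in seq_along(idx)) {
    v <- idx[i]
    if (!is.na(last[v])) gaps <- c(gaps, i - last[v])
    last[v] <- i
  }
  if (!length(gaps)) {
    stop_undefined("Repetition gap undefined: no value recurs.", index = "rep_gap")
  }
  mean(gaps)
}

profile_one <- function(x, alphabet) {
  idx <- list(redundancy = redundancy, fpr = fpr_index, nsq = nsq,
              coupon = coupon_score, rep_gap = repetition_gap_mean)
  vals <- list()
  flags <- character(0)
  for (nm in names(idx)) {
    vals[[nm]] <- tryCatch(idx[[nm]](x, alphabet), morrarand_error_undefined = function(e) {
      flags <<- c(flags, nm)
      NA_real_
    })
  }
  tibble(
    n = length(x),
    redundancy = vals$redundancy, fpr = vals$fpr, nsq = vals$nsq,
    coupon = vals$coupon, rep_gap = vals$rep_gap,
    flags = paste(flags, collapse = ","),
    singlets = list(singlet_counts(x, alphabet)),
    digrams = list(digram_counts(x, alphabet))
  )
}

#' Compute randomness profiles for a table of sequences
#'
#' Data-frame-first wrapper around the five indices: takes the long sequence
#' format (`participant_id`, optional `group`/`task`, `position`, `value`),
#' computes one profile per sequence, and returns one tibble row each.
#' Indices whose defining counts are degenerate (e.g. no recurrence) are
#' returned as `NA` and named in `flags`, never silently zeroed. Any
#' length-57 sequence over a five-symbol alphabet has all five defined.
#'
#' @param data A data frame in long sequence format, or a bare numeric
#'   vector for a single unlabelled sequence.
#' @param alphabet Response alphabet (default `1:5`).
#' @return A tibble with columns `participant_id`, `group`, `task` (when
#'   present in the input), `n`, `redundancy`, `fpr`, `nsq`, `coupon`,
#'   `rep_gap`, `flags`, and list-columns `singlets` and `digrams`.
#' @export
#' @examples
#' seqs <- generate_study(study_design(seed = 1))
#' randomness_profile(standardize(seqs))
randomness_profile <- function(data, alphabet = 1:5) {
  if (!is.data.frame(data)) {
    return(profile_one(check_sequence(data, alphabet, min_n = 2L), alphabet))
  }
  if (!"value" %in% names(data)) stop_input("`data` must have a `value` column.")
  keys <- intersect(c("participant_id", "group", "task"), names(data))
  if (!length(keys)) {
    x <- data$value
    if ("position" %in% names(data)) x <- x[order(data$position)]
    return(profile_one(check_sequence(x, alphabet, min_n = 2L), alphabet))
  }
  if (nrow(data) == 0) {
    empty <- profile_one(c(1L, 2L), alphabet)[0, ]
    ids <- as_tibble(data)[, keys, drop = FALSE]
    return(dplyr::bind_cols(ids[0, , drop = FALSE], empty))
  }
  grouped <- dplyr::group_by(data, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::reframe(grouped, {
    x <- .data$value
    if ("position" %in% names(data)) x <- x[order(.data$position)]
    profile_one(check_sequence(x, alphabet, min_n = 2L), alphabet)
  })
  as_tibble(out)
}
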