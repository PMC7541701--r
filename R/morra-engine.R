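#' The 25 valid Morra plays
#'
#' A Morra play shows a hand number `hand` (1-5 fingers) while calling a
#' number `call` (2-10), the player's guess at the sum of both hands. A play
#' is valid iff the call could be achieved, i.e. `1 <= call - hand <= 5`.
#' Exactly 25 such plays exist; they are returned sorted by `(hand, call)`,
#' the conventional payoff-matrix row order.
#'
#' @return A tibble with columns `hand`, `call` and `label` (e.g. `"1,2"`),
#'   one row per valid play.
#' @export
#' @examples
#' morra_plays()
morra_plays <- function() {
  grid <- expand.grid(call = 2:10, hand = 1:5)
  keep <- grid$call - grid$hand >= 1 & grid$call - grid$hand <= 5
  out <- tibble(hand = grid$hand[keep], call = grid$call[keep])
  out <- out[order(out$hand, out$call), ]
  out$label <- paste(out$hand, out$call, sep = ",")
  out
}

#' Validate Morra plays
#'
#' Checks hand/call pairs against the game's validity rule and labels the
#' classic beginner errors: calling more than `hand + 5` (the opponent cannot
#' show more than five fingers), calling the own hand number (the sum is
#' always larger), and calling less than the own hand.
#'
#' @param hand Integer vector of fingers shown (valid range 1-5).
#' @param call Integer vector of numbers called (valid range 2-10).
#' @return A tibble with columns `hand`, `call`, `valid` (logical) and
#'   `reason` (`"ok"`, `"hand out of range"`, `"call out of range"`,
#'   `"call exceeds hand+5"`, `"call equals hand"`, `"call below hand"`).
#' @export
#' @examples
#' validate_play(c(1, 3, 1), c(7, 3, 2))
validate_play <- function(hand, call) {
  if (!is.numeric(hand) || !is.numeric(call) || anyNA(hand) || anyNA(call) ||
      any(hand != floor(hand)) || any(call != floor(call))) {
    stop_input("`hand` and `call` must be integer vectors without missing values.")
  }
  if (length(hand) != length(call)) {
    stop_input("`hand` and `call` must have the same length.")
  }
  hand <- as.integer(hand)
  call <- as.integer(call)
  reason <- rep("ok", length(hand))
  reason[call < 2 | call > 10] <- "call out of range"
  reason[hand < 1 | hand > 5] <- "hand out of range"
  in_range <- reason == "ok"
  reason[in_range & call - hand > 5] <- "call exceeds hand+5"
  reason[in_range & call == hand] <- "call equals hand"
  reason[in_range & call < hand] <- "call below hand"
  tibble(hand = hand, call = call, valid = reason == "ok", reason = reason)
}

#' Adjudicate Morra rounds
#'
#' A player scores when their call equals the sum of the two hands and the
#' opponent's call does not. If both or neither call the sum, nobody scores.
#'
#' @param hand_a,call_a Player A's play(s).
#' @param hand_b,call_b Player B's play(s).
#' @return A tibble with the plays, the `sum` of hands, and `winner`
#'   (`"A"`, `"B"` or `"none"`).
#' @export
#' @examples
#' adjudicate_round(hand_a = 1, call_a = 3, hand_b = 1, call_b = 2)
adjudicate_round <- function(hand_a, call_a, hand_b, call_b) {
  va <- validate_play(hand_a, call_a)
  vb <- validate_play(hand_b, call_b)
  if (!all(va$valid)) {
    stop_input(paste0("Invalid play for A: ", va$reason[!va$valid][1], "."),
               reason = va$reason[!va$valid][1])
  }
  if (!all(vb$valid)) {
    stop_input(paste0("Invalid play for B: ", vb$reason[!vb$valid][1], "."),
               reason = vb$reason[!vb$valid][1])
  }
  s <- va$hand + vb$hand
  a_hit <- va$call == s
  b_hit <- vb$call == s
  winner <- rep("none", length(s))
  winner[a_hit & !b_hit] <- "A"
  winner[b_hit & !a_hit] <- "B"
  tibble(
    hand_a = va$hand, call_a = va$call,
    hand_b = vb$hand, call_b = vb$call,
    sum = s, winner = winner
  )
}

#' Build the full Morra payoff matrix
#'
#' Enumerates all 625 pairs of valid plays and adjudicates each, giving the
#' complete payoff structure of the game from player B's perspective: rows
#' are B's plays, columns A's plays, both in `(hand, call)` order.
#'
#' @return A 25 x 25 character matrix of class `morra_payoff` with entries
#'   `"B"` (B scores), `"A"` (A scores) or `"none"`, dimnames the play labels.
#' @export
#' @examples
#' pm <- build_payoff_matrix()
#' pm["1,2", "1,3"]
build_payoff_matrix <- function() {
  plays <- morra_plays()
  grid <- expand.grid(b = seq_len(nrow(plays)), a = seq_len(nrow(plays)))
  adj <- adjudicate_round(
    hand_a = plays$hand[grid$a], call_a = plays$call[grid$a],
    hand_b = plays$hand[grid$b], call_b = plays$call[grid$b]
  )
  m <- matrix(adj$winner, nrow = nrow(plays), ncol = nrow(plays),
              dimnames = list(B = plays$label, A = plays$label))
  class(m) <- c("morra_payoff", class(m))
  m
}

#' Plot a payoff matrix
#'
#' @param object A `morra_payoff` matrix from [build_payoff_matrix()].
#' @param ... Unused.
#' @return A ggplot heatmap of round outcomes.
#' @exportS3Method ggplot2::autoplot
autoplot.morra_payoff <- function(object, ...) {
  labels <- rownames(unclass(object))
  df <- expand.grid(b = labels, a = labels, stringsAsFactors = FALSE)
  df$winner <- as.vector(unclass(object))
  df$a <- factor(df$a, levels = labels)
  df$b <- factor(df$b, levels = rev(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$winner)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c(A = "#d95f02", B = "#1b9e77", none = "grey95")) +
    ggplot2::labs(x = "Player A play (hand,call)", y = "Player B play (hand,call)",
                  fill = "Scorer") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

# agents -----------------------------------------------------------------

#' Create a Morra agent
#'
#' An agent bundles a player id with a hand-number generator and a call rule.
#' The default call rule predicts the opponent's hand uniformly, so built-in
#' agents always emit valid plays; a custom `play` function may emit invalid
#' plays, which [simulate_match()] handles per its `on_invalid` policy.
#'
#' @param id Player identifier (character scalar).
#' @param hand_fun Function of the agent's own previous hand (`NA` on the
#'   first play) returning the next hand number in 1-5. Default: iid uniform.
#' @param play Optional full play function of the previous hand returning
#'   `c(hand, call)`; overrides `hand_fun` + the uniform call rule.
#' @return An object of class `morra_agent`.
#' @seealso [markov_agent()] for agents with bias, perseveration and load.
#' @export
morra_agent <- function(id, hand_fun = NULL, play = NULL) {
  if (is.null(hand_fun)) hand_fun <- function(prev) sample(5L, 1L)
  if (is.null(play)) {
    play <- function(prev) {
      h <- hand_fun(prev)
      c(hand = h, call = h + sample(5L, 1L))
    }
  }
  structure(list(id = as.character(id), play = play), class = "morra_agent")
}

#' Simulate a Morra match
#'
#' Plays rounds until one side first reaches `target_score`. In team mode
#' each side fields two players; after a scored round the scorer stays on
#' and the losing side substitutes its active player (the bench player
#' re-enters with its own memory of its previous plays intact). Rounds in
#' which both or neither player calls the sum score for nobody and play
#' continues.
#'
#' @param side_a,side_b A single [morra_agent()] (singles) or a list of two
#'   (team mode).
#' @param target_score Points needed to win; defaults to 16 in team mode and
#'   10 in singles, the traditional targets.
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @param on_invalid What to do when an agent emits an invalid play:
#'   `"resample"` (redraw, counted) or `"abort"`.
#' @param max_rounds Safety cap on the number of rounds.
#' @return A `morra_match` object: a list with `rounds` (tibble, one row per
#'   round: round, player ids, hands, calls, sum, winner), `scores`,
#'   `target_score`, `team_mode` and `n_invalid`.
#' @export
#' @examples
#' m <- simulate_match(morra_agent("a1"), morra_agent("b1"),
#'                     target_score = 3, seed = 1)
#' m$scores
simulate_match <- function(side_a, side_b, target_score = NULL, seed = NULL,
                           on_invalid = c("resample", "abort"),
                           max_rounds = 100000L) {
  on_invalid <- match.arg(on_invalid)
  as_side <- function(x, nm) {
    if (inherits(x, "morra_agent")) x <- list(x)
    if (!is.list(x) || !all(vapply(x, inherits, logical(1), "morra_agent")) ||
        !(length(x) %in% 1:2)) {
      stop_input(sprintf("`%s` must be a morra_agent or a list of two.", nm))
    }
    x
  }
  side_a <- as_side(side_a, "side_a")
  side_b <- as_side(side_b, "side_b")
  team_mode <- length(side_a) == 2 || length(side_b) == 2
  if (is.null(target_score)) target_score <- if (team_mode) 16L else 10L
  target_score <- check_count(target_score, "target_score")

  with_seed_if(seed, {
    ids <- c(vapply(side_a, `[[`, "", "id"), vapply(side_b, `[[`, "", "id"))
    if (anyDuplicated(ids)) stop_input("Agent ids must be unique.")
    prev <- setNames(rep(NA_integer_, length(ids)), ids)
    active <- c(A = 1L, B = 1L)
    scores <- c(A = 0L, B = 0L)
    n_invalid <- 0L
    rows <- vector("list", 256L)
    r <- 0L

    draw_play <- function(agent) {
      for (try in 1:100) {
        p <- agent$play(prev[[agent$id]])
        v <- validate_play(p[[1]], p[[2]])
        if (v$valid) return(c(v$hand, v$call))
        n_invalid <<- n_invalid + 1L
        if (on_invalid == "abort") {
          stop_input(sprintf("Agent %s emitted an invalid play (%s).",
                             agent$id, v$reason))
        }
      }
      stop_input(sprintf("Agent %s failed to produce a valid play in 100 draws.",
                         agent$id))
    }

    while (max(scores) < target_score && r < max_rounds) {
      r <- r + 1L
      ag_a <- side_a[[active[["A"]]]]
      ag_b <- side_b[[active[["B"]]]]
      pa <- draw_play(ag_a)
      pb <- draw_play(ag_b)
      prev[[ag_a$id]] <- pa[1]
      prev[[ag_b$id]] <- pb[1]
      adj <- adjudicate_round(pa[1], pa[2], pb[1], pb[2])
      if (adj$winner != "none") {
        scores[[adj$winner]] <- scores[[adj$winner]] + 1L
        loser <- setdiff(c("A", "B"), adj$winner)
        side <- if (loser == "A") side_a else side_b
        if (length(side) == 2) active[[loser]] <- 3L - active[[loser]]
      }
      if (r > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[r]] <- tibble(
        round = r, player_a = ag_a$id, player_b = ag_b$id,
        hand_a = pa[1], call_a = pa[2], hand_b = pb[1], call_b = pb[2],
        sum = adj$sum, winner = adj$winner
      )
    }
    if (max(scores) < target_score) {
      warn(sprintf("Match stopped at max_rounds = %d before reaching target.",
                   max_rounds))
    }
    structure(
      list(rounds = dplyr::bind_rows(rows[seq_len(r)]), scores = scores,
           target_score = target_score, team_mode = team_mode,
           n_invalid = n_invalid),
      class = "morra_match"
    )
  })
}

#' @export
print.morra_match <- function(x, ...) {
  cat(sprintf("Morra match (%s): %d rounds, score A %d - B %d (target %d)\n",
              if (x$team_mode) "team" else "singles", nrow(x$rounds),
              x$scores[["A"]], x$scores[["B"]], x$target_score))
  if (x$n_invalid > 0) cat(sprintf("  %d invalid plays resampled\n", x$n_invalid))
  invisible(x)
}

#' Extract per-player hand-number sequences from a match
#'
#' Returns the defensive channel of the game: the ordered hand numbers each
#' player showed, one row per response, skipping rounds in which the player
#' was benched. This is the long sequence format the preprocessing and index
#' functions consume.
#'
#' @param match A `morra_match` from [simulate_match()].
#' @return A tibble with columns `participant_id`, `position` (1-based,
#'   contiguous per player) and `value`.
#' @export
extract_hand_sequences <- function(match) {
  if (!inherits(match, "morra_match") || nrow(match$rounds) == 0) {
    stop_input("`match` must be a non-empty morra_match.")
  }
  r <- match$rounds
  long <- dplyr::bind_rows(
    tibble(participant_id = r$player_a, round = r$round, value = r$hand_a),
    tibble(participant_id = r$player_b, round = r$round, value = r$hand_b)
  )
  long <- dplyr::arrange(long, .data$participant_id, .data$round)
  long <- dplyr::mutate(dplyr::group_by(long, .data$participant_id),
                        position = dplyr::row_number())
  dplyr::select(dplyr::ungroup(long), "participant_id", "position", "value")
}

#' Write and read a match record
#'
#' `write_match()` writes the round table as delimited text plus a JSON
#' sidecar (`<path>.json`) holding scores, target and mode; `read_match()`
#' reconstructs the `morra_match` losslessly.
#'
#' @param match A `morra_match`.
#' @param path Output CSV path.
#' @return `write_match()` returns `path` invisibly; `read_match()` a
#'   `morra_match`.
#' @export
write_match <- function(match, path) {
  if (!inherits(match, "morra_match")) stop_input("`match` must be a morra_match.")
  readr::write_csv(match$rounds, path)
  meta <- list(scores = as.list(match$scores), target_score = match$target_score,
               team_mode = match$team_mode, n_invalid = match$n_invalid)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_match
#' @export
read_match <- function(path) {
  rounds <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              round = "i", player_a = "c", player_b = "c",
                              hand_a = "i", call_a = "i", hand_b = "i",
                              call_b = "i", sum = "i", winner = "c"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(
    list(rounds = as_tibble(rounds),
         scores = c(A = as.integer(meta$scores$A), B = as.integer(meta$scores$B)),
         target_score = as.integer(meta$target_score),
         team_mode = isTRUE(meta$team_mode),
         n_invalid = as.integer(meta$n_invalid)),
    class = "morra_match"
  )
}
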