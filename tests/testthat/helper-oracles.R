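# Independent brute-force oracles: deliberately written with naive counting
# loops, sharing no code with the package implementations.

naive_redundancy <- function(x, a = 5) {
  n <- length(x)
  h <- 0
  for (k in 1:a) {
    p <- sum(x == k) / n
    if (p > 0) h <- h - p * log2(p)
  }
  100 * (1 - h / log2(a))
}

naive_fpr <- function(x, a = 5) {
  num <- 0
  for (i in 1:a) for (j in 1:a) {
    cnt <- 0
    for (t in seq_len(length(x) - 1)) {
      if (x[t] == i && x[t + 1] == j) cnt <- cnt + 1
    }
    if (cnt > 1) num <- num + cnt * log2(cnt)
  }
  den <- 0
  for (i in 1:a) {
    cnt <- sum(x == i)
    if (cnt > 1) den <- den + cnt * log2(cnt)
  }
  if (den == 0) return(NA_real_)
  num / den
}

naive_nsq <- function(x, a = 5) {
  missing <- 0
  for (i in 1:a) for (j in 1:a) {
    found <- FALSE
    for (t in seq_len(length(x) - 1)) {
      if (x[t] == i && x[t + 1] == j) { found <- TRUE; break }
    }
    if (!found) missing <- missing + 1
  }
  100 * missing / (a^2 - 1)
}

naive_coupon <- function(x, a = 5) {
  lens <- c()
  pos <- 1
  while (pos <= length(x)) {
    need <- 1:a
    len <- 0
    complete <- FALSE
    for (t in pos:length(x)) {
      len <- len + 1
      need <- setdiff(need, x[t])
      if (length(need) == 0) { complete <- TRUE; break }
    }
    if (!complete) break
    lens <- c(lens, len)
    pos <- pos + len
  }
  if (length(lens) == 0) NA_real_ else mean(lens)
}

naive_repgap <- function(x, a = 5) {
  gaps <- c()
  for (k in 1:a) {
    pos <- which(x == k)
    if (length(pos) > 1) gaps <- c(gaps, diff(pos))
  }
  if (length(gaps) == 0) NA_real_ else mean(gaps)
}

# The printed payoff table, transcribed by its row structure: the row for
# play (h, c) marks the four cells of the opponent-hand block b = c - h,
# skipping the tie column where the opponent also calls c.
payoff_wins_fixture <- function() {
  labels <- paste(rep(1:5, each = 5), unlist(lapply(1:5, function(h) (h + 1):(h + 5))),
                  sep = ",")
  m <- matrix(FALSE, 25, 25, dimnames = list(B = labels, A = labels))
  for (h in 1:5) for (c_ in (h + 1):(h + 5)) {
    b <- c_ - h               # opponent hand block the row targets
    block_calls <- (b + 1):(b + 5)
    marked <- block_calls[block_calls != c_]
    row <- paste(h, c_, sep = ",")
    for (cc in marked) m[row, paste(b, cc, sep = ",")] <- TRUE
  }
  m
}

cycling57 <- function() rep(1:5, length.out = 57)

# long-format sequence tibble from a list of named integer vectors
make_long <- function(seqs, group = "expert", task = "morra") {
  dplyr::bind_rows(lapply(names(seqs), function(id) {
    tibble::tibble(participant_id = id, group = group, task = task,
                   position = seq_along(seqs[[id]]), value = seqs[[id]])
  }))
}

# Published per-sequence rankings (subjective and actual, most to least
# frequent), with their printed per-rank distances, totals and percentages.
published_ranking_rows <- function() {
  list(
    list(id = "seq1", subj = c(4, 3, 5, 2, 1), act = c(2, 1, 4, 3, 5),
         dist = c(2, 2, 2, 3, 3), total = 12, pct = 100, consistent = TRUE),
    list(id = "seq2", subj = c(2, 4, 3, 5, 1), act = c(3, 2, 1, 4, 5),
         dist = c(1, 2, 2, 1, 2), total = 8, pct = 67, consistent = TRUE),
    list(id = "seq3", subj = c(1, 5, 2, 3, 4), act = c(4, 1, 2, 5, 3),
         dist = c(4, 3, 0, 1, 4), total = 12, pct = 100, consistent = FALSE),
    list(id = "seq4", subj = c(3, 4, 2, 5, 1), act = c(1, 5, 3, 4, 2),
         dist = c(2, 2, 2, 2, 4), total = 12, pct = 100, consistent = TRUE),
    list(id = "seq5", subj = c(1, 4, 3, 2, 5), act = c(4, 1, 3, 2, 5),
         dist = c(1, 1, 0, 0, 0), total = 2, pct = 17, consistent = TRUE),
    list(id = "seq6", subj = c(4, 2, 1, 3, 5), act = c(5, 2, 4, 3, 1),
         dist = c(4, 0, 2, 0, 4), total = 10, pct = 83, consistent = FALSE),
    list(id = "seq7", subj = c(4, 3, 1, 5, 2), act = c(5, 2, 4, 3, 1),
         dist = c(2, 2, 2, 3, 3), total = 12, pct = 100, consistent = TRUE),
    list(id = "seq8", subj = c(3, 1, 5, 4, 2), act = c(2, 5, 4, 3, 1),
         dist = c(3, 3, 1, 1, 4), total = 12, pct = 100, consistent = TRUE),
    list(id = "seq9", subj = c(3, 4, 2, 5, 1), act = c(2, 1, 4, 5, 3),
         dist = c(4, 1, 2, 0, 3), total = 10, pct = 83, consistent = TRUE),
    list(id = "seq10", subj = c(4, 3, 2, 1, 5), act = c(3, 2, 1, 4, 5),
         dist = c(3, 1, 1, 3, 0), total = 8, pct = 67, consistent = FALSE),
    list(id = "seq11", subj = c(2, 3, 1, 5, 4), act = c(1, 2, 3, 4, 5),
         dist = c(1, 1, 2, 1, 1), total = 6, pct = 50, consistent = TRUE)
  )
}
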