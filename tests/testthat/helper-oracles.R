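# Independent brute-force oracles. Each reimplements a contract from
# scratch, structured differently from the package code, so agreement is
# meaningful.

# -- mature-matching rule checker ------------------------------------------
# enumerate every end shift in -2..2 and apply the four counting rules
# literally; returns list(valid, n_mismatches) with n_mismatches the best
# over valid shifts
oracle_match <- function(tag, mature) {
  tc <- strsplit(tag, "")[[1]]
  mc <- strsplit(mature, "")[[1]]
  best <- Inf
  for (s5 in -2:2) {
    # lay the tag over the mature: tag position t sits at mature position
    # t + s5
    m_pos <- seq_along(tc) + s5
    s3 <- (length(tc) + s5) - length(mc)
    if (abs(s3) > 2) next
    inside <- m_pos >= 1 & m_pos <= length(mc)
    mism <- m_pos[inside][mc[m_pos[inside]] != tc[inside]]
    rule1 <- length(mism) <= 2
    rule2 <- sum(mism >= 1 & mism <= 9) <= 1
    rule3 <- sum(mism %in% 10:11) == 0
    rule4 <- sum(mism >= 12) <= 2
    if (rule1 && rule2 && rule3 && rule4) best <- min(best, length(mism))
  }
  list(valid = is.finite(best), n_mismatches = if (is.finite(best)) best else NA)
}

# -- exhaustive folding oracle ---------------------------------------------
# enumerate every non-crossing pair set with hairpin loops >= 3 nt, discard
# structures containing a helix shorter than two stacked pairs, score the
# rest, return the maximum weight (0 when no valid structure pairs)
oracle_fold_best <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  w <- function(i, j) {
    a <- ch[i]; b <- ch[j]
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(1)
    0
  }
  # all pair sets on positions i..j (lists of 2-col matrices)
  enum <- function(i, j) {
    if (j - i < 4) return(list(matrix(integer(0), ncol = 2)))
    out <- enum(i + 1, j)
    for (k in (i + 4):j) {
      if (w(i, k) == 0) next
      inner <- enum(i + 1, k - 1)
      outer <- if (k < j) enum(k + 1, j) else list(matrix(integer(0), ncol = 2))
      for (si in inner) for (so in outer)
        out[[length(out) + 1L]] <- rbind(c(i, k), si, so)
    }
    out
  }
  no_lonely <- function(ps) {
    if (nrow(ps) == 0) return(TRUE)
    key <- paste(ps[, 1], ps[, 2])
    all(paste(ps[, 1] + 1, ps[, 2] - 1) %in% key |
        paste(ps[, 1] - 1, ps[, 2] + 1) %in% key)
  }
  best <- 0
  for (ps in enum(1, n)) {
    if (!no_lonely(ps)) next
    sc <- if (nrow(ps) == 0) 0 else sum(mapply(w, ps[, 1], ps[, 2]))
    best <- max(best, sc)
  }
  best
}

# -- hairpin feature oracle -------------------------------------------------
# for a clean single stem-loop (as the generator plants): read the pairing
# table directly, taking the unit as the full paired region
oracle_features <- function(dot_bracket, mature_span) {
  ch <- strsplit(dot_bracket, "")[[1]]
  n <- length(ch)
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") {
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  partner <- integer(n)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  unit <- c(min(pairs), max(pairs))
  innermost <- pairs[which.min(pairs[, 2] - pairs[, 1]), ]
  loop <- c(innermost[1] + 1L, innermost[2] - 1L)
  arms <- c(unit[1]:innermost[1], innermost[2]:unit[2])
  mpos <- mature_span[1]:mature_span[2]
  stem_bp <- sum(pairs[, 1] %in% arms & pairs[, 2] %in% arms)
  mature_bp <- sum(pairs[, 1] %in% mpos | pairs[, 2] %in% mpos)
  pm <- 100 * sum(mpos %in% arms) / length(mpos)
  # biased bulges: unpaired runs in the mature whose flanking pairs have
  # adjacent partners
  unp <- mpos[partner[mpos] == 0]
  biased <- 0L
  if (length(unp) > 0) {
    for (run in split(unp, cumsum(c(1, diff(unp) != 1)))) {
      lo <- run[1] - 1L; hi <- run[length(run)] + 1L
      while (lo >= 1 && partner[lo] == 0) lo <- lo - 1L
      while (hi <= n && partner[hi] == 0) hi <- hi + 1L
      if (lo < 1 || hi > n) next
      if (abs(partner[lo] - partner[hi]) == 1L) biased <- biased + 1L
    }
  }
  list(stem_bp = stem_bp, mature_bp = mature_bp, pm = pm,
       loop_len = loop[2] - loop[1] + 1L,
       hairpin_len = unit[2] - unit[1] + 1L,
       biased_bulges_mature = biased)
}

# -- Benjamini-Hochberg oracle ---------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# -- degradome category oracle ---------------------------------------------
oracle_category <- function(counts, pos) {
  x <- counts[pos]
  if (x == 0) return(NA_integer_)
  if (x == 1) return(4L)
  nz <- sort(counts[counts > 0])
  M <- nz[length(nz)]
  med <- stats::median(nz)
  is_max <- x == M
  n_at_max <- sum(counts == M)
  if (is_max && n_at_max == 1) return(0L)
  if (is_max) return(1L)
  if (x > med) return(2L)
  3L
}

# random DNA string helpers for fixtures
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
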