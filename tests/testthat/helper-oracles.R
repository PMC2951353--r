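# Independent oracles used across the suite.  Each reimplements the
# quantity under test by a different route (exhaustive dynamic
# programming, run-length enumeration, label permutation) so the
# package's own code path is never checked against itself.

# Exhaustive Gotoh (affine-gap Needleman-Wunsch) global score.
# Convention: a gap of length L costs gap_open + L * gap_ext.
oracle_global_score <- function(a, b, match = 1, mismatch = -2,
                                gap_open = -6, gap_ext = -1) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- gap_open + i * gap_ext
  for (j in seq_len(m)) Y[1L, j + 1L] <- gap_open + j * gap_ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open + gap_ext,
                               X[i, j + 1L] + gap_ext,
                               Y[i, j + 1L] + gap_open + gap_ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open + gap_ext,
                               Y[i + 1L, j] + gap_ext,
                               X[i + 1L, j] + gap_open + gap_ext)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Brute-force PM/GC/Amb classification for co-linear substitution-only
# instances.  Donor strings are found by enumerating the maximal
# clone-donor agreement runs (equivalent to enumerating every donor
# substring of length >= L_min and testing it for an exact clone match
# covering the mutation).
oracle_classify <- function(parent, clone, donors, L_min = 10L) {
  pc <- strsplit(parent, "")[[1L]]
  cc <- strsplit(clone, "")[[1L]]
  dcs <- lapply(donors, function(d) strsplit(d, "")[[1L]])
  n <- length(pc)
  muts <- which(cc != pc)                      # 1-based positions
  # longest agreement run between clone and donor containing p
  run_len <- function(d, p) {
    eq <- cc == dcs[[d]]
    if (!eq[p]) return(0L)
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(starts <= p & ends >= p)
    r$lengths[k]
  }
  assigned <- rep(NA_character_, length(muts))
  names(assigned) <- as.character(muts)
  events <- list()
  for (p in muts) {
    if (!is.na(assigned[as.character(p)])) next
    q <- vapply(names(donors), function(d) run_len(d, p), integer(1))
    qual <- names(donors)[q >= L_min]
    if (length(qual) == 0L) {
      assigned[as.character(p)] <- "PM"
      events[[length(events) + 1L]] <- list(category = "PM", members = p)
      next
    }
    explained <- lapply(qual, function(d) {
      muts[is.na(assigned[as.character(muts)]) &
             vapply(muts, function(pp) dcs[[d]][pp] == cc[pp], logical(1))]
    })
    names(explained) <- qual
    ord <- order(-vapply(explained, length, integer(1)),
                 -q[qual], qual)
    best <- qual[ord[1L]]
    if (length(explained[[best]]) >= 2L) {
      for (pp in explained[[best]]) assigned[as.character(pp)] <- "GC"
      events[[length(events) + 1L]] <-
        list(category = "GC", members = explained[[best]], donor = best)
    } else {
      assigned[as.character(p)] <- "AMB"
      events[[length(events) + 1L]] <- list(category = "AMB", members = p,
                                            donor = best)
    }
  }
  list(per_mutation = assigned, events = events)
}

# Exhaustive label-permutation Mann-Whitney: U for sample a and the
# two-sided p as twice the smaller exact tail, capped at 1.
oracle_mann_whitney <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  rk <- rank(pool)
  u_of <- function(sel) sum(rk[sel]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  sels <- utils::combn(length(pool), na)
  us <- apply(sels, 2L, u_of)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# Random substitution-only classification instance with known structure:
# donors diverge from the parent, the clone copies some donor positions
# and picks up some random substitutions.
random_instance <- function(n = 150L, n_donors = 3L, divergence = 0.04) {
  bases <- c("A", "C", "G", "T")
  pc <- sample(bases, n, replace = TRUE)
  donors <- list()
  for (i in seq_len(n_donors)) {
    dc <- pc
    at <- sample.int(n, max(1L, round(divergence * n)))
    for (p in at) dc[p] <- sample(setdiff(bases, pc[p]), 1L)
    donors[[sprintf("d%02d", i)]] <- dc
  }
  cc <- pc
  # a donor-copied block
  if (stats::runif(1) < 0.7) {
    di <- sample.int(n_donors, 1L)
    len <- sample(10:60, 1L)
    start <- sample.int(n - len + 1L, 1L)
    idx <- start:(start + len - 1L)
    cc[idx] <- donors[[di]][idx]
  }
  # scattered substitutions
  for (k in seq_len(sample(0:3, 1L))) {
    p <- sample.int(n, 1L)
    cc[p] <- sample(setdiff(bases, pc[p]), 1L)
  }
  list(parent = paste(pc, collapse = ""),
       clone = paste(cc, collapse = ""),
       donors = vapply(donors, paste, character(1), collapse = ""))
}
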