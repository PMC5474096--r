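# Independent Smith-Waterman oracle for ANI, coded from the DP recurrence
# with a linear gap penalty and an explicit traceback. Deliberately separate
# from the package's alignment path; row-vectorized so kilobase pairs stay
# tractable.

sw_oracle <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  n <- length(av)
  m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  jj <- seq_len(m)
  gj <- gap * jj
  for (i in seq_len(n)) {
    s <- ifelse(av[i] == bv, match, mismatch)
    cand <- pmax(0, H[i, jj] + s, H[i, jj + 1L] + gap)
    # resolve the in-row (left) dependency via a running-max identity
    H[i + 1L, jj + 1L] <- cummax(cand - gj) + gj
  }
  best <- which(H == max(H), arr.ind = TRUE)[1, ]
  i <- best[1] - 1L
  j <- best[2] - 1L
  ident <- 0L
  columns <- 0L
  used_a <- 0L
  used_b <- 0L
  acgt <- utf8ToInt("ACGT")
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0L) {
    h <- H[i + 1L, j + 1L]
    s <- if (av[i] == bv[j]) match else mismatch
    if (h == H[i, j] + s) {
      if (av[i] == bv[j] && av[i] %in% acgt) ident <- ident + 1L
      columns <- columns + 1L
      used_a <- used_a + 1L
      used_b <- used_b + 1L
      i <- i - 1L
      j <- j - 1L
    } else if (h == H[i, j + 1L] + gap) {
      columns <- columns + 1L
      used_a <- used_a + 1L
      i <- i - 1L
    } else {
      columns <- columns + 1L
      used_b <- used_b + 1L
      j <- j - 1L
    }
  }
  shorter <- min(n, m)
  list(
    ani = if (columns > 0) 100 * ident / columns else 0,
    aligned_fraction_shorter = (if (n <= m) used_a else used_b) / shorter
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# scatter n_sub substitutions at distinct positions, always to a different base
mutate_seq <- function(seq, n_sub) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), n_sub)
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}
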