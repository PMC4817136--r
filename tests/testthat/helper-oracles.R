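# Independent oracles used across the test files. These deliberately do not
# share code with the package internals they check.

# Affine-gap optimal alignment score by memoized recursion over
# (i, j, previous-op). A maximal gap run of length L costs open + extend * L,
# charged as (open + extend) on entry and extend per continuation.
oracle_align_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 5, gap_extend = 2) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (j <= m) {  # gap in a, consume b
      cost <- if (prev == "ga") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1, "ga"))
    }
    if (i <= n) {  # gap in b, consume a
      cost <- if (prev == "gb") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1, j, "gb"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "m")
}

# Full enumeration of every alignment (op strings over M/I/D), used only to
# validate oracle_align_score itself on tiny inputs.
oracle_align_enumerate <- function(a, b, match = 1, mismatch = -2,
                                   gap_open = 5, gap_extend = 2) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  walk <- function(i, j, score, prev) {
    if (i > n && j > m) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= n && j <= m)
      walk(i + 1, j + 1, score + if (av[i] == bv[j]) match else mismatch, "m")
    if (j <= m)
      walk(i, j + 1, score - if (prev == "ga") gap_extend else gap_open + gap_extend, "ga")
    if (i <= n)
      walk(i + 1, j, score - if (prev == "gb") gap_extend else gap_open + gap_extend, "gb")
  }
  walk(1, 1, 0, "m")
  best
}

# All-positions Hamming scan for primer binding, both strands.
oracle_binding_scan <- function(primer, sequence, max_mismatch = 2,
                                require_3prime_exact = TRUE) {
  n <- nchar(primer)
  L <- nchar(sequence)
  rc <- reverse_complement(primer)
  hits <- list()
  pb <- strsplit(primer, "")[[1L]]
  rb <- strsplit(rc, "")[[1L]]
  sb <- strsplit(sequence, "")[[1L]]
  for (s in 0:(L - n)) {
    win <- sb[(s + 1):(s + n)]
    mmf <- sum(win != pb)
    if (mmf <= max_mismatch &&
        (!require_3prime_exact || all(win[(n - 2):n] == pb[(n - 2):n])))
      hits[[length(hits) + 1L]] <- data.frame(pos = s, strand = "+", mismatches = mmf)
    mmr <- sum(win != rb)
    if (mmr <= max_mismatch &&
        (!require_3prime_exact || all(win[1:3] == rb[1:3])))
      hits[[length(hits) + 1L]] <- data.frame(pos = s + n - 1L, strand = "-", mismatches = mmr)
  }
  if (!length(hits))
    return(data.frame(pos = integer(0), strand = character(0), mismatches = integer(0)))
  out <- do.call(rbind, hits)
  out <- out[order(out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

# Nearest-neighbor Tm recomputed from the published unified parameter table,
# written as straight-line arithmetic.
oracle_tm_santalucia <- function(seq, salt_mM = 50, primer_uM = 0.25) {
  H <- list(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
            GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  S <- list(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
            GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  b <- strsplit(seq, "")[[1L]]
  n <- length(b)
  dh <- 0; ds <- 0
  for (i in 1:(n - 1)) {
    d <- paste0(b[i], b[i + 1])
    dh <- dh + H[[d]]
    ds <- ds + S[[d]]
  }
  for (term in b[c(1, n)]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(salt_mM / 1000)
  1000 * dh / (ds + 1.987 * log(primer_uM * 1e-6 / 4)) - 273.15
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
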