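# Independent oracles used across the suite. Each restates its model from
# scratch (frozen constants, different algorithmic formulation) so that
# agreement with the package implementation is informative.

# --- Benjamini-Hochberg: naive O(m^2) step-up -------------------------------
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (k in seq_len(m)) {
    suffix <- vapply(k:m, function(j) m * p[o[j]] / j, numeric(1))
    q[o[k]] <- min(1, suffix)
  }
  q
}

# --- cis relation: explicit case enumeration --------------------------------
# One interval pair at a time; written as a flat decision list over the
# mRNA-strand cases rather than the vectorized side arithmetic.
brute_relation <- function(l_chrom, l_start, l_end, l_strand,
                           m_chrom, m_start, m_end, m_strand,
                           up = 10000, down = 20000) {
  if (l_chrom != m_chrom) return(list(relation = "none", distance = NA_real_))
  if (l_start <= m_end && m_start <= l_end) {
    rel <- if (l_strand == m_strand) "overlap" else "anti-overlap"
    return(list(relation = rel, distance = 0))
  }
  if (l_end < m_start) {         # lncRNA on the left
    g <- m_start - l_end
    side <- if (m_strand == "+") "upstream" else "downstream"
  } else {                       # lncRNA on the right
    g <- l_start - m_end
    side <- if (m_strand == "+") "downstream" else "upstream"
  }
  lim <- if (side == "upstream") up else down
  list(relation = if (g <= lim) side else "none", distance = as.numeric(g))
}

# --- duplex MFE: exhaustive chain enumeration -------------------------------
# Frozen energy constants restated here; structures are enumerated
# recursively (every antiparallel non-crossing pair chain under the loop
# caps), not solved by dynamic programming.
oracle_pair_strength <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("AU", "UA")) return(1.3)
  if (key %in% c("CG", "GC")) return(3.4)
  if (key %in% c("GU", "UG")) return(0.9)
  -1
}

oracle_loop_pen <- function(a, b) {
  if (a == 0 && b == 0) return(0)
  if (a == 0 || b == 0) {
    if (a + b > 3) return(NA_real_)
    return(3.0 + 0.5 * (a + b))
  }
  if (a + b > 4) return(NA_real_)
  2.5 + 0.5 * (a + b)
}

oracle_duplex <- function(s1, s2) {
  x <- strsplit(chartr("T", "U", toupper(s1)), "")[[1]]
  y <- strsplit(chartr("T", "U", toupper(s2)), "")[[1]]
  n1 <- length(x)
  n2 <- length(y)
  best <- 0
  recurse <- function(i, j, e) {
    best <<- min(best, e)
    for (a in 0:3) {
      for (b in 0:3) {
        if (a > 0 && b > 0 && a + b > 4) next
        ni <- i + 1 + a
        nj <- j - 1 - b
        if (ni > n1 || nj < 1) next
        sp <- oracle_pair_strength(x[ni], y[nj])
        if (sp < 0) next
        if (a == 0 && b == 0) {
          step <- -(oracle_pair_strength(x[i], y[j]) + sp) / 2
        } else {
          step <- oracle_loop_pen(a, b)
          if (is.na(step)) next
        }
        recurse(ni, nj, e + step)
      }
    }
  }
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      if (oracle_pair_strength(x[i], y[j]) >= 0) recurse(i, j, 0)
    }
  }
  best
}

# --- alignment score: closed-form predecessor recursion ---------------------
# h(i, k) = best score of a local alignment whose last column matches miRNA
# position i with reversed-window position k; gap runs between match columns
# are single-direction and costed in closed form. Constants restated.
oracle_align <- function(mirna, window) {
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  w <- rev(strsplit(chartr("T", "U", toupper(window)), "")[[1]])
  nm <- length(m)
  nw <- length(w)
  wgt <- ifelse(seq_len(nm) %in% 2:8, 4, 1)
  pair_sc <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("AU", "UA", "CG", "GC")) 5
    else if (key %in% c("GU", "UG")) 2
    else -3
  }
  h <- matrix(NA_real_, nm, nw)
  hv <- function(i, k) {
    if (i < 1 || k < 1) return(-Inf)
    if (!is.na(h[i, k])) return(h[i, k])
    sc <- wgt[i] * pair_sc(m[i], w[k])
    best_prev <- 0
    best_prev <- max(best_prev, hv(i - 1, k - 1))
    # gap run consuming miRNA rows (i-a)..(i-1): each row charged open/ext
    if (i >= 3) {
      for (a in seq_len(i - 2)) {
        rows <- (i - a):(i - 1)
        cost <- sum(wgt[rows] * c(-9, rep(-4, a - 1)))
        best_prev <- max(best_prev, hv(i - 1 - a, k - 1) + cost)
      }
    }
    # gap run consuming window positions, charged at the previous match row
    if (k >= 3 && i >= 2) {
      for (b in seq_len(k - 2)) {
        cost <- wgt[i - 1] * (-9 + (b - 1) * -4)
        best_prev <- max(best_prev, hv(i - 1, k - 1 - b) + cost)
      }
    }
    h[i, k] <<- sc + best_prev
    h[i, k]
  }
  best <- 0
  for (i in seq_len(nm)) for (k in seq_len(nw)) best <- max(best, hv(i, k))
  best
}

# --- Fickett TESTCODE: table-driven second implementation -------------------
fickett_oracle <- function(seq) {
  seq <- chartr("U", "T", toupper(seq))
  chars <- strsplit(seq, "")[[1]]
  tabs <- list(
    A = list(pos = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
             cont = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
             wp = 0.26, wc = 0.11),
    C = list(pos = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
             cont = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
             wp = 0.18, wc = 0.12),
    G = list(pos = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
             cont = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
             wp = 0.31, wc = 0.15),
    T = list(pos = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09),
             cont = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58),
             wp = 0.33, wc = 0.14)
  )
  pos_bin <- function(v) 11 - findInterval(v, c(1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9)) - 1
  cont_bin <- function(v) 11 - findInterval(v, c(0.17, 0.19, 0.21, 0.23, 0.25, 0.27, 0.29, 0.31, 0.33)) - 1
  total <- 0
  for (b in names(tabs)) {
    by_phase <- vapply(1:3, function(ph) {
      sum(chars[seq(ph, length(chars), by = 3)] == b)
    }, numeric(1))
    posv <- max(by_phase) / (min(by_phase) + 1)
    contv <- mean(chars == b)
    total <- total + tabs[[b]]$pos[pos_bin(posv)] * tabs[[b]]$wp +
      tabs[[b]]$cont[cont_bin(contv)] * tabs[[b]]$wc
  }
  total
}

# --- longest ORF: brute force over every start/stop position ---------------
longest_orf_oracle <- function(seq) {
  seq <- chartr("U", "T", toupper(seq))
  n <- nchar(seq)
  best <- c(start = 0, length = 0)
  for (s in seq_len(max(0, n - 5))) {
    if (substr(seq, s, s + 2) != "ATG") next
    e <- s + 3
    while (e + 2 <= n) {
      cod <- substr(seq, e, e + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- e + 2 - s + 1
        if (len > best["length"]) best <- c(start = s, length = len)
        break
      }
      e <- e + 3
    }
  }
  best
}

# --- small random-sequence helper -------------------------------------------
rand_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
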