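# Fixture builders and independent brute-force oracles used across the
# suite.  The oracles deliberately use naive string/loop implementations
# so they share no code path with the package internals they check.

# count matrix with a dominant consensus (97:1:1:1 per position)
consensus_counts <- function(s, name = s) {
  bases <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  L <- length(bases)
  m <- matrix(1, L, 4)
  m[cbind(seq_len(L), match(bases, c("A", "C", "G", "T")))] <- 97
  motif_matrix(m, name = name)
}

random_counts <- function(L, name = "rnd") {
  m <- matrix(stats::rexp(L * 4) + 0.05, L, 4)
  motif_matrix(m, name = name)
}

consensus_of_counts <- function(m) {
  paste(c("A", "C", "G", "T")[apply(m, 1L, which.max)], collapse = "")
}

anti_consensus_of_counts <- function(m) {
  paste(c("A", "C", "G", "T")[apply(m, 1L, which.min)], collapse = "")
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# --- naive window scoring (string-based, loop-based) ---------------------

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

oracle_window_score <- function(weights, window) {
  bases <- strsplit(window, "", fixed = TRUE)[[1L]]
  idx <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  total <- 0
  for (i in seq_along(idx)) total <- total + weights[i, idx[[i]]]
  total
}

# every defined window score of a PWM over both strands of a set
oracle_all_scores <- function(pwm, seqs) {
  out <- numeric(0)
  for (s in unclass(seqs)) {
    for (strand_seq in c(s, oracle_revcomp(s))) {
      n <- nchar(strand_seq) - pwm$length + 1L
      if (n < 1L) next
      for (off in seq_len(n)) {
        sc <- oracle_window_score(pwm$weights,
                                  substr(strand_seq, off,
                                         off + pwm$length - 1L))
        if (!is.na(sc)) out <- c(out, sc)
      }
    }
  }
  out
}

# survival-fraction table over a flat score list
oracle_err_table <- function(scores, err_ceiling = 0.02) {
  thr <- sort(unique(scores), decreasing = TRUE)
  err <- vapply(thr, function(t) sum(scores >= t) / length(scores),
                numeric(1))
  keep <- err <= err_ceiling
  list(threshold = thr[keep], err = err[keep])
}

# --- naive partial-area oracle -------------------------------------------

# explicit loop trapezoid over an exhaustively enumerated threshold list
oracle_pauprc <- function(pos, neg, errmax) {
  ts <- sort(unique(c(pos, neg)))
  ts <- ts[is.finite(ts) & ts < errmax]
  pts <- list()
  for (t in ts) {
    tp <- sum(pos <= t)
    fp <- sum(neg <= t)
    if (tp + fp == 0) next
    tpr <- tp / length(pos)
    fpr <- fp / length(neg)
    pts[[length(pts) + 1L]] <- c(rec = tpr, prec = tpr / (tpr + fpr))
  }
  if (length(pts) == 0L) return(0)
  area <- 0
  prev_rec <- 0
  prev_prec <- pts[[1L]][["prec"]]
  for (pt in pts) {
    area <- area +
      ((pt[["prec"]] + prev_prec) / 2 - 0.5) * (pt[["rec"]] - prev_rec) * 2
    prev_rec <- pt[["rec"]]
    prev_prec <- pt[["prec"]]
  }
  area
}

# random best-ERR profile with a controllable above-ceiling fraction
random_profile <- function(n, p_ceiling = 0.3, scale = 1e-3) {
  x <- stats::rexp(n, rate = 1 / scale)
  x[stats::runif(n) < p_ceiling] <- Inf
  x
}

# exhaustive-placement similarity oracle (loops over every offset and
# both orientations, explicit Pearson on each aligned column pair)
oracle_similarity <- function(a, b, min_overlap = NULL) {
  fa <- a$counts / rowSums(a$counts)
  fb <- b$counts / rowSums(b$counts)
  if (is.null(min_overlap)) min_overlap <- min(4L, nrow(fa), nrow(fb))
  rc <- function(f) f[nrow(f):1, 4:1, drop = FALSE]
  best <- -Inf
  for (fbb in list(fb, rc(fb))) {
    la <- nrow(fa)
    lb <- nrow(fbb)
    for (start_a in seq.int(-(lb - 1L), la - 1L)) {
      cors <- c()
      for (i in seq_len(la)) {
        j <- i - start_a
        if (j < 1L || j > lb) next
        u <- fa[i, ]
        v <- fbb[j, ]
        if (stats::sd(u) == 0 || stats::sd(v) == 0) {
          cors <- c(cors, if (max(abs(u - v)) < 1e-12) 1 else 0)
        } else {
          cors <- c(cors, stats::cor(u, v))
        }
      }
      if (length(cors) >= min_overlap) best <- max(best, mean(cors))
    }
  }
  best
}

# fixed tiny calibration fixture reused across calibration tests
tiny_universe <- function(seed = 42, n_prom = 6, prom_len = 400) {
  gen_background(n_prom, prom_len, 0.5, seed = seed, label = "promoter")
}

# strip class and annotation attributes, keep only the ERR values
pvals <- function(p) as.vector(unclass(p))
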