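# Shared fixtures and independent brute-force oracles.  The oracles never
# call the implementation paths they are used to check.

# quick single-chromosome panel: n amplicons, pools cycling over `pools`
toy_panel <- function(n, pools = 1L, gene = "G1", exons = NULL) {
  start <- seq(1000L, by = 200L, length.out = n)
  if (is.null(exons)) exons <- paste0(gene, "_ex", seq_len(n))
  as_amplicon_panel(data.frame(
    chrom = "chr1", start = start, end = start + 120L,
    amplicon_id = sprintf("A%02d", seq_len(n)), gene = gene,
    exon_label = exons, pool = rep_len(pools, n)))
}

# counts matrix with dimnames
toy_counts <- function(values, sample_ids, panel) {
  matrix(as.integer(values), nrow = length(sample_ids), byrow = TRUE,
         dimnames = list(sample_ids, panel$amplicon_id))
}

# exhaustive Viterbi: score every one of K^n state paths directly
brute_viterbi <- function(dq, states = c(1L, 2L, 3L), sigma = 0.2,
                          switch_prob = 1e-3, epsilon = 1e-3) {
  K <- length(states)
  n <- length(dq)
  x <- log2(pmax(dq, epsilon))
  em <- sapply(seq_len(K), function(k)
    dnorm(x, log2(states[k] / 2), sigma, log = TRUE))
  em <- matrix(em, nrow = n)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  init <- rep(log(switch_prob / (K - 1)), K)
  init[states == 2L] <- log(1 - switch_prob)
  ll <- init[paths[, 1L]]
  for (i in seq_len(n)) ll <- ll + em[cbind(i, paths[, i])]
  if (n > 1L) {
    for (i in 2:n) {
      same <- paths[, i] == paths[, i - 1L]
      ll <- ll + ifelse(same, log(1 - switch_prob),
                        log(switch_prob / (K - 1)))
    }
  }
  states[paths[which.max(ll), ]]
}

# run enumeration by explicit index walking (no rle)
brute_runs <- function(dq, center, sd, soft_mult = 1, min_run = 3L) {
  n <- length(dq)
  center <- rep_len(center, n)
  sd <- rep_len(sd, n)
  state_of <- function(i, k) {
    if (dq[i] < center[i] - k * sd[i]) "del"
    else if (dq[i] > center[i] + k * sd[i]) "dup"
    else "n"
  }
  collect <- function(k, keep) {
    out <- NULL
    i <- 1L
    while (i <= n) {
      s <- state_of(i, k)
      if (s == "n") {
        i <- i + 1L
        next
      }
      j <- i
      while (j < n && state_of(j + 1L, k) == s) j <- j + 1L
      if (keep(i, j, s)) {
        out <- rbind(out, data.frame(first = i, last = j, type = s))
      }
      i <- j + 1L
    }
    out
  }
  hard <- collect(2, function(i, j, s) TRUE)
  soft <- collect(soft_mult, function(i, j, s) {
    if (j - i + 1L < min_run) return(FALSE)
    all_hard <- all(vapply(i:j, function(p) state_of(p, 2) == s,
                           logical(1L)))
    !all_hard
  })
  if (!is.null(hard)) hard$evidence <- rep("hard", nrow(hard))
  if (!is.null(soft)) soft$evidence <- rep("soft", nrow(soft))
  out <- rbind(hard, soft)
  if (is.null(out)) {
    return(data.frame(first = integer(), last = integer(),
                      type = character(), evidence = character()))
  }
  out <- out[order(out$first, out$evidence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# homology by testing every candidate length with full substring equality
brute_homology <- function(s, start, end, max_h = 500L) {
  best <- 0L
  for (h in seq_len(min(max_h, nchar(s) - end))) {
    if (start + h - 1L > nchar(s)) break
    if (substring(s, start, start + h - 1L) ==
        substring(s, end + 1L, end + h)) {
      best <- h
    }
  }
  best
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random sequence with an exact L-bp repeat planted at both junctions of
# the deletion [start, end]; the repeat stops at exactly L bases
plant_repeat <- function(L, seq_len = 200L) {
  repeat {
    s <- strsplit(rand_dna(seq_len), "")[[1L]]
    start <- sample(20:60, 1L)
    del_len <- sample((L + 2L):(L + 40L), 1L)
    end <- start + del_len - 1L
    if (end + L + 1L > seq_len) next
    if (L > 0L) s[(end + 1L):(end + L)] <- s[start:(start + L - 1L)]
    # force a mismatch one base past the planted repeat
    alt <- setdiff(c("A", "C", "G", "T"), s[start + L])
    s[end + 1L + L] <- alt[1L]
    return(list(seq = paste(s, collapse = ""), start = start, end = end))
  }
}
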