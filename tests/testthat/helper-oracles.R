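# Independent brute-force oracles. These deliberately share no code with the
# implementation: connected components by union-find, O(n^2) overlap checks,
# position-by-position PWM scoring, full rank-assignment enumeration and a
# from-scratch sort-and-average quantile normalizer.

# single-linkage summit merging as connected components of the graph with
# edges between same-chromosome summits <= max_dist apart (union-find)
oracle_merge_components <- function(summits, max_dist) {
  n <- nrow(summits)
  comp <- seq_len(n)
  if (n > 1) {
    repeat {
      changed <- FALSE
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          if (comp[i] != comp[j] &&
              summits$chrom[i] == summits$chrom[j] &&
              abs(summits$pos[i] - summits$pos[j]) <= max_dist) {
            old <- max(comp[i], comp[j])
            new <- min(comp[i], comp[j])
            comp[comp == old] <- new
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  match(comp, unique(comp))
}

# canonical partition signature: sorted list of sorted member index sets
partition_signature <- function(groups, keys) {
  sets <- split(keys, groups)
  sets <- lapply(sets, sort)
  paste(sort(vapply(sets, paste, character(1), collapse = ","), method = "radix"),
        collapse = ";")
}

oracle_overlaps <- function(a, b) {
  a$chrom == b$chrom && max(a$start, b$start) < min(a$end, b$end)
}

# brute-force PWM scan: score every offset on both strands directly from the
# probability matrix, including explicit reverse complementation of the
# sequence window for the minus strand
oracle_scan <- function(seq, prob_mat, threshold, palindromic) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(seq), "")[[1]]
  w <- ncol(prob_mat)
  hits <- list()
  score_window <- function(win) {
    s <- 0
    for (j in seq_len(w)) {
      if (win[j] != "N") s <- s + log(prob_mat[win[j], j] / 0.25)
    }
    s
  }
  if (length(chars) < w) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  }
  for (off in 0:(length(chars) - w)) {
    win <- chars[(off + 1):(off + w)]
    s_plus <- score_window(win)
    if (s_plus >= threshold - 1e-9) {
      hits[[length(hits) + 1]] <- data.frame(offset = off, strand = "+",
                                             score = s_plus)
    }
    if (!palindromic) {
      rc <- rev(unname(comp[win]))
      s_minus <- score_window(rc)
      if (s_minus >= threshold - 1e-9) {
        hits[[length(hits) + 1]] <- data.frame(offset = off, strand = "-",
                                               score = s_minus)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  }
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# exact two-sided Mann-Whitney p by enumerating every assignment of ranks
oracle_ranksum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(statistic = u_obs, p.value = min(1, 2 * min(p_le, p_ge)))
}

# sort-and-average quantile normalization (tie-free inputs)
oracle_quantile_norm <- function(mat, pseudo = 1) {
  mat <- mat + pseudo
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) out[, j] <- ref[rank(mat[, j])]
  out
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                             max_width = 120) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE)
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
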