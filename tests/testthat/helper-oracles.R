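# Independent brute-force oracles used to validate the optimized
# implementations on small instances.

# single-linkage transitive closure at threshold tol: connected components
# of the graph with an edge wherever |rt_i - rt_j| <= tol
oracle_single_linkage <- function(rt, tol) {
  n <- length(rt)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(rt[i] - rt[j]) <= tol && comp[j] != comp[i]) {
          comp[comp == comp[max(i, j)]] <- comp[min(i, j)]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp[order(rt)]))
}

# exhaustive search over all order-preserving matchings among candidate
# pairs; returns the maximum cardinality achievable
oracle_max_chain <- function(rt_a, rt_b) {
  m <- length(rt_a)
  best <- 0L
  recurse <- function(i, last_a, last_b, size) {
    if (size + (m - i + 1L) <= best) return()
    if (i > m) {
      best <<- max(best, size)
      return()
    }
    if (rt_a[i] > last_a && rt_b[i] > last_b) {
      recurse(i + 1L, rt_a[i], rt_b[i], size + 1L)
    }
    recurse(i + 1L, last_a, last_b, size)
  }
  o <- order(rt_a, rt_b)
  rt_a <- rt_a[o]; rt_b <- rt_b[o]
  recurse(1L, -Inf, -Inf, 0L)
  best
}

# weighted-cosine match factor evaluated directly from its definition for
# spectra whose m/z values align exactly (no pairing ambiguity)
oracle_match_score <- function(q, r, int_power = 0.5, mz_power = 1) {
  wq <- q[, 2]^int_power * q[, 1]^mz_power
  wr <- r[, 2]^int_power * r[, 1]^mz_power
  shared_q <- match(intersect(q[, 1], r[, 1]), q[, 1])
  shared_r <- match(intersect(q[, 1], r[, 1]), r[, 1])
  dot <- sum(wq[shared_q] * wr[shared_r])
  round(999 * dot / sqrt(sum(wq^2) * sum(wr^2)))
}

# random peak-table rows for one method, one peak per synthetic sample
random_peak_rows <- function(n, method_id = "m1", rt = NULL) {
  if (is.null(rt)) rt <- round(runif(n, 1, 20), 3)
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    animal_id = sprintf("a%d", seq_len(n) %% 6 + 1),
    method_id = method_id,
    is_blank = FALSE,
    rt_min = rt,
    area = exp(rnorm(n, 13, 1)),
    spectrum = vapply(seq_len(n), function(i) {
      encode_spectrum(cbind(mz = sample(30:300, 5),
                            intensity = c(999, sample(10:800, 4))))
    }, ""),
    stringsAsFactors = FALSE
  )
}
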