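# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the code paths they check.

# hypergeometric upper/lower tail by direct binomial-coefficient summation
oracle_hyper_tail <- function(a, b, c, d, direction = "positive") {
  # augmented table margins
  N <- a + b + c + d + 2
  K <- a + c + 1          # label-positive column
  m <- a + b + 1          # lesioned row (draws)
  pmf <- function(k) {
    if (k < max(0, m - (N - K)) || k > min(m, K)) return(0)
    exp(lchoose(K, k) + lchoose(N - K, m - k) - lchoose(N, m))
  }
  if (direction == "positive")
    sum(vapply((a + 1):m, pmf, numeric(1)))
  else
    sum(vapply(0:a, pmf, numeric(1)))
}

# one-sided Fisher exact p (greater) on the unaugmented table
oracle_fisher_greater <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), 2, 2)
  stats::fisher.test(m, alternative = "greater")$p.value
}

# BFS flood fill component labeling
oracle_flood_fill <- function(mask, connectivity = 26) {
  shape <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  man <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = man == 1, "18" = man >= 1 & man <= 2,
                    "26" = man >= 1), , drop = FALSE]
  lab <- array(0L, dim = shape)
  nxt <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      cur0 <- cur - 1L
      ci <- cur0 %% shape[1]
      cj <- (cur0 %/% shape[1]) %% shape[2]
      ck <- cur0 %/% (shape[1] * shape[2])
      for (r in seq_len(nrow(off))) {
        ni <- ci + off[r, 1]; nj <- cj + off[r, 2]; nk <- ck + off[r, 3]
        if (ni < 0 || ni >= shape[1] || nj < 0 || nj >= shape[2] ||
            nk < 0 || nk >= shape[3]) next
        lin <- 1L + ni + shape[1] * (nj + shape[2] * nk)
        if (mask[lin] != 0 && lab[lin] == 0L) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# explicit step-by-step ssGSEA running sum for one sample
oracle_ssgsea_one <- function(x, in_set, alpha) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  cum_in <- 0; cum_out <- 0; es <- 0
  tot_in <- sum((r[ord]^alpha)[in_set[ord]])
  n_out <- sum(!in_set)
  for (i in seq_len(n)) {
    g <- ord[i]
    if (in_set[g]) cum_in <- cum_in + r[g]^alpha else cum_out <- cum_out + 1
    es <- es + (cum_in / tot_in - cum_out / n_out)
  }
  es
}

# hand product-limit estimator
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    n_i <- sum(time >= tt[i])
    d_i <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    out[i] <- s
  }
  data.frame(time = tt, surv = out)
}

# hand two-group log-rank chi-square from the event-time table
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in tt) {
    n_i <- sum(time >= t); n1 <- sum(time >= t & g)
    d_i <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    e1 <- d_i * n1 / n_i
    o_minus_e <- o_minus_e + d1 - e1
    if (n_i > 1)
      v <- v + d_i * (n1 / n_i) * (1 - n1 / n_i) * (n_i - d_i) / (n_i - 1)
  }
  (o_minus_e)^2 / v
}

# small random binary cohort on a given grid (every mask non-empty)
random_cohort <- function(n, shape = c(8, 8, 8), seed = 1, p = 0.1) {
  set.seed(seed)
  grid <- vlsmap::volume_grid(shape)
  masks <- lapply(seq_len(n), function(i) {
    v <- array(stats::rbinom(prod(shape), 1, p), dim = shape)
    v[sample(prod(shape), 1)] <- 1L  # guarantee non-empty
    vlsmap::lesion_mask(v, grid, sprintf("S%02d", i))
  })
  vlsmap::lesion_cohort(masks)
}

# every 2x2 table with total n <= nmax
all_tables <- function(nmax) {
  out <- list()
  for (n in 1:nmax) for (a in 0:n) for (b in 0:(n - a))
    for (cc in 0:(n - a - b)) {
      out[[length(out) + 1L]] <- c(a, b, cc, n - a - b - cc)
    }
  do.call(rbind, out)
}
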