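# naive independent reimplementations used as oracles in several files

brute_amova_phi <- function(m, grouping) {
  N <- nrow(m)
  groups <- unique(grouping)
  ss_total <- 0
  for (i in seq_len(N - 1)) for (j in seq(i + 1, N)) ss_total <- ss_total + m[i, j]^2
  ss_total <- ss_total / N
  ss_within <- 0
  for (g in groups) {
    idx <- which(grouping == g)
    if (length(idx) < 2) next
    s <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b) s <- s + m[idx[a], idx[b]]^2
    }
    ss_within <- ss_within + s / length(idx)
  }
  ss_among <- ss_total - ss_within
  g <- length(groups)
  ms_among <- ss_among / (g - 1)
  ms_within <- ss_within / (N - g)
  n_g <- as.numeric(table(grouping)[groups])
  n0 <- (N - sum(n_g^2) / N) / (g - 1)
  s2a <- (ms_among - ms_within) / n0
  s2a / (s2a + ms_within)
}

brute_theta <- function(k, n, variant = "freeman-tukey") {
  switch(variant,
    "freeman-tukey" = pi / 2 - asin(sqrt(k / (n + 1))) - asin(sqrt((k + 1) / (n + 1))),
    "asin-mean" = (asin(1 - 2 * k / n) + asin(1 - 2 * (k + 1) / (n + 1))) / 2,
    "anscombe" = asin(1 - 2 * (k + 0.375) / (n + 0.75))
  )
}

brute_mmd <- function(kA, nA, kB, nB, variant = "freeman-tukey") {
  r <- length(kA)
  total <- 0
  for (i in seq_len(r)) {
    dt <- brute_theta(kA[i], nA[i], variant) - brute_theta(kB[i], nB[i], variant)
    total <- total + dt^2 - 1 / (nA[i] + 0.5) - 1 / (nB[i] + 0.5)
  }
  s2 <- 0
  for (i in seq_len(r)) s2 <- s2 + (1 / nA[i] + 1 / nB[i])^2
  list(mmd = total / r, sd = sqrt(2 * s2 / r^2))
}
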