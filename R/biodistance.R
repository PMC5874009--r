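#' Angular transformation of a trait frequency
#'
#' Variance-stabilizing arcsine transform of a presence count `k` out of
#' `n` scored individuals, used inside the Mean Measure of Divergence.
#' Three variants are available; all are strictly decreasing in `k` at
#' fixed `n`, range over (-pi/2, pi/2] and differ only in their
#' small-sample behaviour:
#'
#' * `"freeman-tukey"` (default): the Freeman-Tukey double arcsine,
#'   `theta = pi/2 - asin(sqrt(k/(n+1))) - asin(sqrt((k+1)/(n+1)))`.
#' * `"asin-mean"`: the mean of two single-arcsine terms,
#'   `theta = (asin(1-2k/n) + asin(1-2(k+1)/(n+1))) / 2`.
#' * `"anscombe"`: `theta = asin(1 - 2(k+3/8)/(n+3/4))`.
#'
#' The default is pinned by reproducing a published divergence matrix from
#' its published frequency table (see the package vignette); the
#' alternatives are retained because the literature uses all three under
#' the same "Freeman-Tukey correction" label.
#'
#' @param k presence count(s), `0 <= k <= n`; non-integer counts recovered
#'   from rounded percentages are accepted.
#' @param n number of individuals scored, `n >= 1`.
#' @param variant one of `"freeman-tukey"`, `"asin-mean"`, `"anscombe"`.
#' @return angle(s) in radians.
#' @examples
#' ft_theta(0, 10)
#' ft_theta(0:10, 10)  # strictly decreasing
#' @export
ft_theta <- function(k, n, variant = c("freeman-tukey", "asin-mean", "anscombe")) {
  variant <- match.arg(variant)
  stopifnot(all(k >= 0), all(k <= n), all(n >= 1))
  switch(variant,
    "freeman-tukey" = pi / 2 - asin(sqrt(k / (n + 1))) - asin(sqrt((k + 1) / (n + 1))),
    "asin-mean" = 0.5 * (asin(1 - 2 * k / n) + asin(1 - 2 * (k + 1) / (n + 1))),
    "anscombe" = asin(1 - 2 * (k + 3 / 8) / (n + 3 / 4))
  )
}

#' Recover presence counts from rounded percentages
#'
#' Published frequency tables usually print a percentage and a sample size
#' per trait; the underlying integer count is `round(percent * n / 100)`.
#' A warning is emitted when the recovered count does not reproduce the
#' printed percentage within `tol` (suggesting a transcription problem).
#'
#' @param percent percentage(s) in \[0, 100\].
#' @param n sample size(s), `n >= 1`.
#' @param tol round-trip tolerance on the percentage scale (default 0.05,
#'   half a unit in the last printed digit).
#' @return integer count(s) `k`.
#' @examples
#' counts_from_percentages(11.1, 18)  # 2
#' counts_from_percentages(85.7, 7)   # 6
#' @export
counts_from_percentages <- function(percent, n, tol = 0.05) {
  stopifnot(all(percent >= 0), all(percent <= 100), all(n >= 1))
  k <- floor(percent * n / 100 + 0.5)  # nearest integer, ties up
  err <- abs(100 * k / n - percent)
  if (any(err > tol)) {
    bad <- which(err > tol)
    warning("recovered count does not round-trip to the printed percentage for ",
            length(bad), " entr", if (length(bad) == 1) "y" else "ies",
            " (max deviation ", format(max(err), digits = 3), "%)")
  }
  as.integer(k)
}

#' Dichotomize ordinal trait scores
#'
#' Converts ASUDAS-style ordinal grades to present/absent using per-trait
#' breakpoints: a score is present iff its grade belongs to the trait's
#' breakpoint set.  One effective score per individual and trait is used,
#' preferring the left side and substituting the antimere (right side)
#' when the left is missing.  Missing grades stay missing.
#'
#' @param scores long data.frame with columns `individual_id`, `trait`,
#'   `side` (`"L"`/`"R"`) and `grade` (numeric, `NA` allowed).
#' @param defs data.frame with columns `trait` and `present_grades` (a
#'   list column of numeric grade vectors) or `breakpoint` (a string such
#'   as `"ASU 2-7"`, `"2+"` or `"1"` parsed to a grade set; `"+"`/`"Y"`
#'   style presence scores are taken as grade 1 on a 0/1 scale).
#' @param scale_max highest grade of the scale used to expand open-ended
#'   breakpoints like `"2+"` (default 9, the widest ASUDAS scale).
#' @return data.frame `individual_id`, `trait`, `present` (logical,
#'   `NA` = unobservable).
#' @examples
#' scores <- data.frame(individual_id = "A", trait = "Carabelli's trait UM1",
#'                      side = "L", grade = 3)
#' defs <- data.frame(trait = "Carabelli's trait UM1", breakpoint = "ASU 2-7")
#' dichotomize(scores, defs)
#' @export
dichotomize <- function(scores, defs, scale_max = 9) {
  stopifnot(all(c("individual_id", "trait", "grade") %in% names(scores)))
  if (!"side" %in% names(scores)) scores$side <- "L"
  if (is.null(defs$present_grades)) {
    if (is.null(defs$breakpoint)) stop("defs needs present_grades or breakpoint")
    defs$present_grades <- lapply(defs$breakpoint, parse_breakpoint, scale_max = scale_max)
  }
  undefined <- setdiff(unique(scores$trait), defs$trait)
  if (length(undefined)) {
    stop("no breakpoint definition for trait(s): ", paste(undefined, collapse = ", "))
  }
  # left side preferred; antimere substituted when the left grade is missing
  scores$side_pref <- ifelse(scores$side == "L", 0L, 1L)
  scores <- scores[order(scores$individual_id, scores$trait,
                         scores$side_pref, is.na(scores$grade)), ]
  eff <- scores[!duplicated(scores[c("individual_id", "trait")]), ]
  # a present non-missing antimere beats a missing left score
  has_na <- is.na(eff$grade)
  if (any(has_na)) {
    alt <- scores[!is.na(scores$grade), ]
    alt <- alt[!duplicated(alt[c("individual_id", "trait")]), ]
    key_eff <- paste(eff$individual_id, eff$trait)
    key_alt <- paste(alt$individual_id, alt$trait)
    idx <- match(key_eff[has_na], key_alt)
    eff$grade[has_na][!is.na(idx)] <- alt$grade[idx[!is.na(idx)]]
  }
  out <- lapply(seq_len(nrow(eff)), function(i) {
    g <- eff$grade[i]
    bp <- defs$present_grades[[match(eff$trait[i], defs$trait)]]
    if (!is.na(g) && (g < 0 || g > scale_max)) {
      stop("grade ", g, " outside the trait scale for individual ",
           sQuote(eff$individual_id[i]), ", trait ", sQuote(eff$trait[i]))
    }
    data.frame(individual_id = eff$individual_id[i], trait = eff$trait[i],
               present = if (is.na(g)) NA else g %in% bp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# "ASU 2-7" -> 2:7, "2+" -> 2:scale_max, "+"/"Y" -> 1, "ASU Y" -> 1
parse_breakpoint <- function(x, scale_max = 9) {
  x <- sub("^ASU\\s*", "", trimws(x))
  if (x %in% c("+", "Y")) return(1)
  m <- regmatches(x, regexec("^([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m)) return(seq(as.integer(m[2]), as.integer(m[3])))
  m <- regmatches(x, regexec("^([0-9]+)\\+$", x))[[1]]
  if (length(m)) return(seq(as.integer(m[2]), scale_max))
  if (grepl("^[0-9]+$", x)) return(as.integer(x))
  stop("cannot parse breakpoint ", sQuote(x))
}

#' Group trait frequencies from individual presence data
#'
#' @param presence data.frame as returned by [dichotomize()] (columns
#'   `individual_id`, `trait`, `present`).
#' @param groups named vector or data.frame (`individual_id`, `group`)
#'   assigning each individual to a group.
#' @return a `group_freq` data.frame (`group`, `trait`, `k`, `n`,
#'   `percent`).
#' @export
group_frequencies <- function(presence, groups) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$individual_id)
  }
  presence$group <- groups[presence$individual_id]
  if (any(is.na(presence$group))) {
    stop("no group for individual(s): ",
         paste(unique(presence$individual_id[is.na(presence$group)]), collapse = ", "))
  }
  obs <- presence[!is.na(presence$present), ]
  agg_n <- stats::aggregate(present ~ group + trait, obs, length)
  agg_k <- stats::aggregate(present ~ group + trait, obs, sum)
  out <- data.frame(group = agg_n$group, trait = agg_n$trait,
                    k = as.integer(agg_k$present), n = as.integer(agg_n$present),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$k / out$n
  class(out) <- c("group_freq", "data.frame")
  out
}

#' Screen traits for inter-trait association
#'
#' Computes the phi coefficient (the signed `sqrt(chi-square / N)` of the
#' 2x2 table) for every trait pair over pairwise-complete individuals and
#' iteratively removes the trait involved in the largest number of pairs
#' with `|r|` above the threshold (ties broken by fewer observations, then
#' column order) until no pair exceeds it.  Traits observed in fewer than
#' `min_n` individuals are excluded beforehand, since their frequencies
#' are too unstable to screen or to compare.
#'
#' @param presence individuals x traits matrix/data.frame of 0/1 with `NA`
#'   for unobservable scores.
#' @param r_threshold absolute phi above which a pair counts as highly
#'   correlated (default 0.5).
#' @param min_n minimum observations per trait (default 5).
#' @return list with `retained`, `removed` (with reasons), and the
#'   pairwise `r` matrix over the pre-screen traits.
#' @examples
#' set.seed(1)
#' m <- matrix(rbinom(200, 1, 0.4), 20, dimnames = list(NULL, paste0("t", 1:10)))
#' m <- cbind(m, dup = m[, 1])  # a perfectly correlated duplicate
#' correlation_screen(m)$removed
#' @export
correlation_screen <- function(presence, r_threshold = 0.5, min_n = 5) {
  m <- as.matrix(presence)
  storage.mode(m) <- "numeric"
  if (is.null(colnames(m))) colnames(m) <- paste0("trait", seq_len(ncol(m)))
  n_obs <- colSums(!is.na(m))
  removed <- data.frame(trait = character(), reason = character(),
                        stringsAsFactors = FALSE)
  low <- colnames(m)[n_obs < min_n]
  if (length(low)) {
    removed <- rbind(removed, data.frame(trait = low,
                                         reason = sprintf("fewer than %d observations", min_n)))
    m <- m[, n_obs >= min_n, drop = FALSE]
  }
  if (ncol(m) < 2) {
    return(list(retained = colnames(m), removed = removed, r = NULL))
  }
  p <- ncol(m)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      ok <- stats::complete.cases(m[, c(i, j)])
      if (sum(ok) < 2) next
      r[i, j] <- r[j, i] <- phi_coefficient(m[ok, i], m[ok, j])
    }
  }
  diag(r) <- 1
  off_all_na <- vapply(seq_len(p), function(i) all(is.na(r[i, -i])), TRUE)
  isolated <- colnames(m)[off_all_na]
  if (length(isolated)) {
    warning("trait(s) with no pairwise overlap retained unscreened: ",
            paste(isolated, collapse = ", "))
  }
  keep <- rep(TRUE, p)
  repeat {
    rr <- abs(r[keep, keep, drop = FALSE])
    diag(rr) <- 0
    over <- rr > r_threshold & !is.na(rr)
    if (!any(over)) break
    counts <- rowSums(over)
    worst <- which(counts == max(counts))
    if (length(worst) > 1) {
      obs <- n_obs[colnames(rr)[worst]]
      worst <- worst[obs == min(obs)]
    }
    victim <- colnames(rr)[worst[1]]
    removed <- rbind(removed, data.frame(
      trait = victim,
      reason = sprintf("|r| > %.2f with %d trait(s)", r_threshold,
                       max(rowSums(over)))
    ))
    keep[match(victim, colnames(m))] <- FALSE
  }
  list(retained = colnames(m)[keep], removed = removed, r = r)
}

# signed phi from two 0/1 vectors
phi_coefficient <- function(x, y) {
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  c <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  denom <- sqrt((a + b) * (c + d) * (a + c) * (b + d))
  if (denom == 0) return(NA_real_)
  (a * d - b * c) / denom
}

#' Mean Measure of Divergence between two groups
#'
#' The MMD between groups A and B over `r` traits is
#' \deqn{MMD = \frac{1}{r}\sum_i \left[(\theta_{Ai}-\theta_{Bi})^2 -
#'   \left(\frac{1}{n_{Ai}+0.5}+\frac{1}{n_{Bi}+0.5}\right)\right]}
#' with \eqn{\theta} the angular transform of [ft_theta()]; the subtracted
#' term removes the expected squared difference under identity, so MMD can
#' be negative for very similar groups.  Its standard deviation is
#' \deqn{SD = \sqrt{\frac{2}{r^2}\sum_i\left(\frac{1}{n_{Ai}}+
#'   \frac{1}{n_{Bi}}\right)^2}}
#' and a divergence is conventionally significant when `MMD > 2 SD`
#' (approximately p < 0.025).
#'
#' @param kA,nA presence counts and sample sizes of group A, one entry per
#'   trait.
#' @param kB,nB same for group B, aligned trait-wise.
#' @param variant angular transform variant, see [ft_theta()].
#' @return list with `mmd`, `sd`, `significant` and `r` (trait count).
#' @examples
#' mmd_pair(kA = c(2, 4), nA = c(10, 12), kB = c(7, 1), nB = c(15, 9))
#' @export
mmd_pair <- function(kA, nA, kB, nB, variant = "freeman-tukey") {
  r <- length(kA)
  stopifnot(r >= 1, length(nA) == r, length(kB) == r, length(nB) == r,
            all(nA >= 1), all(nB >= 1))
  dtheta <- ft_theta(kA, nA, variant) - ft_theta(kB, nB, variant)
  corr <- 1 / (nA + 0.5) + 1 / (nB + 0.5)
  mmd <- mean(dtheta^2 - corr)
  sdev <- sqrt(2 / r^2 * sum((1 / nA + 1 / nB)^2))
  list(mmd = mmd, sd = sdev, significant = mmd > 2 * sdev, r = r)
}

#' Pairwise MMD matrix across groups
#'
#' Applies [mmd_pair()] to every pair of groups over a common trait set.
#' The diagonal is reported as 0 by convention (self-divergence is
#' undefined); negative off-diagonal entries are genuine and are preserved
#' (clamping to zero happens only when the matrix is used as input to
#' ordination or clustering, see [classical_mds()] / [ward_dendrogram()]).
#'
#' @param freq a `group_freq` data.frame (columns `group`, `trait`, `k`,
#'   `n`; see [read_trait_frequencies()] or [group_frequencies()]).
#' @param traits traits to use; default: all traits flagged `in_mmd` if
#'   that column exists, otherwise all shared traits.  An error names any
#'   requested trait missing from a group.
#' @param variant angular transform variant, see [ft_theta()].
#' @return an object of class `mmd_matrix`: list with `mmd`, `sd` and
#'   `significant` matrices (group x group), `groups` and `traits`.
#' @examples
#' freq <- read_trait_frequencies(np_extdata("table4_frequencies.csv"))
#' mm <- mmd_matrix(freq)
#' round(mm$mmd["MVNL", "BRIT"], 3)
#' @export
mmd_matrix <- function(freq, traits = NULL, variant = "freeman-tukey") {
  freq <- as.data.frame(freq)
  if (is.null(traits)) {
    traits <- if ("in_mmd" %in% names(freq)) {
      unique(freq$trait[freq$in_mmd])
    } else {
      unique(freq$trait)
    }
  }
  groups <- unique(freq$group)
  if (length(groups) < 2) stop("need at least two groups")
  per_group <- lapply(groups, function(g) {
    d <- freq[freq$group == g, ]
    miss <- setdiff(traits, d$trait)
    if (length(miss)) {
      stop("group ", sQuote(g), " lacks trait(s): ", paste(miss, collapse = ", "))
    }
    d <- d[match(traits, d$trait), ]
    list(k = d$k, n = d$n)
  })
  names(per_group) <- groups
  ng <- length(groups)
  mmd <- sdm <- matrix(0, ng, ng, dimnames = list(groups, groups))
  sig <- matrix(FALSE, ng, ng, dimnames = list(groups, groups))
  for (i in seq_len(ng - 1)) {
    for (j in seq(i + 1, ng)) {
      p <- mmd_pair(per_group[[i]]$k, per_group[[i]]$n,
                    per_group[[j]]$k, per_group[[j]]$n, variant = variant)
      mmd[i, j] <- mmd[j, i] <- p$mmd
      sdm[i, j] <- sdm[j, i] <- p$sd
      sig[i, j] <- sig[j, i] <- p$significant
    }
  }
  structure(list(mmd = mmd, sd = sdm, significant = sig,
                 groups = groups, traits = traits, variant = variant),
            class = "mmd_matrix")
}

#' @export
print.mmd_matrix <- function(x, digits = 3, ...) {
  cat("MMD matrix over", length(x$groups), "groups,", length(x$traits),
      "traits (", x$variant, "transform )\n")
  m <- round(x$mmd, digits)
  m[upper.tri(m)] <- round(x$sd, digits)[upper.tri(x$sd)]
  cat("lower triangle: MMD; upper triangle: SD\n")
  print(m)
  invisible(x)
}

# negative dissimilarities are meaningless for ordination/clustering;
# clamp to zero without touching the reported matrix
clamp_dissimilarity <- function(d) {
  m <- as.matrix(d)
  m[m < 0] <- 0
  diag(m) <- 0
  m
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a symmetric dissimilarity matrix in `dims` dimensions by double
#' centering and eigendecomposition.  Negative input entries (possible for
#' MMD) are clamped to zero first.  If fewer than `dims` positive
#' eigenvalues exist the embedding is reduced with a warning.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param dims number of output dimensions (default 2).
#' @return list with `points` (n x dims coordinate matrix), `eig`
#'   (all eigenvalues) and `share` (proportion of the total positive
#'   eigenvalue mass captured per returned axis).
#' @examples
#' xy <- cbind(runif(5), runif(5))
#' mds <- classical_mds(as.matrix(dist(xy)))
#' @export
classical_mds <- function(d, dims = 2) {
  m <- clamp_dissimilarity(d)
  if (!isSymmetric(unname(m))) stop("dissimilarity matrix must be symmetric")
  fit <- stats::cmdscale(stats::as.dist(m), k = min(dims, nrow(m) - 1), eig = TRUE)
  pos <- sum(fit$eig > sqrt(.Machine$double.eps))
  if (pos < dims) {
    warning("only ", pos, " positive eigenvalue(s); returning ", pos, " axes")
    fit$points <- fit$points[, seq_len(max(pos, 1)), drop = FALSE]
  }
  share <- fit$eig[seq_len(ncol(fit$points))] / sum(fit$eig[fit$eig > 0])
  list(points = fit$points, eig = fit$eig, share = share)
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering under Ward's minimum-variance criterion
#' (`hclust` method `"ward.D2"`), after clamping negative entries to zero.
#'
#' @param d symmetric dissimilarity matrix (or `dist`) with labels.
#' @return an `hclust` tree.
#' @seealso [write_dendrogram()] to export as Newick.
#' @export
ward_dendrogram <- function(d) {
  m <- clamp_dissimilarity(d)
  if (nrow(m) < 2) stop("need at least two items to cluster")
  stats::hclust(stats::as.dist(m), method = "ward.D2")
}
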