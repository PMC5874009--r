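#' Pairwise Jaccard distances between binary presence profiles
#'
#' For two individuals with good sets X and Y the Jaccard distance is
#' `1 - |X intersect Y| / |X union Y|`.  Two individuals who both possess
#' nothing are assigned distance 0 by convention (an undefined 0/0 is read
#' as identity of the empty profiles).
#'
#' @param x an `artifact_matrix` or a binary individuals x goods matrix.
#' @return a symmetric distance matrix with zero diagonal and the
#'   individuals as dimnames.
#' @examples
#' m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0))
#' jaccard_matrix(m)  # d(a,b) = 2/3, d(a,c) = 0
#' @export
jaccard_matrix <- function(x) {
  m <- if (inherits(x, "artifact_matrix")) x$presence else as.matrix(x)
  if (nrow(m) < 2) stop("need at least two individuals")
  stopifnot(all(m %in% 0:1))
  storage.mode(m) <- "numeric"
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  union <- outer(sizes, sizes, `+`) - inter
  d <- 1 - inter / union
  d[union == 0] <- 0  # both profiles empty
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Farthest-neighbour agglomeration of a symmetric non-negative distance
#' matrix; merge heights are non-decreasing by construction.
#'
#' @param d symmetric non-negative distance matrix (or `dist`).
#' @return an `hclust` tree.
#' @export
complete_linkage <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 2) stop("need at least two items to cluster")
  if (any(m < 0)) stop("distances must be non-negative")
  stats::hclust(stats::as.dist(m), method = "complete")
}

#' Chi-square test of grave-good occurrence across groups
#'
#' Builds the goods x groups table of occurrence counts (each individual
#' contributes 1 to every good it possesses) and applies Pearson's
#' chi-square without continuity correction.  Goods never observed in any
#' retained individual are dropped with a warning before the degrees of
#' freedom are computed, so `df = (goods - 1) * (groups - 1)` refers to
#' the goods actually in the table.  Individuals with a missing group
#' label are excluded.
#'
#' @param x an `artifact_matrix` or binary matrix.
#' @param grouping group label per individual (`NA` = exclude); character
#'   or factor, or the name of a metadata column of `x` (`"sex"`,
#'   `"age_class"`, `"origin"`).
#' @return list with `statistic`, `df`, `p_value`, the occurrence `table`
#'   and `dropped` goods.
#' @examples
#' m <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0, 1))
#' colnames(m) <- c("sword", "mirror")
#' goods_by_group_chisq(m, c("m", "m", "f", "f"))
#' @export
goods_by_group_chisq <- function(x, grouping) {
  m <- if (inherits(x, "artifact_matrix")) x$presence else as.matrix(x)
  grouping <- resolve_grouping(x, grouping)
  keep <- !is.na(grouping)
  m <- m[keep, , drop = FALSE]
  grouping <- factor(grouping[keep])
  if (nlevels(grouping) < 2) stop("need at least two groups")
  tab <- t(rowsum(m, grouping))  # goods x groups occurrence counts
  zero <- rowSums(tab) == 0
  dropped <- rownames(tab)[zero]
  if (length(dropped)) {
    warning("good(s) with zero total occurrence dropped: ",
            paste(dropped, collapse = ", "))
    tab <- tab[!zero, , drop = FALSE]
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = tab, dropped = dropped)
}

# accept a vector, or the name of a metadata column of an artifact_matrix
resolve_grouping <- function(x, grouping) {
  if (length(grouping) == 1 && is.character(grouping) &&
      inherits(x, "artifact_matrix")) {
    col <- switch(grouping,
      origin = {
        oc <- x$meta$origin_code
        ifelse(oc == 1, NA, ifelse(oc == 0, "local", "nonlocal"))
      },
      sex = ifelse(x$meta$sex %in% c("unknown", NA), NA,
                   ifelse(x$meta$sex == "male", "male", "female")),
      age_class = ifelse(x$meta$age_class %in% c("unknown", NA), NA,
                         x$meta$age_class),
      stop("unknown grouping column ", sQuote(grouping))
    )
    return(col)
  }
  as.character(grouping)
}

#' Distance-matrix AMOVA with permutation test of Phi-ST
#'
#' One-level analysis of molecular variance computed directly on a
#' symmetric distance matrix (squared distances enter the sums of
#' squares): with N individuals in g groups,
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within` sums the analogous
#' within-group terms (`1/n_g` weighted), and `SS_among` is the
#' difference.  Variance components use the weighted average group size
#' `n0 = (N - sum n_g^2 / N) / (g - 1)`; `Phi_ST` is the among-group share
#' of the total variance and may be negative when groups are no more
#' different than random sets.  The p-value is the proportion of random
#' relabelings with `Phi >= observed`, with the +1 correction that counts
#' the observed partition itself.
#'
#' Individuals with missing group labels are excluded first; a group of
#' size 1 is allowed (it contributes nothing within) with a warning.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param grouping group label per individual (`NA` = exclude) or a
#'   metadata column name when paired with an `artifact_matrix` via
#'   [jaccard_matrix()] dimnames.
#' @param n_permutations number of random relabelings (default 9999).
#' @param seed integer seed recorded in the result; `NULL` leaves the RNG
#'   state alone.
#' @return an object of class `amova_result`.
#' @examples
#' d <- jaccard_matrix(rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0),
#'                           c = c(0, 0, 1, 1), e = c(0, 0, 1, 1)))
#' amova(d, c("g1", "g1", "g2", "g2"), n_permutations = 99, seed = 1)
#' @export
amova <- function(d, grouping, n_permutations = 9999, seed = NULL) {
  m <- as.matrix(d)
  stopifnot(nrow(m) == length(grouping))
  grouping <- as.character(grouping)
  keep <- !is.na(grouping)
  m <- m[keep, keep, drop = FALSE]
  grouping <- grouping[keep]
  g <- unique(grouping)
  if (length(g) < 2) stop("need at least two groups with labels")
  n_g <- table(grouping)
  if (any(n_g == 1)) {
    warning("group(s) of size 1 contribute no within-group variation: ",
            paste(names(n_g)[n_g == 1], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- amova_phi(m, grouping)
  ge <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    ge[b] <- amova_phi(m, sample(grouping))$phi_st
  }
  p <- (1 + sum(ge >= obs$phi_st)) / (1 + n_permutations)
  structure(c(obs, list(permutation_p = p, n_permutations = n_permutations,
                        seed = seed, n_excluded = sum(!keep))),
            class = "amova_result")
}

# sums of squares, variance components and Phi for one labeling
amova_phi <- function(m, grouping) {
  d2 <- m^2
  N <- nrow(m)
  groups <- unique(grouping)
  g <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (gr in groups) {
    idx <- which(grouping == gr)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_among <- ss_total - ss_within
  df_among <- g - 1
  df_within <- N - g
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n_g <- as.numeric(table(grouping)[groups])
  n0 <- (N - sum(n_g^2) / N) / df_among
  sigma2_within <- ms_within
  sigma2_among <- (ms_among - ms_within) / n0
  phi <- sigma2_among / (sigma2_among + sigma2_within)
  list(phi_st = phi, ss_among = ss_among, ss_within = ss_within,
       ss_total = ss_total, df_among = df_among, df_within = df_within,
       sigma2_among = sigma2_among, sigma2_within = sigma2_within, n0 = n0)
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA: Phi_ST = %.4f (p = %.4g, %d permutations)\n",
              x$phi_st, x$permutation_p, x$n_permutations))
  cat(sprintf("  among:  SS = %.4f, df = %d\n", x$ss_among, x$df_among))
  cat(sprintf("  within: SS = %.4f, df = %d\n", x$ss_within, x$df_within))
  invisible(x)
}

#' Correspondence analysis of a contingency table
#'
#' Singular value decomposition of the matrix of standardized Pearson
#' residuals: with `P` the table divided by its grand total, row masses
#' `r` and column masses `c`, the residual matrix
#' `S = Dr^-1/2 (P - r c') Dc^-1/2` factorizes as `U D V'`; row and
#' column principal coordinates are `Dr^-1/2 U D` and `Dc^-1/2 V D`, and
#' the per-axis inertia `D^2` partitions the total inertia `chi^2 / N`.
#' All-zero rows and columns are dropped with a warning.
#'
#' @param tab non-negative matrix or table with a positive grand total.
#' @param dims number of axes to return (default 2, reduced if rank is
#'   lower).
#' @return list with `row_coords`, `col_coords`, `inertia` (per retained
#'   axis), `share` (inertia shares over retained axes), `total_inertia`.
#' @examples
#' correspondence_analysis(rbind(c(10, 0), c(0, 10)))
#' @export
correspondence_analysis <- function(tab, dims = 2) {
  m <- as.matrix(tab)
  if (any(m < 0)) stop("table entries must be non-negative")
  zr <- rowSums(m) == 0
  zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " all-zero row(s) and ", sum(zc),
            " all-zero column(s)")
    m <- m[!zr, !zc, drop = FALSE]
  }
  N <- sum(m)
  if (N <= 0) stop("table grand total must be positive")
  P <- m / N
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  keep <- which(sv$d > sqrt(.Machine$double.eps))
  k <- min(dims, length(keep))
  if (k == 0) {
    return(list(row_coords = matrix(0, nrow(m), 0), col_coords = matrix(0, ncol(m), 0),
                inertia = numeric(0), share = numeric(0), total_inertia = 0))
  }
  idx <- seq_len(k)
  rowc <- diag(1 / sqrt(r)) %*% sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], k)
  colc <- diag(1 / sqrt(cc)) %*% sv$v[, idx, drop = FALSE] %*% diag(sv$d[idx], k)
  dimnames(rowc) <- list(rownames(m), paste0("Axis", idx))
  dimnames(colc) <- list(colnames(m), paste0("Axis", idx))
  inertia <- sv$d[idx]^2
  total <- sum(sv$d[keep]^2)
  list(row_coords = rowc, col_coords = colc, inertia = inertia,
       share = inertia / total, total_inertia = total)
}

#' Random-Forest variable importance for burial classification
#'
#' Grows a forest of classification trees on bootstrap samples of the
#' individuals, with a random subset of predictors considered at each
#' split (by default the square root of the number of predictors), and
#' reports the mean decrease in Gini impurity per variable, the
#' out-of-bag (OOB) error rate and the OOB confusion matrix.  Fully
#' reproducible for a fixed seed.
#'
#' @param features binary individuals x variables matrix.
#' @param labels class label per individual (factor or character;
#'   `NA` = exclude).  Every retained class needs at least two members,
#'   otherwise OOB estimation is undefined.
#' @param n_trees number of trees (default 500).
#' @param mtry predictors tried per split; default `floor(sqrt(p))`.
#' @param seed integer seed (default `NULL`: RNG state left alone).
#' @return list with `importance` (named, mean Gini decrease),
#'   `oob_error` (fraction), `confusion` (classes x classes, OOB),
#'   `params`.
#' @examples
#' cfg <- synthetic_config(seed = 7)
#' am <- generate_artifacts(generate_individuals(cfg), cfg)
#' rf <- random_forest_importance(am$presence, am$meta$sex, n_trees = 100,
#'                                seed = 7)
#' head(sort(rf$importance, decreasing = TRUE))
#' @export
random_forest_importance <- function(features, labels, n_trees = 500,
                                     mtry = NULL, seed = NULL) {
  m <- if (inherits(features, "artifact_matrix")) features$presence else as.matrix(features)
  labels <- as.character(labels)
  keep <- !is.na(labels)
  m <- m[keep, , drop = FALSE]
  y <- factor(labels[keep])
  if (nlevels(y) < 2) stop("need at least two classes")
  if (any(table(y) < 2)) {
    stop("class(es) with a single member (OOB error undefined): ",
         paste(names(table(y))[table(y) < 2], collapse = ", "))
  }
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(m))))
  if (!is.null(seed)) set.seed(seed)
  fit <- randomForest::randomForest(
    x = as.data.frame(m), y = y, ntree = n_trees, mtry = mtry,
    importance = FALSE, replace = TRUE
  )
  imp <- fit$importance[, "MeanDecreaseGini"]
  conf <- fit$confusion[, levels(y), drop = FALSE]
  oob <- 1 - sum(diag(conf)) / sum(conf)
  list(importance = imp, oob_error = oob, confusion = conf,
       params = list(n_trees = n_trees, mtry = mtry, seed = seed,
                     n_individuals = nrow(m)))
}

#' Stepwise collinearity filtering by variance inflation factor
#'
#' The VIF of a variable is `1 / (1 - R^2)` from regressing it on all
#' other retained variables; values above the threshold flag redundant
#' predictors.  Constant columns are removed first, perfect collinearity
#' yields an infinite VIF and is removed before anything else, and the
#' variable with the largest VIF is dropped repeatedly (ties broken by
#' column order) until all VIFs are at or below the threshold.
#'
#' @param features numeric individuals x variables matrix.
#' @param threshold VIF threshold (default 5).
#' @return list with `retained`, `removed` (in removal order, with the
#'   VIF that triggered removal) and `vif` (final VIFs of the retained
#'   variables).
#' @examples
#' x <- matrix(rbinom(60, 1, 0.5), 20)
#' colnames(x) <- c("a", "b", "c")
#' vif_stepwise(cbind(x, d = x[, 1]))$removed  # the duplicate goes
#' @export
vif_stepwise <- function(features, threshold = 5) {
  m <- as.matrix(features)
  storage.mode(m) <- "numeric"
  if (is.null(colnames(m))) colnames(m) <- paste0("v", seq_len(ncol(m)))
  if (ncol(m) < 2) stop("need at least two variables")
  removed <- data.frame(variable = character(), vif = numeric(),
                        stringsAsFactors = FALSE)
  constant <- apply(m, 2, function(z) stats::sd(z) == 0)
  if (any(constant)) {
    removed <- rbind(removed, data.frame(variable = colnames(m)[constant],
                                         vif = NA_real_))
    m <- m[, !constant, drop = FALSE]
  }
  vifs_of <- function(m) {
    vapply(seq_len(ncol(m)), function(j) {
      r2 <- summary(stats::lm(m[, j] ~ m[, -j, drop = FALSE]))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  while (ncol(m) >= 2) {
    v <- vifs_of(m)
    if (all(v <= threshold)) break
    worst <- which.max(v)  # ties and Inf: first by column order
    removed <- rbind(removed, data.frame(variable = colnames(m)[worst],
                                         vif = v[worst]))
    m <- m[, -worst, drop = FALSE]
  }
  final <- if (ncol(m) >= 2) vifs_of(m) else rep(1, ncol(m))
  list(retained = colnames(m), removed = removed,
       vif = stats::setNames(final, colnames(m)))
}
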