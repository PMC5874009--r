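#' Parse a compact tooth code
#'
#' Tooth codes combine side (`L`/`R`), tooth class (`I`, `C`, `P`, `M` or
#' `dm` for deciduous molars), position within the class, and the dental
#' arch as an explicit suffix: `"LM1-lower"` is the left lower first molar,
#' `"Rdm2-upper"` the right upper second deciduous molar.  Printed tables
#' often encode the arch typographically (subscript = lower, superscript =
#' upper, e.g. `"LM_1_"` or `"RM^2^"`); those spellings are normalized.
#' A code without an arch suffix is accepted with arch `NA`.
#'
#' @param tooth character vector of tooth codes.
#' @return a data.frame with columns `tooth` (normalized code), `side`,
#'   `arch`, `class`, `position` and `rank`, where `rank` is the crown
#'   mineralization rank used to order teeth within an individual
#'   (dm < M1 < P < M2 < M3; see [tooth_rank()]).
#' @seealso [tooth_rank()]
#' @examples
#' parse_tooth(c("LM1-lower", "RM^2^", "Ldm2-upper"))
#' @export
parse_tooth <- function(tooth) {
  raw <- as.character(tooth)
  # typographic arch conventions: _x_ subscript = lower, ^x^ superscript = upper
  norm <- raw
  norm <- sub("\\^([0-9])\\^$", "\\1-upper", norm)
  norm <- sub("_([0-9])_$", "\\1-lower", norm)
  m <- regmatches(norm, regexec("^([LR])(dm|di|dc|[ICPM])([0-9]?)(?:-(upper|lower))?$", norm))
  bad <- lengths(m) == 0 & !is.na(raw) & nzchar(raw)
  if (any(bad)) {
    stop("unparseable tooth code(s): ", paste(unique(raw[bad]), collapse = ", "))
  }
  get_part <- function(i) vapply(m, function(x) if (length(x)) x[i] else NA_character_, "")
  side <- get_part(2)
  class <- get_part(3)
  pos <- suppressWarnings(as.integer(get_part(4)))
  arch <- get_part(5)
  arch[!is.na(arch) & arch == ""] <- NA_character_
  out <- data.frame(
    tooth = norm, side = side, arch = arch, class = class, position = pos,
    stringsAsFactors = FALSE
  )
  out$rank <- tooth_rank_parts(out$class, out$position)
  out
}

# mineralization rank from class/position; NA for classes outside the
# dm < M1 < P < M2 < M3 chronology (incisors/canines are not sampled here)
tooth_rank_parts <- function(class, position) {
  rank <- rep(NA_real_, length(class))
  rank[class == "dm"] <- 1
  rank[class == "M" & position == 1] <- 2
  rank[class == "P"] <- 3
  rank[class == "M" & position == 2] <- 4
  rank[class == "M" & position == 3] <- 5
  rank
}

#' Crown mineralization rank of a tooth
#'
#' Deciduous molars mineralize in utero and in infancy, first permanent
#' molars in early childhood, premolars and second molars in later
#' childhood, third molars last.  The resulting order
#' dm < M1 < P < M2 < M3 decides which sampled tooth carries the earliest
#' residence signal of an individual (the basis of provenance calls) and
#' which the latest (the basis of mobility calls).  Side and arch do not
#' affect the rank.
#'
#' @param tooth character vector of tooth codes (see [parse_tooth()]).
#' @return numeric rank vector; lower rank mineralizes earlier.  `NA` for
#'   teeth outside the molar/premolar chronology.
#' @examples
#' tooth_rank(c("Ldm2-lower", "LM1-lower", "LP4-upper", "RM3-lower"))
#' @export
tooth_rank <- function(tooth) {
  parse_tooth(tooth)$rank
}

#' Read a strontium isotope sample table
#'
#' The expected CSV schema has one measurement per row with columns
#' `individual_id`, `material` (`"enamel"` or `"bone"`), `tooth` (a code
#' understood by [parse_tooth()]; empty for bone), `ratio` (87Sr/86Sr) and
#' `two_se` (2 standard errors of the measurement).  Ratios are kept at
#' full printed precision.
#'
#' @param path path to a CSV file.
#' @return a data.frame of class `isotope_table` with the five schema
#'   columns plus the parsed `arch` and `rank` of each tooth.
#' @examples
#' iso <- read_isotope_table(np_extdata("table2_isotopes.csv"))
#' head(iso)
#' @export
read_isotope_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("individual_id", "material", "tooth", "ratio", "two_se")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("isotope table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- x[needed]
  if (nrow(x) == 0) {
    out <- data.frame(
      individual_id = character(), material = character(), tooth = character(),
      ratio = numeric(), two_se = numeric(), arch = character(), rank = numeric(),
      stringsAsFactors = FALSE
    )
    class(out) <- c("isotope_table", "data.frame")
    return(out)
  }
  ratio <- suppressWarnings(as.numeric(x$ratio))
  two_se <- suppressWarnings(as.numeric(x$two_se))
  bad <- which(is.na(ratio) | ratio <= 0.70 | ratio >= 0.72)
  if (length(bad)) {
    stop("malformed or out-of-range 87Sr/86Sr ratio in row(s) ",
         paste(bad, collapse = ", "), " (value ",
         paste(x$ratio[bad], collapse = ", "), ")")
  }
  bad <- which(is.na(two_se) | two_se <= 0)
  if (length(bad)) stop("non-positive 2SE in row(s) ", paste(bad, collapse = ", "))
  bad <- which(!x$material %in% c("enamel", "bone"))
  if (length(bad)) {
    stop("unknown material ", paste(sQuote(unique(x$material[bad])), collapse = ", "),
         " in row(s) ", paste(bad, collapse = ", "))
  }
  x$tooth[is.na(x$tooth)] <- ""
  if (any(x$material == "bone" & nzchar(x$tooth))) {
    stop("bone samples must not carry a tooth code (row(s) ",
         paste(which(x$material == "bone" & nzchar(x$tooth)), collapse = ", "), ")")
  }
  if (any(x$material == "enamel" & !nzchar(x$tooth))) {
    stop("enamel samples need a tooth code (row(s) ",
         paste(which(x$material == "enamel" & !nzchar(x$tooth)), collapse = ", "), ")")
  }
  parsed <- parse_tooth(ifelse(nzchar(x$tooth), x$tooth, NA_character_))
  key <- paste(x$individual_id, parsed$tooth, x$material)
  if (anyDuplicated(key)) {
    stop("duplicate (individual, tooth) measurement in row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  out <- data.frame(
    individual_id = x$individual_id, material = x$material,
    tooth = ifelse(is.na(parsed$tooth), "", parsed$tooth),
    ratio = ratio, two_se = two_se,
    arch = parsed$arch, rank = parsed$rank,
    stringsAsFactors = FALSE
  )
  class(out) <- c("isotope_table", "data.frame")
  out
}

#' Write a strontium isotope sample table
#'
#' Inverse of [read_isotope_table()]; ratios are written at full precision
#' so that a write/read cycle is lossless.
#'
#' @param x an `isotope_table` (or any data.frame with the schema columns).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_isotope_table <- function(x, path) {
  cols <- c("individual_id", "material", "tooth", "ratio", "two_se")
  y <- as.data.frame(x)[cols]
  y$ratio <- sprintf("%.6f", y$ratio)
  y$two_se <- sprintf("%.6f", y$two_se)
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary grave-good matrix with burial metadata
#'
#' The CSV schema has one individual per row: metadata columns
#' `individual_id`, `sex` (`male`, `female`, `probable_female`, `unknown`),
#' `age_class` (`infant`, `child`, `adolescent`, `young_adult`,
#' `middle_adult`, `old_adult`, `unknown`), `ritual` (`inhumation`,
#' `cremation`) and `origin_code` (0 = local, 1 = missing, 2 = non-local),
#' followed by one 0/1 column per grave-good type.  Column order of the
#' goods is preserved.
#'
#' @param path path to a CSV file.
#' @return an object of class `artifact_matrix`: a list with `presence`
#'   (integer matrix, individuals x goods, dimnames set), `meta`
#'   (data.frame of the metadata columns) and `goods` (character vector).
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' am <- generate_artifacts(generate_individuals(cfg), cfg)
#' tmp <- tempfile(fileext = ".csv")
#' write_artifact_matrix(am, tmp)
#' am2 <- read_artifact_matrix(tmp)
#' identical(am$presence, am2$presence)
#' @export
read_artifact_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("individual_id", "sex", "age_class", "ritual", "origin_code")
  missing_cols <- setdiff(meta_cols, names(x))
  if (length(missing_cols)) {
    stop("artifact matrix is missing metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  goods <- setdiff(names(x), meta_cols)
  if (!length(goods)) stop("artifact matrix has no grave-good columns")
  pres <- as.matrix(x[goods])
  bad <- which(!(pres %in% c(0, 1)) | is.na(pres), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop("non-binary presence value ", sQuote(pres[i, j]), " for individual ",
         sQuote(x$individual_id[i]), ", good ", sQuote(goods[j]))
  }
  storage.mode(pres) <- "integer"
  rownames(pres) <- x$individual_id
  if (anyDuplicated(x$individual_id)) {
    stop("duplicate individual_id: ",
         paste(unique(x$individual_id[duplicated(x$individual_id)]), collapse = ", "))
  }
  if (!all(x$origin_code %in% 0:2)) {
    stop("origin_code outside {0,1,2} for individual(s) ",
         paste(x$individual_id[!x$origin_code %in% 0:2], collapse = ", "))
  }
  artifact_matrix(pres, x[meta_cols])
}

#' Construct an artifact matrix object
#'
#' @param presence individuals x goods matrix of 0/1 with dimnames.
#' @param meta data.frame with columns `individual_id`, `sex`, `age_class`,
#'   `ritual`, `origin_code`, aligned with the rows of `presence`.
#' @return an `artifact_matrix` object.
#' @export
artifact_matrix <- function(presence, meta) {
  stopifnot(nrow(presence) == nrow(meta), all(presence %in% 0:1))
  structure(
    list(presence = presence, meta = as.data.frame(meta),
         goods = colnames(presence)),
    class = "artifact_matrix"
  )
}

#' @export
print.artifact_matrix <- function(x, ...) {
  cat("artifact_matrix:", nrow(x$presence), "individuals x",
      ncol(x$presence), "goods\n")
  cat("  sex:", paste(names(table(x$meta$sex)), table(x$meta$sex),
                      sep = "=", collapse = " "), "\n")
  cat("  origin_code:", paste(names(table(x$meta$origin_code)),
                              table(x$meta$origin_code),
                              sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Write a binary grave-good matrix
#'
#' Inverse of [read_artifact_matrix()].
#'
#' @param x an `artifact_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_artifact_matrix <- function(x, path) {
  stopifnot(inherits(x, "artifact_matrix"))
  out <- cbind(x$meta, as.data.frame(x$presence, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a group-level dental trait frequency table
#'
#' The CSV mirrors the layout of published trait-frequency tables: two rows
#' per trait (`measure` = `"percent"` and `"n"`), columns `trait`,
#' `breakpoint` (the ASUDAS grades counted as present), `in_mmd` (whether
#' the trait enters the divergence analysis) and one column per group.
#' Presence counts are recovered from the rounded percentages with
#' [counts_from_percentages()].
#'
#' @param path path to a CSV file.
#' @return a long data.frame of class `group_freq` with columns `group`,
#'   `trait`, `breakpoint`, `in_mmd`, `percent`, `n` and `k`.
#' @examples
#' freq <- read_trait_frequencies(np_extdata("table4_frequencies.csv"))
#' head(freq)
#' @export
read_trait_frequencies <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("trait", "breakpoint", "in_mmd", "measure")
  missing_cols <- setdiff(fixed, names(x))
  if (length(missing_cols)) {
    stop("frequency table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  groups <- setdiff(names(x), fixed)
  pc <- x[x$measure == "percent", ]
  nn <- x[x$measure == "n", ]
  if (!identical(pc$trait, nn$trait)) {
    stop("percent and n rows do not pair up by trait")
  }
  long <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      group = g, trait = pc$trait, breakpoint = pc$breakpoint,
      in_mmd = as.logical(pc$in_mmd),
      percent = as.numeric(pc[[g]]), n = as.integer(nn[[g]]),
      stringsAsFactors = FALSE
    )
  }))
  long$k <- 0L
  scored <- long$n >= 1
  long$k[scored] <- counts_from_percentages(long$percent[scored], long$n[scored])
  rownames(long) <- NULL
  class(long) <- c("group_freq", "data.frame")
  long
}

#' Export a hierarchical clustering as a Newick tree
#'
#' Converts an [stats::hclust] tree to Newick text with branch lengths
#' derived from the merge heights: each branch length is the difference
#' between the parent's and the child's merge height (leaves sit at height
#' 0), so a two-leaf tree merging at height *h* is written `(A:h,B:h);` and
#' the depth of any leaf equals the height of the root merge.
#'
#' @param tree an `hclust` object with unique leaf labels.
#' @param path output file path; with `NULL`, the Newick string is returned
#'   instead of written.
#' @return the Newick string, invisibly when written to a file.
#' @examples
#' hc <- hclust(dist(c(a = 1, b = 2, c = 5)), method = "complete")
#' cat(write_dendrogram(hc))
#' @export
write_dendrogram <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  labels <- tree$labels
  if (is.null(labels)) labels <- as.character(seq_along(tree$order))
  if (anyDuplicated(labels)) {
    stop("duplicate leaf labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(tree$height < 0)) stop("negative merge heights")
  node_text <- function(idx) {
    # idx < 0: leaf -idx; idx > 0: internal merge row idx
    if (idx < 0) {
      list(text = labels[-idx], height = 0)
    } else {
      l <- node_text(tree$merge[idx, 1])
      r <- node_text(tree$merge[idx, 2])
      h <- tree$height[idx]
      list(
        text = sprintf("(%s:%s,%s:%s)", l$text, format(h - l$height, digits = 12),
                       r$text, format(h - r$height, digits = 12)),
        height = h
      )
    }
  }
  newick <- paste0(node_text(nrow(tree$merge))$text, ";")
  if (is.null(path)) return(newick)
  writeLines(newick, path)
  invisible(newick)
}
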