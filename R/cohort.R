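#' Read a cohort scan table
#'
#' Reads and validates the per-scan cohort CSV. One row is one scan
#' (observation): a subject at a wave, with demographic and nuisance
#' covariates used downstream as model covariates.
#'
#' Required columns: `subject_id`, `group` (control/adhd), `wave` (1-3),
#' `age` (years), `sex` (male/female), `medicated` (logical), `fd_dwi` and
#' `fd_fmri` (mean frame-wise displacement, mm), `scanner`
#' (pre_upgrade/post_upgrade). Categorical fields are parsed
#' case-insensitively.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with one validated row per scan; `group`, `sex`
#'   and `scanner` are factors with fixed level order.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Validate a cohort data frame
#'
#' @param df Data frame with the columns documented in [read_cohort()].
#' @return The validated, type-normalized data frame.
#' @export
validate_cohort <- function(df) {
  required <- c("subject_id", "group", "wave", "age", "sex", "medicated",
                "fd_dwi", "fd_fmri", "scanner")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("missing column %s", paste(missing_cols, collapse = ", ")))

  parse_cat <- function(x, levels, col, aliases = NULL) {
    v <- tolower(trimws(as.character(x)))
    for (a in names(aliases)) v[v == a] <- aliases[[a]]
    bad <- which(!v %in% levels)
    if (length(bad))
      stop(sprintf("unparseable value '%s' in column %s, row %d",
                   x[bad[1]], col, bad[1]))
    factor(v, levels = levels)
  }
  parse_num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("unparseable value '%s' in column %s, row %d",
                   as.character(x)[bad[1]], col, bad[1]))
    v
  }
  parse_lgl <- function(x, col) {
    v <- tolower(trimws(as.character(x)))
    out <- rep(NA, length(v))
    out[v %in% c("true", "t", "1", "yes")] <- TRUE
    out[v %in% c("false", "f", "0", "no")] <- FALSE
    bad <- which(is.na(out))
    if (length(bad))
      stop(sprintf("unparseable value '%s' in column %s, row %d",
                   as.character(x)[bad[1]], col, bad[1]))
    out
  }

  out <- data.frame(
    subject_id = as.character(df$subject_id),
    group = parse_cat(df$group, c("control", "adhd"), "group"),
    wave = parse_num(df$wave, "wave"),
    age = parse_num(df$age, "age"),
    sex = parse_cat(df$sex, c("male", "female"), "sex",
                    aliases = c(m = "male", f = "female")),
    medicated = parse_lgl(df$medicated, "medicated"),
    fd_dwi = parse_num(df$fd_dwi, "fd_dwi"),
    fd_fmri = parse_num(df$fd_fmri, "fd_fmri"),
    scanner = parse_cat(df$scanner, c("pre_upgrade", "post_upgrade"),
                        "scanner"),
    stringsAsFactors = FALSE
  )
  if (any(out$wave != as.integer(out$wave)) ||
      any(out$wave < 1) || any(out$wave > 3))
    stop("wave must be an integer in 1..3")
  out$wave <- as.integer(out$wave)
  dup <- duplicated(out[c("subject_id", "wave")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate (subject %s, wave %d)",
                 out$subject_id[i], out$wave[i]))
  }
  if (any(out$fd_dwi < 0) || any(out$fd_fmri < 0))
    stop("frame-wise displacement values must be >= 0")
  if (any(out$age < 8 | out$age > 16))
    warning(sprintf("%d scan(s) with age outside [8, 16]",
                    sum(out$age < 8 | out$age > 16)))
  out
}

#' Motion quality-control filter
#'
#' Partitions scans by the head-motion exclusion rule: scans whose mean
#' functional frame-wise displacement is strictly greater than `fd_limit`
#' (default 0.5 mm) are excluded from analysis.
#'
#' @param records Validated cohort data frame (see [read_cohort()]).
#' @param fd_limit Exclusion threshold for `fd_fmri`, in mm.
#' @return A list with elements `kept` and `excluded` (the latter gains a
#'   `reason` column). Together they partition the input rows.
#' @export
qc_filter <- function(records, fd_limit = 0.5) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    excluded <- records
    excluded$reason <- character(0)
    return(list(kept = records, excluded = excluded))
  }
  drop <- records$fd_fmri > fd_limit
  excluded <- records[drop, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- sprintf("fd_fmri %.3f > %.3f mm",
                               excluded$fd_fmri, fd_limit)
  else excluded$reason <- character(0)
  list(kept = records[!drop, , drop = FALSE], excluded = excluded)
}

#' Read a region atlas table
#'
#' @param path CSV with columns `node_id`, `label`, `hemisphere` (L/R) and
#'   optionally `network`.
#' @param n Expected number of regions (`NULL` to skip the check).
#' @return Validated atlas data frame ordered by `node_id`.
#' @export
read_atlas <- function(path, n = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("node_id", "label", "hemisphere")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("missing column %s", paste(missing_cols, collapse = ", ")))
  df$node_id <- as.integer(df$node_id)
  df <- df[order(df$node_id), , drop = FALSE]
  if (anyDuplicated(df$node_id)) stop("duplicate node_id in atlas")
  if (!all(df$node_id == seq_len(nrow(df))))
    stop("atlas node_ids must be contiguous 1..n")
  if (!is.null(n) && nrow(df) != n)
    stop(sprintf("atlas has %d regions, expected %d", nrow(df), n))
  if (!all(toupper(df$hemisphere) %in% c("L", "R")))
    stop("hemisphere must be L or R")
  df$hemisphere <- toupper(df$hemisphere)
  if (is.null(df$network)) df$network <- NA_character_
  df
}
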