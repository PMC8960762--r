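#' Dive score from maximum dive depth
#'
#' Ranks a species' overall maximum dive depth on a 0-4 ordinal scale:
#' 0 non-diving (< 1 m), 1 shallow (1-10 m), 2 intermediate (10.1-30 m),
#' 3 deep (30.1-100 m), 4 very deep (> 100 m). Depths are rounded to one
#' decimal before binning, which makes the one-decimal bin labels a total
#' partition of the depth axis.
#'
#' @param max_depth numeric vector of maximum dive depths in metres,
#'   non-negative and finite.
#' @return Integer vector of scores in 0..4.
#' @export
dive_score <- function(max_depth) {
  d <- as.numeric(max_depth)
  if (any(!is.finite(d)))
    stop("dive depths must be finite", call. = FALSE)
  if (any(d < 0))
    stop("dive depths must be non-negative", call. = FALSE)
  d <- round(d, 1)
  ifelse(d < 1, 0L,
  ifelse(d <= 10, 1L,
  ifelse(d <= 30, 2L,
  ifelse(d <= 100, 3L, 4L))))
}

#' Validate and canonicalise ecological group labels
#'
#' The four recognised foraging groups are `terrestrial`, `surface-foraging`,
#' `plunge-diving` and `underwater-pursuit`. Spelling variants differing in
#' case, spaces or underscores are normalised to the canonical hyphenated
#' token; anything else is an error naming the offending rows.
#'
#' @param table data frame with a `group` column (and optionally
#'   `max_depth_m`, from which `dive_score` is filled in when absent).
#' @return The table with canonical `group` labels (and `dive_score` if
#'   derivable).
#' @export
validate_groups <- function(table) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) stop("empty table", call. = FALSE)
  if (!"group" %in% names(table))
    stop("table must contain a 'group' column", call. = FALSE)
  g <- tolower(trimws(as.character(table$group)))
  g <- gsub("[ _]+", "-", g)
  bad <- which(!g %in% .ear_groups)
  if (length(bad))
    stop("unknown ecological group label(s) in row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(table$group[bad]), collapse = ", "), call. = FALSE)
  table$group <- g
  if (!"dive_score" %in% names(table) && "max_depth_m" %in% names(table)) {
    ds <- rep(NA_integer_, nrow(table))
    has <- is.finite(table$max_depth_m)
    ds[has] <- dive_score(table$max_depth_m[has])
    # terrestrial species without depth data are non-divers by definition
    ds[!has & g == "terrestrial"] <- 0L
    table$dive_score <- ds
  }
  table
}

#' Read an ecology CSV
#'
#' Columns: `species`, `group`, optionally `max_depth_m`. Groups are
#' validated and dive scores derived from depth.
#'
#' @param path CSV file path.
#' @return Validated data frame with `dive_score`.
#' @export
read_ecology <- function(path) {
  validate_groups(read.csv(path, stringsAsFactors = FALSE))
}
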