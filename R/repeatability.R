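#' One-way intra-class correlation coefficient
#'
#' Measurement repeatability as ICC(1,1): from the one-way random-effects
#' ANOVA mean squares, `(MSB - MSW) / (MSB + (k0 - 1) MSW)`, where `k0` is
#' the standard replicate coefficient for unbalanced designs,
#' `k0 = (N - sum(n_i^2)/N) / (g - 1)`.
#'
#' @param values named list mapping specimen (group) -> numeric vector of
#'   repeated measurements, or a data frame with columns `specimen_id` and
#'   `value`.
#' @param trait optional trait name carried into the result.
#' @return Object of class `"icc_result"`: `trait`, `icc`, `n_groups`,
#'   `n_per_group`, `ms_between`, `ms_within`.
#' @export
icc_oneway <- function(values, trait = NA_character_) {
  if (is.data.frame(values)) {
    stopifnot(all(c("specimen_id", "value") %in% names(values)))
    values <- split(values$value, values$specimen_id)
  }
  stopifnot(is.list(values))
  ni <- lengths(values)
  g <- length(values)
  if (g < 2L) stop("need at least 2 specimen groups", call. = FALSE)
  if (!any(ni >= 2L))
    stop("all groups are singletons; within-group variance undefined",
         call. = FALSE)
  dat <- data.frame(value = unlist(values, use.names = FALSE),
                    grp = factor(rep(names(values), ni)))
  ms <- summary(aov(value ~ grp, data = dat))[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  N <- sum(ni)
  k0 <- (N - sum(ni^2) / N) / (g - 1)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  structure(list(trait = trait, icc = icc, n_groups = g,
                 n_per_group = as.integer(ni), ms_between = msb,
                 ms_within = msw),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1,1)%s = %.4f  (%d groups, N = %d)\n",
              if (is.na(x$trait)) "" else paste0(" [", x$trait, "]"),
              x$icc, x$n_groups, sum(x$n_per_group)))
  invisible(x)
}

#' Repeatability of each trait from a long-format table
#'
#' @param df data frame with columns `trait`, `specimen_id`, `value`
#'   (a `replicate` column is allowed and ignored).
#' @return Data frame: one row per trait with `icc`, `n_groups`, `n_total`.
#' @export
icc_by_trait <- function(df) {
  stopifnot(all(c("trait", "specimen_id", "value") %in% names(df)))
  out <- lapply(split(df, df$trait), function(d) {
    r <- icc_oneway(d[, c("specimen_id", "value")], trait = d$trait[1])
    data.frame(trait = r$trait, icc = r$icc, n_groups = r$n_groups,
               n_total = sum(r$n_per_group), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
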