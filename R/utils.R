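#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for reported integer percentages so
#' that e.g. 1.57% prints as 2%.  `base::round()` rounds half to even, which
#' would disagree with conventionally reported figures at exact halves.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Normalise a sample->group mapping into a two-column tibble with a
# `group` factor whose first level is "group1" (the disease-like group).
# Accepts a named character vector or a data frame with columns
# sample / group (extra columns such as subgroup are carried along).
as_group_tbl <- function(groups, group1 = NULL) {
  if (is.data.frame(groups)) {
    if (!all(c("sample", "group") %in% names(groups))) {
      abort("`groups` data frame must have columns `sample` and `group`.")
    }
    tbl <- as_tibble(groups)
  } else if (!is.null(names(groups))) {
    tbl <- tibble(sample = names(groups), group = unname(as.character(groups)))
  } else {
    abort("`groups` must be a data frame or a named vector.")
  }
  tbl$sample <- as.character(tbl$sample)
  lev <- unique(as.character(tbl$group))
  if (length(lev) != 2L) {
    abort(sprintf("`groups` must contain exactly two groups, found %d.",
                  length(lev)))
  }
  if (!is.null(group1)) {
    if (!group1 %in% lev) abort(sprintf("group1 = '%s' not found in groups.", group1))
    lev <- c(group1, setdiff(lev, group1))
  }
  tbl$group <- factor(as.character(tbl$group), levels = lev)
  if (anyDuplicated(tbl$sample)) abort("Duplicate sample ids in `groups`.")
  tbl
}

group_levels <- function(group_tbl) levels(group_tbl$group)

# stop unless all columns present
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
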