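# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Thin wrapper around [withr::with_seed()]; keeps the caller's RNG state
#' untouched so no function in the package mutates global randomness.
#' @noRd
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

stop2 <- function(...) stop(..., call. = FALSE)

# Validates a two-level young/old grouping vector aligned to sample ids.
check_groups <- function(groups) {
  if (!all(groups %in% c("young", "old"))) {
    stop2("group labels must be 'young' or 'old'; got: ",
          paste(unique(setdiff(groups, c("young", "old"))), collapse = ", "))
  }
  tab <- table(factor(groups, levels = c("young", "old")))
  if (any(tab < 2)) {
    stop2("each group needs >= 2 samples; got young=", tab[["young"]],
          ", old=", tab[["old"]])
  }
  invisible(factor(groups, levels = c("young", "old")))
}
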