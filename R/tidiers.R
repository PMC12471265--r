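#' Tidy a differential-expression table
#'
#' `de_table`s are already tibbles; `tidy()` strips the subclass and
#' `glance()` reduces the table to one row of headline counts.
#'
#' @param x A `de_table`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.de_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "de_table")
  attr(out, "design") <- NULL
  attr(out, "comparison") <- NULL
  out
}

#' @rdname tidy.de_table
#' @export
glance.de_table <- function(x, ...) {
  tibble::tibble(
    comparison = attr(x, "comparison") %||% NA_character_,
    n_features = nrow(x),
    n_de = sum(x$is_de),
    n_unstable = sum(x$flag == "unstable"),
    median_abs_log2fc = stats::median(abs(x$log2_fc))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
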