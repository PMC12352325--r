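#' Ordinal answer-format scales and their fuzzification
#'
#' The nine physical-activity items come in four answer formats: a 6-point
#' times-per-month scale (`monthly6`, items QB1-QB2), an 8-point days-per-week
#' scale (`weekly8`, QB3/QB5/QB7), a 6-point time-per-day scale (`daily6`,
#' QB4/QB6/QB8) and a 10-point sitting-time scale (`sitting10`, QB9). Each
#' ordinal point maps to a fixed triangular fuzzy number on \[0, 100\]; the
#' two 6-point scales share one mapping. The mapping ships as a plain-text
#' lookup table (`inst/extdata/tfn_scales.csv`) so alternative fuzzification
#' dictionaries can be swapped in for sensitivity analysis.
#'
#' Item codes are stored exactly as answered, with a consistent direction:
#' a higher code always means more physical activity (for sitting time the
#' codes already run from most to least sitting), so no reversal step exists
#' anywhere in the pipeline.
#'
#' @name scales
NULL

.scales_cache <- new.env(parent = emptyenv())

scale_table <- function() {
  if (is.null(.scales_cache$tab)) {
    path <- system.file("extdata", "tfn_scales.csv", package = "pasindex",
                        mustWork = TRUE)
    .scales_cache$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .scales_cache$tab
}

.scale_periods <- c(monthly6 = "times per month", weekly8 = "days per week",
                    daily6 = "time per day", sitting10 = "sitting time per day")

#' Retrieve a registered ordinal scale
#'
#' @param scale_id one of `"monthly6"`, `"weekly8"`, `"daily6"`, `"sitting10"`.
#' @return An object of class `"ordinal_scale"`: a list with `scale_id`,
#'   `n_points`, `period_label` and `mapping` (a `"tfn"` with one row per
#'   ordinal point).
#' @examples
#' get_scale("weekly8")$n_points  # 8
#' @export
get_scale <- function(scale_id) {
  if (!is.character(scale_id) || length(scale_id) != 1L ||
      !scale_id %in% names(.scale_periods))
    stop("unknown scale: ", paste(scale_id, collapse = ", "), call. = FALSE)
  tab <- scale_table()
  rows <- tab[tab$scale_id == scale_id, ]
  rows <- rows[order(rows$point), ]
  structure(list(scale_id = scale_id,
                 n_points = nrow(rows),
                 period_label = unname(.scale_periods[scale_id]),
                 mapping = tfn(rows$lower, rows$mode, rows$upper)),
            class = "ordinal_scale")
}

#' @export
print.ordinal_scale <- function(x, ...) {
  cat("<ordinal_scale> ", x$scale_id, ": ", x$n_points, " points (",
      x$period_label, ")\n", sep = "")
  print(x$mapping)
  invisible(x)
}

#' Convert an ordinal item code to its triangular fuzzy number
#'
#' @param scale_id scale identifier (see [get_scale()]).
#' @param point integer vector of ordinal codes, each in `1..n_points`.
#' @return A `"tfn"` with one row per code.
#' @examples
#' to_tfn("monthly6", 1)  # (0, 0, 30)
#' to_tfn("sitting10", 5) # (27.5, 40, 52.5)
#' @export
to_tfn <- function(scale_id, point) {
  sc <- get_scale(scale_id)
  point <- as.integer(point)
  if (anyNA(point) || any(point < 1L | point > sc$n_points))
    stop("point outside scale ", scale_id, " (1..", sc$n_points, ")",
         call. = FALSE)
  m <- unclass(sc$mapping)[point, , drop = FALSE]
  structure(m, class = c("tfn", "matrix"))
}

#' The nine physical-activity items and their answer scales
#'
#' @return A data.frame with columns `item_id`, `scale_id`, `label`, one row
#'   per item QB1..QB9.
#' @export
pasi_items <- function() {
  data.frame(
    item_id = paste0("QB", 1:9),
    scale_id = c("monthly6", "monthly6", "weekly8", "daily6", "weekly8",
                 "daily6", "weekly8", "daily6", "sitting10"),
    label = c("Sport activity - frequency",
              "Physical activity - frequency",
              "Vigorous physical activity - days last week",
              "Vigorous physical activity - how much time",
              "Moderate physical activity - days last week",
              "Moderate physical activity - how much time",
              "Walked at least 10 minutes - days last week",
              "Walked at least 10 minutes - how much time",
              "Time spent sitting - usual day"),
    stringsAsFactors = FALSE
  )
}
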